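# tcrclust

Birth–death models of T cell receptor (TCR) nano-clustering and
stochastic activation timing.

## The problem

Resting T cells display their antigen receptors partly as monomers and
partly as ligand-independent linear nano-clusters, and memory T cells
carry larger clusters than naive ones. This package implements, for
quantitative immunologists and modelers, the two linked models needed to
ask what that pre-clustering buys a T cell:

1. **Clustering.** Cluster size follows a birth–death chain with growth
   rate `q+` and shrinkage rate `q−`, whose stationary law is geometric,

   π_n = b^(n−1) (1 − b),  b = q+/q− < 1,

   so `b` is simultaneously the geometric decay factor, the fraction of
   multimeric clusters (1 − π₁ = b), and the trimer:dimer ratio. `b` is
   estimated from per-cell cluster-size histograms (immuno-gold EM
   counts) by variance-weighted least squares; the reference fits are
   b_naive = 0.32 and b_memory = 0.55, a 72% higher multimeric fraction
   in memory cells (0.55/0.32 = 1.72).

2. **Activation timing.** Bivalent pMHC ligands bind dimeric TCR
   clusters (rates k_on, k_off) and cross-link them (k₂, k₋₂); a
   cross-linked complex that persists for a dwell time τ yields one
   productive signaling event, and the cell responds once N events have
   accumulated. The package computes the **mean time to signal
   initiation (MTSI)** both by exact Gillespie simulation (C++ inner
   loop, per-complex dwell tracking) and analytically: the expected
   cross-link count C(t) = k₂ ∫ x₃ has a closed form, the MTSI solves
   C(T − τ) = N·exp(2k₋₂τ), and high/intermediate/low-concentration
   asymptotics make the phenotype comparison algebraic. In the
   low-concentration regime the lag (T − τ) scales as 1/(b·N_R), so at
   identical kinetics memory cells respond exactly 72% faster — and at
   saturating ligand the advantage vanishes (T = τ for both).

A dimer/trimer ODE system shows that mixed cluster sizes reduce to the
dimeric model up to a prefactor (1+2b)/(1+b) ∈ (1, 3/2), and a seeded
synthetic-data generator produces per-cell histograms at the
experimental scale (7 cells / 9190 particles naive, 5 cells / 3001
particles memory) for parameter-recovery studies.

## Worked example

```r
library(tcrclust)

# --- synthetic memory-cell histogram and fit -------------------------
h <- sample_cluster_histograms(histogram_scenario(0.55, 5, 3001, seed = 42))
h
#> cluster_histogram: 5 cells, 3001 particles, 1321 clusters, max size 15
fit_b(h)
#> fit_result: b_hat = 0.5666 (stderr 0.0187), chi2 = 1.656 on 8 dof, sizes 1..9 [cluster_count]

phenotype_ratio(0.32, 0.55)
#> [1] 1.71875

# --- stochastic vs analytic MTSI, agonist 4P at 1 nM -----------------
p <- kinetic_parameters("4P", rho = 1e-9, b = 0.32)   # 9600 dimers, ~3e5 ligands
crit <- response_criterion(n_events = 10, tau = 1)
simulate_mtsi(p, crit, n_realizations = 100, horizon = 1e4, seed = 7)
#> mtsi_result: mean T = 6.13 s (sd 1.012, se 0.1012) over 100 realizations (0 censored)
solve_mtsi(p, crit)
#> [1] 6.265463
```

The fitted `b_hat = 0.5666` recovers the generating value 0.55 within
its standard error; the simulated mean MTSI of 6.13 s agrees with the
analytic root 6.27 s within ~1.3 Monte Carlo standard errors, i.e. the
agonist triggers a naive cell in seconds at nanomolar ligand. Swapping
in the antagonist `"4N"` (k_off 500× larger) makes the required raw
event count N·exp(2k₋₂τ) ≈ 10⁷ and the simulation censors instead of
responding.

## Analysis workflow

Numbered scripts under `analysis/` reproduce the full study on synthetic
inputs, writing tables to `results/`:

| script | what it does |
|---|---|
| `01_cluster_fits.R` | generate naive/memory histograms at experimental scale, fit `b`, report the 1.72 ratio |
| `02_mtsi_simulation.R` | 100-realization MTSI panels (τ ∈ {1,4}, k₂ ∈ {10,40}·k_off) and the 4P < 4A ≪ 4N potency hierarchy |
| `03_mtsi_analytic.R` | C(t) tables, MTSI root vs asymptotic branches across a concentration ladder |
| `04_phenotype_comparison.R` | naive vs memory MTSI, simulated and analytic, up to the 72% low-concentration speed-up |

Run them in order from the repository root, e.g.
`Rscript analysis/01_cluster_fits.R`.

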