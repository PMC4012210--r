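# Shared fixtures: reference agonist parameter set and a small helper to
# build integer-count histograms whose per-cell frequencies are (nearly)
# exactly geometric.

params_4p <- function(rho = 1e-9, b = 0.32, ...) {
  kinetic_parameters("4P", rho = rho, b = b, ...)
}

geometric_histogram <- function(b, n_cells = 2, k_max = 20, scale = 1e9) {
  counts <- round(scale * b^(0:(k_max - 1)) * (1 - b))
  df <- do.call(rbind, lapply(seq_len(n_cells), function(i)
    data.frame(cell_id = paste0("c", i), cluster_size = seq_len(k_max),
               count = counts)))
  cluster_histogram(df[df$count > 0, ])
}

total_variation <- function(p, q) {
  n <- max(length(p), length(q))
  p <- c(p, rep(0, n - length(p)))
  q <- c(q, rep(0, n - length(q)))
  0.5 * sum(abs(p - q))
}

# Independent oracle: the expected cross-link count obtained by direct
# numerical integration of the singly-bound/cross-linked rate equations
# with the free-ligand pool held at its initial value, C(t) = k2 int x3.
quadrature_crosslink_count <- function(params, times) {
  kp <- params$k_plus; koff <- params$ligand$k_off
  k2 <- params$k2; km2 <- params$k_minus2
  NB <- params$n_dimers; L0 <- params$ligand_copies
  rhs <- function(t, y, p) {
    x1 <- NB - y[1] - y[2]
    list(c(4 * kp * x1 * L0 - koff * y[1] - k2 * y[1] + 2 * km2 * y[2],
           k2 * y[1] - 2 * km2 * y[2],
           k2 * y[1]))
  }
  sol <- deSolve::ode(c(x3 = 0, x5 = 0, C = 0), times = times, func = rhs,
                      parms = NULL, rtol = 1e-12, atol = 1e-12)
  sol[, "C"]
}
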