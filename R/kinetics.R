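#' Ligand binding kinetics
#'
#' @param name Label, e.g. `"4P"`.
#' @param k_on Association rate constant (M^-1 s^-1), `> 0`.
#' @param k_off Dissociation rate (s^-1), `> 0`.
#' @return Object of class `ligand_kinetics`.
#' @export
ligand_kinetics <- function(name, k_on, k_off) {
  stopifnot(k_on > 0, k_off > 0)
  structure(list(name = name, k_on = k_on, k_off = k_off),
            class = "ligand_kinetics")
}

#' Reference panel of pMHC ligand variants
#'
#' The three altered peptide ligands used throughout: the strong agonist
#' 4P, the weak agonist 4A and the antagonist 4N. They bind the same TCR
#' with nearly identical association rates (within ~6%) but dissociation
#' rates spanning roughly 500-fold, so potency in this model is driven by
#' `k_off`.
#'
#' @return Named list of [ligand_kinetics()]: `4P`, `4A`, `4N` (k_off
#'   increasing in that order).
#' @export
#' @examples
#' ligand_panel()[["4P"]]$k_off  # 0.0169
ligand_panel <- function() {
  list(
    "4P" = ligand_kinetics("4P", k_on = 153691, k_off = 0.0169),
    "4A" = ligand_kinetics("4A", k_on = 157533, k_off = 0.8664),
    "4N" = ligand_kinetics("4N", k_on = 149385, k_off = 8.6643)
  )
}

#' Kinetic parameter set for the bivalent activation model
#'
#' Collects all rates, volumes and copy numbers of the stochastic
#' cross-linking model and derives the per-cell quantities used by both the
#' Gillespie simulation and the analytic formulas:
#' number of dimeric clusters `n_dimers = round(b * n_receptors)`, the
#' reaction volume, the ligand copy number `round(rho * volume * avogadro)`
#' and the per-pair association propensity constant
#' `k_plus = k_on / (volume * avogadro)`.
#'
#' Two volume conventions are supported. The default, `"per_cell"`,
#' simulates a single cell in its average extracellular volume
#' `volume_total / n_cells`; this reproduces the same pseudo-first-order
#' binding rate `k_on * rho` as the bulk reading while keeping copy numbers
#' at single-cell scale. `"bulk"` uses `volume_total` directly.
#'
#' @param ligand A [ligand_kinetics()] object, or a panel name
#'   (`"4P"`, `"4A"`, `"4N"`).
#' @param rho Ligand concentration (M), `> 0`.
#' @param b Clustering parameter in `(0, 1)`; sets the number of dimeric
#'   clusters.
#' @param k2_factor Cross-linking rate as a multiple of `k_off`
#'   (`k2 = k2_factor * k_off`); 10 and 40 are the reference choices.
#' @param k_minus2 Reverse cross-linking rate (s^-1); defaults to `k_off`.
#' @param n_receptors Total TCRs per cell (default 30000).
#' @param volume_total Experiment volume in litres (default 50 microlitres).
#' @param n_cells Number of T cells sharing the volume (default 1e5).
#' @param avogadro Avogadro's number (default 6.023e23, the convention used
#'   with the reference parameter table).
#' @param convention Volume convention, `"per_cell"` (default) or `"bulk"`.
#' @param allow_double_binding Enable the second-ligand channel
#'   (x3 + ligand -> x4)? Disabled by default; negligible at low ligand
#'   concentration and absent from the analytic reduction.
#'
#' @return Object of class `kinetic_parameters` with fields `ligand`, `k2`,
#'   `k_minus2`, `rho`, `b`, `n_receptors`, `n_dimers`, `volume`,
#'   `k_plus`, `ligand_copies`, `convention`, `allow_double_binding`.
#' @export
#' @examples
#' p <- kinetic_parameters("4P", rho = 1e-9, b = 0.32)
#' p$n_dimers       # 9600
#' p$ligand_copies  # ~ 3e5
kinetic_parameters <- function(ligand, rho, b,
                               k2_factor = 10,
                               k_minus2 = NULL,
                               n_receptors = 30000,
                               volume_total = 50e-6,
                               n_cells = 1e5,
                               avogadro = 6.023e23,
                               convention = c("per_cell", "bulk"),
                               allow_double_binding = FALSE) {
  convention <- match.arg(convention)
  if (is.character(ligand)) {
    panel <- ligand_panel()
    if (!ligand %in% names(panel)) stop("unknown ligand: ", ligand)
    ligand <- panel[[ligand]]
  }
  stopifnot(inherits(ligand, "ligand_kinetics"))
  if (rho < 0) stop("'rho' must be >= 0")
  if (b <= 0 || b >= 1) stop("'b' must be in (0, 1)")
  stopifnot(k2_factor > 0, n_receptors > 0, volume_total > 0, n_cells > 0)
  if (is.null(k_minus2)) k_minus2 <- ligand$k_off
  volume <- if (convention == "per_cell") volume_total / n_cells else
    volume_total
  structure(
    list(ligand = ligand,
         k2 = k2_factor * ligand$k_off,
         k2_factor = k2_factor,
         k_minus2 = k_minus2,
         rho = rho,
         b = b,
         n_receptors = n_receptors,
         n_dimers = as.integer(round(b * n_receptors)),
         volume_total = volume_total,
         n_cells = n_cells,
         volume = volume,
         avogadro = avogadro,
         k_plus = ligand$k_on / (volume * avogadro),
         ligand_copies = round(rho * volume * avogadro),
         convention = convention,
         allow_double_binding = allow_double_binding),
    class = "kinetic_parameters"
  )
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat(sprintf(paste0("kinetic_parameters: ligand %s (k_on %.4g, k_off %.4g), ",
                     "k2 = %.4g, k-2 = %.4g, rho = %.3g M\n",
                     "  b = %.2f -> %d dimers; %d ligand copies in %.3g L (%s)\n"),
              x$ligand$name, x$ligand$k_on, x$ligand$k_off, x$k2, x$k_minus2,
              x$rho, x$b, x$n_dimers, x$ligand_copies, x$volume, x$convention))
  invisible(x)
}

#' T cell response criterion
#'
#' A response is initiated the first time `n_events` cross-linked
#' ligand-receptor complexes have each remained cross-linked for at least
#' the dwell time `tau` (the kinetic-proofreading surrogate).
#'
#' @param n_events Number of productive signaling units required (N >= 0).
#' @param tau Minimum dwell time in seconds (>= 0).
#' @return Object of class `response_criterion`.
#' @export
response_criterion <- function(n_events = 10L, tau = 1) {
  stopifnot(n_events >= 0, n_events == floor(n_events), tau >= 0)
  structure(list(n_events = as.integer(n_events), tau = tau),
            class = "response_criterion")
}

#' Expand a parameter grid into runnable configurations
#'
#' Cross-product of ligand names, concentrations, cross-linking factors,
#' dwell times, event thresholds and clustering parameters, with all
#' derived quantities filled in.
#'
#' @param rho Vector of ligand concentrations (M), nonempty.
#' @param ligands Character vector of panel ligand names.
#' @param k2_factor Vector of cross-linking multipliers.
#' @param tau Vector of dwell times (s).
#' @param n_events Vector of event thresholds.
#' @param b Vector of clustering parameters.
#' @param ... Further arguments passed to [kinetic_parameters()].
#' @return A list of `list(params = kinetic_parameters,
#'   criterion = response_criterion)` entries, one per grid point, with the
#'   grid stored as attribute `"grid"`.
#' @export
sweep_config <- function(rho, ligands = "4P", k2_factor = c(10, 40),
                         tau = c(1, 4), n_events = 10, b = 0.32, ...) {
  if (length(rho) == 0) stop("empty concentration ladder")
  grid <- expand.grid(rho = rho, ligand = ligands, k2_factor = k2_factor,
                      tau = tau, n_events = n_events, b = b,
                      stringsAsFactors = FALSE)
  configs <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    list(params = kinetic_parameters(g$ligand, rho = g$rho, b = g$b,
                                     k2_factor = g$k2_factor, ...),
         criterion = response_criterion(g$n_events, g$tau))
  })
  attr(configs, "grid") <- grid
  configs
}
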