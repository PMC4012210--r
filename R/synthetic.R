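#' Scenario for synthetic per-cell cluster histograms
#'
#' Describes a synthetic immuno-gold quantification experiment: `n_cells`
#' cells whose clusters are drawn i.i.d. from the stationary cluster-size
#' law at `b_true`, subject to a total particle budget (summed cluster
#' sizes across cells). By default the total is split across cells by a
#' symmetric multinomial, the simplest exchangeable allocation consistent
#' with mean +/- SD reporting; explicit per-cell budgets may be supplied.
#'
#' @param b_true Generating clustering parameter, in `[0, 1)`.
#' @param n_cells Number of cells (>= 2).
#' @param total_particles Total particles summed over cells.
#' @param allocation Optional integer vector of per-cell particle budgets
#'   (length `n_cells`, summing to `total_particles`).
#' @param weighting_mode Passed through to the generated histogram.
#' @param seed Integer RNG seed; the generator is deterministic given the
#'   scenario and seed.
#' @return Object of class `histogram_scenario`.
#' @export
histogram_scenario <- function(b_true, n_cells, total_particles,
                               allocation = NULL,
                               weighting_mode = "cluster_count",
                               seed = 1L) {
  if (b_true < 0 || b_true >= 1) stop("'b_true' must be in [0, 1)")
  if (n_cells < 2) stop("'n_cells' must be >= 2")
  if (!is.null(allocation)) {
    if (length(allocation) != n_cells || sum(allocation) != total_particles)
      stop("'allocation' must have length n_cells and sum to total_particles")
  }
  structure(list(b_true = b_true, n_cells = as.integer(n_cells),
                 total_particles = as.integer(total_particles),
                 allocation = allocation, weighting_mode = weighting_mode,
                 seed = as.integer(seed)),
            class = "histogram_scenario")
}

# Draw cluster sizes ~ Geometric on {1,2,...} with ratio b until the
# particle budget is exactly met. The final cluster is redrawn (up to 1000
# attempts) until it fits the remaining budget; as a last resort the
# remainder is emitted as monomers.
sample_cell_clusters <- function(b, budget) {
  if (budget == 0L) return(integer(0))
  if (b == 0) return(rep(1L, budget))
  sizes <- integer(0)
  used <- 0L
  while (used < budget) {
    chunk <- rgeom(max(16L, ceiling((budget - used) * (1 - b))), 1 - b) + 1L
    cum <- used + cumsum(chunk)
    take <- which(cum <= budget)
    if (length(take)) {
      sizes <- c(sizes, chunk[take])
      used <- cum[max(take)]
    }
    if (used < budget) {
      # next draw overshot the budget: rejection-sample the last cluster
      ok <- FALSE
      for (i in seq_len(1000L)) {
        s <- rgeom(1L, 1 - b) + 1L
        if (used + s <= budget) {
          sizes <- c(sizes, s); used <- used + s; ok <- TRUE; break
        }
      }
      if (!ok) {
        sizes <- c(sizes, rep(1L, budget - used))
        used <- budget
      }
    }
  }
  sizes
}

#' Sample synthetic per-cell cluster-size histograms
#'
#' Generates a [cluster_histogram()] from a [histogram_scenario()]:
#' per-cell particle budgets are allocated, then each cell's clusters are
#' drawn i.i.d. from the stationary law at `b_true` until its budget is
#' met exactly (see [histogram_scenario()] for the boundary rule).
#'
#' @param scenario A `histogram_scenario`.
#' @return A `cluster_histogram` whose per-cell particle totals equal the
#'   scenario allocation exactly. Counts are numbers of clusters per size.
#' @export
#' @examples
#' h <- sample_cluster_histograms(histogram_scenario(0.55, 5, 3001, seed = 42))
#' fit_b(h)$b_hat
sample_cluster_histograms <- function(scenario) {
  stopifnot(inherits(scenario, "histogram_scenario"))
  set.seed(scenario$seed)
  budgets <- scenario$allocation
  if (is.null(budgets)) {
    budgets <- as.vector(rmultinom(1, scenario$total_particles,
                                   rep(1, scenario$n_cells)))
  }
  rows <- lapply(seq_len(scenario$n_cells), function(i) {
    sizes <- sample_cell_clusters(scenario$b_true, budgets[i])
    tb <- tabulate(sizes)
    data.frame(cell_id = sprintf("cell%02d", i),
               cluster_size = seq_along(tb), count = tb)
  })
  df <- do.call(rbind, rows)
  cluster_histogram(df[df$count > 0, , drop = FALSE],
                    weighting_mode = scenario$weighting_mode)
}
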