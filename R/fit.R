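#' Variance-weighted least-squares fit of the clustering parameter
#'
#' Fits the geometric stationary law \eqn{\pi_n = b^{n-1}(1-b)} to an
#' observed per-cell cluster-size histogram by minimizing the weighted
#' residual sum
#' \deqn{\chi^2(b) = \sum_n w_n \, (f_n - \pi_n(b))^2,}
#' where `f_n` is the cross-cell mean of the per-cell normalized
#' cluster-size frequencies and the weights are the inverse cross-cell
#' variances on the frequency scale, `w_n = 1 / max(sd_n^2, floor^2)`. The
#' variance floor is the smallest nonzero frequency SD observed, so bins in
#' which every cell happens to agree exactly do not get infinite weight
#' (a warning is emitted when the floor is used). Minimization is a
#' deterministic bounded scalar search on `b` in `[0, 1)`; the objective is
#' smooth and one-dimensional, so no restarts are needed.
#'
#' By default the fit uses all sizes up to the largest size observed in
#' *every* cell (the largest size for which a cross-cell SD is meaningful),
#' overridable via `n_max_fit`.
#'
#' @param hist A [cluster_histogram()] with at least 2 cells and at least 2
#'   size bins with nonzero mean frequency.
#' @param n_max_fit Largest size bin entering the fit; `NULL` (default) for
#'   the largest size shared by all cells.
#'
#' @return Object of class `fit_result`: list with `b_hat`, `chi2`, `dof`
#'   (bins used minus 1 fitted parameter), `stderr_b` (from the local
#'   curvature of chi^2 at the minimum), `sizes_used` and `weighting_mode`.
#' @export
#' @examples
#' h <- sample_cluster_histograms(histogram_scenario(0.32, 7, 9190, seed = 1))
#' fit_b(h)$b_hat
fit_b <- function(hist, n_max_fit = NULL) {
  stopifnot(inherits(hist, "cluster_histogram"))
  if (length(hist$cell_ids) < 2L)
    stop("need >=2 cells for variance weights")
  if (sum(hist$counts) == 0) stop("all-zero histogram")
  shared_max <- min(apply(hist$counts, 2, function(cc) max(which(cc > 0))))
  k_max <- if (is.null(n_max_fit)) shared_max else
    min(n_max_fit, nrow(hist$counts))
  freq <- cell_frequencies(hist, k_max = k_max)
  f <- rowMeans(freq)
  s <- apply(freq, 1, sd)
  use <- f > 0                        # bins observed in zero cells excluded
  if (sum(use) < 2L) stop("need >=2 size bins with nonzero mean frequency")
  f <- f[use]; s <- s[use]
  sizes <- seq_len(k_max)[use]
  if (any(s == 0)) {
    if (all(s == 0)) {
      warning("all cross-cell SDs are zero; using equal weights")
      s2 <- rep(1, length(s))
    } else {
      warning("zero cross-cell SD in some bins; variance floor applied")
      s2 <- pmax(s^2, min(s[s > 0])^2)
    }
  } else {
    s2 <- s^2
  }
  w <- 1 / s2
  chi2_fun <- function(b) sum(w * (f - stationary_pmf(b, sizes))^2)
  opt <- optimize(chi2_fun, interval = c(0, 1 - 1e-9), tol = 1e-9)
  b_hat <- opt$minimum
  chi2 <- opt$objective
  # stderr from local curvature: var(b_hat) ~ 2 / chi2''(b_hat)
  h <- 1e-5
  d2 <- (chi2_fun(min(b_hat + h, 1 - 1e-9)) - 2 * chi2 +
           chi2_fun(max(b_hat - h, 0))) / h^2
  stderr_b <- if (is.finite(d2) && d2 > 0) sqrt(2 / d2) else NA_real_
  structure(
    list(b_hat = b_hat, chi2 = chi2, dof = length(sizes) - 1L,
         stderr_b = stderr_b, sizes_used = sizes,
         weighting_mode = hist$weighting_mode),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: b_hat = %.4f (stderr %.4f), chi2 = %.4g on %d dof, sizes %d..%d [%s]\n",
              x$b_hat, x$stderr_b, x$chi2, x$dof, min(x$sizes_used),
              max(x$sizes_used), x$weighting_mode))
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' @param fit A `fit_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
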