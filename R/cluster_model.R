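#' Birth-death model of TCR nano-cluster growth
#'
#' A TCR nano-cluster of size `n` (a linear chain of `n` TCR-CD3 complexes)
#' gains one monomer at rate `q_plus` and loses one at rate `q_minus`,
#' independently of its current size. The stationary cluster-size law of this
#' chain depends on the rates only through the dimensionless clustering
#' parameter `b = q_plus / q_minus`.
#'
#' @param q_plus Growth rate (per cluster, per unit time), `>= 0`.
#' @param q_minus Shrinkage rate (per cluster, per unit time), `> 0`.
#' @param n_max Maximum cluster size. `Inf` (default) for the unbounded
#'   chain; a finite value imposes a reflecting boundary (no growth out of
#'   `n_max`).
#'
#' @return An object of class `birth_death_model` with fields `q_plus`,
#'   `q_minus`, `b` and `n_max`.
#' @seealso [stationary_distribution()], [transient_probabilities()]
#' @export
#' @examples
#' m <- birth_death_model(q_plus = 0.32, q_minus = 1)
#' m$b
birth_death_model <- function(q_plus, q_minus, n_max = Inf) {
  stopifnot(is.numeric(q_plus), is.numeric(q_minus), length(q_plus) == 1L,
            length(q_minus) == 1L)
  if (q_plus < 0) stop("'q_plus' must be >= 0")
  if (q_minus <= 0) stop("'q_minus' must be > 0")
  if (!(is.infinite(n_max) || (n_max >= 1 && n_max == floor(n_max))))
    stop("'n_max' must be a positive integer or Inf")
  structure(
    list(q_plus = q_plus, q_minus = q_minus, b = q_plus / q_minus,
         n_max = n_max),
    class = "birth_death_model"
  )
}

#' Stationary cluster-size distribution
#'
#' Stationary law of the birth-death oligomerization chain. For a finite
#' state space `1..n_max` the probabilities are
#' \deqn{\pi_n = b^{n-1} (1 - b) / (1 - b^{N_{max}}),}
#' which at `b = 1` has the removable limit \eqn{\pi_n = 1/N_{max}}. For the
#' unbounded chain (`n_max = Inf`, requires `b < 1`) this reduces to the
#' geometric law \eqn{\pi_n = b^{n-1}(1-b)}. In either case successive
#' probabilities satisfy \eqn{\pi_{n+1}/\pi_n = b}, so `b` is both the
#' geometric decay factor and (via \eqn{1-\pi_1 = b}) the fraction of
#' multimeric clusters.
#'
#' @param b Clustering parameter `q_plus/q_minus`. Must satisfy
#'   `0 <= b < 1` when `n_max = Inf`; any `b >= 0` is admissible for finite
#'   `n_max`.
#' @param n_max Truncation size (positive integer) or `Inf` (default).
#' @param length_out For the unbounded law, how many leading probabilities
#'   to tabulate in the returned vector (the law itself is analytic; the
#'   vector is a convenience). Defaults to the smallest `L` with tail mass
#'   `b^L < 1e-15` (at least 10).
#'
#' @return An object of class `cluster_distribution`: a list with `b`,
#'   `n_max` and `probabilities` (named by cluster size, starting at 1).
#' @export
#' @examples
#' stationary_distribution(0.5)$probabilities[1:4]   # 0.5 0.25 0.125 0.0625
#' stationary_distribution(0, n_max = 10)$probabilities[1]  # all monomers
stationary_distribution <- function(b, n_max = Inf, length_out = NULL) {
  stopifnot(is.numeric(b), length(b) == 1L)
  if (b < 0) stop("'b' must be >= 0")
  if (is.infinite(n_max)) {
    if (b >= 1)
      stop("no normalizable stationary law for b >= 1 on the unbounded chain")
    if (is.null(length_out)) {
      length_out <- if (b == 0) 10L else max(10L, ceiling(log(1e-15) / log(b)))
    }
    n <- seq_len(length_out)
    p <- b^(n - 1) * (1 - b)
  } else {
    if (!(n_max >= 1 && n_max == floor(n_max)))
      stop("'n_max' must be a positive integer or Inf")
    n <- seq_len(n_max)
    if (b == 1) {
      p <- rep(1 / n_max, n_max)  # removable singularity of the finite law
    } else {
      p <- b^(n - 1) * (1 - b) / (1 - b^n_max)
    }
  }
  names(p) <- n
  structure(list(b = b, n_max = n_max, probabilities = p),
            class = "cluster_distribution")
}

#' Stationary probability of a given cluster size
#'
#' Analytic point evaluation of the stationary law, vectorized over `n`.
#'
#' @param b Clustering parameter.
#' @param n Cluster sizes (positive integers).
#' @param n_max Truncation, as in [stationary_distribution()].
#' @return Numeric vector of probabilities.
#' @export
stationary_pmf <- function(b, n, n_max = Inf) {
  stopifnot(all(n >= 1), all(n == floor(n)))
  if (is.infinite(n_max)) {
    if (b >= 1) stop("b must be < 1 for the unbounded law")
    b^(n - 1) * (1 - b)
  } else {
    out <- numeric(length(n))
    keep <- n <= n_max
    out[keep] <- if (b == 1) 1 / n_max else
      b^(n[keep] - 1) * (1 - b) / (1 - b^n_max)
    out
  }
}

#' Transient cluster-size probabilities
#'
#' Integrates the forward Kolmogorov equations of the oligomerization chain
#' \deqn{dp_n/dt = q_+ p_{n-1} + q_- p_{n+1} - (q_+ + q_-) p_n, \quad n \ge 2,}
#' \deqn{dp_1/dt = q_- p_2 - q_+ p_1,}
#' on the state space `1..n_max` with a reflecting upper boundary (no growth
#' out of `n_max`). If the model is unbounded, a truncation is chosen so
#' that the stationary mass at the boundary is below `1e-12`.
#'
#' @param model A [birth_death_model()].
#' @param p0 Initial distribution over sizes `1..length(p0)`; must sum to 1.
#' @param times Increasing time grid starting at 0.
#' @param ... Passed to [deSolve::ode()] (e.g. `rtol`, `atol`).
#'
#' @return Object of class `transient_distribution`: list with `times` and
#'   matrix `p` (rows = times, columns = cluster sizes); every row sums to 1
#'   to integration tolerance.
#' @export
transient_probabilities <- function(model, p0, times, ...) {
  stopifnot(inherits(model, "birth_death_model"))
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-8)
    stop("'p0' must be a probability vector summing to 1")
  n_max <- model$n_max
  if (is.infinite(n_max)) {
    if (model$b >= 1)
      stop("unbounded transient integration requires b < 1; supply finite n_max")
    # boundary placed where the stationary law is numerically negligible
    n_max <- if (model$b == 0) max(length(p0), 10L) else
      max(length(p0), ceiling(log(1e-12) / log(model$b)) + 1L)
  }
  if (length(p0) > n_max) stop("'p0' longer than the truncated state space")
  y0 <- c(p0, rep(0, n_max - length(p0)))
  qp <- model$q_plus; qm <- model$q_minus
  rhs <- function(t, p, parms) {
    up <- c(0, qp * p[-n_max])            # growth into n from n-1
    down <- c(qm * p[-1], 0)              # shrinkage into n from n+1
    out_rate <- c(qp, rep(qp + qm, n_max - 2L), qm) * p
    list(up + down - out_rate)
  }
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      rtol = 1e-10, atol = 1e-12, ...)
  p <- unname(sol[, -1, drop = FALSE])
  structure(list(times = times, p = p, n_max = n_max),
            class = "transient_distribution")
}

#' Fraction of multimeric clusters
#'
#' Under the unbounded stationary law the probability that a cluster has
#' size larger than one is `1 - pi_1 = b`: the clustering parameter itself.
#'
#' @param b Clustering parameter in `[0, 1)`.
#' @return `b`, computed as `1 - pi_1` for definitional consistency.
#' @export
multimeric_fraction <- function(b) {
  stopifnot(b >= 0, b < 1)
  1 - stationary_pmf(b, 1L)
}

#' Ratio of clustering parameters between two phenotypes
#'
#' Because the multimeric fraction equals `b`, the ratio `b_b / b_a` is also
#' the ratio of multimeric-cluster fractions between two cell phenotypes
#' (e.g. memory over naive), and the low-concentration speed-up factor of
#' the activation model.
#'
#' @param b_a Reference phenotype clustering parameter, in `(0, 1)`.
#' @param b_b Comparison phenotype clustering parameter, in `(0, 1)`.
#' @return `b_b / b_a`.
#' @export
#' @examples
#' phenotype_ratio(0.32, 0.55)  # 1.72 to two decimals
phenotype_ratio <- function(b_a, b_b) {
  if (b_a <= 0 || b_a >= 1 || b_b <= 0 || b_b >= 1)
    stop("both parameters must lie in (0, 1)")
  b_b / b_a
}
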