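#' xfuzzen: cross-fuzzy entropy for bivariate time series
#'
#' Cross entropies quantify the (a)synchrony of two concurrent time series by
#' comparing short embedded templates drawn from each.  `xfuzzen` implements
#' cross-sample entropy (Heaviside template matching) and cross-fuzzy entropy
#' (exponential fuzzy similarity with per-template baseline removal), plus the
#' surrogate-signal generators, Monte-Carlo characterisation experiments, and
#' the gait-symmetry feature/classification pipeline built on top of them.
#'
#' @keywords internal
"_PACKAGE"

# ---- validation helpers -----------------------------------------------------

.check_pair <- function(u, v, m) {
  if (!is.numeric(u) || !is.numeric(v))
    stop("`u` and `v` must be numeric vectors", call. = FALSE)
  if (length(u) != length(v))
    stop("`u` and `v` must have equal length (got ", length(u), " and ",
         length(v), ")", call. = FALSE)
  if (!all(is.finite(u)) || !all(is.finite(v)))
    stop("series must contain only finite values (no NA/NaN/Inf)", call. = FALSE)
  if (m < 1 || m != round(m))
    stop("`m` must be a positive integer", call. = FALSE)
  if (length(u) < m + 2)
    stop("series length must be at least m + 2 (need ", m + 2,
         ", got ", length(u), ")", call. = FALSE)
  invisible(TRUE)
}

.zscore <- function(x) (x - mean(x)) / stats::sd(x)

#' Construct a validated time-series pair
#'
#' Bundles two equal-length, all-finite numeric series.  Entropy functions
#' accept either a pair object or the two raw vectors.
#'
#' @param u,v Numeric vectors of equal length with finite values.
#' @return An object of class `"time_series_pair"`: a list with elements
#'   `u`, `v` and `N`.
#' @examples
#' p <- time_series_pair(sin(1:50), cos(1:50))
#' p$N
#' @export
time_series_pair <- function(u, v) {
  .check_pair(u, v, 1)
  structure(list(u = as.numeric(u), v = as.numeric(v), N = length(u)),
            class = "time_series_pair")
}

#' @export
print.time_series_pair <- function(x, ...) {
  cat("<time_series_pair> N =", x$N, "\n")
  invisible(x)
}

# ---- template machinery -----------------------------------------------------

#' Embed a series into delay templates
#'
#' Slices a series into consecutive windows (templates) of a given length,
#' optionally subtracting each window's own mean (baseline removal, the
#' preprocessing used by the fuzzy similarity measure so that template shape,
#' not absolute level, is compared).
#'
#' By default `n_templates = length(series) - m`, the sample-entropy
#' convention under which order-`m` and order-`(m+1)` embeddings of the same
#' series yield equal numbers of templates (request `n_templates = N - m`
#' when embedding at order `m + 1`).
#'
#' @param series Numeric vector, length at least `m + 1`.
#' @param m Window (template) length, a positive integer.
#' @param center If `TRUE`, subtract each window's mean from its components.
#' @param n_templates Number of leading windows to return.
#' @return A numeric matrix with `n_templates` rows and `m` columns; row `i`
#'   is `series[i..(i + m - 1)]` (centered if requested).
#' @examples
#' embed_templates(c(1, 2, 3, 4), 2)
#' embed_templates(c(1, 2, 3, 4), 2, center = TRUE)
#' @export
embed_templates <- function(series, m, center = FALSE,
                            n_templates = length(series) - m) {
  if (m < 1 || m != round(m)) stop("`m` must be a positive integer", call. = FALSE)
  if (length(series) < m + 1)
    stop("series too short to embed: need at least m + 1 = ", m + 1,
         " points, got ", length(series), call. = FALSE)
  max_t <- length(series) - m + 1
  if (n_templates < 1 || n_templates > max_t)
    stop("`n_templates` must be between 1 and ", max_t, call. = FALSE)
  idx <- seq_len(n_templates)
  M <- vapply(seq_len(m) - 1L, function(k) series[idx + k],
              numeric(n_templates))
  if (n_templates == 1L) M <- matrix(M, nrow = 1L)
  if (center) M <- M - rowMeans(M)
  M
}

#' Chebyshev (maximum-coordinate) distance between two templates
#'
#' @param x,y Numeric vectors of equal length.
#' @return `max(abs(x - y))`, a nonnegative scalar, symmetric in its arguments.
#' @examples
#' chebyshev_distance(c(1, 4), c(2, 2))
#' @export
chebyshev_distance <- function(x, y) {
  if (length(x) != length(y))
    stop("templates must have equal dimension", call. = FALSE)
  max(abs(x - y))
}

# Cross-distance matrix between template sets A (a x m) and B (b x m):
# D[i, j] = max_k |A[i, k] - B[j, k]|.
.cheb_cross <- function(A, B) {
  D <- abs(outer(A[, 1L], B[, 1L], "-"))
  w <- ncol(A)
  if (w > 1L)
    for (k in 2:w) D <- pmax(D, abs(outer(A[, k], B[, k], "-")))
  D
}

# ---- similarity functions ---------------------------------------------------

#' Heaviside (hard-threshold) template similarity
#'
#' The match indicator of cross-sample entropy: 1 when the distance is
#' strictly below the tolerance `r`, 0 otherwise.  The inequality is strict,
#' so `d == r` does not count as a match.
#'
#' @param d Nonnegative distance(s).
#' @param r Positive tolerance.
#' @return 0/1 numeric of the same length as `d`.
#' @export
heaviside_similarity <- function(d, r) {
  stopifnot(all(d >= 0), r > 0)
  as.numeric(d < r)
}

#' Exponential fuzzy template similarity
#'
#' The fuzzy membership function `exp(-d^n / r)`: equal to 1 at zero
#' distance, strictly decreasing, and always positive — the property that
#' makes cross-fuzzy entropy defined for every input.  `r` controls the
#' width of the membership function and `n` the steepness of its boundary.
#'
#' @param d Nonnegative distance(s).
#' @param r Positive tolerance (width).
#' @param n Positive gradient exponent (default 2).
#' @return Values in (0, 1], same length as `d`.
#' @examples
#' fuzzy_similarity(0.2, r = 0.04)  # exp(-1)
#' @export
fuzzy_similarity <- function(d, r, n = 2) {
  stopifnot(all(d >= 0), r > 0, n > 0)
  exp(-d^n / r)
}

# ---- entropy statistics -----------------------------------------------------

.resolve_pair <- function(u, v) {
  if (inherits(u, "time_series_pair")) list(u = u$u, v = u$v) else list(u = u, v = v)
}

.maybe_preprocess <- function(u, v, r, normalize, scale_r) {
  if (normalize) {
    u <- .zscore(u)
    v <- .zscore(v)
  }
  if (scale_r)
    r <- r * stats::sd(c(u - mean(u), v - mean(v)))
  list(u = u, v = v, r = r)
}

.ce_result <- function(measure, m, r, n, N, phi_m, phi_m1,
                       value = NULL, defined = NULL) {
  if (is.null(defined)) defined <- phi_m1 > 0
  if (is.null(value))
    value <- if (defined) -log(phi_m1 / phi_m) else NA_real_
  structure(
    list(measure = measure, m = m, r = r, n = n, N = N,
         phi_m = phi_m, phi_m1 = phi_m1, value = value, defined = defined),
    class = "cross_entropy")
}

# log(mean(exp(x))) computed stably; keeps C-FuzzyEn finite when every
# individual similarity exp(-d^n/r) underflows (tiny r).
.log_mean_exp <- function(x) {
  mx <- max(x)
  mx + log(mean(exp(x - mx)))
}

#' @export
print.cross_entropy <- function(x, ...) {
  cat(sprintf("<%s> m=%d r=%g N=%d\n", x$measure, x$m, x$r, x$N))
  if (x$defined)
    cat(sprintf("  value = %.6f  (phi_m = %.6g, phi_m+1 = %.6g)\n",
                x$value, x$phi_m, x$phi_m1))
  else
    cat(sprintf("  UNDEFINED (no template matches at order m+1; phi_m = %.6g)\n",
                x$phi_m))
  invisible(x)
}

#' @export
as.data.frame.cross_entropy <- function(x, ...) {
  data.frame(measure = x$measure, m = x$m, r = x$r, n = x$n, N = x$N,
             phi_m = x$phi_m, phi_m1 = x$phi_m1, value = x$value,
             defined = x$defined)
}

#' Cross-sample entropy of two time series
#'
#' C-SampleEn between series `u` and `v`: embed both at orders `m` and
#' `m + 1` (no baseline removal, `N - m` templates at both orders), count
#' Heaviside matches (Chebyshev distance strictly below `r`) over all
#' `(N - m)^2` cross-template pairs, and return
#' `-log(B_{m+1} / B_m)` where `B_m` and `B_{m+1}` are the grand-mean match
#' fractions.  Because there are no self-matches, the statistic is
#' *undefined* whenever no order-`(m+1)` match occurs; this is reported by
#' the `defined` flag (value `NA`), not as an error, so that parameter
#' sweeps can tabulate definedness rates.
#'
#' @param u,v Equal-length numeric series (or a [time_series_pair] as `u`).
#' @param m Embedding dimension (template length), default 2.
#' @param r Tolerance, in the units of the series (absolute, not scaled by
#'   the series SD, unless `scale_r = TRUE`).
#' @param normalize If `TRUE`, z-score both series first (default off).
#' @param scale_r If `TRUE`, multiply `r` by the pooled SD of the two
#'   centered series (default off).
#' @return A `"cross_entropy"` object: list with `measure`, `m`, `r`, `n`
#'   (`NA` here), `N`, `phi_m`, `phi_m1`, `value` and `defined`.
#' @seealso [cross_fuzzy_entropy()]
#' @examples
#' set.seed(1)
#' cross_sample_entropy(runif(100), runif(100), m = 2, r = 0.3)
#' @export
cross_sample_entropy <- function(u, v = NULL, m = 2, r,
                                 normalize = FALSE, scale_r = FALSE) {
  p <- .resolve_pair(u, v)
  .check_pair(p$u, p$v, m)
  stopifnot(r > 0)
  pp <- .maybe_preprocess(p$u, p$v, r, normalize, scale_r)
  N <- length(pp$u)
  nt <- N - m
  A_m  <- embed_templates(pp$u, m,      n_templates = nt)
  B_m  <- embed_templates(pp$v, m,      n_templates = nt)
  A_m1 <- embed_templates(pp$u, m + 1L, n_templates = nt)
  B_m1 <- embed_templates(pp$v, m + 1L, n_templates = nt)
  phi_m  <- mean(.cheb_cross(A_m,  B_m)  < pp$r)
  phi_m1 <- mean(.cheb_cross(A_m1, B_m1) < pp$r)
  .ce_result("csampleen", m, r, NA_real_, N, phi_m, phi_m1)
}

#' Cross-fuzzy entropy of two time series
#'
#' C-FuzzyEn shares the averaging structure of [cross_sample_entropy()] but
#' (a) removes the baseline (window mean) from every template at both orders,
#' so that template *shape* rather than absolute level is compared, and
#' (b) replaces the hard Heaviside match by the exponential fuzzy similarity
#' `exp(-d^n / r)`.  Every similarity is strictly positive, so the statistic
#' is defined for any valid input, however small `r` or short the series.
#'
#' @inheritParams cross_sample_entropy
#' @param n Fuzzy-boundary gradient exponent, default 2.
#' @return A `"cross_entropy"` object (see [cross_sample_entropy()]);
#'   `defined` is always `TRUE`.
#' @examples
#' set.seed(1)
#' cross_fuzzy_entropy(runif(100), runif(100), m = 2, r = 0.3)
#' @export
cross_fuzzy_entropy <- function(u, v = NULL, m = 2, r, n = 2,
                                normalize = FALSE, scale_r = FALSE) {
  p <- .resolve_pair(u, v)
  .check_pair(p$u, p$v, m)
  stopifnot(r > 0, n > 0)
  pp <- .maybe_preprocess(p$u, p$v, r, normalize, scale_r)
  N <- length(pp$u)
  nt <- N - m
  A_m  <- embed_templates(pp$u, m,      center = TRUE, n_templates = nt)
  B_m  <- embed_templates(pp$v, m,      center = TRUE, n_templates = nt)
  A_m1 <- embed_templates(pp$u, m + 1L, center = TRUE, n_templates = nt)
  B_m1 <- embed_templates(pp$v, m + 1L, center = TRUE, n_templates = nt)
  # average the similarities in log space: every exp(-d^n/r) is positive in
  # exact arithmetic, and the log-sum-exp keeps that totality under floating
  # point even when r is far below the distance scale
  lphi_m  <- .log_mean_exp(-.cheb_cross(A_m,  B_m)^n  / pp$r)
  lphi_m1 <- .log_mean_exp(-.cheb_cross(A_m1, B_m1)^n / pp$r)
  .ce_result("cfuzzyen", m, r, n, N, exp(lphi_m), exp(lphi_m1),
             value = lphi_m - lphi_m1, defined = TRUE)
}

#' Cross-fuzzy entropy profile over a tolerance grid
#'
#' Evaluates C-FuzzyEn at many tolerances `r` for one pair.  The template
#' distance matrices do not depend on `r`, so they are computed once and
#' reused — this is what makes dense tolerance screens (e.g. the gait
#' parameter-selection grid) cheap.
#'
#' @inheritParams cross_fuzzy_entropy
#' @param r_values Vector of positive tolerances.
#' @return Numeric vector of entropy values, one per element of `r_values`.
#' @export
cfuzzyen_profile <- function(u, v = NULL, r_values, m = 1, n = 2) {
  p <- .resolve_pair(u, v)
  .check_pair(p$u, p$v, m)
  stopifnot(all(r_values > 0), n > 0)
  N <- length(p$u)
  nt <- N - m
  Dm  <- .cheb_cross(embed_templates(p$u, m,      center = TRUE, n_templates = nt),
                     embed_templates(p$v, m,      center = TRUE, n_templates = nt))^n
  Dm1 <- .cheb_cross(embed_templates(p$u, m + 1L, center = TRUE, n_templates = nt),
                     embed_templates(p$v, m + 1L, center = TRUE, n_templates = nt))^n
  vapply(r_values,
         function(r) .log_mean_exp(-Dm / r) - .log_mean_exp(-Dm1 / r),
         numeric(1))
}
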