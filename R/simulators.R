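# Surrogate-signal generators: i.i.d. uniform noise, MIX(p) processes, and
# synthetic paired stride-interval series for exercising the gait pipeline.

#' i.i.d. uniform series
#'
#' Independent uniform draws, Uniform(0, 1) by default.  The Monte-Carlo
#' sweeps use the unit-variance support `c(-sqrt(3), sqrt(3))` — the same
#' convention as the noise component of [mix_process()] — so that the
#' tolerance grids shared with the MIX experiments stay on one scale.
#'
#' @param n Series length (>= 1).
#' @param min,max Support bounds (defaults 0 and 1).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of `n` independent uniform draws.
#' @export
iid_uniform <- function(n, min = 0, max = 1, seed = NULL) {
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  stats::runif(n, min, max)
}

# unit-variance uniform, the simulation-experiment convention
.unit_uniform <- function(n) stats::runif(n, -sqrt(3), sqrt(3))

#' MIX(p) surrogate process
#'
#' A composite of a deterministic and a stochastic component: the
#' unit-variance sine `sqrt(2) * sin(2*pi*j/12)`, `j = 1..n`, with points
#' replaced by i.i.d. Uniform(-sqrt(3), sqrt(3)) draws (also unit variance).
#' `p = 0` gives the pure period-12 sine; `p = 1` pure noise; the marginal
#' variance is approximately 1 for every `p`.
#'
#' Under the default `"bernoulli"` substitution each point is independently
#' replaced with probability `p` (the original construction; the random
#' substitution count is a genuine between-realisation variance source that
#' the Monte-Carlo experiments rely on).  `"exact"` substitutes exactly
#' `round(p * n)` distinct, uniformly chosen positions.
#'
#' @param n Series length.
#' @param p Proportion of randomised points, in \[0, 1\].
#' @param seed Optional integer seed.
#' @param substitution `"bernoulli"` (default) or `"exact"`.
#' @return Numeric vector of length `n`.
#' @examples
#' mix_process(24, p = 0, seed = 1)  # exactly periodic
#' @export
mix_process <- function(n, p, seed = NULL,
                        substitution = c("bernoulli", "exact")) {
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  if (p < 0 || p > 1) stop("`p` must be in [0, 1]", call. = FALSE)
  substitution <- match.arg(substitution)
  if (!is.null(seed)) set.seed(seed)
  x <- sqrt(2) * sin(2 * pi * seq_len(n) / 12)
  idx <- if (substitution == "bernoulli") {
    which(stats::runif(n) < p)
  } else {
    k <- round(p * n)
    if (k > 0) sample.int(n, k) else integer(0)
  }
  if (length(idx))
    x[idx] <- stats::runif(length(idx), -sqrt(3), sqrt(3))
  x
}

# Stationary AR(1) with marginal SD `sd` (innovation SD scaled accordingly).
.ar1 <- function(n, phi, sd) {
  e <- stats::rnorm(n, sd = sd * sqrt(1 - phi^2))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, sd = sd)
  for (i in seq_len(n - 1)) x[i + 1] <- phi * x[i] + e[i + 1]
  x
}

#' Synthetic left/right stride-interval pair
#'
#' Generates a paired stride-time series emulating bilateral gait rhythm
#' recordings: both limbs share a common slow fluctuation (fraction
#' `coupling`) plus limb-specific fluctuations (fraction `1 - coupling`),
#' all AR(1)-smooth with marginal SD `noise_sd`, on top of a constant
#' baseline stride time.  High coupling mimics the tight bilateral synchrony
#' of healthy gait (low cross-fuzzy entropy); low coupling with larger
#' `noise_sd` mimics the asymmetric, more variable gait of Parkinsonian
#' walkers.  Optionally, individual intervals are inflated 2--4 fold at rate
#' `outlier_rate`, emulating hallway-turnaround artefacts that the outlier
#' preprocessing must remove.
#'
#' This generator is fixture machinery for offline testing, not a
#' biomechanical gait model.
#'
#' @param n_strides Number of strides per limb (default 200).
#' @param base_interval Baseline stride time in seconds (default 1.1).
#' @param coupling Shared-signal fraction in \[0, 1\].
#' @param noise_sd Marginal SD of the fluctuation components, seconds.
#' @param outlier_rate Per-point probability of a turnaround outlier.
#' @param seed Optional integer seed.
#' @param ar_phi AR(1) coefficient of the fluctuations (default 0.9).
#' @return A [time_series_pair] with `u` = left and `v` = right intervals.
#' @export
synthetic_gait_pair <- function(n_strides = 200, base_interval = 1.1,
                                coupling = 0.9, noise_sd = 0.025,
                                outlier_rate = 0, seed = NULL,
                                ar_phi = 0.9) {
  stopifnot(n_strides >= 3, base_interval > 0,
            coupling >= 0, coupling <= 1, noise_sd >= 0,
            outlier_rate >= 0, outlier_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  shared <- .ar1(n_strides, ar_phi, noise_sd)
  left  <- base_interval + coupling * shared +
    (1 - coupling) * .ar1(n_strides, ar_phi, noise_sd)
  right <- base_interval + coupling * shared +
    (1 - coupling) * .ar1(n_strides, ar_phi, noise_sd)
  if (outlier_rate > 0) {
    oL <- stats::runif(n_strides) < outlier_rate
    oR <- stats::runif(n_strides) < outlier_rate
    left[oL]  <- left[oL]  * stats::runif(sum(oL), 2, 4)
    right[oR] <- right[oR] * stats::runif(sum(oR), 2, 4)
  }
  # stride intervals are physical durations; clamp far-tail draws positive
  left  <- pmax(left, 1e-3)
  right <- pmax(right, 1e-3)
  time_series_pair(left, right)
}

#' Synthetic two-group gait cohort
#'
#' Builds a cohort of [gait_record]s with a control-like group (high
#' bilateral coupling, low variability) and a PD-like group (low coupling,
#' higher variability), each subject an independent [synthetic_gait_pair].
#' Defaults mirror the 15-patient / 16-control cohort size of the gait
#' rhythm dataset this pipeline targets.
#'
#' @param n_pd,n_co Group sizes (defaults 15 and 16).
#' @param n_strides Strides per subject (default 200).
#' @param seed Master seed; each subject gets a derived child seed.
#' @param pd_coupling,pd_noise_sd PD-like group parameters (0.3, 0.045 s).
#' @param co_coupling,co_noise_sd Control-like group parameters (0.95, 0.025 s).
#' @param outlier_rate Turnaround-outlier rate for both groups (default 0.02).
#' @return List of `gait_record` objects with groups `"PD"` and `"CO"`.
#' @export
synthetic_gait_cohort <- function(n_pd = 15, n_co = 16, n_strides = 200,
                                  seed = 1,
                                  pd_coupling = 0.3, pd_noise_sd = 0.045,
                                  co_coupling = 0.95, co_noise_sd = 0.025,
                                  outlier_rate = 0.02) {
  make <- function(i, group, coupling, noise_sd) {
    pair <- synthetic_gait_pair(
      n_strides = n_strides, coupling = coupling, noise_sd = noise_sd,
      outlier_rate = outlier_rate,
      seed = child_seed(seed, if (group == "PD") 1L else 2L, i))
    gait_record(sprintf("%s%02d", tolower(group), i), group, pair$u, pair$v)
  }
  c(lapply(seq_len(n_pd), make, group = "PD",
           coupling = pd_coupling, noise_sd = pd_noise_sd),
    lapply(seq_len(n_co), make, group = "CO",
           coupling = co_coupling, noise_sd = co_noise_sd))
}

#' Derive a child RNG seed from a master seed
#'
#' Deterministic integer mixing so that Monte-Carlo sweeps can seed each
#' (parameter point, run) independently of execution order.  All results
#' stay below 2^31.
#'
#' @param master Master seed (integer).
#' @param ... One or more integer indices identifying the stream.
#' @return A single integer seed.
#' @export
child_seed <- function(master, ...) {
  s <- as.double(master) %% 2147483629
  for (k in c(...)) s <- (s * 104729 + as.double(k) + 1) %% 2147483629
  as.integer(s)
}
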