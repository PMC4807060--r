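# Monte-Carlo characterisation experiments: tolerance sweep, data-length
# sweep, and the relative-consistency test on MIX(p) pairs.  Every parameter
# point is summarised over `runs` independently regenerated signal pairs
# (200 by default); undefined C-SampleEn runs are excluded from mean/SD and
# tracked through `defined_fraction`.

#' Default simulation tolerance grid
#'
#' The grid \[0.01 : 0.01 : 0.1\] followed by \[0.11 : 0.1 : 1\] (19 values;
#' the second leg steps 0.11, 0.21, ..., 0.91).
#'
#' @return Numeric vector of tolerances.
#' @export
default_r_grid <- function() {
  c(seq(0.01, 0.1, by = 0.01), seq(0.11, 1, by = 0.1))
}

# mean/sd/defined_fraction of one cell; sd of a single defined value is 0.
.mc_stats <- function(x) {
  d <- x[!is.na(x)]
  c(mean = if (length(d)) mean(d) else NA_real_,
    sd = if (length(d) > 1) stats::sd(d) else if (length(d) == 1) 0 else NA_real_,
    defined_fraction = length(d) / length(x))
}

.both_entropies <- function(u, v, m, r, n) {
  c(cfuzzyen = cross_fuzzy_entropy(u, v, m = m, r = r, n = n)$value,
    csampleen = cross_sample_entropy(u, v, m = m, r = r)$value)
}

#' Data-length sweep on i.i.d. uniform pairs
#'
#' For each data length `N`, generates `runs` fresh pairs of independent
#' i.i.d. unit-variance uniform series and computes C-FuzzyEn (`n = 2`) and
#' C-SampleEn at each embedding dimension in `m_values`, all at tolerance
#' `r`.  Both measures and all `m` are scored on the *same* generated pair
#' within a run, giving a paired comparison; across runs the pairs are
#' independent.
#'
#' @param N_values Integer vector of data lengths (default 50 to 500 by 50).
#' @param r Tolerance (default 0.3).
#' @param m_values Embedding dimensions (default `c(2, 3)`).
#' @param runs Runs per data length (default 200).
#' @param seed Master seed; each (N, run) gets a child seed.
#' @param n Fuzzy gradient (default 2).
#' @return A tibble with one row per (measure, m, N): columns `measure`,
#'   `m`, `N`, `mean`, `sd`, `defined_fraction`, `runs`.
#' @seealso [sweep_aggregates()] for the mean-of-SD / SD-of-mean summaries.
#' @export
length_sweep <- function(N_values = seq(50, 500, by = 50), r = 0.3,
                         m_values = c(2, 3), runs = 200, seed = 1, n = 2) {
  stopifnot(length(N_values) >= 1, runs >= 1)
  rows <- list()
  for (iN in seq_along(N_values)) {
    N <- N_values[iN]
    vals <- array(NA_real_,
                  dim = c(2L, length(m_values), runs),
                  dimnames = list(c("cfuzzyen", "csampleen"), NULL, NULL))
    for (run in seq_len(runs)) {
      set.seed(child_seed(seed, iN, run))
      u <- .unit_uniform(N)
      v <- .unit_uniform(N)
      for (im in seq_along(m_values))
        vals[, im, run] <- .both_entropies(u, v, m_values[im], r, n)
    }
    for (im in seq_along(m_values))
      for (meas in c("cfuzzyen", "csampleen")) {
        s <- .mc_stats(vals[meas, im, ])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          measure = meas, m = m_values[im], N = N, r = r,
          mean = s[["mean"]], sd = s[["sd"]],
          defined_fraction = s[["defined_fraction"]], runs = runs)
      }
  }
  do.call(rbind, rows)
}

#' Tolerance sweep on an (i.i.d. uniform, MIX(p)) pair
#'
#' For each tolerance in `r_values`, generates `runs` fresh pairs of an
#' i.i.d. unit-variance uniform series and a MIX(`mix_p`) series of length
#' `N`, and
#' summarises both cross entropies.  The definedness fraction of C-SampleEn
#' documents where the hard-threshold statistic breaks down at small `r`.
#'
#' @param r_values Tolerance grid (default [default_r_grid()]).
#' @param N Data length (default 100).
#' @param m Embedding dimension (default 2).
#' @param mix_p MIX parameter of the second series (default 0.6).
#' @inheritParams length_sweep
#' @return Tibble with one row per (measure, r).
#' @export
r_sweep <- function(r_values = default_r_grid(), N = 100, m = 2,
                    mix_p = 0.6, runs = 200, seed = 1, n = 2) {
  stopifnot(length(r_values) >= 1, runs >= 1)
  rows <- list()
  for (ir in seq_along(r_values)) {
    r <- r_values[ir]
    vals <- matrix(NA_real_, nrow = 2L, ncol = runs,
                   dimnames = list(c("cfuzzyen", "csampleen"), NULL))
    for (run in seq_len(runs)) {
      set.seed(child_seed(seed, ir, run))
      u <- .unit_uniform(N)
      v <- mix_process(N, mix_p)
      vals[, run] <- .both_entropies(u, v, m, r, n)
    }
    for (meas in c("cfuzzyen", "csampleen")) {
      s <- .mc_stats(vals[meas, ])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        measure = meas, m = m, N = N, r = r,
        mean = s[["mean"]], sd = s[["sd"]],
        defined_fraction = s[["defined_fraction"]], runs = runs)
    }
  }
  do.call(rbind, rows)
}

#' Relative-consistency experiment on MIX(p) pairs
#'
#' Scores both cross entropies on the signal pairs (MIX(0.2), MIX(0.3)) and
#' (MIX(0.3), MIX(0.4)) across a tolerance grid.  The second pair is more
#' disordered, so a relatively consistent statistic should rank it above the
#' first at *every* tolerance; the per-measure `verdict` is `TRUE` exactly
#' when that holds over all grid points where both pair means are defined.
#'
#' @param N Data length (default 100).
#' @param pair_ps Two length-2 vectors of MIX parameters (defaults
#'   `c(0.2, 0.3)` and `c(0.3, 0.4)`).
#' @inheritParams r_sweep
#' @return A list of class `"consistency_report"`: `summary` (tibble of
#'   per-(measure, pair, r) mean/sd/defined_fraction), `verdict` (named
#'   logical per measure), and `mean_of_sd` (tibble of per-(measure, pair)
#'   mean of the per-r SDs over points with `defined_fraction > 0.5`).
#' @export
relative_consistency <- function(N = 100, r_values = default_r_grid(),
                                 m = 2, runs = 200, seed = 1, n = 2,
                                 pair_ps = list(c(0.2, 0.3), c(0.3, 0.4))) {
  stopifnot(length(pair_ps) == 2)
  rows <- list()
  for (ir in seq_along(r_values)) {
    r <- r_values[ir]
    vals <- array(NA_real_, dim = c(2L, 2L, runs),
                  dimnames = list(c("cfuzzyen", "csampleen"), NULL, NULL))
    for (run in seq_len(runs)) {
      set.seed(child_seed(seed, ir, run))
      for (ip in 1:2) {
        u <- mix_process(N, pair_ps[[ip]][1])
        v <- mix_process(N, pair_ps[[ip]][2])
        vals[, ip, run] <- .both_entropies(u, v, m, r, n)
      }
    }
    for (ip in 1:2)
      for (meas in c("cfuzzyen", "csampleen")) {
        s <- .mc_stats(vals[meas, ip, ])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          measure = meas, pair = ip, m = m, N = N, r = r,
          mean = s[["mean"]], sd = s[["sd"]],
          defined_fraction = s[["defined_fraction"]], runs = runs)
      }
  }
  summary <- do.call(rbind, rows)
  verdict <- vapply(c("cfuzzyen", "csampleen"), function(meas) {
    s1 <- summary[summary$measure == meas & summary$pair == 1, ]
    s2 <- summary[summary$measure == meas & summary$pair == 2, ]
    ok <- !is.na(s1$mean) & !is.na(s2$mean)
    any(ok) && all(s1$mean[ok] < s2$mean[ok])
  }, logical(1))
  mos <- do.call(rbind, lapply(c("cfuzzyen", "csampleen"), function(meas)
    do.call(rbind, lapply(1:2, function(ip) {
      s <- summary[summary$measure == meas & summary$pair == ip, ]
      keep <- s$defined_fraction > 0.5 & !is.na(s$sd)
      tibble::tibble(measure = meas, pair = ip,
                     mean_of_sd = mean(s$sd[keep]),
                     n_r_included = sum(keep))
    }))))
  structure(list(summary = summary, verdict = verdict, mean_of_sd = mos,
                 N = N, m = m, runs = runs),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("<consistency_report> N=%d m=%d runs=%d\n", x$N, x$m, x$runs))
  cat("  verdict (pair-1 mean < pair-2 mean at every defined r):\n")
  for (meas in names(x$verdict))
    cat(sprintf("    %-10s %s\n", meas, x$verdict[[meas]]))
  print(x$mean_of_sd)
  invisible(x)
}

#' Aggregate sweep summaries across parameter points
#'
#' Collapses a sweep table to its stability aggregates per (measure, m): the
#' mean of the per-point SDs (how much the statistic scatters across runs)
#' and the SD of the per-point means (how much the central value drifts
#' across the sweep).  Parameter points where the measure was undefined in
#' more than half the runs are excluded (threshold configurable), since
#' scatter estimated from a thin defined subset is not comparable.
#'
#' @param sweep A tibble from [length_sweep()] or [r_sweep()].
#' @param min_defined Minimum `defined_fraction` for a point to count
#'   (default 0.5, exclusive).
#' @return Tibble with one row per (measure, m): `mean_of_sd`,
#'   `sd_of_mean`, `n_points_included`.
#' @export
sweep_aggregates <- function(sweep, min_defined = 0.5) {
  combos <- unique(sweep[, c("measure", "m")])
  do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    s <- sweep[sweep$measure == combos$measure[i] & sweep$m == combos$m[i], ]
    keep <- s$defined_fraction > min_defined & !is.na(s$sd)
    tibble::tibble(
      measure = combos$measure[i], m = combos$m[i],
      mean_of_sd = if (any(keep)) mean(s$sd[keep]) else NA_real_,
      sd_of_mean = if (sum(keep) > 1) stats::sd(s$mean[keep]) else NA_real_,
      n_points_included = sum(keep))
  }))
}

#' Mean-and-SD sweep plot
#'
#' Quick mean +/- SD visualisation of a sweep table, one panel per measure.
#' Requires ggplot2.
#'
#' @param sweep Tibble from [length_sweep()] or [r_sweep()].
#' @param x Which column to put on the x axis: `"N"` or `"r"`.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, x = c("N", "r")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_sweep() requires ggplot2", call. = FALSE)
  x <- match.arg(x)
  df <- data.frame(x = sweep[[x]], mean = sweep$mean, sd = sweep$sd,
                   measure = sweep$measure,
                   m_lab = factor(paste0("m = ", sweep$m)))
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = mean, colour = m_lab)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sd, ymax = mean + sd),
                           width = 0) +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = x, y = "cross entropy (nats)", colour = NULL)
}
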