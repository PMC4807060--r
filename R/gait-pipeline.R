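# Gait-symmetry pipeline: file reading, turnaround-outlier preprocessing,
# per-subject symmetry features (C-FuzzyEn, C-SampleEn, ASI), tolerance
# screening by Mann-Whitney U, and small reporting utilities.

#' Construct a gait record
#'
#' A subject's paired left/right stride-interval series with identifiers.
#'
#' @param subject_id Character label.
#' @param group Group label, conventionally `"PD"` or `"CO"`.
#' @param left_stride,right_stride Numeric stride-interval series (seconds);
#'   trimmed to their common length.
#' @return Object of class `"gait_record"`.
#' @export
gait_record <- function(subject_id, group, left_stride, right_stride) {
  n <- min(length(left_stride), length(right_stride))
  if (n < 1) stop("empty stride series for subject ", subject_id, call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 group = as.character(group),
                 left_stride = as.numeric(left_stride[seq_len(n)]),
                 right_stride = as.numeric(right_stride[seq_len(n)])),
            class = "gait_record")
}

#' @export
print.gait_record <- function(x, ...) {
  cat(sprintf("<gait_record> %s (%s): %d strides, mean L/R = %.3f/%.3f s\n",
              x$subject_id, x$group, length(x$left_stride),
              mean(x$left_stride), mean(x$right_stride)))
  invisible(x)
}

#' Read a gait rhythm text file
#'
#' Reads a whitespace- or comma-delimited numeric text file and extracts the
#' left and right stride-interval columns.  The default column map is the
#' PhysioNet gait-rhythm layout: elapsed time in column 1, left stride in
#' column 2, right stride in column 3 (1-based).  Trailing missing values in
#' either column are dropped and the two series trimmed to their common
#' length; non-numeric cells elsewhere are an error.
#'
#' @param path File path.
#' @param left_col,right_col 1-based column indices (defaults 2 and 3).
#' @param subject_id Subject label (default: file name without extension).
#' @param group Group label (default `NA`).
#' @return A [gait_record].
#' @export
read_gait_file <- function(path, left_col = 2, right_col = 3,
                           subject_id = sub("\\.[^.]*$", "", basename(path)),
                           group = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("empty gait file: ", path, call. = FALSE)
  sep <- if (grepl(",", first)) "," else ""
  # tolerate an optional single header line of non-numeric labels
  fields1 <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(fields1))))
  dat <- utils::read.table(path, sep = sep, header = has_header,
                           fill = TRUE, blank.lines.skip = TRUE,
                           stringsAsFactors = FALSE)
  if (nrow(dat) == 0L) stop("no data rows in gait file: ", path, call. = FALSE)
  for (col in c(left_col, right_col))
    if (col > ncol(dat))
      stop("gait file ", path, " has ", ncol(dat),
           " columns; requested column ", col, " is absent", call. = FALSE)
  pull <- function(col, label) {
    x <- dat[[col]]
    if (!is.numeric(x)) {
      x_num <- suppressWarnings(as.numeric(x))
      if (any(is.na(x_num) & !is.na(x) & nzchar(trimws(x))))
        stop("non-numeric cells in ", label, " column ", col,
             " of ", path, call. = FALSE)
      x <- x_num
    }
    # drop trailing missing values only
    while (length(x) > 0 && is.na(x[length(x)])) x <- x[-length(x)]
    if (anyNA(x))
      stop("missing values inside ", label, " column ", col,
           " of ", path, call. = FALSE)
    x
  }
  left <- pull(left_col, "left-stride")
  right <- pull(right_col, "right-stride")
  gait_record(subject_id, group, left, right)
}

#' Remove turnaround outliers from a stride-interval series
#'
#' Hallway walking protocols force a turnaround at each end of the walkway;
#' the affected strides are grossly inflated relative to steady-state
#' walking.  This removes every point lying outside
#' `median(x) +/- sd_mult * sd(x)` (default 3 SDs, SD taken over the raw
#' series including the outliers), returning the retained points in their
#' original order.
#'
#' @param x Numeric series, length >= 10 (shorter series cannot support a
#'   spread estimate and raise an error).
#' @param sd_mult Exclusion multiplier (default 3).
#' @return List with `series` (retained points), `removed` (indices
#'   removed), and `n_removed`.
#' @export
remove_outliers <- function(x, sd_mult = 3) {
  if (length(x) < 10)
    stop("series too short for outlier screening (need >= 10 points, got ",
         length(x), ")", call. = FALSE)
  keep <- abs(x - stats::median(x)) <= sd_mult * stats::sd(x)
  list(series = x[keep], removed = which(!keep), n_removed = sum(!keep))
}

#' Preprocess a gait record (paired outlier removal)
#'
#' Applies [remove_outliers()] to both limbs and removes the *union* of the
#' flagged indices from both series, so that the left/right pairing by
#' stride index is preserved.  (Removing each side independently would
#' desynchronise the limbs.)
#'
#' @param record A [gait_record].
#' @param sd_mult Exclusion multiplier (default 3).
#' @return The preprocessed [gait_record], with an `n_outliers_removed`
#'   attribute.
#' @export
preprocess_gait_record <- function(record, sd_mult = 3) {
  stopifnot(inherits(record, "gait_record"))
  bad <- union(remove_outliers(record$left_stride, sd_mult)$removed,
               remove_outliers(record$right_stride, sd_mult)$removed)
  out <- record
  if (length(bad)) {
    out$left_stride <- record$left_stride[-bad]
    out$right_stride <- record$right_stride[-bad]
  }
  attr(out, "n_outliers_removed") <- length(bad)
  out
}

#' Absolute symmetry index
#'
#' `ASI = 100 * (T_R - T_L) / (0.5 * (T_R + T_L))`, the classic clinical
#' bilateral symmetry measure for a scalar gait feature `T` computed per
#' limb (here, typically the mean stride interval).  Zero for perfect
#' symmetry; sign indicates the longer side; invariant to rescaling both
#' limbs by the same factor.
#'
#' @param t_left,t_right Scalar feature values for the left and right limb.
#' @return ASI in percent.
#' @examples
#' asi(1.0, 1.2)  # 18.18...
#' @export
asi <- function(t_left, t_right) {
  100 * (t_right - t_left) / (0.5 * (t_right + t_left))
}

#' Symmetry features for one subject
#'
#' Truncates the (preprocessed) left/right series to their first `N_use`
#' points and computes the three bilateral symmetry features: C-FuzzyEn and
#' C-SampleEn of the (left, right) pair, and the ASI of the mean stride
#' interval per side over the same window.
#'
#' @param record A preprocessed [gait_record] with at least `N_use` strides
#'   per side.
#' @param r Entropy tolerance in seconds (default 0.004).
#' @param m Embedding dimension (default 1 — appropriate for the short
#'   series typical of hallway protocols).
#' @param n Fuzzy gradient (default 2).
#' @param N_use Window length (default 150).
#' @return One-row tibble: `subject_id`, `group`, `cfuzzyen`, `csampleen`,
#'   `csampleen_defined`, `asi`, `T_L`, `T_R`, `n_used`.
#' @export
symmetry_features <- function(record, r = 0.004, m = 1, n = 2, N_use = 150) {
  stopifnot(inherits(record, "gait_record"))
  if (length(record$left_stride) < N_use || length(record$right_stride) < N_use)
    stop("subject ", record$subject_id, " has fewer than N_use = ", N_use,
         " strides after preprocessing (",
         min(length(record$left_stride), length(record$right_stride)), ")",
         call. = FALSE)
  l <- record$left_stride[seq_len(N_use)]
  rgt <- record$right_stride[seq_len(N_use)]
  cf <- cross_fuzzy_entropy(l, rgt, m = m, r = r, n = n)
  cs <- cross_sample_entropy(l, rgt, m = m, r = r)
  t_l <- mean(l)
  t_r <- mean(rgt)
  tibble::tibble(subject_id = record$subject_id, group = record$group,
                 cfuzzyen = cf$value, csampleen = cs$value,
                 csampleen_defined = cs$defined,
                 asi = asi(t_l, t_r), T_L = t_l, T_R = t_r, n_used = N_use)
}

#' Per-subject feature table for a cohort
#'
#' Preprocesses each record (paired outlier removal) and computes
#' [symmetry_features()], assembling the cohort feature table.
#'
#' @param records List of [gait_record]s.
#' @param preprocess Apply [preprocess_gait_record()] first (default TRUE).
#' @param sd_mult Outlier exclusion multiplier.
#' @inheritParams symmetry_features
#' @return Tibble with one row per subject, plus `n_outliers_removed`.
#' @export
gait_feature_table <- function(records, r = 0.004, m = 1, n = 2,
                               N_use = 150, preprocess = TRUE, sd_mult = 3) {
  do.call(rbind, lapply(records, function(rec) {
    n_out <- 0L
    if (preprocess) {
      rec <- preprocess_gait_record(rec, sd_mult)
      n_out <- attr(rec, "n_outliers_removed")
    }
    ft <- symmetry_features(rec, r = r, m = m, n = n, N_use = N_use)
    ft$n_outliers_removed <- n_out
    ft
  }))
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent groups.  The U statistic counts
#' pairs where a `group_a` value exceeds a `group_b` value (ties count
#' half).  With both groups of size <= 8 (or `exact = TRUE`) the two-sided
#' p-value is computed by exact enumeration of all label assignments; larger
#' groups use the tie-corrected normal approximation without continuity
#' correction.
#'
#' @param group_a,group_b Numeric vectors, each non-empty; ties allowed.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` (default) switches on both sizes <= 8.
#' @return List with `statistic` (U, a-over-b orientation), `p_value`, and
#'   `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(group_a, group_b, exact = NULL) {
  if (length(group_a) < 1 || length(group_b) < 1)
    stop("both groups must be non-empty", call. = FALSE)
  na <- length(group_a)
  nb <- length(group_b)
  pooled <- c(group_a, group_b)
  rk <- rank(pooled)
  # U via rank sum: U_a = R_a - na(na+1)/2 counts (a > b) pairs, ties half
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  use_exact <- if (is.null(exact)) (na <= 8 && nb <= 8) else isTRUE(exact)
  if (use_exact) {
    combs <- utils::combn(na + nb, na)
    Us <- colSums(matrix(rk[combs], nrow = na)) - na * (na + 1) / 2
    tol <- 1e-8
    p <- 2 * min(mean(Us <= U + tol), mean(Us >= U - tol))
    p <- min(1, p)
    method <- "exact enumeration"
  } else {
    ntot <- na + nb
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (ntot * (ntot - 1))
    sigma2 <- na * nb / 12 * ((ntot + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1  # all values tied: no evidence of a shift
    } else {
      z <- (U - na * nb / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation, tie-corrected"
  }
  list(statistic = U, p_value = p, method = method)
}

#' Default gait-screening tolerance grid
#'
#' \[0.0001 : 0.0001 : 0.001\] followed by \[0.002 : 0.001 : 0.01\]
#' (19 values), the fine grid appropriate to second-valued stride times.
#' The coarser \[0.01 : 0.01 : 0.1\] tail can be appended via
#' `include_coarse_tail = TRUE`.
#'
#' @param include_coarse_tail Append `seq(0.02, 0.1, 0.01)` (default FALSE).
#' @return Numeric vector of tolerances.
#' @export
gait_r_grid <- function(include_coarse_tail = FALSE) {
  g <- c(seq(1e-4, 1e-3, by = 1e-4), seq(2e-3, 0.01, by = 1e-3))
  if (include_coarse_tail) g <- c(g, seq(0.02, 0.1, by = 0.01))
  g
}

#' Tolerance selection by Mann-Whitney screening
#'
#' For each candidate tolerance, computes per-subject C-FuzzyEn on the
#' (left, right) pair and the two-sided Mann-Whitney p-value between the two
#' groups; returns the tolerance giving the smallest p together with the
#' full screening table.  Template distances are computed once per subject
#' and reused across the grid.
#'
#' @param records List of [gait_record]s covering exactly two groups, each
#'   with at least 3 subjects.
#' @param r_values Candidate tolerances (default [gait_r_grid()]).
#' @inheritParams gait_feature_table
#' @return List with `best_r`, `best_p`, and `table` (tibble of `r`, `U`,
#'   `p_value`).
#' @export
select_r <- function(records, r_values = gait_r_grid(), m = 1, n = 2,
                     N_use = 150, preprocess = TRUE, sd_mult = 3) {
  groups <- vapply(records, function(r) r$group, character(1))
  glev <- unique(groups)
  if (length(glev) != 2)
    stop("exactly two groups are required (got: ",
         paste(glev, collapse = ", "), ")", call. = FALSE)
  if (any(table(groups) < 3))
    stop("each group needs at least 3 subjects for the rank test",
         call. = FALSE)
  profiles <- vapply(records, function(rec) {
    if (preprocess) rec <- preprocess_gait_record(rec, sd_mult)
    if (length(rec$left_stride) < N_use)
      stop("subject ", rec$subject_id, " too short after preprocessing",
           call. = FALSE)
    cfuzzyen_profile(rec$left_stride[seq_len(N_use)],
                     rec$right_stride[seq_len(N_use)],
                     r_values = r_values, m = m, n = n)
  }, numeric(length(r_values)))
  if (length(r_values) == 1L) profiles <- matrix(profiles, nrow = 1L)
  tab <- do.call(rbind, lapply(seq_along(r_values), function(ir) {
    mw <- mann_whitney_u(profiles[ir, groups == glev[1]],
                         profiles[ir, groups == glev[2]])
    tibble::tibble(r = r_values[ir], U = mw$statistic, p_value = mw$p_value)
  }))
  best <- which.min(tab$p_value)
  list(best_r = tab$r[best], best_p = tab$p_value[best], table = tab)
}

#' Min-max normalisation to \[0, 1\]
#'
#' `(x - min) / (max - min)`; rank-preserving rescale used for boxplot-style
#' display of features on a common scale.  Errors when all values are
#' identical (zero range).
#'
#' @param x Numeric vector with at least 2 distinct values.
#' @return Numeric vector in \[0, 1\] with minimum 0 and maximum 1.
#' @export
min_max_normalize <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0)
    stop("all values identical: min-max normalisation undefined", call. = FALSE)
  (x - rng[1]) / diff(rng)
}
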