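as_measurement_matrix <- function(table) {
  if (is.data.frame(table)) table <- as.matrix(table)
  if (!is.matrix(table) || !is.numeric(table)) {
    abort("measurement table must be a numeric matrix or data frame.")
  }
  if (anyNA(table)) abort("measurement table has missing cells (complete design required).")
  if (nrow(table) < 2 || ncol(table) < 2) {
    abort("measurement table needs >= 2 subjects (rows) and >= 2 raters/sessions (columns).")
  }
  table
}

#' Two-way ANOVA mean squares of a subjects-by-raters table
#'
#' Decomposes a complete `n x k` table (n subjects as rows, k raters or
#' sessions as columns, one measurement per cell) into the mean squares the
#' intraclass correlation coefficients are built from: `ms_rows` (between
#' subjects), `ms_cols` (between raters), `ms_error` (subject-by-rater
#' residual), and `ms_within` (within-subject, pooling rater and residual
#' variation).
#'
#' @param table Numeric `n x k` matrix or data frame, no missing cells.
#' @return An object of class `mean_squares`: list with `ms_rows`, `ms_cols`,
#'   `ms_error`, `ms_within`, `n`, `k`.
#' @export
anova_mean_squares <- function(table) {
  m <- as_measurement_matrix(table)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_error <- sum((m - outer(row_means, col_means, "+") + grand)^2)
  ss_within <- sum(sweep(m, 1, row_means)^2)
  if (all(m == m[, 1])) {
    # Exactly identical replicate columns (the deterministic re-extraction
    # case): the column, interaction, and within-row sums are zero by
    # construction; avoid floating-point residue so ICC comes out exactly 1.
    ss_cols <- 0; ss_error <- 0; ss_within <- 0
  }
  structure(
    list(ms_rows = ss_rows / (n - 1),
         ms_cols = ss_cols / (k - 1),
         ms_error = ss_error / ((n - 1) * (k - 1)),
         ms_within = ss_within / (n * (k - 1)),
         n = n, k = k),
    class = "mean_squares"
  )
}

#' Intraclass correlation coefficient from a two-way ANOVA
#'
#' Single-measurement ICC from a complete subjects-by-raters table.
#' `model = "agreement"` is ICC(A,1): absolute agreement, penalizing systematic
#' rater offsets via the rater mean square. `model = "consistency"` is
#' ICC(C,1): consistency, invariant to adding a constant to any rater's column.
#'
#' \deqn{ICC(A,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))}
#' \deqn{ICC(C,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E)}
#'
#' Internally the estimate is formed from the moment-based variance components
#' `var_subject = (MS_R - MS_E)/k`, `var_rater = (MS_C - MS_E)/n`,
#' `var_error = MS_E`, each truncated at zero as is standard in moment
#' estimation. The truncation keeps the estimate in \[0, 1\] (the ICC measures
#' consistency on that scale) and guarantees `ICC(C,1) >= ICC(A,1)`, with
#' equality exactly when `MS_C <= MS_E`.
#'
#' A table whose cells are all identical (zero total variance, the perfect-
#' reproducibility case produced by deterministic re-extraction) is defined as
#' ICC = 1 and flagged `degenerate`.
#'
#' `strict = TRUE` evaluates the printed variants
#' `(MS_R - MS_E) / (MS_R + (k+1) MS_E + (k/n)(MS_C - MS_E))` and
#' `(MS_R - MS_W) / (MS_R + (k-1) MS_R)` instead; these are provided for
#' auditability only — the printed consistency form returns `1/k` rather than
#' 1 for identical columns, and the printed agreement form over-weights the
#' error term.
#'
#' @param table Numeric `n x k` matrix or data frame.
#' @param model `"agreement"` (A,1) or `"consistency"` (C,1).
#' @param strict Use the non-standard printed formulas (default `FALSE`).
#' @return An object of class `icc_result`: list with `value`, `model`
#'   (`"A1"`/`"C1"`), `group` (reproducibility bin), `degenerate`, `strict`,
#'   `mean_squares`, `n`, `k`.
#' @export
icc <- function(table, model = c("agreement", "consistency"), strict = FALSE) {
  model <- match.arg(model)
  ms <- anova_mean_squares(table)
  degenerate <- ms$ms_rows == 0 && ms$ms_cols == 0 && ms$ms_error == 0 &&
    ms$ms_within == 0
  if (degenerate) {
    value <- 1
  } else if (strict) {
    value <- if (model == "agreement") {
      (ms$ms_rows - ms$ms_error) /
        (ms$ms_rows + (ms$k + 1) * ms$ms_error +
           ms$k / ms$n * (ms$ms_cols - ms$ms_error))
    } else {
      (ms$ms_rows - ms$ms_within) / (ms$ms_rows + (ms$k - 1) * ms$ms_rows)
    }
  } else {
    var_subject <- max((ms$ms_rows - ms$ms_error) / ms$k, 0)
    var_rater <- max((ms$ms_cols - ms$ms_error) / ms$n, 0)
    var_error <- ms$ms_error
    denom <- if (model == "agreement") {
      var_subject + var_rater + var_error
    } else {
      var_subject + var_error
    }
    if (denom <= 0) abort("ICC undefined: non-positive denominator for a non-degenerate table.")
    value <- var_subject / denom
  }
  structure(
    list(value = value,
         model = if (model == "agreement") "A1" else "C1",
         group = if (value <= 1) categorize_icc(value) else NA_character_,
         degenerate = degenerate, strict = strict,
         mean_squares = ms, n = ms$n, k = ms$k),
    class = "icc_result"
  )
}

#' @rdname icc
#' @export
icc_agreement <- function(table, strict = FALSE) icc(table, "agreement", strict)

#' @rdname icc
#' @export
icc_consistency <- function(table, strict = FALSE) icc(table, "consistency", strict)

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s) = %.4f  [%s]%s\n",
              sub("1", ",1", x$model), x$value, x$group,
              if (x$degenerate) "  (degenerate: zero total variance)" else ""))
  invisible(x)
}

#' Reproducibility bin of an ICC value
#'
#' Bins: Poor `[-Inf, 0.4)`, Fair `[0.4, 0.6)`, Good `[0.6, 0.75)`, Excellent
#' `[0.75, 1]`. The interior cut points follow the conventional reproducibility
#' grouping; boundaries are half-open so every value lands in exactly one bin.
#'
#' @param value Numeric ICC value(s), each <= 1.
#' @return Character vector of bins (factor levels Poor < Fair < Good <
#'   Excellent available via [icc_bins()]).
#' @export
categorize_icc <- function(value) {
  if (any(value > 1 + 1e-12)) abort("ICC values must be <= 1.")
  dplyr::case_when(
    value < 0.4 ~ "Poor",
    value < 0.6 ~ "Fair",
    value < 0.75 ~ "Good",
    TRUE ~ "Excellent"
  )
}

#' @rdname categorize_icc
#' @export
icc_bins <- function() c("Poor", "Fair", "Good", "Excellent")

#' Wilcoxon rank-sum test (two-sided)
#'
#' Midranks are used for ties. When `length(x) + length(y) <= 12` the p-value
#' is exact, from full enumeration of the rank-sum permutation distribution
#' (valid with or without ties); otherwise a normal approximation with tie
#' correction and continuity correction is used. The statistic is the rank sum
#' of `x` in the pooled sample.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `statistic` (rank sum of `x`), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) abort("both samples must be non-empty.")
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  w <- sum(r[seq_len(nx)])
  mu <- nx * (nx + ny + 1) / 2
  if (nx + ny <= 12) {
    sums <- combn(r, nx, sum)
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- nx * ny / 12 *
      ((nx + ny + 1) - sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
      p <- min(2 * pnorm(-max(z, 0)), 1)
    }
    method <- "normal approximation with tie and continuity correction"
  }
  list(statistic = w, p_value = p, method = method)
}

#' Feature-stability report across segmentation arms
#'
#' Computes, for every feature of every arm, the single-measurement ICC of its
#' subjects-by-replicates table, bins the values into reproducibility groups,
#' and summarizes each arm (group counts and percentages, mean and population
#' SD of ICC). Arms are compared pairwise with the two-sided Wilcoxon rank-sum
#' test on their per-feature ICC values.
#'
#' @param measurements Long-format data frame with columns `subject`, `arm`,
#'   `feature`, `replicate` (rater/session label), `value`. Every
#'   (arm, feature) cell must form a complete subjects-by-replicates table and
#'   all arms must share the same feature set.
#' @param model ICC model, `"agreement"` or `"consistency"`.
#' @param strict Use the printed-formula variants (see [icc()]).
#' @return An object of class `stability_report`: list with tibbles `icc`
#'   (arm, feature, icc, group, degenerate), `bin_counts` (arm, group, n_features,
#'   pct), `summary` (arm, n_features, mean_icc, sd_icc), `pairwise`
#'   (arm1, arm2, statistic, p_value), and `model`.
#' @export
stability_report <- function(measurements, model = c("agreement", "consistency"),
                             strict = FALSE) {
  model <- match.arg(model)
  required <- c("subject", "arm", "feature", "replicate", "value")
  missing_cols <- setdiff(required, names(measurements))
  if (length(missing_cols)) {
    abort(paste0("`measurements` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  arms <- unique(measurements$arm)
  feats_by_arm <- lapply(arms, function(a) {
    sort(unique(measurements$feature[measurements$arm == a]))
  })
  ref <- feats_by_arm[[1]]
  for (i in seq_along(arms)[-1]) {
    miss <- union(setdiff(ref, feats_by_arm[[i]]), setdiff(feats_by_arm[[i]], ref))
    if (length(miss)) {
      abort(paste0("feature registry mismatch between arms '", arms[1], "' and '",
                   arms[i], "': ", paste(miss, collapse = ", ")))
    }
  }

  icc_tbl <- measurements |>
    dplyr::group_by(.data$arm, .data$feature) |>
    dplyr::group_modify(function(d, key) {
      wide <- tidyr::pivot_wider(d[, c("subject", "replicate", "value")],
                                 names_from = "replicate", values_from = "value")
      m <- as.matrix(wide[, -1, drop = FALSE])
      fit <- icc(m, model = model, strict = strict)
      tibble(icc = fit$value, group = fit$group, degenerate = fit$degenerate)
    }) |>
    dplyr::ungroup()

  bin_counts <- icc_tbl |>
    dplyr::mutate(group = factor(.data$group, levels = icc_bins())) |>
    dplyr::count(.data$arm, .data$group, name = "n_features", .drop = FALSE) |>
    dplyr::group_by(.data$arm) |>
    dplyr::mutate(pct = 100 * .data$n_features / sum(.data$n_features)) |>
    dplyr::ungroup()

  summary_tbl <- icc_tbl |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      n_features = dplyr::n(),
      mean_icc = mean(.data$icc),
      sd_icc = sqrt(mean((.data$icc - mean(.data$icc))^2)),
      .groups = "drop"
    )

  pairwise <- if (length(arms) < 2) {
    tibble(arm1 = character(), arm2 = character(),
           statistic = numeric(), p_value = numeric())
  } else {
    pairs <- combn(as.character(arms), 2)
    purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      a1 <- pairs[1, j]; a2 <- pairs[2, j]
      wt <- wilcoxon_rank_sum(icc_tbl$icc[icc_tbl$arm == a1],
                              icc_tbl$icc[icc_tbl$arm == a2])
      tibble(arm1 = a1, arm2 = a2, statistic = wt$statistic,
             p_value = wt$p_value)
    })
  }

  structure(
    list(icc = icc_tbl, bin_counts = bin_counts, summary = summary_tbl,
         pairwise = pairwise, model = if (model == "agreement") "A1" else "C1"),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Feature stability report  [ICC(%s)]\n", sub("1", ",1", x$model)))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %s: mean ICC %.3f +/- %.3f over %d features\n",
                x$summary$arm[i], x$summary$mean_icc[i], x$summary$sd_icc[i],
                x$summary$n_features[i]))
  }
  invisible(x)
}

#' @rdname icc
#' @param x An `icc_result`.
#' @param ... Unused.
#' @method tidy icc_result
#' @export
tidy.icc_result <- function(x, ...) {
  tibble(model = x$model, icc = x$value, group = x$group,
         degenerate = x$degenerate,
         ms_rows = x$mean_squares$ms_rows, ms_cols = x$mean_squares$ms_cols,
         ms_error = x$mean_squares$ms_error, ms_within = x$mean_squares$ms_within,
         n_subjects = x$n, n_raters = x$k)
}

#' @rdname icc
#' @method glance icc_result
#' @export
glance.icc_result <- function(x, ...) {
  tibble(model = x$model, icc = x$value, group = x$group,
         n_subjects = x$n, n_raters = x$k)
}

#' @rdname stability_report
#' @param x A `stability_report`.
#' @param ... Unused.
#' @method tidy stability_report
#' @export
tidy.stability_report <- function(x, ...) x$icc

#' @rdname stability_report
#' @method glance stability_report
#' @export
glance.stability_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$bin_counts[, c("arm", "group", "n_features")],
    names_from = "group", values_from = "n_features"
  )
  dplyr::left_join(x$summary, wide, by = "arm")
}
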