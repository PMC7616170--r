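# Outcome statistics: empirical ROC with Youden-J optimal cutoffs, Pearson
# correlation and paired between-threshold differences.

#' Youden's J statistic
#'
#' @param sensitivity,specificity Fractions in `[0, 1]`.
#' @return `sensitivity + specificity - 1`.
#' @export
j_statistic <- function(sensitivity, specificity) {
  sensitivity + specificity - 1
}

#' Empirical ROC analysis of a scar metric against a binary outcome
#'
#' The AUC is computed with the rank (Mann-Whitney) formulation, ties
#' contributing one half — the probability that a randomly chosen positive
#' case scores above a randomly chosen negative one. Candidate cutoffs are
#' the midpoints between consecutive sorted unique metric values plus the
#' two infinities; sensitivity and specificity are evaluated at each
#' candidate under the stated direction, and the Youden-optimal operating
#' point is selected by [youden_optimal()].
#'
#' @param values Numeric metric, one per patient; no missing values.
#' @param labels Binary outcome (0/1 or logical), both classes present.
#' @param direction `"higher_predicts_positive"` (default: large metric
#'   values call the outcome) or `"lower_predicts_positive"`.
#' @return An object of class `roc_result`: `auc`, `direction`, `curve`
#'   (data.frame of cutoff / sensitivity / specificity / j), the selected
#'   `cutoff`, `sensitivity`, `specificity`, `j_statistic`, `n_pos`,
#'   `n_neg`, and an asymptotic (Hanley-McNeil) `p_value` for AUC = 0.5.
#' @export
empirical_roc <- function(values, labels,
                          direction = c("higher_predicts_positive",
                                        "lower_predicts_positive")) {
  direction <- match.arg(direction)
  if (anyNA(values) || anyNA(labels)) {
    stop("missing values are not allowed", call. = FALSE)
  }
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be binary (0/1)", call. = FALSE)
  }
  if (length(values) != length(labels)) {
    stop("values and labels must have equal length", call. = FALSE)
  }
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both outcome classes must be present", call. = FALSE)
  }

  score <- if (direction == "higher_predicts_positive") values else -values
  r <- rank(score, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  u <- sort(unique(values))
  cand <- if (length(u) > 1) {
    c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf)
  } else {
    c(-Inf, Inf)
  }
  iu <- match(values, u)
  pos_at <- tabulate(iu[labels == 1L], length(u))
  neg_at <- tabulate(iu[labels == 0L], length(u))
  if (direction == "higher_predicts_positive") {
    # predicted positive iff value >= cutoff
    pos_ge <- rev(cumsum(rev(pos_at)))  # positives with value >= u[i]
    neg_ge <- rev(cumsum(rev(neg_at)))
    sens <- c(1, pos_ge[-1] / n1, 0)
    spec <- c(0, 1 - neg_ge[-1] / n0, 1)
  } else {
    # predicted positive iff value <= cutoff
    pos_le <- cumsum(pos_at)
    neg_le <- cumsum(neg_at)
    sens <- c(0, pos_le[-length(u)] / n1, 1)
    spec <- c(1, 1 - neg_le[-length(u)] / n0, 0)
  }
  if (length(u) == 1) {
    sens <- if (direction == "higher_predicts_positive") c(1, 0) else c(0, 1)
    spec <- if (direction == "higher_predicts_positive") c(0, 1) else c(1, 0)
  }
  curve <- data.frame(cutoff = cand, sensitivity = sens,
                      specificity = spec,
                      j = j_statistic(sens, spec))

  # Hanley-McNeil asymptotic test of AUC = 0.5 (reported for convenience).
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  p <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se) else NA_real_

  res <- structure(
    list(auc = auc, direction = direction, curve = curve,
         cutoff = NA_real_, sensitivity = NA_real_,
         specificity = NA_real_, j_statistic = NA_real_,
         n_pos = n1, n_neg = n0, p_value = p),
    class = "roc_result"
  )
  youden_optimal(res)
}

#' Select the Youden-optimal operating point of a ROC curve
#'
#' Picks the candidate cutoff maximizing J = sensitivity + specificity - 1.
#' Ties are broken toward the cutoff with the highest sensitivity (the
#' operating point "with the highest possible sensitivity"), then toward
#' the lower cutoff value.
#'
#' @param roc A `roc_result` (its `curve` is reused; the selected operating
#'   point is overwritten).
#' @return The `roc_result` with `cutoff`, `sensitivity`, `specificity` and
#'   `j_statistic` set.
#' @export
youden_optimal <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  cv <- roc$curve
  ord <- order(-cv$j, -cv$sensitivity, cv$cutoff)
  best <- cv[ord[1], ]
  roc$cutoff <- best$cutoff
  roc$sensitivity <- best$sensitivity
  roc$specificity <- best$specificity
  roc$j_statistic <- best$j
  roc
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%d pos / %d neg, %s)\n",
              x$auc, x$n_pos, x$n_neg, x$direction))
  cat(sprintf("  Youden cutoff %.4g: sens %.3f, spec %.3f, J = %.3f\n",
              x$cutoff, x$sensitivity, x$specificity, x$j_statistic))
  invisible(x)
}

#' Pearson correlation between a scar metric and an outcome
#'
#' Standard product-moment coefficient via [stats::cor.test()], wrapped in
#' the contract used by the reporting layer (errors on degenerate input
#' rather than returning `NA`).
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, both with nonzero
#'   variance.
#' @return A list of class `correlation_result` with `r`, `n`, `p_value`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), n = length(x),
                 p_value = ct$p.value),
            class = "correlation_result")
}

#' Paired mean difference with t-based confidence interval
#'
#' Mean of the within-patient differences `a - b` with a t-interval, for
#' comparing one scar metric between two threshold configurations on the
#' same patients. With `m_comparisons > 1` the interval is
#' Bonferroni-scaled.
#'
#' @param a,b Numeric vectors of equal length (complete pairs, `n >= 2`).
#' @param conf_level Nominal confidence level before Bonferroni scaling.
#' @param m_comparisons Number of simultaneous comparisons.
#' @return A list of class `paired_difference` with `mean_diff`, `ci95`
#'   (length-2), `n_pairs`, `conf_level`, `m_comparisons`.
#' @export
paired_difference <- function(a, b, conf_level = 0.95, m_comparisons = 1L) {
  if (length(a) != length(b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("pairs must be complete", call. = FALSE)
  n <- length(a)
  if (n < 2) stop("need n >= 2 pairs", call. = FALSE)
  d <- a - b
  m <- mean(d)
  se <- stats::sd(d) / sqrt(n)
  alpha <- (1 - conf_level) / m_comparisons
  tq <- stats::qt(1 - alpha / 2, df = n - 1)
  structure(
    list(mean_diff = m, ci95 = c(m - tq * se, m + tq * se),
         n_pairs = n, conf_level = conf_level,
         m_comparisons = m_comparisons),
    class = "paired_difference"
  )
}

#' @export
print.paired_difference <- function(x, ...) {
  cat(sprintf("<paired_difference> %.3g [%.0f%% CI %.3g to %.3g], n = %d\n",
              x$mean_diff, 100 * x$conf_level, x$ci95[1], x$ci95[2],
              x$n_pairs))
  invisible(x)
}

#' ROC summary table across metrics and threshold configurations
#'
#' For every scar metric and threshold configuration in the cohort,
#' computes the AUC against recurrence; for metrics whose AUC exceeds the
#' gate (strictly greater than 0.7 by default), the Youden-optimal cutoff,
#' sensitivity, specificity and J are reported, otherwise those cells stay
#' blank.
#'
#' @param cohort A `cohort_table` (or data.frame) with a binary
#'   `recurrence` column and metric columns named `<metric>_<config id>`.
#' @param metrics Character vector of base metric names.
#' @param configs List of [threshold_config()] (defaults to the four
#'   presets); only their `id`s are used.
#' @param auc_gate Operating points are reported only when `auc > auc_gate`.
#' @param direction Passed to [empirical_roc()].
#' @return A data.frame with one row per metric x configuration: `metric`,
#'   `config`, `auc`, `p_value`, `cutoff`, `sensitivity`, `specificity`,
#'   `j_statistic`.
#' @export
table3_report <- function(cohort,
                          metrics = c("total_enhancement_g", "bz_mass_g",
                                      "scar_g", "total_corridors",
                                      "corridor_mass_g",
                                      "surface_healthy_he_cm2",
                                      "surface_bz_core_cm2"),
                          configs = psi_threshold_presets(),
                          auc_gate = 0.7,
                          direction = "higher_predicts_positive") {
  if (!"recurrence" %in% names(cohort)) {
    stop("cohort must have a 'recurrence' column", call. = FALSE)
  }
  y <- cohort$recurrence
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop("need at least 2 patients per outcome class", call. = FALSE)
  }
  ids <- vapply(configs, `[[`, "", "id")
  rows <- list()
  for (m in metrics) {
    for (id in ids) {
      col <- paste0(m, "_", id)
      if (!col %in% names(cohort)) next
      roc <- empirical_roc(cohort[[col]], y, direction = direction)
      gated <- roc$auc > auc_gate
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, config = id, auc = roc$auc, p_value = roc$p_value,
        cutoff = if (gated) roc$cutoff else NA_real_,
        sensitivity = if (gated) roc$sensitivity else NA_real_,
        specificity = if (gated) roc$specificity else NA_real_,
        j_statistic = if (gated) roc$j_statistic else NA_real_
      )
    }
  }
  do.call(rbind, rows)
}
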