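#' Multi-reader agreement statistics
#'
#' Measurements live in a tidy table with one row per (lesion_id, reader_id,
#' session) and an `adc_value` column, a complete block design per session:
#' every reader measured every lesion. Agreement among readers is summarised
#' Bland-Altman style against the per-lesion mean across readers; agreement
#' with the computed reference is an intraclass correlation; measurement
#' methods (sessions) are compared on their absolute deviations with a
#' Friedman omnibus test and Holm-adjusted Wilcoxon post-hocs.
#'
#' @name agreement_stats
NULL

check_complete_block <- function(table, session) {
  tab <- table[table$session == session, , drop = FALSE]
  if (nrow(tab) == 0) stop("no rows for session ", session)
  lesions <- sort(unique(table$lesion_id))
  readers <- sort(unique(table$reader_id))
  want <- expand.grid(lesion_id = lesions, reader_id = readers,
                      stringsAsFactors = FALSE)
  key <- paste(tab$lesion_id, tab$reader_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (lesion, reader) cells in session ", session)
  }
  missing <- want[!paste(want$lesion_id, want$reader_id, sep = "\r") %in% key, ,
                  drop = FALSE]
  if (nrow(missing) > 0) {
    stop("incomplete block for session ", session, "; missing cells: ",
         paste(sprintf("(lesion %s, reader %s)", missing$lesion_id,
                       missing$reader_id)[seq_len(min(5, nrow(missing)))],
               collapse = ", "),
         if (nrow(missing) > 5) sprintf(" and %d more", nrow(missing) - 5))
  }
  tab
}

#' Multi-reader Bland-Altman limits of agreement
#'
#' Differences are taken from the per-lesion mean across readers, so the bias
#' is zero by construction and the 95% limits of agreement are +/- 1.96 times
#' the SD of the pooled differences. No small-sample or reader-count
#' inflation correction is applied — the plotted quantity is exactly these
#' differences. The SD denominator is the sample estimator by default
#' (`sd_denominator = "n-1"`); `"n"` gives the population form (at 400
#' differences they differ by about 0.1%).
#'
#' @param table Tidy measurement data.frame (lesion_id, reader_id, session,
#'   adc_value).
#' @param session Session to analyse (1, 2 or 3).
#' @param sd_denominator `"n-1"` (sample SD) or `"n"`.
#' @return An object of class `adc_agreement`: bias, sd_diff,
#'   loa_half_width, and the per-(lesion, reader) differences for downstream
#'   method comparison.
#' @export
bland_altman_multireader <- function(table, session,
                                     sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  if (length(unique(table$reader_id)) < 2) stop("need >= 2 readers")
  if (length(unique(table$lesion_id)) < 2) stop("need >= 2 lesions")
  tab <- check_complete_block(table, session)
  lesion_mean <- tapply(tab$adc_value, tab$lesion_id, mean)
  diffs <- tab$adc_value - lesion_mean[as.character(tab$lesion_id)]
  n <- length(diffs)
  sd_diff <- if (sd_denominator == "n-1") stats::sd(diffs) else {
    sqrt(sum((diffs - mean(diffs))^2) / n)
  }
  structure(
    list(session = session,
         bias = mean(diffs),
         sd_diff = sd_diff,
         loa_half_width = 1.96 * sd_diff,
         n = n,
         deviations = data.frame(lesion_id = tab$lesion_id,
                                 reader_id = tab$reader_id,
                                 mean_adc = unname(
                                   lesion_mean[as.character(tab$lesion_id)]),
                                 diff = unname(diffs))),
    class = "adc_agreement"
  )
}

#' @export
print.adc_agreement <- function(x, ...) {
  cat(sprintf(
    "<adc_agreement> session %s: 95%% limits of agreement +/- %.1f (SD %.1f, n = %d)\n",
    x$session, x$loa_half_width, x$sd_diff, x$n))
  invisible(x)
}

#' Intraclass correlation against a reference
#'
#' ICC between one reader's per-lesion values and the computed reference,
#' treated as two raters of the same lesions. The default form is two-way
#' random effects, absolute agreement, single measures — ICC(2,1) — which
#' penalises a fixed reader bias; `model = "ICC3"` gives the two-way mixed,
#' consistency form. Confidence intervals use the standard F-based
#' (McGraw-Wong) construction.
#'
#' @param reader_values Numeric vector of one reader's per-lesion values.
#' @param reference_values Reference values for the same lesions, same order.
#' @param model `"ICC2"` (absolute agreement) or `"ICC3"` (consistency).
#' @param conf_level Confidence level for the interval.
#' @return List with estimate, ci_low, ci_high, model_tag, n.
#' @export
icc_vs_reference <- function(reader_values, reference_values,
                             model = c("ICC2", "ICC3"), conf_level = 0.95) {
  model <- match.arg(model)
  x <- cbind(reader_values, reference_values)
  if (length(reader_values) != length(reference_values)) {
    stop("reader and reference vectors must have equal length")
  }
  n <- nrow(x)
  if (n < 3) stop("need >= 3 lesions for an ICC")
  if (any(!is.finite(x))) stop("values must be finite")
  if (stats::var(as.vector(x)) == 0) stop("zero total variance: ICC undefined")
  k <- 2
  subj_means <- rowMeans(x)
  rater_means <- colMeans(x)
  grand <- mean(x)
  MSB <- k * sum((subj_means - grand)^2) / (n - 1)       # between subjects
  MSJ <- n * sum((rater_means - grand)^2) / (k - 1)      # between raters
  resid <- x - outer(subj_means, rep(1, k)) -
    outer(rep(1, n), rater_means) + grand
  MSE <- sum(resid^2) / ((n - 1) * (k - 1))
  alpha <- 1 - conf_level
  if (model == "ICC3") {
    est <- (MSB - MSE) / (MSB + (k - 1) * MSE)
    F3 <- MSB / MSE
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
    FL <- F3 / stats::qf(1 - alpha / 2, df1, df2)
    FU <- F3 * stats::qf(1 - alpha / 2, df2, df1)
    lo <- (FL - 1) / (FL + k - 1)
    hi <- (FU - 1) / (FU + k - 1)
  } else {
    est <- (MSB - MSE) / (MSB + (k - 1) * MSE + k * (MSJ - MSE) / n)
    # McGraw & Wong (1996) CI for ICC(A,1)
    Fj <- MSJ / MSE
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * Fj + b)^2 /
      (a^2 * Fj^2 / (k - 1) + b^2 / ((n - 1) * (k - 1)))
    F2U <- stats::qf(1 - alpha / 2, n - 1, v)
    F2L <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (MSB - F2U * MSE) /
      (F2U * (k * MSJ + (k * n - k - n) * MSE) + n * MSB)
    hi <- n * (F2L * MSB - MSE) /
      (k * MSJ + (k * n - k - n) * MSE + n * F2L * MSB)
  }
  list(estimate = est, ci_low = lo, ci_high = hi,
       model_tag = if (model == "ICC2") {
         "two-way random, absolute agreement, single measures"
       } else "two-way mixed, consistency, single measures",
       n = n)
}

#' Per-session absolute deviations for method comparison
#'
#' For each session, each reader's difference from the per-lesion multi-reader
#' mean is computed as in [bland_altman_multireader()]; the absolute
#' deviations are returned as blocks for the Friedman test. Default blocks
#' are (lesion, reader) cells; `block = "lesion"` averages the absolute
#' deviations over readers first.
#'
#' @inheritParams bland_altman_multireader
#' @param sessions Sessions forming the method columns.
#' @param block `"lesion_reader"` or `"lesion"`.
#' @return Numeric matrix, one column per session, one row per block.
#' @export
method_deviation_table <- function(table, sessions = c(1, 2, 3),
                                   block = c("lesion_reader", "lesion")) {
  block <- match.arg(block)
  cols <- lapply(sessions, function(s) {
    dev <- bland_altman_multireader(table, s)$deviations
    dev <- dev[order(dev$lesion_id, dev$reader_id), , drop = FALSE]
    if (block == "lesion") {
      tapply(abs(dev$diff), dev$lesion_id, mean)
    } else {
      stats::setNames(abs(dev$diff),
                      paste(dev$lesion_id, dev$reader_id, sep = ":"))
    }
  })
  m <- do.call(cbind, cols)
  colnames(m) <- paste0("session", sessions)
  m
}

#' Friedman test across measurement methods
#'
#' Omnibus test that the absolute deviations differ across methods
#' (sessions), blocks being lesions or lesion-reader cells. Mid-ranks are
#' used for ties (via [stats::friedman.test()]).
#'
#' @param deviation_table Matrix from [method_deviation_table()] (blocks x
#'   methods).
#' @return List with statistic, df, p_value.
#' @export
friedman_across_methods <- function(deviation_table) {
  if (!is.matrix(deviation_table) || ncol(deviation_table) < 2) {
    stop("`deviation_table` must be a matrix with >= 2 method columns")
  }
  if (any(!is.finite(deviation_table))) stop("incomplete blocks (non-finite)")
  ft <- stats::friedman.test(deviation_table)
  stat <- unname(ft$statistic)
  p <- ft$p.value
  if (is.nan(stat)) {   # every block fully tied: no evidence of a difference
    stat <- 0
    p <- 1
  }
  list(statistic = stat, df = unname(ft$parameter), p_value = p)
}

#' Pairwise post-hoc tests with Holm adjustment
#'
#' Wilcoxon tests between method columns, Holm (step-down Bonferroni)
#' adjusted. The published analysis names the rank-sum (unpaired) flavor, so
#' that is the default even though the blocks are paired;
#' `flavor = "signed_rank"` gives the paired test.
#'
#' @inheritParams friedman_across_methods
#' @param pairs List of 2-element column index/name pairs; default all pairs.
#' @param flavor `"rank_sum"` (Mann-Whitney) or `"signed_rank"` (paired).
#' @return data.frame with columns pair, p_raw, p_adj.
#' @export
posthoc_pairwise <- function(deviation_table, pairs = NULL,
                             flavor = c("rank_sum", "signed_rank")) {
  flavor <- match.arg(flavor)
  if (!is.matrix(deviation_table) || ncol(deviation_table) < 2) {
    stop("need >= 2 method columns")
  }
  cn <- colnames(deviation_table)
  if (is.null(pairs)) {
    pairs <- utils::combn(ncol(deviation_table), 2, simplify = FALSE)
  }
  p_raw <- vapply(pairs, function(pr) {
    stats::wilcox.test(deviation_table[, pr[1]], deviation_table[, pr[2]],
                       paired = flavor == "signed_rank",
                       exact = FALSE)$p.value
  }, numeric(1))
  data.frame(
    pair = vapply(pairs, function(pr) {
      paste(cn[unlist(pr)], collapse = " vs ")
    }, character(1)),
    p_raw = p_raw,
    p_adj = stats::p.adjust(p_raw, method = "holm")
  )
}

#' Unpaired two-group comparison
#'
#' Two-sample t-test for group contrasts such as scanner model or endorectal
#' coil use. Welch's unequal-variance form by default; `var_equal = TRUE`
#' gives the Student form.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param var_equal Assume equal variances.
#' @return List with t, p_value, mean_a, mean_b, df.
#' @export
unpaired_group_test <- function(values_a, values_b, var_equal = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs n >= 2")
  }
  tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_a = mean(values_a), mean_b = mean(values_b),
       df = unname(tt$parameter))
}

#' Full agreement report for a reader study
#'
#' Runs the whole statistical battery on a measurement table and its
#' reference values: per-session limits of agreement, per-reader ICC against
#' the matching reference column (the 9-pixel minimum-mean for sessions 1-2,
#' the whole-lesion 10th percentile for session 3), the Friedman omnibus on
#' absolute deviations, and the Holm-adjusted post-hocs.
#'
#' @param measurements Tidy measurement table (lesion_id, reader_id, session,
#'   adc_value, ...).
#' @param reference data.frame with columns lesion_id, ref_9px, ref_p10.
#' @param icc_model Passed to [icc_vs_reference()].
#' @return List with elements `loa`, `icc`, `friedman`, `posthoc`.
#' @export
agreement_report <- function(measurements, reference, icc_model = "ICC2") {
  sessions <- sort(unique(measurements$session))
  loa <- lapply(sessions, function(s) {
    ba <- bland_altman_multireader(measurements, s)
    list(session = s, bias = ba$bias, sd_diff = ba$sd_diff,
         loa_half_width = ba$loa_half_width, n = ba$n)
  })
  readers <- sort(unique(measurements$reader_id))
  icc_rows <- list()
  for (s in sessions) {
    ref_col <- if (s == 3) "ref_p10" else "ref_9px"
    for (r in readers) {
      sub <- measurements[measurements$session == s &
                            measurements$reader_id == r, , drop = FALSE]
      sub <- sub[order(sub$lesion_id), , drop = FALSE]
      ref <- reference[match(sub$lesion_id, reference$lesion_id), ref_col]
      icc <- icc_vs_reference(sub$adc_value, ref, model = icc_model)
      icc_rows[[length(icc_rows) + 1]] <- data.frame(
        session = s, reader_id = r, icc = icc$estimate,
        ci_low = icc$ci_low, ci_high = icc$ci_high,
        bias = mean(sub$adc_value - ref))
    }
  }
  icc_tab <- do.call(rbind, icc_rows)
  dev <- method_deviation_table(measurements, sessions)
  list(loa = loa,
       icc = icc_tab,
       friedman = friedman_across_methods(dev),
       posthoc = posthoc_pairwise(dev))
}

#' Bland-Altman plot of one session
#'
#' Differences from the per-lesion multi-reader mean against that mean, with
#' the zero bias line and the 95% limits of agreement. Requires ggplot2.
#'
#' @inheritParams bland_altman_multireader
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(table, session) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ba <- bland_altman_multireader(table, session)
  d <- ba$deviations
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_adc, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * ba$loa_half_width,
                        linetype = 2) +
    ggplot2::labs(
      x = expression(paste("Mean ADC across readers (", 10^-6, " ", mm^2,
                           "/s)")),
      y = "Difference from lesion mean",
      title = sprintf("Session %s: limits of agreement %s %.0f",
                      session, "±", ba$loa_half_width)) +
    ggplot2::theme_minimal()
}
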