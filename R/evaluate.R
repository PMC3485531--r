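#' Per-patient metric table for a cohort
#'
#' Runs [analyze_study()] on every baseline and follow-up study and
#' assembles one row per patient: all scalar metrics at both time points,
#' the percent ESV change, and the responder flag from
#' [classify_response()].
#'
#' @param cohort An `stv_cohort` from [simulate_cohort()], or a plain list
#'   of patient entries each holding `patient_id`, `baseline` and
#'   `followup` [curve_set()]s.
#' @param n_samples,sdi_divisor Passed to [analyze_study()].
#' @return data.frame with columns `patient_id`, `<metric>_baseline`,
#'   `<metric>_followup` for the eight scalar metrics, `delta_esv_pct`,
#'   `responder`, and (when present in the input) `true_responder`.
#' @export
cohort_metrics <- function(cohort, n_samples = 201L,
                           sdi_divisor = c("n_minus_1", "n")) {
  sdi_divisor <- match.arg(sdi_divisor)
  patients <- if (inherits(cohort, "stv_cohort")) cohort$patients else cohort
  rows <- lapply(patients, function(p) {
    rb <- analyze_study(p$baseline, n_samples, sdi_divisor)
    cb <- coef(rb)
    names(cb) <- paste0(names(cb), "_baseline")
    row <- data.frame(patient_id = p$patient_id, t(cb))
    if (!is.null(p$followup)) {
      rf <- analyze_study(p$followup, n_samples, sdi_divisor)
      cf <- coef(rf)
      names(cf) <- paste0(names(cf), "_followup")
      cls <- classify_response(rb$esv, rf$esv)
      row <- cbind(row, t(cf),
                   data.frame(delta_esv_pct = cls$delta_esv_pct,
                              responder = cls$responder))
    }
    if (!is.null(p$true_responder)) row$true_responder <- p$true_responder
    row
  })
  do.call(rbind, rows)
}

#' Evaluate baseline dyssynchrony markers as predictors of CRT response
#'
#' The full evaluation pipeline on a paired cohort: classifies responders
#' by the >= 10% ESV-reduction rule, then for each baseline marker computes
#' the ROC curve with AUC, Hanley-McNeil CI and Youden cutoff
#' (sensitivity/specificity/NPV/PPV), the responder vs non-responder group
#' comparison (Student t), and the Pearson correlation with percent ESV
#' change. Also reports the DeLong paired comparison of the Pre-STV AUC
#' against the SDI AUC, the study's head-to-head question.
#'
#' @param cohort An `stv_cohort`, a list of patient entries (see
#'   [cohort_metrics()]), or a precomputed metric data.frame with
#'   `responder`, `delta_esv_pct` and `<metric>_baseline` columns.
#' @param metrics Baseline markers to evaluate.
#' @param directions Named character vector of ROC directions per metric;
#'   unlisted metrics default to `"higher_is_positive"`. Directions are
#'   never auto-flipped.
#' @param t_test Passed to [group_compare()].
#' @param n_samples,sdi_divisor Passed to [analyze_study()] when raw curve
#'   sets are supplied.
#' @return Object of class `stv_eval`: list with `table` (the per-patient
#'   data.frame), `markers` (per-metric list of `roc`, `group_comparison`,
#'   `correlation`), `auc_comparison` (Pre-STV vs SDI, when both present),
#'   `n_responders`, `n_non_responders`.
#' @export
evaluate_cohort <- function(cohort,
                            metrics = c("pre_stv", "post_stv", "sdi", "le"),
                            directions = character(),
                            t_test = c("student", "welch"),
                            n_samples = 201L,
                            sdi_divisor = c("n_minus_1", "n")) {
  t_test <- match.arg(t_test)
  tab <- if (is.data.frame(cohort)) cohort
         else cohort_metrics(cohort, n_samples, sdi_divisor)
  if (!"responder" %in% names(tab))
    stop("cohort has no follow-up studies: responder status unavailable")
  labels <- as.logical(tab$responder)
  markers <- list()
  for (m in metrics) {
    col <- paste0(m, "_baseline")
    if (!col %in% names(tab)) stop("metric column '", col, "' not found")
    dir <- if (m %in% names(directions)) directions[[m]]
           else "higher_is_positive"
    markers[[m]] <- list(
      roc = roc_curve(tab[[col]], labels, direction = dir),
      group_comparison = group_compare(tab, m, t_test = t_test),
      correlation = correlate_remodelling(tab[[col]], tab$delta_esv_pct))
  }
  auc_cmp <- NULL
  if (all(c("pre_stv", "sdi") %in% metrics))
    auc_cmp <- compare_auc_paired(tab$pre_stv_baseline, tab$sdi_baseline,
                                  labels)
  structure(list(table = tab, markers = markers, auc_comparison = auc_cmp,
                 n_responders = sum(labels),
                 n_non_responders = sum(!labels)),
            class = "stv_eval")
}

#' @export
print.stv_eval <- function(x, ...) {
  cat(sprintf("CRT response evaluation: %d responders / %d non-responders\n",
              x$n_responders, x$n_non_responders))
  for (m in names(x$markers)) {
    mk <- x$markers[[m]]
    cat(sprintf(
      "  %-9s AUC %.2f (%.2f-%.2f)  cutoff %6.2f  sens %5.1f%%  spec %5.1f%%  r(dESV) %+.2f (p=%.3g)\n",
      m, mk$roc$auc, mk$roc$auc_ci_95[1], mk$roc$auc_ci_95[2],
      mk$roc$cutoff, mk$roc$sensitivity, mk$roc$specificity,
      mk$correlation$r, mk$correlation$p_value))
  }
  if (!is.null(x$auc_comparison))
    cat(sprintf("  Pre-STV vs SDI AUC: %.2f vs %.2f, DeLong p = %.3g\n",
                x$auc_comparison$auc_a, x$auc_comparison$auc_b,
                x$auc_comparison$p_value))
  invisible(x)
}

#' @export
summary.stv_eval <- function(object, ...) {
  print(object)
  for (m in names(object$markers)) {
    cat("\n")
    print(object$markers[[m]]$group_comparison)
  }
  invisible(object)
}
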