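# Confusion-matrix metrics, ROC/AUC, prevalence-adjusted predictive values,
# and the 90/90 "perfect model" comparator. All percentages are on the 0-100
# scale; printing rounds half-up to 2 decimal places to match clinical table
# formatting, while stored values keep full precision.

#' Construct a confusion matrix from counts
#'
#' Real-valued cells are permitted so that expected counts (e.g. 1891.8
#' expected true positives under a hypothetical model) can be represented.
#'
#' @param tp,fn,fp,tn non-negative counts.
#' @return object of class `confusion`.
#' @export
as_confusion <- function(tp, fn, fp, tn) {
  if (any(c(tp, fn, fp, tn) < 0)) stop("counts must be >= 0", call. = FALSE)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn), class = "confusion")
}

#' Cross-tabulate predicted against observed labels
#'
#' @param predicted,observed equal-length vectors of `"AS"`/`"NON_AS"`.
#' @return object of class `confusion`.
#' @export
confusion <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("`predicted` and `observed` must have equal length", call. = FALSE)
  }
  ok <- c("AS", "NON_AS")
  if (!all(predicted %in% ok) || !all(observed %in% ok)) {
    stop('labels must be "AS" or "NON_AS"', call. = FALSE)
  }
  as_confusion(tp = sum(predicted == "AS" & observed == "AS"),
               fn = sum(predicted == "NON_AS" & observed == "AS"),
               fp = sum(predicted == "AS" & observed == "NON_AS"),
               tn = sum(predicted == "NON_AS" & observed == "NON_AS"))
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(OBSERVED = c("AS", "NON_AS"),
                              PREDICTED = c("AS", "NON_AS")))
  print(m)
  invisible(x)
}

#' F value: harmonic mean of sensitivity and positive predictive value
#'
#' The model-selection criterion (the F1 score). Scale-invariant: accepts
#' either fractions or percentages as long as both arguments share a scale.
#'
#' @param sens,ppv sensitivity and PPV.
#' @return harmonic mean on the same scale; `NA` if undefined.
#' @export
f_value <- function(sens, ppv) {
  ifelse(is.na(sens) | is.na(ppv) | sens + ppv == 0, NA_real_,
         2 * sens * ppv / (sens + ppv))
}

#' Derived metrics of a confusion matrix
#'
#' Sensitivity, specificity, positive and negative predictive value,
#' accuracy and F value, all as percentages. A metric whose denominator is
#' zero is reported as `NA` (undefined), never as 0.
#'
#' @param cm a `confusion`.
#' @return list of class `metrics_report`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion"))
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  safe <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  sens <- safe(cm$tp, cm$tp + cm$fn)
  spec <- safe(cm$tn, cm$tn + cm$fp)
  ppv <- safe(cm$tp, cm$tp + cm$fp)
  npv <- safe(cm$tn, cm$tn + cm$fn)
  structure(list(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
                 accuracy = 100 * (cm$tp + cm$tn) / total,
                 f_value = f_value(sens, ppv),
                 flagged_fraction = 100 * (cm$tp + cm$fp) / total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  v <- unlist(x)
  shown <- ifelse(is.na(v), "undefined",
                  sprintf(paste0("%.", digits, "f%%"), round_half_up(v, digits)))
  for (i in seq_along(v)) cat(sprintf("  %-17s %s\n", names(v)[i], shown[i]))
  invisible(x)
}

#' Prevalence-adjusted predictive values
#'
#' Bayes' rule for the predictive values of a test with the given
#' sensitivity and specificity applied at a population prevalence, plus the
#' flagged fraction (share of the population predicted positive). This is
#' how a model tuned on a 1-in-101 matched cohort deflates when applied at
#' ~0.09% population prevalence.
#'
#' @param sens,spec sensitivity and specificity as fractions in (0, 1).
#' @param prevalence population prevalence in (0, 1); the boundary values
#'   return a degenerate flag.
#' @return list (ppv, npv, flagged_fraction, degenerate) as fractions.
#' @export
prevalence_adjusted <- function(sens, spec, prevalence) {
  stopifnot_fraction(sens, "sens"); stopifnot_fraction(spec, "spec")
  stopifnot_fraction(prevalence, "prevalence")
  if (prevalence %in% c(0, 1)) {
    return(list(ppv = NA_real_, npv = NA_real_, flagged_fraction = NA_real_,
                degenerate = TRUE))
  }
  pp <- sens * prevalence + (1 - spec) * (1 - prevalence)
  list(ppv = sens * prevalence / pp,
       npv = spec * (1 - prevalence) / (1 - pp),
       flagged_fraction = pp,
       degenerate = FALSE)
}

#' Expected performance of a hypothetical "perfect" model
#'
#' Applies a stated sensitivity/specificity (90%/90% by convention — higher
#' would suggest overfitting) to the observed class totals of a population
#' confusion matrix, giving the expected confusion matrix and its metrics.
#' The upper-bound comparator for any developed model on the same
#' population.
#'
#' @param cm_population a `confusion` giving the observed AS / NON_AS totals.
#' @param sensitivity,specificity assumed operating characteristics, in
#'   (0, 1].
#' @return list with `expected` (a real-valued `confusion`) and `report`
#'   (its `metrics_report`).
#' @export
perfect_model <- function(cm_population, sensitivity = 0.9, specificity = 0.9) {
  stopifnot(inherits(cm_population, "confusion"))
  if (sensitivity <= 0 || sensitivity > 1 || specificity <= 0 || specificity > 1) {
    stop("sensitivity and specificity must be in (0, 1]", call. = FALSE)
  }
  n_as <- cm_population$tp + cm_population$fn
  n_non <- cm_population$fp + cm_population$tn
  exp_cm <- as_confusion(tp = sensitivity * n_as,
                         fn = (1 - sensitivity) * n_as,
                         fp = (1 - specificity) * n_non,
                         tn = specificity * n_non)
  list(expected = exp_cm, report = metrics(exp_cm))
}

#' Empirical ROC curve and AUC
#'
#' Threshold sweep over the distinct score values; ties are traversed as
#' groups so the trapezoid-rule area equals the Mann-Whitney U statistic
#' (rank-average tie handling).
#'
#' @param scores continuous per-patient risk scores (e.g. the tree's leaf
#'   case fraction).
#' @param labels `"AS"`/`"NON_AS"` (or logical: case).
#' @return list with `points` (data.frame threshold, fpr, tpr) and `auc`;
#'   `auc` is `NA` with `undefined = TRUE` when only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.logical(labels)) labels else as.character(labels) == "AS"
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) {
    return(list(points = NULL, auc = NA_real_, undefined = TRUE))
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(y & scores >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(!y & scores >= t) / n0, numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc, undefined = FALSE)
}

#' Generalisability evaluation on a full population
#'
#' Predicts over every participant in `features`, reporting metrics both for
#' the whole population and with the model-development participants removed
#' (the all-population vs development-excluded distinction of the published
#' generalisability tables).
#'
#' @param model a fitted `pctree`.
#' @param features binary feature matrix for the population (row names
#'   `"<patient_id>@<index_date>"`).
#' @param observed vector of `"AS"`/`"NON_AS"` truth per row of `features`.
#' @param exclude_ids patient ids used in model development (training and
#'   testing); empty set gives two identical reports.
#' @return list (cm_all, report_all, cm_excluded, report_excluded).
#' @export
generalize <- function(model, features, observed, exclude_ids = character(0)) {
  pred <- predict(model, features)$label
  cm_all <- confusion(pred, observed)
  pid <- sub("@.*$", "", rownames(features))
  keep <- !(pid %in% exclude_ids)
  cm_ex <- confusion(pred[keep], observed[keep])
  list(cm_all = cm_all, report_all = metrics(cm_all),
       cm_excluded = cm_ex, report_excluded = metrics(cm_ex))
}

#' Published reference tables
#'
#' The study's printed confusion-matrix counts (general-population
#' evaluations, by sex, with and without the development participants) and
#' printed metric rows (training/testing/validation), shipped as package
#' data. These are the desk-scale inputs for re-deriving every metric the
#' study reports.
#'
#' @return list with `confusion` and `metrics` data.frames.
#' @export
published_tables <- function() {
  d <- system.file("extdata", package = "aspredict")
  list(
    confusion = utils::read.csv(file.path(d, "published_confusion.csv"),
                                stringsAsFactors = FALSE),
    metrics = utils::read.csv(file.path(d, "published_metrics.csv"),
                              stringsAsFactors = FALSE)
  )
}

#' Plain-text report in the published cross-tabulation layout
#'
#' @param cm a `confusion`.
#' @param path output file; `""` prints to the console.
#' @return the lines, invisibly.
#' @export
write_confusion_report <- function(cm, path = "") {
  r <- metrics(cm)
  fmtn <- function(x) format(x, big.mark = "", trim = TRUE)
  pct <- function(x) if (is.na(x)) "undef" else sprintf("%.2f%%", round_half_up(x, 2))
  lines <- c(
    sprintf("%-10s %-8s %-12s %-12s", "", "", "PREDICTED", ""),
    sprintf("%-10s %-8s %-12s %-12s", "", "", "AS", "NON_AS"),
    sprintf("%-10s %-8s %-12s %-12s %s", "OBSERVED", "AS",
            fmtn(cm$tp), fmtn(cm$fn), pct(r$sensitivity)),
    sprintf("%-10s %-8s %-12s %-12s %s", "", "NON_AS",
            fmtn(cm$fp), fmtn(cm$tn), pct(r$specificity)),
    sprintf("%-10s %-8s %-12s %-12s %s", "", "",
            pct(r$ppv), pct(r$npv), pct(r$accuracy))
  )
  if (nzchar(path)) writeLines(lines, path) else cat(lines, sep = "\n")
  invisible(lines)
}
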