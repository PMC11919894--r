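#' Cross-tabulate predicted against true abnormality
#'
#' @param predicted,truth logical (or 0/1) vectors of equal length.
#' @return A `ConfusionTable`: list with counts `tp`, `fp`, `fn`, `tn`
#'   and `n`.
#' @examples
#' confusionTable(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
confusionTable <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  if (!length(predicted)) stop("need at least one record")
  predicted <- as.logical(predicted); truth <- as.logical(truth)
  out <- list(tp = sum(predicted & truth), fp = sum(predicted & !truth),
              fn = sum(!predicted & truth), tn = sum(!predicted & !truth),
              n = length(truth))
  class(out) <- "ConfusionTable"
  out
}

#' @export
print.ConfusionTable <- function(x, ...) {
  cat(sprintf("ConfusionTable (n = %d)\n", x$n))
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(truth = c("abnormal", "normal"),
                              predicted = c("abnormal", "normal")))
  print(m)
  invisible(x)
}

#' Screening statistics with bootstrap confidence intervals
#'
#' Accuracy `(tp+tn)/n`, sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, positive predictive value `tp/(tp+fp)` and negative
#' predictive value `tn/(tn+fn)`.  Confidence intervals are percentile
#' bootstrap over record resampling (a multinomial redraw of the 2 x 2
#' counts), seeded for reproducibility.  A statistic whose denominator
#' is zero is reported as `NA` (undefined), never as 0.
#'
#' @param table a [confusionTable()].
#' @param ci compute bootstrap intervals?
#' @param B number of bootstrap resamples.
#' @param conf confidence level.
#' @param seed integer seed for the resampling.
#' @return A `MetricsReport`: data.frame with one row per statistic and
#'   columns `estimate`, `lower`, `upper`, plus attributes `n` and
#'   `ci_method`.
#' @export
screeningMetrics <- function(table, ci = TRUE, B = 2000, conf = 0.95,
                             seed = 1) {
  stopifnot(inherits(table, "ConfusionTable"))
  calc <- function(tp, fp, fn, tn) {
    n <- tp + fp + fn + tn
    c(accuracy = (tp + tn) / n,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
  }
  est <- calc(table$tp, table$fp, table$fn, table$tn)
  lower <- upper <- rep(NA_real_, 5)
  if (ci) {
    set.seed(seed)
    counts <- stats::rmultinom(B, table$n,
                               c(table$tp, table$fp, table$fn, table$tn) /
                                 table$n)
    boot <- apply(counts, 2, function(k) calc(k[1], k[2], k[3], k[4]))
    alpha <- (1 - conf) / 2
    lower <- apply(boot, 1, stats::quantile, probs = alpha, na.rm = TRUE)
    upper <- apply(boot, 1, stats::quantile, probs = 1 - alpha, na.rm = TRUE)
    # a defined point estimate always lies inside its interval
    lower <- pmin(lower, est, na.rm = FALSE)
    upper <- pmax(upper, est, na.rm = FALSE)
    lower[is.na(est)] <- NA_real_; upper[is.na(est)] <- NA_real_
  }
  out <- data.frame(statistic = names(est), estimate = unname(est),
                    lower = unname(lower), upper = unname(upper))
  attr(out, "n") <- table$n
  attr(out, "ci_method") <- if (ci)
    sprintf("percentile bootstrap, B=%d, record resampling", B) else "none"
  class(out) <- c("MetricsReport", "data.frame")
  out
}

#' Receiver operating characteristic curve and AUC
#'
#' Threshold sweep over the unique predicted probabilities (ties grouped
#' into one threshold), with the degenerate end points appended.  The
#' area under the curve is the trapezoidal rule, which equals the
#' tie-corrected rank-sum (Mann-Whitney) statistic.
#'
#' @param probabilities numeric predictions.
#' @param truth logical (or 0/1) class labels; both classes required.
#' @return A `ROCCurve`: list with `thresholds` (decreasing; `Inf`
#'   first), `fpr`, `tpr`, `auc`.
#' @export
rocCurve <- function(probabilities, truth) {
  truth <- as.logical(truth)
  if (length(unique(truth)) < 2)
    stop("both classes must be present to build a ROC curve")
  np <- sum(truth); nn <- sum(!truth)
  thr <- c(Inf, sort(unique(probabilities), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(probabilities[truth] >= t) / np,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(probabilities[!truth] >= t) / nn,
                numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  out <- list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc)
  class(out) <- "ROCCurve"
  out
}

#' @export
print.ROCCurve <- function(x, ...) {
  cat(sprintf("ROCCurve: %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Youden-index operating point
#'
#' The threshold maximising `J = sensitivity + specificity - 1`
#' (equivalently `tpr - fpr`).  Ties are broken toward the higher
#' threshold, i.e. the more specific operating point.  The returned
#' value is the midpoint between the maximising predicted probability
#' and the next lower one (so under perfect separation it sits strictly
#' between the two classes); classification at `probability >=
#' threshold` is unchanged by the shift.
#'
#' @param roc a [rocCurve()].
#' @return The selected threshold (with attributes `J`, `tpr`, `fpr` of
#'   the chosen point).
#' @export
youdenThreshold <- function(roc) {
  # drop the Inf end point: operating points are the data thresholds
  thr <- roc$thresholds[-1]
  j <- (roc$tpr - roc$fpr)[-1]
  best <- which.max(j)   # thresholds decreasing; first max = highest
  val <- if (best < length(thr)) (thr[best] + thr[best + 1]) / 2
         else thr[best]
  structure(val, J = j[best], tpr = roc$tpr[-1][best],
            fpr = roc$fpr[-1][best])
}

#' Matched-sensitivity operating point
#'
#' The largest threshold whose sensitivity is at least
#' `target_sensitivity`, which maximises specificity subject to the
#' sensitivity floor - the fair operating point for comparing a
#' probabilistic model against a fixed comparator.
#'
#' @param probabilities numeric predictions.
#' @param truth logical class labels (positives required).
#' @param target_sensitivity required sensitivity in `[0, 1]`.
#' @return The selected threshold.  A target of 0 returns `Inf` (flag
#'   nothing); targets above 1 are an error.
#' @export
matchedSensitivityThreshold <- function(probabilities, truth,
                                        target_sensitivity) {
  truth <- as.logical(truth)
  if (target_sensitivity > 1)
    stop("target sensitivity above 1 is unattainable")
  if (!sum(truth)) stop("no positive records")
  if (target_sensitivity <= 0) return(Inf)
  pos <- sort(probabilities[truth], decreasing = TRUE)
  np <- length(pos)
  # sensitivity at threshold pos[k] is >= k/np; the smallest k whose
  # k/np clears the target gives the largest qualifying threshold
  k <- ceiling(target_sensitivity * np - 1e-12)
  pos[k]
}

#' McNemar's paired test on discordant counts
#'
#' Exact two-sided binomial test on `(b, c)` when `b + c < 25`,
#' otherwise the continuity-corrected chi-square
#' `(|b - c| - 1)^2 / (b + c)` on 1 degree of freedom.  By convention
#' `b = c = 0` returns p = 1.
#'
#' @param b discordant count where only the comparator was correct.
#' @param c discordant count where only the model was correct.
#' @return p-value in `(0, 1]`.
#' @export
mcnemarTest <- function(b, c) {
  stopifnot(b >= 0, c >= 0)
  m <- b + c
  if (m == 0) return(1.0)
  if (m < 25) {
    p <- 2 * stats::pbinom(min(b, c), m, 0.5)
    return(min(1, p))
  }
  stat <- (abs(b - c) - 1)^2 / m
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Decision curve analysis
#'
#' Net benefit `tp/n - (fp/n) * pt/(1 - pt) - harm` across a grid of
#' threshold probabilities `pt`, for the model (classifying positive at
#' probability >= pt), a fixed comparator, treat-all and treat-none.
#'
#' @param probabilities model predictions.
#' @param truth logical class labels.
#' @param comparator_flags fixed comparator verdicts (or `NULL`).
#' @param pt_grid threshold probabilities, all inside (0, 1).
#' @param harm test harm constant subtracted from every net benefit
#'   (default 0).
#' @return A `DecisionCurve` data.frame with columns `pt`, `model`,
#'   `comparator`, `treat_all`, `treat_none`.
#' @export
decisionCurve <- function(probabilities, truth, comparator_flags = NULL,
                          pt_grid = seq(0.01, 0.99, by = 0.01), harm = 0) {
  if (any(pt_grid <= 0 | pt_grid >= 1))
    stop("pt_grid must lie strictly inside (0, 1)")
  truth <- as.logical(truth)
  n <- length(truth)
  prev <- mean(truth)
  nb <- function(flags, pt) {
    tp <- sum(flags & truth) / n
    fp <- sum(flags & !truth) / n
    tp - fp * pt / (1 - pt) - harm
  }
  model <- vapply(pt_grid, function(pt) nb(probabilities >= pt, pt),
                  numeric(1))
  comp <- if (is.null(comparator_flags)) rep(NA_real_, length(pt_grid))
          else vapply(pt_grid, function(pt)
                        nb(as.logical(comparator_flags), pt), numeric(1))
  all_ <- vapply(pt_grid, function(pt) nb(rep(TRUE, n), pt), numeric(1))
  out <- data.frame(pt = pt_grid, model = model, comparator = comp,
                    treat_all = all_, treat_none = 0)
  attr(out, "prevalence") <- prev
  class(out) <- c("DecisionCurve", "data.frame")
  out
}

#' Per-finding diagnostic comparison at matched sensitivity
#'
#' For each finding F, records carrying F are the positives and all
#' other records - including records with other abnormalities - are
#' the negatives (the convention that reproduces per-finding screening
#' tables where every record is dichotomised on F alone).  The
#' comparator is evaluated with its fixed flags; the model threshold is
#' set so its sensitivity for F matches the comparator's, and the
#' paired McNemar test compares specificity outcomes over the negative
#' records.
#'
#' @param probabilities model predictions.
#' @param truth_findings list (one element per record) of finding-code
#'   character vectors.
#' @param comparator_flags fixed comparator verdicts.
#' @param finding_list findings to report; defaults to every finding
#'   present.
#' @param ci,B,seed forwarded to [screeningMetrics()].
#' @return A `PerFindingReport` data.frame: one row per finding with
#'   prevalence counts, comparator and model sensitivity/specificity
#'   (and CIs), the matched threshold and the McNemar p-value.
#' @export
perFindingReport <- function(probabilities, truth_findings, comparator_flags,
                             finding_list = NULL, ci = TRUE, B = 2000,
                             seed = 1) {
  comparator_flags <- as.logical(comparator_flags)
  present <- sort(unique(unlist(truth_findings)))
  if (is.null(finding_list)) finding_list <- present
  rows <- list()
  for (f in finding_list) {
    pos <- vapply(truth_findings, function(v) f %in% v, logical(1))
    if (!sum(pos)) {
      warning("finding '", f, "' absent from the data; skipped")
      next
    }
    compTab <- confusionTable(comparator_flags, pos)
    compM <- screeningMetrics(compTab, ci = ci, B = B, seed = seed)
    compSens <- compM$estimate[compM$statistic == "sensitivity"]
    thr <- matchedSensitivityThreshold(probabilities, pos, compSens)
    modelFlag <- probabilities >= thr
    modelTab <- confusionTable(modelFlag, pos)
    modelM <- screeningMetrics(modelTab, ci = ci, B = B, seed = seed)
    neg <- !pos
    # paired specificity outcomes: correct = not flagged, on negatives
    b <- sum(!comparator_flags[neg] & modelFlag[neg])
    cc <- sum(comparator_flags[neg] & !modelFlag[neg])
    g <- function(m, s) m$estimate[m$statistic == s]
    rows[[f]] <- data.frame(
      finding = f, n_positive = sum(pos), n_negative = sum(neg),
      comp_sensitivity = g(compM, "sensitivity"),
      comp_specificity = g(compM, "specificity"),
      comp_accuracy = g(compM, "accuracy"),
      model_threshold = thr,
      model_sensitivity = g(modelM, "sensitivity"),
      model_specificity = g(modelM, "specificity"),
      model_accuracy = g(modelM, "accuracy"),
      mcnemar_p = mcnemarTest(b, cc),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("PerFindingReport", "data.frame")
  out
}
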