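test_that("confusion tables cross-tabulate correctly", {
  truth <- c(rep(TRUE, 4), rep(FALSE, 6))
  tab <- confusionTable(truth, truth)
  expect_equal(unlist(tab[c("tp", "fp", "fn", "tn")]),
               c(tp = 4, fp = 0, fn = 0, tn = 6))
  inv <- confusionTable(!truth, truth)
  expect_equal(unlist(inv[c("tp", "fp", "fn", "tn")]),
               c(tp = 0, fp = 6, fn = 4, tn = 0))

  set.seed(21)
  for (i in 1:10) {
    p <- runif(40) > 0.5; t <- runif(40) > 0.6
    tab <- confusionTable(p, t)
    expect_equal(tab$tp, sum(p & t));  expect_equal(tab$fp, sum(p & !t))
    expect_equal(tab$fn, sum(!p & t)); expect_equal(tab$tn, sum(!p & !t))
  }
  expect_error(confusionTable(c(TRUE, FALSE), TRUE), "equal length")
})

test_that("zero denominators yield undefined statistics, not zero", {
  m <- screeningMetrics(confusionTable(c(FALSE, FALSE), c(FALSE, FALSE)),
                        ci = FALSE)
  expect_true(is.na(m$estimate[m$statistic == "sensitivity"]))
  expect_true(is.na(m$estimate[m$statistic == "ppv"]))
  expect_false(is.na(m$estimate[m$statistic == "specificity"]))
})

test_that("bootstrap intervals contain the estimate and shrink with n", {
  mkTab <- function(n) {
    tab <- list(tp = round(0.2 * n), fp = round(0.1 * n),
                fn = round(0.05 * n), tn = n - round(0.35 * n))
    tab$n <- n
    class(tab) <- "ConfusionTable"
    tab
  }
  small <- screeningMetrics(mkTab(50), B = 600, seed = 3)
  big <- screeningMetrics(mkTab(5000), B = 600, seed = 3)
  ok <- !is.na(small$estimate)
  expect_true(all(small$lower[ok] <= small$estimate[ok] + 1e-12))
  expect_true(all(small$upper[ok] >= small$estimate[ok] - 1e-12))
  expect_true(all((big$upper - big$lower)[ok] <
                    (small$upper - small$lower)[ok]))
  # seeded: reproducible
  expect_identical(screeningMetrics(mkTab(50), B = 600, seed = 3), small)
})

test_that("ROC handles perfect, constant and random predictions", {
  truth <- c(rep(TRUE, 5), rep(FALSE, 5))
  perfect <- c(runif(5, 0.8, 1), runif(5, 0, 0.2))
  expect_equal(rocCurve(perfect, truth)$auc, 1.0)
  expect_equal(rocCurve(rep(0.4, 10), truth)$auc, 0.5)
  expect_error(rocCurve(runif(5), rep(TRUE, 5)), "both classes")
})

test_that("AUC equals the tie-corrected rank-sum statistic", {
  set.seed(22)
  for (i in 1:40) {
    n <- sample(10:60, 1)
    truth <- runif(n) < runif(1, 0.2, 0.8)
    if (length(unique(truth)) < 2) next
    # coarse probabilities ensure ties
    prob <- round(runif(n), sample(c(1, 2), 1))
    r <- rank(prob)
    n1 <- sum(truth); n0 <- sum(!truth)
    u <- sum(r[truth]) - n1 * (n1 + 1) / 2
    expect_equal(rocCurve(prob, truth)$auc, u / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("AUC matches the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:10) {
    truth <- runif(40) < 0.4
    if (length(unique(truth)) < 2) next
    prob <- round(runif(40), 2)
    ref <- suppressMessages(pROC::auc(pROC::roc(truth, prob,
                                                direction = "<")))
    expect_equal(rocCurve(prob, truth)$auc, as.numeric(ref),
                 tolerance = 1e-12)
  }
})

test_that("the Youden threshold agrees with an exhaustive scan", {
  set.seed(24)
  for (i in 1:20) {
    n <- sample(15:50, 1)
    truth <- runif(n) < 0.4
    if (length(unique(truth)) < 2) next
    prob <- round(runif(n), 2)
    thr <- youdenThreshold(rocCurve(prob, truth))
    jAt <- function(t) {
      mean(prob[truth] >= t) - mean(prob[!truth] >= t)
    }
    bestJ <- max(vapply(unique(prob), jAt, numeric(1)))
    expect_equal(unname(attr(thr, "J")), bestJ, tolerance = 1e-12)
    expect_equal(jAt(thr), bestJ, tolerance = 1e-12)
  }
})

test_that("perfect separation puts the Youden threshold inside the gap", {
  truth <- c(rep(TRUE, 6), rep(FALSE, 8))
  prob <- c(runif(6, 0.7, 1), runif(8, 0, 0.3))
  thr <- youdenThreshold(rocCurve(prob, truth))
  expect_gt(thr, max(prob[!truth]))
  expect_lt(thr, min(prob[truth]))
  expect_equal(unname(attr(thr, "J")), 1)

  flat <- youdenThreshold(rocCurve(rep(0.4, 10), truth[1:10]))
  expect_equal(unname(attr(flat, "J")), 0)
})

test_that("matched-sensitivity threshold maximises specificity", {
  set.seed(25)
  for (i in 1:20) {
    n <- sample(15:50, 1)
    truth <- runif(n) < 0.5
    if (!any(truth) || all(truth)) next
    prob <- round(runif(n), 2)
    target <- runif(1, 0.1, 1)
    thr <- matchedSensitivityThreshold(prob, truth, target)
    sens <- function(t) mean(prob[truth] >= t)
    expect_gte(sens(thr), target)
    # oracle: largest candidate threshold whose sensitivity clears target
    cands <- sort(unique(prob), decreasing = TRUE)
    ok <- cands[vapply(cands, sens, numeric(1)) >= target]
    expect_equal(thr, ok[1])
  }
  # a target of 1 forces the threshold to the weakest positive
  truth <- c(TRUE, TRUE, FALSE)
  prob <- c(0.9, 0.4, 0.6)
  expect_lte(matchedSensitivityThreshold(prob, truth, 1), 0.4)
  expect_error(matchedSensitivityThreshold(prob, truth, 1.2),
               "unattainable")
})

test_that("exact McNemar equals binomial tail sums for all b + c <= 24", {
  expect_equal(mcnemarTest(5, 5), 1.0)
  expect_equal(mcnemarTest(0, 10), 2 * (1 / 2)^10)
  expect_equal(mcnemarTest(0, 0), 1.0)
  for (m in 1:24) {
    for (b in 0:m) {
      cc <- m - b
      oracle <- min(1, 2 * sum(dbinom(0:min(b, cc), m, 0.5)))
      expect_equal(mcnemarTest(b, cc), oracle, tolerance = 1e-12)
    }
  }
})

test_that("large-sample McNemar uses the continuity-corrected chi-square", {
  b <- 25; cc <- 50
  oracle <- pchisq((abs(b - cc) - 1)^2 / (b + cc), 1, lower.tail = FALSE)
  expect_equal(mcnemarTest(b, cc), oracle)
  ref <- mcnemar.test(matrix(c(10, b, cc, 10), 2), correct = TRUE)
  expect_equal(mcnemarTest(b, cc), unname(ref$p.value))
})

test_that("decision curves satisfy the closed-form identities", {
  set.seed(26)
  truth <- runif(200) < 0.3
  prob <- pmin(pmax(truth * 0.6 + runif(200, 0, 0.4), 0), 1)
  grid <- seq(0.05, 0.95, by = 0.05)
  dc <- decisionCurve(prob, truth, comparator_flags = NULL, pt_grid = grid)
  prev <- mean(truth)
  expect_true(all(dc$treat_none == 0))
  expect_equal(dc$treat_all, prev - (1 - prev) * grid / (1 - grid))
  expect_true(all(dc$model <= prev + 1e-12))
  # treat-all crosses zero where pt equals prevalence
  dc2 <- decisionCurve(prob, truth, pt_grid = prev)
  expect_equal(dc2$treat_all, 0)
  # a perfect model attains the prevalence everywhere
  dcP <- decisionCurve(as.numeric(truth), truth, pt_grid = grid)
  expect_true(all(abs(dcP$model - prev) < 1e-12))
  expect_error(decisionCurve(prob, truth, pt_grid = c(0.5, 1)), "inside")
})

test_that("per-finding reports follow the all-other-records convention", {
  # 12 records, two findings; negatives for each finding include the
  # records carrying the other finding
  fnd <- list(c("st_t"), c("st_t"), c("crbbb"), c("st_t", "crbbb"),
              character(), character(), character(), character(),
              character(), character(), character(), character())
  prob <- c(0.9, 0.8, 0.85, 0.95, 0.1, 0.2, 0.7, 0.3, 0.15, 0.25, 0.05, 0.4)
  comp <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE,
            FALSE, FALSE, TRUE)
  rep_ <- perFindingReport(prob, fnd, comp, ci = FALSE)
  st <- rep_[rep_$finding == "st_t", ]
  expect_equal(st$n_positive, 3)
  expect_equal(st$n_negative, 9)
  expect_equal(st$comp_sensitivity, 1)
  expect_equal(st$comp_specificity, 5 / 9)    # hand count: 4 of 9 flagged
  # model at matched sensitivity 1: threshold 0.8; flags 6 of 9 negatives? ->
  # negatives with prob >= 0.8: records 3 (0.85) and 4 is positive... hand:
  # negative probs: .85,.1,.2,.7,.3,.15,.25,.05,.4 -> one >= 0.8
  expect_equal(st$model_sensitivity, 1)
  expect_equal(st$model_specificity, 8 / 9)

  cb <- rep_[rep_$finding == "crbbb", ]
  expect_equal(cb$n_positive, 2)
  expect_equal(cb$n_negative, 10)

  expect_warning(perFindingReport(prob, fnd, comp,
                                  finding_list = c("st_t", "wpw"),
                                  ci = FALSE),
                 "wpw")
})

test_that("degenerate comparators produce the expected per-finding rows", {
  co <- smallCohort()
  truthF <- strsplit(co$manifest$findings, ",")
  prob <- as.numeric(nzchar(co$manifest$findings))   # oracle model
  allFlag <- rep(TRUE, nrow(co$manifest))
  rep_ <- suppressWarnings(
    perFindingReport(prob, truthF, allFlag, ci = FALSE))
  expect_true(all(rep_$comp_sensitivity == 1))
  expect_true(all(rep_$comp_specificity == 0))
  expect_true(all(rep_$model_sensitivity >= rep_$comp_sensitivity - 1e-12))

  # single-finding cohort, probabilities equal to truth: the model is
  # perfectly specific at the matched (full) sensitivity
  fnd <- c(rep(list("st_t"), 4), rep(list(character()), 8))
  probT <- c(rep(1, 4), rep(0, 8))
  r2 <- perFindingReport(probT, fnd, rep(TRUE, 12), ci = FALSE)
  expect_equal(r2$model_sensitivity, 1)
  expect_equal(r2$model_specificity, 1)
})
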