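# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# a small mixed cohort used by several files (computed lazily)
smallCohort <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- sampleCohort(cohortSpec(60, seed = 404))
  }
  .fixtures$small
}

cleanRecord <- function(hr = 60, seed = 1, noise = 0, finding = NULL,
                        severity = 1, age = 10, sex = "male") {
  par <- normalDipoleParams(hr)
  par$baseline_noise_sd <- noise
  if (!is.null(finding)) par <- injectAbnormality(par, finding, severity)
  generateECG(par, age = age, sex = sex, seed = seed,
              findings = if (is.null(finding)) character() else finding)
}

# greedy matching of detections to ground truth within a tolerance
matchPeaks <- function(detected, truth, fs = 500, tol_s = 0.02) {
  used <- rep(FALSE, length(detected))
  hits <- 0L
  for (t in truth) {
    d <- abs(detected - t) / fs
    j <- which(!used & d <= tol_s)
    if (length(j)) {
      hits <- hits + 1L
      used[j[which.min(d[j])]] <- TRUE
    }
  }
  c(recall = hits / length(truth), precision = hits / length(detected))
}

# a tiny architecture (128 frequency bins) for fast engine tests
tinyArch <- function() {
  architectureConfig(width_multiplier = 1 / 16, preset = "desk",
                     n_freq = 128)
}

# random spectral-style inputs for engine tests
randomInputs <- function(n, arch = tinyArch(), seed = 1) {
  set.seed(seed)
  d <- arch$n_leads * arch$n_freq
  list(amp = matrix(abs(rnorm(d * n, 0, 0.3)), d, n),
       pha = matrix(runif(d * n, -pi, pi), d, n),
       meta = rbind(runif(n, 6 / 18, 1), sample(0:1, n, TRUE)),
       record_ids = sprintf("r%03d", seq_len(n)),
       fingerprint = "test")
}
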