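#' Synthetic pediatric 12-lead ECGs from a rotating-dipole beat model
#'
#' @description
#' The simulator represents each cardiac cycle as a sum of Gaussian
#' wavelets (P, Q, R, S, T and optional extras) riding on a single
#' time-varying cardiac dipole.  Each wavelet has a time offset relative
#' to the R peak, a width, a magnitude in millivolts, and a direction
#' given by a frontal-plane angle (degrees; 0 = leftward along lead I,
#' +90 = inferior along aVF) and a horizontal-plane elevation (degrees
#' out of the frontal plane).  The 12 leads are fixed projections of the
#' dipole:
#'
#' * lead I and II project onto frontal unit vectors at 0 and 60 degrees;
#'   III, aVR, aVL and aVF are derived from them via the Einthoven and
#'   Goldberger identities (`III = II - I`, `aVR = -(I + II)/2`,
#'   `aVL = I - II/2`, `aVF = II - I/2`), so those identities hold by
#'   construction;
#' * chest leads V1-V6 project onto horizontal-plane unit vectors at
#'   -60, -40, -20, 0, +20 and +40 degrees with a shared unit
#'   attenuation.
#'
#' Because the geometry is shared, injected abnormalities (axis
#' rotation, widened QRS, added R' waves, ST shifts) propagate
#' consistently across all 12 leads.
#'
#' @param heart_rate_bpm resting heart rate in beats per minute.
#' @return `normalDipoleParams()` returns a dipole parameter list with
#'   elements `heart_rate_bpm`, `rr_jitter_sd` (fraction of RR),
#'   `waves` (named wavelet list), `baseline_noise_sd` (mV),
#'   `pr_interval_s`, `qrs_width_scale`, `st_shift_mv`, `extras`
#'   (additional wavelets) and `rhythm`.
#' @examples
#' p <- normalDipoleParams(100)
#' rec <- generateECG(p, age = 8, sex = "male", seed = 42)
#' @export
normalDipoleParams <- function(heart_rate_bpm = 90) {
  wave <- function(t, sigma, amp, theta, phi, qrs = FALSE)
    list(t = t, sigma = sigma, amp = amp, theta = theta, phi = phi, qrs = qrs)
  list(
    heart_rate_bpm = heart_rate_bpm,
    rr_jitter_sd = 0.03,
    waves = list(
      P = wave(-0.14, 0.022, 0.15, 55, 0),
      Q = wave(-0.022, 0.008, -0.10, 60, 30, qrs = TRUE),
      R = wave(0.000, 0.011, 1.40, 60, 30, qrs = TRUE),
      S = wave(0.022, 0.009, -0.35, 25, -20, qrs = TRUE),
      T = wave(0.280, 0.055, 0.35, 40, 10)),
    baseline_noise_sd = 0.01,
    pr_interval_s = 0.14,
    qrs_width_scale = 1,
    st_shift_mv = 0,
    extras = list(),
    rhythm = list(type = "sinus"))
}

validateDipoleParams <- function(params) {
  hr <- params$heart_rate_bpm
  if (!is.numeric(hr) || hr < 50 || hr > 220)
    stop("heart_rate_bpm must lie in [50, 220], got ", hr)
  allw <- c(params$waves, params$extras)
  for (w in allw) {
    if (w$sigma <= 0) stop("wave widths must be positive")
    if (w$theta <= -180 || w$theta > 180)
      stop("frontal angles must lie in (-180, 180]")
  }
  invisible(TRUE)
}

# direction unit vector from frontal angle theta and horizontal
# elevation phi (degrees); x = leftward, y = inferior, z = anterior
waveDirection <- function(theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  c(cos(th) * cos(ph), sin(th) * cos(ph), sin(ph))
}

chestLeadVectors <- function() {
  beta <- c(-60, -40, -20, 0, 20, 40) * pi / 180
  rbind(cos(beta), 0, sin(beta))  # 3 x 6, columns V1..V6
}

# add one Gaussian wavelet to the 3 x n dipole matrix (windowed +-5 sigma)
addWavelet <- function(d, tgrid, center, sigma, amp, u) {
  lo <- max(1L, floor((center - 5 * sigma) * attr(tgrid, "fs")) + 1L)
  hi <- min(length(tgrid), ceiling((center + 5 * sigma) * attr(tgrid, "fs")) + 1L)
  if (lo > hi) return(d)
  g <- amp * exp(-((tgrid[lo:hi] - center)^2) / (2 * sigma^2))
  d[, lo:hi] <- d[, lo:hi] + u %o% g
  d
}

#' Generate one synthetic 12-lead ECG record
#'
#' Renders a dipole parameter set into a 10-second record.  RR intervals
#' are `60/heart_rate_bpm * (1 + e)` with `e ~ N(0, rr_jitter_sd)`;
#' white noise of `baseline_noise_sd` mV plus a low-frequency baseline
#' wander proportional to it are added per lead (so Einthoven identities
#' are exact only at zero noise).  The true R-peak sample indices are
#' stored in the record as generator ground truth.
#'
#' @param params dipole parameters, see [normalDipoleParams()].
#' @param age,sex record metadata.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param duration,fs record length in seconds and sampling rate in Hz.
#' @param findings finding codes carried by the record.
#' @param recordId,patientId identifiers.
#' @return An [ECGRecord-class].
#' @export
generateECG <- function(params, age, sex, seed = NULL, duration = 10,
                        fs = 500, findings = character(),
                        recordId = "syn", patientId = recordId) {
  validateDipoleParams(params)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  tgrid <- (seq_len(n) - 1) / fs
  attr(tgrid, "fs") <- fs
  d <- matrix(0, 3, n)
  rhythm <- params$rhythm$type %||% "sinus"

  beatTimes <- function(rate, jitter, t0) {
    times <- t0
    while (tail(times, 1) < duration + 0.5) {
      rr <- 60 / rate * (1 + rnorm(1, 0, jitter))
      times <- c(times, tail(times, 1) + max(0.22, rr))
    }
    # keep complexes fully inside the record (with detector lookahead room)
    times[times < duration - 0.2 & times > 0.05]
  }

  rTimes <- beatTimes(params$heart_rate_bpm, params$rr_jitter_sd,
                      stats::runif(1, 0.25, 0.45))
  waves <- params$waves
  ws <- params$qrs_width_scale
  # ST shift realised as a wide plateau wavelet between S and T
  stw <- if (abs(params$st_shift_mv) > 0)
    list(list(t = 0.10, sigma = 0.055, amp = params$st_shift_mv,
              theta = waves$R$theta, phi = waves$R$phi, qrs = FALSE))
  else list()
  allWaves <- c(waves, params$extras, stw)

  renderBeat <- function(d, tR, waveSet) {
    for (w in waveSet) {
      scale <- if (isTRUE(w$qrs)) ws else 1
      if (abs(w$amp) < 1e-12) next
      d <- addWavelet(d, tgrid, tR + w$t * scale, w$sigma * scale,
                      w$amp, waveDirection(w$theta, w$phi))
    }
    d
  }

  if (rhythm == "avb3") {
    vrate <- params$rhythm$ventricular_rate_bpm
    arate <- params$rhythm$atrial_rate_bpm %||% params$heart_rate_bpm
    rTimes <- beatTimes(vrate, params$rr_jitter_sd, stats::runif(1, 0.3, 0.8))
    pTimes <- beatTimes(arate, params$rr_jitter_sd, stats::runif(1, 0.1, 0.4))
    qrsT <- allWaves[!names(allWaves) %in% "P"]
    for (tR in rTimes) d <- renderBeat(d, tR, qrsT)
    pw <- waves$P
    for (tP in pTimes)
      d <- addWavelet(d, tgrid, tP, pw$sigma, pw$amp,
                      waveDirection(pw$theta, pw$phi))
  } else if (rhythm == "pvc") {
    k <- params$rhythm$k
    ect <- params$rhythm$ectopic
    for (i in seq_along(rTimes)) {
      if (i %% k == 0) {
        for (w in ect)
          d <- addWavelet(d, tgrid, rTimes[i] + w$t, w$sigma, w$amp,
                          waveDirection(w$theta, w$phi))
      } else d <- renderBeat(d, rTimes[i], allWaves)
    }
  } else {
    for (tR in rTimes) d <- renderBeat(d, tR, allWaves)
  }

  # project onto leads; derived limb leads keep Einthoven/Goldberger exact
  vI <- c(1, 0, 0); vII <- c(cos(pi / 3), sin(pi / 3), 0)
  I <- drop(vI %*% d); II <- drop(vII %*% d)
  III <- II - I
  aVR <- -(I + II) / 2; aVL <- I - II / 2; aVF <- II - I / 2
  chest <- t(chestLeadVectors()) %*% d   # 6 x n
  leads <- cbind(I, II, III, aVR, aVL, aVF, t(chest))
  colnames(leads) <- canonicalLeads()

  if (params$baseline_noise_sd > 0) {
    sdn <- params$baseline_noise_sd
    for (j in seq_len(12)) {
      wander <- 2 * sdn * sin(2 * pi * stats::runif(1, 0.15, 0.4) * tgrid +
                              stats::runif(1, 0, 2 * pi))
      leads[, j] <- leads[, j] + rnorm(n, 0, sdn) + wander
    }
  }
  ECGRecord(leads, fs = fs, age = age, sex = sex, findings = findings,
            recordId = recordId, patientId = patientId,
            rPeaks = as.integer(round(rTimes * fs) + 1L))
}

#' Finding vocabulary of the synthetic cohort
#'
#' Codes for the injectable guideline abnormalities: ST-T abnormality,
#' complete and incomplete right bundle branch block, QRS axis
#' abnormality, right and left ventricular hypertrophy,
#' Wolff-Parkinson-White pre-excitation, supraventricular tachycardia,
#' premature ventricular contractions, Brugada-type ST elevation and
#' third-degree atrioventricular block.
#'
#' @return Character vector of supported finding codes (excluding
#'   `"normal"`).
#' @export
findingVocabulary <- function() {
  c("st_t", "crbbb", "irbbb", "axis_dev", "rvh", "lvh",
    "wpw", "svt", "pvc", "brugada", "avb3")
}

#' Inject an abnormality into dipole parameters
#'
#' Modifies a normal beat template so that the rendered record shows the
#' requested abnormality with standard ECG morphology: wide rsR' in V1
#' for complete right bundle branch block, delta wave plus short PR for
#' WPW, coved right-precordial ST elevation for the Brugada pattern,
#' frontal QRS rotation for axis deviation, voltage scaling for
#' ventricular hypertrophy, ST-segment shift with T inversion for ST-T
#' abnormality, a fast regular narrow rhythm for SVT, dissociated P
#' waves for third-degree AV block, and interleaved wide ectopics for
#' PVCs.  All modifications scale linearly (monotonically) with
#' `severity`; severity 0 returns the parameters unchanged.
#'
#' @param params base (normal) dipole parameters.
#' @param finding a code from [findingVocabulary()], or `"normal"`.
#' @param severity scalar in `[0, 1]`.
#' @return Modified dipole parameter list.
#' @export
injectAbnormality <- function(params, finding, severity = 1) {
  stopifnot(severity >= 0, severity <= 1)
  if (finding == "normal" || severity == 0) return(params)
  s <- severity
  w <- function(t, sigma, amp, theta, phi, qrs = FALSE)
    list(t = t, sigma = sigma, amp = amp, theta = theta, phi = phi, qrs = qrs)
  rotateQRS <- function(p, deg) {
    for (nm in names(p$waves))
      if (isTRUE(p$waves[[nm]]$qrs))
        p$waves[[nm]]$theta <- wrapAngleDeg(p$waves[[nm]]$theta + deg)
    p
  }
  p <- params
  switch(finding,
    st_t = {
      p$st_shift_mv <- p$st_shift_mv - 0.22 * s
      p$waves$T$amp <- p$waves$T$amp * (1 - 1.6 * s)
    },
    crbbb = {
      p$qrs_width_scale <- p$qrs_width_scale * (1 + 0.9 * s)
      p$extras <- c(p$extras, list(
        Rprime = w(0.050, 0.016, 0.90 * s, -150, -50, qrs = TRUE)))
    },
    irbbb = {
      p$qrs_width_scale <- p$qrs_width_scale * (1 + 0.22 * s)
      p$extras <- c(p$extras, list(
        rprime = w(0.038, 0.012, 0.45 * s, -150, -50, qrs = TRUE)))
    },
    axis_dev = {
      p <- rotateQRS(p, 90 * s)
    },
    rvh = {
      p <- rotateQRS(p, 25 * s)
      p$extras <- c(p$extras, list(
        Rv1 = w(0.004, 0.010, 2.00 * s, -150, -50, qrs = TRUE)))
    },
    lvh = {
      for (nm in c("Q", "R", "S"))
        p$waves[[nm]]$amp <- p$waves[[nm]]$amp * (1 + 1.3 * s)
    },
    wpw = {
      p$waves$P$t <- p$waves$P$t + 0.05 * s       # short PR
      p$qrs_width_scale <- p$qrs_width_scale * (1 + 0.3 * s)
      p$extras <- c(p$extras, list(
        delta = w(-0.035, 0.020, 0.55 * s, 30, 20, qrs = TRUE)))
    },
    svt = {
      target <- 185 + 35 * s
      p$heart_rate_bpm <- min(220, (1 - s) * p$heart_rate_bpm + s * target)
      p$waves$P$amp <- p$waves$P$amp * (1 - s)
      p$rr_jitter_sd <- p$rr_jitter_sd * (1 - 0.9 * s)
    },
    pvc = {
      p$rhythm <- list(type = "pvc", k = max(2L, as.integer(round(8 - 6 * s))),
        ectopic = list(
          Rect = w(0.000, 0.030, 1.60, -60, -30, qrs = TRUE),
          Tect = w(0.300, 0.070, -0.50, 60, 10)))
    },
    brugada = {
      p$extras <- c(p$extras, list(
        coved = w(0.060, 0.050, 0.38 * s, -120, -60),
        tneg = w(0.230, 0.050, -0.22 * s, -120, -60)))
    },
    avb3 = {
      p$rhythm <- list(type = "avb3",
        ventricular_rate_bpm = max(50, (1 - s) * p$heart_rate_bpm + s * 50),
        atrial_rate_bpm = p$heart_rate_bpm)
    },
    stop("unknown finding code: ", finding))
  p
}

wrapAngleDeg <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a == -180, 180, a)
}

#' Age-dependent resting heart rate schedule
#'
#' Linear pediatric schedule: 120 bpm at age 6 falling 4 bpm per year to
#' 72 bpm at age 18, before per-record jitter.
#'
#' @param age age in years.
#' @return Heart rate in bpm.
#' @export
ageHeartRate <- function(age) 120 - 4 * (age - 6)

#' Cohort specification for the synthetic simulator
#'
#' Defaults emulate the composition of a screening test cohort: 27%
#' of records carry at least one abnormal finding, with per-finding
#' mixture weights proportional to the observed finding counts of such
#' a cohort (ST-T abnormality dominating, rarities like WPW and the
#' Brugada pattern at single counts).
#'
#' @param n_records number of records to simulate (>= 2).
#' @param abnormal_fraction fraction of abnormal records in `[0, 1]`.
#' @param weights named non-negative per-finding mixture weights over
#'   [findingVocabulary()]; normalised internally.
#' @param age_range inclusive integer age range in years.
#' @param severity_range range from which per-record severities are
#'   drawn uniformly.
#' @param noise_sd baseline white-noise standard deviation in mV.
#' @param seed integer seed driving every random choice of the cohort.
#' @return A `CohortSpec` list.
#' @export
cohortSpec <- function(n_records, abnormal_fraction = 0.27,
                       weights = c(st_t = 51, crbbb = 17, axis_dev = 16,
                                   rvh = 11, irbbb = 9, svt = 8, lvh = 5,
                                   avb3 = 4, pvc = 3, wpw = 1, brugada = 1),
                       age_range = c(6, 18), severity_range = c(0.7, 1),
                       noise_sd = 0.01, seed = 1) {
  stopifnot(n_records >= 2, abnormal_fraction >= 0, abnormal_fraction <= 1,
            all(names(weights) %in% findingVocabulary()),
            all(weights >= 0), sum(weights) > 0)
  list(n_records = as.integer(n_records),
       abnormal_fraction = abnormal_fraction,
       weights = weights / sum(weights),
       age_range = age_range, severity_range = severity_range,
       noise_sd = noise_sd, seed = as.integer(seed))
}

#' Simulate a labelled cohort of synthetic ECGs
#'
#' Draws `round(n_records * abnormal_fraction)` abnormal records with
#' findings sampled from the mixture weights and severities from
#' `severity_range`; the rest are normal.  Ages are uniform over the age
#' range and drive the heart rate through [ageHeartRate()] with +-10%
#' jitter.  Each record gets its own patient identifier.  The returned
#' manifest also carries the toy rule-based comparator's verdict per
#' record (see [ruleComparator()]).
#'
#' @param spec a [cohortSpec()].
#' @param comparator logical; compute comparator flags (slower).
#' @return A list with `records` (list of [ECGRecord-class]) and
#'   `manifest` (data.frame with columns `record_id`, `patient_id`,
#'   `age_years`, `sex`, `findings` (comma-joined), `severity`,
#'   `comparator_flag`, `path`).
#' @export
sampleCohort <- function(spec, comparator = TRUE) {
  set.seed(spec$seed)
  n <- spec$n_records
  nAb <- round(n * spec$abnormal_fraction)
  codes <- c(sample(names(spec$weights), nAb, replace = TRUE,
                    prob = spec$weights),
             rep("normal", n - nAb))
  codes <- sample(codes)                      # shuffle case order
  ages <- sample(seq(spec$age_range[1], spec$age_range[2]), n, replace = TRUE)
  sexes <- sample(c("male", "female"), n, replace = TRUE)
  sev <- stats::runif(n, spec$severity_range[1], spec$severity_range[2])
  recSeeds <- sample.int(.Machine$integer.max - 1L, n)
  cmpSeeds <- sample.int(.Machine$integer.max - 1L, n)
  records <- vector("list", n)
  flags <- rep(NA, n)
  for (i in seq_len(n)) {
    hr <- ageHeartRate(ages[i]) * (1 + stats::runif(1, -0.1, 0.1))
    par <- normalDipoleParams(hr)
    par$baseline_noise_sd <- spec$noise_sd
    fnd <- character()
    if (codes[i] != "normal") {
      par <- injectAbnormality(par, codes[i], sev[i])
      fnd <- codes[i]
    }
    id <- sprintf("rec%04d", i)
    records[[i]] <- generateECG(par, age = ages[i], sex = sexes[i],
                                seed = recSeeds[i], findings = fnd,
                                recordId = id,
                                patientId = sprintf("pat%04d", i))
    if (comparator)
      flags[i] <- ruleComparator(records[[i]], seed = cmpSeeds[i])
  }
  manifest <- data.frame(
    record_id = vapply(records, recordId, character(1)),
    patient_id = vapply(records, patientId, character(1)),
    age_years = ages, sex = sexes,
    findings = vapply(records, function(r)
      paste(findings(r), collapse = ","), character(1)),
    severity = ifelse(codes == "normal", 0, sev),
    comparator_flag = as.logical(flags),
    path = NA_character_, stringsAsFactors = FALSE)
  list(records = records, manifest = manifest)
}

# ---- waveform measurements ------------------------------------------

#' Measure interpretable features of a record
#'
#' Simple rule-style measurements used by the toy comparator and by
#' validity checks of the simulator: median QRS width (s) from the
#' cross-lead RMS envelope, frontal QRS axis (degrees) from net QRS
#' areas in leads I and aVF, R-wave amplitude in V1 (mV), ST-segment
#' level (mV, mean of leads II and V5 at 110-130 ms after R relative to
#' the PR baseline) and heart rate (bpm) from the median RR interval.
#' Uses the record's ground-truth R peaks when present, otherwise runs
#' the Pan-Tompkins detector.
#'
#' @param record an [ECGRecord-class].
#' @param peaks optional R-peak sample indices overriding the default.
#' @return Named numeric vector `qrs_width_s`, `axis_deg`, `v1_r_mv`,
#'   `v6_r_mv`, `st_level_mv`, `heart_rate_bpm`.
#' @export
measureECGFeatures <- function(record, peaks = NULL) {
  fs <- sampleRate(record)
  x <- leadMatrix(record)
  if (is.null(peaks)) {
    peaks <- truePeaks(record)
    if (!length(peaks))
      peaks <- detectQRS(record)$r_peaks
  }
  n <- nrow(x)
  win <- function(r, lo_s, hi_s)
    max(1L, r + round(lo_s * fs)):min(n, r + round(hi_s * fs))
  base <- vapply(seq_len(12), function(j) stats::median(x[, j]), numeric(1))
  xc <- sweep(x, 2, base)

  widths <- axisI <- axisF <- v1r <- v6r <- stlev <- numeric(0)
  for (r in peaks) {
    if (r + round(0.35 * fs) > n || r - round(0.2 * fs) < 1) next
    qw <- win(r, -0.15, 0.15)
    rms <- sqrt(rowMeans(xc[qw, , drop = FALSE]^2))
    on <- rms > 0.2 * max(rms)
    # bridge sub-20 ms dips (e.g. between R and R' of an rsR' complex)
    runs0 <- rle(on)
    runs0$values[!runs0$values & runs0$lengths <= 0.02 * fs] <- TRUE
    on <- inverse.rle(runs0)
    # width of the contiguous supra-threshold run containing the peak,
    # so P waves or ST shifts cannot bridge into the QRS measurement
    runs <- rle(on)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    ri <- which(runs$values & starts <= which.max(rms) &
                  ends >= which.max(rms))
    widths <- c(widths, (ends[ri] - starts[ri]) / fs)
    aw <- win(r, -0.08, 0.10)
    axisI <- c(axisI, sum(xc[aw, "I"]))
    axisF <- c(axisF, sum(xc[aw, "aVF"]))
    v1r <- c(v1r, max(xc[win(r, -0.08, 0.10), "V1"]))
    v6r <- c(v6r, max(xc[win(r, -0.08, 0.10), "V6"]))
    pr <- win(r, -0.09, -0.06)
    st <- win(r, 0.11, 0.13)
    stlev <- c(stlev, mean(xc[st, c("II", "V5")]) - mean(xc[pr, c("II", "V5")]))
  }
  rr <- diff(peaks) / fs
  c(qrs_width_s = stats::median(widths),
    # aVF carries the Goldberger 0.866 gain relative to the dipole
    axis_deg = atan2(stats::median(axisF) / 0.866, stats::median(axisI)) *
      180 / pi,
    v1_r_mv = stats::median(v1r),
    v6_r_mv = stats::median(v6r),
    st_level_mv = stats::median(stlev),
    heart_rate_bpm = 60 / stats::median(rr))
}

#' Toy rule-based comparator
#'
#' A deliberately sensitive and unspecific rule set standing in for a
#' conventional automated interpreter when demonstrating the evaluation
#' suite.  It flags a record as abnormal when any of the following trips
#' on jittered measurements (the jitter emulates measurement error and
#' is what makes the rules unspecific): QRS width > 110 ms, |frontal
#' axis| > 105 degrees, V1 R amplitude > 0.35 mV, V6 R amplitude >
#' 1.5 mV, |ST level| > 0.1 mV, heart rate > 180 bpm, or heart rate <
#' 58 bpm.  Never used as ground truth.
#'
#' @param record an [ECGRecord-class].
#' @param seed integer seed for the measurement jitter; `NULL` uses the
#'   current RNG stream.
#' @return Logical flag.
#' @export
ruleComparator <- function(record, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- measureECGFeatures(record)
  f["qrs_width_s"] <- f["qrs_width_s"] + rnorm(1, 0, 0.012)
  f["axis_deg"] <- f["axis_deg"] + rnorm(1, 0, 28)
  f["v1_r_mv"] <- f["v1_r_mv"] + rnorm(1, 0, 0.2)
  f["v6_r_mv"] <- f["v6_r_mv"] + rnorm(1, 0, 0.3)
  f["st_level_mv"] <- f["st_level_mv"] + rnorm(1, 0, 0.05)
  unname(f["qrs_width_s"] > 0.110 || abs(f["axis_deg"]) > 105 ||
         f["v1_r_mv"] > 0.35 || f["v6_r_mv"] > 1.5 ||
         abs(f["st_level_mv"]) > 0.10 ||
         f["heart_rate_bpm"] > 180 || f["heart_rate_bpm"] < 58)
}
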