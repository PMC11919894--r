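#' Preprocessing configuration
#'
#' Constants of the raw-record-to-tensor transform: sampling rate,
#' low-pass cutoff, number of target frequency bins, the Cabrera lead
#' sequence and the Pan-Tompkins detector settings.
#'
#' @param fs expected sampling rate in Hz.
#' @param lowpass_hz spectral cutoff; bins above it are discarded.
#' @param n_freq_bins length of the tensor's frequency axis.
#' @param detector_lead signal driving QRS detection: a canonical lead
#'   name, or `"vm"` (default) for the cross-lead vector magnitude
#'   (root-mean-square over the 12 median-centred leads), which keeps
#'   the QRS dominant regardless of the electrical axis.
#' @return A `PreprocessConfig` list, also carrying `cabrera_order` and
#'   the detector band/window constants.
#' @export
preprocessConfig <- function(fs = 500, lowpass_hz = 50, n_freq_bins = 400,
                             detector_lead = "vm") {
  stopifnot(lowpass_hz < fs / 2, n_freq_bins >= 2)
  list(fs = fs, lowpass_hz = lowpass_hz, n_freq_bins = n_freq_bins,
       detector_lead = detector_lead,
       cabrera_order = cabreraLeads(),
       band_hz = c(5, 15), mwi_s = 0.150, refractory_s = 0.200,
       refine_s = 0.050)
}

preprocessFingerprint <- function(cfg) {
  paste0("fs", cfg$fs, "_lp", cfg$lowpass_hz, "_nb", cfg$n_freq_bins,
         "_lead", cfg$detector_lead)
}

#' Pan-Tompkins QRS detection
#'
#' The classic real-time detector chain applied to the configured
#' detector lead: 5-15 Hz band-pass (zero-phase Butterworth), five-point
#' derivative, squaring, 150 ms moving-window integration, then
#' adaptive signal/noise thresholds with a 200 ms refractory period and
#' a search-back pass that revisits long RR gaps at half threshold.
#' Detections are refined to the local extremum of the raw waveform
#' within +-50 ms.
#'
#' @param record an [ECGRecord-class].
#' @param cfg a [preprocessConfig()].
#' @return A list `r_peaks` (strictly increasing 1-based sample
#'   indices), `detector_lead`.  Raises an error mentioning
#'   "insufficient beats" when fewer than 3 QRS complexes are found.
#' @export
detectQRS <- function(record, cfg = preprocessConfig()) {
  fs <- sampleRate(record)
  if (identical(cfg$detector_lead, "vm")) {
    m <- leadMatrix(record)
    ctr <- sweep(m, 2, apply(m, 2, stats::median))
    x <- sqrt(rowMeans(ctr^2))
  } else {
    x <- leadMatrix(record)[, cfg$detector_lead]
  }
  n <- length(x)
  if (stats::sd(x) < 1e-9)
    stop("insufficient beats: detector signal is flat")

  bf <- signal::butter(2, cfg$band_hz / (fs / 2), type = "pass")
  xb <- signal::filtfilt(bf, x - mean(x))
  # five-point derivative (1/8)(2x[n] + x[n-1] - x[n-3] - 2x[n-4])
  xd <- stats::filter(xb, c(2, 1, 0, -1, -2) / 8, sides = 1)
  xd[is.na(xd)] <- 0
  xs <- as.numeric(xd)^2
  mwiN <- max(1L, round(cfg$mwi_s * fs))
  xi <- as.numeric(stats::filter(xs, rep(1 / mwiN, mwiN), sides = 1))
  xi[is.na(xi)] <- 0

  refr <- round(cfg$refractory_s * fs)
  # candidate peaks of the integrated signal
  cand <- which(diff(sign(diff(xi))) < 0) + 1L
  cand <- cand[xi[cand] > 0]
  if (!length(cand)) stop("insufficient beats: no activity detected")

  spki <- max(xi[seq_len(min(n, 2 * fs))]) * 0.5
  npki <- mean(xi[seq_len(min(n, 2 * fs))]) * 0.5
  thr <- function() npki + 0.25 * (spki - npki)
  peaks <- integer()
  rrAvg <- NA_real_
  lastQ <- -Inf
  # one QRS complex can carry several local maxima of the integrated
  # signal; the complex is represented by the largest within a
  # refractory span of the first threshold crossing
  complexMax <- function(p) {
    cw <- cand[cand >= p & cand < p + refr]
    cw[which.max(xi[cw])]
  }
  for (p in cand) {
    if (p - lastQ < refr) next
    if (xi[p] >= thr()) {
      # search-back: a long gap since the previous beat is rescanned
      if (!is.na(rrAvg) && length(peaks) && (p - lastQ) > 1.66 * rrAvg) {
        gap <- cand[cand > lastQ + refr & cand < p - refr / 2]
        gap <- gap[xi[gap] >= thr() / 2]
        if (length(gap)) {
          gb <- gap[which.max(xi[gap])]
          peaks <- c(peaks, gb)
          spki <- 0.25 * xi[gb] + 0.75 * spki
        }
      }
      cm <- complexMax(p)
      peaks <- c(peaks, cm)
      spki <- 0.125 * xi[cm] + 0.875 * spki
      if (length(peaks) >= 2) {
        rrs <- diff(tail(peaks, 9))
        rrAvg <- mean(rrs)
      }
      lastQ <- cm
    } else {
      npki <- 0.125 * xi[p] + 0.875 * npki
    }
  }
  if (length(peaks) < 3)
    stop("insufficient beats: only ", length(peaks), " QRS detections")

  # refine to the raw-waveform extremum within +-refine_s of the
  # integration peak corrected for the moving window's group delay
  half <- as.integer(round(cfg$refine_s * fs))
  delay <- as.integer(round(mwiN / 2))
  xc <- x - stats::median(x)
  refined <- vapply(peaks, function(p) {
    ctr <- max(1L, p - delay)
    lo <- max(1L, ctr - half); hi <- min(n, ctr + half)
    as.integer(lo + which.max(abs(xc[lo:hi])) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory invariant after refinement
  keep <- c(TRUE, diff(refined) >= 0.2 * fs)
  while (!all(keep)) {
    refined <- refined[keep]
    keep <- c(TRUE, diff(refined) >= 0.2 * fs)
  }
  if (length(refined) < 3)
    stop("insufficient beats: only ", length(refined), " QRS detections")
  list(r_peaks = refined, detector_lead = cfg$detector_lead)
}

#' Extract the analysis segment between the second and last QRS
#'
#' Returns, for every lead, the samples in the half-open window from the
#' second R peak (inclusive) to the last R peak (exclusive), so the
#' segment covers a whole number of cardiac cycles.
#'
#' @param record an [ECGRecord-class].
#' @param ann annotation from [detectQRS()] (or a compatible list with
#'   `r_peaks`).
#' @return List with `segment` (L x 12 matrix, canonical lead order),
#'   `L`, `fs`, `record_id`.
#' @export
extractSegment <- function(record, ann) {
  r <- ann$r_peaks
  if (length(r) < 3) stop("insufficient beats: need at least 3 R peaks")
  lo <- r[2]; hi <- r[length(r)] - 1L
  seg <- leadMatrix(record)[lo:hi, , drop = FALSE]
  fs <- sampleRate(record)
  if (nrow(seg) < 0.4 * fs)
    stop("segment too short: ", nrow(seg), " samples")
  list(segment = seg, L = nrow(seg), fs = fs, record_id = recordId(record))
}

#' Per-lead amplitude and phase spectra with a 50 Hz low-pass
#'
#' Real-input discrete Fourier transform of each lead of a segment.
#' Amplitudes are scaled by `2/L` (DC and, for even `L`, the Nyquist bin
#' by `1/L`) so that a unit-amplitude sinusoid contributes a bin
#' amplitude of about 1 mV regardless of segment length.  Only the
#' `B = floor(lowpass_hz * L / fs) + 1` bins at or below the cutoff are
#' retained; phases come from the same coefficients.
#'
#' @param seg segment list from [extractSegment()].
#' @param cfg a [preprocessConfig()].
#' @return List with `amplitude` and `phase` (B x 12 matrices, canonical
#'   lead order), `freq` (Hz), `L`, `fs`, `B`, `record_id`.
#' @export
spectralTransform <- function(seg, cfg = preprocessConfig()) {
  L <- seg$L; fs <- seg$fs
  if (L < 2) stop("degenerate segment length")
  B <- floor(cfg$lowpass_hz * L / fs) + 1L
  co <- stats::mvfft(seg$segment)[seq_len(B), , drop = FALSE]
  scale <- rep(2 / L, B)
  scale[1] <- 1 / L
  if (L %% 2 == 0 && B == L / 2 + 1) scale[B] <- 1 / L
  amplitude <- abs(co) * scale
  phase <- Arg(co)
  list(amplitude = amplitude, phase = phase,
       freq = (seq_len(B) - 1) * fs / L, L = L, fs = fs, B = B,
       record_id = seg$record_id)
}

#' Invert retained amplitude/phase spectra back to the time domain
#'
#' Reconstructs the low-passed segment from the retained bins: the
#' amplitude scaling of [spectralTransform()] is undone, bins above the
#' cutoff are zero, and conjugate symmetry is restored before the
#' inverse FFT.  With the full retained grid this reproduces the 50 Hz
#' low-passed segment to numerical precision.
#'
#' @param amplitude,phase B x k matrices (any number of columns).
#' @param L,fs segment length (samples) and sampling rate (Hz).
#' @return L x k matrix of reconstructed signals.
#' @export
inverseSpectralTransform <- function(amplitude, phase, L, fs) {
  B <- nrow(amplitude)
  k <- ncol(amplitude)
  nb <- floor(L / 2) + 1L           # one-sided spectrum length
  out <- matrix(0, L, k)
  scale <- rep(L / 2, B)
  scale[1] <- L
  if (L %% 2 == 0 && B == L / 2 + 1) scale[B] <- L
  for (j in seq_len(k)) {
    half <- complex(modulus = 1, argument = 0) * numeric(nb)
    half[seq_len(B)] <- amplitude[, j] * scale *
      complex(modulus = 1, argument = phase[, j])
    full <- c(half, Conj(rev(half[2:(L - nb + 1)])))
    out[, j] <- Re(stats::fft(full, inverse = TRUE)) / L
  }
  out
}

#' Reorder leads into the Cabrera sequence
#'
#' Arranges the frontal leads in contiguous anatomical angle order with
#' aVR sign-inverted (-aVR), then appends the chest leads: aVL, I,
#' -aVR, II, aVF, III, V1..V6.  A pure permutation plus one sign flip,
#' hence exactly invertible with [cabreraInverse()].
#'
#' @param x matrix or data with leads along `margin`; lead names must be
#'   the canonical set.
#' @param margin 1 if rows are leads, 2 if columns are leads.
#' @return Same data with the lead axis in Cabrera order (names from
#'   [cabreraLeads()]).
#' @export
cabreraReorder <- function(x, margin = 2) {
  ord <- c("aVL", "I", "aVR", "II", "aVF", "III",
           "V1", "V2", "V3", "V4", "V5", "V6")
  nm <- if (margin == 2) colnames(x) else rownames(x)
  missing_leads <- setdiff(canonicalLeads(), nm)
  if (length(missing_leads))
    stop("missing lead(s): ", paste(missing_leads, collapse = ", "))
  if (margin == 2) {
    out <- x[, ord, drop = FALSE]
    out[, "aVR"] <- -out[, "aVR"]
    colnames(out) <- cabreraLeads()
  } else {
    out <- x[ord, , drop = FALSE]
    out["aVR", ] <- -out["aVR", ]
    rownames(out) <- cabreraLeads()
  }
  out
}

#' @rdname cabreraReorder
#' @export
cabreraInverse <- function(x, margin = 2) {
  nm <- if (margin == 2) colnames(x) else rownames(x)
  if (!identical(nm, cabreraLeads()))
    stop("input is not in Cabrera order")
  if (margin == 2) {
    x[, "-aVR"] <- -x[, "-aVR"]
    colnames(x)[colnames(x) == "-aVR"] <- "aVR"
    x[, canonicalLeads(), drop = FALSE]
  } else {
    x["-aVR", ] <- -x["-aVR", ]
    rownames(x)[rownames(x) == "-aVR"] <- "aVR"
    x[canonicalLeads(), , drop = FALSE]
  }
}

wrapPhase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

#' Resample retained spectra onto the tensor's frequency grid
#'
#' Linear interpolation of the amplitude spectrum onto `n_freq_bins`
#' equally spaced frequencies over `[0, lowpass_hz]`.  Phase is
#' interpolated on the unwrapped phase and rewrapped to `(-pi, pi]`,
#' which avoids spurious discontinuities at the +-pi boundary.  When the
#' source grid is finer than the target, values are interpolated at the
#' target frequencies (not bin-averaged).  Beyond the last retained
#' source frequency the end value is carried forward.
#'
#' @param amplitude,phase B x k source matrices.
#' @param freq source frequencies (Hz, length B, ascending).
#' @param n_freq_bins target bin count.
#' @param lowpass_hz top of the target grid.
#' @return List `amplitude`, `phase` (n_freq_bins x k), `freq`.
#' @export
resizeSpectrum <- function(amplitude, phase, freq, n_freq_bins = 400,
                           lowpass_hz = 50) {
  if (length(freq) < 2) stop("need at least 2 source bins to resize")
  target <- seq(0, lowpass_hz, length.out = n_freq_bins)
  k <- ncol(amplitude)
  ampOut <- matrix(0, n_freq_bins, k, dimnames = list(NULL, colnames(amplitude)))
  phaOut <- ampOut
  for (j in seq_len(k)) {
    ampOut[, j] <- stats::approx(freq, amplitude[, j], xout = target,
                                 rule = 2)$y
    unwrapped <- signal::unwrap(phase[, j])
    phaOut[, j] <- wrapPhase(stats::approx(freq, unwrapped, xout = target,
                                           rule = 2)$y)
  }
  list(amplitude = ampOut, phase = phaOut, freq = target)
}

# inverse of the resize mapping: take tensor-grid values back to the
# record's retained source grid by interpolation
unresizeSpectrum <- function(values, targetFreq, srcFreq) {
  apply(values, 2, function(v)
    stats::approx(targetFreq, v, xout = srcFreq, rule = 2)$y)
}

#' Build the model input for one record
#'
#' Full preprocessing chain: Pan-Tompkins detection, segment extraction
#' between the second and last QRS, per-lead Fourier amplitude/phase
#' with 50 Hz low-pass, Cabrera lead reordering (with -aVR) and
#' resampling onto the tensor's frequency grid.  The returned tensor
#' keeps the original retained-bin spectra in its metadata so that the
#' saliency mapping can invert the transform.
#'
#' @param record an [ECGRecord-class].
#' @param cfg a [preprocessConfig()].
#' @return List with `tensor` (a [SpectralTensor-class]) and `meta_vector`
#'   (`c(age/18, sex)` with male = 1, female = 0).
#' @export
buildInputTensor <- function(record, cfg = preprocessConfig()) {
  ann <- detectQRS(record, cfg)
  seg <- extractSegment(record, ann)
  sp <- spectralTransform(seg, cfg)
  ampC <- cabreraReorder(sp$amplitude, margin = 2)
  phaC <- cabreraReorder(sp$phase, margin = 2)
  # the sign flip of -aVR belongs in the complex coefficient, i.e. a
  # phase shift of pi with unchanged magnitude
  ampC[, "-aVR"] <- abs(ampC[, "-aVR"])
  phaC[, "-aVR"] <- wrapPhase(sp$phase[, "aVR"] + pi)
  rs <- resizeSpectrum(ampC, phaC, sp$freq, cfg$n_freq_bins, cfg$lowpass_hz)
  values <- array(0, dim = c(2, 12, cfg$n_freq_bins))
  values[1, , ] <- t(rs$amplitude)
  values[2, , ] <- t(rs$phase)
  tensor <- new("SpectralTensor", values = values, freq = rs$freq,
                meta = list(L = sp$L, fs = sp$fs, B = sp$B,
                            srcFreq = sp$freq, phase = phaC,
                            amplitude = ampC,
                            fingerprint = preprocessFingerprint(cfg)),
                recordId = recordId(record))
  sexCode <- if (recordSex(record) == "male") 1 else 0
  list(tensor = tensor, meta_vector = c(recordAge(record) / 18, sexCode))
}

#' Preprocess a whole cohort into stacked model inputs
#'
#' Applies [buildInputTensor()] to every record and stacks the results
#' into the flat matrices the training engine consumes.
#'
#' @param records list of [ECGRecord-class] objects.
#' @param cfg a [preprocessConfig()].
#' @param keep_tensors also return the per-record [SpectralTensor-class]
#'   objects (needed for saliency mapping; disable for large training
#'   cohorts to halve memory).
#' @param verbose print progress every 200 records.
#' @return List with `amp`, `pha` (4800 x n matrices: 12 leads x
#'   `n_freq_bins` bins, lead-fastest), `meta` (2 x n), `record_ids`,
#'   `tensors` (list of [SpectralTensor-class], or `NULL`),
#'   `fingerprint`.
#' @export
cohortTensors <- function(records, cfg = preprocessConfig(),
                          keep_tensors = TRUE, verbose = FALSE) {
  n <- length(records)
  d <- 12 * cfg$n_freq_bins
  amp <- matrix(0, d, n); pha <- matrix(0, d, n); meta <- matrix(0, 2, n)
  tensors <- vector("list", n)
  for (i in seq_len(n)) {
    bi <- buildInputTensor(records[[i]], cfg)
    v <- tensorValues(bi$tensor)
    amp[, i] <- as.numeric(v[1, , ])   # lead index fastest
    pha[, i] <- as.numeric(v[2, , ])
    meta[, i] <- bi$meta_vector
    if (keep_tensors) tensors[[i]] <- bi$tensor
    if (verbose && i %% 200 == 0)
      message("preprocessed ", i, "/", n, " records")
  }
  list(amp = amp, pha = pha, meta = meta,
       record_ids = vapply(records, recordId, character(1)),
       tensors = if (keep_tensors) tensors,
       fingerprint = preprocessFingerprint(cfg))
}
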