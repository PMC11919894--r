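test_that("a flat record raises an insufficient-beats error", {
  x <- matrix(0, 5000, 12)
  colnames(x) <- canonicalLeads()
  rec <- ECGRecord(x, age = 10, sex = "male")
  expect_error(detectQRS(rec), "insufficient beats")
  expect_error(buildInputTensor(rec), "insufficient beats")
})

test_that("detection matches generator truth on clean records", {
  rec60 <- cleanRecord(hr = 60, seed = 1, noise = 0.01)
  ann <- detectQRS(rec60)
  m <- matchPeaks(ann$r_peaks, truePeaks(rec60))
  expect_equal(unname(m["recall"]), 1)
  expect_equal(unname(m["precision"]), 1)

  rec150 <- cleanRecord(hr = 150, seed = 2, noise = 0.01)
  ann <- detectQRS(rec150)
  expect_gte(length(ann$r_peaks), 24)
  expect_lte(length(ann$r_peaks), 26)
  m <- matchPeaks(ann$r_peaks, truePeaks(rec150))
  expect_equal(unname(m["recall"]), 1)
})

test_that("detections respect the refractory invariant and record bounds", {
  for (seed in 1:5) {
    rec <- cleanRecord(hr = sample(60:180, 1), seed = seed, noise = 0.02)
    r <- detectQRS(rec)$r_peaks
    expect_true(all(diff(r) >= 0.2 * sampleRate(rec)))
    expect_true(all(r >= 1 & r <= nrow(leadMatrix(rec))))
  }
})

test_that("Pan-Tompkins attains 0.99 recall and precision on clean cohorts", {
  set.seed(13)
  hits <- truthN <- detN <- 0
  for (i in 1:25) {
    hr <- sample(60:180, 1)
    code <- sample(c("normal", findingVocabulary()), 1)
    rec <- cleanRecord(hr = hr, seed = 3000 + i, noise = 0.02,
                       finding = if (code == "normal") NULL else code,
                       severity = runif(1, 0.7, 1))
    det <- detectQRS(rec)$r_peaks
    tr <- truePeaks(rec)
    m <- matchPeaks(det, tr)
    hits <- hits + m["recall"] * length(tr)
    truthN <- truthN + length(tr)
    detN <- detN + length(det)
  }
  expect_gte(hits / truthN, 0.99)   # recall
  expect_gte(hits / detN, 0.99)     # precision
})

test_that("segment extraction spans [second R, last R)", {
  rec <- cleanRecord(seed = 4)
  seg <- extractSegment(rec, list(r_peaks = c(100L, 600L, 4600L)))
  expect_equal(seg$L, 4000)
  expect_equal(seg$segment[1, ], leadMatrix(rec)[600, ])
  expect_equal(seg$segment[seg$L, ], leadMatrix(rec)[4599, ])

  # exactly three peaks -> the middle RR span only
  seg3 <- extractSegment(rec, list(r_peaks = c(200L, 900L, 1600L)))
  expect_equal(seg3$L, 700)
  expect_error(extractSegment(rec, list(r_peaks = c(1L, 2L))),
               "insufficient beats")
})

test_that("an HR 60 record yields a segment of about 8 cardiac cycles", {
  rec <- cleanRecord(hr = 60, seed = 6, noise = 0.01)
  ann <- detectQRS(rec)
  seg <- extractSegment(rec, ann)
  tr <- truePeaks(rec)
  expected <- tr[length(tr)] - tr[2]
  expect_equal(seg$L, expected, tolerance = 0.02)
})

makeSeg <- function(x, fs = 500) {
  m <- matrix(rep(x, 12), ncol = 12)
  colnames(m) <- canonicalLeads()
  list(segment = m, L = length(x), fs = fs, record_id = "seg")
}

test_that("a unit sinusoid below the cutoff lands in its bin at 1 mV", {
  L <- 4000; fs <- 500
  tt <- (seq_len(L) - 1) / fs
  sp <- spectralTransform(makeSeg(sin(2 * pi * 10 * tt)))
  expect_equal(nrow(sp$amplitude), floor(50 * L / fs) + 1)
  k <- which.max(sp$amplitude[, 1])
  expect_equal(sp$freq[k], 10)
  expect_lt(abs(sp$amplitude[k, 1] - 1), 0.01)
})

test_that("content above the 50 Hz cutoff is discarded", {
  L <- 4000; fs <- 500
  tt <- (seq_len(L) - 1) / fs
  sp <- spectralTransform(makeSeg(sin(2 * pi * 60 * tt)))
  expect_lt(max(sp$amplitude), 1e-6)
})

test_that("retained spectra invert to the low-passed segment", {
  set.seed(8)
  L <- 3100; fs <- 500
  tt <- (seq_len(L) - 1) / fs
  # mixed content: in-band bin-aligned tones + an out-of-band tone
  kIn <- c(12, 77, 240)            # bin indices (freq = k*fs/L < 50)
  x <- rowSums(sapply(kIn, function(k)
    runif(1, 0.2, 1) * cos(2 * pi * k * tt / (L / fs) + runif(1, 0, 2 * pi))))
  x60 <- 0.5 * sin(2 * pi * 60 * tt)
  sp <- spectralTransform(makeSeg(x + x60))
  back <- inverseSpectralTransform(sp$amplitude, sp$phase, sp$L, sp$fs)
  # oracle: zero all FFT coefficients above the cutoff, invert directly
  co <- stats::fft(x + x60)
  keep <- c(seq_len(sp$B), seq(L - sp$B + 2, L))
  co[setdiff(seq_len(L), keep)] <- 0
  oracle <- Re(stats::fft(co, inverse = TRUE)) / L
  expect_lt(max(abs(back[, 1] - oracle)) / max(abs(oracle)), 1e-9)
})

test_that("Cabrera reorder is the documented signed permutation", {
  set.seed(9)
  x <- matrix(rnorm(12 * 30), 30, 12)
  colnames(x) <- canonicalLeads()
  y <- cabreraReorder(x)
  expect_identical(colnames(y), cabreraLeads())
  perm <- c("aVL", "I", "aVR", "II", "aVF", "III", paste0("V", 1:6))
  sign <- ifelse(perm == "aVR", -1, 1)
  for (j in seq_along(perm))
    expect_equal(y[, j], sign[j] * x[, perm[j]], ignore_attr = TRUE)
  expect_identical(cabreraInverse(y), x[, canonicalLeads()])

  onlyAVR <- matrix(0, 10, 12, dimnames = list(NULL, canonicalLeads()))
  onlyAVR[, "aVR"] <- 1:10
  z <- cabreraReorder(onlyAVR)
  expect_equal(unname(z[, 3]), -(1:10))
  expect_true(all(z[, -3] == 0))

  expect_error(cabreraReorder(x[, 1:11]), "missing lead")
})

test_that("spectrum resize is exact on a matching grid and keeps constants", {
  fs <- 500; L <- 3990           # source grid == target grid (400 bins)
  B <- floor(50 * L / fs) + 1
  expect_equal(B, 400)
  freq <- (seq_len(B) - 1) * fs / L
  set.seed(10)
  amp <- matrix(abs(rnorm(B * 3)), B, 3)
  pha <- matrix(runif(B * 3, -pi, pi), B, 3)
  rs <- resizeSpectrum(amp, pha, freq, 400, 50)
  expect_equal(rs$amplitude, amp, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(rs$phase, pha, ignore_attr = TRUE, tolerance = 1e-12)

  constAmp <- matrix(0.7, 101, 1)
  rs2 <- resizeSpectrum(constAmp, matrix(1.1, 101, 1),
                        seq(0, 50, length.out = 101), 400, 50)
  expect_true(all(abs(rs2$amplitude - 0.7) < 1e-12))
  expect_true(all(abs(rs2$phase - 1.1) < 1e-12))
})

test_that("a single source bin stays localised after resize", {
  B <- 101
  freq <- seq(0, 50, length.out = B)
  amp <- matrix(0, B, 1); amp[41, 1] <- 2    # 20 Hz
  rs <- resizeSpectrum(amp, matrix(0, B, 1), freq, 400, 50)
  mass <- which(rs$amplitude[, 1] > 1e-9)
  expect_true(all(abs(rs$freq[mass] - 20) <= diff(freq)[1] + 1e-9))
  # off-grid target bins interpolate the peak; its height stays bounded
  expect_gt(max(rs$amplitude), 1.5)
  expect_lte(max(rs$amplitude), 2)
})

test_that("phase resize interpolates on the unwrapped phase", {
  # a linear phase ramp crossing the +-pi boundary must stay a ramp
  B <- 51
  freq <- seq(0, 50, length.out = B)
  ramp <- seq(0, 6 * pi, length.out = B)
  wrapped <- (ramp + pi) %% (2 * pi) - pi
  rs <- resizeSpectrum(matrix(1, B, 1), matrix(wrapped, B, 1), freq, 200, 50)
  target_ramp <- stats::approx(freq, ramp, xout = rs$freq)$y
  rewrapped <- (target_ramp + pi) %% (2 * pi) - pi
  rewrapped[rewrapped <= -pi] <- pi
  expect_lt(max(abs(rs$phase[, 1] - rewrapped)), 1e-9)
})

test_that("the input tensor has shape 2 x 12 x 400 with valid channels", {
  rec <- cleanRecord(hr = 90, seed = 12, noise = 0.01)
  bi <- buildInputTensor(rec)
  v <- tensorValues(bi$tensor)
  expect_identical(dim(v), c(2L, 12L, 400L))
  expect_true(all(is.finite(v)))
  expect_true(all(v[1, , ] >= 0))
  expect_true(all(v[2, , ] > -pi - 1e-9 & v[2, , ] <= pi + 1e-9))
  expect_equal(bi$meta_vector, c(10 / 18, 1))
})

test_that("lead order in the input file does not affect the tensor", {
  rec <- cleanRecord(seed = 14, noise = 0.01)
  x <- leadMatrix(rec)
  shuffled <- x[, sample(12)]
  rec2 <- ECGRecord(shuffled, age = recordAge(rec), sex = recordSex(rec),
                    recordId = recordId(rec))
  expect_identical(tensorValues(buildInputTensor(rec)$tensor),
                   tensorValues(buildInputTensor(rec2)$tensor))
})
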