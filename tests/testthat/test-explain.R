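engine <- asNamespace("schoolECG")

# a network whose convolutions are pass-through (centre-tap averaging
# kernels, zero bias) and whose dense path is non-negative: the feature
# map at any conv layer is then a hand-computable max-pool cascade of
# the amplitude input
passthroughModel <- function(arch) {
  params <- buildModel(arch, 1)
  plan <- schoolECG:::convPlan(arch)
  for (l in seq_len(nrow(plan))) {
    W <- matrix(0, plan$cout[l], 9 * plan$cin[l])
    centre <- 4 * plan$cin[l] + seq_len(plan$cin[l])   # j = 4 block
    W[, centre] <- 1 / plan$cin[l]
    params$conv[[l]]$W <- W
    params$conv[[l]]$b <- numeric(plan$cout[l])
  }
  for (l in 1:3) {
    params$dense[[l]]$W <- abs(params$dense[[l]]$W)
    params$dense[[l]]$b <- numeric(length(params$dense[[l]]$b))
  }
  params
}

maxpool2 <- function(m, ph, pw) {
  Ho <- nrow(m) %/% ph; Wo <- ncol(m) %/% pw
  out <- matrix(0, Ho, Wo)
  for (i in seq_len(Ho)) for (j in seq_len(Wo))
    out[i, j] <- max(m[((i - 1) * ph + 1):(i * ph),
                       ((j - 1) * pw + 1):(j * pw)])
  out
}

test_that("feature maps of a pass-through network are the pooled input", {
  arch <- tinyArch()
  params <- passthroughModel(arch)
  set.seed(3)
  amp <- matrix(abs(rnorm(arch$n_leads * arch$n_freq)) + 0.1, 12, arch$n_freq)
  inp <- list(amp = matrix(as.numeric(amp), ncol = 1),
              pha = matrix(0, length(amp), 1),
              meta = matrix(c(0.5, 1), 2, 1))
  # expected map at trunk conv 5 (engine layer 6): pools applied so far
  # are the stem (1,4) pool and the (1,2) pool after trunk conv 2; the
  # zero-phase stem contributes half of the averaged channels
  expected <- maxpool2(maxpool2(amp, 1, 4), 1, 2) / 2
  gc <- engine$cnn_gradcam_cpp(params, arch, inp$amp, inp$pha, inp$meta, 6L)
  for (ch in seq_len(dim(gc$fmap)[3]))
    expect_equal(gc$fmap[, , ch], expected, tolerance = 1e-5,
                 ignore_attr = TRUE)
  # with an all-positive head, saliency gradients are non-negative
  expect_true(all(gc$grad >= -1e-7))
})

trainedTinyEnsemble <- function() {
  if (is.null(.fixtures$tinyEns)) {
    arch <- tinyArch()
    set.seed(40)
    n <- 80
    d <- arch$n_leads * arch$n_freq
    y <- rep(c(0, 1), n / 2)
    pattern <- abs(rnorm(d)) * (runif(d) < 0.1)
    inputs <- list(amp = matrix(abs(rnorm(d * n, 0, 0.2)), d, n) +
                     outer(pattern, y),
                   pha = matrix(runif(d * n, -pi, pi), d, n),
                   meta = rbind(runif(n, 0.3, 1), sample(0:1, n, TRUE)),
                   record_ids = sprintf("r%03d", 1:n),
                   fingerprint = "test")
    ens <- trainEnsemble(inputs, y, sprintf("p%02d", 1:n), arch,
                         trainConfig("desk", epochs = 2, seed = 2))
    .fixtures$tinyEns <- list(ens = ens, inputs = inputs)
  }
  .fixtures$tinyEns
}

test_that("grad-CAM maps are normalised and match the input geometry", {
  te <- trainedTinyEnsemble()
  for (ci in c(3, 12, 16)) {
    cam <- gradCAM(te$ens, te$inputs, index = 2, conv_index = ci)
    expect_identical(dim(cam$values), c(12L, 128L))   # tiny input grid
    expect_true(all(cam$values >= 0))
    expect_true(all(cam$values <= 1))
    if (max(cam$values) > 0) expect_equal(max(cam$values), 1)
  }
  expect_error(gradCAM(te$ens, te$inputs, index = 1, conv_index = 17),
               "conv_index")

  # at the standard tensor geometry the map is 12 x 400 at any layer
  rec <- cleanRecord(hr = 80, seed = 81, noise = 0.01)
  inputs <- cohortTensors(list(rec))
  arch <- architectureConfig(preset = "desk")
  model <- list(params = buildModel(arch, 1), arch = arch)
  for (ci in c(5, 12)) {
    cam <- gradCAM(model, inputs, index = 1, conv_index = ci)
    expect_identical(dim(cam$values), c(12L, 400L))
  }
})

tensorForRecord <- function(seed = 55) {
  rec <- cleanRecord(hr = 80, seed = seed, noise = 0.01)
  buildInputTensor(rec)
}

test_that("an all-zero CAM maps to an all-zero heatmap", {
  bi <- tensorForRecord()
  cam <- structure(list(values = matrix(0, 12, 400), conv_index = 12,
                        record_id = recordId(bi$tensor)),
                   class = "ClassActivationMap")
  sal <- camToTime(cam, bi$tensor, normalize = FALSE)
  expect_true(all(sal == 0))
  expect_equal(nrow(sal), tensorMeta(bi$tensor)$L)
  hm <- camToTime(cam, bi$tensor)   # normalised form stays all zero
  expect_true(all(hm@values == 0))
})

test_that("a single-bin CAM with zero phase is a smoothed cosine envelope", {
  bi <- tensorForRecord()
  meta <- tensorMeta(bi$tensor)
  L <- meta$L; fs <- meta$fs
  # pick an exact retained-bin frequency and zero the stored phase
  kSrc <- 80
  f0 <- meta$srcFreq[kSrc]
  tensor0 <- bi$tensor
  tensor0@meta$phase <- matrix(0, meta$B, 12)
  vals <- matrix(0, 12, 400)
  # place the CAM mass at the target bin nearest the source frequency
  target <- seq(0, 50, length.out = 400)
  vals[, which.min(abs(target - f0))] <- 1
  cam <- structure(list(values = vals, conv_index = 12,
                        record_id = recordId(bi$tensor)),
                   class = "ClassActivationMap")
  sal <- camToTime(cam, tensor0, normalize = FALSE)
  # closed form: the CAM row resampled back to the source grid spreads
  # over the neighbouring bins; reconstruct that spectrum analytically
  ampB <- stats::approx(target, vals[1, ], xout = meta$srcFreq,
                        rule = 2)$y
  tt <- (seq_len(L) - 1) / fs
  wave <- rowSums(sapply(which(ampB > 0), function(k)
    ampB[k] * cos(2 * pi * meta$srcFreq[k] * tt)))
  win <- round(0.040 * fs)
  sm <- as.numeric(stats::filter(abs(wave), rep(1 / win, win), sides = 2))
  keep <- !is.na(sm)
  expect_lt(max(abs(sal[keep, 1] - sm[keep])) / max(sm[keep]), 0.02)
})

test_that("the un-normalised heatmap is homogeneous in the CAM", {
  bi <- tensorForRecord()
  set.seed(5)
  vals <- matrix(runif(12 * 400), 12, 400)
  mk <- function(v) structure(list(values = v, conv_index = 12,
                                   record_id = recordId(bi$tensor)),
                              class = "ClassActivationMap")
  h1 <- camToTime(mk(vals), bi$tensor, normalize = FALSE)
  h2 <- camToTime(mk(2 * vals), bi$tensor, normalize = FALSE)
  expect_equal(h2, 2 * h1, tolerance = 1e-9)
})

test_that("heatmap length equals the segment length across records", {
  for (seed in c(61, 62, 63)) {
    bi <- tensorForRecord(seed)
    cam <- structure(list(values = matrix(runif(4800), 12, 400),
                          conv_index = 12,
                          record_id = recordId(bi$tensor)),
                     class = "ClassActivationMap")
    hm <- camToTime(cam, bi$tensor)
    expect_equal(nrow(hm@values), tensorMeta(bi$tensor)$L)
    expect_true(all(hm@values >= 0 & hm@values <= 1))
  }
})

test_that("record/CAM mismatches are refused", {
  bi <- tensorForRecord()
  cam <- structure(list(values = matrix(0, 12, 400), conv_index = 12,
                        record_id = "someone_else"),
                   class = "ClassActivationMap")
  expect_error(camToTime(cam, bi$tensor), "belongs")
})

test_that("the overlay renderer writes deterministic images", {
  skip_if_not_installed("png")
  tmp <- withr::local_tempdir()
  rec <- cleanRecord(hr = 80, seed = 71, noise = 0.01)
  bi <- buildInputTensor(rec)
  cam <- structure(list(values = matrix(runif(4800), 12, 400),
                        conv_index = 12, record_id = recordId(rec)),
                   class = "ClassActivationMap")
  hm <- camToTime(cam, bi$tensor)
  p1 <- file.path(tmp, "o1.png"); p2 <- file.path(tmp, "o2.png")
  renderOverlay(rec, hm, p1)
  renderOverlay(rec, hm, p2)
  expect_gt(file.size(p1), 0)
  d1 <- dim(png::readPNG(p1)); d2 <- dim(png::readPNG(p2))
  expect_identical(d1, d2)

  zero <- new("TimeHeatmap", values = matrix(0, nrow(hm@values), 12,
                                             dimnames = list(NULL,
                                                             cabreraLeads())),
              fs = 500, recordId = recordId(rec))
  p3 <- file.path(tmp, "plain.png")
  renderOverlay(rec, zero, p3)
  expect_gt(file.size(p3), 0)
})
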