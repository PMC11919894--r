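#' Grad-CAM on the spectral input
#'
#' Gradient-weighted class activation mapping of the abnormality logit
#' at a chosen convolutional layer: per-channel weights are the spatial
#' mean of the logit's gradient on that layer's feature maps, the map is
#' the ReLU of the weighted feature-map sum, bilinearly upsampled from
#' the layer's lead x frequency resolution to 12 x 400 and
#' max-normalised.  Convolutions are indexed through the amplitude stem
#' (1-2) and then the trunk (3-16); the default target is the 12th.
#' For an ensemble the per-fold maps are averaged before normalisation,
#' matching the mean-probability prediction rule.
#'
#' @param model an [ECGEnsemble-class], or a list `list(params, arch)`
#'   for a single network.
#' @param inputs stacked tensors from [cohortTensors()].
#' @param index which record (column) of `inputs` to explain.
#' @param conv_index 1-based convolution index; defaults to the
#'   architecture's `gradcam_conv`.
#' @return A `ClassActivationMap`: list with `values` (12 x 400 in
#'   `[0, 1]`, Cabrera lead order), `conv_index`, `record_id`.
#' @export
gradCAM <- function(model, inputs, index = 1, conv_index = NULL) {
  if (is(model, "ECGEnsemble")) {
    arch <- model@arch
    paramSets <- lapply(model@folds, function(f) f$params)
  } else {
    arch <- model$arch
    paramSets <- list(model$params)
  }
  if (is.null(conv_index)) conv_index <- arch$gradcam_conv
  nConv <- 2 + length(arch$trunk_channels)
  if (conv_index < 1 || conv_index > nConv)
    stop("conv_index must lie in 1..", nConv)
  xa <- inputs$amp[, index, drop = FALSE]
  xp <- inputs$pha[, index, drop = FALSE]
  mv <- inputs$meta[, index, drop = FALSE]
  acc <- NULL
  for (p in paramSets) {
    gc <- cnn_gradcam_cpp(p, arch, xa, xp, mv, conv_index - 1L)
    w <- apply(gc$grad, 3, mean)
    cam <- matrix(0, dim(gc$fmap)[1], dim(gc$fmap)[2])
    for (ch in seq_along(w)) cam <- cam + w[ch] * gc$fmap[, , ch]
    cam[cam < 0] <- 0
    acc <- if (is.null(acc)) cam else acc + cam
  }
  cam <- bilinearUpsample(acc / length(paramSets), arch$n_leads, arch$n_freq)
  cam[cam < 0] <- 0
  if (max(cam) > 0) cam <- cam / max(cam)
  out <- list(values = cam, conv_index = conv_index,
              record_id = inputs$record_ids[index] %||% NA_character_)
  class(out) <- "ClassActivationMap"
  out
}

# centre-aligned bilinear upsampling of a matrix to (H, W)
bilinearUpsample <- function(m, H, W) {
  sh <- nrow(m); sw <- ncol(m)
  srcRow <- if (sh == 1) rep(1, H) else (seq_len(H) - 0.5) * sh / H + 0.5
  srcCol <- if (sw == 1) rep(1, W) else (seq_len(W) - 0.5) * sw / W + 0.5
  rows <- if (sh == 1) matrix(m[1, ], 1) else
    apply(m, 2, function(v) stats::approx(seq_len(sh), v, xout = srcRow,
                                          rule = 2)$y)
  rows <- matrix(rows, nrow = H)
  t(apply(rows, 1, function(v) stats::approx(seq_len(sw), v, xout = srcCol,
                                             rule = 2)$y))
}

#' Map a class activation map back to the time domain
#'
#' Treats the CAM row of each lead as a surrogate amplitude spectrum:
#' it is resampled from the 400-bin tensor grid back to the record's
#' retained frequency bins (the inverse of the resize interpolation),
#' combined with the record's original phase spectrum, and inverse-FFT'd
#' to the segment length.  Saliency is the absolute value of that
#' reconstruction, smoothed with a 40 ms moving average and, by
#' default, max-normalised per record.
#'
#' @param cam a [gradCAM()] result.
#' @param tensor the record's [SpectralTensor-class] (its metadata
#'   carries the original phase, retained-bin count and segment length).
#' @param normalize max-normalise to `[0, 1]` (the default).  With
#'   `FALSE` the raw linear response is returned as a plain L x 12
#'   matrix, useful for inspecting the mapping's linearity.
#' @return A [TimeHeatmap-class] (values L x 12, Cabrera lead order),
#'   or the raw saliency matrix when `normalize = FALSE`.
#' @export
camToTime <- function(cam, tensor, normalize = TRUE) {
  stopifnot(inherits(cam, "ClassActivationMap"))
  meta <- tensorMeta(tensor)
  if (!is.na(cam$record_id) && !identical(cam$record_id, recordId(tensor)))
    stop("CAM was computed for record '", cam$record_id,
         "', tensor belongs to '", recordId(tensor), "'")
  target <- seq(0, 50, length.out = ncol(cam$values))
  ampB <- unresizeSpectrum(t(cam$values), target, meta$srcFreq)  # B x 12
  wave <- inverseSpectralTransform(ampB, meta$phase, meta$L, meta$fs)
  sal <- abs(wave)
  win <- max(1L, round(0.040 * meta$fs))
  kern <- rep(1 / win, win)
  sal <- apply(sal, 2, function(v) {
    s <- stats::filter(v, kern, sides = 2)
    s[is.na(s)] <- v[is.na(s)]
    as.numeric(s)
  })
  colnames(sal) <- cabreraLeads()
  if (!normalize) return(sal)
  if (max(sal) > 0) sal <- sal / max(sal)
  new("TimeHeatmap", values = sal, fs = meta$fs, recordId = recordId(tensor))
}

#' Render an ECG with a saliency overlay
#'
#' Draws the analysed segment's 12 leads in Cabrera order with the
#' time-domain saliency as background colour intensity (white through
#' yellow to red), one row per lead, and writes a PNG.
#'
#' @param record the source [ECGRecord-class].
#' @param heatmap a [camToTime()] result for that record.
#' @param path output PNG path.
#' @param cfg preprocessing configuration used to locate the analysed
#'   segment (must match the one used for the tensor).
#' @return The output path, invisibly.
#' @export
renderOverlay <- function(record, heatmap, path,
                          cfg = preprocessConfig()) {
  stopifnot(is(heatmap, "TimeHeatmap"))
  ann <- detectQRS(record, cfg)
  seg <- extractSegment(record, ann)
  x <- cabreraReorder(seg$segment, margin = 2)
  L <- nrow(x)
  if (L != nrow(heatmap@values))
    stop("heatmap length does not match the record's segment")
  pal <- grDevices::colorRampPalette(c("#FFFFFF", "#FFE873", "#FF3B1F"))(101)
  tt <- (seq_len(L) - 1) / seg$fs
  grDevices::png(path, width = 1400, height = 1600, res = 150)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(12, 1), mar = c(0.4, 4, 0.1, 1), oma = c(3, 0, 2, 0))
  nBlock <- min(L, 400)
  edges <- seq(1, L, length.out = nBlock + 1)
  for (j in seq_len(12)) {
    ylim <- range(x[, j]) + c(-0.05, 0.05)
    graphics::plot(NA, xlim = range(tt), ylim = ylim, xlab = "", ylab =
                     colnames(x)[j], xaxt = if (j == 12) "s" else "n",
                   las = 1, cex.axis = 0.6)
    blockSal <- vapply(seq_len(nBlock), function(b) {
      idx <- ceiling(edges[b]):floor(edges[b + 1])
      max(heatmap@values[idx, j])
    }, numeric(1))
    graphics::rect(tt[pmax(1, ceiling(edges[-length(edges)]))],
                   ylim[1], tt[pmin(L, floor(edges[-1]))], ylim[2],
                   col = pal[pmin(101, 1 + round(100 * blockSal))],
                   border = NA)
    graphics::lines(tt, x[, j], lwd = 0.7)
  }
  graphics::mtext(sprintf("record %s - saliency overlay", recordId(record)),
                  outer = TRUE, line = 0.5)
  graphics::mtext("time since segment start (s)", side = 1, outer = TRUE,
                  line = 1.5)
  invisible(path)
}
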