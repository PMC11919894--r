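#' Architecture configuration of the spectral-tensor classifier
#'
#' A 21-weight-layer VGG-style network: two private 2-convolution stems
#' read the amplitude and phase channels of the 12 x 400 input, their
#' feature maps are fused by channel concatenation, a 14-convolution
#' trunk in blocks of widths `64x2, 128x3, 256x3, 512x3, 512x3` (times
#' `width_multiplier`) with 3 x 3 kernels follows, max-pools at block
#' boundaries halve the frequency axis every block and the lead axis
#' twice, and after flattening the age/sex vector is concatenated ahead
#' of dense layers 128 -> 32 -> 1 with a sigmoid output.  That is
#' 18 convolution + 3 dense = 21 weight layers.
#'
#' @param width_multiplier scales every convolutional width; 1 is the
#'   full-size network, the `"desk"` preset uses 1/16.
#' @param preset `"full"` (full-size) or `"desk"` (CPU-scale: thin
#'   widths and an extra post-stem frequency pool).
#' @param n_leads,n_freq input map extent.
#' @param gradcam_conv 1-based convolution index targeted by grad-CAM,
#'   counting the amplitude stem (1-2) then the trunk (3-16).
#' @param dropout kept for interface compatibility; the compiled engine
#'   trains without dropout.
#' @return An `ArchitectureConfig` list understood by [buildModel()] and
#'   [trainEnsemble()].
#' @export
architectureConfig <- function(width_multiplier = 1,
                               preset = c("full", "desk"),
                               n_leads = 12, n_freq = 400,
                               gradcam_conv = 12, dropout = 0) {
  preset <- match.arg(preset)
  stem_pool <- c(1L, 1L)
  if (preset == "desk" && missing(width_multiplier)) width_multiplier <- 1 / 16
  if (preset == "desk") stem_pool <- c(1L, 4L)
  base <- c(64, 64, 128, 128, 128, 256, 256, 256,
            512, 512, 512, 512, 512, 512)
  trunk <- pmax(4L, as.integer(round(base * width_multiplier)))
  stem <- pmax(4L, as.integer(round(64 * width_multiplier)))
  pool_after <- matrix(1L, nrow = 14, ncol = 2)
  pool_after[2, ] <- c(1L, 2L)
  pool_after[5, ] <- c(2L, 2L)
  pool_after[8, ] <- c(1L, 2L)
  pool_after[11, ] <- c(2L, 2L)
  pool_after[14, ] <- c(1L, 2L)
  arch <- list(preset = preset, n_leads = as.integer(n_leads),
               n_freq = as.integer(n_freq), stem_channels = stem,
               trunk_channels = trunk, stem_pool = as.integer(stem_pool),
               pool_after = pool_after, dense_units = c(128L, 32L),
               gradcam_conv = as.integer(gradcam_conv), dropout = dropout)
  if (arch$gradcam_conv > 2 + length(trunk))
    stop("gradcam_conv exceeds the convolution count")
  fe <- finalExtent(arch)
  if (any(fe < 1))
    stop("pooling schedule collapses the ", names(fe)[fe < 1][1],
         " axis; enlarge the input or remove pools")
  arch
}

#' Number of weight layers of an architecture
#'
#' @param arch an [architectureConfig()].
#' @return Integer count of parameterised layers (convolutions in both
#'   stems and the trunk, plus dense layers).
#' @export
nWeightLayers <- function(arch) {
  4L + length(arch$trunk_channels) + length(arch$dense_units) + 1L
}

# shapes of all conv layers: in/out channels in engine order
convPlan <- function(arch) {
  s <- arch$stem_channels
  tc <- arch$trunk_channels
  ins <- c(1, s, 1, s, 2 * s, tc[-length(tc)])
  outs <- c(s, s, s, s, tc)
  data.frame(cin = ins, cout = outs)
}

# spatial extent of the map entering dense layers
finalExtent <- function(arch) {
  H <- arch$n_leads; W <- arch$n_freq
  H <- H %/% arch$stem_pool[1]; W <- W %/% arch$stem_pool[2]
  for (i in seq_len(nrow(arch$pool_after))) {
    H <- H %/% arch$pool_after[i, 1]
    W <- W %/% arch$pool_after[i, 2]
  }
  c(H = H, W = W)
}

#' Initialise model parameters
#'
#' He-normal initialisation of all convolution and dense weights,
#' deterministic given the seed; biases start at zero.
#'
#' @param arch an [architectureConfig()].
#' @param seed integer seed.
#' @return List with `conv` (18 layers of `W` `Cout x 9*Cin`, `b`) and
#'   `dense` (3 layers), the layout the compiled engine consumes.
#' @export
buildModel <- function(arch, seed = 1) {
  set.seed(seed)
  plan <- convPlan(arch)
  conv <- lapply(seq_len(nrow(plan)), function(i) {
    cin <- plan$cin[i]; cout <- plan$cout[i]
    list(W = matrix(rnorm(cout * 9 * cin, 0, sqrt(2 / (9 * cin))),
                    cout, 9 * cin),
         b = numeric(cout))
  })
  fe <- finalExtent(arch)
  flat <- fe["H"] * fe["W"] * tail(arch$trunk_channels, 1) + 2
  du <- arch$dense_units
  dims <- rbind(c(du[1], flat), c(du[2], du[1]), c(1, du[2]))
  dense <- lapply(seq_len(3), function(i) {
    fanin <- dims[i, 2]
    sdv <- if (i < 3) sqrt(2 / fanin) else sqrt(1 / fanin)
    list(W = matrix(rnorm(dims[i, 1] * fanin, 0, sdv), dims[i, 1], fanin),
         b = numeric(dims[i, 1]))
  })
  list(conv = conv, dense = dense)
}

#' Training configuration
#'
#' @param preset `"desk"` (CPU-scale defaults: learning rate 1e-3, 4
#'   epochs) or `"full"` (the full-scale recipe: learning rate 1e-7,
#'   100 epochs).  Both use batch 32, binary cross-entropy, Adam,
#'   five folds and minimum-validation-loss checkpointing.
#' @param batch_size,learning_rate,epochs,k_folds overrides.
#' @param seed integer seed for fold assignment, parameter
#'   initialisation and batch shuffling.
#' @return A `TrainConfig` list.
#' @export
trainConfig <- function(preset = c("desk", "full"), batch_size = 32,
                        learning_rate = NULL, epochs = NULL, k_folds = 5,
                        seed = 1) {
  preset <- match.arg(preset)
  if (is.null(learning_rate))
    learning_rate <- if (preset == "full") 1e-7 else 1e-3
  if (is.null(epochs)) epochs <- if (preset == "full") 100 else 4
  stopifnot(k_folds >= 2, learning_rate >= 0)
  list(preset = preset, batch_size = as.integer(batch_size),
       learning_rate = learning_rate, epochs = as.integer(epochs),
       k_folds = as.integer(k_folds), seed = as.integer(seed))
}

# deterministic sub-seed scheme: every stochastic stage consumes
# base_seed combined with a small stage offset, kept under 2^31
deriveSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 31 + stage) %% .Machine$integer.max)
}

#' Train the five-fold ensemble
#'
#' Splits patients (not records) into `k_folds` groups, trains one
#' network per fold on the remaining groups with Adam and binary
#' cross-entropy, records the loss curves and keeps the parameters of
#' the epoch with the lowest validation loss.  Deterministic given the
#' training seed under single-threaded execution.
#'
#' @param inputs stacked tensors from [cohortTensors()].
#' @param labels logical/0-1 vector of overall abnormality per record.
#' @param patient_ids character vector aligned with records.
#' @param arch an [architectureConfig()].
#' @param cfg a [trainConfig()].
#' @param verbose print per-fold progress.
#' @return An [ECGEnsemble-class].
#' @export
trainEnsemble <- function(inputs, labels, patient_ids,
                          arch = architectureConfig(preset = "desk"),
                          cfg = trainConfig("desk"), verbose = FALSE) {
  labels <- as.numeric(labels)
  n <- length(labels)
  stopifnot(ncol(inputs$amp) == n, length(patient_ids) == n)
  set.seed(deriveSeed(cfg$seed, 1))
  pats <- sample(unique(patient_ids))
  foldOf <- setNames(rep(seq_len(cfg$k_folds), length.out = length(pats)),
                     pats)
  recFold <- foldOf[patient_ids]
  folds <- vector("list", cfg$k_folds)
  for (f in seq_len(cfg$k_folds)) {
    vi <- which(recFold == f); ti <- which(recFold != f)
    if (length(unique(labels[ti])) < 2 || length(unique(labels[vi])) < 2)
      stop("single-class fold: fold ", f,
           " lacks both classes; enlarge or rebalance the cohort")
    params <- buildModel(arch, seed = deriveSeed(cfg$seed, 100 + f))
    fit <- cnn_train_cpp(params, arch, inputs$amp, inputs$pha, inputs$meta,
                         labels, ti - 1L, vi - 1L, cfg$epochs,
                         cfg$batch_size, cfg$learning_rate,
                         deriveSeed(cfg$seed, 200 + f))
    folds[[f]] <- list(params = fit$params, trainLoss = fit$train_loss,
                       valLoss = fit$val_loss,
                       selectedEpoch = fit$selected_epoch,
                       valPatients = unique(patient_ids[vi]))
    if (verbose)
      message(sprintf("fold %d: val loss %.4f at epoch %d", f,
                      min(fit$val_loss), fit$selected_epoch))
  }
  new("ECGEnsemble", folds = folds, arch = arch, trainConfig = cfg,
      fingerprint = inputs$fingerprint %||% "unspecified")
}

#' Predict abnormality probabilities
#'
#' Per-record mean of the five fold models' sigmoid outputs, preserving
#' input order.
#'
#' @param object an [ECGEnsemble-class].
#' @param inputs stacked tensors from [cohortTensors()]; their
#'   preprocessing fingerprint must match the ensemble's.
#' @param ... unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
setMethod("predict", "ECGEnsemble", function(object, inputs, ...) {
  fp <- inputs$fingerprint %||% "unspecified"
  if (!identical(fp, object@fingerprint))
    stop("preprocessing fingerprint mismatch: ensemble expects '",
         object@fingerprint, "', inputs carry '", fp, "'")
  preds <- vapply(object@folds, function(f)
    cnn_forward_cpp(f$params, object@arch, inputs$amp, inputs$pha,
                    inputs$meta),
    numeric(ncol(inputs$amp)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
})
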