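#' Canonical 12-lead names
#'
#' Lead order used throughout the package for storage: the six frontal
#' limb leads followed by the six precordial leads.
#'
#' @return Character vector of the 12 canonical lead names.
#' @export
canonicalLeads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

#' Cabrera lead sequence
#'
#' Frontal leads in contiguous anatomical angle order with aVR inverted
#' (shown as -aVR), followed by the chest leads.  This is the lead axis
#' of the model's input tensor.
#'
#' @return Character vector of 12 display names; `"-aVR"` marks the
#'   sign-inverted aVR row.
#' @export
cabreraLeads <- function() {
  c("aVL", "I", "-aVR", "II", "aVF", "III",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

#' ECGRecord: one 12-lead pediatric ECG
#'
#' Container for a single resting 12-lead ECG: a samples x 12 matrix of
#' voltages in millivolts (columns in [canonicalLeads()] order), the
#' sampling rate, patient metadata (age in years, sex), the set of
#' guideline finding codes assigned to the record, and - for synthetic
#' records - the generator's ground-truth R-peak sample indices.
#'
#' @slot recordId character scalar, unique record identifier.
#' @slot patientId character scalar; repeat ECGs of one patient share it.
#' @slot fs sampling rate in Hz (500 for standard records).
#' @slot leads numeric matrix, samples x 12, millivolts.
#' @slot age age in whole years (6-18 for the screening population).
#' @slot sex `"male"` or `"female"`.
#' @slot findings character vector of finding codes; empty when normal.
#' @slot rPeaks integer vector of true R-peak sample indices (1-based);
#'   empty for records without generator ground truth.
#'
#' @export
setClass("ECGRecord",
  representation(recordId = "character", patientId = "character",
                 fs = "numeric", leads = "matrix", age = "numeric",
                 sex = "character", findings = "character",
                 rPeaks = "integer"))

setValidity("ECGRecord", function(object) {
  msg <- character()
  if (ncol(object@leads) != 12L ||
      !identical(colnames(object@leads), canonicalLeads()))
    msg <- c(msg, "leads must be a samples x 12 matrix with canonical lead names")
  if (!all(is.finite(object@leads)))
    msg <- c(msg, sprintf("non-finite samples in lead(s): %s",
      paste(colnames(object@leads)[!apply(is.finite(object@leads), 2, all)],
            collapse = ", ")))
  if (length(object@fs) != 1L || object@fs < 250)
    msg <- c(msg, "fs must be a single rate of at least 250 Hz")
  if (length(object@age) != 1L || object@age < 1 || object@age > 100)
    msg <- c(msg, "age must be a single plausible value in years")
  if (!object@sex %in% c("male", "female"))
    msg <- c(msg, "sex must be 'male' or 'female'")
  if (anyDuplicated(object@findings))
    msg <- c(msg, "findings must not contain duplicates")
  if (length(object@rPeaks) &&
      (min(object@rPeaks) < 1L || max(object@rPeaks) > nrow(object@leads)))
    msg <- c(msg, "rPeaks must lie within the record")
  if (length(msg)) msg else TRUE
})

#' SpectralTensor: the 2 x 12 x 400 model input
#'
#' Amplitude and phase spectra of one ECG segment on a fixed frequency
#' grid.  Channel 1 holds amplitudes (millivolts, non-negative), channel
#' 2 phases (radians in (-pi, pi]).  The lead axis follows
#' [cabreraLeads()]; the frequency axis spans 0-50 Hz in `nFreq` equal
#' steps.  `meta` retains everything required to invert the transform
#' (segment length, sampling rate, retained bin count, and the original
#' per-lead phase spectra), which the saliency mapping reuses.
#'
#' @slot values numeric array `c(2, 12, nFreq)`.
#' @slot freq numeric vector of the `nFreq` target frequencies (Hz).
#' @slot meta list with elements `L`, `fs`, `B`, `srcFreq`, `phase`
#'   (B x 12, Cabrera order), `amplitude` (B x 12, Cabrera order).
#' @slot recordId source record identifier.
#'
#' @export
setClass("SpectralTensor",
  representation(values = "array", freq = "numeric", meta = "list",
                 recordId = "character"))

setValidity("SpectralTensor", function(object) {
  d <- dim(object@values)
  msg <- character()
  if (length(d) != 3L || d[1] != 2L || d[2] != 12L)
    msg <- c(msg, "values must be a 2 x 12 x nFreq array")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "tensor values must be finite")
  if (any(object@values[1, , ] < 0))
    msg <- c(msg, "amplitude channel must be non-negative")
  if (length(object@freq) != d[3])
    msg <- c(msg, "freq must match the tensor's frequency axis")
  if (length(msg)) msg else TRUE
})

#' ECGEnsemble: five fold-trained classifiers
#'
#' The product of five-fold patient-level cross-validated training: one
#' parameter set per fold (checkpointed at its minimum validation loss),
#' the architecture and training configurations that produced them, and
#' a fingerprint of the preprocessing configuration the folds were
#' trained on.  Prediction averages the five sigmoid outputs.
#'
#' @slot folds list of per-fold results (`params`, `trainLoss`,
#'   `valLoss`, `selectedEpoch`, `valPatients`).
#' @slot arch architecture configuration list, see [architectureConfig()].
#' @slot trainConfig training configuration list, see [trainConfig()].
#' @slot fingerprint character scalar identifying the preprocessing
#'   configuration of the tensors the ensemble expects.
#'
#' @export
setClass("ECGEnsemble",
  representation(folds = "list", arch = "list", trainConfig = "list",
                 fingerprint = "character"))

setValidity("ECGEnsemble", function(object) {
  msg <- character()
  if (!length(object@folds))
    msg <- c(msg, "ensemble must contain at least one fold")
  ok <- vapply(object@folds, function(f)
    all(c("params", "trainLoss", "valLoss", "selectedEpoch") %in% names(f)),
    logical(1))
  if (!all(ok)) msg <- c(msg, "each fold needs params and loss curves")
  for (f in object@folds)
    if (length(f$valLoss) &&
        abs(f$valLoss[f$selectedEpoch] - min(f$valLoss)) > 1e-12)
      msg <- c(msg, "selected epoch must attain the minimum validation loss")
  if (length(msg)) msg else TRUE
})

#' TimeHeatmap: per-lead saliency in the time domain
#'
#' Saliency of each sample of the analysed segment, per lead in Cabrera
#' order, scaled to `[0, 1]` with the record-wide maximum at 1.
#'
#' @slot values numeric matrix, segment samples x 12 (Cabrera order).
#' @slot fs sampling rate in Hz.
#' @slot recordId source record identifier.
#'
#' @export
setClass("TimeHeatmap",
  representation(values = "matrix", fs = "numeric", recordId = "character"))

setValidity("TimeHeatmap", function(object) {
  msg <- character()
  if (ncol(object@values) != 12L)
    msg <- c(msg, "values must have 12 lead columns")
  if (any(object@values < 0) || any(object@values > 1 + 1e-9))
    msg <- c(msg, "saliency must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
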