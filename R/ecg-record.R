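#' Construct an ECGRecord
#'
#' Builds and validates the package's single-ECG container.  Leads may
#' be supplied in any order; they are normalised to the canonical order.
#'
#' @param leads numeric matrix (samples x 12) with lead names as column
#'   names, or a named list of equal-length sample vectors; millivolts.
#' @param fs sampling rate in Hz.
#' @param age age in whole years.
#' @param sex `"male"` or `"female"`.
#' @param findings character vector of finding codes (empty = normal).
#' @param recordId,patientId identifiers; `patientId` defaults to the
#'   record id (one record per patient).
#' @param rPeaks optional integer vector of ground-truth R-peak sample
#'   indices (1-based), carried by synthetic records.
#'
#' @return A validated [ECGRecord-class] object.
#' @examples
#' rec <- generateECG(normalDipoleParams(), age = 10, sex = "female", seed = 1)
#' sampleRate(rec)
#' isAbnormal(rec)
#' @export
ECGRecord <- function(leads, fs = 500, age, sex, findings = character(),
                      recordId = "ecg", patientId = recordId,
                      rPeaks = integer()) {
  if (is.list(leads)) {
    len <- vapply(leads, length, integer(1))
    if (length(unique(len)) != 1L)
      stop("all leads must have the same number of samples (got lengths ",
           paste(unique(len), collapse = ", "), ")")
    leads <- do.call(cbind, leads)
  }
  missing_leads <- setdiff(canonicalLeads(), colnames(leads))
  if (length(missing_leads))
    stop("missing lead(s): ", paste(missing_leads, collapse = ", "))
  leads <- leads[, canonicalLeads(), drop = FALSE]
  bad <- !apply(is.finite(leads), 2, all)
  if (any(bad))
    stop("non-finite samples in lead(s): ",
         paste(colnames(leads)[bad], collapse = ", "))
  new("ECGRecord", recordId = as.character(recordId),
      patientId = as.character(patientId), fs = as.numeric(fs),
      leads = leads, age = as.numeric(age), sex = as.character(sex),
      findings = as.character(findings), rPeaks = as.integer(rPeaks))
}

#' @describeIn ECGRecord record identifier.
#' @param x an `ECGRecord`.
#' @export
setMethod("recordId", "ECGRecord", function(x) x@recordId)

#' @describeIn ECGRecord patient identifier.
#' @export
setMethod("patientId", "ECGRecord", function(x) x@patientId)

#' @describeIn ECGRecord sampling rate in Hz.
#' @export
setMethod("sampleRate", "ECGRecord", function(x) x@fs)

#' @describeIn ECGRecord samples x 12 voltage matrix (mV).
#' @export
setMethod("leadMatrix", "ECGRecord", function(x) x@leads)

#' @describeIn ECGRecord age in years.
#' @export
setMethod("recordAge", "ECGRecord", function(x) x@age)

#' @describeIn ECGRecord sex, `"male"` or `"female"`.
#' @export
setMethod("recordSex", "ECGRecord", function(x) x@sex)

#' @describeIn ECGRecord finding codes (empty when normal).
#' @export
setMethod("findings", "ECGRecord", function(x) x@findings)

#' @describeIn ECGRecord `TRUE` when the findings set is non-empty.
#' @export
setMethod("isAbnormal", "ECGRecord", function(x) length(x@findings) > 0L)

#' @describeIn ECGRecord generator ground-truth R-peak indices.
#' @export
setMethod("truePeaks", "ECGRecord", function(x) x@rPeaks)

setMethod("show", "ECGRecord", function(object) {
  cat(sprintf("ECGRecord '%s' (patient %s)\n", object@recordId,
              object@patientId))
  cat(sprintf("  %d leads x %d samples @ %g Hz (%.1f s)\n",
              ncol(object@leads), nrow(object@leads), object@fs,
              nrow(object@leads) / object@fs))
  cat(sprintf("  age %g, %s; findings: %s\n", object@age, object@sex,
              if (length(object@findings))
                paste(object@findings, collapse = ", ") else "none (normal)"))
  if (length(object@rPeaks))
    cat(sprintf("  %d ground-truth R peaks\n", length(object@rPeaks)))
})

setMethod("show", "SpectralTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("SpectralTensor for record '%s': %d x %d x %d\n",
              object@recordId, d[1], d[2], d[3]))
  cat(sprintf("  frequency axis 0-%g Hz (%d bins, %d retained from L=%d)\n",
              max(object@freq), d[3], object@meta$B, object@meta$L))
})

#' @describeIn SpectralTensor the `c(2, 12, nFreq)` value array.
#' @param x a `SpectralTensor`.
#' @export
setMethod("tensorValues", "SpectralTensor", function(x) x@values)

#' @describeIn SpectralTensor inversion metadata list.
#' @export
setMethod("tensorMeta", "SpectralTensor", function(x) x@meta)

#' @describeIn SpectralTensor source record identifier.
#' @export
setMethod("recordId", "SpectralTensor", function(x) x@recordId)

setMethod("show", "ECGEnsemble", function(object) {
  cat(sprintf("ECGEnsemble: %d folds, %d weight layers, preset '%s'\n",
              length(object@folds), nWeightLayers(object@arch),
              object@trainConfig$preset %||% "custom"))
  sel <- vapply(object@folds, function(f) f$selectedEpoch, numeric(1))
  cat(sprintf("  selected epochs: %s\n", paste(sel, collapse = ", ")))
})

setMethod("show", "TimeHeatmap", function(object) {
  cat(sprintf("TimeHeatmap for record '%s': %d samples x 12 leads @ %g Hz\n",
              object@recordId, nrow(object@values), object@fs))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
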