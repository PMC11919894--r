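#' Read and write ECG records
#'
#' @description
#' Two on-disk dialects are supported:
#'
#' * `"csvjson"`: a bundle of `<base>.json` (identifiers, sampling rate,
#'   age, sex, findings, and - for synthetic records - ground-truth R
#'   peaks under the key `true_r_peaks`) and `<base>.csv` (12 named lead
#'   columns, millivolts, full `%.17g` precision so the round trip is
#'   bit-lossless).
#' * `"wfdb"`: a WFDB header/signal pair (`<base>.hea`, `<base>.dat`)
#'   in format 16 (interleaved little-endian 16-bit integers) with a
#'   gain of 1000 ADC units per millivolt, i.e. samples are quantised
#'   to 1 microvolt.  Metadata travel in `#`-prefixed header comments.
#'
#' Both readers normalise lead order to [canonicalLeads()] and validate
#' the record; a missing lead, unequal lead lengths, or non-finite
#' samples raise an error naming the offending lead.
#'
#' @param path base path (no extension) of the record files.
#' @param format `"csvjson"` or `"wfdb"`.
#' @return `readECGRecord()` returns an [ECGRecord-class];
#'   `writeECGRecord()` returns `path` invisibly.
#' @export
readECGRecord <- function(path, format = c("csvjson", "wfdb")) {
  format <- match.arg(format)
  if (format == "csvjson") {
    hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    sig <- utils::read.csv(paste0(path, ".csv"), check.names = FALSE)
    missing_leads <- setdiff(canonicalLeads(), colnames(sig))
    if (length(missing_leads))
      stop("missing lead(s): ", paste(missing_leads, collapse = ", "))
    ECGRecord(as.matrix(sig), fs = hdr$fs, age = hdr$age_years,
              sex = hdr$sex, findings = unlist(hdr$findings) %||% character(),
              recordId = hdr$record_id, patientId = hdr$patient_id,
              rPeaks = as.integer(unlist(hdr$true_r_peaks) %||% integer()))
  } else {
    readWFDBRecord(path)
  }
}

#' @rdname readECGRecord
#' @param record an [ECGRecord-class] to write.
#' @export
writeECGRecord <- function(record, path, format = c("csvjson", "wfdb")) {
  format <- match.arg(format)
  validObject(record)
  if (format == "csvjson") {
    hdr <- list(record_id = recordId(record), patient_id = patientId(record),
                fs = sampleRate(record), age_years = recordAge(record),
                sex = recordSex(record), findings = I(findings(record)),
                true_r_peaks = I(truePeaks(record)))
    jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    x <- leadMatrix(record)
    con <- file(paste0(path, ".csv"), "w")
    on.exit(close(con), add = TRUE)
    writeLines(paste(colnames(x), collapse = ","), con)
    writeLines(apply(x, 1, function(row)
      paste(sprintf("%.17g", row), collapse = ",")), con)
  } else {
    writeWFDBRecord(record, path)
  }
  invisible(path)
}

WFDB_GAIN <- 1000  # ADC units per mV -> 1 uV resolution

writeWFDBRecord <- function(record, path) {
  x <- leadMatrix(record)
  adc <- round(x * WFDB_GAIN)
  if (any(abs(adc) > 32767))
    stop("signal exceeds the 16-bit WFDB range at gain ", WFDB_GAIN)
  base <- basename(path)
  n <- nrow(x)
  hea <- c(sprintf("%s 12 %g %d", base, sampleRate(record), n),
           vapply(seq_len(12), function(j)
             sprintf("%s.dat 16 %d(0)/mV 16 0 %d 0 0 %s", base, WFDB_GAIN,
                     as.integer(adc[1, j]), colnames(x)[j]), character(1)),
           sprintf("# record_id: %s", recordId(record)),
           sprintf("# patient_id: %s", patientId(record)),
           sprintf("# age_years: %g", recordAge(record)),
           sprintf("# sex: %s", recordSex(record)),
           sprintf("# findings: %s", paste(findings(record), collapse = ",")),
           sprintf("# true_r_peaks: %s",
                   paste(truePeaks(record), collapse = ",")))
  writeLines(hea, paste0(path, ".hea"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.integer(t(adc)), con, size = 2, endian = "little")
  invisible(path)
}

readWFDBRecord <- function(path) {
  hea <- readLines(paste0(path, ".hea"))
  meta <- hea[startsWith(hea, "#")]
  body <- hea[!startsWith(hea, "#")]
  top <- strsplit(body[1], "\\s+")[[1]]
  nsig <- as.integer(top[2]); fs <- as.numeric(top[3]); n <- as.integer(top[4])
  sigl <- strsplit(body[1 + seq_len(nsig)], "\\s+")
  leadNames <- vapply(sigl, function(f) f[length(f)], character(1))
  gains <- vapply(sigl, function(f)
    as.numeric(sub("\\(.*", "", f[3])), numeric(1))
  raw <- readBin(paste0(path, ".dat"), what = "integer", size = 2,
                 endian = "little", signed = TRUE, n = nsig * n)
  if (length(raw) != nsig * n)
    stop("signal file length mismatch: expected ", nsig * n, " samples")
  x <- t(matrix(raw, nrow = nsig))
  x <- sweep(x, 2, gains, "/")
  colnames(x) <- leadNames
  getMeta <- function(key) {
    line <- grep(sprintf("^# %s:", key), meta, value = TRUE)
    if (!length(line)) return("")
    trimws(sub(sprintf("^# %s:", key), "", line[1]))
  }
  fnd <- getMeta("findings")
  fnd <- if (nzchar(fnd)) strsplit(fnd, ",")[[1]] else character()
  rp <- getMeta("true_r_peaks")
  rp <- if (nzchar(rp)) as.integer(strsplit(rp, ",")[[1]]) else integer()
  ECGRecord(x, fs = fs, age = as.numeric(getMeta("age_years")),
            sex = getMeta("sex"), findings = fnd,
            recordId = getMeta("record_id"), patientId = getMeta("patient_id"),
            rPeaks = rp)
}

#' Read or write a cohort manifest
#'
#' Manifests are tab-separated tables with columns `record_id`,
#' `patient_id`, `age_years`, `sex`, `findings` (comma-joined codes,
#' empty = normal), `comparator_flag` (optional logical) and `path`.
#'
#' @param path TSV file path.
#' @return `readManifest()` returns the manifest data.frame (validated:
#'   unique record ids, findings drawn from the supported vocabulary).
#' @export
readManifest <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = "NA",
                         colClasses = c(findings = "character"))
  if (anyDuplicated(m$record_id))
    stop("duplicate record_id values in manifest")
  codes <- unique(unlist(strsplit(m$findings[!is.na(m$findings) &
                                               nzchar(m$findings)], ",")))
  bad <- setdiff(codes, findingVocabulary())
  if (length(bad))
    stop("unsupported finding code(s) in manifest: ",
         paste(bad, collapse = ", "))
  m
}

#' @rdname readManifest
#' @param manifest the manifest data.frame to write.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Patient-level train/test split
#'
#' Randomly assigns whole patients - never individual ECGs - to the
#' training or test group, so repeat records of one patient can never
#' straddle the split.  The training group size is
#' `round(train_fraction * n_patients)` (half away from zero) and the
#' split is deterministic given the seed.
#'
#' @param manifest a manifest data.frame (needs `patient_id`).
#' @param train_fraction proportion of patients assigned to training,
#'   strictly inside (0, 1).
#' @param seed integer seed.
#' @return A `Split`: list with `train_patient_ids`, `test_patient_ids`,
#'   `train_fraction`, `seed`.
#' @examples
#' m <- data.frame(record_id = paste0("r", 1:6),
#'                 patient_id = paste0("p", c(1, 1, 2, 3, 3, 4)))
#' patientSplit(m, 0.5, seed = 7)
#' @export
patientSplit <- function(manifest, train_fraction, seed) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  patients <- unique(manifest$patient_id)
  if (length(patients) < 2)
    stop("need at least 2 patients to split")
  nTrain <- floor(train_fraction * length(patients) + 0.5)
  nTrain <- max(1L, min(length(patients) - 1L, nTrain))
  set.seed(seed)
  shuffled <- sample(patients)
  out <- list(train_patient_ids = sort(shuffled[seq_len(nTrain)]),
              test_patient_ids = sort(shuffled[-seq_len(nTrain)]),
              train_fraction = train_fraction, seed = seed)
  class(out) <- "Split"
  out
}

#' @export
print.Split <- function(x, ...) {
  cat(sprintf("Split: %d train / %d test patients (fraction %.3f, seed %d)\n",
              length(x$train_patient_ids), length(x$test_patient_ids),
              x$train_fraction, x$seed))
  invisible(x)
}
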