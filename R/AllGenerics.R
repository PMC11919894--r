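#' @name schoolECG-generics
#' @title Accessor generics
#' @description Accessors for the package's S4 containers.
#' @param x an object.
#' @keywords internal
NULL

#' @rdname schoolECG-generics
#' @export
setGeneric("recordId", function(x) standardGeneric("recordId"))

#' @rdname schoolECG-generics
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname schoolECG-generics
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname schoolECG-generics
#' @export
setGeneric("leadMatrix", function(x) standardGeneric("leadMatrix"))

#' @rdname schoolECG-generics
#' @export
setGeneric("recordAge", function(x) standardGeneric("recordAge"))

#' @rdname schoolECG-generics
#' @export
setGeneric("recordSex", function(x) standardGeneric("recordSex"))

#' @rdname schoolECG-generics
#' @export
setGeneric("findings", function(x) standardGeneric("findings"))

#' @rdname schoolECG-generics
#' @export
setGeneric("isAbnormal", function(x) standardGeneric("isAbnormal"))

#' @rdname schoolECG-generics
#' @export
setGeneric("truePeaks", function(x) standardGeneric("truePeaks"))

#' @rdname schoolECG-generics
#' @export
setGeneric("tensorValues", function(x) standardGeneric("tensorValues"))

#' @rdname schoolECG-generics
#' @export
setGeneric("tensorMeta", function(x) standardGeneric("tensorMeta"))
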