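#' @rdname MethylationExperiment-accessors
#' @export
setGeneric("betas", function(x, ...) standardGeneric("betas"))

#' @rdname MethylationExperiment-accessors
#' @export
setGeneric("ages", function(x, ...) standardGeneric("ages"))

#' @rdname MethylationExperiment-accessors
#' @export
setGeneric("platforms", function(x, ...) standardGeneric("platforms"))

#' @rdname MethylationExperiment-accessors
#' @export
setGeneric("replicates", function(x, ...) standardGeneric("replicates"))

#' @rdname MethylationExperiment-accessors
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @rdname MethylationExperiment-accessors
#' @export
setGeneric("cpgIds", function(x, ...) standardGeneric("cpgIds"))
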