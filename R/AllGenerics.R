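#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("readDepth", function(x) standardGeneric("readDepth"))

#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("samplePloidy", function(x) standardGeneric("samplePloidy"))

#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("sampleTable", function(x) standardGeneric("sampleTable"))

#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("ancestralAllele", function(x) standardGeneric("ancestralAllele"))

#' @rdname AlleleFreqTable-accessors
#' @export
setGeneric("freqs", function(x) standardGeneric("freqs"))

#' @rdname AlleleFreqTable-accessors
#' @export
setGeneric("chromosomesSampled", function(x) standardGeneric("chromosomesSampled"))
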