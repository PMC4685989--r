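#' @rdname PTMProteome-accessors
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @rdname PTMProteome-accessors
#' @export
setGeneric("modifications", function(x) standardGeneric("modifications"))

#' @rdname PTMProteome-accessors
#' @export
setGeneric("mutations", function(x) standardGeneric("mutations"))

#' @rdname PTMProteome-accessors
#' @export
setGeneric("goTerms", function(x) standardGeneric("goTerms"))

#' @rdname PTMProteome-accessors
#' @export
setGeneric("proteinSequences", function(x) standardGeneric("proteinSequences"))

#' @rdname PTMProteome-accessors
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))

#' @rdname PTMProteome-accessors
#' @export
setGeneric("nProteins", function(x) standardGeneric("nProteins"))

#' @rdname PTMProteome-accessors
#' @export
setGeneric("proteinLengths", function(x) standardGeneric("proteinLengths"))

#' @rdname record-api
#' @export
setGeneric("getMutations", function(x, acc) standardGeneric("getMutations"))

#' @rdname record-api
#' @export
setGeneric("getPTMs", function(x, acc) standardGeneric("getPTMs"))

#' @rdname record-api
#' @export
setGeneric("getSequence", function(x, acc) standardGeneric("getSequence"))

#' @rdname record-api
#' @export
setGeneric("getGoTerms", function(x, acc) standardGeneric("getGoTerms"))
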