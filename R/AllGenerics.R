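# Accessor generics for the package's S4 containers.

#' @rdname UTRSet-class
#' @param x a UTRSet
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname UTRSet-class
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))

#' @rdname UTRSet-class
#' @export
setGeneric("utrLength", function(x) standardGeneric("utrLength"))

#' @rdname UTRSet-class
#' @export
setGeneric("utrSeqs", function(x) standardGeneric("utrSeqs"))

#' @rdname UTRSet-class
#' @export
setGeneric("utrRanges", function(x) standardGeneric("utrRanges"))

#' @rdname PermTestResult-class
#' @param x a PermTestResult
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname PermTestResult-class
#' @export
setGeneric("observedStat", function(x) standardGeneric("observedStat"))

#' @rdname PermTestResult-class
#' @export
setGeneric("nullStats", function(x) standardGeneric("nullStats"))

#' @rdname PositionalProfile-class
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @rdname PositionalProfile-class
#' @export
setGeneric("siteCounts", function(x) standardGeneric("siteCounts"))
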