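#' @include AllClasses.R
NULL

#' Accessors for HaplotypeTable and DistanceMatrix
#'
#' `haplotypeNames`, `haplotypeCounts`, `haplotypeFrequencies`,
#' `haplotypeSequences`, `memberIds` and `haplotypeInfo` read the
#' corresponding parts of a [HaplotypeTable-class]; `distLabels` and
#' `distModel` read a [DistanceMatrix-class]. `as.matrix` on a
#' `DistanceMatrix` returns the plain labelled matrix.
#'
#' @param x a `HaplotypeTable` or `DistanceMatrix`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("haplotypeNames", function(x) standardGeneric("haplotypeNames"))
#' @rdname accessors
#' @export
setGeneric("haplotypeCounts", function(x) standardGeneric("haplotypeCounts"))
#' @rdname accessors
#' @export
setGeneric("haplotypeFrequencies",
           function(x) standardGeneric("haplotypeFrequencies"))
#' @rdname accessors
#' @export
setGeneric("haplotypeSequences",
           function(x) standardGeneric("haplotypeSequences"))
#' @rdname accessors
#' @export
setGeneric("memberIds", function(x) standardGeneric("memberIds"))
#' @rdname accessors
#' @export
setGeneric("haplotypeInfo", function(x) standardGeneric("haplotypeInfo"))
#' @rdname accessors
#' @export
setGeneric("distLabels", function(x) standardGeneric("distLabels"))
#' @rdname accessors
#' @export
setGeneric("distModel", function(x) standardGeneric("distModel"))

setMethod("haplotypeNames", "HaplotypeTable",
          function(x) names(x@sequences))
setMethod("haplotypeCounts", "HaplotypeTable", function(x) {
  stats::setNames(x@counts, names(x@sequences))
})
setMethod("haplotypeFrequencies", "HaplotypeTable", function(x) {
  stats::setNames(x@counts / sum(x@counts), names(x@sequences))
})
setMethod("haplotypeSequences", "HaplotypeTable", function(x) x@sequences)
setMethod("memberIds", "HaplotypeTable",
          function(x) stats::setNames(x@memberIds, names(x@sequences)))
setMethod("haplotypeInfo", "HaplotypeTable", function(x) x@info)
setMethod("length", "HaplotypeTable", function(x) length(x@sequences))

setMethod("distLabels", "DistanceMatrix", function(x) rownames(x@values))
setMethod("distModel", "DistanceMatrix", function(x) x@model)
setMethod("as.matrix", "DistanceMatrix", function(x, ...) x@values)
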