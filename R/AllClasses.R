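#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement matchPattern DNAString width
NULL

#' HaplotypeTable: collapsed unique COI sequences with membership and counts
#'
#' A `HaplotypeTable` holds the unique sequences of a set of aligned barcode
#' records, the ids of the records carried by each haplotype, and arbitrary
#' per-haplotype annotation (reproductive-mode fragment pattern, phylogenetic
#' group, ...). Frequencies are always derived from the counts, so they sum
#' to one by construction.
#'
#' @slot sequences named [Biostrings::DNAStringSet] of unique sequences,
#'   one per haplotype; all the same width.
#' @slot counts integer vector, number of records per haplotype (>= 1).
#' @slot memberIds list of character vectors, record ids per haplotype.
#' @slot info data.frame of per-haplotype annotation (zero or more columns).
#' @export
setClass("HaplotypeTable",
  representation(
    sequences = "DNAStringSet",
    counts    = "integer",
    memberIds = "list",
    info      = "data.frame"
  )
)

setValidity("HaplotypeTable", function(object) {
  n <- length(object@sequences)
  msg <- character()
  if (is.null(names(object@sequences)) || anyDuplicated(names(object@sequences)))
    msg <- c(msg, "haplotype names must be present and unique")
  if (length(object@counts) != n)
    msg <- c(msg, "counts length must match number of sequences")
  if (n > 0 && any(object@counts < 1L))
    msg <- c(msg, "all counts must be >= 1")
  if (length(object@memberIds) != n)
    msg <- c(msg, "memberIds length must match number of sequences")
  if (n > 0 && any(lengths(object@memberIds) != object@counts))
    msg <- c(msg, "counts must equal the number of member ids")
  if (n > 1 && length(unique(Biostrings::width(object@sequences))) != 1)
    msg <- c(msg, "all haplotype sequences must have equal length")
  if (nrow(object@info) != 0 && nrow(object@info) != n)
    msg <- c(msg, "info must have one row per haplotype (or none)")
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypeTable
#'
#' @param sequences named `DNAStringSet` (or named character vector).
#' @param counts integer record counts per haplotype.
#' @param memberIds list of record-id vectors; defaults to one synthetic id
#'   per counted record.
#' @param info optional data.frame of per-haplotype annotation.
#' @return A [HaplotypeTable-class] object.
#' @export
HaplotypeTable <- function(sequences, counts, memberIds = NULL, info = NULL) {
  if (is.character(sequences)) sequences <- DNAStringSet(sequences)
  counts <- as.integer(counts)
  if (is.null(memberIds)) {
    nm <- names(sequences)
    memberIds <- mapply(function(h, k) paste0(h, "_", seq_len(k)),
                        nm, counts, SIMPLIFY = FALSE)
  }
  if (is.null(info)) info <- data.frame(row.names = names(sequences))
  new("HaplotypeTable", sequences = sequences, counts = counts,
      memberIds = memberIds, info = info)
}

setMethod("show", "HaplotypeTable", function(object) {
  n <- length(object@sequences)
  cat("HaplotypeTable with", n, "haplotypes,",
      sum(object@counts), "records,",
      if (n) Biostrings::width(object@sequences)[1] else 0, "nt\n")
  if (n) {
    f <- object@counts / sum(object@counts)
    top <- order(object@counts, decreasing = TRUE)[seq_len(min(5, n))]
    for (i in top)
      cat(sprintf("  %-6s count %4d  freq %.3f\n",
                  names(object@sequences)[i], object@counts[i], f[i]))
    if (n > 5) cat("  ...\n")
  }
  if (ncol(object@info))
    cat("info columns:", paste(colnames(object@info), collapse = ", "), "\n")
})

#' DistanceMatrix: labelled symmetric distances with a model tag
#'
#' @slot values symmetric numeric matrix with zero diagonal; dimnames carry
#'   the labels.
#' @slot model character, one of `"p"`, `"JC69"`, `"K2P"`, `"MCL"` for
#'   sequence distances (substitutions/site) or `"haversine"` for geographic
#'   distances (km).
#' @slot deletion character, `"pairwise"`, `"complete"` or `"none"`.
#' @export
setClass("DistanceMatrix",
  representation(values = "matrix", model = "character", deletion = "character")
)

setValidity("DistanceMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "row and column labels must be present and identical")
  if (any(!is.finite(v))) msg <- c(msg, "all values must be finite")
  else {
    if (max(abs(v - t(v))) > 1e-8) msg <- c(msg, "matrix must be symmetric")
    if (any(abs(diag(v)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
    if (any(v < -1e-12)) msg <- c(msg, "distances must be non-negative")
  }
  if (!object@model %in% c("p", "JC69", "K2P", "MCL", "haversine"))
    msg <- c(msg, "unknown model tag")
  if (!object@deletion %in% c("pairwise", "complete", "none"))
    msg <- c(msg, "unknown deletion mode")
  if (length(msg)) msg else TRUE
})

#' Construct a DistanceMatrix
#' @param values square symmetric matrix with labels as dimnames.
#' @param model model tag (see [DistanceMatrix-class]).
#' @param deletion missing-data handling used to compute the values.
#' @return A [DistanceMatrix-class] object.
#' @export
DistanceMatrix <- function(values, model, deletion = "none") {
  new("DistanceMatrix", values = values, model = model, deletion = deletion)
}

setMethod("show", "DistanceMatrix", function(object) {
  cat("DistanceMatrix:", nrow(object@values), "x", ncol(object@values),
      " model =", object@model, " deletion =", object@deletion, "\n")
  v <- object@values[upper.tri(object@values)]
  if (length(v))
    cat(sprintf("  range [%.4g, %.4g], mean %.4g\n", min(v), max(v), mean(v)))
})
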