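#' @include AllClasses.R seqio.R
NULL

#' The COI amplification and reproductive-mode primers
#'
#' The universal barcoding pair (MTD7.2F/MTD9.2R) and the reproductive-mode
#' assay primers: TCOR (universal reverse), TCOS (forward, amplifies a
#' 261-nt fragment from the arrhenotokous mitotype) and TCOC (forward,
#' amplifies a 451-nt fragment from the thelytokous mitotype). Heteroplasmic
#' individuals carry both mitotypes and amplify both fragments.
#'
#' @return data.frame with columns name, sequence, orientation, role.
#' @export
thripsPrimers <- function() {
  data.frame(
    name = c("MTD7.2F", "MTD9.2R", "TCOR", "TCOS", "TCOC"),
    sequence = c("ATTAGGAGCHCCHGAYATAGCATT",
                 "CAGGCAAGATTAAAATATAAACTTCTG",
                 "ATTGCGTAAATTATTCCTAAAAGTCCA",
                 "AACAGCTATTCTCCTTCTTTATCTC",
                 "GAACAGTATATCCACCTTTATCAACG"),
    orientation = c("F", "R", "R", "F", "F"),
    role = c("barcode_forward", "barcode_reverse", "universal_reverse",
             "arrhenotoky_specific", "thelytoky_specific"),
    stringsAsFactors = FALSE
  )
}

# fragment sizes of the reproductive-mode assay (nt, gel-observed lengths)
MODE_FRAGMENTS <- c(thelytokous = 451L, arrhenotokous = 261L)

#' Find primer binding sites on a template
#'
#' IUPAC-aware matching: a primer code matches a template base iff the base
#' is in the code's set (e.g. H = \{A, C, T\}). On the minus strand the
#' reverse complement of the primer is searched on the plus strand, and the
#' reported offset is the plus-strand position of the primer's 5' end (the
#' 3' end of its footprint).
#'
#' @param template a single sequence (character or `DNAString(Set)`).
#' @param primer primer sequence 5'->3' (IUPAC allowed).
#' @param maxMismatch allowed mismatches (default 0).
#' @param strand `"+"` or `"-"`.
#' @return integer vector of 0-based offsets of the primer's 5' end.
#' @export
matchPrimer <- function(template, primer, maxMismatch = 0,
                        strand = c("+", "-")) {
  strand <- match.arg(strand)
  subj <- DNAString(toupper(as.character(template)[1]))
  pat <- DNAString(toupper(primer))
  if (length(pat) >= length(subj)) stop("primer must be shorter than template")
  if (strand == "-") pat <- reverseComplement(pat)
  hits <- matchPattern(pat, subj, max.mismatch = maxMismatch, fixed = FALSE)
  if (strand == "+") Biostrings::start(hits) - 1L else Biostrings::end(hits) - 1L
}

#' In-silico PCR on a template
#'
#' Emulates a multiplex reaction: each forward primer is located on the plus
#' strand, the reverse primer on the minus strand, and every (forward site,
#' reverse site) pair with the forward 5' end upstream of the reverse 5' end
#' yields an amplicon. Lengths are measured 5'-of-forward through
#' 5'-of-reverse inclusive, i.e. they include both primer footprints (the
#' gel-observed product size).
#'
#' @param template a single template sequence.
#' @param fwdPrimers named character vector of forward primers.
#' @param revPrimer the (shared) reverse primer.
#' @param maxMismatch allowed mismatches per primer (default 0: the
#'   mode-specific primers work by exact specificity).
#' @param maxAmplicon longest amplicon reported.
#' @return data.frame with columns fwd, rev, length, start (0-based offset
#'   of the forward 5' end); zero rows if nothing amplifies.
#' @export
inSilicoPCR <- function(template, fwdPrimers, revPrimer, maxMismatch = 0,
                        maxAmplicon = 2000) {
  if (is.null(names(fwdPrimers))) names(fwdPrimers) <- paste0("F", seq_along(fwdPrimers))
  rsites <- matchPrimer(template, revPrimer, maxMismatch, strand = "-")
  out <- data.frame(fwd = character(), rev = character(),
                    length = integer(), start = integer(),
                    stringsAsFactors = FALSE)
  if (length(rsites) == 0) return(out)
  for (nm in names(fwdPrimers)) {
    fsites <- matchPrimer(template, fwdPrimers[[nm]], maxMismatch, strand = "+")
    for (f in fsites) for (r in rsites) {
      len <- r - f + 1L
      if (len >= nchar(fwdPrimers[[nm]]) + nchar(revPrimer) && len <= maxAmplicon)
        out <- rbind(out, data.frame(fwd = nm, rev = "rev", length = len,
                                     start = f, stringsAsFactors = FALSE))
    }
  }
  out
}

#' Classify amplicon lengths into the mode-fragment pattern
#'
#' @param lengths integer amplicon lengths (possibly empty).
#' @param tol match tolerance in nt around the nominal 451/261 sizes
#'   (default 0; +/- 3 mimics gel resolution).
#' @return sorted integer subset of c(261, 451).
#' @export
classifyAmplicons <- function(lengths, tol = 0) {
  pat <- integer()
  for (f in MODE_FRAGMENTS)
    if (any(abs(lengths - f) <= tol)) pat <- c(pat, f)
  sort(pat)
}

#' Call the reproductive mode from a fragment pattern
#'
#' `\{451\}` is thelytokous, `\{261\}` arrhenotokous, `\{451, 261\}`
#' heteroplasmic and `\{\}` undetermined. Heteroplasmic calls are resolved
#' through the phylogenetic group (group1 -> thelytokous, group2 ->
#' arrhenotokous); heteroplasmic individuals in no group, and undetermined
#' patterns, resolve to undetermined.
#'
#' @param pattern integer subset of `c(261, 451)`.
#' @param group `"group1"`, `"group2"` or `"ungrouped"`.
#' @return one-row data.frame: fragment_pattern, raw_call, group,
#'   resolved_mode, resolution_source.
#' @export
callMode <- function(pattern, group = "ungrouped") {
  pattern <- sort(unique(as.integer(pattern)))
  if (length(setdiff(pattern, MODE_FRAGMENTS)))
    stop("unknown fragment length(s) in pattern: ",
         paste(setdiff(pattern, MODE_FRAGMENTS), collapse = ", "))
  if (!group %in% c("group1", "group2", "ungrouped"))
    stop("group must be group1, group2 or ungrouped")
  patStr <- paste(pattern, collapse = "+")
  if (setequal(pattern, MODE_FRAGMENTS)) {
    raw <- "heteroplasmic"
    resolved <- switch(group, group1 = "thelytokous",
                       group2 = "arrhenotokous", "undetermined")
    src <- if (group == "ungrouped") "none" else "phylogeny"
  } else if (identical(pattern, 451L)) {
    raw <- "thelytokous"; resolved <- "thelytokous"; src <- "fragment"
  } else if (identical(pattern, 261L)) {
    raw <- "arrhenotokous"; resolved <- "arrhenotokous"; src <- "fragment"
  } else {
    raw <- "undetermined"; resolved <- "undetermined"; src <- "none"
  }
  data.frame(fragment_pattern = patStr, raw_call = raw, group = group,
             resolved_mode = resolved, resolution_source = src,
             stringsAsFactors = FALSE)
}

#' Vectorised mode calls
#'
#' @param patterns list of integer fragment patterns (subsets of
#'   `c(261, 451)`), named by haplotype or individual.
#' @param groups character vector of groups, recycled names-matched to
#'   `patterns`.
#' @return data.frame with one row per entry, first column `id`.
#' @export
callModes <- function(patterns, groups) {
  if (is.null(names(patterns))) names(patterns) <- paste0("x", seq_along(patterns))
  if (!is.null(names(groups))) groups <- groups[names(patterns)]
  rows <- mapply(function(p, g) callMode(p, g), patterns, groups,
                 SIMPLIFY = FALSE)
  cbind(data.frame(id = names(patterns), stringsAsFactors = FALSE),
        do.call(rbind, rows))
}

#' Per-group heteroplasmy fractions
#'
#' Fraction of haplotypes (or individuals) whose fragment pattern contains
#' both the 451- and 261-nt products, per phylogenetic group, as rounded
#' percent.
#'
#' @param calls data.frame from [callModes()] (columns raw_call, group).
#' @return named numeric vector of rounded percentages, one per group
#'   (ungrouped excluded); `NA` for an empty group.
#' @export
heteroplasmySummary <- function(calls) {
  grps <- setdiff(unique(calls$group), "ungrouped")
  out <- stats::setNames(numeric(length(grps)), sort(grps))
  for (g in names(out)) {
    sel <- calls$group == g
    out[g] <- if (!any(sel)) NA_real_ else
      round(100 * mean(calls$raw_call[sel] == "heteroplasmic"))
  }
  out
}
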