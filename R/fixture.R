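#' @include AllClasses.R haplotyping.R
NULL

.extdata <- function(f) {
  p <- system.file("extdata", f, package = "ThripsCOI")
  if (p == "") stop("missing packaged data file: ", f)
  p
}

#' Build the published 58-haplotype study fixture
#'
#' Reconstructs the 58 Thrips tabaci COI haplotypes from the packaged
#' variable-site table (52 polymorphic positions over the 434-nt fragment),
#' together with the published per-haplotype frequencies, reproductive-mode
#' fragment patterns and phylogenetic groups, the 14 sampling locations
#' with decimal coordinates, and the two per-location compositions printed
#' in the study's main text (Tulancingo de Bravo: 33 x H1; Huron: 32 x H1 +
#' 1 x HU40). Compositions of the remaining locations were published only
#' as supplementary material and are flagged unavailable rather than
#' invented.
#'
#' Haplotype record counts are derived as `round(frequency * 545)` (545
#' sequenced individuals), which reproduces the published total exactly.
#' The invariant background outside the 52 listed positions is seeded and
#' arbitrary: pairwise differences depend only on the listed states.
#'
#' @param backgroundSeed seed for the invariant background sequence.
#' @return list: `haplotypes` ([HaplotypeTable-class] with info columns
#'   `frequency` (printed), `fragment`, `group`), `patterns` (named list of
#'   integer fragment patterns), `groups` (named character vector,
#'   `group1`/`group2`/`ungrouped`), `locations` (data.frame),
#'   `compositions` (named list of haplotype count vectors; `NULL` where
#'   unavailable).
#' @export
buildStudyFixture <- function(backgroundSeed = 1) {
  vs <- readVariableSites(.extdata("study_variable_sites.tsv"))
  counts <- as.integer(round(vs$extra$frequency * 545))
  counts[counts < 1L] <- 1L
  ht <- reconstructHaplotypes(vs, fragmentLength = 434,
                              backgroundSeed = backgroundSeed,
                              counts = counts)
  frag <- vs$extra$fragment
  patterns <- lapply(frag, function(f) {
    if (is.na(f) || f == "") integer() else
      sort(as.integer(strsplit(f, "[^0-9]+")[[1]]))
  })
  names(patterns) <- rownames(vs$states)
  grp <- as.character(vs$extra$group)
  groups <- ifelse(is.na(grp) | grp == "", "ungrouped", paste0("group", grp))
  names(groups) <- rownames(vs$states)

  locations <- utils::read.delim(.extdata("study_locations.tsv"),
                                 stringsAsFactors = FALSE)
  compositions <- stats::setNames(
    vector("list", nrow(locations)), locations$location)
  compositions[["Tulancingo de Bravo"]] <- c(H1 = 33L)
  compositions[["Huron"]] <- c(H1 = 32L, HU40 = 1L)

  list(haplotypes = ht, patterns = patterns, groups = groups,
       locations = locations, compositions = compositions)
}

#' Expand a per-location haplotype composition into sequences
#'
#' @param fixture output of [buildStudyFixture()].
#' @param composition named integer vector of haplotype counts, e.g.
#'   `c(H1 = 32, HU40 = 1)`.
#' @return `DNAStringSet` with one entry per individual.
#' @export
expandComposition <- function(fixture, composition) {
  ht <- fixture$haplotypes
  miss <- setdiff(names(composition), haplotypeNames(ht))
  if (length(miss)) stop("unknown haplotype(s): ", paste(miss, collapse = ", "))
  seqs <- rep(as.character(haplotypeSequences(ht))[names(composition)],
              times = composition)
  out <- DNAStringSet(seqs)
  names(out) <- paste0(rep(names(composition), composition), "_",
                       unlist(lapply(composition, seq_len)))
  out
}
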