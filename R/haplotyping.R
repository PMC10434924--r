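#' @include AllClasses.R seqio.R
NULL

#' Collapse aligned records into haplotypes
#'
#' Under `missingPolicy = "strict"` (default) two records share a haplotype
#' iff their sequences are string-identical. Under `"merge"` a record joins
#' the first existing haplotype with which it agrees at every mutually
#' resolved site (intended for QC-passed records with a few terminal missing
#' nucleotides); the haplotype's representative sequence is completed from
#' the new member where it was missing. Merge compatibility is not
#' transitive, so merging is first-match in input order.
#'
#' @param x aligned records (`DNAStringSet` or character), equal widths;
#'   names are the record ids.
#' @param missingPolicy `"strict"` or `"merge"`.
#' @return A [HaplotypeTable-class] with provisional names `hap1..hapk` in
#'   order of first occurrence; use [nameHaplotypes()] for H/HU naming.
#' @export
collapseHaplotypes <- function(x, missingPolicy = c("strict", "merge")) {
  missingPolicy <- match.arg(missingPolicy)
  x <- asDNA(x)
  if (length(x) == 0) stop("no records to collapse")
  if (is.null(names(x)))
    names(x) <- paste0("rec", seq_along(x))
  s <- toupper(as.character(x))
  if (length(unique(nchar(s))) > 1)
    stop("records must be aligned to equal length before collapsing")

  if (missingPolicy == "strict") {
    grp <- match(s, unique(s))
    reps <- unique(s)
    members <- split(names(x), grp)
  } else {
    reps <- character()
    members <- list()
    chars <- strsplit(s, "")
    for (i in seq_along(s)) {
      ci <- chars[[i]]
      placed <- FALSE
      for (k in seq_along(reps)) {
        rk <- strsplit(reps[k], "")[[1]]
        both <- ci %in% RESOLVED_BASES & rk %in% RESOLVED_BASES
        if (all(ci[both] == rk[both])) {
          fill <- !(rk %in% RESOLVED_BASES) & ci %in% RESOLVED_BASES
          rk[fill] <- ci[fill]
          reps[k] <- paste(rk, collapse = "")
          members[[k]] <- c(members[[k]], names(x)[i])
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        reps <- c(reps, s[i])
        members <- c(members, list(names(x)[i]))
      }
    }
  }
  seqs <- DNAStringSet(reps)
  names(seqs) <- paste0("hap", seq_along(reps))
  HaplotypeTable(seqs, counts = lengths(members),
                 memberIds = unname(members))
}

#' Name haplotypes H / HU by frequency rank
#'
#' Non-singleton haplotypes are named `H1..Hm` in descending count (ties
#' broken by first occurrence in the table order); singletons are named
#' `HU(m+1)..HUn` in table order. Deterministic for a fixed input order.
#'
#' @param ht a [HaplotypeTable-class].
#' @return the table with haplotypes renamed and reordered H first, HU last.
#' @export
nameHaplotypes <- function(ht) {
  stopifnot(is(ht, "HaplotypeTable"))
  cnt <- ht@counts
  shared <- which(cnt > 1L)
  unique_ <- which(cnt == 1L)
  shared <- shared[order(-cnt[shared], shared)]
  ord <- c(shared, unique_)
  nm <- c(if (length(shared)) paste0("H", seq_along(shared)),
          if (length(unique_)) paste0("HU", length(shared) + seq_along(unique_)))
  seqs <- ht@sequences[ord]
  names(seqs) <- nm
  info <- ht@info
  if (nrow(info)) info <- info[ord, , drop = FALSE]
  HaplotypeTable(seqs, counts = cnt[ord], memberIds = ht@memberIds[ord],
                 info = info)
}

#' Variable (polymorphic) sites of a haplotype table
#'
#' Returns exactly the alignment columns at which at least two states occur
#' among the haplotypes, with states written relative to a reference
#' haplotype (`"."` = identical to the reference).
#'
#' @param ht a [HaplotypeTable-class].
#' @param reference name of the reference haplotype (default: first).
#' @return list of class `"VariableSiteTable"`: `reference`, `positions`
#'   (sorted 1-based), `states` (character matrix haplotypes x positions),
#'   `dots` (same, with `"."` notation), plus the fragment length.
#' @export
variableSites <- function(ht, reference = haplotypeNames(ht)[1]) {
  stopifnot(is(ht, "HaplotypeTable"))
  if (!reference %in% haplotypeNames(ht))
    stop("reference haplotype '", reference, "' not in table")
  m <- charMatrix(ht@sequences)
  poly <- which(apply(m, 2, function(z) length(unique(z)) > 1))
  states <- m[, poly, drop = FALSE]
  colnames(states) <- poly
  dots <- states
  refrow <- states[reference, ]
  for (j in seq_along(poly))
    dots[states[, j] == refrow[j], j] <- "."
  dots[reference, ] <- refrow
  structure(list(reference = reference, positions = poly, states = states,
                 dots = dots, length = ncol(m)),
            class = "VariableSiteTable")
}

#' @export
print.VariableSiteTable <- function(x, ...) {
  cat("VariableSiteTable:", length(x$positions), "polymorphic sites over",
      x$length, "nt,", nrow(x$states), "haplotypes (reference ",
      x$reference, ")\n", sep = " ")
  invisible(x)
}

#' Write / read a variable-site table as TSV
#'
#' Mirrors the published layout: one row per haplotype, one column per
#' polymorphic position with `"."` meaning identical to the reference row
#' (which is first and fully spelled out), plus optional annotation columns
#' such as `frequency`, `fragment`, `group`.
#'
#' @param vst a `VariableSiteTable` (from [variableSites()]).
#' @param path TSV path.
#' @param extra optional data.frame of annotation columns (one row per
#'   haplotype, in table order).
#' @export
writeVariableSites <- function(vst, path, extra = NULL) {
  df <- data.frame(haplotype = rownames(vst$dots), vst$dots,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("haplotype", vst$positions)
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVariableSites
#' @return `readVariableSites` returns a list: `positions`, `states`
#'   (resolved character matrix), `extra` (annotation columns), `reference`.
#' @export
readVariableSites <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (colnames(df)[1] != "haplotype") stop("first column must be 'haplotype'")
  poscols <- grep("^[0-9]+$", colnames(df))
  positions <- as.integer(colnames(df)[poscols])
  if (is.unsorted(positions)) stop("position columns must be sorted")
  states <- as.matrix(df[, poscols])
  rownames(states) <- df$haplotype
  ref <- states[1, ]
  if (any(ref == ".")) stop("reference (first) row must spell out all bases")
  for (j in seq_along(positions)) {
    dup <- states[, j] %in% c(".", "")
    states[dup, j] <- ref[j]
  }
  bad <- !(states %in% c("A", "C", "G", "T"))
  if (any(bad)) stop("conflicting or non-nucleotide states in table")
  extra <- df[, -c(1, poscols), drop = FALSE]
  rownames(extra) <- df$haplotype
  list(positions = positions, states = states, extra = extra,
       reference = df$haplotype[1])
}

#' Reconstruct full-length haplotype sequences from a variable-site table
#'
#' Builds full sequences of length `fragmentLength` by laying the listed
#' states over a seeded, invariant background. Because all haplotypes share
#' the background, pairwise differences (hence p-distances) depend only on
#' the listed states and are invariant to `backgroundSeed`.
#'
#' @param vs output of [readVariableSites()] (or a compatible list).
#' @param fragmentLength full fragment length (434 for the COI barcode).
#' @param backgroundSeed seed for the invariant background sequence.
#' @param counts optional integer record counts per haplotype; default 1.
#' @return A [HaplotypeTable-class] carrying the annotation columns of the
#'   source table in `haplotypeInfo()`.
#' @export
reconstructHaplotypes <- function(vs, fragmentLength = 434,
                                  backgroundSeed = 1, counts = NULL) {
  if (max(vs$positions) > fragmentLength)
    stop("positions exceed fragment length")
  rng <- .seededRNG(backgroundSeed)
  background <- sample(c("A", "T", "C", "G"), fragmentLength, replace = TRUE,
                       prob = c(0.35, 0.35, 0.15, 0.15))
  .restoreRNG(rng)
  n <- nrow(vs$states)
  seqs <- vapply(seq_len(n), function(i) {
    s <- background
    s[vs$positions] <- vs$states[i, ]
    paste(s, collapse = "")
  }, "")
  dss <- DNAStringSet(seqs)
  names(dss) <- rownames(vs$states)
  if (is.null(counts)) counts <- rep(1L, n)
  HaplotypeTable(dss, counts = counts, info = vs$extra)
}

#' Write a haplotype table as TSV
#' @param ht a [HaplotypeTable-class].
#' @param path TSV path.
#' @export
writeHaplotypeTable <- function(ht, path) {
  df <- data.frame(name = haplotypeNames(ht),
                   count = haplotypeCounts(ht),
                   frequency = haplotypeFrequencies(ht),
                   sequence = as.character(haplotypeSequences(ht)),
                   stringsAsFactors = FALSE)
  if (ncol(ht@info)) df <- cbind(df, ht@info)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# run code under a temporary RNG state, restoring whatever was there
.seededRNG <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
.restoreRNG <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
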