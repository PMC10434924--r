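#' @include AllClasses.R
NULL

# characters that count as resolved for distance purposes
RESOLVED_BASES <- c("A", "C", "G", "T")

# split a DNAStringSet (or character vector) into a character matrix,
# one row per sequence; errors if lengths differ
charMatrix <- function(x) {
  nm <- names(x)
  s <- toupper(as.character(x))
  names(s) <- nm
  w <- nchar(s)
  if (length(unique(w)) > 1)
    stop("sequences must all have the same length (got widths ",
         paste(sort(unique(w)), collapse = ", "), ")")
  m <- matrix(unlist(strsplit(s, ""), use.names = FALSE),
              nrow = length(s), byrow = TRUE)
  rownames(m) <- names(s)
  m
}

asDNA <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  nm <- names(x)
  out <- DNAStringSet(toupper(as.character(x)))
  names(out) <- nm
  out
}

#' Read a COI FASTA file
#'
#' Reads one record per individual. Sequence ids are the first whitespace
#' token of each description line and must be unique; bases are uppercased.
#'
#' @param path path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
readCoiFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(readDNAStringSet(path, format = "fasta"),
                error = function(e) stop("malformed FASTA in '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  if (length(x)) {
    names(x) <- vapply(strsplit(names(x), "[ \t]+"), `[`, "", 1)
    dup <- names(x)[duplicated(names(x))]
    if (length(dup))
      stop("duplicate sequence id(s) in '", path, "': ",
           paste(unique(dup), collapse = ", "))
    x <- DNAStringSet(toupper(as.character(x)))
  }
  x
}

#' Write sequences to FASTA
#' @param x named `DNAStringSet` or character vector.
#' @param path output path.
#' @export
writeCoiFasta <- function(x, path) {
  writeXStringSet(asDNA(x), path, format = "fasta")
  invisible(path)
}

#' Read / write the sample metadata table
#'
#' Tab-separated with header columns `sample_id`, `location`, `latitude`,
#' `longitude`, `date`, `host`; unknown columns are preserved. Coordinates
#' are validated against decimal-degree ranges.
#'
#' @param path path to a TSV file.
#' @return data.frame with at least the six standard columns.
#' @export
readSampleMetadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "location", "latitude", "longitude")
  miss <- setdiff(req, colnames(md))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  for (opt in c("date", "host")) if (!opt %in% colnames(md)) md[[opt]] <- NA
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata")
  checkCoordinates(md$latitude, md$longitude)
  md
}

#' @rdname readSampleMetadata
#' @param md metadata data.frame.
#' @export
writeSampleMetadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

checkCoordinates <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(lat < -90) || any(lat > 90) || any(lon < -180) || any(lon > 180))
    stop("latitude must lie in [-90, 90] and longitude in [-180, 180]")
  invisible(TRUE)
}

#' Read a primer definition file
#'
#' Plain text, tab-separated: `name  sequence(5'->3')  orientation(F|R)`.
#' IUPAC ambiguity codes are allowed in the sequences.
#'
#' @param path path to the primer file.
#' @return data.frame with columns name, sequence, orientation.
#' @export
readPrimerTable <- function(path) {
  pr <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("name", "sequence", "orientation")
  if (!all(req %in% colnames(pr)))
    stop("primer file needs columns: ", paste(req, collapse = ", "))
  pr$sequence <- toupper(pr$sequence)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", pr$sequence)
  if (any(bad))
    stop("non-IUPAC characters in primer(s): ",
         paste(pr$name[bad], collapse = ", "))
  if (!all(pr$orientation %in% c("F", "R")))
    stop("primer orientation must be F or R")
  pr
}

#' Trim amplification primers off sequences
#'
#' The forward primer is searched on the plus strand, the reverse primer as
#' its reverse complement (both IUPAC-aware). The returned sequence is the
#' region strictly between the two primer footprints. Sequences in which a
#' primer is not found within `maxMismatch` are returned unchanged and
#' flagged.
#'
#' @param x sequences (`DNAStringSet` or character).
#' @param fwd,rev primer sequences, both written 5'->3'.
#' @param maxMismatch maximum mismatches allowed when locating a primer.
#' @return `DNAStringSet` with a logical attribute `"trimmed"` per sequence.
#' @export
trimPrimers <- function(x, fwd, rev, maxMismatch = 1) {
  x <- asDNA(x)
  fwd <- DNAString(toupper(fwd))
  rev <- DNAString(toupper(rev))
  if (any(Biostrings::width(x) < max(length(fwd), length(rev))))
    stop("primer longer than sequence")
  rcrev <- reverseComplement(rev)
  out <- character(length(x))
  flag <- logical(length(x))
  for (i in seq_along(x)) {
    s <- x[[i]]
    mf <- matchPattern(fwd, s, max.mismatch = maxMismatch, fixed = FALSE)
    mr <- matchPattern(rcrev, s, max.mismatch = maxMismatch, fixed = FALSE)
    ok <- length(mf) >= 1 && length(mr) >= 1
    if (ok) {
      from <- Biostrings::end(mf)[1] + 1L
      to <- Biostrings::start(mr)[length(mr)] - 1L
      ok <- from <= to
    }
    if (ok) {
      out[i] <- as.character(Biostrings::subseq(s, from, to))
      flag[i] <- TRUE
    } else {
      out[i] <- as.character(s)
    }
  }
  if (!all(flag))
    warning(sum(!flag), " sequence(s) returned untrimmed (primer not found)")
  res <- DNAStringSet(out)
  names(res) <- names(x)
  attr(res, "trimmed") <- flag
  res
}

#' Extract the analysis window from aligned sequences
#'
#' The window is half-open, 1-based, start-inclusive / end-exclusive, so the
#' default `(341, 775)` yields the 434-nt COI barcode fragment.
#'
#' @param x sequences (`DNAStringSet` or character), reference-aligned.
#' @param start,end window bounds (1-based, `[start, end)`).
#' @return `DNAStringSet` of width `end - start`.
#' @export
windowTrim <- function(x, start = 341, end = 775) {
  x <- asDNA(x)
  if (end <= start) stop("window must have positive length (start < end)")
  if (start < 1 || any(Biostrings::width(x) < end - 1))
    stop("window [", start, ", ", end, ") outside sequence bounds")
  res <- Biostrings::subseq(x, start, end - 1L)
  names(res) <- names(x)
  res
}

#' Quality-filter windowed sequences on end-missing data
#'
#' A record is discarded iff it misses more than `maxEndMissing` nucleotides
#' at the beginning or at the end of the window (runs of gap/ambiguous
#' characters). Records with up to `maxEndMissing` missing at either end are
#' kept; their missing sites are handled downstream by pairwise deletion.
#'
#' @param x sequences (`DNAStringSet` or character), all of width
#'   `windowLen`.
#' @param windowLen expected window length (434 for the COI fragment).
#' @param maxEndMissing largest tolerated terminal run of missing data.
#' @return list with elements `kept` and `discarded` (both `DNAStringSet`).
#' @export
qcFilter <- function(x, windowLen = 434, maxEndMissing = 5) {
  x <- asDNA(x)
  if (length(x) == 0) return(list(kept = x, discarded = x))
  if (any(Biostrings::width(x) != windowLen))
    stop("all sequences must have width ", windowLen, " (align/trim first)")
  m <- charMatrix(x)
  missing <- !(m %in% RESOLVED_BASES)
  dim(missing) <- dim(m)
  lead <- apply(missing, 1, function(z) { r <- rle(z); if (r$values[1]) r$lengths[1] else 0L })
  trail <- apply(missing, 1, function(z) { r <- rle(rev(z)); if (r$values[1]) r$lengths[1] else 0L })
  drop <- lead > maxEndMissing | trail > maxEndMissing
  list(kept = x[!drop], discarded = x[drop])
}
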