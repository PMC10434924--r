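#' @include AllClasses.R seqio.R
NULL

DIST_MODELS <- c("p", "JC69", "K2P", "MCL")

# per-pair site statistics under pairwise deletion of unresolved characters
.pairStats <- function(a, b) {
  ok <- (a %in% RESOLVED_BASES) & (b %in% RESOLVED_BASES)
  a <- a[ok]; b <- b[ok]
  L <- length(a)
  if (L == 0) stop("no mutually resolved sites between the two sequences")
  diff <- a != b
  ts1 <- sum((a == "A" & b == "G") | (a == "G" & b == "A")) # purine transitions
  ts2 <- sum((a == "C" & b == "T") | (a == "T" & b == "C")) # pyrimidine transitions
  tv <- sum(diff) - ts1 - ts2
  counts <- table(factor(c(a, b), levels = RESOLVED_BASES))
  list(L = L, mismatches = sum(diff), P1 = ts1 / L, P2 = ts2 / L, Q = tv / L,
       freqs = as.numeric(counts) / (2 * L))
}

.distFromStats <- function(st, model) {
  p <- st$mismatches / st$L
  switch(model,
    p = p,
    JC69 = {
      if (p >= 0.75)
        stop("JC69 distance undefined: proportion of differences >= 3/4")
      -0.75 * log(1 - 4 * p / 3)
    },
    K2P = {
      P <- st$P1 + st$P2; Q <- st$Q
      w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
      if (w1 <= 0 || w2 <= 0)
        stop("K2P distance undefined: sequences too divergent")
      -0.5 * log(w1 * sqrt(w2))
    },
    MCL = .mclDistance(st),
    stop("unknown model: ", model)
  )
}

# Composite-likelihood-style distance: Tamura-Nei-form correction using the
# empirical base frequencies of the pair (computed over the compared sites of
# both sequences). Converges to the p-distance as p -> 0 and stays within a
# few percent of JC69 at barcode-scale divergences.
.mclDistance <- function(st) {
  f <- st$freqs # A C G T
  piA <- f[1]; piC <- f[2]; piG <- f[3]; piT <- f[4]
  piR <- piA + piG; piY <- piC + piT
  safe <- function(num, den) if (num == 0) 0 else num / den
  k1 <- 2 * safe(piA * piG, piR)
  k2 <- 2 * safe(piT * piC, piY)
  k3 <- 2 * (piR * piY - safe(piA * piG * piY, piR) - safe(piT * piC * piR, piY))
  d <- 0
  term <- function(k, w) {
    if (k == 0) return(0)
    if (w <= 0) stop("MCL distance undefined: sequences too divergent")
    -k * log(w)
  }
  if (k1 > 0) d <- d + term(k1, 1 - st$P1 / k1 - st$Q / (2 * piR))
  else if (st$P1 > 0) stop("inconsistent pair statistics (purine transitions without purines)")
  if (k2 > 0) d <- d + term(k2, 1 - st$P2 / k2 - st$Q / (2 * piY))
  else if (st$P2 > 0) stop("inconsistent pair statistics (pyrimidine transitions without pyrimidines)")
  if (k3 > 0) d <- d + term(k3, 1 - st$Q / (2 * piR * piY))
  else if (st$Q > 0) stop("MCL distance undefined for this base composition")
  d
}

#' Pairwise distance between two nucleotide sequences
#'
#' Distances are numbers of base substitutions per site. Gap, `N` and IUPAC
#' ambiguity characters count as missing and are removed per pair
#' (`deletion = "pairwise"`). Models: `"p"` (proportion of differing sites),
#' `"JC69"`, `"K2P"` (transition/transversion partition) and `"MCL"`, a
#' composite-likelihood-style correction using the empirical base
#' frequencies of the pair (Tamura-Nei form).
#'
#' @param a,b sequences of equal length (character or `DNAString(Set)`).
#' @param model one of `"p"`, `"JC69"`, `"K2P"`, `"MCL"`.
#' @return distance in substitutions/site.
#' @export
pairwiseDistance <- function(a, b, model = c("p", "JC69", "K2P", "MCL")) {
  model <- match.arg(model)
  a <- strsplit(toupper(as.character(a))[1], "")[[1]]
  b <- strsplit(toupper(as.character(b))[1], "")[[1]]
  if (length(a) != length(b)) stop("sequences must have equal length")
  .distFromStats(.pairStats(a, b), model)
}

#' All-pairs distance matrix for a set of aligned sequences
#'
#' @param x aligned sequences (`DNAStringSet`, character vector) or a
#'   [HaplotypeTable-class].
#' @param model distance model, see [pairwiseDistance()].
#' @param deletion `"pairwise"` (per-pair removal of unresolved sites) or
#'   `"complete"` (sites unresolved in any sequence removed globally).
#' @return A [DistanceMatrix-class].
#' @export
seqDistanceMatrix <- function(x, model = c("p", "JC69", "K2P", "MCL"),
                              deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  if (is(x, "HaplotypeTable")) x <- haplotypeSequences(x)
  m <- charMatrix(x)
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  if (deletion == "complete") {
    keep <- apply(m, 2, function(z) all(z %in% RESOLVED_BASES))
    if (!any(keep)) stop("no fully resolved sites under complete deletion")
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- .distFromStats(.pairStats(m[i, ], m[j, ]), model)
    }
  }
  DistanceMatrix(d, model = model, deletion = deletion)
}

#' Nei within-sample genetic diversity
#'
#' Mean number of base substitutions per site over all n(n-1)/2 unordered
#' pairs of sequences in one sample (identical pairs contribute zero).
#'
#' @param x the sample's sequences (aligned; `DNAStringSet` or character),
#'   n >= 2.
#' @inheritParams seqDistanceMatrix
#' @return list with `sample_label` (attr), `n`, `mean_pairwise_distance`,
#'   `model`.
#' @export
withinSampleDiversity <- function(x, model = c("MCL", "p", "JC69", "K2P"),
                                  deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  if (length(x) < 2)
    stop("within-sample diversity needs at least two sequences ",
         "(undefined for n = 1)")
  # collapse duplicate sequences: identical pairs contribute zero, so the
  # mean is a weighted sum over unique-sequence pairs
  s <- toupper(as.character(x))
  u <- unique(s)
  w <- as.numeric(table(factor(s, levels = u)))
  n <- length(s)
  tot <- 0
  if (length(u) > 1) {
    dm <- as.matrix(seqDistanceMatrix(u, model = model, deletion = deletion))
    for (i in seq_len(length(u) - 1)) for (j in (i + 1):length(u))
      tot <- tot + w[i] * w[j] * dm[i, j]
  }
  list(n = n, mean_pairwise_distance = tot / (n * (n - 1) / 2),
       model = model)
}

#' Nei between-sample genetic distance
#'
#' Mean distance over all |A| x |B| cross pairs of sequences.
#'
#' @param a,b two non-empty samples of aligned sequences.
#' @inheritParams seqDistanceMatrix
#' @return distance in substitutions/site.
#' @export
betweenSampleDistance <- function(a, b, model = c("MCL", "p", "JC69", "K2P"),
                                  deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  if (length(a) == 0 || length(b) == 0) stop("samples must be non-empty")
  sa <- toupper(as.character(a)); sb <- toupper(as.character(b))
  if (length(unique(nchar(c(sa, sb)))) > 1)
    stop("samples must be aligned to equal length")
  # weight cross pairs by duplicate multiplicities (exact, faster)
  ua <- unique(sa); ub <- unique(sb)
  wa <- as.numeric(table(factor(sa, levels = ua)))
  wb <- as.numeric(table(factor(sb, levels = ub)))
  ma <- charMatrix(ua); mb <- charMatrix(ub)
  if (deletion == "complete") {
    keep <- apply(rbind(ma, mb), 2, function(z) all(z %in% RESOLVED_BASES))
    ma <- ma[, keep, drop = FALSE]; mb <- mb[, keep, drop = FALSE]
  }
  tot <- 0
  for (i in seq_len(nrow(ma))) for (j in seq_len(nrow(mb))) {
    if (identical(ma[i, ], mb[j, ])) next
    tot <- tot + wa[i] * wb[j] *
      .distFromStats(.pairStats(ma[i, ], mb[j, ]), model)
  }
  tot / (length(sa) * length(sb))
}

#' Unweighted mean pairwise distance among haplotypes
#'
#' @param ht a [HaplotypeTable-class] with >= 2 haplotypes.
#' @inheritParams seqDistanceMatrix
#' @return mean distance over all haplotype pairs (each haplotype counted
#'   once, regardless of frequency).
#' @export
meanHaplotypeDistance <- function(ht, model = c("MCL", "p", "JC69", "K2P"),
                                  deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  if (length(ht) < 2) stop("need at least two haplotypes")
  dm <- as.matrix(seqDistanceMatrix(ht, model = model, deletion = deletion))
  mean(dm[upper.tri(dm)])
}

#' Between-population distance matrix
#'
#' @param pops named list of aligned sequence sets (one per population).
#' @inheritParams seqDistanceMatrix
#' @return A [DistanceMatrix-class] of between-sample means (diagonal 0).
#' @export
popDistanceMatrix <- function(pops, model = c("MCL", "p", "JC69", "K2P"),
                              deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  if (is.null(names(pops))) stop("populations must be named")
  n <- length(pops)
  d <- matrix(0, n, n, dimnames = list(names(pops), names(pops)))
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- betweenSampleDistance(pops[[i]], pops[[j]],
                                                model = model,
                                                deletion = deletion)
  DistanceMatrix(d, model = model, deletion = deletion)
}

#' Write a distance matrix as a labelled square TSV
#' @param dm a [DistanceMatrix-class] (or plain labelled matrix).
#' @param path output path.
#' @export
writeDistanceTSV <- function(dm, path) {
  v <- if (is(dm, "DistanceMatrix")) as.matrix(dm) else dm
  df <- data.frame(label = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix in PHYLIP lower-triangle format
#' @inheritParams writeDistanceTSV
#' @export
writePhylipLower <- function(dm, path) {
  v <- if (is(dm, "DistanceMatrix")) as.matrix(dm) else dm
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%5d", nrow(v)), con)
  for (i in seq_len(nrow(v))) {
    row <- if (i > 1) paste(sprintf("%.6f", v[i, seq_len(i - 1)]), collapse = " ") else ""
    writeLines(trimws(sprintf("%-10s %s", rownames(v)[i], row), "right"), con)
  }
  invisible(path)
}
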