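# Independent oracle implementations used to cross-check the package.
# These deliberately use naive per-site loops and their own bookkeeping.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

oracleRevComp <- function(s) {
  comp <- c(A = "T", T = "A", C = "G", G = "C", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# exhaustive sliding-window scan; a primer code matches a template base iff
# the sets intersect; returns 0-based offsets of the primer's 5' end
oracleMatchPrimer <- function(template, primer, maxMismatch = 0,
                              strand = "+") {
  if (strand == "-") primer <- oracleRevComp(primer)
  t <- strsplit(toupper(template), "")[[1]]
  p <- strsplit(toupper(primer), "")[[1]]
  hits <- integer()
  for (s in 0:(length(t) - length(p))) {
    mm <- 0
    for (k in seq_along(p)) {
      ts <- IUPAC_SETS[[t[s + k]]]
      ps <- IUPAC_SETS[[p[k]]]
      if (is.null(ts) || is.null(ps) || !length(intersect(ts, ps)))
        mm <- mm + 1
    }
    if (mm <= maxMismatch)
      hits <- c(hits, if (strand == "+") s else s + length(p) - 1L)
  }
  hits
}

# site-loop pairwise distance with its own formula bookkeeping
oracleDistance <- function(a, b, model = "p") {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  acgt <- c("A", "C", "G", "T")
  L <- 0; nd <- 0; ts_ag <- 0; ts_ct <- 0; tv <- 0
  cnt <- c(A = 0, C = 0, G = 0, T = 0)
  for (i in seq_along(a)) {
    if (a[i] %in% acgt && b[i] %in% acgt) {
      L <- L + 1
      cnt[a[i]] <- cnt[a[i]] + 1
      cnt[b[i]] <- cnt[b[i]] + 1
      if (a[i] != b[i]) {
        nd <- nd + 1
        pair <- sort(c(a[i], b[i]))
        if (identical(pair, c("A", "G"))) ts_ag <- ts_ag + 1
        else if (identical(pair, c("C", "T"))) ts_ct <- ts_ct + 1
        else tv <- tv + 1
      }
    }
  }
  if (L == 0) stop("no comparable sites")
  p <- nd / L
  if (model == "p") return(p)
  if (model == "JC69") return(-0.75 * log(1 - 4 * p / 3))
  P <- (ts_ag + ts_ct) / L; Q <- tv / L
  if (model == "K2P") return(-0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q)))
  if (model == "MCL") { # Tamura-Nei form with pair base frequencies
    f <- cnt / (2 * L)
    pR <- f["A"] + f["G"]; pY <- f["C"] + f["T"]
    P1 <- ts_ag / L; P2 <- ts_ct / L
    k1 <- 2 * f["A"] * f["G"] / pR
    k2 <- 2 * f["T"] * f["C"] / pY
    k3 <- 2 * (pR * pY - f["A"] * f["G"] * pY / pR - f["T"] * f["C"] * pR / pY)
    d <- 0
    if (k1 > 0) d <- d - k1 * log(1 - P1 / k1 - Q / (2 * pR))
    if (k2 > 0) d <- d - k2 * log(1 - P2 / k2 - Q / (2 * pY))
    if (k3 > 0) d <- d - k3 * log(1 - Q / (2 * pR * pY))
    return(unname(d))
  }
  stop("unknown model")
}

# random aligned sequences, optionally with terminal missing data
randomAlignment <- function(n, len, pDiff = 0.03, missingEnds = 0) {
  base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  out <- vapply(seq_len(n), function(i) {
    s <- base
    k <- rbinom(1, len, pDiff)
    if (k > 0) {
      sites <- sample.int(len, k)
      for (j in sites) s[j] <- sample(setdiff(c("A", "C", "G", "T"), s[j]), 1)
    }
    if (missingEnds > 0) {
      e <- sample(0:missingEnds, 2, replace = TRUE)
      if (e[1] > 0) s[seq_len(e[1])] <- "-"
      if (e[2] > 0) s[len - seq_len(e[2]) + 1] <- "-"
    }
    paste(s, collapse = "")
  }, "")
  names(out) <- paste0("s", seq_len(n))
  out
}

# spherical law of cosines great-circle distance, km
oracleGreatCircle <- function(lat1, lon1, lat2, lon2, R = 6371.0088) {
  r <- pi / 180
  d <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  R * acos(pmin(pmax(d, -1), 1))
}

# Pearson chi-square from the textbook formula
oracleChisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Mantel p by full enumeration of label permutations (small n only)
oracleMantelExact <- function(x, y, alternative = "two.sided") {
  n <- nrow(x)
  ut <- upper.tri(x)
  xv <- x[ut]
  robs <- cor(xv, y[ut])
  perms <- NULL
  permute <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in permute(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  allp <- permute(seq_len(n))
  rs <- vapply(allp, function(p) cor(xv, y[p, p][ut]), 0)
  if (alternative == "two.sided") mean(abs(rs) >= abs(robs) - 1e-12)
  else mean(rs >= robs - 1e-12)
}

studyFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildStudyFixture()
    cache
  }
})
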