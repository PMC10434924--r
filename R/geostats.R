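#' @include AllClasses.R seqio.R
#' @importFrom geosphere distHaversine
NULL

EARTH_RADIUS_KM <- 6371.0088 # mean Earth radius

#' Great-circle distance matrix between sampling locations
#'
#' Haversine distances on a sphere of mean Earth radius 6371.0088 km.
#' Repeated samples of one location (location-time populations) can be
#' listed with identical coordinates and get distance zero.
#'
#' @param locations data.frame with columns `location`, `latitude`,
#'   `longitude` (decimal degrees); one row per population.
#' @return A [DistanceMatrix-class] in kilometres (model `"haversine"`).
#' @export
geoDistanceMatrix <- function(locations) {
  req <- c("location", "latitude", "longitude")
  if (!all(req %in% colnames(locations)))
    stop("locations needs columns: ", paste(req, collapse = ", "))
  checkCoordinates(locations$latitude, locations$longitude)
  n <- nrow(locations)
  labs <- make.unique(as.character(locations$location))
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  pts <- as.matrix(locations[, c("longitude", "latitude")])
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <-
      geosphere::distHaversine(pts[i, ], pts[j, ], r = EARTH_RADIUS_KM * 1000) / 1000
  DistanceMatrix(d, model = "haversine", deletion = "none")
}

#' Mantel permutation test between two distance matrices
#'
#' The statistic is the Pearson correlation over the off-diagonal
#' upper-triangle entries; the null is built by jointly permuting the rows
#' and columns of `y`. The p-value uses the +1/+1 rule (the observed
#' statistic counts as an exceedance), two-sided on |r| by default, with a
#' one-sided `"greater"` option mirroring classical population-genetics
#' software.
#'
#' @param x,y [DistanceMatrix-class] objects or square symmetric matrices
#'   with identical dimensions (and labels, if present).
#' @param nPermutations number of label permutations (default 999).
#' @param seed integer seed for the permutation stream (required for
#'   reproducibility).
#' @param alternative `"two.sided"` or `"greater"`.
#' @return list of class `"mantelResult"`: `r`, `r_squared`, `p_value`,
#'   `n_permutations`, `seed`, `alternative`.
#' @export
mantelTest <- function(x, y, nPermutations = 999, seed,
                       alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (missing(seed)) stop("a seed is required for the permutation stream")
  xm <- if (is(x, "DistanceMatrix")) as.matrix(x) else x
  ym <- if (is(y, "DistanceMatrix")) as.matrix(y) else y
  if (!all(dim(xm) == dim(ym))) stop("matrices must have identical dimensions")
  if (!is.null(rownames(xm)) && !is.null(rownames(ym))) {
    if (!setequal(rownames(xm), rownames(ym)))
      stop("matrices must carry the same labels")
    ym <- ym[rownames(xm), rownames(xm)]
  }
  ut <- upper.tri(xm)
  xv <- xm[ut]
  if (stats::sd(xv) == 0 || stats::sd(ym[ut]) == 0)
    stop("Mantel statistic undefined for a constant matrix")
  robs <- stats::cor(xv, ym[ut])
  n <- nrow(xm)
  rng <- .seededRNG(seed)
  exceed <- 0L
  for (b in seq_len(nPermutations)) {
    p <- sample.int(n)
    rp <- stats::cor(xv, ym[p, p][ut])
    hit <- if (alternative == "two.sided") abs(rp) >= abs(robs) else rp >= robs
    exceed <- exceed + hit
  }
  .restoreRNG(rng)
  structure(list(r = robs, r_squared = robs^2,
                 p_value = (exceed + 1) / (nPermutations + 1),
                 n_permutations = nPermutations, seed = seed,
                 alternative = alternative),
            class = "mantelResult")
}

#' @export
print.mantelResult <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f (R^2 = %.3g), p = %.4g (%s, %d permutations, seed %s)\n",
              x$r, x$r_squared, x$p_value, x$alternative, x$n_permutations,
              format(x$seed)))
  invisible(x)
}

#' Chi-square homogeneity of reproductive modes across locations
#'
#' Pearson chi-square (no continuity correction) of a 2 x L table of
#' thelytokous/arrhenotokous counts per location against homogeneity,
#' expected counts from the margins; df = L - 1. Individuals with an
#' undetermined mode must be excluded before tabulating; locations with a
#' zero total are dropped with a warning.
#'
#' @param counts 2 x L matrix of non-negative integers (rows = modes,
#'   columns = locations), L >= 2.
#' @return list of class `"chisqHomogeneity"`: `statistic`, `df`,
#'   `p_value`, `N`, `table`.
#' @export
modeHomogeneityChisq <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2) stop("expected a 2 x L table (two modes)")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  zero <- colSums(counts) == 0
  if (any(zero)) {
    warning("dropping location(s) with zero total: ",
            paste(colnames(counts)[zero], collapse = ", "))
    counts <- counts[, !zero, drop = FALSE]
  }
  if (ncol(counts) < 2) stop("need at least two locations with counts")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(statistic = unname(ht$statistic),
                 df = ncol(counts) - 1L,
                 p_value = unname(ht$p.value),
                 N = sum(counts), table = counts),
            class = "chisqHomogeneity")
}

#' @export
print.chisqHomogeneity <- function(x, ...) {
  cat(sprintf("Mode homogeneity: X^2(%d, N = %d) = %.2f, p = %.3g\n",
              x$df, x$N, x$statistic, x$p_value))
  invisible(x)
}

#' Haplotype detection probability of a sampling design
#'
#' Probability that at least one carrier of a haplotype at population
#' frequency `freq` appears in a random sample of `n` individuals:
#' 1 - (1 - freq)^n.
#'
#' @param freq haplotype frequency, 0 < freq <= 1.
#' @param n sample size, n >= 1.
#' @return detection probability.
#' @export
detectionProbability <- function(freq, n) {
  if (any(freq <= 0) || any(freq > 1)) stop("freq must be in (0, 1]")
  if (any(n < 1)) stop("n must be >= 1")
  1 - (1 - freq)^n
}

#' Smallest sample size detecting a haplotype frequency with given confidence
#'
#' @inheritParams detectionProbability
#' @param confidence required detection probability (default 0.95).
#' @return smallest integer n with `detectionProbability(freq, n) >=
#'   confidence`.
#' @export
minSampleSize <- function(freq, confidence = 0.95) {
  if (freq <= 0 || freq > 1) stop("freq must be in (0, 1]")
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  if (freq == 1) return(1L)
  n <- ceiling(log(1 - confidence) / log(1 - freq))
  # guard against floating-point edge at the boundary
  while (detectionProbability(freq, n) < confidence) n <- n + 1L
  while (n > 1L && detectionProbability(freq, n - 1L) >= confidence) n <- n - 1L
  as.integer(n)
}
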