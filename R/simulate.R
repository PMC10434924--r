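#' @include AllClasses.R seqio.R haplotyping.R modeTyping.R
NULL

#' Configuration for the synthetic thrips-population generator
#'
#' Defaults emulate the study design the analysis assumes: 14 sampling
#' locations, 33 individuals each (one location with 16), two mitochondrial
#' lineage groups whose core sequences differ at 13 of the 434 barcode
#' sites, sparse private mutations within groups, and per-location
#' reproductive-mode compositions in which heteroplasmy occurs only where
#' both lineages co-occur.
#'
#' @param seed integer seed; the whole simulation is a pure function of it.
#' @param nLocations number of sampling locations.
#' @param nPerLocation integer vector of sample sizes (recycled); default
#'   33 per location with a single 16.
#' @param groupCoreDivergence number of fixed differences between the two
#'   group core sequences (default 13).
#' @param withinGroupMutationRate per-site probability of a private
#'   mutation in an individual's barcode (default 0.0015, i.e. about 0.65
#'   expected mutations per 434-nt sequence).
#' @param modeComposition `nLocations` x 4 matrix of per-location fractions
#'   (columns thelytokous, arrhenotokous, heteroplasmic, none), rows
#'   summing to 1. Default: five pure-thelytokous locations and nine
#'   sympatric mixtures with heteroplasmy.
#' @param geography `"panmictic"` (seeded worldwide coordinates, no
#'   relation between genetic and geographic distance) or
#'   `"isolation_by_distance"` (single-lineage cline along an equatorial
#'   transect: genetic distance grows linearly with distance).
#' @param ibdStep mutations added per transect step in
#'   isolation-by-distance mode.
#' @param interspecificContaminantFraction fraction of individuals replaced
#'   by a second species diverged ~19% from the ingroup.
#' @param fragmentLength barcode length (434).
#' @return list of class `"simConfig"`.
#' @export
simConfig <- function(seed = 1, nLocations = 14,
                      nPerLocation = c(rep(33L, 13), 16L),
                      groupCoreDivergence = 13,
                      withinGroupMutationRate = 0.0015,
                      modeComposition = NULL,
                      geography = c("panmictic", "isolation_by_distance"),
                      ibdStep = 3,
                      interspecificContaminantFraction = 0,
                      fragmentLength = 434) {
  geography <- match.arg(geography)
  nPerLocation <- rep_len(as.integer(nPerLocation), nLocations)
  if (is.null(modeComposition)) {
    # four location archetypes (pure thelytokous through arrhenotoky-
    # dominated sympatry), allotted 5:4:3:2 by largest remainder so the
    # 14-location default has five pure-thelytokous populations
    types <- rbind(c(1, 0, 0, 0), c(0.60, 0.25, 0.15, 0),
                   c(0.45, 0.35, 0.20, 0), c(0.25, 0.55, 0.20, 0))
    share <- c(5, 4, 3, 2) / 14 * nLocations
    cnt <- floor(share)
    rem <- order(share - cnt, decreasing = TRUE)
    k <- nLocations - sum(cnt)
    if (k > 0) cnt[rem[seq_len(k)]] <- cnt[rem[seq_len(k)]] + 1L
    modeComposition <- types[rep(seq_len(4), cnt), , drop = FALSE]
  }
  modeComposition <- as.matrix(modeComposition)
  if (ncol(modeComposition) != 4 || nrow(modeComposition) != nLocations)
    stop("modeComposition must be nLocations x 4 ",
         "(thelytokous, arrhenotokous, heteroplasmic, none)")
  if (any(modeComposition < 0) ||
      any(abs(rowSums(modeComposition) - 1) > 1e-9))
    stop("modeComposition rows must be non-negative and sum to 1")
  if (withinGroupMutationRate < 0 || withinGroupMutationRate > 1)
    stop("withinGroupMutationRate must be in [0, 1]")
  if (groupCoreDivergence > fragmentLength)
    stop("groupCoreDivergence cannot exceed the fragment length")
  structure(list(seed = seed, nLocations = nLocations,
                 nPerLocation = nPerLocation,
                 groupCoreDivergence = groupCoreDivergence,
                 withinGroupMutationRate = withinGroupMutationRate,
                 modeComposition = modeComposition, geography = geography,
                 ibdStep = ibdStep,
                 interspecificContaminantFraction =
                   interspecificContaminantFraction,
                 fragmentLength = fragmentLength),
            class = "simConfig")
}

.randomSeq <- function(n) {
  # AT-rich background resembling insect mitochondrial DNA
  sample(c("A", "T", "C", "G"), n, replace = TRUE,
         prob = c(0.35, 0.35, 0.15, 0.15))
}

.mutateSites <- function(seq, sites) {
  for (s in sites) seq[s] <- sample(setdiff(c("A", "C", "G", "T"), seq[s]), 1)
  seq
}

# reproductive-mode assay fragments with implanted primer sites; the
# thelytokous fragment carries the arrhenotoky primer site corrupted by a
# T insertion (at fragment position 212), so a pure thelytokous template
# can never yield the 261-nt product
.assayFragments <- function() {
  pr <- thripsPrimers()
  tcor <- pr$sequence[pr$name == "TCOR"]
  tcos <- pr$sequence[pr$name == "TCOS"]
  tcoc <- pr$sequence[pr$name == "TCOC"]
  rcTcor <- as.character(reverseComplement(DNAString(tcor)))
  corruptedTcos <- paste0(substr(tcos, 1, 21), "T", substr(tcos, 22, 25))
  fillerA <- paste(.randomSeq(261 - nchar(tcos) - nchar(tcor)), collapse = "")
  fillerB <- paste(.randomSeq(190 - nchar(tcoc)), collapse = "")
  fillerC <- paste(.randomSeq(451 - nchar(tcoc) - nchar(fillerB) -
                              nchar(corruptedTcos) - nchar(tcor)), collapse = "")
  list(
    arrhenotokous = paste0(tcos, fillerA, rcTcor),
    thelytokous = paste0(tcoc, fillerB, corruptedTcos, fillerC, rcTcor),
    blank = paste(.randomSeq(400), collapse = "")
  )
}

#' Simulate geo-referenced barcode populations
#'
#' Per individual: a 434-nt barcode built from its lineage-group core plus
#' binomially sprinkled private mutations, and a reproductive-mode assay
#' template set (two mitotypes iff heteroplasmic, none amplifying for
#' `"none"` individuals and interspecific contaminants). Fully reproducible
#' given the config seed.
#'
#' @param config a [simConfig()].
#' @param dir optional directory; if given, `barcodes.fasta`,
#'   `metadata.tsv` and `truth.tsv` are written there.
#' @return list: `sequences` (barcodes, `DNAStringSet`), `metadata`
#'   (sample_id, location, latitude, longitude, date, host), `truth`
#'   (sample_id, location, group, mode, pattern, species), `assayTemplates`
#'   (per-individual character vectors of templates), `locations`, `cores`,
#'   `config`.
#' @export
simulateThrips <- function(config = simConfig(), dir = NULL) {
  stopifnot(inherits(config, "simConfig"))
  rng <- .seededRNG(config$seed)
  on.exit(.restoreRNG(rng))
  L <- config$fragmentLength
  nl <- config$nLocations

  core1 <- .randomSeq(L)
  divSites <- sample.int(L, config$groupCoreDivergence)
  core2 <- .mutateSites(core1, divSites)
  contamCore <- .mutateSites(core1, sample.int(L, round(0.19 * L)))

  if (config$geography == "panmictic") {
    lat <- round(stats::runif(nl, -40, 55), 4)
    lon <- round(stats::runif(nl, -180, 180), 4)
  } else {
    lat <- rep(0, nl)
    lon <- seq(0, by = 3, length.out = nl) # ~333 km per step on the equator
    ladder <- sample.int(L) # cumulative cline sites
  }
  locNames <- sprintf("Loc%02d", seq_len(nl))
  locations <- data.frame(location = locNames, latitude = lat,
                          longitude = lon, stringsAsFactors = FALSE)

  frag <- .assayFragments()
  pad5 <- paste(.randomSeq(30), collapse = "")
  pad3 <- paste(.randomSeq(30), collapse = "")
  template <- function(kind) paste0(pad5, frag[[kind]], pad3)

  ids <- character(); locv <- character(); groupv <- character()
  modev <- character(); patv <- character(); specv <- character()
  seqs <- character(); templates <- list()
  for (i in seq_len(nl)) {
    coreA <- core1
    if (config$geography == "isolation_by_distance" && i > 1)
      coreA <- .mutateSites(core1,
                            ladder[seq_len((i - 1) * config$ibdStep)])
    for (k in seq_len(config$nPerLocation[i])) {
      id <- sprintf("%s_ind%02d", locNames[i], k)
      contaminant <- config$interspecificContaminantFraction > 0 &&
        stats::runif(1) < config$interspecificContaminantFraction
      if (config$geography == "isolation_by_distance") {
        mode <- "thelytokous" # single-lineage cline
      } else {
        mode <- sample(c("thelytokous", "arrhenotokous", "heteroplasmic",
                         "none"), 1, prob = config$modeComposition[i, ])
      }
      group <- switch(mode,
        thelytokous = "group1", arrhenotokous = "group2",
        heteroplasmic = sample(c("group1", "group2"), 1),
        none = "ungrouped")
      core <- if (contaminant) contamCore
              else if (group == "group2") core2 else coreA
      nmut <- stats::rbinom(1, L, config$withinGroupMutationRate)
      bc <- if (nmut > 0) .mutateSites(core, sample.int(L, nmut)) else core
      tmpl <- if (contaminant || mode == "none") template("blank")
              else switch(mode,
                thelytokous = template("thelytokous"),
                arrhenotokous = template("arrhenotokous"),
                heteroplasmic = c(template("thelytokous"),
                                  template("arrhenotokous")))
      ids <- c(ids, id); locv <- c(locv, locNames[i])
      groupv <- c(groupv, if (contaminant) "ungrouped" else group)
      modev <- c(modev, if (contaminant) "undetermined" else
                          if (mode == "none") "undetermined" else
                          if (mode == "heteroplasmic")
                            switch(group, group1 = "thelytokous",
                                   group2 = "arrhenotokous") else mode)
      patv <- c(patv, if (contaminant || mode == "none") "" else
                        switch(mode, thelytokous = "451",
                               arrhenotokous = "261",
                               heteroplasmic = "261+451"))
      specv <- c(specv, if (contaminant) "Frankliniella_synthetica"
                        else "Thrips_tabaci")
      seqs <- c(seqs, paste(bc, collapse = ""))
      templates[[id]] <- tmpl
    }
  }
  sequences <- DNAStringSet(seqs)
  names(sequences) <- ids
  metadata <- data.frame(sample_id = ids, location = locv,
                         latitude = locations$latitude[match(locv, locNames)],
                         longitude = locations$longitude[match(locv, locNames)],
                         date = NA, host = "Allium cepa",
                         stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = ids, location = locv, group = groupv,
                      mode = modev, pattern = patv, species = specv,
                      stringsAsFactors = FALSE)
  out <- list(sequences = sequences, metadata = metadata, truth = truth,
              assayTemplates = templates, locations = locations,
              cores = list(group1 = paste(core1, collapse = ""),
                           group2 = paste(core2, collapse = "")),
              config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeCoiFasta(sequences, file.path(dir, "barcodes.fasta"))
    writeSampleMetadata(metadata, file.path(dir, "metadata.tsv"))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}
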