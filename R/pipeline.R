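#' @include AllClasses.R seqio.R haplotyping.R distances.R nj.R modeTyping.R
#' @include geostats.R
NULL

#' Run the full barcode population analysis
#'
#' Orchestrates QC, haplotype collapsing and naming, haplotype distances,
#' Neighbor-Joining with optional outgroup rooting and anchored group
#' assignment, reproductive-mode calling from in-silico PCR templates,
#' per-location Nei diversity, the chi-square homogeneity test of modes
#' across locations, and the Mantel test of genetic versus geographic
#' distance. Stages without their required inputs are skipped (reported as
#' `NULL`); every number in the report is recomputable from the inputs and
#' the seed.
#'
#' @param sequences barcode sequences (`DNAStringSet` or FASTA path).
#' @param metadata sample metadata (data.frame or TSV path) with columns
#'   sample_id, location, latitude, longitude.
#' @param assayTemplates optional named list (per sample_id) of
#'   reproductive-mode assay template sequences (>= 1 per individual).
#' @param outgroup optional single named sequence used to root the tree.
#' @param anchors optional named list of anchor haplotype names for
#'   [assignGroups()].
#' @param model distance model (default `"MCL"`).
#' @param nPermutations Mantel permutations (default 999).
#' @param seed integer seed for all randomness in the run.
#' @param windowLen barcode window length for QC (434).
#' @param maxEndMissing QC threshold on terminal missing nucleotides.
#' @return list of class `"thripsReport"`.
#' @export
runPipeline <- function(sequences, metadata, assayTemplates = NULL,
                        outgroup = NULL, anchors = NULL, model = "MCL",
                        nPermutations = 999, seed = 1, windowLen = 434,
                        maxEndMissing = 5) {
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences))
    sequences <- readCoiFasta(sequences)
  if (is.character(metadata) && length(metadata) == 1)
    metadata <- readSampleMetadata(metadata)
  sequences <- asDNA(sequences)

  qc <- qcFilter(sequences, windowLen = windowLen,
                 maxEndMissing = maxEndMissing)
  kept <- qc$kept
  if (length(kept) == 0) stop("no sequences pass QC")
  md <- metadata[match(names(kept), metadata$sample_id), ]
  if (anyNA(md$sample_id)) stop("metadata is missing QC-passing sample ids")

  ht <- nameHaplotypes(collapseHaplotypes(kept))
  recHap <- stats::setNames(rep(haplotypeNames(ht), haplotypeCounts(ht)),
                            unlist(memberIds(ht)))[names(kept)]

  hdist <- if (length(ht) >= 2) seqDistanceMatrix(ht, model = model) else NULL

  tree <- rooted <- NULL
  groups <- stats::setNames(rep("ungrouped", length(ht)), haplotypeNames(ht))
  if (!is.null(hdist) && length(ht) >= 3) {
    treeInput <- hdist
    ogName <- NULL
    if (!is.null(outgroup)) {
      ogName <- if (!is.null(names(outgroup))) names(outgroup)[1] else "outgroup"
      aln <- c(haplotypeSequences(ht), asDNA(stats::setNames(
        as.character(outgroup)[1], ogName)))
      treeInput <- seqDistanceMatrix(aln, model = model)
    }
    tree <- neighborJoining(treeInput)
    if (!is.null(ogName)) {
      rooted <- rootWithOutgroup(tree, ogName)
      if (!is.null(anchors))
        groups <- assignGroups(rooted, anchors, exclude = ogName)
    }
  }

  modeCalls <- NULL
  if (!is.null(assayTemplates)) {
    pr <- thripsPrimers()
    fwd <- stats::setNames(pr$sequence[pr$name %in% c("TCOC", "TCOS")],
                           pr$name[pr$name %in% c("TCOC", "TCOS")])
    rev <- pr$sequence[pr$name == "TCOR"]
    patterns <- lapply(assayTemplates, function(tmpls) {
      lens <- unlist(lapply(tmpls, function(t)
        inSilicoPCR(t, fwd, rev)$length))
      classifyAmplicons(lens)
    })
    indGroups <- groups[recHap[names(patterns)]]
    indGroups[is.na(indGroups)] <- "ungrouped"
    modeCalls <- callModes(patterns, unname(indGroups))
    modeCalls$haplotype <- unname(recHap[modeCalls$id])
    modeCalls$location <- metadata$location[match(modeCalls$id,
                                                  metadata$sample_id)]
  }

  pops <- split(seq_along(kept), md$location)
  diversity <- do.call(rbind, lapply(names(pops), function(loc) {
    idx <- pops[[loc]]
    data.frame(location = loc, n = length(idx),
               diversity = if (length(idx) >= 2)
                 withinSampleDiversity(kept[idx],
                                       model = model)$mean_pairwise_distance
               else NA_real_,
               stringsAsFactors = FALSE)
  }))

  popDist <- geo <- mantel <- NULL
  if (length(pops) >= 3) {
    popDist <- popDistanceMatrix(lapply(pops, function(i) kept[i]),
                                 model = model)
    locs <- unique(md[, c("location", "latitude", "longitude")])
    locs <- locs[match(names(pops), locs$location), ]
    geo <- geoDistanceMatrix(locs)
    mantel <- tryCatch(
      mantelTest(geo, popDist, nPermutations = nPermutations, seed = seed),
      error = function(e) NULL)
  }

  chisq <- NULL
  if (!is.null(modeCalls)) {
    resolved <- modeCalls[modeCalls$resolved_mode %in%
                            c("thelytokous", "arrhenotokous"), ]
    if (nrow(resolved) && length(unique(resolved$location)) >= 2) {
      tab <- table(factor(resolved$resolved_mode,
                          levels = c("thelytokous", "arrhenotokous")),
                   resolved$location)
      chisq <- tryCatch(modeHomogeneityChisq(unclass(tab)),
                        error = function(e) NULL)
    }
  }

  structure(list(
    n_input = length(sequences), n_kept = length(kept),
    haplotypes = ht, record_haplotype = recHap,
    haplotype_distances = hdist, tree = tree, rooted_tree = rooted,
    groups = groups, mode_calls = modeCalls, diversity = diversity,
    population_distances = popDist, geographic_distances = geo,
    mantel = mantel, chisq = chisq,
    provenance = list(seed = seed, model = model,
                      n_permutations = nPermutations,
                      window_length = windowLen,
                      max_end_missing = maxEndMissing,
                      package_version = as.character(
                        utils::packageVersion("ThripsCOI")),
                      schema = "thrips-report/1")
  ), class = "thripsReport")
}

#' @export
print.thripsReport <- function(x, ...) {
  cat("Barcode population analysis report\n")
  cat(sprintf("  records: %d input, %d after QC; %d haplotypes\n",
              x$n_input, x$n_kept, length(x$haplotypes)))
  if (!is.null(x$haplotype_distances))
    cat(sprintf("  mean haplotype distance (%s): %.4f\n",
                distModel(x$haplotype_distances),
                mean(as.matrix(x$haplotype_distances)[
                  upper.tri(as.matrix(x$haplotype_distances))])))
  if (!is.null(x$mantel))
    cat(sprintf("  Mantel: r = %.3f, p = %.3g\n", x$mantel$r,
                x$mantel$p_value))
  if (!is.null(x$chisq))
    cat(sprintf("  mode homogeneity: X^2(%d, N = %d) = %.2f, p = %.3g\n",
                x$chisq$df, x$chisq$N, x$chisq$statistic, x$chisq$p_value))
  invisible(x)
}

#' Write an analysis report (and per-stage outputs) to a directory
#'
#' Writes `report.json` plus TSV/newick stage outputs under `dir`.
#'
#' @param report a `"thripsReport"` from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return the path to `report.json`, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeHaplotypeTable(report$haplotypes, file.path(dir, "haplotypes.tsv"))
  if (!is.null(report$haplotype_distances))
    writeDistanceTSV(report$haplotype_distances,
                     file.path(dir, "haplotype_distances.tsv"))
  if (!is.null(report$tree))
    ape::write.tree(report$tree, file.path(dir, "nj_tree.nwk"))
  if (!is.null(report$mode_calls))
    utils::write.table(report$mode_calls, file.path(dir, "mode_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$diversity, file.path(dir, "diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  json <- list(
    schema = report$provenance$schema,
    n_input = report$n_input, n_kept = report$n_kept,
    n_haplotypes = length(report$haplotypes),
    haplotype_frequencies = as.list(haplotypeFrequencies(report$haplotypes)),
    groups = as.list(report$groups),
    diversity = report$diversity,
    mean_haplotype_distance = if (!is.null(report$haplotype_distances)) {
      m <- as.matrix(report$haplotype_distances)
      mean(m[upper.tri(m)])
    },
    mantel = if (!is.null(report$mantel)) unclass(report$mantel),
    chisq = if (!is.null(report$chisq))
      list(statistic = report$chisq$statistic, df = report$chisq$df,
           p_value = report$chisq$p_value, N = report$chisq$N),
    provenance = report$provenance
  )
  path <- file.path(dir, "report.json")
  jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
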