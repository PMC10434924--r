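#' @include AllClasses.R distances.R
NULL

#' Read a labelled species reference panel from FASTA
#'
#' Description lines must carry a `species=` key, e.g.
#' `>ref1 species=Thrips_tabaci`.
#'
#' @param path FASTA path.
#' @return list: `sequences` (named `DNAStringSet`), `species` (character
#'   vector parallel to the sequences).
#' @export
readReferencePanel <- function(path) {
  x <- tryCatch(readDNAStringSet(path, format = "fasta"),
                error = function(e) stop("malformed FASTA in '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  desc <- names(x)
  sp <- regmatches(desc, regexpr("species=[^ \t]+", desc))
  if (length(sp) != length(x))
    stop("every reference needs a 'species=' key in its description line")
  species <- sub("^species=", "", sp)
  names(x) <- vapply(strsplit(desc, "[ \t]+"), `[`, "", 1)
  list(sequences = DNAStringSet(toupper(as.character(x))), species = species)
}

#' Assign query sequences to species across the COI barcode gap
#'
#' Nearest-reference assignment: a query takes the species of its closest
#' reference iff that distance is at most `conspecificMax` (the empirical
#' within-species ceiling, ~5% for thrips COI). Distances between
#' `conspecificMax` and `heterospecificMin` fall in the barcode gap;
#' distances at or beyond `heterospecificMin` (~20%, the between-species
#' range) are heterospecific. In both cases the query is unassigned.
#'
#' @param queries aligned query sequences (`DNAStringSet` or character).
#' @param panel reference panel: list as from [readReferencePanel()], or a
#'   named `DNAStringSet` plus `species` vector.
#' @param species species labels if `panel` is a plain sequence set.
#' @param conspecificMax within-species distance ceiling (default 0.05).
#' @param heterospecificMin between-species distance floor (default 0.15).
#' @param model distance model (default `"p"`).
#' @return data.frame: query_id, best_reference, best_distance, species,
#'   zone (`conspecific` / `gap` / `heterospecific`).
#' @export
assignSpecies <- function(queries, panel, species = NULL,
                          conspecificMax = 0.05, heterospecificMin = 0.15,
                          model = c("p", "JC69", "K2P", "MCL")) {
  model <- match.arg(model)
  if (is.list(panel) && !is.null(panel$sequences)) {
    species <- panel$species
    panel <- panel$sequences
  }
  if (length(panel) == 0) stop("reference panel is empty")
  if (is.null(species) || length(species) != length(panel))
    stop("need one species label per reference")
  if (conspecificMax >= heterospecificMin)
    stop("conspecificMax must be below heterospecificMin")
  queries <- asDNA(queries)
  if (is.null(names(queries))) names(queries) <- paste0("q", seq_along(queries))
  qm <- charMatrix(queries)
  pm <- charMatrix(panel)
  if (ncol(qm) != ncol(pm))
    stop("queries and references must be aligned to the same window")
  refnames <- if (!is.null(rownames(pm))) rownames(pm) else paste0("ref", seq_len(nrow(pm)))
  out <- vector("list", nrow(qm))
  for (i in seq_len(nrow(qm))) {
    d <- vapply(seq_len(nrow(pm)), function(j)
      .distFromStats(.pairStats(qm[i, ], pm[j, ]), model), 0)
    best <- which(d == min(d))
    if (length(best) > 1)
      warning("tie on best distance for query '", rownames(qm)[i],
              "'; keeping first reference in panel order")
    best <- best[1]
    zone <- if (d[best] <= conspecificMax) "conspecific"
            else if (d[best] < heterospecificMin) "gap"
            else "heterospecific"
    out[[i]] <- data.frame(
      query_id = rownames(qm)[i],
      best_reference = refnames[best],
      best_distance = d[best],
      species = if (zone == "conspecific") species[best] else "unassigned",
      zone = zone, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
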