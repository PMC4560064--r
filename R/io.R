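#' @importFrom utils read.delim write.table
NULL

#' Read an OTU count table
#'
#' Parses a TSV with OTU ids in the first column, an optional taxonomy
#' column second (detected by non-numeric content), and time-ordered count
#' columns after that. Empty cells and `"NA"` are recorded in the missing
#' mask.
#'
#' @param path path to the TSV file.
#' @return An [AbundanceTable].
#' @export
readOTUTable <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   na.strings = c("NA", ""), stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L) stop("readOTUTable: need an id column and data columns")
  ids <- df[[1L]]
  if (anyNA(ids)) stop("readOTUTable: missing OTU id")
  if (anyDuplicated(ids))
    stop("readOTUTable: duplicate OTU id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  dataStart <- 2L
  taxonomy <- NULL
  col2 <- df[[2L]]
  if (ncol(df) > 2L && any(is.na(suppressWarnings(as.numeric(col2[!is.na(col2)]))))) {
    taxonomy <- col2
    dataStart <- 3L
  }
  raw <- df[, dataStart:ncol(df), drop = FALSE]
  counts <- matrix(NA_real_, nrow(df), ncol(raw),
                   dimnames = list(ids, colnames(raw)))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(!is.na(raw[[j]]) & is.na(v))
    if (length(bad))
      stop(sprintf("readOTUTable: non-numeric count '%s' at line %d, column '%s'",
                   raw[[j]][bad[1L]], bad[1L] + 1L, colnames(raw)[j]))
    neg <- which(!is.na(v) & v < 0)
    if (length(neg))
      stop(sprintf("readOTUTable: negative count at line %d, column '%s'",
                   neg[1L] + 1L, colnames(raw)[j]))
    counts[, j] <- v
  }
  AbundanceTable(counts, taxonomy = taxonomy)
}

#' Write an SRP matrix as TSV
#'
#' @param x an [SRPMatrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSRPTable <- function(x, path) {
  stopifnot(is(x, "SRPMatrix"))
  df <- data.frame(otu_id = rownames(x), srp(x), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a triplet score table as TSV
#'
#' Columns: `rank` (if present), `m`, `c`, `t`, `L`, `Ld`, `D`, `I`.
#'
#' @param triplets triplet data.frame (ideally from [rankTriplets()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTripletTable <- function(triplets, path) {
  cols <- intersect(c("rank", "m", "c", "t", "L", "Ld", "D", "I"),
                    names(triplets))
  write.table(triplets[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a regulatory network to disk
#'
#' `"tsv"` writes the edge table (`source`, `target`, `sign`,
#' `n_supporting_triplets`, `best_I`); `"sif"` writes Cytoscape SIF lines
#' (`source coop|comp target`). Edges are sorted by source, target, sign
#' so equal networks produce byte-identical files.
#'
#' @param net a [RegulatoryNetwork].
#' @param path output path.
#' @param format `"tsv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  stopifnot(is(net, "RegulatoryNetwork"))
  e <- edges(net)
  e <- e[order(e$source, e$target, e$sign), , drop = FALSE]
  if (format == "tsv") {
    out <- data.frame(source = e$source, target = e$target, sign = e$sign,
                      n_supporting_triplets = e$nSupporting, best_I = e$bestI)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    rel <- ifelse(e$sign == "cooperative", "coop", "comp")
    writeLines(sprintf("%s\t%s\t%s", e$source, rel, e$target), path)
  }
  invisible(path)
}

#' Read a regulatory network edge TSV
#'
#' Inverse of [writeNetwork()] (TSV format). Provenance is not stored on
#' disk and comes back empty.
#'
#' @param path path to an edge TSV.
#' @return A [RegulatoryNetwork].
#' @export
readNetwork <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  e <- data.frame(source = as.character(df$source),
                  target = as.character(df$target),
                  sign = as.character(df$sign),
                  nSupporting = as.integer(df$n_supporting_triplets),
                  bestI = as.numeric(df$best_I), stringsAsFactors = FALSE)
  e <- e[order(e$source, e$target, e$sign), , drop = FALSE]
  rownames(e) <- NULL
  RegulatoryNetwork(nodes = sort(unique(c(e$source, e$target))), edges = e,
                    provenance = rep(list(character()), nrow(e)))
}

#' Run the full inference pipeline and write its outputs
#'
#' Executes preprocess (optional) -> scan -> filter -> rank -> build on an
#' OTU table and writes the ranked triplet table, the network edge TSV and
#' SIF, and a JSON run manifest recording every parameter and a
#' configuration hash (also stamped in the manifest so reruns are
#' verifiable). Thresholds default to the sensitivity-oriented setting for
#' noisy real data (`ldMax = 3.8`, `dMax = 0.8`).
#'
#' @param input path to a count TSV, an [AbundanceTable], or an
#'   [SRPMatrix] (already preprocessed).
#' @param outDir output directory (created if needed).
#' @param ldMax,dMax,topK triplet filter/cap settings.
#' @param conflict edge sign-conflict policy, see [buildNetwork()].
#' @param preprocessArgs list of arguments for [preprocessPipeline()].
#' @return Invisibly, a list with `srp`, `triplets` (ranked, filtered),
#'   `network` and the output `paths`.
#' @export
runInference <- function(input, outDir, ldMax = 3.8, dMax = 0.8, topK = NULL,
                         conflict = "error", preprocessArgs = list()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- "preprocess"
  result <- tryCatch({
    x <- if (is.character(input)) readOTUTable(input) else input
    srpMat <- if (is(x, "SRPMatrix")) x
      else do.call(preprocessPipeline, c(list(x), preprocessArgs))
    stage <- "scan"
    trips <- scanTriplets(srpMat)
    stage <- "filter"
    kept <- filterTriplets(trips, ldMax, dMax)
    stage <- "rank"
    ranked <- rankTriplets(kept)
    stage <- "build"
    net <- buildNetwork(ranked, topK = topK, conflict = conflict)
    list(srp = srpMat, triplets = ranked, network = net)
  }, error = function(e) {
    stop(sprintf("runInference failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  cfg <- list(input = if (is.character(input)) input else class(input)[1L],
              ldMax = ldMax, dMax = dMax,
              topK = if (is.null(topK)) NA else topK, conflict = conflict,
              preprocessArgs = preprocessArgs)
  cfg$hash <- rlang::hash(cfg)
  paths <- list(triplets = file.path(outDir, "triplets.tsv"),
                networkTsv = file.path(outDir, "network.tsv"),
                networkSif = file.path(outDir, "network.sif"),
                srp = file.path(outDir, "srp.tsv"),
                manifest = file.path(outDir, "manifest.json"))
  writeTripletTable(result$triplets, paths$triplets)
  writeNetwork(result$network, paths$networkTsv, "tsv")
  writeNetwork(result$network, paths$networkSif, "sif")
  writeSRPTable(result$srp, paths$srp)
  jsonlite::write_json(
    c(cfg, list(nOTUs = nrow(result$srp), nTimepoints = ncol(result$srp),
                nTriplets = nrow(result$triplets),
                nEdges = nrow(edges(result$network)))),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(result, list(paths = paths, config = cfg)))
}
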