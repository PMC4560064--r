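#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

setClass("OTUTimeSeries", contains = "SummarizedExperiment")

#' OTU abundance time series containers
#'
#' Three `SummarizedExperiment`-derived classes carry an OTU table through
#' the preprocessing pipeline. `AbundanceTable` holds raw read counts,
#' `ProportionTable` holds per-time-point relative proportions, and
#' `SRPMatrix` holds standardized relative proportions (SRPs): per-OTU
#' min-max scaled values in \[0, 1\], the quantity the triplet model
#' consumes. Rows are OTUs (with optional genus-level taxonomy in
#' `rowData`), columns are time-ordered samples. `AbundanceTable` and
#' `ProportionTable` carry a logical `missing` assay marking absent
#' measurements; an `SRPMatrix` is always complete.
#'
#' @param counts numeric matrix of non-negative read counts (OTU x time);
#'   `NA` entries are treated as missing measurements.
#' @param props numeric matrix of relative proportions in \[0, 1\].
#' @param srp numeric matrix of standardized relative proportions; every
#'   row must attain both 0 and 1.
#' @param taxonomy optional character vector of per-OTU taxonomy labels.
#' @param missing optional logical matrix marking missing entries; defaults
#'   to `is.na()` of the value matrix.
#'
#' @return An object of the corresponding class.
#' @examples
#' counts <- matrix(c(2, 3, 5, 1, 0, 4), nrow = 2, byrow = TRUE,
#'                  dimnames = list(c("OTU1", "OTU2"), paste0("t", 1:3)))
#' ab <- AbundanceTable(counts)
#' pr <- relativeAbundance(ab)
#' colSums(props(pr))
#' @aliases AbundanceTable-class ProportionTable-class SRPMatrix-class
#' @exportClass AbundanceTable ProportionTable SRPMatrix
#' @name OTUTimeSeries-classes
NULL

.check_table_dims <- function(object, value_assay) {
  a <- assays(object)
  msg <- character()
  if (!all(c(value_assay, "missing") %in% assayNames(object)))
    msg <- c(msg, sprintf("assays '%s' and 'missing' are required", value_assay))
  else {
    v <- a[[value_assay]]
    m <- a[["missing"]]
    if (!is.logical(m))
      msg <- c(msg, "'missing' assay must be logical")
    if (!identical(dim(v), dim(m)))
      msg <- c(msg, "value and missing assays must have identical dimensions")
    if (anyNA(v[!m]))
      msg <- c(msg, "NA values present outside the missing mask")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "rownames (OTU ids) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "colnames (time labels) must be present and unique")
  msg
}

setClass("AbundanceTable", contains = "OTUTimeSeries", validity = function(object) {
  msg <- .check_table_dims(object, "counts")
  if (length(msg)) return(msg)
  v <- assay(object, "counts")
  m <- assay(object, "missing")
  if (any(v[!m] < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

setClass("ProportionTable", contains = "OTUTimeSeries", validity = function(object) {
  msg <- .check_table_dims(object, "props")
  if (length(msg)) return(msg)
  v <- assay(object, "props")
  m <- assay(object, "missing")
  obs <- v[!m]
  if (length(obs) && (min(obs) < -1e-12 || max(obs) > 1 + 1e-12))
    msg <- c(msg, "proportions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setClass("SRPMatrix", contains = "OTUTimeSeries", validity = function(object) {
  msg <- character()
  if (!("srp" %in% assayNames(object)))
    return("assay 'srp' is required")
  v <- assay(object, "srp")
  if (anyNA(v)) msg <- c(msg, "SRP matrix may not contain missing values")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "rownames (OTU ids) must be present and unique")
  if (!anyNA(v) && nrow(v) > 0 && ncol(v) > 1) {
    rmin <- apply(v, 1L, min)
    rmax <- apply(v, 1L, max)
    if (any(abs(rmin) > 1e-9) || any(abs(rmax - 1) > 1e-9))
      msg <- c(msg, "every SRP row must attain min 0 and max 1")
  }
  if (length(msg)) msg else TRUE
})

.make_table <- function(class, assay_name, values, taxonomy, missing) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("OTU", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("T", seq_len(ncol(values)))
  if (is.null(missing)) missing <- is.na(values)
  missing <- as.matrix(missing)
  mode(missing) <- "logical"
  dimnames(missing) <- dimnames(values)
  values[missing] <- NA_real_
  rd <- DataFrame(row.names = rownames(values))
  if (!is.null(taxonomy)) {
    stopifnot(length(taxonomy) == nrow(values))
    rd$taxonomy <- as.character(taxonomy)
  }
  assays <- stats::setNames(list(values, missing), c(assay_name, "missing"))
  se <- SummarizedExperiment(assays = assays, rowData = rd)
  new(class, se)
}

#' @rdname OTUTimeSeries-classes
#' @export
AbundanceTable <- function(counts, taxonomy = NULL, missing = NULL) {
  .make_table("AbundanceTable", "counts", counts, taxonomy, missing)
}

#' @rdname OTUTimeSeries-classes
#' @export
ProportionTable <- function(props, taxonomy = NULL, missing = NULL) {
  .make_table("ProportionTable", "props", props, taxonomy, missing)
}

#' @rdname OTUTimeSeries-classes
#' @export
SRPMatrix <- function(srp, taxonomy = NULL) {
  srp <- as.matrix(srp)
  if (is.null(rownames(srp)))
    rownames(srp) <- paste0("OTU", seq_len(nrow(srp)))
  if (is.null(colnames(srp)))
    colnames(srp) <- paste0("T", seq_len(ncol(srp)))
  rd <- DataFrame(row.names = rownames(srp))
  if (!is.null(taxonomy)) {
    stopifnot(length(taxonomy) == nrow(srp))
    rd$taxonomy <- as.character(taxonomy)
  }
  se <- SummarizedExperiment(assays = list(srp = srp), rowData = rd)
  new("SRPMatrix", se)
}

#' Signed directed regulatory network
#'
#' Holds the network assembled from retained OTU-triplets: nodes are OTU
#' ids and each edge is a directed, signed link from a regulator to a
#' target, with sign `"cooperative"` (regulator up, target up) or
#' `"competitive"` (regulator up, target down). The `edges` slot records,
#' per edge, how many retained triplets support it and the best (smallest)
#' integrated score among them; `provenance` lists the supporting triplet
#' labels. An ordered OTU pair may carry at most one sign.
#'
#' @param nodes character vector of OTU ids.
#' @param edges data.frame with columns `source`, `target`, `sign`,
#'   `nSupporting`, `bestI`.
#' @param provenance list (one element per edge) of supporting triplet
#'   identifiers.
#' @return A `RegulatoryNetwork` object.
#' @aliases RegulatoryNetwork-class
#' @seealso [buildNetwork()], [writeNetwork()]
#' @export RegulatoryNetwork
#' @exportClass RegulatoryNetwork
RegulatoryNetwork <- function(nodes = character(), edges = emptyEdgeFrame(),
                              provenance = rep(list(character()), nrow(edges))) {
  new("RegulatoryNetwork", nodes = as.character(nodes), edges = edges,
      provenance = provenance)
}

setClass("RegulatoryNetwork",
  representation(nodes = "character", edges = "data.frame",
                 provenance = "list"),
  validity = function(object) {
    e <- object@edges
    msg <- character()
    need <- c("source", "target", "sign", "nSupporting", "bestI")
    if (!all(need %in% names(e)))
      return(paste("edges must have columns", paste(need, collapse = ", ")))
    if (nrow(e)) {
      if (!all(e$sign %in% c("cooperative", "competitive")))
        msg <- c(msg, "edge sign must be 'cooperative' or 'competitive'")
      if (any(e$source == e$target))
        msg <- c(msg, "self-edges are not allowed")
      if (!all(e$source %in% object@nodes) || !all(e$target %in% object@nodes))
        msg <- c(msg, "edge endpoints must be listed in nodes")
      key <- paste(e$source, e$target)
      if (anyDuplicated(paste(key, e$sign)))
        msg <- c(msg, "duplicate edges are not allowed")
      if (anyDuplicated(key))
        msg <- c(msg, "an ordered OTU pair may not carry both signs")
    }
    if (length(object@provenance) != nrow(e))
      msg <- c(msg, "provenance must have one element per edge")
    if (length(msg)) msg else TRUE
  })

emptyEdgeFrame <- function() {
  data.frame(source = character(), target = character(), sign = character(),
             nSupporting = integer(), bestI = numeric(),
             stringsAsFactors = FALSE)
}

#' Simulated benchmark dataset
#'
#' Container for one synthetic microbial community: the 10 x T abundance
#' matrix generated by the benchmark model, the 3 x T latent-factor draws,
#' the additive noise matrix, the per-OTU integer signal-to-noise ratios,
#' the ground-truth signed network, and the simulation settings.
#'
#' @aliases SimulatedDataset-class
#' @seealso [simulateDataset()]
#' @exportClass SimulatedDataset
setClass("SimulatedDataset",
  representation(abundances = "matrix", latent = "matrix", noise = "matrix",
                 snr = "integer", truth = "RegulatoryNetwork",
                 config = "list"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@abundances) != 10L)
      msg <- c(msg, "abundances must have 10 OTU rows")
    if (ncol(object@latent) != ncol(object@abundances) ||
        !identical(dim(object@noise), dim(object@abundances)))
      msg <- c(msg, "latent/noise dimensions must match abundances")
    if (length(object@snr) != nrow(object@abundances))
      msg <- c(msg, "one SNR value per OTU is required")
    v <- object@abundances
    if (any(v < 0 | v > 1)) msg <- c(msg, "abundances must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })
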