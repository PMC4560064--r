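#' Accessors for OTU time-series containers and networks
#'
#' `otuIds()` and `timeLabels()` return the row and column identifiers;
#' `taxonomy()` the per-OTU taxonomy labels (or `NULL`); `missingMask()`
#' the logical matrix of absent measurements; `counts()`, `props()` and
#' `srp()` the value matrix of the respective class; `edges()` and
#' `nodes()` the edge table and node set of a [RegulatoryNetwork].
#'
#' @param object,x an `AbundanceTable`, `ProportionTable`, `SRPMatrix`,
#'   `RegulatoryNetwork` or `SimulatedDataset` as appropriate.
#' @return The component named by the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("otuIds", function(x) standardGeneric("otuIds"))
#' @rdname accessors
#' @export
setGeneric("timeLabels", function(x) standardGeneric("timeLabels"))
#' @rdname accessors
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))
#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))
#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("props", function(x) standardGeneric("props"))
#' @rdname accessors
#' @export
setGeneric("srp", function(x) standardGeneric("srp"))
#' @rdname accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))
#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))
#' @rdname accessors
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))

#' @rdname accessors
setMethod("otuIds", "OTUTimeSeries", function(x) rownames(x))
#' @rdname accessors
setMethod("timeLabels", "OTUTimeSeries", function(x) colnames(x))
#' @rdname accessors
setMethod("taxonomy", "OTUTimeSeries", function(x) rowData(x)$taxonomy)
#' @rdname accessors
setMethod("missingMask", "OTUTimeSeries", function(x) {
  if ("missing" %in% assayNames(x)) assay(x, "missing")
  else matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x))
})
#' @rdname accessors
setMethod("counts", "AbundanceTable", function(x) assay(x, "counts"))
#' @rdname accessors
setMethod("props", "ProportionTable", function(x) assay(x, "props"))
#' @rdname accessors
setMethod("srp", "SRPMatrix", function(x) assay(x, "srp"))

#' @rdname accessors
setMethod("nodes", "RegulatoryNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("edges", "RegulatoryNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname accessors
setMethod("abundances", "SimulatedDataset", function(x) x@abundances)
#' @rdname accessors
#' @export
setGeneric("latentFactors", function(x) standardGeneric("latentFactors"))
#' @rdname accessors
setMethod("latentFactors", "SimulatedDataset", function(x) x@latent)
#' @rdname accessors
#' @export
setGeneric("snr", function(x) standardGeneric("snr"))
#' @rdname accessors
setMethod("snr", "SimulatedDataset", function(x) x@snr)
#' @rdname accessors
setMethod("truth", "SimulatedDataset", function(x) x@truth)

setMethod("show", "RegulatoryNetwork", function(object) {
  e <- object@edges
  cat(sprintf("RegulatoryNetwork: %d nodes, %d edges (%d cooperative, %d competitive)\n",
              length(object@nodes), nrow(e),
              sum(e$sign == "cooperative"), sum(e$sign == "competitive")))
  if (nrow(e)) {
    arrow <- ifelse(e$sign == "cooperative", "->", "-|")
    shown <- head(seq_len(nrow(e)), 10L)
    for (i in shown)
      cat(sprintf("  %s %s %s  (support %d, best I %.4g)\n",
                  e$source[i], arrow[i], e$target[i], e$nSupporting[i],
                  e$bestI[i]))
    if (nrow(e) > 10L) cat(sprintf("  ... and %d more edges\n", nrow(e) - 10L))
  }
  invisible(NULL)
})

setMethod("show", "SimulatedDataset", function(object) {
  cfg <- object@config
  cat(sprintf(
    "SimulatedDataset: %d OTUs x %d time points, noise '%s', seed %s\n",
    nrow(object@abundances), ncol(object@abundances),
    cfg$noise, format(cfg$seed)))
  cat(sprintf("  ground truth: %d signed edges; SNR range [%d, %d]\n",
              nrow(object@truth@edges), min(object@snr), max(object@snr)))
  invisible(NULL)
})
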