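## Accessor generics and show methods.

#' @name accessors
#' @title Accessors for repoBench classes
#' @description Extract identifiers, counts and component tables from the
#'   package's S4 containers without touching slots directly.
#' @param x an object of one of the repoBench S4 classes.
#' @return `drugIds`, `indicationIds`, `proteinIds`: character vectors.
#'   `nDrugs`, `nIndications`, `nAssociations`: integer counts.
#'   `associations`, `perQuery`, `perIndication`, `aggregated`,
#'   `nullControl`: data.frames. `scores`, `distances`: numeric matrices
#'   (or, for a `NeighborRanking`, the ordered distance vector).
#'   `indicationSizes`: named integer vector of drugs per indication.
#'   `indicationDrugs`: character vector of one indication's drugs.
#'   `aia`: data.frame of average indication accuracy per cutoff.
NULL

#' @rdname accessors
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))
#' @rdname accessors
#' @export
setGeneric("indicationIds", function(x) standardGeneric("indicationIds"))
#' @rdname accessors
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))
#' @rdname accessors
#' @export
setGeneric("nDrugs", function(x) standardGeneric("nDrugs"))
#' @rdname accessors
#' @export
setGeneric("nIndications", function(x) standardGeneric("nIndications"))
#' @rdname accessors
#' @export
setGeneric("nAssociations", function(x) standardGeneric("nAssociations"))
#' @rdname accessors
#' @export
setGeneric("associations", function(x) standardGeneric("associations"))
#' @rdname accessors
#' @export
setGeneric("indicationSizes", function(x) standardGeneric("indicationSizes"))
#' @rdname accessors
#' @param indication a single indication id.
#' @export
setGeneric("indicationDrugs",
           function(x, indication) standardGeneric("indicationDrugs"))
#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))
#' @rdname accessors
#' @export
setGeneric("rankedDrugs", function(x) standardGeneric("rankedDrugs"))
#' @rdname accessors
#' @export
setGeneric("queryDrug", function(x) standardGeneric("queryDrug"))
#' @rdname accessors
#' @export
setGeneric("perQuery", function(x) standardGeneric("perQuery"))
#' @rdname accessors
#' @export
setGeneric("perIndication", function(x) standardGeneric("perIndication"))
#' @rdname accessors
#' @export
setGeneric("aia", function(x) standardGeneric("aia"))
#' @rdname accessors
#' @export
setGeneric("aggregated", function(x) standardGeneric("aggregated"))
#' @rdname accessors
#' @export
setGeneric("nullControl", function(x) standardGeneric("nullControl"))

#' @rdname accessors
setMethod("drugIds", "AssociationStandard", function(x) x@drugs)
#' @rdname accessors
setMethod("indicationIds", "AssociationStandard", function(x) x@indications)
#' @rdname accessors
setMethod("nDrugs", "AssociationStandard", function(x) length(x@drugs))
#' @rdname accessors
setMethod("nIndications", "AssociationStandard",
          function(x) length(x@indications))
#' @rdname accessors
setMethod("nAssociations", "AssociationStandard",
          function(x) nrow(x@associations))
#' @rdname accessors
setMethod("associations", "AssociationStandard", function(x) x@associations)
#' @rdname accessors
setMethod("indicationSizes", "AssociationStandard", function(x) {
  tab <- table(factor(x@associations$indication_id, levels = x@indications))
  stats::setNames(as.integer(tab), x@indications)
})
#' @rdname accessors
setMethod("indicationDrugs", "AssociationStandard",
          function(x, indication) {
  if (!indication %in% x@indications)
    stop("unknown indication: ", indication)
  x@associations$drug_id[x@associations$indication_id == indication]
})

#' @rdname accessors
setMethod("drugIds", "SignatureMatrix", function(x) rownames(x@scores))
#' @rdname accessors
setMethod("proteinIds", "SignatureMatrix", function(x) colnames(x@scores))
#' @rdname accessors
setMethod("nDrugs", "SignatureMatrix", function(x) nrow(x@scores))
#' @rdname accessors
setMethod("scores", "SignatureMatrix", function(x) x@scores)

#' @rdname accessors
setMethod("drugIds", "SimilarityMatrix", function(x) rownames(x@dist))
#' @rdname accessors
setMethod("nDrugs", "SimilarityMatrix", function(x) nrow(x@dist))
#' @rdname accessors
setMethod("distances", "SimilarityMatrix", function(x) x@dist)

#' @rdname accessors
setMethod("queryDrug", "NeighborRanking", function(x) x@query)
#' @rdname accessors
setMethod("rankedDrugs", "NeighborRanking", function(x) x@rankedDrugs)
#' @rdname accessors
setMethod("distances", "NeighborRanking", function(x) x@distances)

#' @rdname accessors
setMethod("perQuery", "LooResult", function(x) x@perQuery)
#' @rdname accessors
setMethod("perIndication", "LooResult", function(x) x@perIndicationAccuracy)
#' @rdname accessors
setMethod("aia", "LooResult", function(x) x@aia)

#' @rdname accessors
setMethod("perIndication", "MetricReport", function(x) x@perIndication)
#' @rdname accessors
setMethod("aggregated", "MetricReport", function(x) x@aggregate)
#' @rdname accessors
setMethod("nullControl", "MetricReport", function(x) x@nullControl)

setMethod("show", "AssociationStandard", function(object) {
  cat("AssociationStandard:", length(object@drugs), "drugs,",
      length(object@indications), "indications,",
      nrow(object@associations), "associations\n")
  sz <- indicationSizes(object)
  cat("  indication sizes: min", min(sz), "/ median", stats::median(sz),
      "/ max", max(sz), "\n")
})

setMethod("show", "SignatureMatrix", function(object) {
  cat("SignatureMatrix:", nrow(object@scores), "drugs x",
      ncol(object@scores), "proteins\n")
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat("SimilarityMatrix (", object@measure, "): ", nrow(object@dist),
      " x ", ncol(object@dist), " drugs\n", sep = "")
})

setMethod("show", "NeighborRanking", function(object) {
  cat("NeighborRanking for query '", object@query, "': ",
      length(object@rankedDrugs), " neighbors\n", sep = "")
  n <- min(5L, length(object@rankedDrugs))
  if (n) {
    cat("  top:", paste(sprintf("%s (%.4g)", object@rankedDrugs[seq_len(n)],
                                object@distances[seq_len(n)]),
                        collapse = ", "), "\n")
  }
})

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts: TP =", object@tp, "FP =", object@fp,
      "TN =", object@tn, "FN =", object@fn, "\n")
})

setMethod("show", "BenchmarkConfig", function(object) {
  cat("BenchmarkConfig: cutoffs {",
      paste(object@cutoffs, collapse = ", "),
      "}, minIndicationSize ", object@minIndicationSize,
      ", measure ", object@measure, ", alpha ", object@alpha, "\n", sep = "")
})

setMethod("show", "LooResult", function(object) {
  cat("LooResult:", nrow(object@perQuery), "drug-indication pairs,",
      length(unique(object@perIndicationAccuracy$indication_id)),
      "eligible indications\n")
  if (nrow(object@aia)) {
    cat("  AIA:", paste(sprintf("top%d = %.1f%%", object@aia$cutoff,
                                object@aia$aia), collapse = ", "), "\n")
  }
})

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport:", length(unique(object@perIndication$indication_id)),
      "indications,", length(unique(object@aggregate$metric)),
      "metrics\n")
  if (nrow(object@nullControl))
    cat("  includes a null-control block\n")
})

setMethod("show", "NullSpec", function(object) {
  cat("NullSpec:", object@method, "x", object@replicates,
      "replicates (seed", object@seed, ")\n")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", object@nDrugs, "drugs,", object@nIndications,
      "indications,", object@nAssociations, "associations,",
      object@nProteins, "proteins\n")
  cat("  sizeSkew", object@sizeSkew, "| signalStrength",
      object@signalStrength, "| noiseSd", object@noiseSd,
      "| seed", object@seed, "\n")
})
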