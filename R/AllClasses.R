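#' @import methods
NULL

## Central S4 containers. All identifiers are opaque, case-sensitive strings;
## indication IDs typically follow the MeSH "D######" pattern but are not
## validated against any vocabulary. Ranks are 1-based everywhere.

#' AssociationStandard: a drug-indication gold standard
#'
#' Holds a curated set of (drug, indication) associations -- the "gold
#' standard" against which similarity rankings are scored -- together with
#' the full drug and indication universes. Drugs with zero associations are
#' permitted (they act as inactives everywhere); every listed indication must
#' have at least one associated drug.
#'
#' @slot associations data.frame with character columns \code{drug_id} and
#'   \code{indication_id}; one row per unique association.
#' @slot drugs character vector of all drug identifiers (ordered, unique).
#' @slot indications character vector of all indication identifiers.
#'
#' @seealso [readAssociationStandard()], [generateStandard()]
#' @export
setClass("AssociationStandard",
  representation(
    associations = "data.frame",
    drugs        = "character",
    indications  = "character"
  )
)

setValidity("AssociationStandard", function(object) {
  a <- object@associations
  msg <- character()
  if (!all(c("drug_id", "indication_id") %in% names(a)))
    return("associations must have columns drug_id and indication_id")
  if (anyDuplicated(object@drugs))
    msg <- c(msg, "duplicate drug ids")
  if (anyDuplicated(object@indications))
    msg <- c(msg, "duplicate indication ids")
  if (nrow(a)) {
    if (anyDuplicated(paste(a$drug_id, a$indication_id, sep = "\r")))
      msg <- c(msg, "duplicate (drug, indication) pairs")
    if (!all(a$drug_id %in% object@drugs))
      msg <- c(msg, "association drug_id not in drug universe")
    if (!all(a$indication_id %in% object@indications))
      msg <- c(msg, "association indication_id not in indication universe")
  }
  if (!all(object@indications %in% a$indication_id))
    msg <- c(msg, "every indication must have at least one associated drug")
  if (length(msg)) msg else TRUE
})

#' Construct an AssociationStandard from association pairs
#'
#' @param drug_id,indication_id parallel character vectors of associations.
#' @param drugs optional full drug universe; defaults to the sorted unique
#'   drugs appearing in the associations. May include drugs with no
#'   association.
#' @param indications optional indication universe; defaults to the sorted
#'   unique indications in the associations. Every indication must appear in
#'   at least one association.
#' @return An [AssociationStandard-class] object. Duplicate pairs are dropped
#'   with a message reporting how many were removed.
#' @examples
#' std <- AssociationStandard(c("d1", "d2", "d1"), c("D000001", "D000001", "D000002"))
#' nAssociations(std)
#' @export
AssociationStandard <- function(drug_id, indication_id,
                                drugs = NULL, indications = NULL) {
  stopifnot(length(drug_id) == length(indication_id))
  drug_id <- as.character(drug_id)
  indication_id <- as.character(indication_id)
  key <- paste(drug_id, indication_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate association(s) dropped")
    drug_id <- drug_id[!dup]
    indication_id <- indication_id[!dup]
  }
  if (is.null(drugs)) drugs <- sort(unique(drug_id))
  if (is.null(indications)) indications <- sort(unique(indication_id))
  new("AssociationStandard",
      associations = data.frame(drug_id = drug_id,
                                indication_id = indication_id,
                                stringsAsFactors = FALSE),
      drugs = as.character(drugs),
      indications = as.character(indications))
}

#' SignatureMatrix: drugs x proteins interaction scores
#'
#' Each drug is characterized by a vector of real-valued interaction scores
#' against a protein library; similarity between these signatures proxies
#' similarity of therapeutic behaviour. Scores are dimensionless and used
#' raw (no normalization before distance computation).
#'
#' @slot scores numeric matrix, rows = drugs, columns = proteins, with
#'   unique dimnames and finite entries.
#' @seealso [readSignatureMatrix()], [pairwiseDistances()]
#' @export
setClass("SignatureMatrix", representation(scores = "matrix"))

setValidity("SignatureMatrix", function(object) {
  s <- object@scores
  msg <- character()
  if (!is.numeric(s)) msg <- c(msg, "scores must be numeric")
  if (is.null(rownames(s)) || is.null(colnames(s)))
    msg <- c(msg, "scores must have drug rownames and protein colnames")
  else {
    if (anyDuplicated(rownames(s))) msg <- c(msg, "duplicate drug ids")
    if (anyDuplicated(colnames(s))) msg <- c(msg, "duplicate protein ids")
  }
  if (is.numeric(s) && !all(is.finite(s)))
    msg <- c(msg, "all scores must be finite (no NA/NaN/Inf)")
  if (length(msg)) msg else TRUE
})

#' Construct a SignatureMatrix
#'
#' @param scores numeric matrix of interaction scores with drug rownames and
#'   protein colnames (supplied via `drug_ids`/`protein_ids` if absent).
#' @param drug_ids,protein_ids optional dimnames when `scores` has none.
#' @return A [SignatureMatrix-class].
#' @export
SignatureMatrix <- function(scores, drug_ids = rownames(scores),
                            protein_ids = colnames(scores)) {
  scores <- as.matrix(scores)
  rownames(scores) <- as.character(drug_ids)
  colnames(scores) <- as.character(protein_ids)
  new("SignatureMatrix", scores = scores)
}

#' SimilarityMatrix: pairwise drug-drug signature distances
#'
#' Square symmetric matrix of pairwise distances between drug interaction
#' signatures; smaller distance means more similar. The diagonal is zero.
#'
#' @slot dist numeric square matrix with identical row/column drug names.
#' @slot measure character, the distance measure used ("rmsd" or "cosine",
#'   or "shuffled"/"custom" for derived matrices).
#' @seealso [pairwiseDistances()], [rankNeighbors()]
#' @export
setClass("SimilarityMatrix",
  representation(dist = "matrix", measure = "character"))

setValidity("SimilarityMatrix", function(object) {
  d <- object@dist
  msg <- character()
  if (nrow(d) != ncol(d)) msg <- c(msg, "dist must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    msg <- c(msg, "dist must have identical row/column drug names")
  if (!all(is.finite(d))) msg <- c(msg, "distances must be finite")
  else {
    if (any(d < 0)) msg <- c(msg, "distances must be non-negative")
    if (max(abs(diag(d))) > 1e-8) msg <- c(msg, "diagonal must be zero")
    if (max(abs(d - t(d))) > 1e-8) msg <- c(msg, "dist must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SimilarityMatrix-class
#' @param dist square symmetric non-negative matrix with drug dimnames.
#' @param measure label for the measure that produced the distances.
#' @export
SimilarityMatrix <- function(dist, measure = "custom") {
  dist <- as.matrix(dist)
  new("SimilarityMatrix", dist = dist, measure = measure)
}

#' NeighborRanking: all drugs ranked by similarity to one query
#'
#' The ordered list of every non-query drug, most similar (smallest
#' distance) first. Ties are broken lexicographically by drug id so the
#' ranking is deterministic.
#'
#' @slot query character, the query drug id.
#' @slot rankedDrugs character vector of the other drugs, best rank first.
#' @slot distances numeric, non-decreasing, parallel to `rankedDrugs`.
#' @export
setClass("NeighborRanking",
  representation(query = "character", rankedDrugs = "character",
                 distances = "numeric"))

setValidity("NeighborRanking", function(object) {
  msg <- character()
  if (length(object@query) != 1L) msg <- c(msg, "query must be a single id")
  if (length(object@rankedDrugs) != length(object@distances))
    msg <- c(msg, "rankedDrugs and distances must be parallel")
  if (object@query %in% object@rankedDrugs)
    msg <- c(msg, "query must not appear among rankedDrugs")
  if (anyDuplicated(object@rankedDrugs))
    msg <- c(msg, "rankedDrugs must be unique")
  if (is.unsorted(object@distances))
    msg <- c(msg, "distances must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' BenchmarkConfig: leave-one-out benchmark settings
#'
#' @slot cutoffs strictly increasing positive integer rank cutoffs at which
#'   hits are counted (default 10, 25, 50, 100).
#' @slot minIndicationSize smallest indication (number of associated drugs)
#'   eligible for the leave-one-out benchmark; below 2 a held-out drug has
#'   no possible active, so the default is 2.
#' @slot measure distance measure, "rmsd" or "cosine".
#' @slot alpha early-recognition weight for RIE/BEDROC (default 20).
#' @export
setClass("BenchmarkConfig",
  representation(cutoffs = "integer", minIndicationSize = "integer",
                 measure = "character", alpha = "numeric"))

setValidity("BenchmarkConfig", function(object) {
  msg <- character()
  k <- object@cutoffs
  if (!length(k) || any(k < 1L)) msg <- c(msg, "cutoffs must be positive")
  if (length(k) > 1L && any(diff(k) <= 0L))
    msg <- c(msg, "cutoffs must be strictly increasing")
  if (object@minIndicationSize < 2L)
    msg <- c(msg, "minIndicationSize must be >= 2")
  if (!object@measure %in% c("rmsd", "cosine"))
    msg <- c(msg, "measure must be 'rmsd' or 'cosine'")
  if (object@alpha <= 0) msg <- c(msg, "alpha must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname BenchmarkConfig-class
#' @param cutoffs,minIndicationSize,measure,alpha see slot descriptions.
#' @export
BenchmarkConfig <- function(cutoffs = c(10L, 25L, 50L, 100L),
                            minIndicationSize = 2L,
                            measure = c("rmsd", "cosine"),
                            alpha = 20) {
  new("BenchmarkConfig", cutoffs = as.integer(cutoffs),
      minIndicationSize = as.integer(minIndicationSize),
      measure = match.arg(measure), alpha = alpha)
}

#' LooResult: output of the leave-one-out benchmark
#'
#' @slot perQuery data.frame with columns drug_id, indication_id,
#'   best_active_rank (integer; NA when no active exists in the list).
#' @slot perIndicationAccuracy data.frame with columns indication_id,
#'   cutoff, accuracy (percentage in [0, 100]).
#' @slot aia data.frame with columns cutoff, aia: the average indication
#'   accuracy, i.e. the unweighted mean over indications.
#' @slot config the [BenchmarkConfig-class] used.
#' @export
setClass("LooResult",
  representation(perQuery = "data.frame",
                 perIndicationAccuracy = "data.frame",
                 aia = "data.frame",
                 config = "BenchmarkConfig"))

#' ConfusionCounts: a 2x2 confusion table at a rank cutoff
#'
#' @slot tp,fp,tn,fn non-negative integer counts of true positives, false
#'   positives, true negatives and false negatives.
#' @seealso [confusionAtCutoff()]
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", fp = "integer",
                 tn = "integer", fn = "integer"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@tn, object@fn)
  if (length(v) != 4L || any(is.na(v)) || any(v < 0L))
    "tp, fp, tn, fn must be single non-negative integers"
  else TRUE
})

#' @rdname ConfusionCounts-class
#' @param tp,fp,tn,fn non-negative integer counts.
#' @export
ConfusionCounts <- function(tp, fp, tn, fn) {
  new("ConfusionCounts", tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn))
}

#' MetricReport: per-indication and aggregate metric values
#'
#' Tidy long-format report. `perIndication` holds one row per
#' (indication, metric, cutoff); `aggregate` summarises either over
#' indications (level "indication": the unweighted mean over per-indication
#' values, the AIA convention) or over drug-indication pairs (level
#' "pair"), with mean, median and interquartile range. `nullControl`, when
#' present, has the same shape as `aggregate` and comes from a random
#' control run.
#'
#' @slot perIndication data.frame: indication_id, metric, cutoff, value.
#' @slot aggregate data.frame: metric, cutoff, level, mean, median, q25, q75.
#' @slot nullControl data.frame, same columns as aggregate (0 rows if none).
#' @export
setClass("MetricReport",
  representation(perIndication = "data.frame",
                 aggregate = "data.frame",
                 nullControl = "data.frame"))

setValidity("MetricReport", function(object) {
  pi <- object@perIndication
  ag <- object@aggregate
  need_pi <- c("indication_id", "metric", "cutoff", "value")
  need_ag <- c("metric", "cutoff", "level", "mean", "median", "q25", "q75")
  if (!all(need_pi %in% names(pi)))
    return("perIndication must have columns indication_id, metric, cutoff, value")
  if (!all(need_ag %in% names(ag)))
    return("aggregate must have columns metric, cutoff, level, mean, median, q25, q75")
  ## indication-level aggregate means must equal the arithmetic mean of the
  ## matching per-indication values
  ind <- ag[ag$level == "indication", , drop = FALSE]
  if (nrow(ind) && nrow(pi)) {
    for (r in seq_len(nrow(ind))) {
      sel <- pi$metric == ind$metric[r] &
        (is.na(ind$cutoff[r]) & is.na(pi$cutoff) |
           !is.na(ind$cutoff[r]) & !is.na(pi$cutoff) &
           pi$cutoff == ind$cutoff[r])
      v <- pi$value[sel]
      if (length(v) &&
          abs(mean(v, na.rm = TRUE) - ind$mean[r]) > 1e-8 * max(1, abs(ind$mean[r])))
        return(sprintf("aggregate mean for %s (cutoff %s) != mean of per-indication values",
                       ind$metric[r], ind$cutoff[r]))
    }
  }
  TRUE
})

emptyMetricFrame <- function() {
  data.frame(metric = character(), cutoff = integer(), level = character(),
             mean = numeric(), median = numeric(), q25 = numeric(),
             q75 = numeric(), stringsAsFactors = FALSE)
}

#' @rdname MetricReport-class
#' @param perIndication,aggregate,nullControl see slot descriptions.
#' @export
MetricReport <- function(perIndication =
                           data.frame(indication_id = character(),
                                      metric = character(),
                                      cutoff = integer(), value = numeric(),
                                      stringsAsFactors = FALSE),
                         aggregate = emptyMetricFrame(),
                         nullControl = emptyMetricFrame()) {
  new("MetricReport", perIndication = perIndication, aggregate = aggregate,
      nullControl = nullControl)
}

#' NullSpec: specification of an empirical random control
#'
#' @slot method "shuffle_similarities" (permute the observed pairwise
#'   distances, destroying structure but keeping the value distribution) or
#'   "uniform_rankings" (fully random neighbor orderings).
#' @slot replicates number of random replicates.
#' @slot seed root RNG seed; replicate r uses seed + r so each replicate is
#'   reproducible in isolation.
#' @export
setClass("NullSpec",
  representation(method = "character", replicates = "integer",
                 seed = "integer"))

setValidity("NullSpec", function(object) {
  msg <- character()
  if (!object@method %in% c("shuffle_similarities", "uniform_rankings"))
    msg <- c(msg, "method must be 'shuffle_similarities' or 'uniform_rankings'")
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname NullSpec-class
#' @param method,replicates,seed see slot descriptions.
#' @export
NullSpec <- function(method = c("shuffle_similarities", "uniform_rankings"),
                     replicates = 100L, seed = 1L) {
  new("NullSpec", method = match.arg(method),
      replicates = as.integer(replicates), seed = as.integer(seed))
}

#' SyntheticSpec: parameters of the synthetic benchmark generator
#'
#' Defaults emulate a platform-scale drug-indication standard: 2162 drugs,
#' 2178 indications and 18709 associations, with heavy-tailed indication
#' sizes (hundreds of drugs for common indications, single digits for rare
#' ones) governed by a power-law exponent.
#'
#' @slot nDrugs,nProteins,nIndications,nAssociations positive integers.
#' @slot sizeSkew power-law exponent for indication sizes (larger = more
#'   skewed toward small indications).
#' @slot signalStrength weight of the shared indication protein profile in a
#'   drug's signature; 0 means signatures are pure noise, independent of the
#'   standard.
#' @slot noiseSd standard deviation of the independent per-drug noise.
#' @slot seed RNG seed for reproducible generation.
#' @export
setClass("SyntheticSpec",
  representation(nDrugs = "integer", nProteins = "integer",
                 nIndications = "integer", nAssociations = "integer",
                 sizeSkew = "numeric", signalStrength = "numeric",
                 noiseSd = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (any(c(object@nDrugs, object@nProteins, object@nIndications,
            object@nAssociations) < 1L))
    msg <- c(msg, "all counts must be positive")
  if (object@nAssociations < object@nIndications)
    msg <- c(msg, "nAssociations must be >= nIndications (every indication needs a drug)")
  if (as.double(object@nAssociations) >
      as.double(object@nDrugs) * as.double(object@nIndications))
    msg <- c(msg, "nAssociations exceeds nDrugs * nIndications")
  if (object@sizeSkew <= 0) msg <- c(msg, "sizeSkew must be positive")
  if (object@signalStrength < 0) msg <- c(msg, "signalStrength must be >= 0")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname SyntheticSpec-class
#' @param nDrugs,nProteins,nIndications,nAssociations,sizeSkew,signalStrength,noiseSd,seed
#'   see slot descriptions.
#' @export
SyntheticSpec <- function(nDrugs = 2162L, nProteins = 512L,
                          nIndications = 2178L, nAssociations = 18709L,
                          sizeSkew = 1.5, signalStrength = 1,
                          noiseSd = 1, seed = 1L) {
  new("SyntheticSpec", nDrugs = as.integer(nDrugs),
      nProteins = as.integer(nProteins),
      nIndications = as.integer(nIndications),
      nAssociations = as.integer(nAssociations),
      sizeSkew = sizeSkew, signalStrength = signalStrength,
      noiseSd = noiseSd, seed = as.integer(seed))
}
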