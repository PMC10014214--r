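## Leave-one-out benchmarking.
##
## For every (drug, indication) association in the standard, the drug is
## held out, every other drug is ranked by signature similarity to it, and
## the rank of the best-ranked drug sharing the indication is recorded.
## Per-indication accuracy at a cutoff k is the percentage of the
## indication's drugs whose best same-indication neighbor sits at rank <= k;
## the unweighted mean over indications is the average indication accuracy
## (AIA).

#' Rank of the first active in a neighbor ranking
#'
#' @param ranking a [NeighborRanking-class].
#' @param actives character vector of active drug ids (must not contain the
#'   query drug; may be empty).
#' @return The smallest 1-based rank occupied by an active, or `NA` when no
#'   active appears in the list ("none").
#' @examples
#' sim <- SimilarityMatrix(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
#'   dimnames = list(c("a", "b", "q"), c("a", "b", "q"))))
#' bestActiveRank(rankNeighbors(sim, "q"), actives = "b")
#' @export
bestActiveRank <- function(ranking, actives) {
  stopifnot(is(ranking, "NeighborRanking"))
  actives <- as.character(actives)
  if (queryDrug(ranking) %in% actives)
    stop("actives must not contain the query drug '", queryDrug(ranking), "'")
  hit <- which(rankedDrugs(ranking) %in% actives)
  if (!length(hit)) NA_integer_ else min(hit)
}

#' Per-indication accuracy at a rank cutoff
#'
#' The percentage of an indication's held-out drugs whose best
#' same-indication neighbor achieves rank at most `cutoff`. For the
#' canonical worked example -- an indication with 58 associated drugs, 23
#' of which see another of its drugs within their top 10 -- the top-10
#' accuracy is 23/58 x 100 = 39.6%.
#'
#' @param loo_ranks integer vector of best-active ranks, one per held-out
#'   drug; `NA` means no active was found ("none") and counts as a miss.
#' @param cutoff positive integer rank cutoff.
#' @return A percentage in [0, 100].
#' @export
indicationAccuracy <- function(loo_ranks, cutoff) {
  if (!length(loo_ranks)) stop("loo_ranks must be non-empty")
  if (length(cutoff) != 1L || is.na(cutoff) || cutoff < 1)
    stop("cutoff must be a positive integer")
  100 * mean(!is.na(loo_ranks) & loo_ranks <= cutoff)
}

## rank position of every drug in every query's neighbor list:
## pos[q, d] = rank of drug d when querying q (NA on the diagonal).
## Ties broken lexicographically by drug id (C collation).
looPositions <- function(sim) {
  d <- distances(sim)
  ids <- drugIds(sim)
  n <- length(ids)
  if (n < 2L) stop("need at least 2 drugs")
  pos <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    di <- d[i, -i]
    oth <- ids[-i]
    ord <- order(di, oth, method = "radix")
    p <- integer(n - 1L)
    p[ord] <- seq_len(n - 1L)
    pos[i, -i] <- p
  }
  pos
}

#' Run the leave-one-out benchmark
#'
#' Executes the hold-one-out protocol over every (drug, indication)
#' association whose indication has at least `minIndicationSize` drugs
#' (below that a held-out drug has no possible active, so such indications
#' are excluded rather than contributing a structural zero).
#'
#' @param standard an [AssociationStandard-class]; every associated drug
#'   must be present in `sim`.
#' @param sim a [SimilarityMatrix-class] over at least the standard's
#'   drugs; extra drugs act as decoys in the rankings.
#' @param config a [BenchmarkConfig-class]. Each cutoff must be at most
#'   (number of drugs in `sim`) - 1.
#' @return A [LooResult-class] with per-query best-active ranks,
#'   per-indication accuracies and the AIA at each cutoff.
#' @examples
#' spec <- SyntheticSpec(nDrugs = 60, nProteins = 20, nIndications = 6,
#'   nAssociations = 40, signalStrength = 3, noiseSd = 0.5, seed = 7)
#' std <- generateStandard(spec)
#' sig <- generateSignatures(std, spec)
#' sim <- pairwiseDistances(sig)
#' runLooBenchmark(std, sim, BenchmarkConfig(cutoffs = c(5, 10)))
#' @export
runLooBenchmark <- function(standard, sim, config = BenchmarkConfig()) {
  stopifnot(is(standard, "AssociationStandard"),
            is(sim, "SimilarityMatrix"),
            is(config, "BenchmarkConfig"))
  a <- associations(standard)
  missing <- setdiff(unique(a$drug_id), drugIds(sim))
  if (length(missing))
    stop("drug(s) in standard missing from similarity matrix: ",
         paste(missing, collapse = ", "))
  nCand <- nDrugs(sim) - 1L
  if (any(config@cutoffs > nCand))
    stop("cutoff(s) exceed number of candidate drugs (", nCand, "): ",
         paste(config@cutoffs[config@cutoffs > nCand], collapse = ", "))
  sz <- indicationSizes(standard)
  eligible <- names(sz)[sz >= config@minIndicationSize]
  if (!length(eligible))
    stop("no indication has >= ", config@minIndicationSize,
         " associated drugs")
  pos <- looPositions(sim)

  keep <- a$indication_id %in% eligible
  aq <- a[keep, , drop = FALSE]
  byInd <- split(aq$drug_id, aq$indication_id)
  ranks <- integer(nrow(aq))
  o <- 0L
  drug_col <- character(nrow(aq))
  ind_col <- character(nrow(aq))
  for (ind in names(byInd)) {
    ds <- byInd[[ind]]
    sub <- pos[ds, ds, drop = FALSE]
    ## row minimum over same-indication co-drugs (diagonal is NA = self)
    best <- suppressWarnings(apply(sub, 1L, min, na.rm = TRUE))
    best[!is.finite(best)] <- NA_integer_
    idx <- o + seq_along(ds)
    ranks[idx] <- as.integer(best)
    drug_col[idx] <- ds
    ind_col[idx] <- ind
    o <- o + length(ds)
  }
  perQuery <- data.frame(drug_id = drug_col, indication_id = ind_col,
                         best_active_rank = ranks, stringsAsFactors = FALSE)

  cutoffs <- config@cutoffs
  accRows <- do.call(rbind, lapply(stringSortC(names(byInd)), function(ind) {
    r <- perQuery$best_active_rank[perQuery$indication_id == ind]
    data.frame(indication_id = ind, cutoff = cutoffs,
               accuracy = vapply(cutoffs,
                                 function(k) indicationAccuracy(r, k),
                                 numeric(1)),
               stringsAsFactors = FALSE)
  }))
  aiaRows <- data.frame(
    cutoff = cutoffs,
    aia = vapply(cutoffs, function(k)
      mean(accRows$accuracy[accRows$cutoff == k]), numeric(1)))
  new("LooResult", perQuery = perQuery,
      perIndicationAccuracy = accRows, aia = aiaRows, config = config)
}

## C-locale sort, independent of session locale
stringSortC <- function(x) sort(x, method = "radix")
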