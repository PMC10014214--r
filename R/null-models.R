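## Random controls.
##
## Theoretical: under a uniformly random ordering of N candidates of which
## n are actives, the probability that at least one active lands in the top
## k is hypergeometric: 1 - C(N - n, k) / C(N, k). Averaging over
## indications gives the expected AIA of a structureless benchmark.
## Empirical: shuffle the observed pairwise distances (keeping their value
## distribution) or draw fully uniform rankings, and rerun the benchmark.

## evaluate RNG-consuming code under a seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Probability that a random top-k contains at least one active
#'
#' Closed-form hypergeometric tail: with `n_actives` actives among
#' `N_candidates` uniformly shuffled items,
#' \deqn{P(\ge 1\ \mathrm{hit\ in\ top\ }k) =
#'   1 - \binom{N - n}{k} \big/ \binom{N}{k}.}
#' Computed in log space ([lchoose()]) so it is exact to double precision
#' at any feasible size.
#'
#' @param N_candidates number of ranked candidates (positive integer).
#' @param n_actives number of actives among them (0 <= n <= N).
#' @param k rank cutoff, 1 <= k <= N_candidates.
#' @return A probability in [0, 1].
#' @examples
#' hypergeomHitProbability(4, 1, 2)  # 0.5
#' @export
hypergeomHitProbability <- function(N_candidates, n_actives, k) {
  if (k < 1 || k > N_candidates)
    stop("k must be in 1..", N_candidates)
  if (n_actives < 0 || n_actives > N_candidates)
    stop("n_actives must be in 0..", N_candidates)
  if (n_actives == 0) return(0)
  if (k > N_candidates - n_actives) return(1)
  1 - exp(lchoose(N_candidates - n_actives, k) - lchoose(N_candidates, k))
}

#' Expected AIA of a structureless (random) benchmark
#'
#' For each indication with at least `minIndicationSize` drugs, a held-out
#' drug faces `nDrugs - 1` candidates of which `size - 1` are actives; the
#' chance of a top-`cutoff` hit is [hypergeomHitProbability()]. The
#' expected average indication accuracy is the unweighted mean of these
#' probabilities times 100.
#'
#' @param standard an [AssociationStandard-class].
#' @param cutoff rank cutoff.
#' @param nDrugs total number of drugs in the ranked universe (defaults to
#'   the standard's drug count; pass the similarity-matrix drug count if
#'   decoy drugs outside the standard are ranked too).
#' @param minIndicationSize smallest eligible indication (default 2, as in
#'   the benchmark).
#' @return The expected AIA as a percentage.
#' @export
expectedRandomAia <- function(standard, cutoff,
                              nDrugs = repoBench::nDrugs(standard),
                              minIndicationSize = 2L) {
  stopifnot(is(standard, "AssociationStandard"))
  sz <- indicationSizes(standard)
  sz <- sz[sz >= minIndicationSize]
  if (!length(sz))
    stop("no indication has >= ", minIndicationSize, " associated drugs")
  100 * mean(vapply(sz, function(s)
    hypergeomHitProbability(nDrugs - 1L, s - 1L, cutoff), numeric(1)))
}

#' Shuffle a similarity matrix
#'
#' Permutes the condensed upper triangle of the pairwise distance matrix
#' and mirrors it back, preserving the distribution of distance values
#' while destroying all drug-drug structure. This is the empirical
#' stand-in for "similarity expected by chance".
#'
#' @param sim a [SimilarityMatrix-class].
#' @param seed RNG seed.
#' @return A [SimilarityMatrix-class] with measure `"shuffled"`.
#' @export
shuffleSimilarities <- function(sim, seed) {
  stopifnot(is(sim, "SimilarityMatrix"))
  d <- distances(sim)
  up <- upper.tri(d)
  v <- d[up]
  v <- withSeed(seed, sample(v))
  out <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  out[up] <- v
  out <- out + t(out)
  SimilarityMatrix(out, measure = "shuffled")
}

## a SimilarityMatrix of iid Uniform(0,1) distances => uniformly random,
## tie-free neighbor orderings for every query
uniformRandomSimilarity <- function(ids, seed) {
  n <- length(ids)
  v <- withSeed(seed, stats::runif(n * (n - 1L) / 2L))
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  out[upper.tri(out)] <- v
  out <- out + t(out)
  SimilarityMatrix(out, measure = "uniform")
}

#' Run an empirical random control
#'
#' Repeats the full leave-one-out benchmark and metric suite on randomized
#' similarity data: either the observed distances with their pairing
#' shuffled away (`"shuffle_similarities"`) or fresh uniform random
#' distances (`"uniform_rankings"`). Replicate r uses seed `spec@seed + r`,
#' so any replicate is reproducible in isolation; the whole run is
#' bit-reproducible given the same spec.
#'
#' @param standard an [AssociationStandard-class].
#' @param config a [BenchmarkConfig-class].
#' @param spec a [NullSpec-class].
#' @param sim the observed [SimilarityMatrix-class]; required for
#'   `"shuffle_similarities"` (source of the value distribution), optional
#'   for `"uniform_rankings"` (only its drug universe is used).
#' @param metrics metric selection passed to [runMetricSuite()].
#' @return A [MetricReport-class] whose `aggregate` slot holds, per metric
#'   / cutoff / level, the mean, median and IQR of the per-replicate means,
#'   and whose `perIndication` slot holds per-indication values averaged
#'   over replicates.
#' @export
runNullControl <- function(standard, config = BenchmarkConfig(), spec,
                           sim = NULL,
                           metrics = c("indication_accuracy", "AUROC",
                                       "BEDROC", "NDCG")) {
  stopifnot(is(standard, "AssociationStandard"), is(spec, "NullSpec"),
            is(config, "BenchmarkConfig"))
  if (spec@method == "shuffle_similarities" && is.null(sim))
    stop("shuffle_similarities needs the observed similarity matrix")
  ids <- if (is.null(sim)) drugIds(standard) else drugIds(sim)

  aggList <- vector("list", spec@replicates)
  piSum <- NULL
  for (r in seq_len(spec@replicates)) {
    seed_r <- spec@seed + r
    simR <- if (spec@method == "shuffle_similarities")
      shuffleSimilarities(sim, seed_r)
    else
      uniformRandomSimilarity(ids, seed_r)
    repOut <- runMetricSuite(standard, simR, config, metrics = metrics)
    agr <- aggregated(repOut)
    agr$replicate <- r
    aggList[[r]] <- agr
    pir <- perIndication(repOut)
    if (is.null(piSum)) {
      piSum <- pir
    } else {
      piSum$value <- piSum$value + pir$value
    }
  }
  piMean <- piSum
  piMean$value <- piMean$value / spec@replicates

  all <- do.call(rbind, aggList)
  ## character key: NA cutoffs (cutoff-free metrics) must not be dropped
  key <- paste(all$metric, all$cutoff, all$level, sep = "\r")
  agg <- do.call(rbind, lapply(split(all, key), function(g) {
    data.frame(metric = g$metric[1L], cutoff = g$cutoff[1L],
               level = g$level[1L],
               mean = mean(g$mean), median = stats::median(g$mean),
               q25 = unname(stats::quantile(g$mean, 0.25)),
               q75 = unname(stats::quantile(g$mean, 0.75)),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  new("MetricReport", perIndication = piMean, aggregate = agg,
      nullControl = emptyMetricFrame())
}
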