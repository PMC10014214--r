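## Signature similarity and neighbor ranking.
##
## Both measures are *distances*: smaller = more similar = better rank.
## Signatures are compared raw, with no normalization.

#' Root-mean-square deviation between two interaction signatures
#'
#' \deqn{d(a, b) = \sqrt{\frac{1}{p}\sum_{j=1}^{p} (a_j - b_j)^2}}
#'
#' @param sig_a,sig_b numeric vectors of equal length (>= 1).
#' @return A non-negative scalar; 0 iff the signatures are identical.
#' @examples
#' rmsdDistance(c(1, 0, 0), c(0, 1, 0))  # sqrt(2/3)
#' @export
rmsdDistance <- function(sig_a, sig_b) {
  if (!length(sig_a)) stop("empty signature vectors")
  if (length(sig_a) != length(sig_b))
    stop("signature length mismatch: ", length(sig_a), " vs ", length(sig_b))
  sqrt(mean((sig_a - sig_b)^2))
}

#' Cosine distance between two interaction signatures
#'
#' One minus the cosine of the angle between the vectors:
#' \eqn{1 - a \cdot b / (\|a\| \|b\|)}. Ranges over [0, 2]; 0 for parallel
#' vectors, 1 for orthogonal, 2 for anti-parallel. Undefined (an error) for
#' a zero vector, which has no direction.
#'
#' @inheritParams rmsdDistance
#' @return A scalar in [0, 2].
#' @export
cosineDistance <- function(sig_a, sig_b) {
  if (!length(sig_a)) stop("empty signature vectors")
  if (length(sig_a) != length(sig_b))
    stop("signature length mismatch: ", length(sig_a), " vs ", length(sig_b))
  na <- sqrt(sum(sig_a^2))
  nb <- sqrt(sum(sig_b^2))
  if (na == 0 || nb == 0)
    stop("cosine distance undefined for a zero-norm signature")
  1 - sum(sig_a * sig_b) / (na * nb)
}

#' All pairwise signature distances
#'
#' Computes the full symmetric drug-drug distance matrix under the chosen
#' measure. RMSD is the Euclidean distance scaled by \eqn{1/\sqrt{p}} (p =
#' number of proteins) and is computed through [stats::dist()].
#'
#' @param sig a [SignatureMatrix-class] with at least 2 drugs.
#' @param measure `"rmsd"` (default) or `"cosine"`.
#' @return A [SimilarityMatrix-class].
#' @export
pairwiseDistances <- function(sig, measure = c("rmsd", "cosine")) {
  stopifnot(is(sig, "SignatureMatrix"))
  measure <- match.arg(measure)
  m <- scores(sig)
  if (nrow(m) < 2L) stop("need at least 2 drugs")
  if (measure == "rmsd") {
    d <- as.matrix(stats::dist(m, method = "euclidean")) / sqrt(ncol(m))
  } else {
    nrm <- sqrt(rowSums(m^2))
    if (any(nrm == 0))
      stop("cosine distance undefined for zero-norm signature(s): ",
           paste(rownames(m)[nrm == 0], collapse = ", "))
    cs <- tcrossprod(m / nrm)
    d <- 1 - cs
    ## clamp numerical noise so distances stay in [0, 2] with a zero diagonal
    d[d < 0] <- 0
    diag(d) <- 0
  }
  dimnames(d) <- list(rownames(m), rownames(m))
  SimilarityMatrix(d, measure = measure)
}

#' Rank all drugs by similarity to a query
#'
#' Orders every non-query drug by ascending distance to the query; rank 1
#' is the most similar drug. Ties are broken lexicographically by drug id
#' (C collation), so the ranking is total and deterministic across runs and
#' platforms.
#'
#' @param sim a [SimilarityMatrix-class].
#' @param query a drug id present in `sim`.
#' @return A [NeighborRanking-class].
#' @export
rankNeighbors <- function(sim, query) {
  stopifnot(is(sim, "SimilarityMatrix"))
  ids <- drugIds(sim)
  if (!query %in% ids) stop("unknown query drug: ", query)
  d <- distances(sim)[query, ]
  others <- setdiff(ids, query)
  d <- d[others]
  ## radix order on character is C-locale: tie-break is locale-independent
  ord <- order(d, others, method = "radix")
  new("NeighborRanking", query = query, rankedDrugs = others[ord],
      distances = unname(d[ord]))
}
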