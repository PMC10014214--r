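## Ranking-quality metrics.
##
## Two input conventions are used, both 1-based:
##   * a relevance vector `rel`: rel[i] is the (integer >= 0) relevance of
##     the item at rank i; binary {0, 1} by default;
##   * "early recognition" inputs: the ranks of the actives (`active_ranks`)
##     in a list of total length N, from which the ratio of actives
##     Ra = n/N, ratio of inactives Ri = 1 - Ra and relative ranks
##     x_i = r_i/N derive.

validRel <- function(rel) {
  if (!length(rel)) stop("relevance vector must be non-empty")
  if (anyNA(rel) || any(rel < 0) || any(rel != floor(rel)))
    stop("relevance grades must be non-negative integers")
  as.numeric(rel)
}

validActiveRanks <- function(active_ranks, N, allowEmpty = FALSE,
                             allowFull = FALSE) {
  if (length(N) != 1L || is.na(N) || N < 1 || N != floor(N))
    stop("N must be a positive integer")
  if (anyNA(active_ranks) || any(active_ranks < 1) ||
      any(active_ranks > N) || any(active_ranks != floor(active_ranks)))
    stop("active ranks must be distinct integers in 1..N")
  if (anyDuplicated(active_ranks)) stop("active ranks must be distinct")
  n <- length(active_ranks)
  if (!allowEmpty && n == 0L) stop("need at least one active (n > 0)")
  if (!allowFull && n == N) stop("need at least one inactive (n < N)")
  as.numeric(active_ranks)
}

#' Ranks of the actives in a relevance vector
#'
#' @param rel relevance vector (integer grades, position = 1-based rank).
#' @return Integer vector of the 1-based ranks where `rel > 0`.
#' @export
activeRanks <- function(rel) {
  which(validRel(rel) > 0)
}

#' Mean reciprocal rank
#'
#' The average over queries of 1 / (rank of the first retrieved active).
#' Queries whose ranking contains no active (`NA`) contribute 0.
#'
#' @param first_active_ranks vector of positive integer ranks of the first
#'   active per query; `NA` for "none".
#' @return A value in [0, 1].
#' @examples
#' meanReciprocalRank(c(2, 4))  # 0.375
#' @export
meanReciprocalRank <- function(first_active_ranks) {
  if (!length(first_active_ranks)) stop("need at least one query")
  ok <- !is.na(first_active_ranks)
  if (any(first_active_ranks[ok] < 1))
    stop("ranks must be positive integers")
  inv <- ifelse(ok, 1 / as.numeric(first_active_ranks), 0)
  mean(inv)
}

#' Precision at rank K
#'
#' Fraction of the top `k` positions occupied by actives.
#'
#' @param rel relevance vector.
#' @param k cutoff, 1 <= k <= length(rel).
#' @return A value in [0, 1].
#' @export
precisionAtK <- function(rel, k) {
  rel <- validRel(rel)
  if (length(k) != 1L || is.na(k) || k < 1 || k > length(rel))
    stop("k must be in 1..", length(rel))
  mean(rel[seq_len(k)] > 0)
}

#' Average precision and mean average precision
#'
#' AP is the mean, over the positions of the actives, of the precision at
#' each such position; MAP is the mean of per-query APs. For binary
#' relevance AP equals the area under the step-interpolated
#' precision-recall curve (see [auprc()]).
#'
#' @param rel relevance vector with at least one active.
#' @return A value in [0, 1].
#' @examples
#' averagePrecision(c(1, 0, 1))  # (1 + 2/3)/2
#' @export
averagePrecision <- function(rel) {
  rel <- validRel(rel)
  pos <- which(rel > 0)
  if (!length(pos)) stop("average precision undefined with no actives")
  mean(seq_along(pos) / pos)
}

#' @rdname averagePrecision
#' @param rel_list list of relevance vectors, one per query.
#' @export
meanAveragePrecision <- function(rel_list) {
  if (!length(rel_list)) stop("need at least one query")
  mean(vapply(rel_list, averagePrecision, numeric(1)))
}

#' Enrichment factor at a list fraction
#'
#' The concentration of actives in the top `fraction` of the list relative
#' to the active rate of the whole list:
#' \eqn{EF = (\mathrm{actives\ in\ top\ }k / k) / (n/N)} with
#' \eqn{k = \lfloor fraction \cdot N \rfloor}. Expected value 1 under
#' uniform random ranking; maximum N/n.
#'
#' @param active_ranks 1-based ranks of the actives.
#' @param N total list length.
#' @param fraction top fraction of the list, in (0, 1]; must give k >= 1.
#' @return A non-negative scalar.
#' @export
enrichmentFactor <- function(active_ranks, N, fraction) {
  r <- validActiveRanks(active_ranks, N, allowFull = TRUE)
  k <- floor(fraction * N)
  if (k < 1) stop("fraction ", fraction, " yields an empty top list (k = 0)")
  (sum(r <= k) / k) / (length(r) / N)
}

## continuous RIE normalization: mean of exp(-alpha * r/N) over a uniform
## random rank, i.e. (1/N) (1 - e^-alpha) / (e^(alpha/N) - 1)
rieDenominator <- function(N, alpha) {
  (1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1)
}

rieFromRanks <- function(r, n, N, alpha) {
  mean(exp(-alpha * r / N)) / rieDenominator(N, alpha)
}

#' Robust initial enhancement (RIE)
#'
#' Exponentially rank-weighted enrichment:
#' \deqn{RIE = \frac{\frac{1}{n}\sum_{i=1}^{n} e^{-\alpha x_i}}
#'   {\frac{1}{N}\,\frac{1 - e^{-\alpha}}{e^{\alpha/N} - 1}}}
#' with relative ranks \eqn{x_i = r_i / N}. The denominator is the
#' expectation of \eqn{e^{-\alpha x}} over a uniformly random rank, so the
#' expected RIE of a random ranking is 1. The weight parameter
#' \eqn{\alpha} controls how early "early recognition" is: roughly the top
#' \eqn{1/\alpha} fraction of the list carries the weight.
#'
#' @param active_ranks 1-based ranks of the actives (0 < n < N).
#' @param N total list length.
#' @param alpha positive early-recognition weight (default 20).
#' @return A positive scalar.
#' @export
rie <- function(active_ranks, N, alpha = 20) {
  r <- validActiveRanks(active_ranks, N)
  if (alpha <= 0) stop("alpha must be positive")
  rieFromRanks(r, length(r), N, alpha)
}

#' Boltzmann-enhanced discrimination of ROC (BEDROC)
#'
#' The min-max normalization of [rie()] to [0, 1]:
#' \deqn{BEDROC = \frac{RIE - RIE_{min}}{RIE_{max} - RIE_{min}}}
#' where \eqn{RIE_{max}} places all n actives at ranks 1..n and
#' \eqn{RIE_{min}} at ranks N-n+1..N. Interpretable as the probability
#' that an active is ranked before a random inactive drawn from an
#' exponential weighting of the list when \eqn{\alpha R_a \ll 1}; a warning
#' is emitted when \eqn{\alpha R_a > 0.1}, outside that regime.
#'
#' @inheritParams rie
#' @return A value in [0, 1]: 1 when all actives fill the top ranks, 0 when
#'   they fill the bottom.
#' @export
bedroc <- function(active_ranks, N, alpha = 20) {
  r <- validActiveRanks(active_ranks, N)
  if (alpha <= 0) stop("alpha must be positive")
  n <- length(r)
  Ra <- n / N
  if (alpha * Ra > 0.1)
    warning("alpha * Ra = ", signif(alpha * Ra, 3),
            " > 0.1: outside the early-recognition validity regime ",
            "(alpha * Ra << 1)")
  v <- rieFromRanks(r, n, N, alpha)
  vmax <- rieFromRanks(seq_len(n), n, N, alpha)
  vmin <- rieFromRanks(N - n + seq_len(n), n, N, alpha)
  if (vmax <= vmin)
    stop("degenerate (N, n): RIE_max equals RIE_min")
  (v - vmin) / (vmax - vmin)
}

#' AUROC from active ranks (closed-form)
#'
#' The rank-formula area under the ROC curve,
#' \deqn{AUROC = \frac{1 - \bar{x} - R_a/2}{R_i}, \qquad
#'   \bar{x} = \frac{1}{nN}\sum_{i=1}^n r_i,}
#' with \eqn{R_a = n/N} the ratio of actives and \eqn{R_i = 1 - R_a} the
#' ratio of inactives. This is the continuous approximation; the exact
#' discrete counterpart adds \eqn{1/(2 N R_i)} and then equals the pairwise
#' Mann-Whitney AUROC on tie-free rankings (`correction = "discrete"`).
#'
#' @inheritParams rie
#' @param correction `"continuous"` (the formula as printed) or
#'   `"discrete"` (adds \eqn{1/(2NR_i)}; exact for tie-free ranked lists).
#' @return The AUROC estimate.
#' @examples
#' aurocRankFormula(c(1, 2), N = 10)                        # 0.9375
#' aurocRankFormula(c(1, 2), N = 10, correction = "discrete")  # 1
#' @export
aurocRankFormula <- function(active_ranks, N,
                             correction = c("continuous", "discrete")) {
  r <- validActiveRanks(active_ranks, N)
  correction <- match.arg(correction)
  n <- length(r)
  Ra <- n / N
  Ri <- 1 - Ra
  xbar <- sum(r) / (n * N)
  v <- (1 - xbar - Ra / 2) / Ri
  if (correction == "discrete") v <- v + 1 / (2 * N * Ri)
  v
}

#' Discounted cumulative gain and its normalizations
#'
#' \deqn{DCG_p = \sum_{i=1}^{p} \frac{2^{rel_i} - 1}{\log_2(i + 1)}}
#' `idcg` evaluates the same sum for the ideal ordering (all actives first,
#' highest grades first) truncated at `p`; `ndcg` is their ratio, in
#' [0, 1], defined as 0 when the ideal gain is 0 (no actives).
#'
#' @param rel relevance vector (binary or graded, position = rank).
#' @param p evaluation depth, 1 <= p <= length(rel).
#' @return Non-negative gain (`dcg`, `idcg`) or a value in [0, 1] (`ndcg`).
#' @examples
#' ndcg(c(1, 0, 1), p = 3)  # 1.5 / (1 + 1/log2(3))
#' @export
dcg <- function(rel, p) {
  rel <- validRel(rel)
  if (length(p) != 1L || is.na(p) || p < 1 || p > length(rel))
    stop("p must be in 1..", length(rel))
  i <- seq_len(p)
  sum((2^rel[i] - 1) / log2(i + 1))
}

#' @rdname dcg
#' @export
idcg <- function(rel, p) {
  rel <- validRel(rel)
  ideal <- sort(rel, decreasing = TRUE)
  dcg(ideal, p)
}

#' @rdname dcg
#' @export
ndcg <- function(rel, p) {
  d <- dcg(rel, p)
  id <- idcg(rel, p)
  if (id == 0) 0 else d / id
}
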