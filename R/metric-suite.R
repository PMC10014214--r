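## End-to-end metric suite: run the leave-one-out benchmark and score every
## (drug, indication) pair's ranking with the full metric battery, then
## aggregate per indication (the AIA convention: unweighted mean over
## indications) and per pair, side by side.

#' Names of the metrics computed by [runMetricSuite()]
#' @return Character vector of metric names.
#' @export
suiteMetricNames <- function() {
  c("indication_accuracy", "MRR", "AP", "AUROC", "RIE", "BEDROC", "NDCG",
    "EF", "precision", "sensitivity", "specificity", "FDR", "FPR",
    "accuracy", "F1", "MCC")
}

#' Run the full benchmark and metric suite
#'
#' Holds out each associated drug, ranks all other drugs by signature
#' similarity, and scores the resulting ranked list against the drug's
#' indication (the remaining same-indication drugs are the actives; the
#' relevance vector is binary and tie-free by construction). Per-pair
#' scores are averaged within each indication ("indication" level, the
#' convention behind AIA) and across all drug-indication pairs ("pair"
#' level); both aggregations are reported because skewed standards make
#' them differ.
#'
#' Cutoff-free metrics (MRR, AP, AUROC, RIE, BEDROC) are reported with
#' `cutoff = NA`; the rest (NDCG, EF and the confusion-matrix metrics) are
#' evaluated at each cutoff of `config`. AUROC uses the closed-form rank
#' formula with the discrete correction, which on these tie-free lists
#' equals the pairwise Mann-Whitney statistic. BEDROC's early-recognition
#' regime (alpha x ratio-of-actives below 0.1) is checked once over the
#' whole standard, with a single warning if any indication violates it.
#'
#' @param standard an [AssociationStandard-class].
#' @param sim a [SimilarityMatrix-class] covering the standard's drugs.
#' @param config a [BenchmarkConfig-class] (cutoffs, eligibility, alpha).
#' @param metrics subset of `suiteMetricNames()` to compute.
#' @return A [MetricReport-class]. The per-indication accuracy rows carry
#'   metric name `"indication_accuracy"`; its indication-level aggregate is
#'   duplicated under metric name `"AIA"`.
#' @export
runMetricSuite <- function(standard, sim, config = BenchmarkConfig(),
                           metrics = suiteMetricNames()) {
  stopifnot(is(standard, "AssociationStandard"),
            is(sim, "SimilarityMatrix"),
            is(config, "BenchmarkConfig"))
  metrics <- match.arg(metrics, suiteMetricNames(), several.ok = TRUE)
  loo <- runLooBenchmark(standard, sim, config)
  pos <- looPositions(sim)
  N <- nDrugs(sim) - 1L            # ranked-list length in LOO mode
  cutoffs <- config@cutoffs
  alpha <- config@alpha

  a <- associations(standard)
  sz <- indicationSizes(standard)
  eligible <- names(sz)[sz >= config@minIndicationSize]
  aq <- a[a$indication_id %in% eligible, , drop = FALSE]
  byInd <- split(aq$drug_id, aq$indication_id)

  maxAlphaRa <- max(alpha * (sz[eligible] - 1L) / N)
  if ("BEDROC" %in% metrics && maxAlphaRa > 0.1)
    warning("alpha * Ra reaches ", signif(maxAlphaRa, 3),
            " ( > 0.1) for the largest indication; BEDROC's ",
            "early-recognition interpretation weakens there")

  denom <- rieDenominator(N, alpha)
  cutFree <- intersect(metrics, c("MRR", "AP", "AUROC", "RIE", "BEDROC"))
  cutBased <- intersect(metrics,
                        c("NDCG", "EF", "precision", "sensitivity",
                          "specificity", "FDR", "FPR", "accuracy",
                          "F1", "MCC"))
  disc <- 1 / log2(seq_len(N) + 1)   # DCG discounts
  discCum <- cumsum(disc)            # ideal binary DCG prefix sums

  keyMetric <- c(cutFree, rep(cutBased, each = length(cutoffs)))
  keyCutoff <- c(rep(NA_integer_, length(cutFree)),
                 rep(cutoffs, times = length(cutBased)))
  nKeys <- length(keyMetric)

  pairInd <- character(0)
  pairVals <- NULL
  if (nKeys) {
    blocks <- vector("list", length(byInd))
    for (j in seq_along(byInd)) {
      ds <- byInd[[j]]
      sub <- pos[ds, ds, drop = FALSE]
      n <- length(ds) - 1L           # actives per held-out query
      Ra <- n / N; Ri <- 1 - Ra
      m <- matrix(NA_real_, length(ds), nKeys)
      for (q in seq_along(ds)) {
        ar <- sort(sub[q, -q])
        v <- numeric(0)
        for (f in cutFree) {
          v <- c(v, switch(f,
            MRR = 1 / ar[1L],
            AP = mean(seq_along(ar) / ar),
            AUROC = (1 - sum(ar) / (n * N) - Ra / 2) / Ri +
              1 / (2 * N * Ri),
            RIE = mean(exp(-alpha * ar / N)) / denom,
            BEDROC = {
              rieV <- mean(exp(-alpha * ar / N)) / denom
              vmax <- mean(exp(-alpha * seq_len(n) / N)) / denom
              vmin <- mean(exp(-alpha * (N - n + seq_len(n)) / N)) / denom
              (rieV - vmin) / (vmax - vmin)
            }))
        }
        for (f in cutBased) {
          for (k in cutoffs) {
            tp <- sum(ar <= k); fp <- k - tp; fn <- n - tp; tn <- N - k - fn
            v <- c(v, switch(f,
              NDCG = sum(disc[ar[ar <= k]]) / discCum[min(n, k)],
              EF = (tp / k) / (n / N),
              precision = tp / k,
              sensitivity = tp / n,
              specificity = tn / (N - n),
              FDR = fp / k,
              FPR = fp / (N - n),
              accuracy = (tp + tn) / N,
              F1 = 2 * tp / (2 * tp + fp + fn),
              MCC = {
                den <- sqrt(as.numeric(tp + fp) * (tp + fn) *
                              (tn + fp) * (tn + fn))
                if (den == 0) 0 else (tp * tn - fp * fn) / den
              }))
          }
        }
        m[q, ] <- v
      }
      blocks[[j]] <- m
    }
    pairVals <- do.call(rbind, blocks)
    pairInd <- rep(names(byInd), times = vapply(byInd, length, integer(1)))
  }

  ## per-indication means of the per-pair values
  perInd <- data.frame(indication_id = character(), metric = character(),
                       cutoff = integer(), value = numeric(),
                       stringsAsFactors = FALSE)
  if (!is.null(pairVals)) {
    indMeans <- rowsum(pairVals, pairInd) /
      as.vector(table(pairInd)[sort(unique(pairInd))])
    inds <- rownames(indMeans)
    perInd <- data.frame(
      indication_id = rep(inds, each = nKeys),
      metric = rep(keyMetric, times = length(inds)),
      cutoff = rep(keyCutoff, times = length(inds)),
      value = as.vector(t(indMeans)), stringsAsFactors = FALSE)
  }
  if ("indication_accuracy" %in% metrics) {
    acc <- perIndication(loo)
    perInd <- rbind(perInd,
                    data.frame(indication_id = acc$indication_id,
                               metric = "indication_accuracy",
                               cutoff = acc$cutoff, value = acc$accuracy,
                               stringsAsFactors = FALSE))
  }

  statRow <- function(metric, cutoff, level, x) {
    x <- x[!is.na(x)]
    data.frame(metric = metric, cutoff = cutoff, level = level,
               mean = mean(x), median = stats::median(x),
               q25 = unname(stats::quantile(x, 0.25)),
               q75 = unname(stats::quantile(x, 0.75)),
               stringsAsFactors = FALSE)
  }
  aggRows <- list()
  if (!is.null(pairVals)) {
    indMat <- t(matrix(perInd$value[perInd$metric %in% keyMetric],
                       nrow = nKeys))
    for (i in seq_len(nKeys)) {
      aggRows[[length(aggRows) + 1L]] <-
        statRow(keyMetric[i], keyCutoff[i], "indication", indMat[, i])
      aggRows[[length(aggRows) + 1L]] <-
        statRow(keyMetric[i], keyCutoff[i], "pair", pairVals[, i])
    }
  }
  if ("indication_accuracy" %in% metrics) {
    accInd <- perIndication(loo)
    for (k in cutoffs) {
      x <- accInd$accuracy[accInd$cutoff == k]
      aggRows[[length(aggRows) + 1L]] <-
        statRow("indication_accuracy", k, "indication", x)
      aggRows[[length(aggRows) + 1L]] <- statRow("AIA", k, "indication", x)
    }
  }
  agg <- if (length(aggRows)) do.call(rbind, aggRows) else emptyMetricFrame()
  rownames(agg) <- NULL
  new("MetricReport", perIndication = perInd, aggregate = agg,
      nullControl = emptyMetricFrame())
}
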