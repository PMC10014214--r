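## Shared fixtures and independent oracles. All fixtures are built in code.

## SimilarityMatrix from a plain symmetric matrix
simFromMatrix <- function(m, ids = rownames(m)) {
  dimnames(m) <- list(ids, ids)
  SimilarityMatrix(m)
}

## uniform random symmetric distance matrix over n drugs
randomSim <- function(n, ids = sprintf("d%03d", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2)
  simFromMatrix(m + t(m), ids)
}

## binary relevance vector with actives at the given 1-based ranks
relFromRanks <- function(active_ranks, N) {
  rel <- integer(N)
  rel[active_ranks] <- 1L
  rel
}

## draw a uniformly random tie-free instance: n active ranks out of N
randomActiveRanks <- function(N, n) sort(sample.int(N, n))

## brute-force Mann-Whitney AUROC: fraction of (active, inactive) pairs
## with the active ranked better (rank = smaller is better; tie-free)
pairwiseAurocOracle <- function(active_ranks, N) {
  inact <- setdiff(seq_len(N), active_ranks)
  wins <- 0
  for (a in active_ranks) wins <- wins + sum(a < inact)
  wins / (length(active_ranks) * length(inact))
}

## geometric fixture reproducing the worked melanoma-style example:
## one indication ("D008545") with 58 drugs, of which exactly 23 have a
## same-indication drug within their top 10 most-similar signatures
## (10 tight pairs + 1 tight triple), while each of the remaining 35 is
## surrounded by 10 closer decoy drugs with no association.
melanomaFixture <- function() {
  drugs <- character(0)
  x <- numeric(0)
  mel <- character(0)
  site <- 0
  ## 10 pairs and one triple of near-identical signatures: 23 hit drugs
  for (p in 1:10) {
    site <- site + 1
    ids <- sprintf("mel_hit_p%02d_%d", p, 1:2)
    drugs <- c(drugs, ids); mel <- c(mel, ids)
    x <- c(x, site * 1e4, site * 1e4 + 1e-3)
  }
  site <- site + 1
  ids <- sprintf("mel_hit_t01_%d", 1:3)
  drugs <- c(drugs, ids); mel <- c(mel, ids)
  x <- c(x, site * 1e4, site * 1e4 + 1e-3, site * 1e4 + 2e-3)
  ## 35 isolated drugs, each with 10 nearer unassociated decoys
  for (m in 1:35) {
    site <- site + 1
    id <- sprintf("mel_miss_%02d", m)
    drugs <- c(drugs, id); mel <- c(mel, id)
    x <- c(x, site * 1e4)
    dec <- sprintf("decoy_%02d_%02d", m, 1:10)
    drugs <- c(drugs, dec)
    x <- c(x, site * 1e4 + (1:10) * 1e-2)
  }
  sig <- SignatureMatrix(cbind(x, 0),
                         drug_ids = drugs, protein_ids = c("p1", "p2"))
  std <- AssociationStandard(mel, rep("D008545", length(mel)),
                             drugs = drugs)
  list(standard = std, signatures = sig)
}

## small planted-signal synthetic dataset for smoke tests
smallSynthetic <- function(seed = 3, signal = 2) {
  spec <- SyntheticSpec(nDrugs = 80, nProteins = 25, nIndications = 10,
                        nAssociations = 60, signalStrength = signal,
                        noiseSd = 0.5, seed = seed)
  std <- generateStandard(spec)
  sig <- generateSignatures(std, spec)
  list(spec = spec, standard = std, signatures = sig,
       sim = pairwiseDistances(sig))
}
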