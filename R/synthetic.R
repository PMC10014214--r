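## Synthetic benchmark generator.
##
## Real drug-indication standards are heavily imbalanced: a few common
## indications (pain, hypertension, seizures) carry hundreds of associated
## drugs while rare ones carry single digits. Indication sizes are
## therefore drawn from a truncated power law (Zipf-like) with exponent
## `sizeSkew`, then renormalized so the total association count is hit
## exactly. Signatures carry a planted signal: each indication owns a
## latent protein profile, and a drug's signature is
## signalStrength x (mean of its indications' profiles) + Gaussian noise.

#' Generate a synthetic association standard
#'
#' Draws per-indication drug-set sizes from a truncated power law
#' (P(size = s) proportional to s^-sizeSkew, s = 1..nDrugs), rescales them
#' to sum exactly to `nAssociations`, and fills each indication with drugs
#' sampled uniformly without within-indication duplication. Fully
#' reproducible from `spec@seed`.
#'
#' @param spec a [SyntheticSpec-class].
#' @return An [AssociationStandard-class] with exactly
#'   `spec@nAssociations` associations over `spec@nDrugs` drugs (zero-width
#'   padded ids `drug0001`...) and `spec@nIndications` indications
#'   (MeSH-style ids `D000001`...).
#' @export
generateStandard <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  nD <- spec@nDrugs; nI <- spec@nIndications; nA <- spec@nAssociations
  drugs <- sprintf("drug%0*d", nchar(nD), seq_len(nD))
  inds <- sprintf("D%06d", seq_len(nI))
  withSeed(spec@seed, {
    sizes <- drawIndicationSizes(nI, nA, nD, spec@sizeSkew)
    pairs <- lapply(seq_len(nI), function(i) {
      data.frame(drug_id = drugs[sample.int(nD, sizes[i])],
                 indication_id = inds[i], stringsAsFactors = FALSE)
    })
    a <- do.call(rbind, pairs)
    AssociationStandard(a$drug_id, a$indication_id,
                        drugs = drugs, indications = inds)
  })
}

## Power-law sizes in 1..maxSize, adjusted to sum exactly to total.
## The residual between the drawn sum and the target is absorbed one
## association at a time by indications sampled with probability
## proportional to their current size (size - 1 for removals), i.e.
## preferential attachment: this keeps both the size-1 mass and the heavy
## tail intact, which a uniform spread over indications would not.
drawIndicationSizes <- function(nI, total, maxSize, skew) {
  support <- seq_len(maxSize)
  sizes <- sample(support, nI, replace = TRUE, prob = support^(-skew))
  delta <- total - sum(sizes)
  while (delta > 0L) {
    w <- ifelse(sizes < maxSize, sizes, 0)
    take <- min(delta, max(1L, delta %/% 2L))
    pick <- sample.int(nI, take, replace = TRUE, prob = w)
    add <- tabulate(pick, nI)
    add <- pmin(add, maxSize - sizes)
    sizes <- sizes + add
    delta <- delta - sum(add)
  }
  while (delta < 0L) {
    w <- sizes - 1L
    take <- min(-delta, max(1L, (-delta) %/% 2L))
    pick <- sample.int(nI, take, replace = TRUE, prob = w)
    sub <- tabulate(pick, nI)
    sub <- pmin(sub, sizes - 1L)
    sizes <- sizes - sub
    delta <- delta + sum(sub)
  }
  sizes
}

#' Generate synthetic interaction signatures with a planted signal
#'
#' Each indication receives a latent protein profile drawn from a standard
#' normal over the `nProteins` dimensions. A drug's signature is
#' `signalStrength` times the unweighted mean of its indications' profiles
#' plus independent Gaussian noise of standard deviation `noiseSd`; drugs
#' with no association are pure noise. At `signalStrength = 0` the
#' signatures are independent of the standard (a true null); as
#' `signalStrength` grows, same-indication drugs become mutual nearest
#' neighbors and the benchmark accuracy approaches 100%.
#'
#' @param standard an [AssociationStandard-class] (typically from
#'   [generateStandard()]).
#' @param spec a [SyntheticSpec-class]; signature generation uses
#'   `spec@seed + 1` so standard and signatures are independently
#'   reproducible.
#' @return A [SignatureMatrix-class] of dimension drugs x `spec@nProteins`.
#' @export
generateSignatures <- function(standard, spec) {
  stopifnot(is(standard, "AssociationStandard"), is(spec, "SyntheticSpec"))
  drugs <- drugIds(standard)
  inds <- indicationIds(standard)
  nP <- spec@nProteins
  withSeed(spec@seed + 1L, {
    profiles <- matrix(stats::rnorm(length(inds) * nP), length(inds), nP,
                       dimnames = list(inds, NULL))
    noise <- matrix(stats::rnorm(length(drugs) * nP, sd = spec@noiseSd),
                    length(drugs), nP, dimnames = list(drugs, NULL))
    sig <- noise
    if (spec@signalStrength > 0) {
      a <- associations(standard)
      byDrug <- split(a$indication_id, a$drug_id)
      for (d in names(byDrug)) {
        prof <- profiles[byDrug[[d]], , drop = FALSE]
        sig[d, ] <- sig[d, ] + spec@signalStrength * colMeans(prof)
      }
    }
    colnames(sig) <- sprintf("prot%0*d", nchar(nP), seq_len(nP))
    SignatureMatrix(sig)
  })
}
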