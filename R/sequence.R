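# Per-column entropy, pairwise mutual information, mean coevolution per
# residue, and an entropy-based conservation surrogate.
#
# Conventions: natural logarithms throughout (the entropy ceiling for 20
# amino-acid types is ln 20 = 2.9957 nats). Entropy is computed over the 20
# amino-acid types with gaps excluded and probabilities renormalized over
# the observed amino acids; mutual information counts the gap as a 21st
# type. The asymmetry between the two conventions is deliberate and is
# preserved from the underlying method.

#' Per-column Shannon entropy of an alignment
#'
#' S(i) = -sum_a P(a_i) ln P(a_i) over the 20 amino-acid types, gaps
#' excluded and probabilities renormalized over the observed amino acids.
#' A column that is 100 percent gaps is marked NA, never zero.
#'
#' @param aln a \linkS4class{SequenceAlignment}.
#' @return numeric vector of per-column entropies in nats, in [0, ln 20].
#' @export
shannonEntropyProfile <- function(aln) {
  chars <- alignmentMatrix(aln)
  apply(chars, 2, function(col) {
    col <- col[col %in% AA_ALPHABET20]
    if (!length(col)) return(NA_real_)
    p <- tabulate(match(col, AA_ALPHABET20), 20L)
    p <- p[p > 0] / length(col)
    -sum(p * log(p))
  })
}

# encode alignment columns as integers 1..21 (gap and unknowns = 21)
.encode21 <- function(chars) {
  codes <- match(chars, AA_ALPHABET20)
  codes[is.na(codes)] <- 21L
  matrix(codes, nrow = nrow(chars))
}

#' Mutual information matrix of an alignment
#'
#' Plug-in mutual information I(i,j) over 21 states (gap counted as type
#' 21) for every pair of columns; the diagonal holds the 21-state entropy
#' of each column. Optional average-product correction (APC) is available
#' behind a flag and is off by default.
#'
#' @param aln a \linkS4class{SequenceAlignment}.
#' @param apc apply the average-product correction (default FALSE).
#' @return symmetric N x N numeric matrix in nats.
#' @export
mutualInformationMatrix <- function(aln, apc = FALSE) {
  codes <- .encode21(alignmentMatrix(aln))
  n <- nrow(codes)
  N <- ncol(codes)
  ent21 <- apply(codes, 2, function(x) {
    p <- tabulate(x, 21L)
    p <- p[p > 0] / n
    -sum(p * log(p))
  })
  mi <- matrix(0, N, N)
  diag(mi) <- ent21
  if (N >= 2L) {
    for (i in seq_len(N - 1L)) {
      ci <- codes[, i]
      for (j in (i + 1L):N) {
        joint <- tabulate((ci - 1L) * 21L + codes[, j], 441L)
        joint <- joint[joint > 0] / n
        hj <- -sum(joint * log(joint))
        mi[i, j] <- mi[j, i] <- max(ent21[i] + ent21[j] - hj, 0)
      }
    }
  }
  if (apc) {
    off <- mi
    diag(off) <- 0
    rowm <- rowSums(off) / (N - 1)
    corr <- outer(rowm, rowm) / (sum(off) / (N * (N - 1)))
    diag(corr) <- 0
    mi <- mi - corr
  }
  mi
}

#' Mean mutual information per residue
#'
#' Row mean of the MI matrix excluding the diagonal; the per-residue
#' coevolution summary used as the MI_mean feature.
#'
#' @param mi symmetric MI matrix from \code{\link{mutualInformationMatrix}}.
#' @return numeric vector, length nrow(mi).
#' @export
meanMiPerResidue <- function(mi) {
  stopifnot(is.matrix(mi), nrow(mi) == ncol(mi))
  n <- nrow(mi)
  if (n < 2L) return(rep(NA_real_, n))
  (rowSums(mi) - diag(mi)) / (n - 1)
}

#' Entropy-based conservation grades 1..9
#'
#' Bins columns into nine grades by entropy nonuples: the lowest-entropy
#' (most conserved) nonuple gets grade 9, the highest grade 1, so grades
#' are monotone non-increasing in entropy. Exact ties share a grade via
#' average ranks; a degenerate all-equal profile maps to the median grade 5.
#' This surrogate stands in only when an externally computed conservation
#' column is not supplied; outputs are flagged with their provenance.
#'
#' @param entropy per-column entropies from
#'   \code{\link{shannonEntropyProfile}}.
#' @return integer vector of grades in 1..9 (NA where entropy is NA).
#' @export
conservationSurrogate <- function(entropy) {
  ok <- !is.na(entropy)
  out <- rep(NA_integer_, length(entropy))
  x <- entropy[ok]
  if (!length(x)) return(out)
  if (max(x) - min(x) < 1e-12) {
    out[ok] <- 5L
    return(out)
  }
  r <- rank(x, ties.method = "average")
  out[ok] <- 10L - as.integer(ceiling(9 * r / length(x)))
  out
}
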