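# Synthetic-data generators: alignments with controllable per-column
# entropy and coevolution, coarse-grained dimer structures with a
# contact-rich interface, phenotype-labelled mutation sets following the
# directional structure the analysis assumes (severe at conserved, buried,
# destabilizing sites; control at variable, exposed sites), contact-count
# tables, and trajectory ensembles sampled from elastic-network covariance.
# Every generator is a pure function of (spec, seed).

#' Construct a SyntheticSpec
#'
#' Defaults define a desk-scale homodimer study: a 1000 x 60 alignment with
#' per-column entropy targets spread over (0.1, 2.9) nats, a two-chain
#' 60-residue-per-chain dimer, 30 mutations per phenotype class with
#' directional class effects on conservation, exposure and the ddG
#' surrogate, and 500-frame mode-sampled trajectories.
#'
#' @param seed master seed; every generator derives its own stream from it.
#' @param nSequences,nColumns alignment dimensions.
#' @param conservationTargets per-column entropy targets in nats (recycled);
#'   default a seed-shuffled spread over (0.1, 2.9).
#' @param coevolvingPairs data.frame (i, j, coupling in [0,1]).
#' @param nResiduesPerChain,nChains structure size.
#' @param classEffect named standardized mean shifts between the control
#'   and severe classes (mild halfway); recognized names "S_i", "RASA"
#'   (site-selection direction) and "ddG" (surrogate shift).
#' @param nMutationsPerClass mutations per phenotype class.
#' @param nFrames trajectory frames.
#' @param temperatureScale multiplier on the elastic-network covariance.
#' @return \linkS4class{SyntheticSpec}
#' @export
syntheticSpec <- function(seed = 1L, nSequences = 1000L, nColumns = 60L,
                          conservationTargets = NULL,
                          coevolvingPairs = data.frame(i = integer(0),
                                                       j = integer(0),
                                                       coupling = numeric(0)),
                          nResiduesPerChain = 60L, nChains = 2L,
                          classEffect = c(S_i = 1, RASA = 1, ddG = 1.5),
                          nMutationsPerClass = 30L, nFrames = 500L,
                          temperatureScale = 1) {
  if (is.null(conservationTargets)) {
    set.seed(childSeed(seed, "targets"))
    conservationTargets <- sample(seq(0.1, 2.9, length.out = nColumns))
  }
  if (any(conservationTargets > log(20)))
    stopf("entropy target above ln 20 = %.4f is unreachable", log(20))
  methods::new("SyntheticSpec", seed = as.integer(seed),
               nSequences = as.integer(nSequences),
               nColumns = as.integer(nColumns),
               conservationTargets = conservationTargets,
               coevolvingPairs = coevolvingPairs,
               nResiduesPerChain = as.integer(nResiduesPerChain),
               nChains = as.integer(nChains), classEffect = classEffect,
               nMutationsPerClass = as.integer(nMutationsPerClass),
               nFrames = as.integer(nFrames),
               temperatureScale = temperatureScale)
}

# column distribution hitting a target entropy: one peaked type at
# probability (1-w) + w/20, the rest at w/20; H(w) is continuous and
# strictly increasing from 0 (w=0) to ln 20 (w=1), solved by uniroot
.columnDistribution <- function(target, peak) {
  entropyOf <- function(w) {
    p <- rep(w / 20, 20)
    p[peak] <- 1 - w + w / 20
    p <- p[p > 0]
    -sum(p * log(p))
  }
  if (target <= 0) w <- 0
  else if (target >= log(20)) w <- 1
  else w <- stats::uniroot(function(w) entropyOf(w) - target,
                           c(1e-12, 1), tol = 1e-12)$root
  p <- rep(w / 20, 20)
  p[peak] <- 1 - w + w / 20
  p
}

#' Generate a synthetic multiple sequence alignment
#'
#' Columns are drawn i.i.d. from distributions solved to hit the
#' per-column entropy targets; a coevolving pair (i, j, coupling c) copies
#' column i into column j per sequence with probability c (identical
#' columns at c = 1), drawing independently from the same marginal
#' otherwise. The first row is the ungapped reference sequence, set to the
#' peak (modal) type of each column.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return \linkS4class{SequenceAlignment}
#' @export
makeMsa <- function(spec) {
  set.seed(childSeed(spec@seed, "msa"))
  n <- spec@nSequences
  L <- spec@nColumns
  targets <- rep_len(spec@conservationTargets, L)
  peaks <- sample.int(20L, L, replace = TRUE)
  codes <- matrix(0L, n, L)
  dists <- vector("list", L)
  # quota sampling: per-column counts round the target distribution, so
  # the empirical entropy tracks the target to O(types/n), well inside
  # the +/- 0.15 nat tolerance at n >= 500
  quotaColumn <- function(p, n) {
    k <- floor(n * p)
    rem <- n - sum(k)
    if (rem > 0) {
      extra <- order(n * p - k, decreasing = TRUE)[seq_len(rem)]
      k[extra] <- k[extra] + 1L
    }
    sample(rep.int(seq_along(p), k))
  }
  for (j in seq_len(L)) {
    dists[[j]] <- .columnDistribution(targets[j], peaks[j])
    codes[, j] <- quotaColumn(dists[[j]], n)
  }
  cp <- spec@coevolvingPairs
  for (k in seq_len(nrow(cp))) {
    i <- cp$i[k]; j <- cp$j[k]; cc <- cp$coupling[k]
    copy <- stats::runif(n) < cc
    codes[copy, j] <- codes[copy, i]
    codes[!copy, j] <- sample.int(20L, sum(!copy), replace = TRUE,
                                  prob = dists[[i]])
    peaks[j] <- peaks[i]
  }
  chars <- matrix(AA_ALPHABET20[codes], n, L)
  # reference row: the modal residue of each column, ungapped by design
  chars[1, ] <- AA_ALPHABET20[peaks]
  methods::new("SequenceAlignment",
               ids = c("reference", sprintf("seq%04d", seq_len(n - 1L))),
               chars = chars, referenceIndex = 1L)
}

# one compact self-avoiding C-alpha walk: 3.8 A steps, non-consecutive
# pairs kept >= 3.5 A apart, confined to a globular radius (about 113 A^3
# per residue, protein-like) so the 7 A contact graph stays contact-rich;
# connectivity is guaranteed by the 3.8 A backbone steps alone
.selfAvoidingChain <- function(n, minSep = 3.5, step = 3.8,
                               maxRestart = 60L) {
  radius <- 3.0 * n^(1 / 3)
  for (restart in seq_len(maxRestart)) {
    xyz <- matrix(NA_real_, n, 3)
    xyz[1, ] <- c(0, 0, 0)
    ok <- TRUE
    for (i in 2:n) {
      placed <- FALSE
      centroid <- colMeans(xyz[seq_len(i - 1L), , drop = FALSE])
      for (try in 1:150) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        cand <- xyz[i - 1L, ] + step * u
        if (sqrt(sum((cand - centroid)^2)) > radius) next
        if (i > 2L) {
          prev <- xyz[seq_len(i - 2L), , drop = FALSE]
          d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
                (prev[, 3] - cand[3])^2
          if (min(d2) < minSep^2) next
        }
        xyz[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(xyz)
  }
  stopf("self-avoidance failed after %d restarts; use fewer residues or a larger box",
        maxRestart)
}

# pseudo C-beta 1.53 A from C-alpha along the local normal
.placeCb <- function(xyz) {
  n <- nrow(xyz)
  cb <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (i == 1L) v <- xyz[1, ] - xyz[2, ]
    else if (i == n) v <- xyz[n, ] - xyz[n - 1L, ]
    else v <- 2 * xyz[i, ] - xyz[i - 1L, ] - xyz[i + 1L, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-6) v <- c(0, 0, 1) else v <- v / nv
    cb[i, ] <- xyz[i, ] + 1.53 * v
  }
  cb
}

#' Generate a coarse-grained (homo)dimer structure
#'
#' Each chain is a compact self-avoiding C-alpha walk (consecutive spacing
#' exactly 3.8 A, non-consecutive pairs at least 3.5 A apart, connected at
#' the 7 A GNM cutoff because consecutive residues are always in contact).
#' For two chains, the second is a reflected copy docked along x until the
#' interface holds at least \code{minInterfacePairs} residue pairs within
#' 8 A at no clash. Residue types come from the alignment reference row
#' when supplied (homodimer: both chains share the sequence), otherwise
#' from a seeded draw; non-glycines get a pseudo C-beta 1.53 A from the
#' C-alpha along the local normal.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param aln optional \linkS4class{SequenceAlignment} whose ungapped
#'   reference supplies the residue types.
#' @param minInterfacePairs required inter-chain pairs within 8 A
#'   (default 10).
#' @return \linkS4class{StructureModel}
#' @export
makeDimerStructure <- function(spec, aln = NULL, minInterfacePairs = 10L) {
  if (spec@nResiduesPerChain < 20L)
    stopf("need at least 20 residues per chain")
  set.seed(childSeed(spec@seed, "structure"))
  n <- spec@nResiduesPerChain
  a <- .selfAvoidingChain(n)
  if (!is.null(aln)) {
    ref <- referenceRow(aln)
    ref <- ref[ref != "-"]
    if (length(ref) < n)
      stopf("ungapped reference length %d < residues per chain %d",
            length(ref), n)
    seqAA <- ref[seq_len(n)]
  } else {
    seqAA <- sample(AA_ALPHABET20, n, replace = TRUE,
                    prob = ifelse(AA_ALPHABET20 == "G", 2, 1))
  }
  chains <- list(A = a)
  if (spec@nChains == 2L) {
    b0 <- a
    b0[, 1] <- -b0[, 1]                       # reflected copy
    spanA <- range(a[, 1])
    placed <- FALSE
    for (try in 1:40) {
      if (try > 1L) {                          # re-orient and retry
        th <- stats::runif(1, 0, 2 * pi)
        rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                      3, 3)
        b0 <- a %*% rot
        b0[, 1] <- -b0[, 1]
      }
      start <- spanA[2] - min(b0[, 1]) + 3.6
      for (shift in seq(start - 8, start + 40, by = 0.25)) {
        b <- b0
        b[, 1] <- b[, 1] + shift
        d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
        if (min(d2) < 3.5^2) next              # clash: move apart
        if (sum(d2 <= 64) >= minInterfacePairs) { placed <- TRUE; break }
        if (min(d2) > 64) break                # drifting apart: re-orient
      }
      if (placed) break
    }
    if (!placed)
      stopf("could not dock a contact-rich interface; use a larger box or more residues")
    chains$B <- b
  }
  res <- do.call(rbind, lapply(names(chains), function(ch) {
    xyz <- chains[[ch]]
    cb <- .placeCb(xyz)
    cb[seqAA == "G", ] <- NA_real_
    data.frame(chain = ch, position = seq_len(n), resid = aa123(seqAA),
               aa = seqAA, ca.x = xyz[, 1], ca.y = xyz[, 2], ca.z = xyz[, 3],
               cb.x = cb[, 1], cb.y = cb[, 2], cb.z = cb[, 3],
               stringsAsFactors = FALSE)
  }))
  structureModel(res)
}

#' Generate a phenotype-labelled mutation set
#'
#' Sites are drawn from chain A with class-directional weights: with
#' positive class effects on "S_i" and "RASA", severe mutations come
#' preferentially from low-entropy (conserved), low-RASA (buried) sites and
#' control mutations from variable, exposed sites, with mild in between.
#' The ddG surrogate is a class-shifted Gaussian (control mean 0.5
#' kcal/mol, sd 1, severe shifted by classEffect["ddG"], mild halfway);
#' a conservation grade (1-9 entropy surrogate) is attached. With all
#' class effects zero the three classes are statistically exchangeable.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param struct structure from \code{\link{makeDimerStructure}}.
#' @param aln alignment from \code{\link{makeMsa}}.
#' @param siteFeatures optional precomputed data.frame (position, entropy,
#'   rasa) to avoid recomputation across repeated draws.
#' @return mutation data.frame (wt_aa, position, mut_aa, chain, phenotype,
#'   ddG, conservation).
#' @export
makeMutationSet <- function(spec, struct, aln, siteFeatures = NULL) {
  set.seed(childSeed(spec@seed, "mutations"))
  r <- struct@residues
  sites <- r[r$chain == r$chain[1], , drop = FALSE]
  if (is.null(siteFeatures)) {
    ent <- shannonEntropyProfile(aln)
    rasa <- computeRasa(struct)
    ras <- rasa$rasa[match(residueKey(sites$chain, sites$position),
                           residueKey(rasa$chain, rasa$position))]
    siteFeatures <- data.frame(position = sites$position,
                               entropy = ent[seq_len(nrow(sites))],
                               rasa = ras)
  }
  m <- match(sites$position, siteFeatures$position)
  zS <- scale(siteFeatures$entropy[m])[, 1]
  zR <- scale(siteFeatures$rasa[m])[, 1]
  zS[is.na(zS)] <- 0; zR[is.na(zR)] <- 0
  effS <- unname(spec@classEffect["S_i"] %|NA|% 0)
  effR <- unname(spec@classEffect["RASA"] %|NA|% 0)
  effG <- unname(spec@classEffect["ddG"] %|NA|% 0)
  nPer <- spec@nMutationsPerClass
  if (nPer > nrow(sites))
    stopf("only %d eligible sites for %d mutations per class",
          nrow(sites), nPer)
  grades <- conservationSurrogate(siteFeatures$entropy[m])
  used <- character(0)              # global mutation keys, kept unique
  out <- lapply(c(control = -1, mild = 0, severe = 1), function(s) {
    w <- exp(-s * (effS * zS + effR * zR) / 2)
    idx <- sample.int(nrow(sites), nPer, replace = FALSE, prob = w)
    sev01 <- (s + 1) / 2
    mut_aa <- character(nPer)
    for (k in seq_len(nPer)) {
      free <- character(0)
      for (try in 1:nrow(sites)) {
        cand <- setdiff(AA_ALPHABET20, sites$aa[idx[k]])
        free <- cand[!paste(sites$position[idx[k]], cand) %in% used]
        if (length(free)) break
        idx[k] <- sample.int(nrow(sites), 1L, prob = w)  # site exhausted
      }
      mut_aa[k] <- if (length(free) > 1L) sample(free, 1L) else free
      used <<- c(used, paste(sites$position[idx[k]], mut_aa[k]))
    }
    data.frame(wt_aa = sites$aa[idx], position = sites$position[idx],
               mut_aa = mut_aa, chain = sites$chain[idx],
               phenotype = NA_character_,
               ddG = stats::rnorm(nPer, mean = 0.5 + effG * sev01, sd = 1),
               conservation = as.numeric(grades[idx]),
               stringsAsFactors = FALSE)
  })
  for (ph in names(out)) out[[ph]]$phenotype <- ph
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# coalesce NA lookups from named vectors
`%|NA|%` <- function(a, b) if (length(a) != 1L || is.na(a)) b else a

#' Generate a feature table with prescribed class effects
#'
#' Distribution-level companion to \code{\link{makeMutationSet}}: each
#' feature is standard Gaussian per mutation plus its classEffect shift
#' scaled by severity (control 0, mild 0.5, severe 1). With all effects
#' zero the three classes are exchangeable -- the null for type-I
#' calibration; named effects make the designated features informative
#' for recovery experiments.
#'
#' @param spec a \linkS4class{SyntheticSpec}; classEffect entries are
#'   matched to feature names (unnamed features get no shift).
#' @param features feature columns to generate (default the full
#'   registered vocabulary).
#' @return \linkS4class{FeatureTable}
#' @export
makeFeatureTable <- function(spec, features = FEATURE_VOCABULARY) {
  set.seed(childSeed(spec@seed, "feature-table"))
  nPer <- spec@nMutationsPerClass
  n <- 3L * nPer
  sev01 <- rep(c(control = 0, mild = 0.5, severe = 1), each = nPer)
  muts <- data.frame(
    wt_aa = sample(AA_ALPHABET20, n, replace = TRUE),
    position = seq_len(n),
    mut_aa = NA_character_, chain = "A",
    phenotype = rep(PHENOTYPE_LEVELS, each = nPer),
    stringsAsFactors = FALSE)
  muts$mut_aa <- vapply(muts$wt_aa, function(a)
    sample(setdiff(AA_ALPHABET20, a), 1L), "")
  vals <- as.data.frame(lapply(stats::setNames(features, features),
    function(f) {
      eff <- spec@classEffect[f] %|NA|% 0
      stats::rnorm(n) + unname(eff) * sev01
    }))
  featureTable(muts, vals)
}

#' Sample a trajectory from elastic-network covariance
#'
#' Frames are the mean structure plus Gaussian displacements in mode
#' space: each nonzero mode k receives an independent N(0,
#' temperatureScale / lambda_k) amplitude per Cartesian axis (isotropic
#' GNM sampling), so the empirical per-residue mean-square fluctuation
#' converges to the analytic elastic-network profile as frames grow.
#' C-beta atoms ride rigidly with their C-alpha.
#'
#' @param spectrum a GNM \linkS4class{ModeSpectrum} of the structure.
#' @param struct the \linkS4class{StructureModel} providing mean
#'   coordinates.
#' @param nFrames number of frames (at least 2).
#' @param temperatureScale variance multiplier (0 gives identical frames).
#' @param seed integer seed.
#' @return \linkS4class{TrajectoryEnsemble}
#' @export
makeTrajectory <- function(spectrum, struct, nFrames, temperatureScale = 1,
                           seed = 1L) {
  if (nFrames < 2L) stopf("a trajectory needs at least 2 frames")
  if (temperatureScale < 0) stopf("temperatureScale must be nonnegative")
  set.seed(childSeed(seed, "trajectory"))
  r <- struct@residues
  n <- nrow(r)
  if (length(spectrum@values) != n)
    stopf("spectrum has %d modes but structure has %d residues",
          length(spectrum@values), n)
  keep <- setdiff(seq_len(n), spectrum@zeroModes)
  u <- spectrum@vectors[, keep, drop = FALSE]
  sd_k <- sqrt(temperatureScale / spectrum@values[keep])
  ca0 <- as.matrix(r[, c("ca.x", "ca.y", "ca.z")])
  cb0 <- as.matrix(r[, c("cb.x", "cb.y", "cb.z")])
  ca <- array(NA_real_, c(nFrames, n, 3))
  cb <- array(NA_real_, c(nFrames, n, 3))
  off <- cb0 - ca0
  for (f in seq_len(nFrames)) {
    disp <- vapply(1:3, function(axis)
      as.numeric(u %*% (stats::rnorm(length(keep)) * sd_k)), numeric(n))
    ca[f, , ] <- ca0 + disp
    cb[f, , ] <- ca[f, , ] + off
  }
  methods::new("TrajectoryEnsemble", ca = ca, cb = cb, residues = r,
               source = "synthetic")
}

#' Generate a contact-count table
#'
#' Observed counts are a multinomial sample of \code{nContacts} unordered
#' contacts over the 20 residue types plus solvent (class 0) under a
#' mixing model with marginal type probabilities \code{typeProbs} and
#' optional pairwise enrichment factors; reference counts follow the
#' random-mixing model with the marginals of the observed sample (so all
#' marginals are consistent by construction).
#'
#' @param seed integer seed.
#' @param nContacts total contacts (at least 1000).
#' @param typeProbs named probabilities over c("0", AA_ALPHABET20);
#'   default 25 percent solvent, the rest uniform.
#' @param enrichPairs optional data.frame (a, b, factor) multiplying the
#'   sampling probability of specific type pairs.
#' @param sampled logical; TRUE (default) draws a multinomial sample,
#'   FALSE stores the exact expected counts of the mixing model (useful
#'   for noise-free checks: without enrichment the observed counts are
#'   then exactly proportional to the reference and every contact energy
#'   is zero).
#' @return \linkS4class{ContactCountTable}
#' @export
makeCountTable <- function(seed, nContacts = 20000L, typeProbs = NULL,
                           enrichPairs = NULL, sampled = TRUE) {
  if (nContacts < 1000L) stopf("need at least 1000 contacts")
  set.seed(childSeed(seed, "counts"))
  classes <- c("0", AA_ALPHABET20)
  if (is.null(typeProbs))
    typeProbs <- stats::setNames(c(0.25, rep(0.75 / 20, 20)), classes)
  q <- typeProbs[classes]
  p <- outer(q, q)
  p[upper.tri(p)] <- 2 * p[upper.tri(p)]   # unordered pairs
  p[lower.tri(p)] <- 0
  if (!is.null(enrichPairs)) {
    for (k in seq_len(nrow(enrichPairs))) {
      i <- enrichPairs$a[k]; j <- enrichPairs$b[k]
      lo <- classes[pmin(match(i, classes), match(j, classes))]
      hi <- classes[pmax(match(i, classes), match(j, classes))]
      p[lo, hi] <- p[lo, hi] * enrichPairs$factor[k]
    }
  }
  p <- p / sum(p)
  if (sampled) {
    draw <- stats::rmultinom(1, nContacts, as.vector(p))[, 1]
    N <- matrix(draw, 21, 21, dimnames = list(classes, classes))
  } else {
    N <- matrix(nContacts * as.vector(p), 21, 21,
                dimnames = list(classes, classes))
  }
  N <- N + t(N) - diag(diag(N))
  # random-mixing reference with the observed marginals
  occ <- rowSums(N) + diag(N)              # each contact counts both ends
  x <- occ / sum(occ)
  C <- sum(N[upper.tri(N, diag = TRUE)]) * (2 * outer(x, x))
  diag(C) <- diag(C) / 2
  methods::new("ContactCountTable", observed = N, reference = C)
}
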