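# Elastic-network models and the five dynamics features.

test_that("Kirchhoff matrices follow the cutoff rule exactly", {
  st <- fixtureStructure(cbind(c(0, 5), 0, 0))
  k <- buildGnm(st, cutoff = 7)
  m <- k@mat; attributes(m) <- list(dim = dim(m))
  expect_equal(m, matrix(c(1, -1, -1, 1), 2))
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(ev), c(0, 2))

  # beyond the cutoff: zero matrix, both modes zero
  st2 <- fixtureStructure(cbind(c(0, 8), 0, 0))
  k2 <- suppressWarnings(buildGnm(st2, cutoff = 7))
  m2 <- k2@mat; attributes(m2) <- list(dim = dim(m2))
  expect_equal(m2, matrix(0, 2, 2))

  # row sums vanish on a real fixture
  spec <- syntheticSpec(seed = 2, nResiduesPerChain = 50, nChains = 1)
  k3 <- buildGnm(makeDimerStructure(spec))
  expect_equal(max(abs(rowSums(k3@mat))), 0)
})

test_that("ANM Hessian has the standard super-element structure", {
  # pair within cutoff: off-diagonal block is -gamma * rhat rhat^T
  st <- fixtureStructure(cbind(c(0, 3), c(0, 4), 0))
  h <- buildAnm(st, cutoff = 13, gamma = 2)
  rhat <- c(3, 4, 0) / 5
  expect_equal(h@mat[1:3, 4:6], -2 * tcrossprod(rhat))
  expect_equal(h@mat[1:3, 1:3], 2 * tcrossprod(rhat))

  # tetrahedral 4-residue fixture: 12 x 12 with exactly 6 zero modes
  xyz <- 3 * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  sp <- modeSpectrum(buildAnm(fixtureStructure(xyz)))
  expect_equal(dim(sp@vectors), c(12L, 12L))
  expect_length(zeroModes(sp), 6L)

  # rigid rotation leaves the spectrum untouched
  th <- 1.1
  rot <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  sp2 <- modeSpectrum(buildAnm(fixtureStructure(xyz %*% rot)))
  expect_equal(sp2@values, sp@values, tolerance = 1e-9)
})

test_that("zero-mode counts track connectivity", {
  spec <- syntheticSpec(seed = 8, nResiduesPerChain = 35, nChains = 1)
  st <- makeDimerStructure(spec)
  expect_length(zeroModes(modeSpectrum(buildGnm(st))), 1L)
  expect_length(zeroModes(modeSpectrum(buildAnm(st))), 6L)
  # two far-apart fragments: 2 GNM zero modes
  r <- residueTable(st)
  r2 <- r
  half <- seq_len(17)
  r2[-half, c("ca.x")] <- r2[-half, "ca.x"] + 500
  k <- suppressWarnings(buildGnm(structureModel(r2)))
  expect_length(zeroModes(modeSpectrum(k)), 2L)
})

test_that("MSF equals an independent pseudoinverse route", {
  spec <- syntheticSpec(seed = 5, nResiduesPerChain = 30, nChains = 1)
  st <- makeDimerStructure(spec)
  gnm <- buildGnm(st)
  sp <- modeSpectrum(gnm)
  m <- msf(sp)
  # deflation route: invert K + ones-projector, subtract projector
  k <- gnm@mat; attr(k, "components") <- NULL
  n <- nrow(k)
  pj <- matrix(1 / n, n, n)
  pinv <- solve(k + pj) - pj
  expect_equal(m, unname(3 * diag(pinv)), tolerance = 1e-8)
  # symmetric two-node system fluctuates symmetrically
  st2 <- fixtureStructure(cbind(c(0, 5), 0, 0))
  m2 <- msf(modeSpectrum(buildGnm(st2)))
  expect_equal(m2[1], m2[2])
})

test_that("adding a spring never increases total MSF", {
  for (s in 1:5) {
    spec <- syntheticSpec(seed = s, nResiduesPerChain = 25, nChains = 1)
    st <- makeDimerStructure(spec)
    gnm <- buildGnm(st)
    sp <- modeSpectrum(gnm)
    tot0 <- sum(msf(sp))
    mobile <- order(msf(sp), decreasing = TRUE)[1:2]
    k <- gnm@mat; attr(k, "components") <- NULL
    if (k[mobile[1], mobile[2]] == 0) {
      k[mobile[1], mobile[2]] <- k[mobile[2], mobile[1]] <- -1
      k[mobile[1], mobile[1]] <- k[mobile[1], mobile[1]] + 1
      k[mobile[2], mobile[2]] <- k[mobile[2], mobile[2]] + 1
      e <- eigen(k, symmetric = TRUE)
      keep <- e$values > 1e-8 * max(e$values)
      tot1 <- 3 * sum(rowSums(sweep(e$vectors[, keep, drop = FALSE]^2, 2,
                                    e$values[keep], "/")))
      expect_lte(tot1, tot0 + 1e-9)
    }
  }
})

test_that("PRS is self-normalized and symmetric systems are uniform", {
  xyz <- 3 * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  sp <- modeSpectrum(buildAnm(fixtureStructure(xyz)))
  p <- prs(sp)
  expect_equal(diag(p$matrix), rep(1, 4))
  # all four tetrahedron nodes are equivalent
  expect_equal(max(p$effectiveness) - min(p$effectiveness), 0,
               tolerance = 1e-9)
  expect_equal(max(p$sensitivity) - min(p$sensitivity), 0,
               tolerance = 1e-9)
})

test_that("PRS matches the explicit random-force oracle", {
  spec <- syntheticSpec(seed = 11, nResiduesPerChain = 20, nChains = 1)
  st <- makeDimerStructure(spec)
  sp <- modeSpectrum(buildAnm(st))
  p <- prs(sp)
  cov <- alloscan:::.covFromSpectrum(sp)
  n <- 20
  set.seed(99)
  relErr <- c()
  for (i in seq_len(n)) {
    resp <- matrix(0, 500, n)
    for (d in 1:500) {
      f <- rnorm(3); f <- f / sqrt(sum(f^2))
      dr <- cov[, (3 * i - 2):(3 * i)] %*% f
      resp[d, ] <- vapply(seq_len(n), function(j)
        sum(dr[(3 * j - 2):(3 * j)]^2), numeric(1))
    }
    mresp <- colMeans(resp)
    oracle <- mresp / mresp[i]
    relErr <- c(relErr, abs(oracle - p$matrix[i, ]) / pmax(oracle, 1e-12))
  }
  # aggregate agreement; per-entry deviations are Monte-Carlo limited
  expect_lt(mean(relErr), 0.02)
})

test_that("MBS ranks bridges above leaves with stated degenerate cases", {
  mb <- mechanicalBridgingScore(buildGnm(pathStructure(5), cutoff = 4))
  expect_gt(mb$MBS[3], mb$MBS[1])          # middle beats leaf on P5
  expect_true(all(mb$MBS >= 0))
  expect_true(mb$disconnects[3])           # middle is an articulation point

  # node with no springs scores 0
  r <- fixtureResidues(rbind(c(0, 0, 0), c(3.8, 0, 0), c(100, 0, 0)))
  k <- suppressWarnings(buildGnm(structureModel(r), cutoff = 7))
  mb2 <- mechanicalBridgingScore(k)
  expect_equal(mb2$MBS[3], 0)

  # complete graph: all nodes equivalent
  xyz <- 3 * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  mb3 <- mechanicalBridgingScore(buildGnm(fixtureStructure(xyz), cutoff = 10))
  expect_equal(max(mb3$MBS) - min(mb3$MBS), 0, tolerance = 1e-9)
})

test_that("stiffness recovers single-spring constants and scales linearly", {
  st <- fixtureStructure(cbind(c(0, 3.8), 0, 0))
  k1 <- suppressWarnings(stiffness(modeSpectrum(buildAnm(st, gamma = 1))))
  expect_equal(k1$matrix[1, 2], 1)
  k4 <- suppressWarnings(stiffness(modeSpectrum(buildAnm(st, gamma = 4))))
  expect_equal(k4$matrix[1, 2], 4)

  spec <- syntheticSpec(seed = 4, nResiduesPerChain = 20, nChains = 1)
  stx <- makeDimerStructure(spec)
  s1 <- stiffness(modeSpectrum(buildAnm(stx, gamma = 1)))
  s2 <- stiffness(modeSpectrum(buildAnm(stx, gamma = 2)))
  expect_equal(s2$matrix, 2 * s1$matrix, tolerance = 1e-9)
  expect_equal(max(abs(s1$matrix - t(s1$matrix)), na.rm = TRUE), 0,
               tolerance = 1e-9)
})

test_that("dynamics features are invariant to rigid motion and relabeling", {
  spec <- syntheticSpec(seed = 19, nResiduesPerChain = 20, nChains = 1)
  st <- makeDimerStructure(spec)
  r <- residueTable(st)
  th <- 0.9
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  r2 <- r
  r2[, c("ca.x", "ca.y", "ca.z")] <-
    as.matrix(r[, c("ca.x", "ca.y", "ca.z")]) %*% rot + 7
  st2 <- structureModel(r2)

  expect_equal(msf(modeSpectrum(buildGnm(st2))),
               msf(modeSpectrum(buildGnm(st))), tolerance = 1e-8)
  p1 <- prs(modeSpectrum(buildAnm(st)))
  p2 <- prs(modeSpectrum(buildAnm(st2)))
  expect_equal(p2$effectiveness, p1$effectiveness, tolerance = 1e-7)
  expect_equal(p2$sensitivity, p1$sensitivity, tolerance = 1e-7)
  k1 <- stiffness(modeSpectrum(buildAnm(st)))
  k2 <- stiffness(modeSpectrum(buildAnm(st2)))
  expect_equal(k2$perResidue, k1$perResidue, tolerance = 1e-7)

  # node relabeling permutes features coherently
  perm <- rev(seq_len(nrow(r)))
  r3 <- r[perm, ]
  r3$position <- r$position
  st3 <- structureModel(r3)
  expect_equal(msf(modeSpectrum(buildGnm(st3))),
               msf(modeSpectrum(buildGnm(st)))[perm], tolerance = 1e-8)
  mb1 <- mechanicalBridgingScore(buildGnm(st))
  mb3 <- mechanicalBridgingScore(buildGnm(st3))
  expect_equal(mb3$MBS, mb1$MBS[perm], tolerance = 1e-9)
})
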