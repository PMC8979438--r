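# RMSD/RMSF, dynamic residue networks, shortest paths.

# trajectory built directly from a list of coordinate matrices
fixtureTrajectory <- function(frames, aa = "A") {
  n <- nrow(frames[[1]])
  ca <- array(NA_real_, c(length(frames), n, 3))
  for (f in seq_along(frames)) ca[f, , ] <- frames[[f]]
  new("TrajectoryEnsemble", ca = ca, cb = ca + 1.0,
      residues = fixtureResidues(frames[[1]], aa = aa),
      source = "synthetic")
}

test_that("RMSD is zero for identical or rigidly rotated frames", {
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0), c(0, 3.8, 1))
  tr <- fixtureTrajectory(list(xyz, xyz, xyz))
  expect_equal(rmsdSeries(tr), rep(0, 3), tolerance = 1e-9)

  th <- pi / 2
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  tr2 <- fixtureTrajectory(list(xyz, xyz %*% rot + 3))
  expect_equal(rmsdSeries(tr2)[2], 0, tolerance = 1e-9)
})

test_that("RMSD matches an independent Kabsch oracle", {
  set.seed(5)
  a <- matrix(rnorm(12, sd = 4), 4, 3)
  for (trial in 1:10) {
    b <- a + matrix(rnorm(12, sd = 1), 4, 3)
    tr <- fixtureTrajectory(list(a, b))
    # the reference implementation reports 3 decimals
    expect_equal(rmsdSeries(tr)[2], oracleKabschRmsd(a, b),
                 tolerance = 1e-3)
  }
})

test_that("RMSF is zero without variance and delta-RMSF is a difference", {
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0))
  tr <- fixtureTrajectory(list(xyz, xyz, xyz))
  expect_equal(rmsfProfile(tr), rep(0, 3), tolerance = 1e-9)
  expect_equal(deltaRmsf(tr, tr), rep(0, 3), tolerance = 1e-9)
  expect_equal(deltaRmsf(c(1, 2, 3), c(0.5, 1, 1.5)), c(0.5, 1, 1.5))
  expect_error(deltaRmsf(c(1, 2), c(1, 2, 3)), "differ")
})

test_that("empirical RMSF converges to the analytic fluctuation profile", {
  spec <- syntheticSpec(seed = 5, nResiduesPerChain = 30, nChains = 1)
  st <- makeDimerStructure(spec)
  sp <- modeSpectrum(buildGnm(st))
  tr <- makeTrajectory(sp, st, nFrames = 1500, temperatureScale = 1,
                       seed = 2)
  expect_gt(cor(rmsfProfile(tr)^2, msf(sp)), 0.9)
})

test_that("DRN occupancies and frame graphs follow the distance rule", {
  # static trajectory: occupancies are 0 or 1 and frames agree
  xyz <- rbind(c(0, 0, 0), c(5, 0, 0), c(30, 0, 0))
  tr <- fixtureTrajectory(list(xyz, xyz), aa = "G")  # C-alpha nodes
  drn <- buildDrn(tr)
  expect_true(all(drn@occupancy %in% c(0, 1)))
  expect_identical(drn@frameEdges[[1]], drn@frameEdges[[2]])

  # pair crossing the cutoff in half the frames: occupancy 0.5, retained
  far <- xyz; far[2, 1] <- 7
  tr2 <- fixtureTrajectory(list(xyz, far), aa = "G")
  drn2 <- buildDrn(tr2, cutoff = 6.5, threshold = 0.5)
  expect_equal(drn2@occupancy[1, 2], 0.5)
  expect_true(igraph::are_adjacent(drn2@consensus, "A:1", "A:2"))

  # frame graphs equal the brute-force distance check
  spec <- syntheticSpec(seed = 9, nResiduesPerChain = 25, nChains = 1)
  st <- makeDimerStructure(spec)
  sp <- modeSpectrum(buildGnm(st))
  tr3 <- makeTrajectory(sp, st, nFrames = 5, temperatureScale = 0.5,
                        seed = 3)
  drn3 <- buildDrn(tr3)
  r <- residueTable(st)
  for (f in 1:5) {
    rep_ <- tr3@cb[f, , ]
    gly <- r$aa == "G"
    rep_[gly, ] <- tr3@ca[f, gly, ]
    d <- as.matrix(dist(rep_))
    want <- which(d <= 6.5 & upper.tri(d), arr.ind = TRUE)
    got <- drn3@frameEdges[[f]]
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 unname(want[order(want[, 1], want[, 2]), , drop = FALSE]))
  }
})

test_that("frame-averaged betweenness matches hand-computed means", {
  # single frame: equals static betweenness
  xyz <- rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0))
  tr <- fixtureTrajectory(list(xyz, xyz), aa = "G")
  drn <- buildDrn(tr)
  bc <- drnBetweenness(drn)
  stat <- centralities(drn@consensus)
  expect_equal(bc$BC, stat$BC)

  # path frame and star frame: mean of the two hand-derived vectors
  pathF <- rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0), c(15, 0, 0))
  starF <- rbind(c(0, 0, 0), c(5, 0, 0), c(5, 5, 0), c(5, -5, 0))
  # star: node 2 adjacent to all, others pairwise > 6.5 apart
  tr2 <- fixtureTrajectory(list(pathF, starF), aa = "G")
  drn2 <- buildDrn(tr2)
  bc2 <- drnBetweenness(drn2)
  bcPath <- c(0, 2 / 3, 2 / 3, 0)    # P4 interior nodes route 2 of 3 pairs
  bcStar <- c(0, 1, 0, 0)            # star centre routes all pairs
  expect_equal(bc2$BC, (bcPath + bcStar) / 2)

  # permuting frame order leaves the average unchanged
  tr3 <- fixtureTrajectory(list(starF, pathF), aa = "G")
  expect_equal(drnBetweenness(buildDrn(tr3))$BC, bc2$BC)
})

test_that("shortest paths: anchors, tie-break, unreachable targets", {
  xyz <- rbind(c(0, 0, 0), c(5, 0, 0), c(40, 0, 0))
  tr <- fixtureTrajectory(list(xyz, xyz), aa = "G")
  drn <- buildDrn(tr)
  p <- shortestPaths(drn, "A:1", "A:2")
  expect_equal(pathNodes(p[[1]]), c("A:1", "A:2"))
  expect_equal(p[[1]]@hops, 1L)
  expect_warning(p2 <- shortestPaths(drn, "A:1", "A:3"), "unreachable")
  expect_null(p2[[1]])

  # two equal-hop routes: lexicographically smaller node sequence wins
  g <- igraph::make_graph(~ s - m1, s - m2, m1 - t, m2 - t)
  p3 <- shortestPaths(g, "s", "t")
  expect_equal(pathNodes(p3[[1]]), c("s", "m1", "t"))
  p3b <- shortestPaths(g, "s", "t")
  expect_identical(pathNodes(p3[[1]]), pathNodes(p3b[[1]]))
})

test_that("Floyd-Warshall equals Dijkstra on random weighted graphs", {
  set.seed(31)
  for (trial in 1:100) {
    n <- sample(5:50, 1)
    adj <- randomAdjacency(n, runif(1, 0.1, 0.5))
    if (!any(adj)) next
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    wts <- runif(igraph::ecount(g), 0.1, 3)
    igraph::E(g)$weight <- wts
    w <- matrix(Inf, n, n)
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    w[ends] <- wts; w[ends[, 2:1, drop = FALSE]] <- wts
    diag(w) <- 0
    expect_equal(floydWarshall(w),
                 unname(igraph::distances(g, algorithm = "dijkstra")),
                 tolerance = 1e-12)
  }
})

test_that("every returned path length equals the distance-matrix entry", {
  spec <- syntheticSpec(seed = 23, nResiduesPerChain = 30)
  st <- makeDimerStructure(spec)
  sp <- modeSpectrum(buildGnm(st))
  tr <- makeTrajectory(sp, st, nFrames = 10, temperatureScale = 0.4,
                       seed = 6)
  drn <- buildDrn(tr)
  w <- alloscan:::.lengthMatrix(drn)
  d <- floydWarshall(w)
  keys <- rownames(w)
  src <- "A:1"
  paths <- suppressWarnings(
    shortestPaths(drn, src, keys[seq(5, 55, by = 10)]))
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (is.null(p)) next
    tgt <- sub(".*->", "", nm)
    expect_equal(p@hops, unname(d[src, tgt]))
    # consecutive nodes are edges of the consensus network
    for (i in seq_len(p@hops))
      expect_true(igraph::are_adjacent(drn@consensus, p@nodes[i],
                                       p@nodes[i + 1]))
  }
})

test_that("path comparison reports hop differences, sharing and domains", {
  mk <- function(nodes) new("PathResult", nodes = nodes,
                            hops = length(nodes) - 1L,
                            annotations = character(0), provenance = list())
  a <- list("s->t" = mk(sprintf("A:%d", 1:16)))
  b <- list("s->t" = mk(sprintf("A:%d", c(1:10, 12:16))))
  ann <- setNames(c("active", "active", "interface"),
                  c("A:2", "A:12", "A:15"))
  cmp <- pathCompare(a, b, ann)
  expect_equal(cmp$hop_diff, -1L)
  expect_equal(cmp$n_shared, length(intersect(a[[1]]@nodes, b[[1]]@nodes)))
  expect_equal(cmp$active_a, 2L)
  expect_equal(cmp$active_b, 2L)
  expect_equal(cmp$interface_a, 1L)

  same <- pathCompare(a, a)
  expect_equal(same$hop_diff, 0L)
  expect_equal(same$n_shared, 16L)

  tf <- tempfile(fileext = ".tsv")
  writePathTable(a, tf)
  back <- read.delim(tf)
  expect_equal(back$hops, 15L)
  expect_equal(strsplit(back$nodes, ";")[[1]], a[[1]]@nodes)
})
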