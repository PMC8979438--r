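# Contact energies, AACEN construction, centralities, mutation deltas.

test_that("contact energies follow the count-ratio formula", {
  # observed proportional to reference: all energies zero
  ct <- makeCountTable(1, sampled = FALSE)
  expect_equal(max(abs(contactEnergyFromCounts(ct))), 0, tolerance = 1e-9)

  # doubling one observed pair count, all else equal: e = -ln 2
  N <- ct@observed; C <- ct@reference
  N["A", "V"] <- N["V", "A"] <- 2 * N["A", "V"]
  # keep the solvent and marginal terms of the ratio unchanged
  ct2 <- new("ContactCountTable", observed = N, reference = C)
  expect_equal(contactEnergyFromCounts(ct2)["A", "V"], -log(2))

  # hand-coded evaluator on 10 random pairs of a sampled table
  ct3 <- makeCountTable(8, nContacts = 40000)
  e <- suppressWarnings(contactEnergyFromCounts(ct3))
  N <- ct3@observed; C <- ct3@reference
  set.seed(2)
  for (k in 1:10) {
    ij <- sample(AA_ALPHABET20, 2)
    i <- ij[1]; j <- ij[2]
    hand <- -log((N[i, j] * N["0", "0"] * C[i, "0"] * C[j, "0"]) /
                 (N[i, "0"] * N[j, "0"] * C[i, j] * C["0", "0"]))
    if (is.finite(hand)) expect_equal(e[i, j], hand)
  }

  # zero counts: undefined entries unless a pseudo-count is configured
  N0 <- ct3@observed; N0["W", ] <- N0[, "W"] <- 0
  ct4 <- new("ContactCountTable", observed = N0, reference = ct3@reference)
  expect_warning(e4 <- contactEnergyFromCounts(ct4), "undefined")
  expect_true(all(is.na(e4["W", ])))
  e5 <- contactEnergyFromCounts(ct4, pseudocount = 0.5)
  expect_true(all(is.finite(e5)))
})

test_that("AACEN contact rule: geometry, neighbours, interface", {
  en <- matrix(-1, 20, 20, dimnames = list(AA_ALPHABET20, AA_ALPHABET20))
  # 3 collinear residues 7 A apart with neighbour exclusion off: path graph
  st <- fixtureStructure(cbind(c(0, 7, 14), 0, 0))
  net <- buildAacen(st, en, list(cutoff = 8, representative = "ca",
                                 excludeNeighbors = 0L))
  g <- networkGraph(net)
  expect_equal(igraph::ecount(g), 2L)
  expect_true(igraph::are_adjacent(g, "A:1", "A:2"))
  expect_true(igraph::are_adjacent(g, "A:2", "A:3"))
  expect_false(igraph::are_adjacent(g, "A:1", "A:3"))

  # default rule excludes |i-j| <= 1 within a chain; with the remaining
  # pair beyond the cutoff the network is empty, which is an error
  expect_error(buildAacen(st, en, list(cutoff = 8, representative = "ca",
                                       excludeNeighbors = 1L)),
               "empty network")

  # dimer fixture: inter-chain edges exist at the generated interface
  spec <- syntheticSpec(seed = 6, nResiduesPerChain = 30)
  dimer <- makeDimerStructure(spec)
  netD <- buildAacen(dimer, en)
  ends <- igraph::as_data_frame(networkGraph(netD), "edges")
  chains <- cbind(sub(":.*", "", ends$from), sub(":.*", "", ends$to))
  expect_gt(sum(chains[, 1] != chains[, 2]), 0L)
})

test_that("AACEN edge set equals the brute-force distance oracle", {
  spec <- syntheticSpec(seed = 10, nResiduesPerChain = 50, nChains = 1)
  st <- makeDimerStructure(spec)
  en <- matrix(-0.5, 20, 20, dimnames = list(AA_ALPHABET20, AA_ALPHABET20))
  net <- buildAacen(st, en)
  r <- residueTable(st)
  # oracle: representative C-beta (C-alpha for Gly), all-pairs distances
  rep_ <- as.matrix(r[, c("cb.x", "cb.y", "cb.z")])
  gly <- r$aa == "G"
  rep_[gly, ] <- as.matrix(r[gly, c("ca.x", "ca.y", "ca.z")])
  want <- character(0)
  for (i in 1:(nrow(r) - 1)) for (j in (i + 1):nrow(r)) {
    if (abs(r$position[i] - r$position[j]) <= 1) next
    if (sqrt(sum((rep_[i, ] - rep_[j, ])^2)) <= 8)
      want <- c(want, paste(i, j))
  }
  ends <- igraph::ends(networkGraph(net), igraph::E(networkGraph(net)),
                       names = FALSE)
  got <- paste(pmin(ends[, 1], ends[, 2]), pmax(ends[, 1], ends[, 2]))
  expect_setequal(got, want)
})

test_that("network build is invariant to rotation and translation", {
  spec <- syntheticSpec(seed = 12, nResiduesPerChain = 25, nChains = 1)
  st <- makeDimerStructure(spec)
  en <- matrix(-1, 20, 20, dimnames = list(AA_ALPHABET20, AA_ALPHABET20))
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  r <- residueTable(st)
  ca <- as.matrix(r[, c("ca.x", "ca.y", "ca.z")]) %*% rot + 5
  cb <- as.matrix(r[, c("cb.x", "cb.y", "cb.z")]) %*% rot + 5
  r2 <- r
  r2[, c("ca.x", "ca.y", "ca.z")] <- ca
  r2[, c("cb.x", "cb.y", "cb.z")] <- cb
  n1 <- buildAacen(st, en)
  n2 <- buildAacen(structureModel(r2), en)
  expect_identical(igraph::as_edgelist(networkGraph(n1)),
                   igraph::as_edgelist(networkGraph(n2)))
})

test_that("centralities match closed-form anchors", {
  # path P3: middle node carries the single routed pair
  adj <- matrix(FALSE, 3, 3); adj[1, 2] <- adj[2, 3] <- TRUE
  adj <- adj | t(adj)
  c3 <- centralities(adjacencyNetwork(adj))
  expect_equal(c3$BC, c(0, 1, 0))
  # complete K4: everything saturates
  k4 <- matrix(TRUE, 4, 4); diag(k4) <- FALSE
  c4 <- centralities(adjacencyNetwork(k4))
  expect_equal(c4$CC, rep(1, 4))
  expect_equal(c4$C, rep(1, 4))
  expect_equal(c4$DC, rep(3, 4))
})

test_that("centralities equal the exhaustive enumeration oracle", {
  set.seed(42)
  for (trial in 1:100) {
    n <- sample(4:10, 1)
    adj <- randomAdjacency(n, p = runif(1, 0.25, 0.7))
    got <- centralities(adjacencyNetwork(adj))
    want <- oracleCentralities(adj)
    expect_equal(got$DC, want$DC)
    expect_equal(got$BC, want$BC, tolerance = 1e-12)
    expect_equal(got$CC, want$CC, tolerance = 1e-12)
    expect_equal(got$C, want$C, tolerance = 1e-12)
    expect_equal(got$componentSize, want$componentSize)
  }
})

test_that("raw betweenness mass equals total intermediate traversals", {
  # conservation: summing unnormalized BC over nodes counts every
  # shortest path's interior nodes once (split across ties)
  set.seed(7)
  for (trial in 1:20) {
    n <- sample(5:9, 1)
    adj <- randomAdjacency(n, 0.45)
    want <- oracleCentralities(adj)
    g <- adjacencyNetwork(adj)
    raw <- igraph::betweenness(g, weights = NA, directed = FALSE)
    expect_equal(sum(raw), sum(want$BCraw), tolerance = 1e-9)
  }
})

test_that("type-swap mutations behave as specified", {
  spec <- syntheticSpec(seed = 14, nResiduesPerChain = 30, nChains = 1)
  st <- makeDimerStructure(spec)
  r <- residueTable(st)
  site <- which(r$aa != "G")[5]
  # two residue types with identical energy rows: swapping is a no-op
  en <- matrix(-1, 20, 20, dimnames = list(AA_ALPHABET20, AA_ALPHABET20))
  mut <- data.frame(wt_aa = r$aa[site], position = r$position[site],
                    mut_aa = setdiff(AA_ALPHABET20,
                                     c(r$aa[site], "G"))[1],
                    chain = "A", phenotype = "mild",
                    stringsAsFactors = FALSE)
  wt <- buildAacen(st, en)
  m1 <- mutateNetwork(st, mut, en, wtNet = wt)
  expect_equal(igraph::E(m1@graph)$weight, igraph::E(wt@graph)$weight)

  # strictly larger |e| on the mutant type: weighted degree increases
  en2 <- en
  en2[mut$mut_aa, ] <- en2[, mut$mut_aa] <- -3
  wt2 <- buildAacen(st, en2)
  m2 <- mutateNetwork(st, mut, en2, wtNet = wt2)
  cw <- centralities(wt2, weighted = TRUE)
  cm <- centralities(m2, weighted = TRUE)
  key <- paste0("A:", r$position[site])
  if (en2[mut$wt_aa, mut$wt_aa] != -3)  # wt row differs from mutant row
    expect_gt(cm$DC[cm$key == key], cw$DC[cw$key == key])

  # proxy equals a provided mutant structure with identical coordinates
  r3 <- r
  r3$aa[site] <- mut$mut_aa
  r3$resid[site] <- c(A = "ALA", V = "VAL", C = "CYS")[mut$mut_aa]
  m3 <- mutateNetwork(st, mut, en2, mutantStruct = structureModel(r3))
  expect_equal(sort(igraph::E(m3@graph)$weight),
               sort(igraph::E(m2@graph)$weight))
})

test_that("delta centralities are signed differences at the site", {
  adj <- matrix(FALSE, 4, 4)
  adj[1, 2] <- adj[2, 3] <- adj[3, 4] <- TRUE
  adj <- adj | t(adj)
  a <- centralities(adjacencyNetwork(adj))
  expect_equal(unname(deltaCentrality(a, a, "A:2")$signed),
               rep(0, 4))
  # adding one edge at the site raises its degree by exactly 1
  adj2 <- adj; adj2[2, 4] <- adj2[4, 2] <- TRUE
  b <- centralities(adjacencyNetwork(adj2))
  expect_equal(unname(deltaCentrality(a, b, "A:2")$signed["dDC"]), 1)
  expect_error(deltaCentrality(a, b, "A:99"), "absent")
  l1 <- deltaCentralityL1(a, b)
  expect_equal(unname(l1["dDC_L1"]), sum(abs(b$DC - a$DC)))
})

test_that("edge lists export and read back", {
  spec <- syntheticSpec(seed = 3, nResiduesPerChain = 22, nChains = 1)
  st <- makeDimerStructure(spec)
  en <- matrix(-1, 20, 20, dimnames = list(AA_ALPHABET20, AA_ALPHABET20))
  net <- buildAacen(st, en)
  tf <- tempfile(fileext = ".tsv")
  writeEdgeList(net, tf)
  back <- read.delim(tf)
  expect_equal(nrow(back), igraph::ecount(networkGraph(net)))
  expect_named(back, c("node_a", "node_b", "weight"))
})
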