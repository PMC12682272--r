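test_that("shared-ortholog matrix cross-tabulates correctly", {
  hm <- sharedOrthologMatrix(two_block_table(10L))
  C <- homologyCounts(hm)
  expect_equal(unname(C), matrix(c(10L, 0L, 0L, 10L), 2, 2))
  expect_equal(sum(C), 20L)
  one <- sharedOrthologMatrix(syntenyTable("og1", "A", 1, "B", 1))
  expect_equal(dim(homologyCounts(one)), c(1L, 1L))
  # simulator construction: FUSE(A,B) -> S gives C[A,S]=nA, C[B,S]=nB
  anc <- makeAncestor(2, 10)
  fused <- applyEvent(anc, karyoEvent("FUSE", c("anc01", "anc02")))$genome
  hm2 <- sharedOrthologMatrix(emitObserved(anc, fused, 1, seed = 1))
  expect_equal(unname(homologyCounts(hm2)[, "anc01+anc02"]), c(10L, 10L))
})

test_that("one-sided Fisher p-values match the worked hypergeometric values", {
  hm <- sharedOrthologMatrix(two_block_table(10L))
  expect_equal(fisherAssociation(hm, "A1", "B1"), 1 / choose(20, 10),
               tolerance = 1e-12)
  flat <- homologyMatrix(matrix(5L, 2, 2,
                                dimnames = list(c("A1", "A2"),
                                                c("B1", "B2"))))
  expect_equal(fisherAssociation(flat, 1, 1), brute_fisher_tail(5, 10, 10, 20),
               tolerance = 1e-12)
  expect_equal(round(fisherAssociation(flat, 1, 1), 4), 0.6719)
  # a = 0 with positive margins: the whole support, p = 1
  z <- homologyMatrix(matrix(c(0L, 5L, 5L, 0L), 2, 2,
                             dimnames = list(c("A1", "A2"),
                                             c("B1", "B2"))))
  expect_equal(fisherAssociation(z, 1, 1), 1)
  expect_error(fisherAssociation(homologyMatrix(matrix(0L, 1, 1,
    dimnames = list("A", "B"))), 1, 1), "positive grand total")
})

test_that("Fisher tail agrees with brute-force enumeration on random tables", {
  set.seed(5)
  for (i in 1:200) {
    N <- sample(2:40, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    support <- seq.int(max(0, K + n - N), min(K, n))
    a <- support[sample.int(length(support), 1)]
    C <- matrix(c(a, K - a, n - a, N - K - n + a), 2, 2,
                dimnames = list(c("r1", "r2"), c("c1", "c2")))
    hm <- homologyMatrix(C)
    expect_equal(fisherAssociation(hm, 1, 1), brute_fisher_tail(a, K, n, N),
                 tolerance = 1e-12)
  }
})

test_that("Bonferroni adjustment is capped, monotone arithmetic", {
  expect_equal(bonferroniAdjust(0.001, 46), 0.046)
  expect_equal(bonferroniAdjust(0.5, 10), 1)
  expect_equal(bonferroniAdjust(c(0.2, 0.9), 1), c(0.2, 0.9))
  expect_error(bonferroniAdjust(1.2, 3), "0, 1")
})

test_that("significant homologies form the expected bipartite graph", {
  hm <- testHomologies(sharedOrthologMatrix(two_block_table(10L)))
  g <- significantHomologies(hm, alpha = 0.05)
  expect_equal(nrow(graphEdges(g)), 2L)
  expect_setequal(paste(graphEdges(g)$scaffold_a, graphEdges(g)$scaffold_b),
                  c("A1 B1", "A2 B2"))
  expect_equal(nrow(graphEdges(significantHomologies(hm, alpha = 0))), 0L)
})

test_that("chromosome fates follow the simulator's ground truth", {
  anc <- makeAncestor(4, 30)
  g1 <- applyEvent(anc, karyoEvent("FUSE_MIX", c("anc01", "anc02"), m = 1),
                   seed = 2)$genome
  g2 <- applyEvent(g1, karyoEvent("FISSION", "anc03", index = 15))$genome
  graph <- significantHomologies(testHomologies(
    sharedOrthologMatrix(emitObserved(anc, g2, 1, seed = 3))))
  expect_equal(chromosomeFate(graph, "anc01")@fate, "fused")
  expect_true("anc01+anc02" %in% chromosomeFate(graph, "anc02")@partners)
  expect_equal(chromosomeFate(graph, "anc03")@fate, "split")
  expect_equal(chromosomeFate(graph, "anc04")@fate, "one_to_one")
  expect_error(chromosomeFate(graph, "anc99"), "not in the graph")
})

test_that("fate calls are invariant to scaffold relabeling", {
  sc <- fwm_scenario(nMix = 3L, k = 8L, g = 25L, seed = 9L)
  tab <- emitObserved(sc$ancestor, sc$genome, 1, seed = 1)
  fates <- chromosomeFates(significantHomologies(testHomologies(
    sharedOrthologMatrix(tab))))
  # permute the query scaffold names and recompute
  df <- syntenyRows(tab)
  ids <- unique(df$scaffold_b)
  remap <- stats::setNames(sprintf("Q%02d", seq_along(ids)), sample(ids))
  tab2 <- syntenyTable(df$ortholog, df$scaffold_a, df$pos_a,
                       remap[df$scaffold_b], df$pos_b)
  fates2 <- chromosomeFates(significantHomologies(testHomologies(
    sharedOrthologMatrix(tab2))))
  expect_equal(fates$fate[order(fates$scaffold)],
               fates2$fate[order(fates2$scaffold)])
})

test_that("contig co-occurrence test detects joint presence", {
  # 10 contigs carry both refs, 10 carry neither (a third ref instead)
  tab <- syntenyTable(
    ortholog = sprintf("og%02d", 1:40),
    scaffoldA = c(rep(c("r1", "r2"), 10), rep("r3", 20)),
    posA = rep(seq_len(20) * 50, 2),
    scaffoldB = c(rep(sprintf("c%02d", 1:10), each = 2),
                  rep(sprintf("c%02d", 11:20), each = 2)),
    posB = rep(c(100, 200), 20))
  expect_equal(cooccurrenceFwmTest(tab, "r1", "r2"), 1 / choose(20, 10),
               tolerance = 1e-12)
  # perfectly segregated contigs: no co-occurrence, p = 1
  seg <- syntenyTable(
    ortholog = sprintf("og%02d", 1:20),
    scaffoldA = rep(c("r1", "r2"), each = 10),
    posA = rep(seq_len(10) * 50, 2),
    scaffoldB = rep(c("cA", "cB"), each = 10),
    posB = rep(seq_len(10) * 50, 2))
  expect_equal(cooccurrenceFwmTest(seg, "r1", "r2"), 1)
  expect_error(cooccurrenceFwmTest(seg, "r1", "r9"), "absent")
})

test_that("mixed fusions are detected on fragmented assemblies", {
  # FUSE_MIX(r1, r2), fragment into ~20-gene contigs: p < 0.05 nearly always
  hits <- 0L
  for (seed in 1:20) {
    sc <- fwm_scenario(nMix = 1L, k = 4L, g = 100L, seed = seed)
    frag <- fragmentGenome(sc$genome, fragmentationProfile(20), seed = seed)
    tab <- filterScaffolds(emitObserved(sc$ancestor, frag, 1, seed = seed),
                           minGenes = 15)
    p <- cooccurrenceFwmTest(tab, sc$truth$a[1], sc$truth$b[1])
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits, 19L)
})

test_that("fusion counting matches the simulated scenario", {
  sc <- fwm_scenario(nMix = 5L, k = 12L, g = 60L, seed = 3L)
  graph <- significantHomologies(testHomologies(sharedOrthologMatrix(
    filterScaffolds(emitObserved(sc$ancestor, sc$genome, 1, seed = 1), 15))))
  cf <- countFused(graph, "chromosome")
  expect_equal(cf$nFused, 10L)
  expect_equal(cf$nUnfused, 2L)
  expect_equal(cf$total, 12L)
  pairs <- unique(cf$fusedPairs[, c("ref1", "ref2")])
  expect_setequal(paste(pairs$ref1, pairs$ref2),
                  paste(sc$truth$a, sc$truth$b))
  # no events: nothing fused
  anc <- makeAncestor(5, 30)
  g0 <- significantHomologies(testHomologies(sharedOrthologMatrix(
    emitObserved(anc, anc, 1, seed = 2))))
  expect_equal(countFused(g0, "chromosome")$nFused, 0L)
})

test_that("mixed/sharp classification uses the inclusive Q1 boundary", {
  q <- c(0.105, 0.209)
  expect_equal(classifyFusedPair(0.081, q), "sharp")
  expect_equal(classifyFusedPair(0.193, q), "mixed")
  expect_equal(classifyFusedPair(0.105, q), "mixed")   # exactly Q1
  expect_error(classifyFusedPair(0.1, c(0.3, 0.2)), "Q1")
})
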