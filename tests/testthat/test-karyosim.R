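test_that("ancestor construction honors counts and degenerate sizes", {
  anc <- makeAncestor(46, 100)
  expect_length(genomeScaffolds(anc), 46L)
  expect_length(geneAncestry(anc), 4600L)
  expect_identical(makeAncestor(46, 100), anc)   # deterministic
  tiny <- makeAncestor(1, 1)
  expect_equal(lengths(genomeScaffolds(tiny)), c(anc01 = 1L))
  expect_error(makeAncestor(0, 10), "k")
})

test_that("sharp fusion concatenates with a single label change-point", {
  anc <- makeAncestor(2, 10)
  fused <- applyEvent(anc, karyoEvent("FUSE", c("anc01", "anc02")))$genome
  expect_length(genomeScaffolds(fused), 1L)
  lab <- scaffoldLabels(fused, "anc01+anc02")@labels
  expect_equal(lab, rep(c("anc01", "anc02"), each = 10L))
  expect_equal(sum(lab[-1] != lab[-length(lab)]), 1L)
})

test_that("fusion-with-mixing conserves the label multiset", {
  anc <- makeAncestor(2, 10)
  res <- applyEvent(anc, karyoEvent("FUSE_MIX", c("anc01", "anc02"), m = 1),
                    seed = 5)
  lab <- scaffoldLabels(res$genome, "anc01+anc02")@labels
  expect_equal(as.integer(table(lab)[c("anc01", "anc02")]), c(10L, 10L))
})

test_that("event error contracts: unknown scaffolds and bad indices", {
  anc <- makeAncestor(3, 10)
  expect_error(applyEvent(anc, karyoEvent("FUSE", c("anc01", "nope"))),
               "unknown scaffold")
  expect_error(applyEvent(anc, karyoEvent("FISSION", "anc01", index = 10)),
               "out of range")
  expect_error(karyoEvent("FUSE_MIX", c("a", "b"), m = 2), "m must lie")
})

test_that("LOSS at rate 0 is the identity; at rate r it is binomial", {
  anc <- makeAncestor(4, 50)
  same <- applyEvent(anc, karyoEvent("LOSS", rate = 0), seed = 1)$genome
  expect_identical(genomeScaffolds(same), genomeScaffolds(anc))
  set.seed(99)
  losses <- vapply(1:40, function(i) {
    g <- applyEvent(anc, karyoEvent("LOSS", rate = 0.3))$genome
    200L - sum(lengths(genomeScaffolds(g)))
  }, integer(1))
  # mean 60, sd sqrt(200*.3*.7) ~ 6.5; mean of 40 reps within 4 sd
  expect_gt(mean(losses), 60 - 4 * 6.5 / sqrt(40))
  expect_lt(mean(losses), 60 + 4 * 6.5 / sqrt(40))
})

test_that("gene counts are conserved by all events except LOSS", {
  set.seed(7)
  anc <- makeAncestor(4, 30)
  events <- list(karyoEvent("FUSE", c("anc01", "anc02")),
                 karyoEvent("FUSE_MIX", c("anc03", "anc04"), m = 0.5),
                 karyoEvent("FISSION", "anc01+anc02", index = 25),
                 karyoEvent("TRANSLOCATE", c("anc03+anc04", "anc01+anc02.1"),
                            start = 3, width = 7, at = 0),
                 karyoEvent("INTRA_SHUFFLE", "anc01+anc02.2"))
  g <- anc
  for (e in events) {
    g <- applyEvent(g, e)$genome
    expect_equal(sum(lengths(genomeScaffolds(g))), 120L)
  }
  # ancestral labels immutable through the whole sequence
  expect_identical(geneAncestry(g), geneAncestry(anc))
})

test_that("full mixing yields the expected number of label change-points", {
  # random arrangement of 100+100: E[change-points] = 2*nA*nB/(nA+nB) = 100
  anc <- makeAncestor(2, 100)
  set.seed(31)
  cps <- vapply(1:50, function(i) {
    g <- applyEvent(anc, karyoEvent("FUSE_MIX", c("anc01", "anc02"),
                                    m = 1))$genome
    lab <- scaffoldLabels(g, "anc01+anc02")@labels
    sum(lab[-1] != lab[-length(lab)])
  }, integer(1))
  expect_lt(abs(mean(cps) - 100), 5)
})

test_that("mixing intensity is a monotone dial on change-points", {
  anc <- makeAncestor(2, 100)
  set.seed(13)
  mean_cp <- vapply(c(0, 0.25, 0.5, 1), function(m) {
    mean(vapply(1:20, function(i) {
      ev <- if (m == 0) karyoEvent("FUSE", c("anc01", "anc02"))
            else karyoEvent("FUSE_MIX", c("anc01", "anc02"), m = m)
      lab <- scaffoldLabels(applyEvent(anc, ev)$genome,
                            "anc01+anc02")@labels
      sum(lab[-1] != lab[-length(lab)])
    }, integer(1)))
  }, numeric(1))
  expect_true(all(diff(mean_cp) > 0))
})

test_that("evolution is reproducible and bookkeeps scaffold counts", {
  anc <- makeAncestor(46, 10)
  same <- evolveKaryotype(anc, list(), seed = 3)
  expect_identical(genomeScaffolds(same$genome), genomeScaffolds(anc))
  sc <- fwm_scenario(nMix = 20L, k = 46L, g = 10L, seed = 4L)
  expect_length(genomeScaffolds(sc$genome), 26L)   # 46 - 20 fusions
  expect_equal(nrow(sc$truth), 20L)
  sc2 <- fwm_scenario(nMix = 20L, k = 46L, g = 10L, seed = 4L)
  expect_identical(genomeScaffolds(sc$genome), genomeScaffolds(sc2$genome))
})

test_that("emitObserved yields a valid table with the expected row counts", {
  anc <- makeAncestor(46, 100)
  full <- emitObserved(anc, anc, retention = 1, seed = 1)
  expect_equal(length(full), 4600L)
  half1 <- emitObserved(anc, anc, retention = 0.5, seed = 2)
  half2 <- emitObserved(anc, anc, retention = 0.5, seed = 2)
  expect_identical(syntenyRows(half1), syntenyRows(half2))  # reproducible
  # within 5 sd of Binomial(4600, 0.5)
  expect_lt(abs(length(half1) - 2300), 5 * sqrt(4600 * 0.25))
  # table round-trips through the .psynt reader, i.e. ranks are dense
  p <- tempfile(fileext = ".psynt")
  writePsynt(half1, p)
  expect_equal(length(readPsynt(p)), length(half1))
  other <- makeAncestor(3, 5, prefix = "oth")
  expect_error(emitObserved(anc, other, 1), "share no gene")
})

test_that("fragmentation follows the profile and is exactly invertible", {
  g30 <- makeAncestor(1, 30)
  f <- fragmentGenome(g30, fragmentationProfile(10), seed = 1)
  expect_equal(unname(lengths(genomeScaffolds(f))), c(10L, 10L, 10L))
  g25 <- makeAncestor(1, 25)
  f25 <- fragmentGenome(g25, fragmentationProfile(10), seed = 1)
  expect_equal(unname(lengths(genomeScaffolds(f25))), c(10L, 10L, 5L))
  expect_identical(genomeScaffolds(unfragmentGenome(f25)),
                   genomeScaffolds(g25))
  expect_error(fragmentationProfile(integer(0)), "non-empty")
  # unfragment o fragment is the identity on random genomes and profiles
  for (seed in 1:10) {
    sc <- fwm_scenario(nMix = 3L, k = 8L, g = 40L, seed = seed)
    fr <- fragmentGenome(sc$genome, fragmentationProfile(5:25), seed = seed)
    expect_identical(genomeScaffolds(unfragmentGenome(fr)),
                     genomeScaffolds(sc$genome))
  }
})
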