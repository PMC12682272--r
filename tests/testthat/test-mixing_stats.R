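test_that("bigint arithmetic is exact through large doublings", {
  x <- karyofuse:::big_from_int(1)
  for (i in 1:1000) x <- karyofuse:::big_double(x)
  expect_equal(karyofuse:::big_log2(x), 1000)        # x = 2^1000, exactly
  y <- karyofuse:::big_sub(x, karyofuse:::big_from_int(1))
  expect_equal(karyofuse:::big_cmp(y, x), -1L)
  expect_equal(karyofuse:::big_cmp(karyofuse:::big_add(
    y, karyofuse:::big_from_int(1)), x), 0L)
  # small-value oracle against plain arithmetic
  set.seed(3)
  for (i in 1:50) {
    a <- sample(1e6, 1); b <- sample(a, 1)
    A <- karyofuse:::big_from_int(a); B <- karyofuse:::big_from_int(b)
    expect_equal(karyofuse:::big_as_numeric(karyofuse:::big_add(A, B)), a + b)
    expect_equal(karyofuse:::big_as_numeric(karyofuse:::big_sub(A, B)), a - b)
  }
})

test_that("label sequences read a query scaffold in rank order", {
  tab <- syntenyTable(
    ortholog = sprintf("og%d", 1:6),
    scaffoldA = c("Dpe08", "Dpe08", "Dpe09", "Dpe09", "Dpe29", "Dpe29"),
    posA = seq_len(6) * 10,
    scaffoldB = rep("Ovu22", 6),
    posB = c(10, 20, 30, 40, 50, 60))
  seq <- labelSequence(tab, "Ovu22")
  expect_equal(seq@labels, c("Dpe08", "Dpe08", "Dpe09", "Dpe09",
                             "Dpe29", "Dpe29"))
  restr <- labelSequence(tab, "Ovu22", restrictLabels = c("Dpe08", "Dpe09"))
  expect_equal(restr@labels, rep(c("Dpe08", "Dpe09"), each = 2))
  single <- syntenyTable("og1", "A", 1, "B", 1)
  expect_length(labelSequence(single, "B")@labels, 1L)
  expect_error(labelSequence(tab, "nope"), "absent")
  expect_error(labelSequence(tab, "Ovu22", restrictLabels = "Dpe99"),
               "no informative genes")
})

test_that("run-length spells compress adjacent repeats", {
  expect_equal(dssEncode(c("A", "A", "B", "B")),
               list(states = c("A", "B"), durations = c(2L, 2L)))
  expect_equal(dssEncode(c("A", "B", "A", "B"))$durations, rep(1L, 4))
  expect_equal(dssEncode(rep("A", 4)), list(states = "A", durations = 4L))
})

test_that("distinct-subsequence DP matches worked values and enumeration", {
  num <- function(s) karyofuse:::big_as_numeric(countDistinctSubsequences(s))
  expect_equal(num(character(0)), 1)             # only the empty subsequence
  expect_equal(num(c("A", "B")), 4)              # e, A, B, AB
  expect_equal(num(c("A", "B", "A")), 7)         # brute force: 7 distinct
  set.seed(8)
  for (i in 1:100) {
    s <- sample(LETTERS[1:3], sample(1:12, 1), replace = TRUE)
    expect_equal(num(s), brute_subseq_count(s))
  }
})

test_that("turbulence reproduces the worked composites", {
  expect_equal(turbulence(rep("A", 4))@turbulence, 1)
  tb <- turbulence(c("A", "A", "B", "B"))
  expect_equal(tb@d, 2L)
  expect_equal(tb@s2, 0)
  expect_equal(tb@s2max, 1)
  expect_equal(tb@turbulence, 3)
  expect_equal(turbulence(c("A", "B", "A", "B"))@turbulence, log2(12))
})

test_that("normalized turbulence hits its endpoints and worked value", {
  expect_equal(normalizedTurbulence(rep("A", 4)), 0)
  expect_equal(normalizedTurbulence(c("A", "B", "A", "B")), 1)
  expect_equal(normalizedTurbulence(c("A", "A", "B", "B")),
               (3 - 1) / (log2(12) - 1))
  # pluggable normalization strategy
  raw <- normalizedTurbulence(c("A", "A", "B", "B"),
                              normalization = function(T, labels) T)
  expect_equal(raw, 3)
})

test_that("normalized turbulence stays within [0, 1] on random sequences", {
  set.seed(19)
  for (i in 1:200) {
    s <- sample(LETTERS[1:sample(1:3, 1)], sample(1:40, 1), replace = TRUE)
    v <- normalizedTurbulence(s)
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("no precision loss in phi at long sequence lengths", {
  # alternating length 10000: phi exceeds double range; log2 stays finite
  s <- rep(c("A", "B"), 5000)
  tb <- turbulence(s)
  expect_true(is.finite(tb@log2Phi))
  expect_gt(tb@log2Phi, 1024)        # beyond double overflow, still exact
  expect_equal(normalizedTurbulence(s), 1)
})

test_that("pairwise mixing is symmetric and separates sharp from mixed", {
  anc <- makeAncestor(4, 100)
  g <- applyEvent(anc, karyoEvent("FUSE", c("anc01", "anc02")))$genome
  g <- applyEvent(g, karyoEvent("FUSE_MIX", c("anc03", "anc04"), m = 1),
                  seed = 4)$genome
  tab <- emitObserved(anc, g, 1, seed = 5)
  sharp <- pairwiseMixing(tab, "anc01+anc02", "anc01", "anc02")
  sharp_swapped <- pairwiseMixing(tab, "anc01+anc02", "anc02", "anc01")
  expect_equal(sharp, sharp_swapped)
  mixed <- pairwiseMixing(tab, "anc03+anc04", "anc03", "anc04")
  expect_lt(sharp, mixed)
  expect_equal(sharp, 0.1027, tolerance = 0.01)  # sharp 100+100 regime
  expect_error(pairwiseMixing(tab, "anc01+anc02", "anc01", "anc03"),
               "contributes no gene")
})

test_that("mean mixing increases monotonically with mixing intensity", {
  anc <- makeAncestor(2, 100)
  set.seed(23)
  means <- vapply(c(0, 0.25, 0.5, 1), function(m) {
    mean(vapply(1:50, function(i) {
      ev <- if (m == 0) karyoEvent("FUSE", c("anc01", "anc02"))
            else karyoEvent("FUSE_MIX", c("anc01", "anc02"), m = m)
      g <- applyEvent(anc, ev)$genome
      normalizedTurbulence(scaffoldLabels(g, "anc01+anc02"))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("fused-pair quartiles use linear order-statistic interpolation", {
  expect_equal(fusedPairQuartiles(1:8), c(Q1 = 2.75, Q3 = 6.25))
  expect_equal(fusedPairQuartiles(rep(0.3, 6)), c(Q1 = 0.3, Q3 = 0.3))
  set.seed(2)
  v <- runif(11)
  expect_equal(fusedPairQuartiles(v), fusedPairQuartiles(sample(v)))
  expect_error(fusedPairQuartiles(c(0.1, 0.2, 0.3)), "at least 4")
})
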