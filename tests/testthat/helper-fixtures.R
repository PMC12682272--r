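# Fixtures are built in code; no binary files.

# 2*nPer orthologs in two clean diagonal blocks (A1~B1, A2~B2)
two_block_table <- function(nPer = 10L) {
  syntenyTable(ortholog = sprintf("og%02d", seq_len(2L * nPer)),
               scaffoldA = rep(c("A1", "A2"), each = nPer),
               posA = rep(seq_len(nPer) * 1000, 2L),
               scaffoldB = rep(c("B1", "B2"), each = nPer),
               posB = rep(seq_len(nPer) * 1000, 2L))
}

random_synteny_table <- function(nGenes = 30L, nScafA = 3L, nScafB = 4L) {
  syntenyTable(ortholog = sprintf("og%03d", seq_len(nGenes)),
               scaffoldA = sample(sprintf("A%d", seq_len(nScafA)), nGenes,
                                  replace = TRUE),
               posA = sample(1e6, nGenes),
               scaffoldB = sample(sprintf("B%d", seq_len(nScafB)), nGenes,
                                  replace = TRUE),
               posB = sample(1e6, nGenes))
}

# independent oracle: grow the actual set of distinct subsequence strings
brute_subseq_count <- function(chars) {
  S <- ""
  for (ch in chars) S <- unique(c(S, paste0(S, ch)))
  length(S)
}

# independent oracle: hypergeometric tail P(X >= a) from exact choose()
brute_fisher_tail <- function(a, K, n, N) {
  x <- seq.int(max(0, K + n - N), min(K, n))
  terms <- choose(K, x) * choose(N - K, n - x) / choose(N, n)
  sum(terms[x >= a])
}

# an ancestor plus a descendant shaped by sharp and/or mixing fusions
fwm_scenario <- function(nMix = 20L, nSharp = 0L, k = 46L, g = 100L,
                         seed = 1L) {
  anc <- makeAncestor(k, g)
  ids <- names(genomeScaffolds(anc))
  ev <- list()
  used <- 0L
  for (i in seq_len(nSharp)) {
    ev[[length(ev) + 1L]] <- karyoEvent("FUSE", ids[used + 1:2])
    used <- used + 2L
  }
  for (i in seq_len(nMix)) {
    ev[[length(ev) + 1L]] <- karyoEvent("FUSE_MIX", ids[used + 1:2], m = 1)
    used <- used + 2L
  }
  res <- evolveKaryotype(anc, ev, seed = seed)
  list(ancestor = anc, genome = res$genome, log = res$log,
       truth = fusedPairsFromLog(res$log))
}

write_gff3_fixture <- function(path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t10\t.\t+\t.\tID=g1",
               "chr1\tsrc\tgene\t101\t200\t.\t-\t.\tID=g2",
               "chr2\tsrc\tgene\t51\t80\t.\t+\t.\tID=g3",
               "chr1\tsrc\texon\t1\t5\t.\t+\t.\tID=g1.e1"),
             path)
  path
}

write_bed_fixture <- function(path = tempfile(fileext = ".bed")) {
  writeLines(c("chr2\t500\t600\tgB\t0\t-",
               "chr1\t0\t10\tgA\t0\t+"),
             path)
  path
}

# miniprot-style mapping GFF: 3 placements of 2 peptides
write_mapping_fixture <- function(path = tempfile(fileext = ".gff")) {
  writeLines(c("##gff-version 3",
               "scafX\tminiprot\tmRNA\t1001\t2000\t500\t+\t.\tID=MP1;Target=pep1 1 100;Identity=0.97",
               "scafY\tminiprot\tmRNA\t51\t950\t120\t-\t.\tID=MP2;Target=pep1 1 100;Identity=0.61",
               "scafX\tminiprot\tmRNA\t3001\t3900\t444\t-\t.\tID=MP3;Target=pep2 1 90;Identity=0.88"),
             path)
  path
}
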