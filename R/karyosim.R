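# Karyotype-evolution simulator.
#
# Simulates descent of multi-chromosome genomes from a shared ancestor
# under fusion (sharp or with mixing), fission, inter-chromosomal
# translocation, intra-chromosomal shuffling and ortholog loss, plus
# draft-assembly fragmentation. Gene identity and order are simulated, not
# nucleotides: downstream statistics are order statistics. Every gene
# carries an immutable ancestral chromosome label, the ground truth that
# recovery tests score against.

#' Create an ancestral genome
#'
#' Builds a genome of `k` chromosomes, each carrying `genesPerChrom` genes
#' in order; every gene's ancestral label is its own chromosome.
#' Construction is deterministic.
#'
#' @param k chromosome count (the modeled clade's ancestral karyotype has
#'   about 46).
#' @param genesPerChrom genes per chromosome.
#' @param prefix scaffold id prefix.
#' @return A [SimGenome-class].
#' @export
makeAncestor <- function(k = 46L, genesPerChrom = 100L, prefix = "anc") {
  k <- assert_count(k, "k")
  genesPerChrom <- assert_count(genesPerChrom, "genesPerChrom")
  ids <- sprintf("%s%02d", prefix, seq_len(k))
  scaffolds <- lapply(ids, function(s)
    sprintf("%s_g%04d", s, seq_len(genesPerChrom)))
  names(scaffolds) <- ids
  genes <- unlist(scaffolds, use.names = FALSE)
  ancestry <- rep(ids, each = genesPerChrom)
  names(ancestry) <- genes
  new("SimGenome", scaffolds = scaffolds, ancestry = ancestry)
}

check_participants <- function(genome, ids) {
  missing <- setdiff(ids, names(genome@scaffolds))
  if (length(missing))
    stop("unknown scaffold(s): ", paste(missing, collapse = ", "))
}

# Mixing operator: relocate ceiling(m*n) randomly chosen genes to uniform
# random positions (m = 1 draws a full uniform permutation). Relocation is
# non-local, modelling intrachromosomal translocations, and gives a
# monotone dial from the sharp concatenation (m = 0) to full mixing: the
# spell count grows with m from the start, unlike a local
# adjacent-transposition walk whose boundary diffusion can transiently
# lower the turbulence composite below the sharp-fusion value.
mix_order <- function(genes, m) {
  n <- length(genes)
  if (n < 2L || m <= 0) return(genes)
  if (m >= 1) return(genes[sample.int(n)])
  movers <- sample.int(n, ceiling(m * n))
  moved <- genes[movers]
  rest <- genes[-movers]
  for (g in moved) {
    at <- sample.int(length(rest) + 1L, 1L) - 1L
    rest <- append(rest, g, after = at)
  }
  rest
}

#' Apply one karyotype event to a genome
#'
#' Event semantics:
#' \describe{
#'   \item{FUSE}{concatenate two scaffolds with a sharp boundary.}
#'   \item{FUSE_MIX}{concatenate, then mix gene order with intensity
#'     `m` in \[0,1\]: `m = 1` draws a uniform random permutation;
#'     `m < 1` relocates `ceiling(m*n)` randomly chosen genes to uniform
#'     random positions (`n` = merged length), emulating intrachromosomal
#'     translocations.}
#'   \item{FISSION}{split one scaffold after gene `index` (random if
#'     unspecified).}
#'   \item{TRANSLOCATE}{move a contiguous segment (`start`, `width`) from
#'     one scaffold into another at position `at`; random if unspecified.}
#'   \item{INTRA_SHUFFLE}{uniformly permute gene order within a scaffold.}
#'   \item{LOSS}{delete each gene independently with probability `rate`.}
#' }
#' Gene counts are conserved by all events except LOSS; ancestral labels
#' never change.
#'
#' @param genome a [SimGenome-class].
#' @param event a [KaryoEvent-class].
#' @param seed optional integer; if given, the event runs under its own
#'   local RNG stream.
#' @return list with elements `genome` (the derived [SimGenome-class]) and
#'   `realized` (the event's parameters with random choices filled in).
#' @export
applyEvent <- function(genome, event, seed = NULL) {
  stopifnot(is(genome, "SimGenome"), is(event, "KaryoEvent"))
  with_seed(seed, {
    scaf <- genome@scaffolds
    p <- event@params
    realized <- p
    switch(event@type,
      FUSE = ,
      FUSE_MIX = {
        ab <- event@participants
        if (length(ab) != 2L) stop("fusion needs exactly two participants")
        check_participants(genome, ab)
        merged <- c(scaf[[ab[1]]], scaf[[ab[2]]])
        if (event@type == "FUSE_MIX") {
          m <- if (is.null(p$m)) 1 else p$m
          merged <- mix_order(merged, m)
          realized$m <- m
        }
        new_id <- paste(ab, collapse = "+")
        keep <- setdiff(names(scaf), ab)
        scaf <- c(scaf[keep], stats::setNames(list(merged), new_id))
        realized$result <- new_id
      },
      FISSION = {
        a <- event@participants[1]
        check_participants(genome, a)
        n <- length(scaf[[a]])
        if (n < 2L) stop("cannot split a scaffold of fewer than 2 genes")
        idx <- p$index
        if (is.null(idx)) idx <- sample.int(n - 1L, 1L)
        if (idx < 1L || idx > n - 1L)
          stop(sprintf("fission index %d out of range 1..%d for '%s'",
                       idx, n - 1L, a))
        parts <- list(scaf[[a]][seq_len(idx)], scaf[[a]][seq.int(idx + 1L, n)])
        ids <- paste0(a, c(".1", ".2"))
        scaf <- c(scaf[setdiff(names(scaf), a)],
                  stats::setNames(parts, ids))
        realized$index <- idx
        realized$result <- ids
      },
      TRANSLOCATE = {
        ft <- event@participants
        if (length(ft) != 2L) stop("translocation needs donor and recipient")
        check_participants(genome, ft)
        donor <- scaf[[ft[1]]]; recip <- scaf[[ft[2]]]
        n <- length(donor)
        width <- p$width
        if (is.null(width)) width <- sample.int(max(n - 1L, 1L), 1L)
        if (width < 1L || width > n)
          stop("translocated segment width out of range")
        start <- p$start
        if (is.null(start)) start <- sample.int(n - width + 1L, 1L)
        if (start < 1L || start + width - 1L > n)
          stop("translocated segment exceeds donor scaffold")
        at <- p$at
        if (is.null(at)) at <- sample.int(length(recip) + 1L, 1L) - 1L
        if (at < 0L || at > length(recip))
          stop("insertion point out of range")
        seg <- donor[seq.int(start, start + width - 1L)]
        donor <- donor[-seq.int(start, start + width - 1L)]
        recip <- append(recip, seg, after = at)
        scaf[[ft[1]]] <- donor
        scaf[[ft[2]]] <- recip
        if (length(donor) == 0L) scaf[[ft[1]]] <- NULL
        realized$start <- start; realized$width <- width; realized$at <- at
      },
      INTRA_SHUFFLE = {
        a <- event@participants[1]
        check_participants(genome, a)
        scaf[[a]] <- scaf[[a]][sample.int(length(scaf[[a]]))]
      },
      LOSS = {
        rate <- if (is.null(p$rate)) stop("LOSS requires a 'rate'") else p$rate
        targets <- if (length(event@participants)) {
          check_participants(genome, event@participants)
          event@participants
        } else names(scaf)
        for (s in targets) {
          keep <- stats::runif(length(scaf[[s]])) >= rate
          scaf[[s]] <- scaf[[s]][keep]
        }
        scaf <- scaf[lengths(scaf) > 0L]
        realized$rate <- rate
      },
      stop("unknown event type: ", event@type))
    list(genome = new("SimGenome", scaffolds = scaf,
                      ancestry = genome@ancestry),
         realized = realized)
  })
}

#' Evolve a genome through an ordered scenario of events
#'
#' Seeds a single RNG stream once and applies the events in order, so a
#' fixed seed reproduces the descendant and the log bit-for-bit.
#'
#' @param ancestor a [SimGenome-class].
#' @param events list of [KaryoEvent-class] objects, applied in order.
#' @param seed optional integer seed for the whole scenario.
#' @return list with `genome` (the descendant) and `log` (one entry per
#'   event: type, participants, realized parameters).
#' @export
evolveKaryotype <- function(ancestor, events, seed = NULL) {
  stopifnot(is(ancestor, "SimGenome"))
  with_seed(seed, {
    genome <- ancestor
    log <- vector("list", length(events))
    for (i in seq_along(events)) {
      res <- applyEvent(genome, events[[i]])
      genome <- res$genome
      log[[i]] <- list(step = i, type = events[[i]]@type,
                       participants = events[[i]]@participants,
                       realized = res$realized)
    }
    list(genome = genome, log = log)
  })
}

#' Ancestral-chromosome pairs fused by a scenario log
#'
#' Extracts the participant pairs of all FUSE / FUSE_MIX events from an
#' [evolveKaryotype()] log, as ground truth for fusion-recovery tests.
#'
#' @param log the `log` element returned by [evolveKaryotype()].
#' @return data.frame with columns `a`, `b` (sorted within a row), `mixed`.
#' @export
fusedPairsFromLog <- function(log) {
  fused <- Filter(function(e) e$type %in% c("FUSE", "FUSE_MIX"), log)
  if (!length(fused))
    return(data.frame(a = character(), b = character(), mixed = logical()))
  pairs <- t(vapply(fused, function(e) sort(e$participants), character(2)))
  data.frame(a = pairs[, 1], b = pairs[, 2],
             mixed = vapply(fused, function(e) e$type == "FUSE_MIX",
                            logical(1)),
             stringsAsFactors = FALSE)
}

#' Ancestral labels along one scaffold
#' @param genome a [SimGenome-class].
#' @param scaffold scaffold id.
#' @return A [LabelSequence-class] of that scaffold's ancestral labels.
#' @export
scaffoldLabels <- function(genome, scaffold) {
  stopifnot(is(genome, "SimGenome"))
  check_participants(genome, scaffold)
  genes <- genome@scaffolds[[scaffold]]
  labelSeq(unname(genome@ancestry[genes]), scaffold = scaffold)
}

#' Emit an observed synteny table from two simulated genomes
#'
#' Bridges the simulator to the analysis pipeline: genes shared between the
#' two genomes become mutual-best orthologs, each retained independently
#' with probability `retention` (modelling incomplete orthology recovery).
#' Positions are synthesized from gene order at a fixed spacing, since
#' downstream statistics use only order.
#'
#' @param genomeA,genomeB [SimGenome-class] objects descending from one
#'   ancestor (sharing gene ids).
#' @param retention per-gene retention probability in (0, 1].
#' @param seed optional integer seed.
#' @param spacing synthetic inter-gene spacing in bp.
#' @return A [SyntenyTable-class].
#' @export
emitObserved <- function(genomeA, genomeB, retention = 1, seed = NULL,
                         spacing = 10000) {
  stopifnot(is(genomeA, "SimGenome"), is(genomeB, "SimGenome"))
  assert_scalar_number(retention, "retention", lower = 1e-9, upper = 1)
  gene_index <- function(g) {
    sc <- rep(names(g@scaffolds), lengths(g@scaffolds))
    idx <- unlist(lapply(g@scaffolds, seq_along), use.names = FALSE)
    genes <- unlist(g@scaffolds, use.names = FALSE)
    data.frame(gene = genes, scaffold = sc, idx = idx,
               stringsAsFactors = FALSE)
  }
  ia <- gene_index(genomeA); ib <- gene_index(genomeB)
  shared <- intersect(ia$gene, ib$gene)
  if (length(shared) == 0L)
    stop("genomes share no gene ids; they must descend from one ancestor")
  with_seed(seed, {
    keep <- shared[stats::runif(length(shared)) <= retention]
    ia <- ia[match(keep, ia$gene), , drop = FALSE]
    ib <- ib[match(keep, ib$gene), , drop = FALSE]
    syntenyTable(ortholog = keep,
                 scaffoldA = ia$scaffold, posA = ia$idx * spacing,
                 scaffoldB = ib$scaffold, posB = ib$idx * spacing)
  })
}

#' Validate a genes-per-contig fragmentation profile
#'
#' A fragmentation profile is an empirical multiset of genes-per-contig
#' counts (all >= 1), e.g. measured from a draft assembly, from which
#' [fragmentGenome()] draws contig sizes with replacement.
#'
#' @param counts positive integer vector.
#' @return validated integer vector.
#' @export
fragmentationProfile <- function(counts) {
  if (length(counts) == 0L) stop("fragmentation profile must be non-empty")
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != floor(counts)))
    stop("fragmentation profile counts must be positive integers")
  as.integer(counts)
}

#' Fragment a chromosome-level genome into draft-like contigs
#'
#' Cuts each scaffold's ordered gene list into consecutive blocks whose
#' sizes are drawn with replacement from the profile (the last block is
#' truncated to fit). Fragment ids record the parent scaffold and block
#' index, so [unfragmentGenome()] is an exact inverse.
#'
#' @param genome a [SimGenome-class].
#' @param profile a [fragmentationProfile()] vector.
#' @param seed optional integer seed.
#' @return the fragmented [SimGenome-class].
#' @export
fragmentGenome <- function(genome, profile, seed = NULL) {
  stopifnot(is(genome, "SimGenome"))
  profile <- fragmentationProfile(profile)
  with_seed(seed, {
    frags <- list()
    for (s in names(genome@scaffolds)) {
      genes <- genome@scaffolds[[s]]
      n <- length(genes)
      sizes <- integer(0)
      while (sum(sizes) < n)
        sizes <- c(sizes, profile[sample.int(length(profile), 1L)])
      sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
      ends <- cumsum(sizes)
      starts <- c(1L, utils::head(ends, -1L) + 1L)
      ids <- sprintf("%s|f%03d", s, seq_along(sizes))
      blocks <- Map(function(a, b) genes[seq.int(a, b)], starts, ends)
      names(blocks) <- ids
      frags <- c(frags, blocks)
    }
    new("SimGenome", scaffolds = frags, ancestry = genome@ancestry)
  })
}

#' Reassemble a fragmented genome
#'
#' Inverse of [fragmentGenome()]: concatenates fragments of each parent
#' scaffold in block order.
#'
#' @param genome a fragmented [SimGenome-class].
#' @return the reassembled [SimGenome-class].
#' @export
unfragmentGenome <- function(genome) {
  stopifnot(is(genome, "SimGenome"))
  ids <- names(genome@scaffolds)
  parent <- sub("\\|f[0-9]+$", "", ids)
  parents <- unique(parent)     # preserve original scaffold order
  scaf <- lapply(parents, function(p) {
    fids <- sort(ids[parent == p])
    unlist(genome@scaffolds[fids], use.names = FALSE)
  })
  names(scaf) <- parents
  new("SimGenome", scaffolds = scaf, ancestry = genome@ancestry)
}
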