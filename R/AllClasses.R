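PSYNT_COLUMNS <- c("ortholog", "scaffold_a", "pos_a", "rank_a",
                   "scaffold_b", "pos_b", "rank_b")

EVENT_TYPES <- c("FUSE", "FUSE_MIX", "FISSION", "TRANSLOCATE",
                 "INTRA_SHUFFLE", "LOSS")

FATE_LEVELS <- c("one_to_one", "fused", "split", "complex", "unplaced")

# -- SyntenyTable ----------------------------------------------------------

#' SyntenyTable: mutual-best orthologs placed in two genomes
#'
#' One row per mutual-best ortholog, holding its scaffold, position
#' (base-pair midpoint) and ordinal gene rank in each of two genomes.
#' Ranks are dense 0-based indices within each scaffold, obtained by
#' sorting on position with ties broken by ortholog id. This is the
#' in-memory form of a `.psynt` file (see [readPsynt()]).
#'
#' @slot rows data.frame with columns `ortholog`, `scaffold_a`, `pos_a`,
#'   `rank_a`, `scaffold_b`, `pos_b`, `rank_b`.
#' @export
setClass("SyntenyTable", representation(rows = "data.frame"))

validate_dense_ranks <- function(scaffold, rank, side) {
  bad <- vapply(split(rank, scaffold), function(r) {
    !identical(sort(as.integer(r)), seq.int(0L, length(r) - 1L))
  }, logical(1))
  if (any(bad))
    return(sprintf("ranks on side %s are not dense 0..(k-1) for scaffold(s): %s",
                   side, paste(names(bad)[bad], collapse = ", ")))
  NULL
}

setValidity("SyntenyTable", function(object) {
  df <- object@rows
  if (!identical(colnames(df), PSYNT_COLUMNS))
    return(paste("rows must have columns:", paste(PSYNT_COLUMNS, collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  dup <- duplicated(df$ortholog)
  if (any(dup))
    return(paste("duplicate ortholog id(s):",
                 paste(unique(df$ortholog[dup]), collapse = ", ")))
  msg <- c(validate_dense_ranks(df$scaffold_a, df$rank_a, "a"),
           validate_dense_ranks(df$scaffold_b, df$rank_b, "b"))
  if (length(msg)) msg else TRUE
})

#' Construct a SyntenyTable
#'
#' Ranks are (re)computed densely per scaffold from positions, with ties
#' broken lexicographically by ortholog id, so the input needs only the
#' ortholog ids, scaffolds and positions.
#'
#' @param ortholog character vector of ortholog ids (unique).
#' @param scaffoldA,scaffoldB scaffold ids in genomes A and B.
#' @param posA,posB numeric positions (bp midpoints).
#' @return A [SyntenyTable-class] object.
#' @export
syntenyTable <- function(ortholog, scaffoldA, posA, scaffoldB, posB) {
  df <- data.frame(ortholog = as.character(ortholog),
                   scaffold_a = as.character(scaffoldA),
                   pos_a = as.numeric(posA),
                   rank_a = NA_integer_,
                   scaffold_b = as.character(scaffoldB),
                   pos_b = as.numeric(posB),
                   rank_b = NA_integer_,
                   stringsAsFactors = FALSE)
  df <- recompute_ranks(df)
  new("SyntenyTable", rows = df)
}

recompute_ranks <- function(df) {
  rank_within <- function(scaffold, pos, id) {
    r <- integer(length(pos))
    for (s in split(seq_along(pos), scaffold)) {
      r[s[order(pos[s], id[s])]] <- seq.int(0L, length(s) - 1L)
    }
    r
  }
  df$rank_a <- rank_within(df$scaffold_a, df$pos_a, df$ortholog)
  df$rank_b <- rank_within(df$scaffold_b, df$pos_b, df$ortholog)
  df
}

#' @describeIn SyntenyTable-class number of ortholog rows.
#' @param x,object a `SyntenyTable`.
#' @export
setMethod("length", "SyntenyTable", function(x) nrow(x@rows))

#' Rows of a SyntenyTable as a data.frame
#' @param x a [SyntenyTable-class].
#' @return data.frame with the seven `.psynt` columns.
#' @export
syntenyRows <- function(x) {
  stopifnot(is(x, "SyntenyTable"))
  x@rows
}

#' Scaffold ids present on one side of a SyntenyTable
#' @param x a [SyntenyTable-class].
#' @param side `"a"` or `"b"`.
#' @return character vector of scaffold ids, sorted.
#' @export
scaffoldIds <- function(x, side = c("a", "b")) {
  side <- match.arg(side)
  col <- if (side == "a") "scaffold_a" else "scaffold_b"
  sort(unique(syntenyRows(x)[[col]]))
}

setMethod("show", "SyntenyTable", function(object) {
  df <- object@rows
  cat(sprintf("SyntenyTable: %d orthologs, %d scaffolds (A) x %d scaffolds (B)\n",
              nrow(df), length(unique(df$scaffold_a)),
              length(unique(df$scaffold_b))))
  if (nrow(df)) {
    print(utils::head(df, 4L))
    if (nrow(df) > 4L) cat("...\n")
  }
})

# -- HomologyMatrix --------------------------------------------------------

#' HomologyMatrix: shared-ortholog counts per scaffold pair
#'
#' Cross-tabulation of a [SyntenyTable-class]: `counts[i, j]` is the number
#' of mutual-best orthologs sitting on scaffold i of genome A and scaffold
#' j of genome B. [testHomologies()] fills the per-cell one-sided Fisher
#' p-values and their Bonferroni adjustment.
#'
#' @slot counts integer matrix, dimnames = scaffold ids.
#' @slot pRaw,pAdj numeric matrices of raw/adjusted p-values (0x0 until
#'   [testHomologies()] is called).
#' @slot mTests integer, number of cells over which Bonferroni corrected.
#' @export
setClass("HomologyMatrix",
         representation(counts = "matrix", pRaw = "matrix", pAdj = "matrix",
                        mTests = "integer"))

setValidity("HomologyMatrix", function(object) {
  C <- object@counts
  if (is.null(rownames(C)) || is.null(colnames(C)))
    return("counts must carry scaffold ids as dimnames")
  if (any(C < 0)) return("counts must be non-negative")
  if (length(object@pRaw)) {
    if (!identical(dim(object@pRaw), dim(C)) ||
        !identical(dim(object@pAdj), dim(C)))
      return("p-value matrices must match counts in shape")
    if (any(object@pRaw < 0 | object@pRaw > 1, na.rm = TRUE) ||
        any(object@pAdj < 0 | object@pAdj > 1, na.rm = TRUE))
      return("p-values must lie in [0, 1]")
    if (any(object@pAdj < object@pRaw - 1e-12, na.rm = TRUE))
      return("adjusted p-values cannot be smaller than raw ones")
  }
  TRUE
})

#' Construct a HomologyMatrix from a count matrix
#' @param counts non-negative matrix with scaffold ids as dimnames.
#' @return A [HomologyMatrix-class].
#' @export
homologyMatrix <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  new("HomologyMatrix", counts = counts,
      pRaw = matrix(numeric(0), 0, 0), pAdj = matrix(numeric(0), 0, 0),
      mTests = NA_integer_)
}

#' Shared-ortholog count matrix of a HomologyMatrix
#' @param x a [HomologyMatrix-class].
#' @export
homologyCounts <- function(x) {
  stopifnot(is(x, "HomologyMatrix"))
  x@counts
}

#' Adjusted p-value matrix (after [testHomologies()])
#' @param x a [HomologyMatrix-class].
#' @export
pAdjusted <- function(x) {
  stopifnot(is(x, "HomologyMatrix"))
  if (!length(x@pAdj)) stop("run testHomologies() first")
  x@pAdj
}

setMethod("show", "HomologyMatrix", function(object) {
  C <- object@counts
  cat(sprintf("HomologyMatrix: %d x %d scaffolds, N = %d orthologs\n",
              nrow(C), ncol(C), sum(C)))
  cat(if (length(object@pAdj))
    sprintf("  Fisher tests done (Bonferroni m = %d)\n", object@mTests)
    else "  p-values not yet computed\n")
})

# -- AssociationGraph ------------------------------------------------------

#' AssociationGraph: significant chromosome homologies
#'
#' Bipartite graph between scaffolds of two genomes; an edge means the
#' Bonferroni-adjusted one-sided Fisher p-value of their shared-ortholog
#' count fell below alpha.
#'
#' @slot scaffoldsA,scaffoldsB all scaffold ids on each side (so that
#'   degree-0 scaffolds remain representable).
#' @slot edges data.frame with columns `scaffold_a`, `scaffold_b`,
#'   `shared`, `p_adj`.
#' @slot alpha the significance threshold used.
#' @export
setClass("AssociationGraph",
         representation(scaffoldsA = "character", scaffoldsB = "character",
                        edges = "data.frame", alpha = "numeric"))

setValidity("AssociationGraph", function(object) {
  e <- object@edges
  need <- c("scaffold_a", "scaffold_b", "shared", "p_adj")
  if (!all(need %in% colnames(e)))
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  if (nrow(e) &&
      (!all(e$scaffold_a %in% object@scaffoldsA) ||
       !all(e$scaffold_b %in% object@scaffoldsB)))
    return("edge endpoints must be listed scaffolds")
  TRUE
})

setMethod("show", "AssociationGraph", function(object) {
  cat(sprintf("AssociationGraph: %d + %d scaffolds, %d edges at alpha = %g\n",
              length(object@scaffoldsA), length(object@scaffoldsB),
              nrow(object@edges), object@alpha))
})

#' Edge list of an AssociationGraph
#' @param x an [AssociationGraph-class].
#' @export
graphEdges <- function(x) {
  stopifnot(is(x, "AssociationGraph"))
  x@edges
}

# -- FateCall --------------------------------------------------------------

#' FateCall: the inferred fate of one reference chromosome
#'
#' @slot scaffold the reference scaffold id.
#' @slot fate one of `one_to_one`, `fused`, `split`, `complex`, `unplaced`.
#' @slot partners the significantly associated scaffolds on the other side.
#' @slot pAdj adjusted p-values supporting the partner edges.
#' @export
setClass("FateCall",
         representation(scaffold = "character", fate = "character",
                        partners = "character", pAdj = "numeric"))

setValidity("FateCall", function(object) {
  if (!object@fate %in% FATE_LEVELS)
    return(paste("fate must be one of:", paste(FATE_LEVELS, collapse = ", ")))
  TRUE
})

setMethod("show", "FateCall", function(object) {
  cat(sprintf("FateCall: %s -> %s", object@scaffold, object@fate))
  if (length(object@partners))
    cat(" [", paste(object@partners, collapse = ", "), "]", sep = "")
  cat("\n")
})

# -- SimGenome and events --------------------------------------------------

#' SimGenome: a simulated multi-chromosome genome
#'
#' Gene content and order only (no nucleotide sequence): an ordered list of
#' scaffolds, each an ordered vector of gene ids, plus the immutable map
#' from every gene to its ancestral chromosome label. The ancestry map is
#' the ground truth against which fusion/mixing inference is scored.
#'
#' @slot scaffolds named list; each element a character vector of gene ids
#'   in gene order along that scaffold.
#' @slot ancestry named character; `ancestry[gene]` = ancestral chromosome.
#' @export
setClass("SimGenome",
         representation(scaffolds = "list", ancestry = "character"))

setValidity("SimGenome", function(object) {
  genes <- unlist(object@scaffolds, use.names = FALSE)
  if (is.null(names(object@scaffolds)) || any(!nzchar(names(object@scaffolds))))
    return("scaffolds must be named")
  if (anyDuplicated(names(object@scaffolds)))
    return("scaffold ids must be unique")
  if (anyDuplicated(genes)) return("gene ids must be unique genome-wide")
  if (!all(genes %in% names(object@ancestry)))
    return("every gene must carry an ancestral label")
  TRUE
})

setMethod("show", "SimGenome", function(object) {
  ng <- lengths(object@scaffolds)
  cat(sprintf("SimGenome: %d scaffolds, %d genes, %d ancestral labels\n",
              length(ng), sum(ng),
              length(unique(object@ancestry[unlist(object@scaffolds,
                                                   use.names = FALSE)]))))
})

#' Scaffold gene lists of a SimGenome
#' @param x a [SimGenome-class].
#' @export
genomeScaffolds <- function(x) {
  stopifnot(is(x, "SimGenome"))
  x@scaffolds
}

#' Ancestral chromosome labels of a SimGenome
#' @param x a [SimGenome-class].
#' @return named character vector, gene id -> ancestral chromosome label.
#' @export
geneAncestry <- function(x) {
  stopifnot(is(x, "SimGenome"))
  x@ancestry
}

#' KaryoEvent: one karyotype-evolution event
#'
#' @slot type one of FUSE, FUSE_MIX, FISSION, TRANSLOCATE, INTRA_SHUFFLE,
#'   LOSS.
#' @slot participants scaffold ids the event acts on.
#' @slot params event parameters (e.g. `m` mixing intensity in \[0,1\],
#'   `index` fission point, `rate` loss probability).
#' @export
setClass("KaryoEvent",
         representation(type = "character", participants = "character",
                        params = "list"))

setValidity("KaryoEvent", function(object) {
  if (!object@type %in% EVENT_TYPES)
    return(paste("type must be one of:", paste(EVENT_TYPES, collapse = ", ")))
  m <- object@params$m
  if (!is.null(m) && (!is.numeric(m) || m < 0 || m > 1))
    return("mixing intensity m must lie in [0, 1]")
  rate <- object@params$rate
  if (!is.null(rate) && (!is.numeric(rate) || rate < 0 || rate > 1))
    return("loss rate must lie in [0, 1]")
  TRUE
})

#' Construct a KaryoEvent
#' @param type event type (see [KaryoEvent-class]).
#' @param participants scaffold id(s) acted on.
#' @param ... event parameters (`m`, `index`, `rate`, `from`, `to`,
#'   `start`, `width`, `at`).
#' @export
karyoEvent <- function(type, participants = character(), ...) {
  new("KaryoEvent", type = type, participants = as.character(participants),
      params = list(...))
}

setMethod("show", "KaryoEvent", function(object) {
  p <- object@params
  ptxt <- if (length(p))
    paste0(" {", paste(names(p), unlist(lapply(p, format)), sep = "=",
                       collapse = ", "), "}") else ""
  cat(sprintf("KaryoEvent: %s(%s)%s\n", object@type,
              paste(object@participants, collapse = ", "), ptxt))
})

# -- LabelSequence / TurbulenceResult --------------------------------------

#' LabelSequence: ancestral labels ordered along a derived scaffold
#'
#' @slot scaffold the derived (query) scaffold id.
#' @slot labels ancestral/reference chromosome labels in gene order.
#' @slot ranks the source ordinal gene ranks (strictly increasing).
#' @export
setClass("LabelSequence",
         representation(scaffold = "character", labels = "character",
                        ranks = "integer"))

setValidity("LabelSequence", function(object) {
  n <- length(object@labels)
  if (n < 1L) return("a label sequence must contain at least one gene")
  if (length(object@ranks) != n) return("ranks must parallel labels")
  if (n > 1L && any(diff(object@ranks) <= 0L))
    return("ranks must be strictly increasing")
  TRUE
})

#' Construct a LabelSequence directly from labels
#' @param labels character vector of ancestral labels in positional order.
#' @param scaffold scaffold id (cosmetic).
#' @export
labelSeq <- function(labels, scaffold = "seq") {
  new("LabelSequence", scaffold = scaffold, labels = as.character(labels),
      ranks = seq.int(0L, length(labels) - 1L))
}

setMethod("show", "LabelSequence", function(object) {
  cat(sprintf("LabelSequence: %s, n = %d, alphabet = {%s}\n",
              object@scaffold, length(object@labels),
              paste(sort(unique(object@labels)), collapse = ", ")))
})

#' TurbulenceResult: the mixing statistics of one label sequence
#'
#' Components of the sequence-turbulence composite
#' T = log2(phi * (s2max + 1) / (s2 + 1)): the spell count d and durations
#' from run-length encoding, the exact distinct-subsequence count phi of
#' the spell-state sequence (arbitrary precision), the population variance
#' s2 of spell durations and its maximum s2max = (d-1)(1 - tbar)^2.
#'
#' @slot n sequence length (genes).
#' @slot d spell count.
#' @slot durations spell durations (genes), summing to n.
#' @slot phi exact distinct-subsequence count (`kf_bigint`).
#' @slot log2Phi log2 of phi.
#' @slot s2,s2max duration variance and its maximum.
#' @slot turbulence the composite T in bits.
#' @export
setClass("TurbulenceResult",
         representation(n = "integer", d = "integer", durations = "integer",
                        phi = "ANY", log2Phi = "numeric", s2 = "numeric",
                        s2max = "numeric", turbulence = "numeric"))

setValidity("TurbulenceResult", function(object) {
  if (object@d > object@n) return("spell count cannot exceed length")
  if (sum(object@durations) != object@n)
    return("durations must sum to the sequence length")
  TRUE
})

setMethod("show", "TurbulenceResult", function(object) {
  cat(sprintf("TurbulenceResult: n = %d, d = %d, phi = %s, T = %.4f bits\n",
              object@n, object@d, format(object@phi), object@turbulence))
})

# -- PlacementSet ----------------------------------------------------------

#' PlacementSet: best placement of each reference peptide in one genome
#'
#' @slot hits data.frame with one row per placed peptide: `peptide_id`,
#'   `scaffold_id`, `start`, `end`, `strand`, `score`, `identity`.
#' @slot genome tag naming the target genome.
#' @slot scoreAttribute which score field the ranking used.
#' @export
setClass("PlacementSet",
         representation(hits = "data.frame", genome = "character",
                        scoreAttribute = "character"))

setValidity("PlacementSet", function(object) {
  need <- c("peptide_id", "scaffold_id", "start", "end", "strand",
            "score", "identity")
  if (!all(need %in% colnames(object@hits)))
    return(paste("hits must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(object@hits$peptide_id))
    return("at most one placement per peptide")
  TRUE
})

setMethod("show", "PlacementSet", function(object) {
  cat(sprintf("PlacementSet: %d peptides placed in genome '%s' (score: %s)\n",
              nrow(object@hits), object@genome, object@scoreAttribute))
})

#' Placement rows of a PlacementSet
#' @param x a [PlacementSet-class].
#' @export
placementHits <- function(x) {
  stopifnot(is(x, "PlacementSet"))
  x@hits
}

# -- AxisOrder -------------------------------------------------------------

#' AxisOrder: scaffold ordering along one dotplot axis
#'
#' @slot ids ordered scaffold ids.
#' @slot source `"given"` (predefined order) or `"cluster"` (Ward leaf
#'   order).
#' @export
setClass("AxisOrder",
         representation(ids = "character", source = "character"))

setValidity("AxisOrder", function(object) {
  if (anyDuplicated(object@ids)) return("axis order must not repeat ids")
  if (!object@source %in% c("given", "cluster"))
    return("source must be 'given' or 'cluster'")
  TRUE
})

#' Construct an AxisOrder from an explicit id vector
#' @param ids ordered scaffold ids.
#' @param source provenance tag, `"given"` or `"cluster"`.
#' @export
axisOrder <- function(ids, source = "given") {
  new("AxisOrder", ids = as.character(ids), source = source)
}

setMethod("show", "AxisOrder", function(object) {
  cat(sprintf("AxisOrder (%s): %s\n", object@source,
              paste(utils::head(object@ids, 8L), collapse = ", ")))
})
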