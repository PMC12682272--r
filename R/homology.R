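# Statistical core: chromosome-homology matrices, one-sided Fisher exact
# tests with Bonferroni correction, contig co-occurrence tests for
# fusion-with-mixing, chromosome fates and fusion counting.
#
# Every test is an enrichment hypothesis, so the one-sided ("greater")
# Fisher tail is used throughout.

#' Cross-tabulate shared orthologs per scaffold pair
#'
#' @param table a non-empty [SyntenyTable-class].
#' @return A [HomologyMatrix-class] with counts only.
#' @export
sharedOrthologMatrix <- function(table) {
  stopifnot(is(table, "SyntenyTable"))
  df <- syntenyRows(table)
  if (nrow(df) == 0L) stop("cannot tabulate an empty synteny table")
  counts <- table(factor(df$scaffold_a), factor(df$scaffold_b))
  homologyMatrix(unclass(counts))
}

# One-sided hypergeometric tail P(X >= a) for the 2x2 collapse of cell
# (i, j): a = C[i,j], margins K = row total, n = column total, grand N.
# Vectorized over cells.
fisher_tail <- function(a, K, n, N) {
  if (any(N <= 0)) stop("Fisher test needs a positive grand total")
  stats::phyper(a - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' One-sided Fisher exact test for one scaffold pair
#'
#' Collapses the homology matrix to the 2x2 table (on i and on j, on i
#' only, on j only, elsewhere) and returns the exact hypergeometric tail
#' probability P(X >= observed) of enrichment.
#'
#' @param x a [HomologyMatrix-class].
#' @param i,j row/column index or scaffold id.
#' @return the one-sided p-value.
#' @export
fisherAssociation <- function(x, i, j) {
  stopifnot(is(x, "HomologyMatrix"))
  C <- x@counts
  if (is.character(i)) i <- match(i, rownames(C))
  if (is.character(j)) j <- match(j, colnames(C))
  if (is.na(i) || is.na(j)) stop("scaffold not present in the matrix")
  N <- sum(C)
  fisher_tail(C[i, j], sum(C[i, ]), sum(C[, j]), N)
}

#' Bonferroni adjustment
#'
#' @param p numeric vector or matrix of raw p-values in \[0,1\].
#' @param m number of tests (default: `length(p)`).
#' @return `pmin(1, m * p)`, same shape as `p`.
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  m <- assert_count(m, "m")
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  out <- pmin(1, m * p)
  attributes(out) <- attributes(p)
  out
}

#' Fisher-test all cells of a homology matrix
#'
#' Computes the one-sided Fisher p-value of every scaffold pair and the
#' Bonferroni adjustment over the number of tested cells.
#'
#' @param x a [HomologyMatrix-class].
#' @param m number of tests for the correction; defaults to the number of
#'   cells of the (already filtered) matrix.
#' @return the [HomologyMatrix-class] with `pRaw`/`pAdj` filled.
#' @export
testHomologies <- function(x, m = NULL) {
  stopifnot(is(x, "HomologyMatrix"))
  C <- x@counts
  N <- sum(C)
  if (N <= 0) stop("cannot test an empty homology matrix")
  rows <- rowSums(C); cols <- colSums(C)
  K <- matrix(rows, nrow(C), ncol(C))
  n <- matrix(cols, nrow(C), ncol(C), byrow = TRUE)
  p <- fisher_tail(C, K, n, N)
  dimnames(p) <- dimnames(C)
  if (is.null(m)) m <- length(C)
  x@pRaw <- p
  x@pAdj <- bonferroniAdjust(p, m)
  x@mTests <- as.integer(m)
  methods::validObject(x)
  x
}

#' Significant chromosome homologies as a bipartite graph
#'
#' @param x a [HomologyMatrix-class]; tested with [testHomologies()] first
#'   if needed.
#' @param alpha threshold on the Bonferroni-adjusted p-value.
#' @return An [AssociationGraph-class] with an edge per pair with
#'   `p_adj < alpha`.
#' @export
significantHomologies <- function(x, alpha = 0.05) {
  stopifnot(is(x, "HomologyMatrix"))
  assert_scalar_number(alpha, "alpha", 0, 1)
  if (!length(x@pAdj)) x <- testHomologies(x)
  hit <- which(x@pAdj < alpha, arr.ind = TRUE)
  edges <- data.frame(scaffold_a = rownames(x@counts)[hit[, 1]],
                      scaffold_b = colnames(x@counts)[hit[, 2]],
                      shared = x@counts[hit],
                      p_adj = x@pAdj[hit],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$scaffold_a, edges$scaffold_b), , drop = FALSE]
  rownames(edges) <- NULL
  new("AssociationGraph", scaffoldsA = rownames(x@counts),
      scaffoldsB = colnames(x@counts), edges = edges, alpha = alpha)
}

partners_of <- function(edges, r) edges$scaffold_b[edges$scaffold_a == r]

# does r share a partner scaffold with another reference chromosome?
participates_in_fusion <- function(edges, r) {
  for (b in partners_of(edges, r)) {
    if (sum(edges$scaffold_b == b) >= 2L) return(TRUE)
  }
  FALSE
}

#' Call the fate of one reference chromosome
#'
#' Classifies a reference (side a) scaffold from the significant-homology
#' graph: `one_to_one` (one exclusive partner), `fused` (some partner is
#' shared with another reference chromosome), `split` (several partners,
#' each exclusive), `complex` (anything else), `unplaced` (no partner).
#'
#' @param graph an [AssociationGraph-class].
#' @param r reference scaffold id.
#' @return A [FateCall-class].
#' @export
chromosomeFate <- function(graph, r) {
  stopifnot(is(graph, "AssociationGraph"))
  if (!r %in% graph@scaffoldsA)
    stop("reference scaffold '", r, "' not in the graph")
  e <- graph@edges
  partners <- partners_of(e, r)
  padj <- e$p_adj[e$scaffold_a == r]
  fate <- if (length(partners) == 0L) {
    "unplaced"
  } else if (participates_in_fusion(e, r)) {
    "fused"
  } else if (length(partners) == 1L) {
    "one_to_one"
  } else {
    # several partners, none shared: exclusive -> split, else complex
    # (the shared case was caught above, so all partners are exclusive)
    "split"
  }
  new("FateCall", scaffold = r, fate = fate, partners = partners,
      pAdj = padj)
}

#' Fates of all reference chromosomes
#'
#' @param graph an [AssociationGraph-class].
#' @return data.frame with columns `scaffold`, `fate`, `partners`
#'   (comma-separated), `min_p_adj`.
#' @export
chromosomeFates <- function(graph) {
  stopifnot(is(graph, "AssociationGraph"))
  calls <- lapply(graph@scaffoldsA, chromosomeFate, graph = graph)
  data.frame(scaffold = vapply(calls, function(x) x@scaffold, ""),
             fate = vapply(calls, function(x) x@fate, ""),
             partners = vapply(calls, function(x)
               paste(x@partners, collapse = ","), ""),
             min_p_adj = vapply(calls, function(x)
               if (length(x@pAdj)) min(x@pAdj) else NA_real_, 0),
             stringsAsFactors = FALSE)
}

#' Contig co-occurrence test for fusion-with-mixing
#'
#' For a draft (contig-level) query genome, tests whether orthologs of two
#' reference chromosomes co-occur on the same query contigs more often
#' than expected: each contig is classified by presence (>= `presenceMin`
#' orthologs) of each reference chromosome, and the resulting 2x2 table is
#' tested one-sided for positive association. Contigs should be
#' pre-filtered (see [filterScaffolds()]).
#'
#' @param table a [SyntenyTable-class]; reference chromosomes on side a,
#'   query contigs on side b.
#' @param ref1,ref2 reference scaffold ids.
#' @param presenceMin minimal ortholog count for "presence".
#' @return the one-sided Fisher p-value.
#' @export
cooccurrenceFwmTest <- function(table, ref1, ref2, presenceMin = 1L) {
  stopifnot(is(table, "SyntenyTable"))
  presenceMin <- assert_count(presenceMin, "presenceMin")
  df <- syntenyRows(table)
  refs <- unique(df$scaffold_a)
  for (r in c(ref1, ref2)) {
    if (!r %in% refs)
      stop("reference scaffold '", r, "' absent from the table")
  }
  contigs <- unique(df$scaffold_b)
  n1 <- table(factor(df$scaffold_b[df$scaffold_a == ref1], levels = contigs))
  n2 <- table(factor(df$scaffold_b[df$scaffold_a == ref2], levels = contigs))
  p1 <- n1 >= presenceMin
  p2 <- n2 >= presenceMin
  a <- sum(p1 & p2)
  fisher_tail(a, K = sum(p1), n = sum(p2), N = length(contigs))
}

# presence/co-occurrence p-values for all reference pairs, vectorized
all_pair_cooccurrence <- function(df, presenceMin = 1L) {
  P <- unclass(table(factor(df$scaffold_b), factor(df$scaffold_a))) >= presenceMin
  refs <- colnames(P)
  nref <- length(refs)
  if (nref < 2L)
    return(data.frame(ref1 = character(), ref2 = character(), p = numeric()))
  both <- crossprod(P)            # contigs carrying both refs
  pres <- colSums(P)
  idx <- which(upper.tri(both), arr.ind = TRUE)
  p <- fisher_tail(both[idx], K = pres[idx[, 1]], n = pres[idx[, 2]],
                   N = nrow(P))
  data.frame(ref1 = refs[idx[, 1]], ref2 = refs[idx[, 2]], p = as.numeric(p),
             stringsAsFactors = FALSE)
}

#' Count reference chromosomes involved in fusions
#'
#' Two modes, matching the two kinds of query assembly:
#' \describe{
#'   \item{chromosome}{the query is chromosome-level; a reference
#'     chromosome is fused iff it shares a significant partner with
#'     another reference chromosome (pass an [AssociationGraph-class]).}
#'   \item{contig}{the query is a draft; every reference pair is tested
#'     with [cooccurrenceFwmTest()] at `alpha` (uncorrected by default;
#'     set `correct = TRUE` for Bonferroni over the pairs), and a
#'     reference chromosome is fused iff it appears in a significant
#'     pair (pass a [SyntenyTable-class]).}
#' }
#'
#' @param x an [AssociationGraph-class] (chromosome mode) or a
#'   [SyntenyTable-class] (contig mode).
#' @param mode `"chromosome"` or `"contig"`.
#' @param alpha significance threshold for contig mode.
#' @param correct apply Bonferroni over reference pairs in contig mode.
#' @param presenceMin minimal ortholog count for contig-level presence.
#' @return list with `nFused`, `nUnfused`, `total` and `fusedPairs`
#'   (data.frame of the implicated reference pairs).
#' @export
countFused <- function(x, mode = c("chromosome", "contig"), alpha = 0.05,
                       correct = FALSE, presenceMin = 1L) {
  mode <- match.arg(mode)
  if (mode == "chromosome") {
    stopifnot(is(x, "AssociationGraph"))
    e <- x@edges
    refs <- x@scaffoldsA
    fused <- vapply(refs, participates_in_fusion, logical(1), edges = e)
    # implicated pairs: two references sharing one significant partner
    pairs <- list()
    for (b in unique(e$scaffold_b)) {
      ra <- sort(e$scaffold_a[e$scaffold_b == b])
      if (length(ra) >= 2L) {
        cmb <- utils::combn(ra, 2L)
        pairs[[b]] <- data.frame(ref1 = cmb[1, ], ref2 = cmb[2, ],
                                 via = b, stringsAsFactors = FALSE)
      }
    }
    fused_pairs <- if (length(pairs)) do.call(rbind, pairs)
      else data.frame(ref1 = character(), ref2 = character(),
                      via = character())
    rownames(fused_pairs) <- NULL
  } else {
    stopifnot(is(x, "SyntenyTable"))
    df <- syntenyRows(x)
    res <- all_pair_cooccurrence(df, presenceMin = presenceMin)
    padj <- if (correct) bonferroniAdjust(res$p, nrow(res)) else res$p
    sig <- !is.na(padj) & padj < alpha
    fused_pairs <- res[sig, c("ref1", "ref2", "p"), drop = FALSE]
    rownames(fused_pairs) <- NULL
    refs <- sort(unique(df$scaffold_a))
    fused <- refs %in% c(fused_pairs$ref1, fused_pairs$ref2)
    names(fused) <- refs
  }
  list(nFused = sum(fused), nUnfused = sum(!fused), total = length(fused),
       fusedPairs = fused_pairs)
}

#' Classify a fused pair as mixed or sharp by its turbulence
#'
#' A fused pair whose normalized turbulence falls below the first quartile
#' of all fused pairs is called `sharp` (a recent, little-mixed fusion or
#' translocation); values at or above Q1 are `mixed`.
#'
#' @param turbulenceValue normalized turbulence of the pair.
#' @param quartiles numeric `(Q1, Q3)` from [fusedPairQuartiles()].
#' @return `"sharp"` or `"mixed"`.
#' @export
classifyFusedPair <- function(turbulenceValue, quartiles) {
  assert_scalar_number(turbulenceValue, "turbulenceValue")
  if (length(quartiles) != 2L || anyNA(quartiles))
    stop("quartiles must be a numeric (Q1, Q3) pair")
  if (quartiles[1] > quartiles[2])
    stop("Q1 must not exceed Q3")
  if (turbulenceValue < quartiles[1]) "sharp" else "mixed"
}
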