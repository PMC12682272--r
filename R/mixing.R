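# The entropic-mixing statistic.
#
# A derived scaffold is read as the sequence of ancestral (reference)
# chromosome labels of its genes, in gene order. Its turbulence is the
# sequence-complexity composite
#
#   T(x) = log2( phi(x) * (s2max + 1) / (s2 + 1) )
#
# where phi(x) is the exact number of distinct subsequences of the
# spell-state (run-length-compressed) sequence, s2 the population variance
# of spell durations and s2max = (d - 1) * (1 - tbar)^2 its maximum over
# duration configurations with the same spell count d and mean tbar = n/d.
# T is min-max normalized to [0, 1] between the single-spell sequence
# (T = 1) and the strictly alternating sequence of the same length.

#' Ancestral labels along a derived scaffold of a synteny table
#'
#' Reads the reference (side a) scaffold labels of the orthologs on one
#' query (side b) scaffold, ordered by gene rank. Optionally restricts to
#' a set of reference labels, preserving order.
#'
#' @param table a [SyntenyTable-class].
#' @param queryScaffold query scaffold id (side b).
#' @param restrictLabels optional character vector of reference labels to
#'   keep.
#' @return A [LabelSequence-class].
#' @export
labelSequence <- function(table, queryScaffold, restrictLabels = NULL) {
  stopifnot(is(table, "SyntenyTable"))
  df <- syntenyRows(table)
  df <- df[df$scaffold_b == queryScaffold, , drop = FALSE]
  if (nrow(df) == 0L)
    stop("query scaffold '", queryScaffold, "' absent from the table")
  df <- df[order(df$rank_b), , drop = FALSE]
  if (!is.null(restrictLabels))
    df <- df[df$scaffold_a %in% restrictLabels, , drop = FALSE]
  if (nrow(df) == 0L)
    stop("no informative genes on '", queryScaffold,
         "' after restricting to {", paste(restrictLabels, collapse = ", "),
         "}")
  new("LabelSequence", scaffold = queryScaffold, labels = df$scaffold_a,
      ranks = as.integer(df$rank_b))
}

#' Run-length encode a label sequence into spells
#'
#' @param seq a [LabelSequence-class] or character vector of labels.
#' @return list with `states` (adjacent entries differ) and `durations`.
#' @export
dssEncode <- function(seq) {
  labels <- if (is(seq, "LabelSequence")) seq@labels else as.character(seq)
  if (length(labels) < 1L) stop("need at least one label")
  r <- rle(labels)
  list(states = r$values, durations = as.integer(r$lengths))
}

#' Exact count of distinct subsequences
#'
#' Counts the distinct (not necessarily contiguous) subsequences of a
#' symbol sequence, including the empty one, by the standard recurrence
#' `phi_i = 2 phi_(i-1) - phi_(j-1)` with j the previous occurrence of the
#' i-th symbol (term 0 if none). Arbitrary-precision integer arithmetic is
#' used throughout; the count is exact at any length.
#'
#' @param states character vector of symbols (typically the spell states
#'   from [dssEncode()]).
#' @return the exact count as a `kf_bigint`.
#' @export
countDistinctSubsequences <- function(states) {
  states <- as.character(states)
  phi <- big_from_int(1)            # phi_0: the empty subsequence
  last <- new.env(parent = emptyenv())
  for (x in states) {
    nxt <- big_double(phi)
    if (!is.null(last[[x]])) nxt <- big_sub(nxt, last[[x]])
    last[[x]] <- phi                # phi_(j-1) for the next occurrence
    phi <- nxt
  }
  phi
}

#' Turbulence of a label sequence
#'
#' Computes all components of the composite (see the package overview):
#' spell count and durations, exact distinct-subsequence count of the
#' spell states, duration variance and its maximum, and
#' `T = log2(phi * (s2max + 1) / (s2 + 1))` in bits. The log is taken on
#' the exact integer, so there is no precision loss at large phi.
#'
#' @param seq a [LabelSequence-class] or character vector of labels.
#' @return A [TurbulenceResult-class].
#' @export
turbulence <- function(seq) {
  spells <- dssEncode(seq)
  d <- length(spells$durations)
  n <- sum(spells$durations)
  phi <- countDistinctSubsequences(spells$states)
  log2phi <- big_log2(phi)
  tbar <- n / d
  s2 <- mean((spells$durations - tbar)^2)      # population variance
  s2max <- (d - 1) * (1 - tbar)^2
  T <- log2phi + log2(s2max + 1) - log2(s2 + 1)
  new("TurbulenceResult", n = as.integer(n), d = as.integer(d),
      durations = spells$durations, phi = phi, log2Phi = log2phi,
      s2 = s2, s2max = s2max, turbulence = T)
}

# strictly alternating sequence of length n cycling over the alphabet
alternating_sequence <- function(alphabet, n) {
  alphabet <- sort(unique(as.character(alphabet)))
  rep_len(alphabet, n)
}

#' Normalized turbulence in \[0, 1\]
#'
#' Min-max rescaling of [turbulence()]: the minimum is the single-spell
#' sequence of the same length (T = 1), the maximum the strictly
#' alternating sequence of the same length over the observed alphabet.
#' Both endpoints are attainable, so constant sequences map to 0 and
#' strictly alternating ones to 1. If the endpoints coincide (single-label
#' alphabet) the value is 0.
#'
#' The normalization is pluggable: pass a function
#' `function(T, seq) -> numeric` to replace the min-max rule.
#'
#' @param seq a [LabelSequence-class] or character vector of labels.
#' @param normalization `"minmax"` or a function of (T, labels).
#' @return normalized turbulence in \[0, 1\].
#' @export
normalizedTurbulence <- function(seq, normalization = "minmax") {
  labels <- if (is(seq, "LabelSequence")) seq@labels else as.character(seq)
  tb <- turbulence(labels)
  if (is.function(normalization)) return(normalization(tb@turbulence, labels))
  if (!identical(normalization, "minmax"))
    stop("unknown normalization: ", normalization)
  n <- length(labels)
  t_min <- turbulence(rep("A", n))@turbulence       # = 1 for any n
  alphabet <- unique(labels)
  if (length(alphabet) < 2L) return(0)
  t_max <- turbulence(alternating_sequence(alphabet, n))@turbulence
  if (t_max <= t_min) return(0)
  (tb@turbulence - t_min) / (t_max - t_min)
}

#' Pairwise mixing of two reference chromosomes along a query scaffold
#'
#' Restricts the query scaffold's label sequence to the two reference
#' chromosomes and returns its normalized turbulence: values near 0
#' indicate a sharp fusion/translocation boundary, larger values
#' progressively entangled (mixed) gene orders. Symmetric in the two
#' references.
#'
#' @param table a [SyntenyTable-class].
#' @param queryScaffold query scaffold id (side b).
#' @param ref1,ref2 reference scaffold ids (side a); both must contribute
#'   at least one gene.
#' @param normalization passed to [normalizedTurbulence()].
#' @return normalized turbulence in \[0, 1\].
#' @export
pairwiseMixing <- function(table, queryScaffold, ref1, ref2,
                           normalization = "minmax") {
  seq <- labelSequence(table, queryScaffold,
                       restrictLabels = c(ref1, ref2))
  present <- unique(seq@labels)
  for (r in c(ref1, ref2)) {
    if (!r %in% present)
      stop("reference '", r, "' contributes no gene to '", queryScaffold, "'")
  }
  normalizedTurbulence(seq, normalization = normalization)
}

#' Quartiles of normalized turbulence over fused pairs
#'
#' Q1 and Q3 by linear interpolation between order statistics (quantile
#' q of sorted v_1..v_k at position 1 + (k-1) q; R's default type 7).
#'
#' @param values normalized turbulence values of all fused pairs (>= 4).
#' @return named numeric `c(Q1 = ..., Q3 = ...)`.
#' @export
fusedPairQuartiles <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4L)
    stop("need at least 4 fused-pair values for quartiles")
  q <- stats::quantile(values, probs = c(0.25, 0.75), names = FALSE,
                       type = 7)
  c(Q1 = q[1], Q3 = q[2])
}

#' Per-pair mixing over all fused pairs of a dataset
#'
#' Convenience sweep: for each implicated reference pair (as returned in
#' `fusedPairs` by [countFused()]), finds the query scaffold(s) carrying
#' both references and computes the pairwise mixing there.
#'
#' @param table a [SyntenyTable-class].
#' @param fusedPairs data.frame with columns `ref1`, `ref2` (or `a`, `b`).
#' @param normalization passed to [normalizedTurbulence()].
#' @return data.frame with `ref1`, `ref2`, `query`, `n` (informative
#'   genes) and `t_norm`.
#' @export
mixingSweep <- function(table, fusedPairs, normalization = "minmax") {
  stopifnot(is(table, "SyntenyTable"))
  if (all(c("a", "b") %in% colnames(fusedPairs)) &&
      !all(c("ref1", "ref2") %in% colnames(fusedPairs))) {
    fusedPairs$ref1 <- fusedPairs$a
    fusedPairs$ref2 <- fusedPairs$b
  }
  df <- syntenyRows(table)
  out <- list()
  for (i in seq_len(nrow(fusedPairs))) {
    r1 <- fusedPairs$ref1[i]; r2 <- fusedPairs$ref2[i]
    q1 <- unique(df$scaffold_b[df$scaffold_a == r1])
    q2 <- unique(df$scaffold_b[df$scaffold_a == r2])
    for (q in intersect(q1, q2)) {
      seq <- labelSequence(table, q, restrictLabels = c(r1, r2))
      if (!all(c(r1, r2) %in% seq@labels)) next
      out[[length(out) + 1L]] <-
        data.frame(ref1 = r1, ref2 = r2, query = q, n = length(seq@labels),
                   t_norm = normalizedTurbulence(seq,
                                                 normalization = normalization),
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(ref1 = character(), ref2 = character(),
                      query = character(), n = integer(), t_norm = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
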