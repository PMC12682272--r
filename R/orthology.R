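# Mutual-best ortholog construction.
#
# One reference peptide set is mapped independently to two genomes; an
# ortholog pair is the (best-in-A, best-in-B) placements of one peptide,
# with each best placement required to pass an identity floor and a
# uniqueness guard (second-best / best score ratio). This realizes
# "mutual best" deterministically and auditably from per-genome mapping
# output.

#' Select the best placement of each peptide in one genome
#'
#' Keeps, per peptide, the highest-scoring hit iff its identity passes
#' `minIdentity` and the second-best score is at most `scoreRatio` times
#' the best (uniqueness guard). Exact score ties are ambiguous and drop
#' the peptide.
#'
#' @param hits data.frame of mapping hits as from [readMappingGff()].
#' @param minIdentity identity floor in \[0,1\]; hits with unknown (NA)
#'   identity pass only when the floor is 0.
#' @param scoreRatio maximal allowed (second-best / best) score ratio.
#' @param genome tag naming the target genome.
#' @param scoreAttribute provenance note for the score field used.
#' @return A [PlacementSet-class].
#' @export
bestPlacement <- function(hits, minIdentity = 0, scoreRatio = 0.9,
                          genome = "genome", scoreAttribute = "score") {
  assert_scalar_number(minIdentity, "minIdentity", 0, 1)
  assert_scalar_number(scoreRatio, "scoreRatio", 0, 1)
  need <- c("peptide_id", "scaffold_id", "start", "end", "strand",
            "score", "identity")
  if (!all(need %in% colnames(hits)))
    stop("hits must have columns: ", paste(need, collapse = ", "))
  keep_rows <- integer(0)
  if (nrow(hits)) {
    for (rows in split(seq_len(nrow(hits)), hits$peptide_id)) {
      sc <- hits$score[rows]
      best <- which.max(sc)
      if (sum(sc == sc[best]) > 1L) next          # exact tie: ambiguous
      if (length(sc) > 1L) {
        second <- max(sc[-best])
        if (second / sc[best] > scoreRatio) next  # not unique enough
      }
      id <- hits$identity[rows[best]]
      if (minIdentity > 0 && (is.na(id) || id < minIdentity)) next
      keep_rows <- c(keep_rows, rows[best])
    }
  }
  out <- hits[sort(keep_rows), need, drop = FALSE]
  rownames(out) <- NULL
  new("PlacementSet", hits = out, genome = genome,
      scoreAttribute = scoreAttribute)
}

#' Build a pairwise synteny table from two placement sets
#'
#' One row per reference peptide placed in both genomes; positions are
#' placement midpoints, and ordinal gene ranks are computed per scaffold
#' by sorting on position (ties broken by ortholog id).
#'
#' @param pa,pb [PlacementSet-class] objects for genomes A and B, derived
#'   from the same reference peptide set.
#' @return A [SyntenyTable-class].
#' @export
buildPsynt <- function(pa, pb) {
  stopifnot(is(pa, "PlacementSet"), is(pb, "PlacementSet"))
  ha <- placementHits(pa); hb <- placementHits(pb)
  shared <- intersect(ha$peptide_id, hb$peptide_id)
  ha <- ha[match(shared, ha$peptide_id), , drop = FALSE]
  hb <- hb[match(shared, hb$peptide_id), , drop = FALSE]
  syntenyTable(ortholog = shared,
               scaffoldA = ha$scaffold_id,
               posA = interval_midpoint(ha$start, ha$end),
               scaffoldB = hb$scaffold_id,
               posB = interval_midpoint(hb$start, hb$end))
}

#' Drop scaffolds carrying too few orthologs
#'
#' Removes all rows of scaffolds with fewer than `minGenes` orthologs on
#' the chosen side(s), then recomputes dense ranks. With `side = "both"`
#' the filter iterates to a fixed point (removing a scaffold can push a
#' scaffold on the other side below threshold), which makes the operation
#' idempotent. The default threshold of 15 orthologs per contig is the
#' standard guard against sparsely informative draft contigs.
#'
#' @param table a [SyntenyTable-class].
#' @param minGenes minimum orthologs per scaffold.
#' @param side `"a"`, `"b"` or `"both"`.
#' @return the filtered [SyntenyTable-class].
#' @export
filterScaffolds <- function(table, minGenes = 15L, side = c("both", "a", "b")) {
  stopifnot(is(table, "SyntenyTable"))
  minGenes <- assert_count(minGenes, "minGenes")
  side <- match.arg(side)
  df <- syntenyRows(table)
  repeat {
    n0 <- nrow(df)
    if (side %in% c("a", "both")) {
      ok <- table(df$scaffold_a)
      df <- df[df$scaffold_a %in% names(ok)[ok >= minGenes], , drop = FALSE]
    }
    if (side %in% c("b", "both")) {
      ok <- table(df$scaffold_b)
      df <- df[df$scaffold_b %in% names(ok)[ok >= minGenes], , drop = FALSE]
    }
    if (nrow(df) == n0 || side != "both") break
  }
  rownames(df) <- NULL
  df <- recompute_ranks(df)
  new("SyntenyTable", rows = df)
}
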