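# Readers and writers: gene coordinates (GFF3/BED), protein-to-genome
# mapping GFF (miniprot-style), and the .psynt pairwise synteny format.
#
# Internal coordinate convention everywhere: 0-based half-open. GFF3
# (1-based closed) is converted once, at the boundary; BED is already
# 0-based half-open and taken as-is.

gene_record_columns <- c("gene_id", "scaffold_id", "start", "end",
                         "strand", "species_tag")

empty_gene_records <- function() {
  data.frame(gene_id = character(), scaffold_id = character(),
             start = numeric(), end = numeric(), strand = character(),
             species_tag = character(), stringsAsFactors = FALSE)
}

# Cheap structural pre-scan so parse failures carry a line number, which
# rtracklayer's parser does not report.
scan_tabular_lines <- function(path, n_fields, what) {
  lines <- readLines(path, warn = FALSE)
  body <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (length(body)) {
    nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    bad <- body[nf < n_fields]
    if (length(bad))
      stop(sprintf("malformed %s line %d: expected >= %d tab-separated fields, found %d",
                   what, bad[1], n_fields,
                   nf[match(bad[1], body)]), call. = FALSE)
  }
  length(body)
}

#' Read gene coordinates from GFF3 or BED
#'
#' Produces one gene record per selected feature, sorted by
#' (scaffold, start). GFF3 coordinates are converted from 1-based closed
#' to the internal 0-based half-open convention; BED coordinates are
#' already 0-based half-open.
#'
#' @param path path to the annotation file.
#' @param format `"gff3"` or `"bed"`.
#' @param featureType GFF3 feature type to keep (ignored for BED).
#' @param idAttribute GFF3 attribute holding the gene id.
#' @param speciesTag free-text tag recorded on every row.
#' @return data.frame with columns `gene_id`, `scaffold_id`, `start`,
#'   `end`, `strand`, `species_tag`.
#' @export
readGeneCoordinates <- function(path, format = c("gff3", "bed"),
                                featureType = "gene", idAttribute = "ID",
                                speciesTag = "") {
  format <- match.arg(format)
  assert_string(path, "path")
  if (!file.exists(path)) stop("file not found: ", path)
  n_body <- scan_tabular_lines(path, if (format == "gff3") 9L else 3L,
                               toupper(format))
  if (n_body == 0L) {
    kfLog("warning", "no features in ", path)
    warning("no features in ", path, call. = FALSE)
    return(empty_gene_records())
  }
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3") {
    gr <- gr[as.character(gr$type) == featureType]
    if (length(gr) == 0L) {
      kfLog("warning", "no '", featureType, "' features in ", path)
      warning("no '", featureType, "' features in ", path, call. = FALSE)
      return(empty_gene_records())
    }
    ids <- as.character(S4Vectors::mcols(gr)[[idAttribute]])
    if (is.null(ids) || all(is.na(ids)))
      stop("GFF3 features lack the '", idAttribute, "' attribute")
    start0 <- GenomicRanges::start(gr) - 1
  } else {
    ids <- as.character(gr$name)
    if (length(ids) == 0L || all(is.na(ids)))
      ids <- sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
                     GenomicRanges::start(gr) - 1, GenomicRanges::end(gr))
    start0 <- GenomicRanges::start(gr) - 1  # undo rtracklayer's 1-based shift
  }
  dup <- duplicated(ids)
  if (any(dup))
    stop("duplicate gene id(s): ", paste(unique(ids[dup]), collapse = ", "))
  df <- data.frame(gene_id = ids,
                   scaffold_id = as.character(GenomicRanges::seqnames(gr)),
                   start = as.numeric(start0),
                   end = as.numeric(GenomicRanges::end(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   species_tag = speciesTag,
                   stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "."
  if (any(df$start >= df$end)) stop("found gene with start >= end")
  df <- df[order(df$scaffold_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read protein-to-genome mapping placements from GFF
#'
#' Parses spliced-aligner output in GFF dialect (e.g. miniprot `--gff`):
#' one top-level alignment feature per placement, each carrying a numeric
#' alignment score. Multiple placements of the same peptide are preserved;
#' disambiguation is [bestPlacement()]'s job.
#'
#' @param path path to the GFF file.
#' @param scoreAttribute `"score"` for the GFF score column, otherwise the
#'   name of the attribute holding the alignment score.
#' @param featureType top-level alignment feature type (miniprot: `mRNA`).
#' @param identityAttribute attribute holding the identity fraction, if
#'   present.
#' @return data.frame of mapping hits: `peptide_id`, `scaffold_id`,
#'   `start`, `end` (0-based half-open), `strand`, `score`, `identity`.
#' @export
readMappingGff <- function(path, scoreAttribute = "score",
                           featureType = "mRNA",
                           identityAttribute = "Identity") {
  assert_string(path, "path")
  if (!file.exists(path)) stop("file not found: ", path)
  n_body <- scan_tabular_lines(path, 9L, "GFF")
  if (n_body == 0L) {
    warning("no alignment features in ", path, call. = FALSE)
    return(data.frame(peptide_id = character(), scaffold_id = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), score = numeric(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == featureType]
  if (length(gr) == 0L)
    stop("no '", featureType, "' alignment features in ", path)
  mc <- S4Vectors::mcols(gr)
  feat_id <- if (!is.null(mc$ID)) as.character(mc$ID)
             else sprintf("feature %d", seq_along(gr))
  # peptide id: first token of Target=<pep> <s> <e>, falling back to ID
  pep <- if (!is.null(mc$Target))
    vapply(strsplit(as.character(mc$Target), " ", fixed = TRUE), `[[`, "", 1L)
  else feat_id
  if (identical(scoreAttribute, "score")) {
    score <- as.numeric(mc$score)
  } else {
    raw <- mc[[scoreAttribute]]
    if (is.null(raw))
      stop("score attribute '", scoreAttribute, "' absent from ", path)
    score <- suppressWarnings(as.numeric(as.character(raw)))
  }
  if (anyNA(score)) {
    bad <- feat_id[is.na(score)][1]
    stop("missing or non-numeric score ('", scoreAttribute,
         "') on alignment feature ", bad)
  }
  identity <- if (!is.null(mc[[identityAttribute]]))
    suppressWarnings(as.numeric(as.character(mc[[identityAttribute]])))
  else rep(NA_real_, length(gr))
  if (any(identity < 0 | identity > 1, na.rm = TRUE))
    stop("identity values must lie in [0, 1]")
  df <- data.frame(peptide_id = pep,
                   scaffold_id = as.character(GenomicRanges::seqnames(gr)),
                   start = as.numeric(GenomicRanges::start(gr) - 1),
                   end = as.numeric(GenomicRanges::end(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   score = score, identity = identity,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

PSYNT_HEADER <- "#ortholog\tscaffold_a\tpos_a\trank_a\tscaffold_b\tpos_b\trank_b"

#' Read a .psynt pairwise synteny file
#'
#' `.psynt` is a 7-column TSV of mutual-best orthologs with their scaffold,
#' position (bp midpoint) and ordinal gene rank in each of two genomes;
#' the first line is a `#`-prefixed header. [writePsynt()] is its inverse.
#'
#' @param path path to the `.psynt` file.
#' @return A [SyntenyTable-class].
#' @export
readPsynt <- function(path) {
  assert_string(path, "path")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[1], "#"))
    stop("not a .psynt file (missing '#' header line): ", path)
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L)
    return(new("SyntenyTable",
               rows = data.frame(ortholog = character(),
                                 scaffold_a = character(), pos_a = numeric(),
                                 rank_a = integer(), scaffold_b = character(),
                                 pos_b = numeric(), rank_b = integer(),
                                 stringsAsFactors = FALSE)))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 7L)) {
    bad <- which(nf != 7L)[1]
    stop(sprintf("line %d of %s: expected 7 tab-separated columns, found %d",
                 bad + 1L, path, nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 7L, byrow = TRUE)
  df <- data.frame(ortholog = m[, 1], scaffold_a = m[, 2],
                   pos_a = as.numeric(m[, 3]), rank_a = as.integer(m[, 4]),
                   scaffold_b = m[, 5], pos_b = as.numeric(m[, 6]),
                   rank_b = as.integer(m[, 7]), stringsAsFactors = FALSE)
  if (anyNA(df$pos_a) || anyNA(df$pos_b) || anyNA(df$rank_a) || anyNA(df$rank_b))
    stop("non-numeric position or rank field in ", path)
  new("SyntenyTable", rows = df)
}

#' Write a SyntenyTable to a .psynt file
#'
#' @param table a [SyntenyTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePsynt <- function(table, path) {
  stopifnot(is(table, "SyntenyTable"))
  assert_string(path, "path")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(PSYNT_HEADER, con)
  df <- syntenyRows(table)
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}
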