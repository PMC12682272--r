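# Oxford-grid dotplots and clustering-based axis ordering.
#
# Axis coordinate is the cumulative ordinal gene rank, not base pairs:
# the genomes compared differ wildly in physical size and gene order is
# the informative signal. SVG output is written directly (one countable
# <circle> element per ortholog) and is byte-deterministic; PNG/PDF go
# through the usual graphics devices.

#' Order scaffolds along one axis by Ward clustering
#'
#' Agglomerative clustering (ward.D2: squared-update criterion on
#' unsquared Euclidean distances) of the shared-ortholog count vectors,
#' returning the dendrogram leaf order. Rows are pre-sorted by scaffold id
#' so that zero-distance ties resolve lexicographically and the order is
#' invariant to input row shuffling.
#'
#' @param x a [HomologyMatrix-class].
#' @param axis `"a"` (rows) or `"b"` (columns).
#' @return An [AxisOrder-class] with `source = "cluster"`.
#' @export
clusterOrder <- function(x, axis = c("a", "b")) {
  stopifnot(is(x, "HomologyMatrix"))
  axis <- match.arg(axis)
  V <- if (axis == "a") x@counts else t(x@counts)
  V <- V[order(rownames(V)), , drop = FALSE]
  if (nrow(V) < 2L) {
    warning("fewer than 2 scaffolds on axis ", axis,
            "; returning the trivial order")
    return(axisOrder(rownames(V), source = "cluster"))
  }
  hc <- stats::hclust(stats::dist(V, method = "euclidean"),
                      method = "ward.D2")
  new("AxisOrder", ids = rownames(V)[hc$order], source = "cluster")
}

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# cumulative offset (in genes) of each scaffold along an axis
axis_offsets <- function(ids, sizes) {
  sz <- sizes[ids]
  off <- c(0, cumsum(sz))
  list(offset = stats::setNames(off[seq_along(ids)], ids),
       total = off[length(off)])
}

#' Render an Oxford-grid synteny dotplot
#'
#' Each mutual-best ortholog becomes one dot at (cumulative rank in genome
#' A, cumulative rank in genome B); scaffold boundaries are drawn as grid
#' lines. Dots are colored by cell significance (black where the
#' Bonferroni-adjusted Fisher p-value of the scaffold pair is below
#' `alpha`, grey otherwise) or by reference scaffold. `.svg` output is the
#' canonical, deterministic form; `.png` and `.pdf` are rendered through
#' the corresponding graphics devices.
#'
#' @param table the (filtered) [SyntenyTable-class] to plot.
#' @param orderA,orderB [AxisOrder-class] objects covering the table's
#'   scaffolds on each side.
#' @param matrix optional tested [HomologyMatrix-class] (required for
#'   significance coloring).
#' @param alpha significance threshold for black dots.
#' @param colorBy `"significance"` or `"reference_label"`.
#' @param file output path; extension selects the format.
#' @param width,height device size in pixels (SVG/PNG) or inches (PDF).
#' @return `file`, invisibly.
#' @export
renderDotplot <- function(table, orderA, orderB, matrix = NULL,
                          alpha = 0.05,
                          colorBy = c("significance", "reference_label"),
                          file = "dotplot.svg", width = 800, height = 800) {
  stopifnot(is(table, "SyntenyTable"),
            is(orderA, "AxisOrder"), is(orderB, "AxisOrder"))
  colorBy <- match.arg(colorBy)
  df <- syntenyRows(table)
  missA <- setdiff(unique(df$scaffold_a), orderA@ids)
  missB <- setdiff(unique(df$scaffold_b), orderB@ids)
  if (length(missA) || length(missB))
    stop("scaffold(s) in table missing from axis order: ",
         paste(c(missA, missB), collapse = ", "))
  sizesA <- stats::setNames(rep(0L, length(orderA@ids)), orderA@ids)
  ta <- table(df$scaffold_a); sizesA[names(ta)] <- as.integer(ta)
  sizesB <- stats::setNames(rep(0L, length(orderB@ids)), orderB@ids)
  tb <- table(df$scaffold_b); sizesB[names(tb)] <- as.integer(tb)
  offA <- axis_offsets(orderA@ids, sizesA)
  offB <- axis_offsets(orderB@ids, sizesB)
  x <- offA$offset[df$scaffold_a] + df$rank_a + 0.5
  y <- offB$offset[df$scaffold_b] + df$rank_b + 0.5
  if (colorBy == "significance") {
    col <- rep("#bbbbbb", nrow(df))
    if (!is.null(matrix)) {
      padj <- pAdjusted(matrix)
      cell <- padj[cbind(match(df$scaffold_a, rownames(padj)),
                         match(df$scaffold_b, colnames(padj)))]
      col[!is.na(cell) & cell < alpha] <- "#000000"
    }
  } else {
    pal <- grDevices::hcl.colors(max(length(orderA@ids), 3L), "Dark 3")
    col <- pal[match(df$scaffold_a, orderA@ids)]
  }
  ext <- tolower(tools::file_ext(file))
  if (ext == "svg") {
    render_dotplot_svg(file, x, y, col, offA, offB, width, height)
  } else if (ext %in% c("png", "pdf")) {
    if (ext == "png") grDevices::png(file, width = width, height = height)
    else grDevices::pdf(file, width = width / 96, height = height / 96)
    on.exit(grDevices::dev.off())
    graphics::plot(x, y, pch = 16, cex = 0.5, col = col,
                   xlim = c(0, max(offA$total, 1)),
                   ylim = c(0, max(offB$total, 1)),
                   xlab = "genome A (cumulative gene rank)",
                   ylab = "genome B (cumulative gene rank)")
    graphics::abline(v = offA$offset, h = offB$offset, col = "#dddddd")
  } else {
    stop("unsupported dotplot format: .", ext, " (use .svg, .png or .pdf)")
  }
  invisible(file)
}

render_dotplot_svg <- function(file, x, y, col, offA, offB, width, height) {
  con <- tryCatch(file(file, "w"),
                  error = function(e) stop("cannot write dotplot to '",
                                           file, "': ", conditionMessage(e)))
  on.exit(close(con))
  margin <- 40
  sx <- (width - 2 * margin) / max(offA$total, 1)
  sy <- (height - 2 * margin) / max(offB$total, 1)
  px <- function(v) sprintf("%.2f", margin + v * sx)
  py <- function(v) sprintf("%.2f", height - margin - v * sy)  # y up
  out <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                   width, height),
           sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#ffffff"/>',
                   width, height))
  for (v in c(offA$offset, total = offA$total))
    out <- c(out, sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#dddddd" stroke-width="1"/>',
                          px(v), py(0), px(v), py(offB$total)))
  for (v in c(offB$offset, total = offB$total))
    out <- c(out, sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#dddddd" stroke-width="1"/>',
                          px(0), py(v), px(offA$total), py(v)))
  for (s in names(offA$offset))
    out <- c(out, sprintf('<text x="%s" y="%.1f" font-size="8" text-anchor="start">%s</text>',
                          px(offA$offset[[s]]), height - margin / 2,
                          svg_escape(s)))
  for (s in names(offB$offset))
    out <- c(out, sprintf('<text x="%.1f" y="%s" font-size="8" text-anchor="start">%s</text>',
                          margin / 8, py(offB$offset[[s]]), svg_escape(s)))
  out <- c(out, sprintf('<circle cx="%s" cy="%s" r="1.8" fill="%s"/>',
                        vapply(x, px, ""), vapply(y, py, ""), col),
           "</svg>")
  writeLines(out, con)
}
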