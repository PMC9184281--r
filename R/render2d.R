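#' Pseudo-3D ribbon rendering as z-ordered 2D segments
#'
#' Projects a CA trace to 2D and returns plot-ready line segments instead of
#' rasterized output: consecutive residues become segments, segments are
#' sorted by depth so that drawing them in order paints far-to-near, and a
#' shade factor (a fixed linear function of depth, 0.5 at the farthest
#' segment to 1.0 at the nearest) creates the illusion of 3D shading. The
#' result is resolution independent and can be saved as vector graphics.
#'
#' @param coords N x 3 numeric matrix of CA coordinates.
#' @param view 3 x 3 rotation matrix applied before projection onto the
#'   first two axes (third axis = depth towards the viewer).
#' @param color_mode `"index"` (N- to C-terminus rainbow value in `[0, 1]`),
#'   `"metric"` (per-residue values such as pLDDT) or `"chain"`.
#' @param metric per-residue values, required for `color_mode = "metric"`.
#' @param chain optional integer chain id per residue; segments never bridge
#'   chains.
#' @param shade_min shade of the farthest segment, default 0.5.
#' @return A tibble of class `segment_list` with columns `x0, y0, x1, y1,
#'   depth, shade, color`, sorted ascending by depth (stable).
#' @export
ribbon_segments <- function(coords, view = diag(3),
                            color_mode = c("index", "metric", "chain"),
                            metric = NULL, chain = NULL, shade_min = 0.5) {
  color_mode <- match.arg(color_mode)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2) abort("a ribbon needs at least two residues")
  if (is.null(chain)) chain <- rep(1L, n)
  if (color_mode == "metric" && is.null(metric)) {
    abort("color_mode = 'metric' requires per-residue metric values")
  }
  p <- coords %*% t(view)
  i <- seq_len(n - 1)
  same_chain <- chain[i] == chain[i + 1]
  i <- i[same_chain]
  depth <- (p[i, 3] + p[i + 1, 3]) / 2
  color <- switch(color_mode,
    index = (i - 1) / max(n - 2, 1),
    metric = (metric[i] + metric[i + 1]) / 2,
    chain = as.numeric(chain[i])
  )
  seg <- tibble(
    x0 = p[i, 1], y0 = p[i, 2], x1 = p[i + 1, 1], y1 = p[i + 1, 2],
    depth = depth, color = color
  )
  seg <- seg[order(seg$depth), , drop = FALSE]
  rng <- range(seg$depth)
  seg$shade <- if (diff(rng) == 0) rep(1, nrow(seg)) else {
    shade_min + (1 - shade_min) * (seg$depth - rng[[1]]) / diff(rng)
  }
  seg <- seg[, c("x0", "y0", "x1", "y1", "depth", "shade", "color")]
  class(seg) <- unique(c("segment_list", class(seg)))
  seg
}

#' Read a CA trace from a PDB file or coordinate JSON
#'
#' @param path a PDB file (CA atoms extracted) or a JSON array of `[x, y, z]`
#'   triples.
#' @return N x 3 coordinate matrix.
#' @export
read_ca_trace <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    m <- jsonlite::fromJSON(path)
    return(matrix(as.numeric(m), ncol = 3))
  }
  pdb <- bio3d::read.pdb(path)
  ca <- bio3d::atom.select(pdb, "calpha")
  matrix(pdb$xyz[ca$xyz], ncol = 3, byrow = TRUE)
}

#' MSA depth-and-diversity plot data
#'
#' Per query column, the number of rows carrying a residue (coverage depth);
#' per row, the identity to the query, with rows ordered by identity
#' descending as they would be stacked in a coverage plot.
#'
#' @param x an [msa].
#' @return A list with tibbles `coverage` (`position`, `count`) and
#'   `identity` (`row`, `header`, `qid`, ordered by `qid` descending).
#' @export
msa_coverage_plot_data <- function(x) {
  stopifnot(is_msa(x))
  enc <- encode_rows(x$aligned)
  coverage <- tibble(
    position = seq_len(ncol(enc)),
    count = colSums(enc != 0L)
  )
  qid <- c(1, if (nrow(x) > 1) query_identity(x) else numeric(0))
  identity <- tibble(row = seq_len(nrow(x)), header = x$header, qid = qid)
  identity <- identity[order(-identity$qid), , drop = FALSE]
  list(coverage = coverage, identity = identity)
}

#' Plot a segment-list ribbon
#'
#' Draws the z-ordered segments with ggplot2; depth ordering and shading are
#' already baked into the data, so the drawing layer stays thin.
#'
#' @param object a `segment_list` from [ribbon_segments()].
#' @param linewidth segment line width.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.segment_list <- function(object, linewidth = 1.2, ...) {
  ggplot2::ggplot(object) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x0, y = .data$y0,
                   xend = .data$x1, yend = .data$y1,
                   colour = .data$color, alpha = .data$shade),
      linewidth = linewidth, lineend = "round"
    ) +
    ggplot2::scale_alpha_identity() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' @rdname autoplot.segment_list
#' @param x a `segment_list`.
#' @param y ignored.
#' @export
plot.segment_list <- function(x, y, ...) print(autoplot.segment_list(x, ...))

#' Plot MSA coverage
#'
#' @param x an [msa].
#' @return A ggplot object of per-position coverage depth.
#' @export
plot_msa_coverage <- function(x) {
  d <- msa_coverage_plot_data(x)$coverage
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey35") +
    ggplot2::labs(x = "query position", y = "sequences")
}

#' Plot a PAE matrix
#'
#' @param pae square PAE matrix.
#' @return A ggplot raster of predicted aligned error.
#' @export
plot_pae <- function(pae) {
  pae <- as.matrix(pae)
  d <- tibble(
    i = rep(seq_len(nrow(pae)), times = ncol(pae)),
    j = rep(seq_len(ncol(pae)), each = nrow(pae)),
    pae = as.vector(pae)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$j, y = .data$i,
                                  fill = .data$pae)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "aligned residue", y = "scored residue", fill = "PAE (Å)")
}
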