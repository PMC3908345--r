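#' Identity matrix objects
#'
#' The central result container: a numeric matrix of best-hit percent
#' identities with one row per database replicon and one column per seed
#' protein in seed gene order. Missing cells (no significant hit) are `NA`.
#' Row and column annotation ride along as tibbles.
#'
#' @param cells Numeric matrix in `[0, 100]` or `NA`, with replicon
#'   accessions as rownames and seed protein ids as colnames.
#' @param row_meta Tibble with columns `replicon_accession`, `organism_name`,
#'   `replicon_kind`, one row per matrix row, in row order.
#' @param col_meta Tibble with columns `protein_id`, `locus_tag`, `product`,
#'   one row per matrix column, in column order.
#' @return An object of class `identity_matrix`.
#' @export
identity_matrix <- function(cells, row_meta, col_meta) {
  if (!is.matrix(cells) || !is.numeric(cells)) abort("cells must be a numeric matrix")
  vals <- cells[!is.na(cells)]
  if (length(vals) > 0 && (min(vals) < 0 || max(vals) > 100)) {
    abort("identity cells must lie in [0, 100]")
  }
  if (nrow(row_meta) != nrow(cells)) abort("row_meta must have one row per matrix row")
  if (nrow(col_meta) != ncol(cells)) abort("col_meta must have one row per matrix column")
  rownames(cells) <- row_meta$replicon_accession
  colnames(cells) <- col_meta$protein_id
  structure(
    list(cells = cells, row_meta = as_tibble(row_meta), col_meta = as_tibble(col_meta)),
    class = "identity_matrix"
  )
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat(sprintf("<identity_matrix> %d replicon(s) x %d seed protein(s), %.1f%% cells filled\n",
              nrow(x$cells), ncol(x$cells),
              100 * mean(!is.na(x$cells))))
  invisible(x)
}

#' @export
dim.identity_matrix <- function(x) dim(x$cells)

#' Tidy an identity matrix into a long tibble
#'
#' One row per cell, carrying row and column annotation; missing cells are
#' kept with `percent_identity = NA` so column/row completeness is visible.
#'
#' @param x An [identity_matrix].
#' @param ... Unused.
#' @return A tibble with columns `replicon_accession`, `organism_name`,
#'   `replicon_kind`, `protein_id`, `locus_tag`, `product`, `column`
#'   (1-based seed gene order) and `percent_identity`.
#' @export
tidy.identity_matrix <- function(x, ...) {
  nr <- nrow(x$cells)
  nc <- ncol(x$cells)
  tibble(
    replicon_accession = rep(x$row_meta$replicon_accession, times = nc),
    organism_name = rep(x$row_meta$organism_name, times = nc),
    replicon_kind = rep(x$row_meta$replicon_kind, times = nc),
    protein_id = rep(x$col_meta$protein_id, each = nr),
    locus_tag = rep(x$col_meta$locus_tag, each = nr),
    product = rep(x$col_meta$product, each = nr),
    column = rep(seq_len(nc), each = nr),
    percent_identity = as.vector(x$cells)
  )
}

#' One-row summary of an identity matrix
#'
#' @param x An [identity_matrix].
#' @param ... Unused.
#' @return A tibble with replicon/protein counts, the filled-cell fraction,
#'   and mean/median identity over filled cells.
#' @export
glance.identity_matrix <- function(x, ...) {
  vals <- x$cells[!is.na(x$cells)]
  tibble(
    n_replicons = nrow(x$cells),
    n_seed_proteins = ncol(x$cells),
    fill_fraction = mean(!is.na(x$cells)),
    mean_identity = if (length(vals)) mean(vals) else NA_real_,
    median_identity = if (length(vals)) stats::median(vals) else NA_real_
  )
}

#' Heat-map ggplot of an identity matrix
#'
#' A quick-look raster of the full-resolution matrix using the package's
#' anchor colour scale (yellow-green at 20%, blue at 70%, red at 100%).
#' For large matrices or pixel-exact max-sampled output use
#' [render_heatmap()] instead.
#'
#' @param object An [identity_matrix].
#' @param pid_threshold Mask (whiten) cells strictly below this identity.
#' @param scale A [color_scale()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.identity_matrix <- function(object, pid_threshold = 0,
                                     scale = color_scale(), ...) {
  grid <- apply_threshold(object, pid_threshold)
  df <- tidy(identity_matrix(grid, object$row_meta, object$col_meta))
  anchors <- scale$anchors
  bg <- grDevices::rgb(scale$background_rgb[1], scale$background_rgb[2],
                       scale$background_rgb[3], maxColorValue = 255)
  cols <- grDevices::rgb(anchors$r, anchors$g, anchors$b, maxColorValue = 255)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column,
                                   y = .data$replicon_accession,
                                   fill = .data$percent_identity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(
      colours = cols,
      values = scales::rescale(anchors$pid, from = c(0, 100)),
      limits = c(0, 100), na.value = bg, name = "% identity"
    ) +
    ggplot2::scale_y_discrete(limits = rev(object$row_meta$replicon_accession)) +
    ggplot2::labs(x = "seed protein (gene order)", y = "replicon") +
    ggplot2::theme_minimal()
}
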