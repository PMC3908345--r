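#' Anchor colour scale for identity heat maps
#'
#' Percent identity maps to colour by per-channel linear interpolation
#' between anchor points. The defaults follow the conventional legend:
#' pale yellow at 0%, yellow-green at 20%, blue at 70% and red at 100%;
#' masked/missing cells render as the white background.
#'
#' @param anchors Tibble (or data frame) with columns `pid` (strictly
#'   increasing, last = 100) and `hex` colour strings.
#' @param background Hex colour for masked/missing cells.
#' @return A list of class `color_scale` with integer RGB anchor channels.
#' @export
color_scale <- function(anchors = default_anchors(), background = "#FFFFFF") {
  anchors <- as_tibble(anchors)
  if (is.unsorted(anchors$pid, strictly = TRUE)) {
    abort("anchor pids must be strictly increasing")
  }
  if (anchors$pid[nrow(anchors)] != 100) abort("last anchor must be at pid 100")
  rgb <- t(grDevices::col2rgb(anchors$hex))
  structure(
    list(anchors = tibble(pid = anchors$pid, r = rgb[, 1], g = rgb[, 2], b = rgb[, 3]),
         background_rgb = as.integer(grDevices::col2rgb(background)[, 1])),
    class = "color_scale"
  )
}

default_anchors <- function() {
  tibble(pid = c(0, 20, 70, 100),
         hex = c("#FFFFE0", "#9ACD32", "#0000FF", "#FF0000"))
}

#' Map percent identities to RGB colours
#'
#' Exact anchor values return the anchor colour; values between anchors are
#' linearly interpolated per channel (rounded to integers); `NA`
#' (masked/missing) returns the background colour. The mapping is pure:
#' identical inputs give identical output on every platform.
#'
#' @param pid Numeric vector of identities in `[0, 100]`, `NA` allowed.
#' @param scale A [color_scale()].
#' @return An integer matrix with one row per input and columns `r`, `g`, `b`.
#' @export
#' @examples
#' pid_to_color(c(100, 70, NA))
pid_to_color <- function(pid, scale = color_scale()) {
  ok <- is.na(pid) | (pid >= 0 & pid <= 100)
  if (!all(ok)) abort("pid values must lie in [0, 100] (or NA for masked)")
  a <- scale$anchors
  # below the first anchor, clamp to the first anchor colour
  interp <- function(channel) {
    y <- approx(a$pid, a[[channel]], xout = pmax(pid, a$pid[1]),
                method = "linear", rule = 2)$y
    as.integer(round(y))
  }
  out <- cbind(r = interp("r"), g = interp("g"), b = interp("b"))
  masked <- is.na(pid)
  if (any(masked)) {
    out[masked, ] <- matrix(scale$background_rgb, sum(masked), 3, byrow = TRUE)
  }
  out
}

#' Mask cells below a percent-identity threshold
#'
#' Cells strictly below the threshold, and missing cells, become masked
#' (`NA`); cells equal to the threshold are kept. Masking happens before any
#' downscaling, so a filtered value can never win a block maximum.
#'
#' @param matrix An [identity_matrix] or a plain numeric grid.
#' @param pid_threshold Threshold in `[0, 100]`.
#' @return A numeric matrix with masked cells as `NA`.
#' @export
apply_threshold <- function(matrix, pid_threshold) {
  if (pid_threshold < 0 || pid_threshold > 100) {
    abort("pid_threshold must lie in [0, 100]")
  }
  grid <- if (inherits(matrix, "identity_matrix")) matrix$cells else matrix
  grid[!is.na(grid) & grid < pid_threshold] <- NA_real_
  grid
}

#' Max-sampling downscale of a masked grid
#'
#' Partitions the input into `out_rows * out_cols` contiguous rectangular
#' blocks using integer boundaries `floor(i * n / out)` (near-even split,
#' every input cell in exactly one block) and represents each block by the
#' maximum over its non-masked values — so a single high-identity cell
#' survives any zoom level. A block that is entirely masked stays masked.
#' Upscaling is refused.
#'
#' @param grid Numeric matrix, masked cells as `NA`.
#' @param out_rows,out_cols Output dimensions; each must be between 1 and the
#'   corresponding input dimension.
#' @return An `out_rows x out_cols` numeric matrix with `NA` for fully
#'   masked blocks.
#' @export
max_downscale <- function(grid, out_rows, out_cols) {
  nr <- nrow(grid)
  nc <- ncol(grid)
  if (out_rows < 1 || out_cols < 1) abort("output dimensions must be >= 1")
  if (out_rows > nr || out_cols > nc) {
    abort(sprintf("cannot upscale: output %dx%d exceeds input %dx%d",
                  out_rows, out_cols, nr, nc))
  }
  rb <- floor((0:out_rows) * nr / out_rows)
  cb <- floor((0:out_cols) * nc / out_cols)
  out <- matrix(NA_real_, out_rows, out_cols)
  for (i in seq_len(out_rows)) {
    rows <- (rb[i] + 1L):rb[i + 1L]
    for (j in seq_len(out_cols)) {
      block <- grid[rows, (cb[j] + 1L):cb[j + 1L]]
      if (!all(is.na(block))) out[i, j] <- max(block, na.rm = TRUE)
    }
  }
  out
}

#' Order matrix rows by mean identity to selected seed proteins
#'
#' Returns the permutation that sorts rows by ascending mean cell value over
#' the selected columns, so the most similar proteomes land at the bottom of
#' the rendered image. Missing cells count as 0 by default (a proteome
#' lacking the protein is maximally dissimilar for that column); set
#' `missing_as_zero = FALSE` to average over present hits only. Ties break
#' by accession, ascending.
#'
#' @param matrix An [identity_matrix].
#' @param columns Integer column indices to average over, or `NULL` for the
#'   whole proteome.
#' @param missing_as_zero Whether `NA` cells count as 0 in the mean.
#' @return An integer permutation of the row indices (top-to-bottom render
#'   order).
#' @export
sort_rows <- function(matrix, columns = NULL, missing_as_zero = TRUE) {
  cells <- matrix$cells
  if (is.null(columns)) columns <- seq_len(ncol(cells))
  if (length(columns) == 0) abort("column subset must be non-empty")
  if (any(columns < 1 | columns > ncol(cells))) abort("column index out of range")
  sub <- cells[, columns, drop = FALSE]
  if (missing_as_zero) sub[is.na(sub)] <- 0
  means <- rowMeans(sub, na.rm = TRUE)
  means[is.nan(means)] <- 0  # all-missing row under hits-only averaging
  order(means, matrix$row_meta$replicon_accession)
}

#' Find rows and columns matching a text query
#'
#' Case-insensitive substring search over organism names and accessions
#' (rows) and protein ids, locus tags and products (columns).
#'
#' @param matrix An [identity_matrix].
#' @param query Search string.
#' @return A tibble with columns `kind` (`"row"`/`"column"`), `index`,
#'   `matched_field`, `label`. Empty when nothing matches.
#' @export
locate_matrix <- function(matrix, query) {
  q <- stringr::fixed(query, ignore_case = TRUE)
  rm <- matrix$row_meta
  cm <- matrix$col_meta
  hits <- list()
  add <- function(kind, idx, field, label) {
    if (length(idx) > 0) {
      hits[[length(hits) + 1L]] <<- tibble(kind = kind, index = idx,
                                           matched_field = field, label = label[idx])
    }
  }
  add("row", which(stringr::str_detect(rm$replicon_accession, q)),
      "accession", rm$replicon_accession)
  add("row", which(stringr::str_detect(rm$organism_name, q)),
      "organism_name", rm$organism_name)
  add("column", which(stringr::str_detect(cm$protein_id, q)),
      "protein_id", cm$protein_id)
  add("column", which(stringr::str_detect(cm$locus_tag, q)),
      "locus_tag", cm$locus_tag)
  add("column", which(stringr::str_detect(cm$product, q)),
      "product", cm$product)
  if (length(hits) == 0) {
    return(tibble(kind = character(), index = integer(),
                  matched_field = character(), label = character()))
  }
  bind_rows(hits) %>% distinct(.data$kind, .data$index, .keep_all = TRUE)
}

#' Render settings for a heat-map image
#'
#' @param pid_threshold Mask cells strictly below this identity.
#' @param out_rows,out_cols Raster dimensions; requests larger than the
#'   matrix are clamped to the matrix size (no upscaling).
#' @param row_order Integer permutation of row indices (e.g. from
#'   [sort_rows()]), or `NULL` to keep matrix order.
#' @param scale A [color_scale()].
#' @return A list of class `render_spec`.
#' @export
render_spec <- function(pid_threshold = 0, out_rows = NULL, out_cols = NULL,
                        row_order = NULL, scale = color_scale()) {
  structure(list(pid_threshold = pid_threshold, out_rows = out_rows,
                 out_cols = out_cols, row_order = row_order, scale = scale),
            class = "render_spec")
}

#' Render an identity matrix to a PNG heat map
#'
#' Pipeline: reorder rows, mask below the threshold, max-sample down to the
#' requested raster size, map identities to colours, write the raster. Each
#' output pixel is exactly one matrix cell when no downscaling is needed.
#' An optional HTML companion embeds the same raster as a colour table with
#' per-cell hover text (seed proteins, replicons, and the block-maximum
#' identity each pixel represents).
#'
#' @param matrix An [identity_matrix].
#' @param path Output PNG path.
#' @param spec A [render_spec()].
#' @param html_path Optional output path for the HTML variant.
#' @return Invisibly, the downscaled numeric grid that was rendered.
#' @export
render_heatmap <- function(matrix, path, spec = render_spec(), html_path = NULL) {
  cells <- matrix$cells
  row_order <- spec$row_order %||% seq_len(nrow(cells))
  if (!identical(sort(row_order), seq_len(nrow(cells)))) {
    abort("row_order must be a permutation of the row indices")
  }
  ordered <- cells[row_order, , drop = FALSE]
  masked <- apply_threshold(ordered, spec$pid_threshold)
  out_rows <- min(spec$out_rows %||% nrow(masked), nrow(masked))
  out_cols <- min(spec$out_cols %||% ncol(masked), ncol(masked))
  grid <- max_downscale(masked, out_rows, out_cols)

  rgb <- pid_to_color(as.vector(grid), spec$scale)
  arr <- array(0, dim = c(out_rows, out_cols, 3))
  arr[, , 1] <- matrix(rgb[, "r"], out_rows, out_cols) / 255
  arr[, , 2] <- matrix(rgb[, "g"], out_rows, out_cols) / 255
  arr[, , 3] <- matrix(rgb[, "b"], out_rows, out_cols) / 255
  png::writePNG(arr, path)

  if (!is.null(html_path)) {
    write_heatmap_html(matrix, grid, rgb, row_order, out_rows, out_cols, html_path)
  }
  invisible(grid)
}

# Single-file HTML: a table of coloured cells with hover titles describing
# which replicons / seed proteins each pixel aggregates.
write_heatmap_html <- function(matrix, grid, rgb, row_order, out_rows, out_cols,
                               html_path) {
  nr <- nrow(matrix$cells)
  nc <- ncol(matrix$cells)
  rb <- floor((0:out_rows) * nr / out_rows)
  cb <- floor((0:out_cols) * nc / out_cols)
  accs <- matrix$row_meta$replicon_accession[row_order]
  pids <- matrix$col_meta$protein_id
  hex <- grDevices::rgb(rgb[, "r"], rgb[, "g"], rgb[, "b"], maxColorValue = 255)
  hex <- matrix(hex, out_rows, out_cols)
  esc <- function(x) gsub("<", "&lt;", gsub("&", "&amp;", x))
  rows_html <- vapply(seq_len(out_rows), function(i) {
    r1 <- rb[i] + 1L; r2 <- rb[i + 1L]
    rlab <- if (r1 == r2) accs[r1] else sprintf("%s..%s", accs[r1], accs[r2])
    tds <- vapply(seq_len(out_cols), function(j) {
      c1 <- cb[j] + 1L; c2 <- cb[j + 1L]
      clab <- if (c1 == c2) pids[c1] else sprintf("%s..%s", pids[c1], pids[c2])
      val <- if (is.na(grid[i, j])) "masked" else sprintf("%.2f%%", grid[i, j])
      sprintf('<td style="background:%s" title="%s | %s | %s"></td>',
              hex[i, j], esc(rlab), esc(clab), val)
    }, character(1))
    paste0("<tr>", paste(tds, collapse = ""), "</tr>")
  }, character(1))
  html <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<style>table{border-collapse:collapse}td{width:6px;height:6px;padding:0}</style>",
    "</head><body><table>", rows_html, "</table></body></html>"
  )
  writeLines(html, html_path)
  invisible(html_path)
}
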