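#' Matrix file header
#'
#' Provenance metadata written into the `#`-prefixed header lines of the
#' matrix file.
#'
#' @param seed_label Free-text label of the seed genome.
#' @param e_cutoff E-value cutoff the matrix was built with.
#' @param backend `"internal"` or `"blast"`.
#' @param creation_note Free-text note.
#' @param format_version Dialect version; leave at the default.
#' @return A list of class `matrix_header`.
#' @export
matrix_header <- function(seed_label = "", e_cutoff = 1e-20,
                          backend = "internal", creation_note = "",
                          format_version = MATRIX_FORMAT_VERSION) {
  structure(list(format_version = format_version, seed_label = seed_label,
                 e_cutoff = e_cutoff, backend = backend,
                 creation_note = creation_note),
            class = "matrix_header")
}

MATRIX_FORMAT_VERSION <- "repliconmap-matrix/1"

#' Write an identity matrix to the tab-delimited matrix format
#'
#' The file dialect is plain UTF-8, LF line endings:
#' * `#` header lines: format version, seed label, E-value cutoff, backend,
#'   note — echoed verbatim on read;
#' * one `#%col` line per column carrying `protein_id`, `locus_tag`,
#'   `product` (sidecar column metadata, keeping data rows rectangular);
#' * a column-label line: `accession  organism  kind` then the protein ids;
#' * one data line per replicon: three label fields then one cell per seed
#'   protein. Identities are fixed-point with exactly two decimals; missing
#'   cells are empty fields.
#'
#' File row order is the matrix row order; readers must not re-sort.
#'
#' @param matrix An [identity_matrix].
#' @param path Output path.
#' @param header A [matrix_header()].
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, header = matrix_header()) {
  if (!inherits(matrix, "identity_matrix")) abort("matrix must be an identity_matrix")
  clean <- function(x) gsub("[\t\n]", " ", x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  wl <- function(x) writeLines(x, con, sep = "\n", useBytes = TRUE)
  wl(paste0("#format: ", header$format_version))
  wl(paste0("#seed: ", clean(header$seed_label)))
  wl(paste0("#e_cutoff: ", format(header$e_cutoff, scientific = TRUE)))
  wl(paste0("#backend: ", clean(header$backend)))
  wl(paste0("#note: ", clean(header$creation_note)))
  cm <- matrix$col_meta
  wl(sprintf("#%%col\t%s\t%s\t%s", clean(cm$protein_id), clean(cm$locus_tag),
             clean(cm$product)))
  wl(paste(c("accession", "organism", "kind", clean(cm$protein_id)),
           collapse = "\t"))
  cells <- matrix$cells
  body <- vapply(seq_len(nrow(cells)), function(i) {
    vals <- cells[i, ]
    txt <- ifelse(is.na(vals), "", sprintf("%.2f", vals))
    paste(c(clean(matrix$row_meta$replicon_accession[i]),
            clean(matrix$row_meta$organism_name[i]),
            clean(matrix$row_meta$replicon_kind[i]), txt), collapse = "\t")
  }, character(1))
  wl(body)
  invisible(path)
}

#' Read a matrix file back into an identity matrix
#'
#' Re-validates every invariant on load: recognised format version,
#' rectangular rows, all cells in `[0, 100]` or empty. Row order in the file
#' is preserved exactly.
#'
#' @param path Path to a file written by [write_matrix()].
#' @return A list with elements `matrix` (an [identity_matrix]) and `header`
#'   (a [matrix_header()]).
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read matrix file: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort(sprintf("empty matrix file: %s", path))

  is_header <- startsWith(lines, "#")
  header_lines <- lines[is_header & !startsWith(lines, "#%col")]
  col_lines <- lines[startsWith(lines, "#%col")]
  data_lines <- lines[!is_header]
  data_line_nos <- which(!is_header)

  hget <- function(key) {
    hit <- header_lines[startsWith(header_lines, paste0("#", key, ":"))]
    if (length(hit) == 0) return("")
    trimws(sub(paste0("^#", key, ":"), "", hit[1]))
  }
  version <- hget("format")
  if (!identical(version, MATRIX_FORMAT_VERSION)) {
    abort(sprintf("matrix format version mismatch: file says '%s', this reader handles '%s'",
                  version, MATRIX_FORMAT_VERSION))
  }
  header <- matrix_header(
    seed_label = hget("seed"),
    e_cutoff = as.numeric(hget("e_cutoff")),
    backend = hget("backend"),
    creation_note = hget("note")
  )

  if (length(data_lines) < 2) abort("matrix file has no data rows")
  label_fields <- strsplit(data_lines[1], "\t", fixed = TRUE)[[1]]
  if (length(label_fields) < 4 ||
      !identical(label_fields[1:3], c("accession", "organism", "kind"))) {
    abort(sprintf("malformed column-label line (line %d)", data_line_nos[1]))
  }
  protein_ids <- label_fields[-(1:3)]
  n_cols <- length(protein_ids)

  col_meta <- tibble(protein_id = protein_ids, locus_tag = "", product = "")
  if (length(col_lines) > 0) {
    cf <- strsplit(col_lines, "\t", fixed = TRUE)
    bad <- which(stringr::str_count(col_lines, "\t") != 3)
    if (length(bad) > 0) abort(sprintf("malformed #%%col line %d", bad[1]))
    cf <- purrr::map(cf, function(f) c(f, rep("", 4 - length(f))))
    cm <- do.call(rbind, cf)
    if (nrow(cm) != n_cols) {
      abort(sprintf("#%%col metadata covers %d columns but matrix has %d",
                    nrow(cm), n_cols))
    }
    col_meta <- tibble(protein_id = cm[, 2], locus_tag = cm[, 3], product = cm[, 4])
    if (!identical(col_meta$protein_id, protein_ids)) {
      abort("#%col protein ids disagree with the column-label line")
    }
  }

  rows <- strsplit(data_lines[-1], "\t", fixed = TRUE)
  expected <- n_cols + 3L
  lens <- lengths(rows)
  # a trailing missing cell drops the final empty field in strsplit; restore it
  rows <- purrr::map2(rows, lens, function(r, l) {
    if (l < expected) c(r, rep("", expected - l)) else r
  })
  raw_lens <- stringr::str_count(data_lines[-1], "\t") + 1L
  bad <- which(raw_lens != expected)
  if (length(bad) > 0) {
    abort(sprintf("ragged matrix row at line %d: %d field(s), expected %d",
                  data_line_nos[-1][bad[1]], raw_lens[bad[1]], expected))
  }
  mat <- do.call(rbind, rows)
  row_meta <- tibble(replicon_accession = mat[, 1], organism_name = mat[, 2],
                     replicon_kind = mat[, 3])
  cell_txt <- mat[, -(1:3), drop = FALSE]
  cells <- suppressWarnings(
    matrix(as.numeric(ifelse(cell_txt == "", NA, cell_txt)),
           nrow = nrow(mat), ncol = n_cols)
  )
  unparsable <- cell_txt != "" & is.na(cells)
  if (any(unparsable)) {
    abort(sprintf("non-numeric cell '%s' at data row %d",
                  cell_txt[which(unparsable)[1]],
                  which(apply(unparsable, 1, any))[1]))
  }
  out_of_range <- !is.na(cells) & (cells < 0 | cells > 100)
  if (any(out_of_range)) {
    abort(sprintf("identity cell outside [0, 100] at data row %d",
                  which(apply(out_of_range, 1, any))[1]))
  }
  list(matrix = identity_matrix(cells, row_meta, col_meta), header = header)
}

#' Validate a matrix file
#'
#' Runs [read_matrix()] and reports whether every invariant holds.
#'
#' @param path Path to a matrix file.
#' @return `TRUE` invisibly if valid; otherwise signals the underlying
#'   validation error.
#' @export
validate_matrix_file <- function(path) {
  read_matrix(path)
  invisible(TRUE)
}
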