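# Independent oracles, kept deliberately naive so they share no code with the
# implementation paths they check.

# Plain-R Gotoh local alignment: returns the optimal Smith-Waterman score
# under affine gaps where a gap of length L costs open + extend * L.
sw_oracle <- function(query, subject, mat, gap_open, gap_extend) {
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  m <- length(q)
  n <- length(s)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(E[i, j - 1] - gap_extend, H[i, j - 1] - gap_open - gap_extend)
      F[i, j] <- max(F[i - 1, j] - gap_extend, H[i - 1, j] - gap_open - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[q[i - 1], s[j - 1]], E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Assignment-based block maximum: walks every input cell, finds which output
# block it belongs to with findInterval over the boundary formula, and
# accumulates maxima — the inverse strategy of the implementation's slicing.
block_max_oracle <- function(grid, out_rows, out_cols) {
  nr <- nrow(grid)
  nc <- ncol(grid)
  rb <- floor((0:out_rows) * nr / out_rows)
  cb <- floor((0:out_cols) * nc / out_cols)
  out <- matrix(NA_real_, out_rows, out_cols)
  for (r in seq_len(nr)) {
    br <- findInterval(r - 1, rb, rightmost.closed = FALSE)
    for (cc in seq_len(nc)) {
      bc <- findInterval(cc - 1, cb, rightmost.closed = FALSE)
      v <- grid[r, cc]
      if (!is.na(v) && (is.na(out[br, bc]) || v > out[br, bc])) {
        out[br, bc] <- v
      }
    }
  }
  out
}

random_aa_string <- function(len) {
  paste(sample(setdiff(repliconmap:::AA_ALPHABET, "X"), len, replace = TRUE),
        collapse = "")
}

random_masked_grid <- function(nr, nc, missing_frac = 0.3) {
  vals <- round(stats::runif(nr * nc, 0, 100), 2)
  vals[stats::runif(nr * nc) < missing_frac] <- NA_real_
  matrix(vals, nr, nc)
}

# A random identity matrix with 2-decimal cells (the serialization precision)
# and a controllable missing density.
random_identity_matrix <- function(nr, nc, missing_frac) {
  cells <- random_masked_grid(nr, nc, missing_frac)
  identity_matrix(
    cells,
    row_meta = tibble::tibble(
      replicon_accession = sprintf("ACC%03d", seq_len(nr)),
      organism_name = sprintf("Organism %d", seq_len(nr)),
      replicon_kind = sample(c("chromosome", "plasmid", "unknown"), nr, TRUE)
    ),
    col_meta = tibble::tibble(
      protein_id = sprintf("prot%03d", seq_len(nc)),
      locus_tag = sprintf("LT_%03d", seq_len(nc)),
      product = sprintf("product %d", seq_len(nc))
    )
  )
}

# The default synthetic universe and its matrices are shared across test
# files; build them once per test run.
.fixture_cache <- new.env(parent = emptyenv())

get_universe <- function() {
  if (is.null(.fixture_cache$uni)) .fixture_cache$uni <- make_test_universe(42)
  .fixture_cache$uni
}

get_seed_matrix <- function() {
  if (is.null(.fixture_cache$seed_matrix)) {
    uni <- get_universe()
    .fixture_cache$seed_matrix <- build_matrix(uni$seed, uni$db)
  }
  .fixture_cache$seed_matrix
}

get_hgt_matrix <- function() {
  if (is.null(.fixture_cache$hgt_matrix)) {
    uni <- get_universe()
    .fixture_cache$hgt_matrix <- build_matrix(uni$genomes$SYNHGT01, uni$db)
  }
  .fixture_cache$hgt_matrix
}

genbank_fixture <- function(name = "example_replicon.gbk") {
  system.file("extdata", name, package = "repliconmap")
}
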