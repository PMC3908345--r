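#' Search the seed proteome with external BLAST+
#'
#' Exports the seed proteins and the database to temporary FASTA, builds a
#' BLAST protein database with `makeblastdb`, runs `blastp` with tabular
#' output (`-outfmt 6`: qseqid sseqid pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore), and parses the result into the same
#' hits tibble the internal backend produces, so downstream consolidation is
#' identical. Only the top HSP per query-subject pair is kept
#' (`-max_hsps 1`).
#'
#' Note that BLAST's composition-based statistics differ from the internal
#' Karlin-Altschul model, so E-values and low-identity cells differ between
#' backends; matrix layout (rows, columns) never does.
#'
#' @param seed A proteome tibble (or list of them) — the seed replicons.
#' @param db A database from [build_database()].
#' @param e_cutoff E-value cutoff passed to blastp (strict `<` re-applied
#'   after parsing).
#' @return A hits tibble (same columns as [search_seed_protein()];
#'   `raw_score` is `NA` — BLAST reports bit scores only).
#' @export
run_external_blast <- function(seed, db, e_cutoff = 1e-20) {
  if (Sys.which("blastp") == "" || Sys.which("makeblastdb") == "") {
    abort(paste("BLAST+ executables (blastp, makeblastdb) not found on PATH;",
                "use backend = \"internal\" instead"))
  }
  if (is.data.frame(seed)) seed <- list(seed)
  seed_tbl <- bind_rows(seed)

  work <- tempfile("rmapblast")
  dir.create(work)
  on.exit(unlink(work, recursive = TRUE), add = TRUE)
  qf <- file.path(work, "query.faa")
  sf <- file.path(work, "subject.faa")
  of <- file.path(work, "hits.tsv")
  writeLines(paste0(">", seed_tbl$protein_id, "\n", seed_tbl$sequence), qf)
  writeLines(paste0(">", db$protein_id, "\n", db$sequence), sf)

  status <- system2("makeblastdb",
                    c("-in", sf, "-dbtype", "prot", "-out", file.path(work, "bdb")),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) abort("makeblastdb failed")
  status <- system2("blastp",
                    c("-query", qf, "-db", file.path(work, "bdb"),
                      "-outfmt", "6", "-evalue", format(e_cutoff, scientific = TRUE),
                      "-max_hsps", "1", "-out", of),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) abort("blastp failed")

  hits <- parse_blast_tabular(of)
  if (nrow(hits) == 0) return(hits)
  acc_of <- setNames(db$replicon_accession, db$protein_id)
  hits %>%
    mutate(subject_accession = unname(acc_of[.data$subject_id])) %>%
    filter(.data$e_value < e_cutoff)
}

# Parse BLAST outfmt-6 tabular output (12 columns). Empty files are valid
# (no hits); a line with the wrong field count is a parse error that names
# the line number.
parse_blast_tabular <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_hits() %>% select(-"subject_index"))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12)
  if (length(bad) > 0) {
    abort(sprintf("malformed BLAST tabular line %d: expected 12 fields, got %d",
                  bad[1], lengths(fields)[bad[1]]))
  }
  m <- do.call(rbind, fields)
  pident <- as.numeric(m[, 3])
  len <- as.integer(m[, 4])
  tibble(
    query_id = m[, 1],
    subject_id = m[, 2],
    subject_accession = NA_character_,
    percent_identity = pident,
    e_value = as.numeric(m[, 11]),
    bit_score = as.numeric(m[, 12]),
    raw_score = NA_real_,
    align_length = len,
    n_identities = as.integer(round(pident * len / 100))
  )
}
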