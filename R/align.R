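#' Optimal local alignment of a protein pair
#'
#' Runs Smith-Waterman local alignment (affine gaps) between one query and
#' one subject under a [scoring_scheme()], and attaches Karlin-Altschul
#' statistics: `e_value = K * m * n * exp(-lambda * S)` with `m` the query
#' length, `n = search_space_residues`, and `S` the raw score. Percent
#' identity is the BLAST convention, `100 * identities / alignment length`
#' (gap columns included in the length).
#'
#' @param query,subject Amino-acid strings over the 20 canonical letters
#'   plus X (case-insensitive).
#' @param scoring A [scoring_scheme()].
#' @param search_space_residues Residue count of the searched database, at
#'   least the subject length. Defaults to the subject length (single-pair
#'   search space).
#' @return A one-row tibble (`query_id`, `subject_id` set to `NA`; see
#'   [search_seed_protein()] for filled-in hits) with columns
#'   `percent_identity`, `e_value`, `bit_score`, `raw_score`, `align_length`,
#'   `n_identities` — or `NULL` when the optimal local score is 0 (no
#'   alignable segment).
#' @export
#' @examples
#' hit <- align_pair("MKVLITGAGSGIGL", "MKVLITGAGSGIGL")
#' hit$percent_identity
align_pair <- function(query, subject, scoring = scoring_scheme(),
                       search_space_residues = nchar(subject)) {
  stopifnot(length(query) == 1, length(subject) == 1)
  query <- sanitize_sequences(query, "query")
  subject <- sanitize_sequences(subject, "subject")
  if (search_space_residues < nchar(subject)) {
    abort("search_space_residues must be at least the subject length")
  }
  # canonical pair orientation: among co-optimal alignments the traceback
  # depends on argument order, so fix it to make the result fully symmetric
  if (query <= subject) {
    hits <- align_one_vs_many(query, subject, scoring, search_space_residues)
  } else {
    hits <- align_one_vs_many(subject, query, scoring, search_space_residues)
    if (nrow(hits) > 0) {
      m <- nchar(query)
      hits$e_value <- karlin_evalue(hits$raw_score, m, search_space_residues, scoring)
    }
  }
  if (nrow(hits) == 0) return(NULL)
  hits
}

# Vectorized core: one query against a character vector of subjects.
# Returns a tibble with one row per subject whose optimal score is > 0.
align_one_vs_many <- function(query, subjects, scoring, search_space_residues) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(subjects),
    subject = Biostrings::AAString(query),
    type = "local",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open,
    gapExtension = scoring$gap_extend
  )
  raw <- Biostrings::score(aln)
  keep <- which(raw > 0)
  if (length(keep) == 0) {
    return(empty_hits())
  }
  len <- Biostrings::nchar(aln)[keep]
  nid <- Biostrings::nmatch(aln)[keep]
  m <- nchar(query)
  tibble(
    query_id = NA_character_,
    subject_id = NA_character_,
    subject_accession = NA_character_,
    subject_index = keep,
    percent_identity = 100 * nid / len,
    e_value = karlin_evalue(raw[keep], m, search_space_residues, scoring),
    bit_score = karlin_bitscore(raw[keep], scoring),
    raw_score = raw[keep],
    align_length = len,
    n_identities = nid
  )
}

empty_hits <- function() {
  tibble(
    query_id = character(), subject_id = character(),
    subject_accession = character(), subject_index = integer(),
    percent_identity = numeric(), e_value = numeric(), bit_score = numeric(),
    raw_score = numeric(), align_length = integer(), n_identities = integer()
  )
}

#' Search one seed protein against a whole database
#'
#' Aligns the query against every protein in the database and keeps every
#' statistically significant alignment — strictly `e_value < e_cutoff`
#' (default 1e-20), so a hit exactly at the cutoff is excluded. The search
#' space for the E-value is the query length times the database's total
#' residue count.
#'
#' @param query A one-row proteome tibble (one seed protein).
#' @param db A database from [build_database()].
#' @param scoring A [scoring_scheme()].
#' @param e_cutoff Significance cutoff (strict `<`).
#' @param search_space_residues Override for the database residue count used
#'   in the E-value; defaults to [db_total_residues()] of `db`.
#' @return A tibble of hits, one row per significant alignment, tagged with
#'   the subject protein's replicon accession.
#' @export
search_seed_protein <- function(query, db, scoring = scoring_scheme(),
                                e_cutoff = 1e-20,
                                search_space_residues = NULL) {
  if (!is.data.frame(query) || nrow(query) != 1) {
    abort("query must be a one-row proteome tibble")
  }
  if (nrow(db) == 0) abort("database is empty")
  if (is.null(search_space_residues)) search_space_residues <- db_total_residues(db)
  hits <- align_one_vs_many(query$sequence, db$sequence, scoring,
                            search_space_residues)
  if (nrow(hits) == 0) return(hits)
  hits %>%
    mutate(
      query_id = query$protein_id,
      subject_id = db$protein_id[.data$subject_index],
      subject_accession = db$replicon_accession[.data$subject_index]
    ) %>%
    filter(.data$e_value < e_cutoff) %>%
    select(-"subject_index")
}

#' Consolidate hits to the best hit on each replicon
#'
#' From all significant hits of one seed protein, keeps a single best hit per
#' replicon. The default ranking is best-BLAST-hit style — bit score
#' descending, then E-value ascending, then percent identity descending, then
#' subject id ascending as the deterministic tie-break. `rank_by =
#' "identity"` instead ranks by percent identity first (then bit score,
#' E-value, subject id), for the closest-homolog-by-identity reading.
#'
#' @param hits A hits tibble from [search_seed_protein()]; all rows must
#'   share one `query_id`.
#' @param rank_by `"bit_score"` (default) or `"identity"`.
#' @return A tibble with one row per replicon that has at least one hit;
#'   replicons without hits are simply absent.
#' @export
best_hit_per_replicon <- function(hits, rank_by = c("bit_score", "identity")) {
  rank_by <- match.arg(rank_by)
  if (nrow(hits) == 0) return(hits)
  if (length(unique(hits$query_id)) > 1) {
    abort("hits must all share a single query_id")
  }
  ranked <- if (rank_by == "bit_score") {
    arrange(hits, dplyr::desc(.data$bit_score), .data$e_value,
            dplyr::desc(.data$percent_identity), .data$subject_id)
  } else {
    arrange(hits, dplyr::desc(.data$percent_identity),
            dplyr::desc(.data$bit_score), .data$e_value, .data$subject_id)
  }
  ranked %>%
    group_by(.data$subject_accession) %>%
    slice(1) %>%
    ungroup()
}

#' Build the one-versus-all identity matrix
#'
#' The core computation: every protein of the seed genome is searched against
#' the database, significant hits are consolidated to the best hit per
#' replicon, and the best-hit percent identities are laid out as a matrix
#' with one column per seed protein — in seed gene order — and one row per
#' database replicon, in lexicographic accession order (the unsorted
#' default). Cells with no significant hit are `NA` (missing).
#'
#' Multi-replicon seeds contribute columns in the order the replicons are
#' given, each replicon's proteins in ordinal order.
#'
#' @param seed A proteome tibble or list of proteome tibbles (the seed
#'   genome's replicons, in column order).
#' @param db A database from [build_database()]; normally it contains the
#'   seed itself, so the self row is all 100.
#' @param scoring A [scoring_scheme()]; ignored by the blast backend.
#' @param e_cutoff Significance cutoff (strict `<`), default 1e-20.
#' @param backend `"internal"` (Smith-Waterman in-process) or `"blast"`
#'   (external BLAST+ executables; see [run_external_blast()]). The backend
#'   changes cell values only, never the matrix layout.
#' @param rank_by Best-hit ranking, see [best_hit_per_replicon()].
#' @return An [identity_matrix] object.
#' @export
build_matrix <- function(seed, db, scoring = scoring_scheme(),
                         e_cutoff = 1e-20,
                         backend = c("internal", "blast"),
                         rank_by = c("bit_score", "identity")) {
  backend <- match.arg(backend)
  rank_by <- match.arg(rank_by)
  if (is.data.frame(seed)) seed <- list(seed)
  if (length(seed) == 0 || sum(purrr::map_int(seed, nrow)) == 0) {
    abort("seed proteome is empty")
  }
  purrr::walk(seed, validate_proteome)
  seed_tbl <- bind_rows(purrr::map(seed, function(r) {
    # concatenate replicons in argument order, ordinal order within each
    r[order(match(r$replicon_accession, unique(r$replicon_accession)), r$ordinal), ]
  }))

  row_keys <- sort(unique(db$replicon_accession))
  row_meta <- db %>%
    distinct(.data$replicon_accession, .data$organism_name, .data$replicon_kind) %>%
    arrange(.data$replicon_accession)
  col_meta <- seed_tbl %>%
    select("protein_id", "locus_tag", "product")

  cells <- matrix(NA_real_, nrow = length(row_keys), ncol = nrow(seed_tbl),
                  dimnames = list(row_keys, seed_tbl$protein_id))

  all_best <- if (backend == "internal") {
    purrr::map(seq_len(nrow(seed_tbl)), function(i) {
      hits <- search_seed_protein(seed_tbl[i, ], db, scoring, e_cutoff)
      best_hit_per_replicon(hits, rank_by)
    })
  } else {
    hits <- run_external_blast(seed_tbl, db, e_cutoff)
    split_hits <- split(hits, factor(hits$query_id, levels = seed_tbl$protein_id))
    purrr::map(split_hits, best_hit_per_replicon, rank_by = rank_by)
  }

  for (i in seq_along(all_best)) {
    best <- all_best[[i]]
    if (nrow(best) > 0) {
      cells[best$subject_accession, i] <- best$percent_identity
    }
  }

  identity_matrix(cells, row_meta = row_meta, col_meta = col_meta)
}
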