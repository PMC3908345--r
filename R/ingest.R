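#' Parse a GenBank flat file into a replicon proteome
#'
#' Extracts every CDS feature carrying a `/translation` qualifier from a
#' GenBank flat file and returns one row per protein, ordered by the rank of
#' the gene's start coordinate on the replicon (strand is ignored). CDS
#' features flagged `/pseudo` or lacking a translation are skipped and counted
#' in the parse report attached to the result.
#'
#' Replicon kind is inferred from the LOCUS and DEFINITION lines and the
#' source feature's `/plasmid` qualifier: "plasmid" wins over "chromosome";
#' files naming neither are classed "unknown".
#'
#' @param path Path to a GenBank flat file. Multi-record files are supported;
#'   each record becomes its own replicon in the returned tibble.
#' @return A tibble with columns `protein_id`, `locus_tag`, `product`,
#'   `sequence`, `ordinal`, `replicon_accession`, `organism_name`,
#'   `replicon_kind`, carrying a `parse_report` attribute (see
#'   [parse_report()]).
#' @seealso [parse_fasta_proteome()], [build_database()]
#' @export
#' @examples
#' gbk <- system.file("extdata", "example_replicon.gbk", package = "repliconmap")
#' rep <- parse_genbank(gbk)
#' parse_report(rep)
parse_genbank <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read GenBank file: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort(sprintf("empty GenBank file: %s", path))

  term <- which(grepl("^//\\s*$", lines))
  if (length(term) == 0) term <- length(lines)
  starts <- c(1L, head(term, -1) + 1L)
  records <- purrr::map2(starts, term, function(a, b) lines[a:b])
  records <- purrr::keep(records, function(r) any(grepl("^LOCUS", r)))
  if (length(records) == 0) abort(sprintf("no GenBank records found in %s", path))

  parsed <- purrr::map(records, parse_genbank_record)
  out <- bind_rows(purrr::map(parsed, "proteins"))
  report <- bind_rows(purrr::map(parsed, "report"))
  if (nrow(out) == 0) {
    abort(sprintf("no usable CDS features (with /translation) in %s", path))
  }
  out$sequence <- sanitize_sequences(out$sequence, context = basename(path))
  validate_proteome(out, context = basename(path))
  attr(out, "parse_report") <- report
  out
}

#' Retrieve the parse report attached to a parsed proteome
#'
#' @param x A proteome tibble returned by [parse_genbank()] or
#'   [parse_fasta_proteome()].
#' @return A tibble with one row per replicon: counts of CDS features seen,
#'   kept, skipped as pseudo-genes, and skipped for lacking a translation.
#' @export
parse_report <- function(x) {
  rep <- attr(x, "parse_report")
  if (is.null(rep)) {
    rep <- tibble(replicon_accession = character(), n_cds = integer(),
                  n_kept = integer(), n_pseudo = integer(),
                  n_no_translation = integer())
  }
  rep
}

# Parse one GenBank record (LOCUS .. //) into proteins + report row.
parse_genbank_record <- function(lines) {
  locus_line <- lines[grepl("^LOCUS", lines)][1]
  accession <- genbank_field(lines, "VERSION")
  if (is.na(accession)) accession <- genbank_field(lines, "ACCESSION")
  if (is.na(accession)) accession <- strsplit(trimws(sub("^LOCUS", "", locus_line)), "\\s+")[[1]][1]
  accession <- strsplit(accession, "\\s+")[[1]][1]

  definition <- genbank_keyword_block(lines, "DEFINITION")
  organism <- genbank_field(lines, "  ORGANISM")
  if (is.na(organism)) organism <- ""

  feat_start <- which(grepl("^FEATURES", lines))
  feat_end <- which(grepl("^(ORIGIN|CONTIG)", lines))
  feat_end <- if (length(feat_end)) feat_end[1] - 1L else length(lines)
  feats <- if (length(feat_start)) lines[(feat_start[1] + 1L):feat_end] else character()

  features <- split_feature_table(feats)
  src <- purrr::detect(features, function(f) f$key == "source")
  plasmid_qual <- !is.null(src) && any(grepl("^/plasmid", src$qualifiers_raw))

  kind <- infer_replicon_kind(locus_line, definition, plasmid_qual)

  cds <- purrr::keep(features, function(f) f$key == "CDS")
  n_pseudo <- 0L
  n_no_trans <- 0L
  rows <- list()
  for (f in cds) {
    quals <- f$qualifiers
    if (isTRUE(quals$pseudo)) { n_pseudo <- n_pseudo + 1L; next }
    if (is.null(quals$translation) || !nzchar(quals$translation)) {
      n_no_trans <- n_no_trans + 1L
      next
    }
    rows[[length(rows) + 1L]] <- tibble(
      protein_id = quals$protein_id %||% sprintf("%s_cds%d", accession, length(rows) + 1L),
      locus_tag = quals$locus_tag %||% "",
      product = quals$product %||% "",
      sequence = quals$translation,
      start = f$start,
      replicon_accession = accession,
      organism_name = organism,
      replicon_kind = kind
    )
  }
  proteins <- bind_rows(rows)
  if (nrow(proteins) > 0) {
    proteins <- proteins %>%
      arrange(.data$start) %>%
      mutate(ordinal = row_number() - 1L) %>%
      select("protein_id", "locus_tag", "product", "sequence", "ordinal",
             "replicon_accession", "organism_name", "replicon_kind")
  }
  report <- tibble(
    replicon_accession = accession,
    n_cds = length(cds),
    n_kept = nrow(proteins),
    n_pseudo = n_pseudo,
    n_no_translation = n_no_trans
  )
  list(proteins = proteins, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

genbank_field <- function(lines, keyword) {
  hit <- lines[startsWith(lines, keyword)]
  if (length(hit) == 0) return(NA_character_)
  trimws(sub(paste0("^", keyword), "", hit[1]))
}

# A keyword block (e.g. DEFINITION) may wrap onto continuation lines indented
# by 12 spaces; join them into one string.
genbank_keyword_block <- function(lines, keyword) {
  i <- which(startsWith(lines, keyword))
  if (length(i) == 0) return("")
  i <- i[1]
  out <- trimws(sub(paste0("^", keyword), "", lines[i]))
  j <- i + 1L
  while (j <= length(lines) && grepl("^ {12}", lines[j]) && !grepl("^ {12,}/", lines[j])) {
    out <- paste(out, trimws(lines[j]))
    j <- j + 1L
  }
  out
}

# Split the FEATURES table into entries. A feature header line has its key in
# column 6 (5 leading spaces); qualifier/continuation lines are indented by 21.
split_feature_table <- function(feat_lines) {
  is_header <- grepl("^ {5}\\S", feat_lines)
  idx <- which(is_header)
  purrr::map(seq_along(idx), function(k) {
    a <- idx[k]
    b <- if (k < length(idx)) idx[k + 1L] - 1L else length(feat_lines)
    block <- feat_lines[a:b]
    key <- strsplit(trimws(block[1]), "\\s+")[[1]][1]
    loc <- sub("^\\s*\\S+\\s*", "", block[1])
    rest <- block[-1]
    # location may continue over lines until the first qualifier
    qual_start <- which(grepl("^\\s+/", rest))
    if (length(qual_start) == 0) qual_start <- length(rest) + 1L else qual_start <- qual_start[1]
    if (qual_start > 1L && length(rest) >= 1L) {
      loc <- paste0(loc, paste(trimws(rest[seq_len(qual_start - 1L)]), collapse = ""))
    }
    qual_lines <- if (qual_start <= length(rest)) rest[qual_start:length(rest)] else character()
    start <- suppressWarnings(min(as.numeric(
      regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
    )))
    list(key = key, start = start,
         qualifiers_raw = trimws(qual_lines),
         qualifiers = parse_qualifiers(qual_lines))
  })
}

# Fold qualifier continuation lines, then extract the handful we need.
parse_qualifiers <- function(qual_lines) {
  qual_lines <- trimws(qual_lines)
  entries <- list()
  current <- NULL
  for (ln in qual_lines) {
    if (startsWith(ln, "/")) {
      if (!is.null(current)) entries[[length(entries) + 1L]] <- current
      current <- ln
    } else if (!is.null(current)) {
      # translation continuations concatenate without spaces; free text keeps one
      sep <- if (startsWith(current, "/translation")) "" else " "
      current <- paste(current, ln, sep = sep)
    }
  }
  if (!is.null(current)) entries[[length(entries) + 1L]] <- current
  out <- list(pseudo = FALSE)
  for (e in entries) {
    if (grepl("^/pseudo(gene)?\\b", e) || identical(e, "/pseudo")) {
      out$pseudo <- TRUE
    }
    m <- regmatches(e, regexec('^/([A-Za-z_]+)="?([^"]*)"?$', e))[[1]]
    if (length(m) == 3) {
      key <- m[2]
      if (key %in% c("translation", "protein_id", "locus_tag", "product", "plasmid")) {
        out[[key]] <- gsub("\\s+", if (key == "translation") "" else " ", m[3])
      }
    }
  }
  out
}

infer_replicon_kind <- function(locus_line, definition, plasmid_qual) {
  text <- tolower(paste(locus_line, definition))
  if (plasmid_qual || grepl("plasmid", text)) return("plasmid")
  if (grepl("chromosome|complete genome", text)) return("chromosome")
  "unknown"
}

#' Parse a structured protein FASTA file into replicon proteomes
#'
#' Reads protein FASTA whose headers carry replicon identity and gene order:
#' `>protein_id|replicon_accession|ordinal|organism|product` with two optional
#' trailing fields `|locus_tag|replicon_kind` (written by
#' [write_fasta_proteome()] so that a proteome round-trips field-for-field).
#' Ordinals on each replicon must form the contiguous range `0..n-1`.
#'
#' @param path Path to a FASTA file in the dialect above.
#' @return A proteome tibble (see [parse_genbank()] for columns).
#' @export
parse_fasta_proteome <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read FASTA file: %s", path))
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) abort(sprintf("no records in FASTA file: %s", path))
  headers <- names(seqs)
  fields <- strsplit(headers, "|", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields < 5 | n_fields > 7)
  if (length(bad) > 0) {
    abort(sprintf("malformed FASTA header (expected 5-7 '|' fields): record %d '%s'",
                  bad[1], headers[bad[1]]))
  }
  out <- purrr::map2(fields, as.character(seqs), function(f, s) {
    ordinal <- suppressWarnings(as.integer(f[3]))
    if (is.na(ordinal)) {
      abort(sprintf("malformed FASTA header (non-integer ordinal): '%s'",
                    paste(f, collapse = "|")))
    }
    tibble(
      protein_id = f[1],
      locus_tag = if (length(f) >= 6) f[6] else "",
      product = f[5],
      sequence = s,
      ordinal = ordinal,
      replicon_accession = f[2],
      organism_name = f[4],
      replicon_kind = if (length(f) >= 7) f[7] else "unknown"
    )
  }) %>% bind_rows()
  out$sequence <- sanitize_sequences(out$sequence, context = basename(path))
  for (acc in unique(out$replicon_accession)) {
    ords <- sort(out$ordinal[out$replicon_accession == acc])
    if (anyDuplicated(ords)) {
      abort(sprintf("duplicate ordinal %d on replicon %s in %s",
                    ords[which(duplicated(ords))[1]], acc, basename(path)))
    }
    if (!identical(ords, seq(0L, length(ords) - 1L))) {
      abort(sprintf("ordinal gap on replicon %s in %s: ordinals must be contiguous 0..n-1",
                    acc, basename(path)))
    }
  }
  out <- arrange(out, .data$replicon_accession, .data$ordinal)
  validate_proteome(out, context = basename(path))
  out
}

#' Write a proteome to the structured FASTA dialect
#'
#' Emits the 7-field header
#' `>protein_id|replicon_accession|ordinal|organism|product|locus_tag|kind`
#' read back by [parse_fasta_proteome()]; the first five fields form the
#' minimal dialect, so other tools need only supply those.
#'
#' @param proteome A proteome tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_proteome <- function(proteome, path) {
  validate_proteome(proteome)
  proteome <- arrange(proteome, .data$replicon_accession, .data$ordinal)
  clean <- function(x) gsub("[|\n\t]", " ", x)
  headers <- sprintf("%s|%s|%d|%s|%s|%s|%s",
                     clean(proteome$protein_id), clean(proteome$replicon_accession),
                     proteome$ordinal, clean(proteome$organism_name),
                     clean(proteome$product), clean(proteome$locus_tag),
                     clean(proteome$replicon_kind))
  set <- Biostrings::AAStringSet(setNames(proteome$sequence, headers))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Assemble replicon proteomes into a protein database
#'
#' Binds one or more replicon proteomes into the database searched by
#' [build_matrix()]. The seed genome's own replicons belong in the database
#' too — that is what makes the self row render at 100% identity.
#'
#' @param replicons A proteome tibble or a list of proteome tibbles.
#' @return A tibble of class `rmap_db` with a `total_residues` attribute
#'   (see [db_total_residues()]). Replicon accessions must be unique and
#'   protein ids unique database-wide.
#' @export
build_database <- function(replicons) {
  if (is.data.frame(replicons)) replicons <- list(replicons)
  if (length(replicons) == 0) abort("at least one replicon is required")
  purrr::walk(replicons, validate_proteome)
  accs <- purrr::map(replicons, function(r) unique(r$replicon_accession))
  all_accs <- unlist(accs)
  if (anyDuplicated(all_accs)) {
    abort(sprintf("duplicate replicon accession in database: %s",
                  all_accs[which(duplicated(all_accs))[1]]))
  }
  db <- bind_rows(replicons)
  if (anyDuplicated(db$protein_id)) {
    abort(sprintf("duplicate protein_id in database: %s",
                  db$protein_id[which(duplicated(db$protein_id))[1]]))
  }
  attr(db, "total_residues") <- sum(nchar(db$sequence))
  class(db) <- c("rmap_db", class(db))
  db
}

#' Total residue count of a protein database
#'
#' Recomputed from the sequences, so it stays correct after dplyr
#' manipulation drops the cached attribute.
#'
#' @param db A database from [build_database()] (any proteome tibble works).
#' @return Integer: the summed length of all sequences.
#' @export
db_total_residues <- function(db) {
  sum(nchar(db$sequence))
}
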