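#' Generate a random synthetic proteome
#'
#' Draws proteins i.i.d. over the 20 canonical amino acids with uniform
#' composition (which keeps true homologs highly significant at fixture
#' scale), lengths uniform in `length_range`, ordinals `0..n-1`. Pure
#' function of the seed.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param length_range Integer pair `c(min, max)` of protein lengths;
#'   default 150-300 aa so planted homologies clear the significance cutoff
#'   in a small search space.
#' @param rng_seed Integer seed.
#' @param accession,organism,kind Replicon metadata for the result.
#' @return A proteome tibble.
#' @export
random_proteome <- function(n_proteins, length_range = c(150L, 300L), rng_seed,
                            accession = "SYN0001", organism = "Synthetica demo",
                            kind = "chromosome") {
  if (n_proteins < 1) abort("n_proteins must be >= 1")
  if (length(length_range) != 2 || length_range[1] > length_range[2] ||
      length_range[1] < 1) {
    abort("length_range must be an increasing positive integer pair")
  }
  letters20 <- setdiff(AA_ALPHABET, "X")
  with_seed(rng_seed, {
    span <- length_range[2] - length_range[1] + 1L
    lens <- length_range[1] + sample.int(span, n_proteins, replace = TRUE) - 1L
    seqs <- vapply(lens, function(L) {
      paste(sample(letters20, L, replace = TRUE), collapse = "")
    }, character(1))
    tibble(
      protein_id = sprintf("%s_p%03d", accession, seq_len(n_proteins)),
      locus_tag = sprintf("%s_%04d", accession, seq_len(n_proteins)),
      product = sprintf("hypothetical protein %d", seq_len(n_proteins)),
      sequence = seqs,
      ordinal = seq_len(n_proteins) - 1L,
      replicon_accession = accession,
      organism_name = organism,
      replicon_kind = kind
    )
  })
}

#' Mutate a protein sequence at a fixed per-residue substitution rate
#'
#' Each residue is independently replaced, with probability `rate`, by a
#' uniformly chosen *different* canonical letter. Length is preserved (no
#' indels), so the expected aligned identity of original versus evolved is
#' about `100 * (1 - rate)`. Pure function of the seed.
#'
#' @param sequence Amino-acid string.
#' @param rate Substitution probability per residue, in `[0, 1)`.
#' @param rng_seed Integer seed.
#' @return The mutated sequence string.
#' @export
evolve_protein <- function(sequence, rate, rng_seed) {
  if (rate < 0 || rate >= 1) abort("rate must lie in [0, 1)")
  if (rate == 0) return(sequence)
  letters20 <- setdiff(AA_ALPHABET, "X")
  with_seed(rng_seed, {
    chars <- strsplit(sequence, "")[[1]]
    hit <- stats::runif(length(chars)) < rate
    for (i in which(hit)) {
      chars[i] <- sample(setdiff(letters20, chars[i]), 1)
    }
    paste(chars, collapse = "")
  })
}

#' Parameters controlling a derived genome
#'
#' @param substitution_rate Background per-residue substitution rate,
#'   `[0, 1)`.
#' @param fast_clock Optional named numeric vector: names are seed ordinals,
#'   values are elevated rates (each must exceed `substitution_rate`).
#' @param deleted_block Optional integer pair `c(start_ordinal, length)`: a
#'   contiguous gene block removed from the derived genome.
#' @param hgt_block Optional list `list(start, length, source)` where
#'   `source` is the accession of the donor genome: the block's proteins are
#'   near-verbatim copies (rate 0.01) of the donor's proteins at the same
#'   ordinals.
#' @param rng_seed Integer seed.
#' @return A list of class `evolution_params`.
#' @export
evolution_params <- function(substitution_rate, fast_clock = NULL,
                             deleted_block = NULL, hgt_block = NULL,
                             rng_seed) {
  if (substitution_rate < 0 || substitution_rate >= 1) {
    abort("substitution_rate must lie in [0, 1)")
  }
  if (!is.null(fast_clock) && any(fast_clock <= substitution_rate)) {
    abort("fast-clock rates must exceed the background substitution_rate")
  }
  structure(list(substitution_rate = substitution_rate, fast_clock = fast_clock,
                 deleted_block = deleted_block, hgt_block = hgt_block,
                 rng_seed = rng_seed),
            class = "evolution_params")
}

#' Derive an evolved genome from a seed proteome
#'
#' Applies, in order: per-protein substitution at the background rate (or a
#' fast-clock rate for designated ordinals), replacement of the HGT block by
#' near-verbatim copies (rate 0.01) of the donor genome's proteins at the
#' same seed ordinals, and removal of the deleted block. Surviving proteins
#' get fresh contiguous ordinals and ids prefixed by the new accession.
#'
#' @param seed A proteome tibble (single replicon).
#' @param params An [evolution_params()].
#' @param sources Named list of donor proteome tibbles, keyed by accession;
#'   required when `params$hgt_block` is set.
#' @param accession,organism New replicon metadata.
#' @return A proteome tibble.
#' @export
derive_genome <- function(seed, params, sources = NULL,
                          accession = "SYNDRV01",
                          organism = "Synthetica derivata") {
  validate_proteome(seed)
  seed <- arrange(seed, .data$ordinal)
  n <- nrow(seed)
  check_block <- function(b, what) {
    if (!is.null(b) && (b[1] < 0 || b[2] < 1 || b[1] + b[2] > n)) {
      abort(sprintf("%s must lie within the seed proteome (0..%d)", what, n - 1))
    }
  }
  del <- params$deleted_block
  hgt <- params$hgt_block
  check_block(del, "deleted_block")
  if (!is.null(hgt)) check_block(c(hgt$start, hgt$length), "hgt_block")
  if (!is.null(del) && !is.null(hgt)) {
    del_ords <- del[1]:(del[1] + del[2] - 1)
    hgt_ords <- hgt$start:(hgt$start + hgt$length - 1)
    if (length(intersect(del_ords, hgt_ords)) > 0) {
      abort("deleted_block and hgt_block must not overlap")
    }
  }

  rates <- rep(params$substitution_rate, n)
  if (!is.null(params$fast_clock)) {
    idx <- as.integer(names(params$fast_clock)) + 1L
    if (any(idx < 1 | idx > n)) abort("fast-clock ordinal outside the seed proteome")
    rates[idx] <- params$fast_clock
  }

  sub_seeds <- with_seed(params$rng_seed, sample.int(.Machine$integer.max - 1L, n))
  seqs <- vapply(seq_len(n), function(i) {
    evolve_protein(seed$sequence[i], rates[i], sub_seeds[i])
  }, character(1))

  if (!is.null(hgt)) {
    donor <- sources[[hgt$source]]
    if (is.null(donor)) {
      abort(sprintf("hgt_block source genome '%s' not found in sources", hgt$source))
    }
    donor <- arrange(donor, .data$ordinal)
    for (k in seq_len(hgt$length)) {
      ord <- hgt$start + k - 1L
      donor_seq <- donor$sequence[donor$ordinal == ord]
      if (length(donor_seq) != 1) {
        abort(sprintf("donor genome lacks ordinal %d for the hgt_block", ord))
      }
      seqs[ord + 1L] <- evolve_protein(donor_seq, 0.01, sub_seeds[ord + 1L] + 1L)
    }
  }

  keep <- rep(TRUE, n)
  if (!is.null(del)) keep[(del[1] + 1L):(del[1] + del[2])] <- FALSE

  out <- tibble(
    protein_id = sprintf("%s_p%03d", accession, seq_len(sum(keep))),
    locus_tag = sprintf("%s_%04d", accession, seq_len(sum(keep))),
    product = seed$product[keep],
    sequence = seqs[keep],
    ordinal = seq_len(sum(keep)) - 1L,
    replicon_accession = accession,
    organism_name = organism,
    replicon_kind = seed$replicon_kind[1]
  )
  validate_proteome(out)
  out
}

#' Build the default synthetic test universe
#'
#' A fixed cast of genomes exercising every heat-map pattern the package
#' renders: a 20-protein seed; derivatives at substitution rates 0.02, 0.10
#' and 0.30; a deletion genome (rate 0.02) missing the 5-protein block at
#' seed ordinals 8-12; an HGT recipient (rate 0.02) whose 4-protein block at
#' ordinals 3-6 is copied near-verbatim from the distant rate-0.30 genome;
#' and four near-identical strains (rate 0.01) sharing a fast-clock column
#' at ordinal 15 evolving at rate 0.25. The manifest records every planted
#' event so tests can assert against it.
#'
#' @param rng_seed Integer seed; the whole universe is a pure function of it.
#' @return A list with `seed` (the seed proteome), `genomes` (named list of
#'   all proteomes including the seed), `db` (the assembled
#'   [build_database()]) and `manifest` (a tibble of genomes and planted
#'   events).
#' @export
make_test_universe <- function(rng_seed = 42L) {
  seeds <- with_seed(rng_seed, sample.int(.Machine$integer.max - 1L, 12))
  seed <- random_proteome(20, c(150L, 300L), seeds[1], accession = "SYNSEED01",
                          organism = "Synthetica prima", kind = "chromosome")

  mk <- function(acc, org, rate, sub_seed, ...) {
    derive_genome(seed, evolution_params(substitution_rate = rate,
                                         rng_seed = sub_seed, ...),
                  accession = acc, organism = org)
  }
  genomes <- list(SYNSEED01 = seed)
  genomes$SYNDIV02 <- mk("SYNDIV02", "Synthetica proxima", 0.02, seeds[2])
  genomes$SYNDIV10 <- mk("SYNDIV10", "Synthetica media", 0.10, seeds[3])
  genomes$SYNDIV30 <- mk("SYNDIV30", "Synthetica remota", 0.30, seeds[4])
  genomes$SYNDEL01 <- derive_genome(
    seed, evolution_params(0.02, deleted_block = c(8L, 5L), rng_seed = seeds[5]),
    accession = "SYNDEL01", organism = "Synthetica lacunosa")
  genomes$SYNHGT01 <- derive_genome(
    seed, evolution_params(0.02,
                           hgt_block = list(start = 3L, length = 4L,
                                            source = "SYNDIV30"),
                           rng_seed = seeds[6]),
    sources = genomes["SYNDIV30"],
    accession = "SYNHGT01", organism = "Synthetica chimaera")
  fc <- c("15" = 0.25)
  for (k in 1:4) {
    acc <- sprintf("SYNFCS%02d", k)
    genomes[[acc]] <- derive_genome(
      seed, evolution_params(0.01, fast_clock = fc, rng_seed = seeds[6 + k]),
      accession = acc, organism = sprintf("Synthetica gemella str. %d", k))
  }

  manifest <- bind_rows(
    tibble(genome = "SYNSEED01", event = "seed", rate = NA_real_,
           start = NA_integer_, length = NA_integer_, source = NA_character_),
    tibble(genome = c("SYNDIV02", "SYNDIV10", "SYNDIV30"), event = "diverged",
           rate = c(0.02, 0.10, 0.30), start = NA_integer_,
           length = NA_integer_, source = NA_character_),
    tibble(genome = "SYNDEL01", event = "deletion", rate = 0.02,
           start = 8L, length = 5L, source = NA_character_),
    tibble(genome = "SYNHGT01", event = "hgt", rate = 0.02,
           start = 3L, length = 4L, source = "SYNDIV30"),
    tibble(genome = sprintf("SYNFCS%02d", 1:4), event = "fast_clock",
           rate = 0.01, start = 15L, length = 1L, source = NA_character_)
  )

  list(seed = seed, genomes = genomes, db = build_database(unname(genomes)),
       manifest = manifest)
}

# Evaluate code under a temporary RNG state; restores the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
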