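test_that("alignment scores match the brute-force DP oracle on short pairs", {
  sc <- scoring_scheme()
  withr::local_seed(101)
  for (k in 1:25) {
    q <- random_aa_string(sample(8:30, 1))
    s <- random_aa_string(sample(8:30, 1))
    expected <- sw_oracle(q, s, sc$matrix, sc$gap_open, sc$gap_extend)
    hit <- align_pair(q, s, sc, search_space_residues = 1000)
    got <- if (is.null(hit)) 0 else hit$raw_score
    expect_equal(got, expected)
  }
  # 8-residue toy pair, scored through the same independently written oracle
  q <- "MKVLWAAH"
  s <- "MKVWAAHH"
  hit <- align_pair(q, s, sc, search_space_residues = 100)
  expect_equal(hit$raw_score, sw_oracle(q, s, sc$matrix, 11, 1))
})

test_that("self-alignment is gap-free with 100% identity and closed-form E-value", {
  sc <- scoring_scheme()
  withr::local_seed(7)
  s <- random_aa_string(100)
  hit <- align_pair(s, s, sc, search_space_residues = 10000)
  expect_equal(hit$percent_identity, 100)
  expect_equal(hit$align_length, 100L)
  expect_equal(hit$n_identities, 100L)
  # E = K m n exp(-lambda S), evaluated directly
  expect_equal(hit$e_value, 0.041 * 100 * 10000 * exp(-0.267 * hit$raw_score))
  expect_equal(hit$bit_score, (0.267 * hit$raw_score - log(0.041)) / log(2))
  # percent identity recomputes from its own parts
  expect_equal(hit$percent_identity,
               100 * hit$n_identities / hit$align_length, tolerance = 1e-9)
})

test_that("alignment score and identities are symmetric in the pair", {
  sc <- scoring_scheme()
  withr::local_seed(23)
  for (k in 1:20) {
    a <- random_aa_string(sample(15:40, 1))
    b <- random_aa_string(sample(15:40, 1))
    ha <- align_pair(a, b, sc, search_space_residues = 1000)
    hb <- align_pair(b, a, sc, search_space_residues = 1000)
    if (is.null(ha)) {
      expect_null(hb)
    } else {
      expect_equal(ha$raw_score, hb$raw_score)
      expect_equal(ha$n_identities, hb$n_identities)
    }
  }
})

test_that("X is scored zero against everything including itself", {
  sc <- scoring_scheme()
  expect_true(all(sc$matrix["X", ] == 0))
  expect_null(align_pair("XXXXXXXXXX", "XXXXXXXXXX", sc))
  # masked stretch contributes nothing: score equals the unmasked flank alone
  flank <- "WWWWWWWWWW"
  h1 <- align_pair(paste0(flank, "XXXXX"), flank, sc, 1000)
  h2 <- align_pair(flank, flank, sc, 1000)
  expect_equal(h1$raw_score, h2$raw_score)
})

test_that("letters outside the alphabet are rejected", {
  expect_error(align_pair("MK7LL", "MKLL"), "invalid residue")
})

test_that("the significance filter is strictly below the cutoff", {
  sc <- scoring_scheme()
  q <- paste(rep("W", 19), collapse = "")
  subj <- random_proteome(1, c(19L, 19L), 3, accession = "EV1")
  subj$sequence <- q
  db <- build_database(subj)
  raw <- align_pair(q, q, sc, search_space_residues = 19)$raw_score
  # pick search spaces that land the E-value at 1e-19 and 1e-21
  n_for <- function(e) round(e * exp(sc$lambda * raw) / (sc$K * nchar(q)))
  query <- subj
  query$protein_id <- "queryprot"
  hi <- search_seed_protein(query, db, sc, search_space_residues = n_for(1e-19))
  lo <- search_seed_protein(query, db, sc, search_space_residues = n_for(1e-21))
  expect_equal(nrow(hi), 0)  # E ~ 1e-19 > cutoff: excluded
  expect_equal(nrow(lo), 1)  # E ~ 1e-21 < cutoff: retained
  expect_equal(lo$e_value, 1e-21, tolerance = 0.01)
  expect_equal(lo$subject_accession, "EV1")
})

test_that("best-hit consolidation ranks and tie-breaks deterministically", {
  base <- tibble::tibble(
    query_id = "q", subject_id = c("s1", "s2"), subject_accession = "R1",
    percent_identity = c(45, 80), e_value = c(1e-30, 1e-60),
    bit_score = c(100, 200), raw_score = c(250, 500),
    align_length = c(100L, 100L), n_identities = c(45L, 80L)
  )
  best <- best_hit_per_replicon(base)
  expect_equal(nrow(best), 1)
  expect_equal(best$subject_id, "s2")

  tied <- base
  tied$subject_id <- c("B", "A")
  tied$percent_identity <- c(50, 50)
  tied$e_value <- c(1e-40, 1e-40)
  tied$bit_score <- c(150, 150)
  expect_equal(best_hit_per_replicon(tied)$subject_id, "A")

  two <- base
  two$subject_accession <- c("R1", "R2")
  expect_equal(nrow(best_hit_per_replicon(two)), 2)

  mixed <- base
  mixed$query_id <- c("q1", "q2")
  expect_error(best_hit_per_replicon(mixed), "single query_id")

  # identity-first ranking prefers the higher-identity, lower-score hit
  alt <- base
  alt$percent_identity <- c(90, 80)
  expect_equal(best_hit_per_replicon(alt)$subject_id, "s2")
  expect_equal(best_hit_per_replicon(alt, rank_by = "identity")$subject_id, "s1")
})

test_that("build_matrix lays out self, paralog and no-hit rows correctly", {
  seed <- random_proteome(4, c(120L, 150L), 17, accession = "SEEDA",
                          organism = "Seed org")
  # two identical paralogs in the seed
  seed$sequence[2] <- seed$sequence[1]
  unrelated <- random_proteome(3, c(120L, 150L), 99, accession = "FARAWAY",
                               organism = "Unrelated org")
  db <- build_database(list(seed, unrelated))

  m <- build_matrix(seed, db)
  expect_equal(rownames(m$cells), c("FARAWAY", "SEEDA"))  # lexicographic rows
  expect_equal(colnames(m$cells), seed$protein_id)        # seed gene order
  expect_equal(unname(m$cells["SEEDA", ]), rep(100, 4))
  expect_true(all(is.na(m$cells["FARAWAY", ])))
  expect_equal(dim(m), c(2L, 4L))

  expect_error(build_matrix(list(), db), "empty")
})

test_that("multi-replicon seeds concatenate columns in argument order", {
  chr <- random_proteome(3, c(100L, 120L), 31, accession = "MR_CHR")
  pla <- random_proteome(2, c(100L, 120L), 32, accession = "MR_PLA",
                         kind = "plasmid")
  db <- build_database(list(chr, pla))
  m <- build_matrix(list(pla, chr), db)
  expect_equal(colnames(m$cells), c(pla$protein_id, chr$protein_id))
  expect_equal(unname(m$cells["MR_PLA", 1:2]), rep(100, 2))
  expect_equal(unname(m$cells["MR_CHR", 3:5]), rep(100, 3))
})
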