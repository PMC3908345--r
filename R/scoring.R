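#' Construct an alignment scoring scheme
#'
#' Bundles the substitution matrix, affine gap penalties (a gap of length L
#' costs `gap_open + gap_extend * L`) and the Karlin-Altschul parameters used
#' to convert raw Smith-Waterman scores into E-values and bit scores:
#' \deqn{E = K m n e^{-\lambda S}, \qquad S' = (\lambda S - \ln K)/\ln 2}
#' with m the query length and n the search-space residue count.
#'
#' Defaults follow BLASTP: BLOSUM62, gap open 11, gap extend 1, and the
#' gapped-BLOSUM62 constants lambda = 0.267, K = 0.041. The mask letter X is
#' forced to score 0 against every letter including itself, so masked
#' residues can neither help nor hurt an alignment.
#'
#' @param substitution_matrix Square symmetric integer matrix with amino-acid
#'   letter dimnames. Default: BLOSUM62 from Biostrings with the X row/column
#'   zeroed.
#' @param gap_open,gap_extend Positive gap penalties; `gap_extend` must not
#'   exceed `gap_open`.
#' @param lambda,K Positive Karlin-Altschul parameters.
#' @return A list of class `scoring_scheme`.
#' @export
#' @examples
#' sc <- scoring_scheme()
#' sc$matrix["W", "W"]
scoring_scheme <- function(substitution_matrix = NULL,
                           gap_open = 11L, gap_extend = 1L,
                           lambda = 0.267, K = 0.041) {
  if (is.null(substitution_matrix)) {
    substitution_matrix <- default_blosum62_x0()
  }
  if (!isTRUE(all.equal(substitution_matrix, t(substitution_matrix)))) {
    abort("substitution matrix must be symmetric")
  }
  if (gap_open <= 0 || gap_extend <= 0) abort("gap penalties must be positive")
  if (gap_extend > gap_open) abort("gap_extend must not exceed gap_open")
  if (lambda <= 0 || K <= 0) abort("lambda and K must be positive")
  structure(
    list(matrix = substitution_matrix, gap_open = as.integer(gap_open),
         gap_extend = as.integer(gap_extend), lambda = lambda, K = K),
    class = "scoring_scheme"
  )
}

# BLOSUM62 with the X row/column (and the letters folded into X) zeroed.
default_blosum62_x0 <- function() {
  mat <- get_blosum62()
  mat["X", ] <- 0L
  mat[, "X"] <- 0L
  mat
}

get_blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf(
    "<scoring_scheme> %dx%d matrix, gap open %d / extend %d, lambda %.3f, K %.3f\n",
    nrow(x$matrix), ncol(x$matrix), x$gap_open, x$gap_extend, x$lambda, x$K))
  invisible(x)
}

karlin_evalue <- function(raw_score, m, n, scoring) {
  scoring$K * m * n * exp(-scoring$lambda * raw_score)
}

karlin_bitscore <- function(raw_score, scoring) {
  (scoring$lambda * raw_score - log(scoring$K)) / log(2)
}
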