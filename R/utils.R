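# Shared helpers: IUPAC tables, seed derivation, small sequence utilities.

# IUPAC nucleotide codes (incl. gap) accepted by the readers.
IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

# Two-base ambiguity code for an unordered base pair, e.g. c("A","C") -> "M".
HET_CODE <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

BASES <- c("A", "C", "G", "T")

#' Derive a stage-specific random seed from a master seed
#'
#' Each pipeline stage draws from its own stream keyed by
#' `(master_seed, stage)`, so running stages in a different order (or
#' skipping one) does not perturb the results of the others.
#'
#' @param master_seed Non-negative integer master seed.
#' @param stage Character scalar naming the stage.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            master_seed >= 0, is.character(stage), length(stage) == 1L)
  h <- as.double(master_seed) %% 2147483647
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

# Split sequences (character vector) into an aligned character matrix,
# one row per sequence. All sequences must share one length.
seq_char_matrix <- function(seqs) {
  if (length(seqs) == 0L) return(matrix(character(), 0, 0))
  n <- unique(nchar(seqs))
  if (length(n) != 1L) stop("sequences are not of equal length")
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}

chars_to_seq <- function(ch) paste(ch, collapse = "")

# Ungapped end-anchored (5'-aligned) identity over the overlap of two
# sequences; the deterministic comparison used by the greedy clusterers.
ungapped_identity <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0)
  av <- utf8ToInt(substr(a, 1L, n))
  bv <- utf8ToInt(substr(b, 1L, n))
  sum(av == bv) / n
}

# Random DNA string of length n (uses the current RNG state).
random_dna <- function(n) chars_to_seq(sample(BASES, n, replace = TRUE))

`%||%` <- function(a, b) if (is.null(a)) b else a
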