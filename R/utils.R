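# Shared internal helpers.

# Standard one-letter amino-acid alphabet (order used throughout: the
# classic PAM/Dayhoff ordering ARNDCQEGHILKMFPSTWYV).
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Residues additionally allowed in chain records: alignment gap and
# unknown residue.
AA_EXTRA <- c("-", "X")

# Fixed helical-domain widths (sites) of the three collagen (I) chains.
CHAIN_LENGTHS <- c(alpha1 = 1058L, alpha2 = 1041L, alpha3 = 1062L)

CHAINS <- c("alpha1", "alpha2", "alpha3")

#' Round half away from zero
#'
#' Display rounding used for rate tables: 0.95 rounds to 1.0, unlike
#' [round()]'s round-half-even convention.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
#' @noRd
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Split a sequence string into a character vector of residues.
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Validate residues of `s` against an allowed set; returns the index of
# the first offending character or 0L if clean.
first_bad_char <- function(s, allowed) {
  ch <- seq_chars(s)
  bad <- which(!(ch %in% allowed))
  if (length(bad)) bad[1] else 0L
}

# Derive a stream-specific seed from a master seed, keeping the result a
# valid 32-bit integer.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 1009) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
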