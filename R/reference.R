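# Bundled synthetic collagen-like reference sequences.
#
# The discriminator operations need a fixed alpha1 reference to anchor
# helical-position numbering.  No real accession is redistributed here:
# the references are synthetic collagen-like sequences, built
# deterministically in code, that carry the biologically diagnostic
# features at their canonical coordinates -- Gly at (almost) every third
# helical position, conserved K/R tryptic boundaries, the T32/33 window
# at helical positions 334-350 (the published zebrafish peptides
# GGPGVVGPKGATGEPGR for alpha1 and GANGPMGAQGASGESGR for alpha3), and
# Cys/Ser at procollagen position 1264.

T33_WINDOW_START <- 334L
T33_WINDOW_END <- 350L
T33_ALPHA1 <- "GGPGVVGPKGATGEPGR"
T33_ALPHA3 <- "GANGPMGAQGASGESGR"
# alpha2 carries no discriminator; a neutral residue sits at the ninth
# window position so the T33 rule correctly returns 'indeterminate'
T33_ALPHA2 <- "GANGPMGAAGASGESGR"
POS1264 <- 1264L

# residues cycled through non-glycine helical positions (collagen-typical
# X/Y occupants; no K/R so tryptic boundaries stay where placed)
.HELICAL_FILL <- c("P", "A", "S", "E", "D", "Q", "N", "T", "V", "L",
                   "M", "F", "H", "I")
# filler for non-helical procollagen segments
.PRO_FILL <- c("S", "E", "D", "A", "V", "N", "Q", "T", "L", "F", "P",
               "G", "H", "W", "Y", "M", "I")

#' Conserved tryptic-boundary positions of a helical chain
#'
#' Positions of the conserved K/R residues that delimit tryptic
#' peptides, spaced roughly every `spacing` sites and shifted off the
#' glycine frame (positions congruent to 1 mod 3).
#'
#' @param length chain length in sites.
#' @param spacing approximate spacing between boundaries (default 50).
#' @return integer vector of 1-based positions.
#' @export
tryptic_boundary_positions <- function(length, spacing = 50L) {
  p <- seq(spacing, length - 1L, by = spacing)
  p <- vapply(p, function(q) {
    while (q %% 3L == 1L) q <- q - 1L
    q
  }, numeric(1))
  unique(as.integer(p))
}

build_helical <- function(chain = c("alpha1", "alpha2", "alpha3")) {
  chain <- match.arg(chain)
  L <- CHAIN_LENGTHS[[chain]]
  res <- .HELICAL_FILL[(seq_len(L) %% length(.HELICAL_FILL)) + 1L]
  res[seq(1L, L, by = 3L)] <- "G"
  res[tryptic_boundary_positions(L)] <- "R"
  win <- switch(chain, alpha1 = T33_ALPHA1, alpha2 = T33_ALPHA2,
                alpha3 = T33_ALPHA3)
  res[T33_WINDOW_START:T33_WINDOW_END] <- seq_chars(win)
  paste(res, collapse = "")
}

build_procollagen <- function(chain = c("alpha1", "alpha3")) {
  chain <- match.arg(chain)
  n_pro <- 161L   # signal peptide + N-propeptide
  n_telo <- 17L   # N-telopeptide
  c_telo <- 26L   # C-telopeptide
  c_pro <- 246L   # C-propeptide
  fill <- function(n) .PRO_FILL[(seq_len(n) %% length(.PRO_FILL)) + 1L]
  res <- c(fill(n_pro), fill(n_telo), seq_chars(build_helical(chain)),
           fill(c_telo), fill(c_pro))
  res[POS1264] <- if (chain == "alpha1") "C" else "S"
  paste(res, collapse = "")
}

#' Synthetic collagen-like reference sequences
#'
#' Deterministic, code-built reference chains used to anchor helical and
#' procollagen coordinates in the classifiers.  They are synthetic
#' stand-ins, not real accessions, but carry the diagnostic features at
#' their canonical positions: the T32/33 window (helical 334-350) holds
#' the published zebrafish alpha1/alpha3 tryptic peptides, and
#' procollagen position 1264 holds Cys (alpha1) or Ser (alpha3).
#'
#' @param type which reference to build.
#' @return a [chain_record()] with `source_id = "synthetic reference"`.
#' @examples
#' ref <- collagen_reference("alpha1_helical")
#' substr(ref$sequence, 334, 350)   # GGPGVVGPKGATGEPGR
#' @export
collagen_reference <- function(type = c("alpha1_helical", "alpha2_helical",
                                        "alpha3_helical",
                                        "alpha1_procollagen",
                                        "alpha3_procollagen")) {
  type <- match.arg(type)
  chain <- sub("_.*$", "", type)
  region <- sub("^[^_]*_", "", type)
  seqstr <- if (region == "helical") build_helical(chain)
            else build_procollagen(chain)
  chain_record(taxon = "reference", chain = chain, sequence = seqstr,
               region = region, source_id = "synthetic reference",
               relaxed = (region == "procollagen"))
}

#' Invariant-site mask for a simulated collagen chain
#'
#' Positions held fixed during sequence simulation, with their mandated
#' residues: the glycine frame (every third helical position), the
#' conserved K/R tryptic boundaries, and the chain-diagnostic T32/33
#' window (embedding the alpha1/alpha3 discriminator signatures, or the
#' neutral alpha2 window).
#'
#' @param chain `"alpha1"`, `"alpha2"` or `"alpha3"`.
#' @param length chain length (default: the chain's canonical width).
#' @return named character vector: values are residues, names are
#'   1-based positions.
#' @export
default_invariant_mask <- function(chain, length = CHAIN_LENGTHS[[chain]]) {
  res <- character(0)
  gly <- seq(1L, length, by = 3L)
  res[as.character(gly)] <- "G"
  bnd <- tryptic_boundary_positions(length)
  res[as.character(bnd)] <- "R"
  if (length >= T33_WINDOW_END) {
    win <- switch(chain, alpha1 = T33_ALPHA1, alpha2 = T33_ALPHA2,
                  alpha3 = T33_ALPHA3)
    res[as.character(T33_WINDOW_START:T33_WINDOW_END)] <- seq_chars(win)
  }
  res
}
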