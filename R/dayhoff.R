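# Dayhoff empirical amino-acid substitution model.
#
# Exchangeabilities are the published Dayhoff (1978) PAM values in the
# standard lower-triangular PAML layout over the residue order
# ARNDCQEGHILKMFPSTWYV, together with the matching stationary
# frequencies.  These are fixed literature constants, bundled here so the
# model needs no external files.

.DAYHOFF_S_LOWER <- c(
  27, 98, 120, 36, 89, 198, 240, 23, 65, 41, 26, 72, 18, 250, 409, 371,
  0, 24, 208, 32, 0, 23, 246, 1, 9, 240, 64, 15, 464, 90, 14, 103, 154,
  26, 201, 8, 24, 905, 0, 103, 148, 139, 535, 77, 34, 318, 1, 14, 42,
  495, 229, 23, 95, 15, 0, 134, 1153, 125, 86, 24, 0, 71, 0, 0, 13, 95,
  66, 0, 0, 18, 0, 0, 11, 28, 44, 0, 0, 0, 0, 19, 161, 16, 0, 96, 49,
  716, 28, 606, 18, 73, 153, 114, 0, 153, 56, 53, 0, 0, 35, 81, 43, 61,
  11, 83, 30, 0, 51, 79, 34, 0, 22, 37, 10, 0, 7, 27, 17, 15, 34, 234,
  30, 0, 0, 54, 7, 44, 26, 0, 48, 94, 35, 22, 27, 127, 44, 257, 46, 336,
  196, 12, 24, 192, 0, 37, 889, 18, 527, 157, 32, 17, 33, 46, 28, 175,
  243, 0, 33, 96, 136, 0, 13, 10, 92, 17, 62, 104, 0, 0, 258, 11, 46,
  13, 76, 698, 12, 245, 78, 0, 0, 48, 550, 75, 34, 30, 0, 42, 157, 61,
  0, 28)

.DAYHOFF_FREQS <- c(
  0.087127, 0.040904, 0.040432, 0.046872, 0.033474, 0.038255, 0.049530,
  0.088612, 0.033618, 0.036886, 0.085357, 0.080482, 0.014753, 0.039772,
  0.050680, 0.069577, 0.058542, 0.010494, 0.029916, 0.064718)

#' Dayhoff amino-acid substitution model
#'
#' Builds the reversible 20-state rate matrix of the Dayhoff (PAM)
#' empirical model from its published exchangeabilities and stationary
#' frequencies, scaled so that one unit of branch length corresponds to
#' one expected substitution per site at stationarity.
#'
#' @return An object of class `"aa_model"`: a list with elements
#'   `Q` (20 x 20 rate matrix, rows summing to zero), `freqs`
#'   (stationary frequencies, summing to one), `states` (residue order),
#'   and the spectral decomposition used to compute transition
#'   probabilities (`eig_values`, `eig_vectors`, `eig_inv`).
#' @examples
#' m <- dayhoff_model()
#' range(rowSums(m$Q))            # ~0
#' sum(m$freqs * -diag(m$Q))      # 1: unit expected rate
#' @export
dayhoff_model <- function() {
  n <- 20L
  S <- matrix(0, n, n, dimnames = list(AA20, AA20))
  S[lower.tri(S)] <- .DAYHOFF_S_LOWER
  S <- S + t(S)
  pi <- .DAYHOFF_FREQS / sum(.DAYHOFF_FREQS)
  names(pi) <- AA20

  Q <- S * rep(pi, each = n)   # q_ij = s_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  # scale to 1 expected substitution per site per unit branch length
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu

  # symmetrize via pi^(1/2) similarity transform for a stable spectral
  # decomposition (model is time-reversible)
  rp <- sqrt(pi)
  B <- Q * outer(rp, 1 / rp)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  V <- e$vectors / rp          # columns: right eigenvectors of Q
  Vinv <- t(e$vectors * rp)

  structure(
    list(Q = Q, freqs = pi, states = AA20,
         eig_values = e$values, eig_vectors = V, eig_inv = Vinv),
    class = "aa_model")
}

#' Transition-probability matrix of an amino-acid model
#'
#' Computes `expm(Q * t)` for a reversible model via its precomputed
#' spectral decomposition.
#'
#' @param model an `"aa_model"`, see [dayhoff_model()].
#' @param t branch length in expected substitutions per site (>= 0).
#' @return 20 x 20 stochastic matrix of transition probabilities.
#' @export
transition_probs <- function(model, t) {
  stopifnot(inherits(model, "aa_model"), is.finite(t), t >= 0)
  P <- model$eig_vectors %*% (exp(model$eig_values * t) * model$eig_inv)
  # clip tiny negative values from round-off and renormalize rows
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Expected proportion of differing sites at a given divergence
#'
#' For two sequences separated by `b` expected substitutions per site
#' under the model at stationarity, returns the expected fraction of
#' sites at which they differ.  Used by the synthetic-data generator to
#' calibrate paralog divergence.
#'
#' @param model an `"aa_model"`.
#' @param b separation in expected substitutions per site.
#' @return expected differing-site proportion in `[0, 1)`.
#' @export
expected_difference <- function(model, b) {
  P <- transition_probs(model, b)
  1 - sum(model$freqs * diag(P))
}

#' @export
print.aa_model <- function(x, ...) {
  cat("Amino-acid substitution model (Dayhoff), 20 states\n")
  cat("  scaled to 1 expected substitution/site/unit branch length\n")
  invisible(x)
}
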