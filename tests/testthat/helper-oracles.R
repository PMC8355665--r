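# Independent oracles and small fixture builders shared by the tests.

AAS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Random ungapped amino-acid string.
random_aa <- function(n) paste(sample(AAS, n, replace = TRUE), collapse = "")

# Bundled reference with substitutions at the given positions.
mutated_reference <- function(chain = "alpha1_helical", positions,
                              residues = NULL) {
  s <- strsplit(collagen_reference(chain)$sequence, "")[[1]]
  for (i in seq_along(positions)) {
    s[positions[i]] <- if (is.null(residues))
      sample(setdiff(AAS, s[positions[i]]), 1) else residues[i]
  }
  paste(s, collapse = "")
}

# Brute-force quartet state: extract the induced 4-leaf subtree with
# ape::keep.tip and read off its cherry structure.  States match
# quartet_distance's internal encoding over the sorted leaf labels:
# 1 = {q1,q2}|{q3,q4}, 2 = {q1,q3}|{q2,q4}, 3 = {q1,q4}|{q2,q3},
# 0 = unresolved.
oracle_quartet_state <- function(tree, q) {
  kt <- ape::unroot(ape::keep.tip(tree, q))
  if (kt$Nnode < 2L) return(0L)
  pp <- ape::prop.part(kt)
  labs <- attr(pp, "labels")
  pair <- NULL
  for (cl in pp) if (length(cl) == 2L) pair <- labs[cl]
  if (is.null(pair)) {
    # cherry containing the root side: take complement of a 2-set
    for (cl in pp) if (length(cl) == 2L) pair <- labs[cl]
  }
  if (is.null(pair)) return(0L)
  if (q[1] %in% pair) partner <- setdiff(pair, q[1])
  else partner <- setdiff(q[-1], pair)
  match(partner, q[-1])
}

oracle_quartet_distance <- function(t1, t2) {
  tips <- sort(t1$tip.label)
  qs <- utils::combn(tips, 4L)
  d <- 0L
  for (k in seq_len(ncol(qs))) {
    if (oracle_quartet_state(t1, qs[, k]) !=
        oracle_quartet_state(t2, qs[, k])) d <- d + 1L
  }
  d
}

# Euclidean-embeddability check used by the Cailliez scan oracle:
# spectrum of the double-centered -0.5 * (D+c)^2 matrix.
oracle_is_euclidean <- function(D, tol = 1e-9) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D * D) %*% J
  ev <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol * max(abs(ev), 1)
}

# Bisection scan for the smallest additive constant making D Euclidean.
oracle_cailliez_scan <- function(D, upper = NULL, tol = 1e-7) {
  if (oracle_is_euclidean(D)) return(0)
  if (is.null(upper)) upper <- 2 * max(D)
  while (!oracle_is_euclidean(offdiag_add(D, upper))) upper <- 2 * upper
  lo <- 0; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (oracle_is_euclidean(offdiag_add(D, mid))) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

offdiag_add <- function(D, c) {
  Dc <- D + c
  diag(Dc) <- 0
  Dc
}

# Explicit-enumeration log-likelihood: marginalize internal-node states
# by brute force.  Independent of the pruning recursion.
oracle_loglik <- function(chars, tree, rate, model) {
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_int <- tr$Nnode
  states <- model$states
  ns <- length(states)
  P <- lapply(seq_len(nrow(tr$edge)), function(e)
    transition_probs(model, rate * tr$edge.length[e]))
  root <- n_tip + 1L
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), n_int)))
  pat <- chars[tr$tip.label, , drop = FALSE]
  total <- 0
  for (s in seq_len(ncol(pat))) {
    obs <- match(pat[, s], states)      # NA = missing
    lik <- 0
    for (g in seq_len(nrow(grid))) {
      node_state <- function(v) {
        if (v <= n_tip) obs[v] else grid[g, v - n_tip]
      }
      p <- unname(model$freqs[grid[g, root - n_tip]])
      for (e in seq_len(nrow(tr$edge))) {
        par <- node_state(tr$edge[e, 1L])
        chi <- node_state(tr$edge[e, 2L])
        p <- p * if (is.na(chi)) 1 else P[[e]][par, chi]
        if (p == 0) break
      }
      lik <- lik + p
    }
    total <- total + log(lik)
  }
  total
}

# Write a small chain FASTA fixture; returns the path.
write_fixture_fasta <- function(entries) {
  path <- tempfile(fileext = ".fasta")
  lines <- unlist(lapply(names(entries), function(h)
    c(paste0(">", h), entries[[h]])))
  writeLines(lines, path)
  path
}

# Three-taxon full record set built from the bundled references.
full_record_set <- function(taxa = c("tax_a", "tax_b", "tax_c")) {
  recs <- list()
  for (tx in taxa) {
    for (ch in c("alpha1", "alpha2", "alpha3")) {
      recs[[length(recs) + 1L]] <- chain_record(
        tx, ch, collagen_reference(paste0(ch, "_helical"))$sequence)
    }
  }
  recs
}
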