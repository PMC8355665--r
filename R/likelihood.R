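# Felsenstein pruning likelihood on a fixed chronogram and
# maximum-likelihood estimation of per-partition site rates.

# Compress an alignment partition (character matrix, taxa x sites) into
# unique site patterns.  Gap '-' and 'X' are treated as missing data.
compress_patterns <- function(chars) {
  keys <- apply(chars, 2L, paste, collapse = "\r")
  uniq <- !duplicated(keys)
  w <- as.vector(table(factor(keys, levels = keys[uniq])))
  list(chars = chars[, uniq, drop = FALSE], weights = w)
}

# Conditional-likelihood pruning for one partition at a given rate.
# `tree` must carry branch lengths in Ma; branch lengths in expected
# substitutions are rate * duration.  Returns the total log-likelihood.
partition_loglik <- function(chars, tree, rate, model) {
  stopifnot(is.matrix(chars), rate >= 0)
  taxa <- rownames(chars)
  if (!setequal(taxa, tree$tip.label))
    stop("alignment taxa and chronogram leaves differ")
  cp <- compress_patterns(chars)
  pat <- cp$chars[tree$tip.label, , drop = FALSE]
  npat <- ncol(pat)
  ns <- 20L

  tr <- ape::reorder.phylo(tree, "postorder")
  if (is.null(tr$edge.length)) stop("chronogram must have branch lengths")
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode

  # tip conditionals: indicator columns, all-ones for missing residues
  tipL <- function(i) {
    m <- matrix(0, ns, npat)
    idx <- match(pat[i, ], model$states)
    miss <- is.na(idx)
    m[cbind(idx[!miss], which(!miss))] <- 1
    m[, miss] <- 1
    m
  }

  L <- vector("list", n_node)
  logscale <- numeric(npat)
  parents <- unique(tr$edge[, 1L])
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]
    chi <- tr$edge[e, 2L]
    childL <- if (chi <= n_tip) tipL(chi) else L[[chi]]
    P <- transition_probs(model, rate * tr$edge.length[e])
    contrib <- P %*% childL
    L[[par]] <- if (is.null(L[[par]])) contrib else L[[par]] * contrib
    cm <- apply(L[[par]], 2L, max)
    if (any(cm < 1e-120)) {       # rescale against underflow on deep trees
      sc <- pmax(cm, 1e-300)
      L[[par]] <- sweep(L[[par]], 2L, sc, "/")
      logscale <- logscale + log(sc)
    }
  }
  root <- parents[length(parents)]
  rootL <- L[[root]]
  # guard against underflow on deep trees
  mx <- apply(rootL, 2L, max)
  site_lik <- colSums(model$freqs * sweep(rootL, 2L, mx, "/"))
  sum(cp$weights * (log(site_lik) + log(mx) + logscale))
}

#' Log-likelihood of a partitioned alignment on a chronogram
#'
#' Felsenstein pruning over all three chain partitions.  Within each
#' partition, the branch length in expected substitutions is the
#' partition's site rate times the branch duration in Ma; transition
#' probabilities come from the matrix exponential of the scaled model.
#' Gaps and `X` are treated as missing data, so a dash-filled (absent)
#' alpha3 chain contributes nothing to that partition.
#'
#' @param aln a `"concat_alignment"`.
#' @param chronogram `phylo` with branch lengths in Ma; leaf set must
#'   equal the alignment taxa.
#' @param site_rates named per-chain rates in substitutions per site
#'   per Ma (all > 0).
#' @param model an `"aa_model"` (default: [dayhoff_model()]).
#' @return total log-likelihood (numeric scalar).
#' @export
pruning_loglik <- function(aln, chronogram, site_rates,
                           model = dayhoff_model()) {
  stopifnot(inherits(aln, "concat_alignment"))
  if (any(site_rates <= 0)) stop("site rates must be positive")
  chains <- aln$partitions$chain
  if (!all(chains %in% names(site_rates)))
    stop("site_rates must name every partition: ",
         paste(chains, collapse = ", "))
  ll <- 0
  for (ch in chains) {
    ll <- ll + partition_loglik(alignment_partition(aln, ch), chronogram,
                                site_rates[[ch]], model)
  }
  ll
}

#' Maximum-likelihood per-partition site rates on a fixed chronogram
#'
#' Estimates each chain's substitution rate (substitutions per site per
#' Ma) by maximizing the pruning likelihood over that partition alone;
#' with the chronogram fixed, partitions are independent, so the joint
#' optimum decomposes into three bounded one-dimensional optimizations
#' (on the log-rate scale).  Profile-likelihood confidence intervals
#' are reported per rate.
#'
#' This is a desk-scale point estimator of the same quantity a
#' partitioned relaxed-clock Bayesian analysis summarizes as the
#' product of its mean clock rate and relative partition rates.
#'
#' @param aln a `"concat_alignment"`.
#' @param chronogram `phylo` with branch lengths in Ma (total duration
#'   must be positive).
#' @param model an `"aa_model"`.
#' @param interval search interval for each rate (subs/site/Ma).
#' @param conf_level profile-interval coverage (default 0.95).
#' @param tol relative optimizer tolerance on the log-rate scale.
#' @return object of class `"chain_rates_fit"` with components `rates`
#'   (named vector), `ci` (chains x 2 matrix), `loglik` (per chain),
#'   `chronogram`, `interval`, `conf_level`.  Supports `coef()`,
#'   `confint()`, `logLik()`, `print()`, `summary()`.
#' @export
fit_chain_rates <- function(aln, chronogram, model = dayhoff_model(),
                            interval = c(1e-6, 0.05), conf_level = 0.95,
                            tol = 1e-7) {
  stopifnot(inherits(aln, "concat_alignment"))
  if (is.null(chronogram$edge.length) || sum(chronogram$edge.length) <= 0)
    stop("degenerate chronogram: total duration must be positive")
  if (!setequal(aln$taxa, chronogram$tip.label))
    stop("alignment taxa and chronogram leaves differ")
  chains <- aln$partitions$chain
  rates <- stats::setNames(numeric(length(chains)), chains)
  lls <- stats::setNames(numeric(length(chains)), chains)
  ci <- matrix(NA_real_, length(chains), 2L,
               dimnames = list(chains, c("lower", "upper")))
  drop <- stats::qchisq(conf_level, df = 1) / 2

  for (i in seq_along(chains)) {
    ch <- chains[i]
    chars <- alignment_partition(aln, ch)
    if (all(chars %in% c("-", "X")))
      stop("partition ", ch, " contains no observed residues")
    f <- function(lr) partition_loglik(chars, chronogram, exp(lr), model)
    opt <- stats::optimize(f, interval = log(interval), maximum = TRUE,
                           tol = tol)
    rates[ch] <- exp(opt$maximum)
    lls[ch] <- opt$objective

    g <- function(lr) f(lr) - (opt$objective - drop)
    lo <- log(interval[1]); hi <- log(interval[2])
    ci[ch, 1] <- if (g(lo) < 0)
      exp(stats::uniroot(g, c(lo, opt$maximum), tol = tol)$root)
    else interval[1]
    ci[ch, 2] <- if (g(hi) < 0)
      exp(stats::uniroot(g, c(opt$maximum, hi), tol = tol)$root)
    else interval[2]
  }

  structure(
    list(rates = rates, ci = ci, loglik = lls,
         chronogram = chronogram, interval = interval,
         conf_level = conf_level, model = "Dayhoff"),
    class = "chain_rates_fit")
}

#' @export
coef.chain_rates_fit <- function(object, ...) object$rates

#' @export
confint.chain_rates_fit <- function(object, parm, level, ...) object$ci

#' @export
logLik.chain_rates_fit <- function(object, ...) {
  structure(sum(object$loglik), df = length(object$rates),
            class = "logLik")
}

#' @export
print.chain_rates_fit <- function(x, ...) {
  cat("Maximum-likelihood per-partition site rates (fixed chronogram,",
      x$model, "model)\n")
  tab <- data.frame(
    `subs/site/Ma` = signif(x$rates, 3),
    lower = signif(x$ci[, 1], 3), upper = signif(x$ci[, 2], 3),
    logLik = round(x$loglik, 2), check.names = FALSE)
  print(tab)
  invisible(x)
}

#' @export
summary.chain_rates_fit <- function(object, ...) {
  cat(sprintf("Chronogram: %d taxa, root depth %.1f Ma\n",
              length(object$chronogram$tip.label),
              max(ape::node.depth.edgelength(object$chronogram))))
  print(object)
  rk <- names(sort(object$rates, decreasing = TRUE))
  cat("Rate ordering:", paste(rk, collapse = " > "), "\n")
  invisible(object)
}

#' Per-chain rate table from a fitted rate model
#'
#' Converts maximum-likelihood site rates into the whole-chain
#' substitutions-per-Ma table (the same arithmetic as
#' [per_chain_rate()], with relative rates taken against the mean
#' fitted rate).
#'
#' @param fit a `"chain_rates_fit"`.
#' @param lengths named chain lengths in sites.
#' @return a `"chain_rate_table"`.
#' @export
rate_table_from_fit <- function(fit, lengths = CHAIN_LENGTHS) {
  stopifnot(inherits(fit, "chain_rates_fit"))
  m <- mean(fit$rates)
  per_chain_rate(clock_summary(m, fit$rates / m, source = "ML fit"),
                 lengths = lengths)
}
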