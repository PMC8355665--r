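table2_summary <- function() {
  clock_summary(0.00083, c(alpha1 = 0.00067 / 0.00083,
                           alpha2 = 0.00088 / 0.00083,
                           alpha3 = 0.00094 / 0.00083))
}

test_that("per-chain rates are exact products with display-only rounding", {
  tab <- per_chain_rate(table2_summary())
  # exact before rounding
  expect_equal(tab$chain_rate[1:3], tab$site_rate[1:3] * tab$length[1:3])
  expect_equal(tab$chain_rate[1], 0.00067 * 1058)
  expect_equal(tab$chain_rate[4], mean(tab$chain_rate[1:3]))
  f <- format_chain_rate_table(tab)
  expect_equal(f$chain_rate, c(0.7, 0.9, 1.0, 0.9))
  expect_equal(f$length, c(1058, 1041, 1062, 1054))
  expect_equal(f$site_rate[1:3], c(0.00067, 0.00088, 0.00094))

  expect_error(per_chain_rate(table2_summary(), lengths = c(alpha1 = 1058)),
               "no length given")
  expect_error(clock_summary(0, c(alpha1 = 1)), "positive")
  expect_error(clock_summary(0.001, c(alpha1 = -1)), "positive")
})

test_that("clock summaries parse the .pstat parameter-table dialect", {
  path <- tempfile(fileext = ".pstat")
  writeLines(c(
    "[ID: 1234]",
    "Parameter\tMean\tVariance",
    "TL{all}\t12.4\t0.3",
    "clockrate\t0.00083\t0.000001",
    "m{1}\t0.8072289\t0.001",
    "m{2}\t1.0602410\t0.001",
    "m{3}\t1.1325301\t0.001",
    "igrvar\t0.002\t0.0001"), path)
  suppressMessages(cs <- read_clock_summary(path))
  expect_equal(cs$mean_clockrate, 0.00083)
  tab <- per_chain_rate(cs)
  expect_equal(format_chain_rate_table(tab)$site_rate[1:3],
               c(0.00067, 0.00088, 0.00094))
  expect_equal(format_chain_rate_table(tab)$chain_rate[1:3],
               c(0.7, 0.9, 1.0))

  # unrelated parameters do not change the result
  path2 <- tempfile(fileext = ".pstat")
  writeLines(c("Parameter\tMean", "clockrate\t0.001", "m{1}\t1.0",
               "alpha\t0.5", "pi(A)\t0.08"), path2)
  suppressMessages(cs2 <- read_clock_summary(path2))
  expect_equal(unname(cs2$relative_partition_rates), 1.0)

  empty <- tempfile(); file.create(empty)
  expect_error(read_clock_summary(empty), "empty")
  noclock <- tempfile()
  writeLines(c("Parameter\tMean", "m{1}\t1.0"), noclock)
  expect_error(read_clock_summary(noclock), "clockrate")
})

test_that("the bundled Dayhoff model matches its published constants", {
  m <- dayhoff_model()
  expect_equal(rowSums(m$Q), rep(0, 20), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sum(m$freqs), 1)
  # unit expected substitution rate at stationarity
  expect_equal(sum(m$freqs * -diag(m$Q)), 1)
  # detailed balance (reversibility)
  flux <- m$freqs * m$Q
  expect_equal(flux, t(flux), tolerance = 1e-12)
  # agreement with an independently packaged copy of the same constants
  ph <- get(".Dayhoff", envir = asNamespace("phangorn"))
  expect_equal(unname(m$freqs), unname(ph$bf / sum(ph$bf)),
               tolerance = 1e-9)
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- ph$Q
  S <- S + t(S)
  Qp <- S * rep(m$freqs, each = 20)
  diag(Qp) <- -rowSums(Qp)
  Qp <- Qp / -sum(m$freqs * diag(Qp))
  expect_equal(unname(m$Q), unname(Qp), tolerance = 1e-9)
  # transition probabilities: valid stochastic matrix, identity at t = 0
  P <- transition_probs(m, 0.3)
  expect_equal(rowSums(P), rep(1, 20), ignore_attr = TRUE)
  expect_true(all(P >= 0))
  expect_equal(transition_probs(m, 0), diag(20), tolerance = 1e-10,
               ignore_attr = TRUE)
})

two_leaf_aln <- function(seq1, seq2, chain = "alpha1") {
  L <- nchar(seq1)
  m <- rbind(t1 = strsplit(seq1, "")[[1]], t2 = strsplit(seq2, "")[[1]])
  concat_alignment(m, data.frame(chain = chain, start = 1L, end = L))
}

test_that("pruning likelihood has the exact closed form at zero duration", {
  model <- dayhoff_model()
  s <- "ARNDCQ"
  aln <- two_leaf_aln(s, s)
  tree <- ape::read.tree(text = "(t1:0,t2:0);")
  ll <- pruning_loglik(aln, tree, c(alpha1 = 0.001), model)
  expect_equal(ll, sum(log(model$freqs[strsplit(s, "")[[1]]])))
})

test_that("pruning likelihood equals explicit state enumeration", {
  model <- dayhoff_model()
  set.seed(37)
  tree3 <- ape::read.tree(text = "((t1:80,t2:120):100,t3:230);")
  tree4 <- ape::read.tree(text = "(((t1:50,t2:60):40,t3:110):30,t4:150);")
  for (tree in list(tree3, tree4)) {
    n <- length(tree$tip.label)
    chars <- matrix(sample(model$states, n * 10, replace = TRUE), n, 10,
                    dimnames = list(tree$tip.label, NULL))
    chars[1, 3] <- "-"    # missing data handled identically
    rate <- 0.002
    aln <- concat_alignment(chars, data.frame(chain = "alpha1", start = 1L,
                                              end = 10L))
    expect_equal(pruning_loglik(aln, tree, c(alpha1 = rate), model),
                 oracle_loglik(chars, tree, rate, model),
                 tolerance = 1e-8)
  }
})

test_that("the likelihood is invariant to alignment column order", {
  model <- dayhoff_model()
  set.seed(41)
  tree <- ape::rtree(5)
  tree$edge.length <- tree$edge.length * 100
  chars <- matrix(sample(model$states, 5 * 30, replace = TRUE), 5, 30,
                  dimnames = list(tree$tip.label, NULL))
  p <- data.frame(chain = "alpha1", start = 1L, end = 30L)
  ll1 <- pruning_loglik(concat_alignment(chars, p), tree,
                        c(alpha1 = 0.003), model)
  ll2 <- pruning_loglik(concat_alignment(chars[, sample(30)], p), tree,
                        c(alpha1 = 0.003), model)
  expect_equal(ll1, ll2)

  bad <- chars
  rownames(bad)[1] <- "zzz"
  expect_error(pruning_loglik(concat_alignment(bad, p), tree,
                              c(alpha1 = 0.003), model), "differ")
})

test_that("rate estimation halves when branch durations double", {
  ds <- make_dataset(simulation_config(
    n_taxa = 8, root_age = 200, seed = 43, use_masks = FALSE,
    chain_lengths = c(alpha1 = 150, alpha2 = 150, alpha3 = 150),
    alpha3_missing_fraction = 0, tetraploid_fraction = 0))
  m <- do.call(rbind, lapply(ds$tree$tip.label, function(tx) {
    unlist(lapply(c("alpha1", "alpha2", "alpha3"), function(ch)
      strsplit(ds$chains[[ch]]$sequences[[tx]], "")[[1]]))
  }))
  rownames(m) <- ds$tree$tip.label
  aln <- concat_alignment(
    m, data.frame(chain = c("alpha1", "alpha2", "alpha3"),
                  start = c(1L, 151L, 301L), end = c(150L, 300L, 450L)))
  fit1 <- fit_chain_rates(aln, ds$tree)
  doubled <- ds$tree
  doubled$edge.length <- doubled$edge.length * 2
  fit2 <- fit_chain_rates(aln, doubled)
  expect_equal(unname(coef(fit2)), unname(coef(fit1)) / 2,
               tolerance = 1e-3)

  # degenerate chronogram is rejected for estimation
  zero <- ds$tree
  zero$edge.length[] <- 0
  expect_error(fit_chain_rates(aln, zero), "degenerate")
})

test_that("estimation error shrinks as chain length grows", {
  true_rate <- 0.0009
  err_at <- function(L, seeds) {
    mean(sapply(seeds, function(sd) {
      tr <- sample_timetree(10, root_age = 430, seed = sd)
      sim <- simulate_chain(tr, L, true_rate, seed = sd + 500)
      m <- do.call(rbind, strsplit(sim$sequences, ""))
      rownames(m) <- names(sim$sequences)
      aln <- concat_alignment(m, data.frame(chain = "alpha1", start = 1L,
                                            end = as.integer(L)))
      abs(coef(fit_chain_rates(aln, tr))[["alpha1"]] - true_rate) / true_rate
    }))
  }
  errs <- c(err_at(200, c(1, 2)), err_at(1000, c(3, 4)),
            err_at(3000, c(5, 6)))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.1)

  # all-gap partition is rejected
  tr <- sample_timetree(4, root_age = 100, seed = 9)
  gap <- matrix("-", 4, 10, dimnames = list(tr$tip.label, NULL))
  expect_error(
    fit_chain_rates(concat_alignment(gap,
      data.frame(chain = "alpha1", start = 1L, end = 10L)), tr),
    "no observed residues")
})

test_that("profile intervals cover the generating rate in a typical run", {
  ds <- make_dataset(simulation_config(
    n_taxa = 10, seed = 47, use_masks = FALSE,
    alpha3_missing_fraction = 0, tetraploid_fraction = 0))
  aln <- suppressWarnings(concatenate_chains(ds$records))
  fit <- fit_chain_rates(aln, ds$tree)
  true <- ds$config$site_rates
  for (ch in names(true)) {
    expect_gt(fit$ci[ch, 2], fit$ci[ch, 1])
    expect_lt(abs(coef(fit)[[ch]] - true[[ch]]) / true[[ch]], 0.15)
  }
  # fitted rates convert to a chain-rate table
  tab <- rate_table_from_fit(fit)
  expect_s3_class(tab, "chain_rate_table")
  expect_equal(tab$chain_rate[1:3], unname(coef(fit)) * c(1058, 1041, 1062),
               tolerance = 1e-10)
})
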