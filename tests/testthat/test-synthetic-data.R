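test_that("the timetree sampler honours its conditioning", {
  # n = 2: a single cherry with both pendant branches at the crown age
  cherry <- sample_timetree(2, root_age = 100, seed = 1)
  expect_identical(length(cherry$tip.label), 2L)
  expect_equal(unname(cherry$edge.length), c(100, 100))

  tr <- sample_timetree(20, root_age = 430, seed = 5)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(tr)), 430)
  expect_identical(ape::Ntip(tr), 20L)
  expect_true(ape::is.binary(tr))

  # determinism: identical Newick for identical seeds
  expect_identical(ape::write.tree(sample_timetree(20, root_age = 430,
                                                   seed = 5)),
                   ape::write.tree(tr))

  expect_error(sample_timetree(1, seed = 1), "at least two")
  expect_error(sample_timetree(5, birth = 0.1, death = 0.2, seed = 1),
               "birth > death")
})

test_that("lineages through time match the conditioned birth-death expectation", {
  n <- 8; t_age <- 10; b <- 0.3
  # closed-form: E[lineages at age u] = 2 + (n-2) * (1 - F(u)) with F the
  # conditioned speciation-age CDF (pure birth here)
  Fu <- function(u) (1 - exp(-b * u)) / (1 - exp(-b * t_age))
  us <- c(2, 5, 8)
  reps <- 400
  counts <- matrix(0, reps, length(us))
  for (r in seq_len(reps)) {
    tr <- sample_timetree(n, birth = b, root_age = t_age, seed = 6000 + r)
    ages <- t_age - ape::node.depth.edgelength(tr)[-(1:n)]
    for (k in seq_along(us)) counts[r, k] <- 2 + sum(ages[-1] > us[k])
  }
  for (k in seq_along(us)) {
    expected <- 2 + (n - 2) * (1 - Fu(us[k]))
    se <- sd(counts[, k]) / sqrt(reps)
    expect_lt(abs(mean(counts[, k]) - expected), 3 * se + 1e-9)
  }
})

test_that("chain simulation freezes masks and logs a replayable truth channel", {
  tr <- sample_timetree(8, root_age = 100, seed = 2)
  mask <- default_invariant_mask("alpha1", 300)
  sim <- simulate_chain(tr, 300, 0.002, invariant_mask = mask, seed = 7)

  # masked positions never change in any tip
  for (s in sim$sequences) {
    ch <- strsplit(s, "")[[1]]
    expect_identical(paste(ch[as.integer(names(mask))], collapse = ""),
                     paste(mask, collapse = ""))
  }
  # glycine occupies every third position
  expect_true(all(sapply(sim$sequences, function(s)
    all(strsplit(s, "")[[1]][seq(1, 300, 3)] == "G"))))

  # replaying the event log reproduces every tip exactly
  expect_identical(replay_chain(sim), sim$sequences)

  # no events at masked sites
  expect_false(any(sim$events$site %in% as.integer(names(mask))))

  # determinism and the zero-rate limit
  sim2 <- simulate_chain(tr, 300, 0.002, invariant_mask = mask, seed = 7)
  expect_identical(sim2$sequences, sim$sequences)
  s0 <- simulate_chain(tr, 40, 0, seed = 3)
  expect_true(all(s0$sequences == s0$root_sequence))

  expect_error(simulate_chain(tr, 10, 0.001,
    invariant_mask = c("5" = "-"), seed = 1), "illegal residue")
  expect_error(simulate_chain(tr, 10, 0.001,
    invariant_mask = c("11" = "G"), seed = 1), "within the chain")
})

test_that("substitution counts match the expected Poisson intensity", {
  tr <- sample_timetree(6, root_age = 50, seed = 8)
  total_dur <- sum(tr$edge.length)
  rate <- 0.004
  L <- 3000
  obs <- sapply(1:4, function(i)
    nrow(simulate_chain(tr, L, rate, seed = 100 + i)$events))
  expected <- rate * total_dur * L
  # Poisson-scale Monte-Carlo error of the mean, inflated for the mild
  # overdispersion of state-dependent exit rates
  se <- 1.5 * sqrt(expected / 4)
  expect_lt(abs(mean(obs) - expected), 3 * se)
})

test_that("datasets keep their bookkeeping promises", {
  cfg <- simulation_config(n_taxa = 12, seed = 51,
                           alpha3_missing_fraction = 0.3,
                           tetraploid_fraction = 0.25)
  ds <- make_dataset(cfg)
  n <- 12
  n_missing <- length(ds$alpha3_missing)
  n_tetra <- length(ds$tetraploid)
  tetra_with_a3 <- length(setdiff(ds$tetraploid, ds$alpha3_missing))
  counts <- table(ds$truth$chain)
  expect_identical(unname(counts[["alpha1"]]), as.integer(n + n_tetra))
  expect_identical(unname(counts[["alpha2"]]), as.integer(n + n_tetra))
  expect_identical(unname(counts[["alpha3"]]),
                   as.integer(n - n_missing + tetra_with_a3))
  expect_identical(length(ds$records), nrow(ds$truth))

  # isoform pairs diverge inside the configured band
  for (tx in ds$tetraploid) {
    for (ch in c("alpha1", "alpha2")) {
      pair <- Filter(function(r) r$taxon == tx && r$chain == ch,
                     ds$records)
      expect_length(pair, 2L)
      div <- pairwise_divergence(pair[[1]]$sequence, pair[[2]]$sequence)
      expect_gte(div, cfg$isoform_divergence[1] - 0.01)
      expect_lte(div, cfg$isoform_divergence[2] + 0.01)
    }
  }
})

test_that("alpha1-alpha3 divergence matches its calibrated expectation", {
  ds <- make_dataset(simulation_config(n_taxa = 12, seed = 53,
                                       alpha3_missing_fraction = 0,
                                       tetraploid_fraction = 0))
  div <- sapply(ds$tree$tip.label, function(tx) {
    g <- function(ch) Filter(function(r) r$taxon == tx && r$chain == ch,
                             ds$records)[[1]]$sequence
    pairwise_divergence(substr(g("alpha1"), 1, 1058),
                        substr(g("alpha3"), 1, 1058))
  })
  expect_lt(abs(mean(div) - ds$alpha13_calibration$expected), 0.03)
})

test_that("realized substitution densities rank alpha3 > alpha2 > alpha1", {
  ranks_ok <- sapply(c(61, 62, 63, 64, 65), function(sd) {
    ds <- make_dataset(simulation_config(n_taxa = 8, seed = sd))
    r <- ds$realized_site_rates
    r[["alpha3"]] > r[["alpha2"]] && r[["alpha2"]] > r[["alpha1"]]
  })
  expect_true(all(ranks_ok))
})

test_that("identical configs produce byte-identical dataset files", {
  cfg <- simulation_config(n_taxa = 6, seed = 71)
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(make_dataset(cfg), d1)
  write_dataset(make_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("NNI perturbation moves trees a controlled distance", {
  set.seed(73)
  base <- ape::rtree(12)
  copies <- perturb_tree_sample(base, 4, 0, seed = 1)
  expect_true(all(sapply(copies, function(t)
    quartet_distance(base, t) == 0)))
  moved <- perturb_tree_sample(base, 4, 1, seed = 2)
  expect_true(all(sapply(moved, function(t)
    quartet_distance(base, t) > 0)))
  star <- ape::read.tree(text = "(a,b,c,d,e);")
  expect_error(perturb_tree_sample(star, 2, 1), "binary")
})
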