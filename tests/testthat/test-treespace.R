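test_that("pruning to the common leaf set induces the correct subtrees", {
  t5 <- ape::read.tree(text = "((((a:1,b:1):1,c:2):1,d:3):1,e:4);")
  t4 <- ape::read.tree(text = "(((a:1,b:1):1,c:2):1,d:3);")
  pr <- prune_to_common(list(t5, t4))
  expect_setequal(pr[[1]]$tip.label, c("a", "b", "c", "d"))
  # the pruned 5-leaf tree matches the 4-leaf topology (zero quartet diff)
  expect_identical(quartet_distance(pr[[1]], pr[[2]]), 0L)
  # branch lengths along suppressed paths are summed
  expect_equal(sum(pr[[1]]$edge.length), sum(t4$edge.length))

  same <- prune_to_common(list(t5, t5))
  expect_identical(quartet_distance(same[[1]], t5), 0L)

  t_disjoint <- ape::read.tree(text = "((x,y),z);")
  expect_error(prune_to_common(list(t5, t_disjoint)), "fewer than two")
})

test_that("congruence counts shared and conflicting bipartitions", {
  set.seed(5)
  tA <- ape::rtree(28)
  self <- congruence(tA, tA)
  expect_identical(self$incongruent_nodes_ab, 0L)
  expect_equal(self$fraction_congruent_ab, 1)

  # one NNI on a 5-leaf caterpillar changes exactly one bipartition
  cat5 <- ape::read.tree(text = "((((a,b),c),d),e);")
  nni <- ape::read.tree(text = "((((a,c),b),d),e);")
  cc <- congruence(cat5, nni)
  expect_identical(cc$incongruent_nodes_ab, 1L)
  expect_identical(cc$shared_nodes, 1L)

  # a star tree shares no internal bipartition with anything
  star <- ape::read.tree(text = "(a,b,c,d,e);")
  expect_identical(congruence(star, cat5)$shared_nodes, 0L)
  expect_identical(congruence(star, cat5)$n_splits_a, 0L)

  expect_error(congruence(cat5, ape::read.tree(text = "((a,b),(c,f));")),
               "different leaf sets")
})

test_that("congruence incongruence counts agree with Robinson-Foulds", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    a <- ape::rtree(n)
    b <- ape::rtree(n)
    cc <- congruence(a, b)
    expect_equal(cc$incongruent_nodes_ab + cc$incongruent_nodes_ba,
                 as.numeric(phangorn::RF.dist(a, b)))
  }
})

test_that("quartet distance matches the induced-subtree oracle", {
  # the two resolved 4-leaf topologies differ in their single quartet
  q1 <- ape::read.tree(text = "((a,b),(c,d));")
  q2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_identical(quartet_distance(q1, q2), 1L)
  expect_identical(quartet_distance(q1, q1), 0L)

  set.seed(13)
  for (i in 1:12) {
    n <- sample(6:9, 1)
    a <- ape::rtree(n)
    b <- ape::rtree(n)
    d <- quartet_distance(a, b)
    expect_identical(d, oracle_quartet_distance(a, b))
    # symmetry and the C(n,4) bound
    expect_identical(quartet_distance(b, a), d)
    expect_lte(d, choose(n, 4))
  }
})

test_that("quartet distance is invariant under joint leaf relabelling", {
  set.seed(17)
  a <- ape::rtree(8)
  b <- ape::rtree(8)
  d0 <- quartet_distance(a, b)
  perm <- sample(a$tip.label)
  relabel <- function(t) {
    t$tip.label <- perm[match(t$tip.label, sort(a$tip.label))]
    t
  }
  expect_identical(quartet_distance(relabel(a), relabel(b)), d0)
})

test_that("quartet distance handles unresolved quartets per policy", {
  star <- ape::read.tree(text = "(a,b,c,d);")
  q1 <- ape::read.tree(text = "((a,b),(c,d));")
  expect_identical(quartet_distance(star, q1, "differ"), 1L)
  expect_identical(quartet_distance(star, q1, "ignore"), 0L)
})

test_that("the pairwise quartet matrix is consistent and counts duplicates", {
  set.seed(19)
  base <- ape::rtree(7)
  trees <- c(replicate(5, base, simplify = FALSE))
  D <- pairwise_quartet_matrix(trees)
  expect_true(all(D$values == 0))
  expect_identical(attr(D, "duplicates"), rep(5L, 5))

  trees3 <- list(ape::rtree(7), ape::rtree(7), ape::rtree(7))
  M <- pairwise_quartet_matrix(trees3)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(M$values[i, j],
                 quartet_distance(trees3[[i]], trees3[[j]]))

  # mean distance from a group to a designated reference
  expect_equal(mean_distance_to_reference(M, 1:2, 3),
               mean(M$values[1:2, 3]))
})

test_that("cailliez returns zero for Euclidean input and the minimal constant otherwise", {
  D_line <- as.matrix(dist(c(0, 1, 2)))
  cc <- cailliez(D_line)
  expect_equal(cc$c, 0)
  expect_identical(cc$D$is_euclidean, "yes")

  # the triangle-violating 4-point configuration
  Dn <- matrix(c(0, 1, 1, 3, 1, 0, 1, 1, 1, 1, 0, 1, 3, 1, 1, 0), 4, 4)
  cc2 <- cailliez(Dn)
  expect_gt(cc2$c, 0)
  expect_equal(cc2$c, oracle_cailliez_scan(Dn), tolerance = 1e-5)
  # agreement with the base-R additive-constant computation
  expect_equal(cc2$c, cmdscale(as.dist(Dn), add = TRUE)$ac,
               tolerance = 1e-8)
  # idempotence: the corrected matrix needs no further constant
  expect_equal(cailliez(cc2$D)$c, 0)

  expect_error(cailliez(matrix(c(0, -1, -1, 0), 2, 2)), "negative")
})

test_that("classical MDS reconstructs Euclidean configurations exactly", {
  set.seed(23)
  pts <- matrix(rnorm(10), 5, 2)
  D <- dist_matrix(as.matrix(dist(pts)), is_euclidean = "yes")
  emb <- classical_mds(D, k = 2)
  expect_equal(as.matrix(dist(emb$coordinates)), unname(D$values),
               tolerance = 1e-10, ignore_attr = TRUE)
  # variance fractions are non-increasing and sum to at most 1
  ve <- emb$variance_explained
  expect_true(all(diff(ve) <= 1e-12))
  expect_lte(sum(ve), 1 + 1e-12)

  # collinear points have a single informative axis
  D1 <- dist_matrix(as.matrix(dist(c(0, 1, 2, 3.5))))
  e1 <- classical_mds(D1, k = 1)
  expect_lt(sort(e1$eigenvalues, decreasing = TRUE)[2], 1e-8)
  expect_error(classical_mds(D1, k = 3), "positive eigenvalues")
})

test_that("NMDS is deterministic, bounded and near-zero on metric input", {
  set.seed(29)
  pts <- matrix(rnorm(16), 8, 2)
  D <- dist_matrix(as.matrix(dist(pts)))
  e1 <- nmds_embed(D, k = 2, seed = 4, restarts = 5)
  expect_lt(e1$stress, 1e-3)
  expect_gte(e1$stress, 0)
  e2 <- nmds_embed(D, k = 2, seed = 4, restarts = 5)
  expect_identical(e1$coordinates, e2$coordinates)

  # best-of-restarts can only improve on a single start
  e_single <- nmds_embed(D, k = 2, seed = 4, restarts = 0)
  expect_lte(e1$stress, e_single$stress + 1e-12)
})

test_that("congruence degrades as NNI moves accumulate", {
  set.seed(31)
  base <- ape::rtree(20)
  frac <- sapply(c(1, 4, 10), function(m) {
    mean(sapply(1:6, function(i) {
      congruence(base, perturb_tree_sample(base, 1, m,
        seed = 100 * m + i)[[1]])$fraction_congruent_ab
    }))
  })
  expect_true(frac[1] > frac[3])
})
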