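# Found sets, pairwise set cardinalities, complete-linkage clustering and
# the ordered synergy matrices.

test_that("pair cardinalities satisfy the set identities, including the worked sizes", {
  mk <- function(cases) structure(list(metric = "x", N = 10, q = "acceptable",
                                       cases = cases), class = "found_set")
  A <- mk(sprintf("c%03d", 1:33))
  expect_equal(pair_cardinalities(A, A)$symdiff, 0)
  expect_equal(pair_cardinalities(A, A)$union, 33)
  # |A| = 33, |B| = 51, intersection 14 -> union 70, symdiff 56
  B <- mk(sprintf("c%03d", c(1:14, 100:136)))
  pc <- pair_cardinalities(A, B)
  expect_equal(pc$union, 70)
  expect_equal(pc$symdiff, 56)
  expect_equal(pc$intersection, 14)
  expect_equal(pc$a_minus_b, 19)
  expect_equal(pc$b_minus_a, 37)
  expect_equal(pc$symdiff, pc$a_minus_b + pc$b_minus_a)
  expect_error(pair_cardinalities(A, mk(character(0))), NA)
  bad <- structure(list(metric = "y", N = 1, q = "acceptable", cases = "c1"),
                   class = "found_set")
  expect_error(pair_cardinalities(A, bad), "different criteria")
  # identities vs brute-force enumeration on random subsets of a
  # 118-element universe
  universe <- sprintf("u%03d", 1:118)
  for (seed in 1:50) {
    set.seed(seed)
    X <- mk(sample(universe, rbinom(1, 118, 0.4)))
    Y <- mk(sample(universe, rbinom(1, 118, 0.4)))
    got <- pair_cardinalities(X, Y)
    want <- oracle_pair_card(X$cases, Y$cases, universe)
    expect_equal(got[names(want)], want)
    expect_equal(got$union, length(X$cases) + length(Y$cases) - got$intersection)
    expect_equal(got$a_minus_b, length(X$cases) - got$intersection)
  }
})

test_that("found sets agree with success counts and with planted truth", {
  classes_good <- c("acceptable", rep("incorrect", 50))
  classes_bad <- c(rep("incorrect", 50), "acceptable")
  res <- lapply(1:6, function(i) {
    cl <- if (i <= 4) classes_good else rep("incorrect", 51)
    planted_case(sprintf("c%d", i),
                 list(good = cl, bad = classes_bad), "acceptable")
  })
  fs <- found_set(res, "good", 10, "acceptable")
  expect_setequal(fs$cases, sprintf("c%d", 1:4))
  expect_equal(length(fs$cases), success_counts(res, "good", 10, "acceptable"))
  expect_length(found_set(res, "bad", 10, "acceptable")$cases, 0)
})

test_that("complete linkage reproduces hand-traced merges and cophenetic heights", {
  # two items: one merge at their dissimilarity
  D2 <- matrix(c(0, 7, 7, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  cl2 <- complete_linkage(D2)
  expect_equal(cl2$cophenetic["a", "b"], 7)
  # three items: {1,2} at 1, then 3 joins at 10
  D3 <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3, 3,
               dimnames = list(c("m1", "m2", "m3"), c("m1", "m2", "m3")))
  cl3 <- complete_linkage(D3)
  expect_equal(cl3$cophenetic["m1", "m2"], 1)
  expect_equal(cl3$cophenetic["m1", "m3"], 10)
  expect_equal(cl3$cophenetic["m2", "m3"], 10)
  expect_equal(sort(cl3$hclust$height), c(1, 10))
  # ultrametric input is a fixed point of the cophenetic map
  expect_equal(complete_linkage(cl3$cophenetic)$cophenetic, cl3$cophenetic)
  expect_error(complete_linkage(matrix(c(0, -1, -1, 0), 2, 2)), "symmetric")
})

test_that("complete linkage matches a naive agglomeration oracle on random matrices", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(4:10, 1)
    # distinct dissimilarities avoid tie-order ambiguity between the
    # implementations
    v <- sample(seq(1, 500), n * (n - 1) / 2)
    D <- matrix(0, n, n, dimnames = list(paste0("m", 1:n), paste0("m", 1:n)))
    D[upper.tri(D)] <- v
    D <- D + t(D)
    got <- complete_linkage(D)$cophenetic
    want <- oracle_complete_linkage_cophenetic(D)
    expect_equal(got, want[rownames(got), colnames(got)])
    # merge heights are non-decreasing
    expect_true(all(diff(complete_linkage(D)$hclust$height) >= 0))
  }
})

test_that("dendrogram Newick export preserves leaves and cophenetic heights", {
  set.seed(5)
  n <- 6
  D <- as.matrix(dist(matrix(runif(n * 2) * 50, ncol = 2)))
  dimnames(D) <- list(paste0("m", 1:n), paste0("m", 1:n))
  cl <- complete_linkage(D)
  p <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl, p)
  tr <- ape::read.tree(p)
  expect_setequal(tr$tip.label, rownames(D))
  coph_tree <- as.matrix(ape::cophenetic.phylo(tr))[rownames(D), rownames(D)]
  # tree path lengths are twice the merge heights (two branches per merge)
  expect_equal(coph_tree, cl$cophenetic, tolerance = 1e-6)
})

test_that("synergy matrices satisfy the set identities and orderings", {
  set.seed(3)
  universe <- sprintf("c%03d", 1:60)
  metrics <- paste0("m", 1:5)
  sets <- lapply(1:5, function(i) sample(universe, 10 + 6 * i))
  names(sets) <- metrics
  res <- lapply(universe, function(cid) {
    ranked <- lapply(metrics, function(m)
      planted_ranked(if (cid %in% sets[[m]]) "acceptable" else "incorrect"))
    names(ranked) <- metrics
    case_result(cid, ranked, "acceptable")
  })
  syn <- synergy_matrices(res, metrics)
  o <- rownames(syn$symdiff)
  expect_setequal(o, metrics)
  expect_true(all(diag(syn$symdiff) == 0))
  expect_equal(diag(syn$union),
               vapply(syn$found_sets[rownames(syn$union)],
                      function(f) length(f$cases), integer(1)),
               ignore_attr = TRUE)
  expect_true(all(diag(syn$relative_complement) == 0))
  # relative complement decomposes the symmetric difference: M + M^T
  rc <- syn$relative_complement
  expect_equal(rc + t(rc),
               syn$symdiff[rownames(rc), colnames(rc)])
  # union identity |A u B| = |A| + |B| - |A n B| entrywise
  for (i in metrics) for (j in metrics) {
    pc <- pair_cardinalities(syn$found_sets[[i]], syn$found_sets[[j]])
    expect_equal(syn$union[i, j], pc$union)
    expect_equal(syn$symdiff[i, j], pc$symdiff)
  }
  # relative-complement ordering is by found-set size, descending
  sizes <- vapply(syn$found_sets[rownames(rc)],
                  function(f) length(f$cases), integer(1))
  expect_true(all(diff(sizes) <= 0))
  # label-permutation equivariance
  perm <- rev(metrics)
  syn2 <- synergy_matrices(res, perm)
  expect_equal(syn2$symdiff[rownames(syn$symdiff), colnames(syn$symdiff)],
               syn$symdiff)
})

test_that("planted orthogonal metric families separate in symmetric difference", {
  # two families, each finding one half of the benchmark; within-family
  # sets nearly identical, cross-family disjoint
  universe <- sprintf("c%03d", 1:40)
  famA <- universe[1:20]; famB <- universe[21:40]
  sets <- list(a1 = famA, a2 = famA[c(1:19, 20)], b1 = famB, b2 = famB)
  metrics <- names(sets)
  res <- lapply(universe, function(cid) {
    ranked <- lapply(metrics, function(m)
      planted_ranked(if (cid %in% sets[[m]]) "acceptable" else "incorrect"))
    names(ranked) <- metrics
    case_result(cid, ranked, "acceptable")
  })
  syn <- synergy_matrices(res, metrics)
  s <- syn$symdiff
  expect_gt(min(s["a1", "b1"], s["a1", "b2"], s["a2", "b1"], s["a2", "b2"]),
            max(s["a1", "a2"], s["b1", "b2"]))
  # the dendrogram pairs each family together first
  coph <- syn$dendrogram$cophenetic
  expect_lt(coph["a1", "a2"], coph["a1", "b1"])
  expect_lt(coph["b1", "b2"], coph["b1", "a1"])
})
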