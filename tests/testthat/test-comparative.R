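test_that("pairwise identity and similarity follow conservation groups", {
  r <- align_pair("S", "S", mode = "global")
  expect_equal(r$identity_pct, 100)
  # MGFLED vs MGFLAD: 5/6 identical; E vs A share no group
  r2 <- align_pair("MGFLED", "MGFLAD", mode = "global")
  expect_equal(r2$identity_pct, 100 * 5 / 6, tolerance = 1e-9)
  expect_equal(r2$similarity_pct, 100 * 5 / 6, tolerance = 1e-9)
  # a D/E column adds to similarity but not identity
  r3 <- align_pair("MGFLDD", "MGFLED", mode = "global")
  expect_equal(r3$identity_pct, 100 * 5 / 6, tolerance = 1e-9)
  expect_equal(r3$similarity_pct, 100, tolerance = 1e-9)
  expect_true(r3$identity_pct <= r3$similarity_pct)
})

test_that("alignment scores are symmetric in their inputs", {
  set.seed(121)
  for (rep in 1:6) {
    a <- rand_protein(40); b <- rand_protein(45)
    for (mode in c("global", "local")) {
      r1 <- align_pair(a, b, mode = mode)
      r2 <- align_pair(b, a, mode = mode)
      expect_equal(r1$identity_pct, r2$identity_pct, tolerance = 1e-9)
      expect_equal(r1$similarity_pct, r2$similarity_pct, tolerance = 1e-9)
    }
  }
})

test_that("consensus annotation marks identity, group conservation, or blank", {
  expect_identical(consensus_line(c("LLL", "LLL")), "***")
  expect_identical(consensus_line(c("DAL", "QAD", "EAX")), ":* ")
  # column {D,E,Q} is one conservation group
  expect_identical(consensus_line(c("D", "E", "Q")), ":")
  expect_identical(consensus_line(c("DL", "D-")), "* ")
  block <- tibble::tibble(id = c("a", "b"), seq = c("MDEL", "MQEV"))
  expect_identical(consensus_line(block), "*:*:")
})

test_that("distance matrix is 1 - identity and consistent with align_pair", {
  seqs <- tibble::tibble(id = c("a", "b"), seq = c("MGFLAD", "MGFLAD"))
  expect_equal(distance_matrix(seqs)["a", "b"], 0)
  seqs2 <- tibble::tibble(id = c("a", "b"), seq = c("KKKK", "DDDD"))
  expect_equal(distance_matrix(seqs2)["a", "b"], 1)
  fam <- gen_two_clade_family(2, 60, 10, 3, seed = 7)
  dm <- distance_matrix(fam$seqs)
  expect_true(isSymmetric(dm))
  expect_true(all(diag(dm) == 0))
  for (i in 1:3) {
    for (j in (i + 1):4) {
      idf <- align_pair(fam$seqs$seq[i], fam$seqs$seq[j],
                        mode = "global")$identity_pct / 100
      expect_equal(dm[i, j], 1 - idf, tolerance = 1e-9)
    }
  }
})

test_that("single linkage reproduces hand-derived merges and midpoint trees", {
  dm2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
                dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- minimum_linkage_tree(dm2)
  expect_identical(sort(tr2$tip.label), c("A", "B"))
  expect_equal(sort(tr2$edge.length), c(0.2, 0.2))
  # d(A,B)=1, d(A,C)=5: A,B join at 1, C at 5
  dm3 <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- single_linkage(dm3)
  expect_equal(hc$height, c(1, 5))
  expect_identical(hc$merge[1, ], c(-2L, -1L))
  expect_error(single_linkage(dm3[1, 1, drop = FALSE]), ">= 2")
})

test_that("single linkage matches the naive oracle on random small matrices", {
  set.seed(131)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- round(stats::runif(n * (n - 1) / 2, 0.05, 1), 3)
    m <- m + t(m)
    dimnames(m) <- list(letters[1:n], letters[1:n])
    hc <- single_linkage(m)
    # merge heights are monotone non-decreasing (single-linkage property)
    expect_true(!is.unsorted(hc$height))
    expect_equal(hc$height, single_linkage_heights(m), tolerance = 1e-12)
    # agrees with stats::hclust single linkage
    expect_equal(hc$height, stats::hclust(stats::as.dist(m),
                                          method = "single")$height,
                 tolerance = 1e-12)
  }
})

test_that("tied merges break toward the lexicographically smallest pair", {
  m <- matrix(0.9, 4, 4)
  diag(m) <- 0
  dimnames(m) <- list(c("d", "c", "b", "a"), c("d", "c", "b", "a"))
  m["c", "d"] <- m["d", "c"] <- 0.2 # tied with the (a, b) pair
  m["a", "b"] <- m["b", "a"] <- 0.2
  hc <- single_linkage(m)
  # first merge is (a, b), not (c, d)
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_identical(first, c("a", "b"))
})

test_that("planted two-clade families are recovered by the linkage tree", {
  ok <- vapply(1:20, function(s) {
    fam <- gen_two_clade_family(3, 200, 30, 5, seed = s)
    tr <- minimum_linkage_tree(distance_matrix(fam$seqs))
    cl <- stats::cutree(single_linkage(distance_matrix(fam$seqs)), k = 2)
    sets <- split(names(cl), cl)
    identical(sort(sets[[1]]), sort(fam$truth$clades$A)) ||
      identical(sort(sets[[1]]), sort(fam$truth$clades$B))
  }, logical(1))
  expect_true(all(ok))
})

test_that("force layout is reproducible and separates planted families", {
  one <- force_layout(matrix(0, 1, 1, dimnames = list("x", "x")), seed = 1)
  expect_equal(c(one$x, one$y), c(0, 0))
  sim <- matrix(0.05, 8, 8)
  sim[1:4, 1:4] <- 0.8
  sim[5:8, 5:8] <- 0.8
  diag(sim) <- 1
  dimnames(sim) <- list(paste0("s", 1:8), paste0("s", 1:8))
  sep <- vapply(1:10, function(s) {
    ly <- force_layout(sim, iterations = 150, seed = s)
    d <- as.matrix(stats::dist(cbind(ly$x, ly$y)))
    intra <- c(d[1:4, 1:4][upper.tri(d[1:4, 1:4])],
               d[5:8, 5:8][upper.tri(d[5:8, 5:8])])
    inter <- as.vector(d[1:4, 5:8])
    stats::median(intra) < stats::median(inter)
  }, logical(1))
  expect_gte(sum(sep), 9L)
  # determinism for a fixed seed
  expect_identical(force_layout(sim, iterations = 60, seed = 4),
                   force_layout(sim, iterations = 60, seed = 4))
  # repulsion-only behaviour: mean pairwise distance grows with node count
  zero5 <- matrix(0, 5, 5); zero12 <- matrix(0, 12, 12)
  m5 <- mean(stats::dist(force_layout(zero5, iterations = 100,
                                      seed = 2)[, c("x", "y")]))
  m12 <- mean(stats::dist(force_layout(zero12, iterations = 100,
                                       seed = 2)[, c("x", "y")]))
  expect_gt(m12, m5)
  p <- ggplot2::autoplot(force_layout(sim, iterations = 30, seed = 1))
  expect_s3_class(p, "ggplot")
})
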