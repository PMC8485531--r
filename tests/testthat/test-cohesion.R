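test_that("connectedness matches the brute-force oracle to 1e-12", {
  for (seed in c(1, 7, 23)) {
    rel <- fixed_toy_rel(seed)
    res <- connectedness(rel, null_iters = 50, persistence_min = 0,
                         seed = seed)
    oracle <- oracle_connectedness(rel, null_iters = 50, seed = seed)
    expect_equal(res$connectedness_pos, oracle$pos, tolerance = 1e-12)
    expect_equal(res$connectedness_neg, oracle$neg, tolerance = 1e-12)
    expect_equal(unname(attr(res, "corrected")), oracle$corrected,
                 tolerance = 1e-12)
  }
})

test_that("cohesion matches the oracle weighting and keeps its sign contract", {
  rel <- fixed_toy_rel(5)
  conn <- connectedness(rel, null_iters = 50, persistence_min = 0, seed = 5)
  coh <- cohesion(rel, conn)
  oracle <- oracle_connectedness(rel, null_iters = 50, seed = 5)
  expect_equal(coh$samples$cohesion_pos,
               as.numeric(rel %*% oracle$pos), tolerance = 1e-12)
  expect_equal(coh$samples$cohesion_neg,
               as.numeric(rel %*% oracle$neg), tolerance = 1e-12)
  expect_true(all(coh$samples$cohesion_pos >= 0))
  expect_true(all(coh$samples$cohesion_neg <= 0))
})

test_that("mirrored taxa have negative connectedness and no positive part", {
  x <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.15, 0.1)
  rel <- cbind(a = x, b = 1 - x)
  rownames(rel) <- paste0("s", 1:10)
  res <- connectedness(rel, null_iters = 100, persistence_min = 0, seed = 2)
  expect_true(all(res$connectedness_neg < 0))
  expect_true(all(res$connectedness_pos == 0))
})

test_that("an all-positive community has negative cohesion exactly zero", {
  # closed compositions force some negative covariance among taxa, so an
  # all-positive connectedness profile is exercised directly: when no
  # taxon has a negative corrected correlation, negative cohesion is 0
  # by construction and the stability ratio is exactly 0
  rel <- fixed_toy_rel(3)
  conn <- data.frame(taxon = colnames(rel),
                     connectedness_pos = seq(0.1, 0.6, by = 0.1),
                     connectedness_neg = 0)
  coh <- cohesion(rel, conn)
  expect_true(all(coh$samples$cohesion_neg == 0))
  expect_true(all(coh$samples$cohesion_pos > 0))
  expect_equal(unname(coh$ratio), 0)
})

test_that("mutually independent taxa have modest connectedness, coupled ones strong", {
  withr::with_seed(11, {
    iid <- matrix(runif(40 * 6), 40, 6,
                  dimnames = list(paste0("s", 1:40), paste0("t", 1:6)))
  })
  rel <- sweep(iid, 1, rowSums(iid), "/")
  res <- connectedness(rel, null_iters = 400, persistence_min = 0,
                       seed = 11)
  # closure induces only weak dependence among iid taxa
  expect_lt(max(abs(c(res$connectedness_pos, res$connectedness_neg))), 0.35)
  # a strongly coupled (mirrored) pair clears that band
  x <- sort(runif(40))
  rel2 <- cbind(a = x, b = x + 0.01) / (2 * x + 0.01)
  rownames(rel2) <- paste0("s", 1:40)
  res2 <- connectedness(rel2, null_iters = 100, persistence_min = 0,
                        seed = 11)
  expect_lt(min(res2$connectedness_neg), -0.8)
})

test_that("cohesion is invariant to per-sample count scaling", {
  rel <- fixed_toy_rel(9)
  counts <- round(rel * 1000)
  scaled <- counts * rep(c(1, 2, 5, 10, 1, 3, 4, 2, 7, 1), times = ncol(rel))
  conn <- connectedness(rel, null_iters = 20, persistence_min = 0, seed = 9)
  c1 <- cohesion(counts, conn)
  c2 <- cohesion(scaled, conn)
  expect_equal(c1$samples$cohesion_pos, c2$samples$cohesion_pos)
  expect_equal(c1$samples$cohesion_neg, c2$samples$cohesion_neg)
})

test_that("stronger planted negative coupling raises the cohesion ratio", {
  # both communities share one positively co-varying pair (so positive
  # cohesion is anchored); the coupled community adds three mirrored
  # inter-guild pairs in composition space, the decoupled one replaces
  # them with structureless noise. A filler taxon absorbs row sums so
  # the planted correlations survive closure.
  ratio_for <- function(coupled, seed) {
    withr::with_seed(seed, {
      n <- 30
      e <- runif(n, -0.05, 0.05)
      p1 <- 0.1 + e
      p2 <- 0.1 + e + rnorm(n, 0, 0.005)
      pairs <- lapply(1:3, function(k) {
        if (coupled) {
          f <- runif(n, -0.05, 0.05)
          list(a = 0.1 + f, b = 0.1 - f)
        } else {
          list(a = 0.1 + rnorm(n, 0, 0.005),
               b = 0.1 + rnorm(n, 0, 0.005))
        }
      })
    })
    m <- cbind(p1, p2,
               do.call(cbind, lapply(pairs, function(p) cbind(p$a, p$b))))
    m <- cbind(m, 1 - rowSums(m))
    colnames(m) <- paste0("t", 1:9)
    rownames(m) <- paste0("s", 1:30)
    conn <- connectedness(m, null_iters = 50, persistence_min = 0,
                          seed = seed)
    cohesion(m, conn)$ratio
  }
  ratios <- vapply(1:20, function(s) {
    c(ratio_for(TRUE, s), ratio_for(FALSE, s))
  }, numeric(2))
  wins <- sum(ratios[1, ] > ratios[2, ], na.rm = TRUE)
  expect_gte(wins, 15)
})

test_that("subcommunity cohesion restricts to the focal neighborhood", {
  cls <- collapse_taxa(tiny_merged(seed = 4), "class")
  whole <- connectedness(cls, null_iters = 30, seed = 4)
  # focal = all taxa reproduces the whole-community cohesion
  all_taxa <- colnames(cls$counts)
  sub_all <- subcommunity_cohesion(cls, focal = all_taxa, null_iters = 30,
                                   seed = 4)
  coh_all <- cohesion(cls, whole)
  expect_setequal(sub_all$members, all_taxa)
  expect_equal(sub_all$samples$cohesion_pos, coh_all$samples$cohesion_pos,
               tolerance = 1e-12)
  expect_error(subcommunity_cohesion(cls, focal = "no_such_class"),
               "absent")
})

test_that("a focal class with no significant edges keeps only its members", {
  withr::with_seed(13, {
    m <- matrix(runif(20 * 5, 10, 20), 20, 5,
                dimnames = list(paste0("s", 1:20),
                                c("focal", paste0("t", 1:4))))
  })
  res <- subcommunity_cohesion(m, focal = "focal", null_iters = 20,
                               persistence_min = 0, seed = 13)
  expect_equal(res$members, "focal")
})
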