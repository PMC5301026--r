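test_that("geographic distances behave in both modes", {
  sites <- scutellaria_sites()
  g <- geographic_distance(sites)
  expect_equal(unname(diag(g)), rep(0, 9L))
  # two synthetic sites differing only by 1 km of altitude
  s2 <- sites[1:2, ]
  s2$latitude <- 25; s2$longitude <- 121.5
  s2$altitude <- c(0, 1000)
  s2$abbreviation <- c("lo", "hi")
  expect_equal(unname(unfold_upper(geographic_distance(s2))), 1)
  # projected distances agree with a haversine + altitude oracle
  ref <- geosphere::distHaversine(
    c(sites["YH", "longitude"], sites["YH", "latitude"]),
    c(sites["DA", "longitude"], sites["DA", "latitude"])) / 1000
  alt <- (sites["YH", "altitude"] - sites["DA", "altitude"]) / 1000
  oracle <- sqrt(ref^2 + alt^2)
  expect_lt(abs(g["YH", "DA"] - oracle) / oracle, 0.01)
  # raw mode mixes degrees and metres as published pipelines did
  graw <- geographic_distance(sites, mode = "paper_raw")
  expect_equal(graw["YH", "DA"],
               sqrt((25.00708 - 25.01841)^2 + (121.5280 - 121.5417)^2 +
                      (15 - 337)^2))
})

test_that("environmental distance is Euclidean over the chosen variables", {
  sites <- scutellaria_sites()
  e <- environmental_distance(sites, standardize = FALSE)
  # brute-force oracle over the full 9 x 9 matrix
  vars <- c("bio2", "bio8", "bio9", "bio13", "bio18", "bio19")
  for (i in 1:8) for (j in (i + 1):9) {
    oracle <- sqrt(sum((as.numeric(sites[i, vars]) -
                          as.numeric(sites[j, vars]))^2))
    expect_equal(unname(e[i, j]), oracle)
  }
  # identical rows -> 0; a single differing variable -> its difference
  s2 <- sites[1:2, ]
  s2[2L, vars] <- s2[1L, vars]
  s2$abbreviation <- c("a", "b")
  expect_equal(unname(unfold_upper(environmental_distance(s2,
                                                          standardize = FALSE))), 0)
  s2[2L, "bio13"] <- s2[1L, "bio13"] + 7
  expect_equal(unname(unfold_upper(environmental_distance(s2,
                                                          standardize = FALSE))), 7)
  expect_error(environmental_distance(sites, variables = "bio99"), "lacks")
})

test_that("Mantel statistics hit their exact bounds on monotone inputs", {
  set.seed(81)
  v <- runif(15L)
  mA <- upper_mat(v)
  mB <- upper_mat(v^3 + 2 * v)            # monotone transform
  r <- mantel_test(mA, mB, perms = 99L, seed = 82L)
  expect_equal(unname(r$statistic), 1)
  mC <- upper_mat(max(v) + min(v) - v)    # rank reversal
  r2 <- mantel_test(mA, mC, perms = 99L, seed = 82L)
  expect_equal(unname(r2$statistic), -1)
  expect_error(mantel_test(upper_mat(rep(1, 15L)), mA), "constant")
})

test_that("Mantel permutation p matches the exhaustive 4x4 oracle", {
  set.seed(83)
  mA <- upper_mat(c(1, 4, 2, 6, 3, 5))
  mB <- upper_mat(c(2, 3, 1, 5, 6, 4))
  A <- as.matrix(mA); B <- as.matrix(mB)
  obs <- cor(unfold_upper(A), unfold_upper(B), method = "spearman")
  allp <- expand.grid(rep(list(1:4), 4L))
  allp <- allp[apply(allp, 1L, function(x) length(unique(x)) == 4L), ]
  null <- apply(allp, 1L, function(p) {
    cor(unfold_upper(A), unfold_upper(B[p, p]), method = "spearman")
  })
  p_exact <- mean(null >= obs - 1e-12)
  r <- mantel_test(mA, mB, perms = 9999L, seed = 84L)
  expect_lt(abs(r$p - p_exact), 0.05)
})

test_that("Mantel and MMRR are invariant to joint relabeling", {
  set.seed(85)
  mA <- upper_mat(runif(21L)); mB <- upper_mat(runif(21L))
  p <- sample.int(7L)
  pm <- function(m) dist_matrix(as.matrix(m)[p, p],
                                rownames(m)[p], attr(m, "kind"))
  r1 <- mantel_test(mA, mB, perms = 49L, seed = 86L)
  r2 <- mantel_test(pm(mA), pm(mB), perms = 49L, seed = 86L)
  expect_equal(r1$statistic, r2$statistic)
  m1 <- mmrr(mA, list(x = mB), perms = 49L, seed = 86L)
  m2 <- mmrr(pm(mA), list(x = pm(mB)), perms = 49L, seed = 86L)
  expect_equal(m1$statistic, m2$statistic, tolerance = 1e-12)
})

test_that("partial Mantel handles identity, independence and collinearity", {
  set.seed(87)
  mA <- upper_mat(runif(36L)); mC <- upper_mat(runif(36L))
  # B = A: partial correlation is 1
  r <- partial_mantel(mA, mA, mC, perms = 99L, seed = 88L)
  expect_equal(unname(r$statistic), 1, tolerance = 1e-12)
  # C uncorrelated with both: partial ~ simple Mantel rho
  mB <- upper_mat(runif(36L))
  rp <- partial_mantel(mA, mB, mC, perms = 99L, seed = 88L)
  rs <- mantel_test(mA, mB, perms = 99L, seed = 88L)
  expect_lt(abs(unname(rp$statistic) - unname(rs$statistic)), 0.15)
  # B fully explained by C (plus small noise): partial centers on 0
  vC <- unfold_upper(mC)
  partials <- replicate(40L, {
    mBC <- upper_mat(abs(vC + rnorm(36L, 0, 0.3 * sd(vC))))
    unname(partial_mantel(mA, mBC, mC, perms = 0L)$statistic)
  })
  expect_lt(abs(mean(partials)), 0.15)
  # exact collinearity of B and C is degenerate
  expect_error(partial_mantel(mA, mC, mC, perms = 9L), "degenerate")
})

test_that("partial Mantel agrees with the vegan implementation", {
  set.seed(89)
  mA <- upper_mat(runif(36L)); mB <- upper_mat(runif(36L))
  mC <- upper_mat(runif(36L))
  ours <- partial_mantel(mA, mB, mC, perms = 999L, seed = 90L)
  ref <- vegan::mantel.partial(as.dist(mA), as.dist(mB), as.dist(mC),
                               method = "spearman", permutations = 999)
  expect_equal(unname(ours$statistic), unname(ref$statistic),
               tolerance = 1e-10)
  simple_ours <- mantel_test(mA, mB, perms = 999L, seed = 91L)
  simple_ref <- vegan::mantel(as.dist(mA), as.dist(mB), method = "spearman",
                              permutations = 999)
  expect_equal(unname(simple_ours$statistic), unname(simple_ref$statistic),
               tolerance = 1e-10)
  expect_lt(abs(simple_ours$p - simple_ref$signif), 0.08)
})

test_that("MMRR reduces to Pearson Mantel with one predictor", {
  set.seed(92)
  mA <- upper_mat(runif(36L)); mB <- upper_mat(runif(36L))
  m <- mmrr(mA, list(geo = mB), perms = 49L, seed = 93L)
  r_pearson <- cor(unfold_upper(mA), unfold_upper(mB))
  expect_equal(unname(m$statistic), r_pearson, tolerance = 1e-10)
  # exact linear combination -> R^2 = 1
  mC <- upper_mat(runif(36L))
  y <- refold_upper(2 * unfold_upper(mB) + 3 * unfold_upper(mC) + 1)
  resp <- dist_matrix(y, rownames(mB))
  m2 <- suppressWarnings(mmrr(resp, list(b = mB, c = mC), perms = 49L,
                              seed = 93L))
  expect_equal(m2$r_squared, 1, tolerance = 1e-12)
  expect_error(mmrr(mA, list(b = mB, b2 = mB), perms = 9L), "collinear")
})

test_that("MMRR coefficients center on zero for independent matrices", {
  set.seed(94)
  betas <- replicate(200L, {
    mA <- upper_mat(runif(36L)); mB <- upper_mat(runif(36L))
    unname(mmrr(mA, list(x = mB), perms = 0L)$statistic)
  })
  expect_lt(abs(mean(betas)), 0.04)
})

test_that("true-null Mantel p-values are roughly uniform", {
  set.seed(95)
  ps <- replicate(120L, {
    mA <- upper_mat(runif(15L)); mB <- upper_mat(runif(15L))
    mantel_test(mA, mB, perms = 49L)$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.001)
})
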