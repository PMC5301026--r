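test_that("VIF pruning keeps independent variables and drops collinear ones", {
  set.seed(111)
  n <- 40L
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  expect_setequal(as.character(vif_prune(X)), c("a", "b"))
  # a duplicated column: one copy survives
  Xd <- data.frame(a = X$a, b = X$b, a2 = X$a)
  kept <- vif_prune(Xd)
  expect_equal(length(kept), 2L)
  expect_true("b" %in% kept)
  expect_true(sum(c("a", "a2") %in% kept) == 1L)
})

test_that("VIF pruning recovers a known independent core from 19 variables", {
  set.seed(112)
  n <- 60L
  core <- matrix(rnorm(n * 6L), n, 6L,
                 dimnames = list(NULL, paste0("core", 1:6)))
  mix <- matrix(0, n, 13L)
  for (j in 1:13) {
    w <- rnorm(6L)
    mix[, j] <- core %*% w                 # exact combos: infinite VIF
  }
  colnames(mix) <- paste0("mix", 1:13)
  X <- as.data.frame(cbind(mix, core))
  kept <- vif_prune(X, threshold = 10)
  expect_setequal(as.character(kept), paste0("core", 1:6))
  expect_true(all(attr(kept, "vif") < 10))
  expect_equal(length(attr(kept, "dropped")), 13L)
})

test_that("climate PCA explains variance as expected on synthetic inputs", {
  set.seed(113)
  n <- 30L
  x <- rnorm(n)
  two_corr <- data.frame(u = x, v = 2 * x + 5)
  pc <- climate_pca(two_corr, c("u", "v"))
  expect_equal(pc$explained[1L], 1, tolerance = 1e-12)
  expect_equal(sum(pc$explained), 1, tolerance = 1e-12)
  # identity covariance: each component explains about 1/p
  p <- 5L
  big <- as.data.frame(matrix(rnorm(4000L * p), ncol = p,
                              dimnames = list(NULL, paste0("w", 1:p))))
  pcb <- climate_pca(big, paste0("w", 1:p))
  expect_true(all(abs(pcb$explained - 1 / p) < 0.05))
  # deterministic loading signs
  expect_true(all(apply(pcb$loadings, 2L, function(l) l[which.max(abs(l))] > 0)))
  cz <- data.frame(a = rnorm(5L), z = rep(1, 5L))
  expect_error(climate_pca(cz, c("a", "z")), "z")
})

test_that("allele-sharing distance and genetic components behave sanely", {
  gt <- make_gt(c("A", "A", "B"),
                list(matrix(c(1L, 1L, 2L, 1L, 2L, 2L), 3L),
                     matrix(c(3L, 3L, 3L, 3L, 3L, 3L), 3L)))
  d <- allele_sharing_distance(gt)
  expect_equal(d[1L, 1L], 0)
  # ind1 (1/1), ind2 (1/2): share one allele at L1, both at L2 -> d = 0.25
  expect_equal(d[1L, 2L], 1 - (0.5 + 1) / 2)
  # ind1 (1/1) vs ind3 (2/2): share none at L1 -> d = 0.25? no: L2 shared
  expect_equal(d[1L, 3L], 1 - (0 + 1) / 2)
  pc <- genetic_components(gt, n_axes = 2L)
  expect_equal(nrow(pc), 3L)
  expect_equal(attr(pc, "demes"), gt$demes)
})

test_that("partial dbRDA partitions inertia exactly on every input", {
  sites <- scutellaria_sites()
  set.seed(114)
  for (rep in 1:3) {
    spec <- scenario_island(9L, 150, 5e-3, n_msat = 6L)
    names_map <- sites$abbreviation
    ds <- simulate_coalescent(
      setNames(list(spec), "s")[[1L]],
      setNames(rep(5L, 9L), spec$demes$label))
    gt <- ds$genotypes
    gt$demes <- names_map[match(gt$demes, spec$demes$label)]
    r <- partial_dbrda(gt, sites, perms = 49L, seed = 115L)
    expect_equal(sum(r$inertia$inertia[1:3]), r$inertia$inertia[4L],
                 tolerance = 1e-9)
    expect_equal(sum(r$inertia$proportion[1:3]), 1, tolerance = 1e-9)
    expect_equal(nrow(r$terms), 6L)
  }
})

test_that("without conditioners the analysis reduces to plain RDA", {
  set.seed(116)
  sites <- scutellaria_sites()
  Y <- matrix(rnorm(45L * 3L), 45L, 3L)
  attr(Y, "demes") <- rep(sites$abbreviation, each = 5L)
  r <- partial_dbrda(Y, sites, predictors = c("bio2", "bio13"),
                     conditioners = NULL, perms = 99L, seed = 117L)
  expect_equal(r$inertia$inertia[r$inertia$component == "conditional"], 0)
  expect_equal(sum(r$inertia$inertia[2:3]), r$inertia$inertia[4L],
               tolerance = 1e-9)
})

test_that("constrained proportion is invariant to predictor re-coding", {
  set.seed(118)
  sites <- scutellaria_sites()
  # invertible linear recoding of the climate block
  s2 <- sites
  s2$bio2 <- sites$bio2 + 2 * sites$bio8
  s2$bio8 <- sites$bio8 - sites$bio9
  Y <- matrix(rnorm(27L * 4L), 27L, 4L)
  attr(Y, "demes") <- rep(sites$abbreviation, each = 3L)
  r1 <- partial_dbrda(Y, sites, perms = 49L, seed = 119L)
  r2 <- partial_dbrda(Y, s2, perms = 49L, seed = 119L)
  expect_equal(r1$inertia$proportion[2L], r2$inertia$proportion[2L],
               tolerance = 1e-9)
})

test_that("null responses give weak constraints; real effects are detected", {
  set.seed(120)
  sites <- scutellaria_sites()
  # null: response independent of climate
  ps <- replicate(15L, {
    Y <- matrix(rnorm(27L * 3L), 27L, 3L)
    attr(Y, "demes") <- rep(sites$abbreviation, each = 3L)
    r <- partial_dbrda(Y, sites, predictors = c("bio13", "bio18"),
                       perms = 49L)
    r$terms$p[1L]
  })
  expect_gt(mean(ps), 0.25)
  # signal: axis built from a climate variable is detected
  hits <- replicate(15L, {
    z <- scale(sites$bio13)[rep(1:9, each = 3L)]
    Y <- cbind(z + rnorm(27L, 0, 0.4), rnorm(27L), rnorm(27L))
    attr(Y, "demes") <- rep(sites$abbreviation, each = 3L)
    r <- partial_dbrda(Y, sites, predictors = c("bio13", "bio18"),
                       conditioners = NULL, perms = 99L)
    r$terms$p[r$terms$term == "bio13"] < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("axis GLM matches a closed-form least-squares oracle", {
  # three points: solvable by hand (exact interpolation, R^2 = 1)
  ax <- cbind(c(0, 1, 2), c(0, 0, 1))
  v <- c(1, 3, 6)
  # closed form: solve X b = v exactly for intercept, b1, b2
  b <- solve(cbind(1, ax), v)
  fit <- suppressWarnings(axis_glm(v, ax))
  expect_equal(unname(coef(lm(v ~ ax))), unname(b), tolerance = 1e-10)
  # variable equal to axis-1 scores: R^2 = 1, axis-1 t dominant
  set.seed(121)
  ax2 <- cbind(rnorm(20L), rnorm(20L))
  r <- suppressWarnings(axis_glm(ax2[, 1L], ax2))
  expect_gt(r$adj_r_squared, 0.999)
  expect_gt(abs(r$t["axis1"]), abs(r$t["axis2"]))
  # pure noise: adjusted R^2 near zero on average
  adj <- replicate(100L, axis_glm(rnorm(20L), ax2)$adj_r_squared)
  expect_lt(abs(mean(adj)), 0.05)
  expect_error(axis_glm(rep(1, 20L), ax2), "constant")
})
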