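test_that("two demes fixed for different alleles give F_ST = 1", {
  gt <- make_gt(rep(c("A", "B"), each = 6L),
                list(cbind(rep(c(1L, 2L), each = 6L),
                           rep(c(1L, 2L), each = 6L))))
  r <- amova(gt, perms = 99L, seed = 1L)
  expect_equal(unname(r$f_statistics["f_st"]), 1)
  expect_equal(r$table$pct_variation[r$table$stratum ==
                                       "among_demes_within_groups"], 100)
  expect_equal(sum(r$table$df), 2L * 12L - 1L)
  expect_lte(unname(r$p_values["f_st"]), 0.05)
})

test_that("AMOVA sums of squares match the one-hot ANOVA oracle", {
  set.seed(41)
  for (rep in 1:4) {
    gt <- random_gt(c(P1 = 4L, P2 = 3L, P3 = 4L),
                    list(P1 = c(`2` = 0.7, `4` = 0.3),
                         P2 = c(`2` = 0.2, `4` = 0.5, `6` = 0.3),
                         P3 = c(`4` = 0.6, `6` = 0.4)), n_loci = 2L)
    grouping <- c(P1 = "g1", P2 = "g1", P3 = "g2")
    r <- suppressWarnings(amova(gt, grouping, perms = 0L))
    ss_oracle <- amova_oracle_ss(gt, grouping)
    got <- setNames(r$table$sum_sq, c("ag", "ap", "wp"))
    expect_equal(got, ss_oracle, tolerance = 1e-10)
    # total variance equals the sum of components; percents sum to 100
    expect_equal(sum(r$table$pct_variation), 100)
  }
})

test_that("repeat-size AMOVA equals a nested ANOVA on raw allele scores", {
  set.seed(45)
  gt <- random_gt(c(P1 = 4L, P2 = 5L, P3 = 3L),
                  list(P1 = c(`10` = 0.5, `12` = 0.5),
                       P2 = c(`10` = 0.3, `12` = 0.3, `14` = 0.4),
                       P3 = c(`12` = 0.6, `16` = 0.4)), n_loci = 2L)
  grouping <- c(P1 = "g1", P2 = "g1", P3 = "g2")
  r <- suppressWarnings(amova(gt, grouping, perms = 0L,
                              metric = "repeat_size"))
  # oracle: per-locus classical nested sums of squares on allele values
  acopy <- rbind(gt$a1, gt$a2)
  pop <- rep(gt$demes, 2L); grp <- grouping[pop]
  ss <- c(ag = 0, ap = 0, wp = 0)
  for (l in 1:2) {
    y <- as.numeric(acopy[, l])
    pm <- tapply(y, pop, mean)[pop]; gm <- tapply(y, grp, mean)[grp]
    ss["wp"] <- ss["wp"] + sum((y - pm)^2)
    ss["ap"] <- ss["ap"] + sum((pm - gm)^2)
    ss["ag"] <- ss["ag"] + sum((gm - mean(y))^2)
  }
  expect_equal(setNames(r$table$sum_sq, c("ag", "ap", "wp")), ss,
               tolerance = 1e-10)
})

test_that("a grouping cutting across structure yields a negative component", {
  # two strongly diverged demes placed in the SAME group, two more in another:
  # the among-group component can go negative and must be reported as-is
  set.seed(42)
  found <- FALSE
  for (try in 1:20) {
    gt <- random_gt(c(P1 = 5L, P2 = 5L, P3 = 5L, P4 = 5L),
                    list(P1 = c(`2` = 0.95, `9` = 0.05),
                         P2 = c(`9` = 0.95, `2` = 0.05),
                         P3 = c(`2` = 0.95, `9` = 0.05),
                         P4 = c(`9` = 0.95, `2` = 0.05)), n_loci = 3L)
    r <- amova(gt, c(P1 = "s1", P2 = "s1", P3 = "s2", P4 = "s2"), perms = 0L)
    comp <- r$table$variance[r$table$stratum == "among_groups"]
    if (comp < 0) { found <- TRUE; break }
  }
  expect_true(found)
  expect_lt(r$table$pct_variation[r$table$stratum == "among_groups"], 0)
})

test_that("permutation p-values respect the add-one convention bounds", {
  set.seed(43)
  gt <- random_gt(c(P1 = 4L, P2 = 4L),
                  list(P1 = c(`2` = 0.5, `4` = 0.5),
                       P2 = c(`2` = 0.5, `4` = 0.5)), n_loci = 2L)
  r <- amova(gt, perms = 49L, seed = 44L)
  expect_gte(r$p_values["f_st"], 1 / 50)
  expect_lte(r$p_values["f_st"], 1)
})

test_that("Nei pairwise G_ST matches hand-computed cases", {
  # identical frequencies -> 0
  gt0 <- make_gt(c("A", "A", "B", "B"),
                 list(matrix(c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L), 4L)))
  expect_equal(unname(unfold_upper(pairwise_fst_nei(gt0))), 0)
  # fixed different alleles -> 1
  gt1 <- make_gt(c("A", "A", "B", "B"),
                 list(matrix(c(1L, 1L, 2L, 2L, 1L, 1L, 2L, 2L), 4L)))
  expect_equal(unname(unfold_upper(pairwise_fst_nei(gt1))), 1)
  # p = (0.5, 0.5) vs (1, 0): H_S = 0.25, H_T = 0.375, G_ST = 1/3
  gt2 <- make_gt(c("A", "A", "B", "B"),
                 list(matrix(c(1L, 1L, 1L, 1L, 2L, 2L, 1L, 1L), 4L)))
  expect_equal(unname(unfold_upper(pairwise_fst_nei(gt2))), 1 / 3)
})

test_that("Rousset linearization is x/(1-x) with a clamp at fixation", {
  m <- upper_mat(c(0, 0.5, 1 / 3), labels = c("a", "b", "c"))
  lin <- rousset_linearize(m)
  expect_equal(attr(lin, "kind"), "linearized_fst")
  expect_equal(unname(unfold_upper(lin)), c(0, 1, 0.5))
  mfix <- upper_mat(c(0.9995, 0.2, 0.2), labels = c("a", "b", "c"))
  expect_message(linf <- rousset_linearize(mfix), "clamped")
  expect_equal(unname(unfold_upper(linf))[1L], 999)
})

test_that("global fixation indices obey the Nei identity and edge cases", {
  # complete selfing: every individual homozygous -> F_IS = 1
  gt <- make_gt(c("A", "A", "B", "B"),
                list(matrix(c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L), 4L)))
  f <- global_f_statistics(gt)
  expect_equal(unname(f["f_is"]), 1)
  expect_equal((1 - f["f_it"]), (1 - f["f_is"]) * (1 - f["f_st"]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # all-monomorphic table -> undefined
  gt_mono <- make_gt(c("A", "B"), list(matrix(5L, 2L, 2L)))
  expect_true(all(is.na(global_f_statistics(gt_mono))))
  # Hardy-Weinberg panmixia: F_IS near zero on simulated draws
  set.seed(51)
  gt_hwe <- random_gt(c(P1 = 200L, P2 = 200L),
                      list(P1 = c(`2` = 0.5, `4` = 0.5),
                           P2 = c(`2` = 0.5, `4` = 0.5)), n_loci = 4L)
  fh <- global_f_statistics(gt_hwe)
  expect_lt(abs(fh["f_is"]), 0.08)
  identity_gap <- (1 - fh["f_it"]) - (1 - fh["f_is"]) * (1 - fh["f_st"])
  expect_lt(abs(identity_gap), 1e-12)
})
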