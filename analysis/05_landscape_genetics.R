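#!/usr/bin/env Rscript
# Isolation by distance / environment and the climate layer (run
# 02_simulate_dataset.R first).
#
# Genetic distance is Rousset-linearized Nei pairwise F_ST from the synthetic
# genotypes; geographic distance is 3-D Euclidean over the packaged site
# coordinates; environmental distance is Euclidean over the six retained
# bioclimatic variables. Mantel / partial Mantel / MMRR use 9,999
# permutations as in the study; the climate block ends with the partial
# dbRDA of the genetic components conditioned on geography and per-variable
# GLMs on the ordination axes.

suppressPackageStartupMessages(library(scutpop))
sites <- scutellaria_sites()
gt <- read_genepop("results/sim/genotypes.gen")

gen <- rousset_linearize(pairwise_fst_nei(gt))
gen <- dist_matrix(as.matrix(gen)[sites$abbreviation, sites$abbreviation],
                   sites$abbreviation, kind = "linearized_fst")
geo <- geographic_distance(sites)
env <- environmental_distance(sites)

P <- 9999L
tests <- list(
  geo_vs_env = mantel_test(geo, env, perms = P, seed = 11L),
  gen_vs_geo = mantel_test(gen, geo, perms = P, seed = 12L),
  gen_vs_env = mantel_test(gen, env, perms = P, seed = 13L),
  gen_vs_env_given_geo = partial_mantel(gen, env, geo, perms = P, seed = 14L))
mm <- list(
  gen_on_geo = mmrr(gen, list(geo = geo), perms = P, seed = 15L),
  gen_on_env = mmrr(gen, list(env = env), perms = P, seed = 16L),
  gen_on_geo_env = mmrr(gen, list(geo = geo, env = env), perms = P,
                        seed = 17L))

tab4 <- data.frame(
  comparison = c(names(tests), names(mm)),
  rho = c(vapply(tests, function(x) unname(x$statistic), numeric(1L)),
          rep(NA, 3L)),
  p_mantel = c(vapply(tests, `[[`, numeric(1L), "p"), rep(NA, 3L)),
  r2 = c(rep(NA, 4L), vapply(mm, `[[`, numeric(1L), "r_squared")),
  beta = c(rep(NA, 4L),
           vapply(mm[1:2], function(x) unname(x$statistic[1L]), numeric(1L)),
           NA),
  p_mmrr = c(rep(NA, 4L), vapply(mm, `[[`, numeric(1L), "p")))
write.table(format(tab4, digits = 4), "results/matrix_tests.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("Matrix association tests (9,999 permutations):\n")
print(tab4, row.names = FALSE, digits = 3)
cat("joint MMRR betas:", paste(names(mm$gen_on_geo_env$statistic),
                               signif(mm$gen_on_geo_env$statistic, 3),
                               collapse = ", "),
    "; per-beta p:", paste(signif(mm$gen_on_geo_env$p_beta, 3),
                           collapse = ", "), "\n")

# climate block
kept <- vif_prune(sites[, c("bio2", "bio8", "bio9", "bio13", "bio18",
                            "bio19")])
cat("\nVIF-stable climate variables:", paste(kept, collapse = ", "), "\n")
pca <- climate_pca(sites)
cat(sprintf("Climate PCA axes 1-2 explain %.1f%% and %.1f%%\n",
            100 * pca$explained[1L], 100 * pca$explained[2L]))

db <- partial_dbrda(gt, sites, perms = 999L, seed = 18L)
cat("\nPartial dbRDA of genetic components | geography:\n")
print(db)
write.table(format(rbind(
  data.frame(term = db$inertia$component, inertia = db$inertia$inertia,
             proportion = db$inertia$proportion, f = NA, p = NA),
  data.frame(term = db$terms$term, inertia = db$terms$inertia,
             proportion = db$terms$proportion, f = db$terms$f,
             p = db$terms$p)), digits = 4),
  "results/dbrda.tsv", sep = "\t", row.names = FALSE, quote = FALSE)

glms <- do.call(rbind, lapply(c("bio2", "bio8", "bio9", "bio13", "bio18",
                                "bio19"), function(v) {
  vals <- sites[match(attr(genetic_components(gt), "demes"),
                      sites$abbreviation), v]
  g <- axis_glm(vals, db$site_scores)
  data.frame(variable = v, t_axis1 = g$t["axis1"], p_axis1 = g$p_t["axis1"],
             t_axis2 = g$t["axis2"], p_axis2 = g$p_t["axis2"],
             adj_r2 = g$adj_r_squared, f = g$f, p = g$p)
}))
write.table(format(glms, digits = 3), "results/axis_glm.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nGLM of climate variables on ordination axes 1-2:\n")
print(glms, row.names = FALSE, digits = 3)
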