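#!/usr/bin/env Rscript
# Chloroplast sequence diversity of the three polymorphic populations.
#
# Only three of the nine populations (YH, MK, EG) are polymorphic at the two
# concatenated cpDNA fragments, each with a single segregating site carried
# by one sequence. From (n, S, singleton configuration) alone the package
# recomputes pi, Watterson's theta and Tajima's D per population, plus the
# coalescent null of D conditioned on S.

suppressPackageStartupMessages(library(scutpop))
dir.create("results", showWarnings = FALSE)

configs <- data.frame(population = c("YH", "MK", "EG"),
                      n = c(14L, 13L, 39L))

rows <- lapply(seq_len(nrow(configs)), function(i) {
  n <- configs$n[i]
  seqs <- rep(strrep("A", 10L), n)
  substr(seqs[1L], 10L, 10L) <- "T"            # the singleton site
  aln <- seq_alignment(paste0(configs$population[i], "_", seq_len(n)),
                       rep(configs$population[i], n), seqs)
  d <- seq_diversity(aln)
  coal <- tajima_coalescent_test(n, d$S, d$tajima_d, reps = 5000L,
                                 seed = 100L + i)
  data.frame(population = configs$population[i], n = n, S = d$S,
             pi = round(d$pi, 3), theta_w = round(d$theta_w, 3),
             tajima_d = round(d$tajima_d, 3),
             p_beta = signif(d$p_beta, 3), p_coalescent = signif(coal$p, 3),
             null_mean_d = round(coal$null_mean_d, 3),
             null_ci_lo = round(coal$ci95[1L], 3),
             null_ci_hi = round(coal$ci95[2L], 3))
})
tab <- do.call(rbind, rows)
write.table(tab, "results/sequence_diversity.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
jsonlite::write_json(tab, "results/sequence_diversity.json", digits = NA)
cat("Sequence diversity of the polymorphic populations:\n")
print(tab, row.names = FALSE)
cat("\nAll three D values are mildly negative (singleton excess) and far\n",
    "from the tails of their conditional coalescent nulls.\n", sep = "")
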