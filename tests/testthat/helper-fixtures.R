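# Shared fixture builders. Everything is generated in code; no binary data.

# alignment of n identical sequences with `singletons` sites where exactly one
# sequence carries a derived base (the chloroplast Table-2 configuration)
make_singleton_alignment <- function(n, singletons = 1L, deme = "POP",
                                     backbone = 8L) {
  len <- backbone + singletons
  base <- strrep("A", len)
  seqs <- rep(base, n)
  for (s in seq_len(singletons)) {
    pos <- backbone + s
    substr(seqs[s], pos, pos) <- "T"   # each singleton on a different sequence
  }
  seq_alignment(paste0(deme, "_", seq_len(n)), rep(deme, n), seqs)
}

# tiny deterministic genotype table: demes x individuals x loci from explicit
# allele vectors; `alleles` is a list of per-locus matrices (n x 2)
make_gt <- function(demes, alleles, loci = NULL) {
  n <- length(demes)
  L <- length(alleles)
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  a1 <- sapply(alleles, function(m) m[, 1L])
  a2 <- sapply(alleles, function(m) m[, 2L])
  if (n == 1L) { a1 <- matrix(a1, 1L); a2 <- matrix(a2, 1L) }
  genotype_table(paste0("ind", seq_len(n)), demes, loci, a1, a2)
}

# random genotype table drawn from per-deme allele frequencies (HWE)
random_gt <- function(n_per_deme, freqs_per_deme, n_loci = 2L) {
  demes <- rep(names(n_per_deme), n_per_deme)
  n <- length(demes)
  draw <- function(d) {
    f <- freqs_per_deme[[d]]
    sample(as.integer(names(f)), 1L, prob = f)
  }
  alleles <- lapply(seq_len(n_loci), function(l) {
    m <- t(vapply(demes, function(d) c(draw(d), draw(d)), integer(2L)))
    m
  })
  make_gt(demes, alleles)
}

# independent AMOVA oracle: expand gene copies to one-hot allele indicators;
# the 0/1 allele-identity distance is half the squared Euclidean distance of
# the indicators, so nested sums of squares from classical ANOVA (times 1/2)
# must reproduce the distance-based decomposition.
amova_oracle_ss <- function(gt, grouping) {
  acopy <- rbind(gt$a1, gt$a2)
  pop <- rep(gt$demes, 2L)
  grp <- grouping[pop]
  ss <- c(ag = 0, ap = 0, wp = 0)
  for (l in seq_len(ncol(acopy))) {
    a <- acopy[, l]
    for (al in sort(unique(a))) {
      y <- as.numeric(a == al) / sqrt(2)     # one-hot / sqrt(2): d = 0/1
      gm <- mean(y)
      pm <- tapply(y, pop, mean)[pop]
      gmu <- tapply(y, grp, mean)[grp]
      ss["wp"] <- ss["wp"] + sum((y - pm)^2)
      ss["ap"] <- ss["ap"] + sum((pm - gmu)^2)
      ss["ag"] <- ss["ag"] + sum((gmu - gm)^2)
    }
  }
  ss
}

# small symmetric matrix with given upper triangle (row-major)
upper_mat <- function(v, labels = NULL) {
  m <- refold_upper(v, labels)
  dist_matrix(m, if (is.null(labels)) paste0("p", seq_len(nrow(m))) else labels)
}
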