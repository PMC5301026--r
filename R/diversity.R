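# Sequence diversity / neutrality statistics and microsatellite diversity.
# pi and theta_W are reported per locus (summed over sites), matching the
# convention of the chloroplast table this pipeline reproduces.

.tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

.tajima_d <- function(n, S, pi) {
  if (S == 0L) return(NA_real_)
  k <- .tajima_constants(n)
  (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

# two-sided p from Tajima's beta approximation of the D null
.tajima_p_beta <- function(n, D) {
  k <- .tajima_constants(n)
  Dmin <- (2 / n - 1 / k$a1) / sqrt(k$e2)
  Dmax <- ((n + 1) / (2 * n) - 1 / k$a1) / sqrt(k$e2)
  tmp1 <- 1 + Dmin * Dmax; tmp2 <- Dmax - Dmin
  a <- -tmp1 * Dmax / tmp2; b <- tmp1 * Dmin / tmp2
  p <- stats::pbeta((D - Dmin) / tmp2, b, a)
  2 * min(p, 1 - p)
}

#' Sequence diversity and Tajima's D for one aligned locus
#'
#' Sites containing gaps or `N` in any sequence are excluded entirely
#' (complete-site deletion). `pi` is the mean number of pairwise differences
#' (per locus, not per site); `theta_w` is Watterson's `S / a_{n-1}`.
#'
#' @param aln a [seq_alignment()] with `n >= 2` sequences.
#' @return List of class `seq_diversity`: `n`, `S`, `pi`, `theta_w`,
#'   `tajima_d` (`NA` when `S = 0`), `p_beta` (beta-approximation two-sided
#'   p), and `site_freqs` (derived/minor allele count per segregating site).
#' @export
seq_diversity <- function(aln) {
  stopifnot(inherits(aln, "seq_alignment"))
  n <- length(aln$seqs)
  if (n < 2L) stop("need at least two sequences for diversity statistics")
  mat <- do.call(rbind, strsplit(aln$seqs, ""))
  keep <- apply(mat, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  mat <- mat[, keep, drop = FALSE]
  seg <- which(apply(mat, 2L, function(col) length(unique(col)) > 1L))
  S <- length(seg)
  pi <- 0; freqs <- integer(0)
  if (S > 0L) {
    pi <- sum(vapply(seg, function(j) {
      cnt <- table(mat[, j])
      (choose(n, 2) - sum(choose(cnt, 2))) / choose(n, 2)
    }, numeric(1L)))
    freqs <- vapply(seg, function(j) min(table(mat[, j])), numeric(1L))
  }
  k <- .tajima_constants(n)
  D <- .tajima_d(n, S, pi)
  structure(list(n = n, S = S, pi = pi, theta_w = S / k$a1,
                 tajima_d = D,
                 p_beta = if (S > 0L) .tajima_p_beta(n, D) else NA_real_,
                 site_freqs = freqs),
            class = "seq_diversity")
}

#' @export
print.seq_diversity <- function(x, ...) {
  cat(sprintf("n=%d S=%d pi=%.3f theta_w=%.3f D=%s\n", x$n, x$S, x$pi,
              x$theta_w,
              if (is.na(x$tajima_d)) "NA" else sprintf("%.3f", x$tajima_d)))
  invisible(x)
}

# one neutral genealogy of n tips conditioned on S mutations; returns D
# (branch lengths in arbitrary units -- only relative lengths matter)
.sim_conditional_d <- function(n, S) {
  desc <- rep(1L, n)            # tip descendants per active lineage
  blen <- rep(0, n)
  br_desc <- integer(2L * (n - 1L)); br_len <- numeric(2L * (n - 1L))
  nb <- 0L
  for (k in n:2) {
    dt <- stats::rexp(1L, rate = k * (k - 1) / 2)
    blen <- blen + dt
    pair <- sample.int(k, 2L)
    for (j in pair) {
      nb <- nb + 1L; br_desc[nb] <- desc[j]; br_len[nb] <- blen[j]
    }
    desc[pair[1L]] <- desc[pair[1L]] + desc[pair[2L]]
    blen[pair[1L]] <- 0
    desc <- desc[-pair[2L]]; blen <- blen[-pair[2L]]
  }
  hit <- sample.int(nb, S, replace = TRUE, prob = br_len[seq_len(nb)])
  d <- br_desc[hit]
  pi <- sum(2 * d * (n - d)) / (n * (n - 1))
  .tajima_d(n, S, pi)
}

#' Coalescent null distribution of Tajima's D conditioned on S
#'
#' Simulates neutral genealogies of `n` tips, drops `S` mutations uniformly
#' on the branches (probability proportional to branch length), and compares
#' the observed D to the resulting null: `p` is the two-sided fraction of
#' null values at least as extreme, `|D_null| >= |D_obs|`.
#'
#' @param n sample size; `S` segregating sites (`> 0`); `observed_d` the
#'   value under test.
#' @param reps number of genealogies (>= 1000).
#' @param seed optional RNG seed.
#' @return List: `null_mean_d`, `ci95` (2.5/97.5% quantiles), `p`, `reps`.
#' @export
tajima_coalescent_test <- function(n, S, observed_d, reps = 10000L,
                                   seed = NULL) {
  if (S < 1L) stop("Tajima's D is undefined for S = 0")
  if (reps < 1000L) stop("use at least 1,000 replicates")
  if (!is.null(seed)) set.seed(seed)
  null_d <- vapply(seq_len(reps), function(i) .sim_conditional_d(n, S),
                   numeric(1L))
  list(null_mean_d = mean(null_d),
       ci95 = unname(quantile(null_d, c(0.025, 0.975))),
       p = mean(abs(null_d) >= abs(observed_d)),
       reps = reps)
}

# ---- microsatellite diversity ------------------------------------------------

# per-deme x per-locus allele counts; returns list of count matrices
.allele_counts <- function(gt) {
  demes <- deme_labels(gt)
  lapply(seq_along(gt$loci), function(l) {
    ac <- c(gt$a1[, l], gt$a2[, l])
    dm <- factor(rep(gt$demes, 2L), levels = demes)
    keep <- !is.na(ac)
    if (!any(keep)) return(matrix(0L, length(demes), 0L,
                                  dimnames = list(demes, NULL)))
    tab <- table(dm[keep], factor(ac[keep]))
    m <- matrix(as.integer(tab), nrow = length(demes),
                dimnames = list(demes, colnames(tab)))
    m
  })
}

#' Per-deme microsatellite diversity indices
#'
#' For each deme: sample size, number of polymorphic loci, mean (+/- SE over
#' loci) number of different alleles `Na`, effective alleles
#' `Ne = 1/sum(p^2)`, Shannon's `I = -sum(p log p)`, private alleles (alleles
#' seen in exactly one deme across the whole table), and unbiased-free
#' expected heterozygosity `He = 1 - sum(p^2)`. Allele frequencies are
#' computed per deme per locus over non-missing gene copies.
#'
#' @param gt a [genotype_table()].
#' @return Data frame, one row per deme, with `<stat>_mean` / `<stat>_se`
#'   columns; per-locus values attached as attribute `"per_locus"`.
#' @export
msat_diversity <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  demes <- deme_labels(gt)
  counts <- .allele_counts(gt)
  L <- length(gt$loci)
  nd <- length(demes)
  scored <- sapply(counts, rowSums)           # nd x L copies scored
  if (is.null(dim(scored))) scored <- matrix(scored, nrow = nd)
  if (any(rowSums(scored) == 0))
    stop("deme with zero scored gene copies at every locus: ",
         demes[rowSums(scored) == 0][1L])
  per <- array(NA_real_, dim = c(nd, L, 5L),
               dimnames = list(demes, gt$loci,
                               c("na", "ne", "shannon", "he", "private")))
  for (l in seq_len(L)) {
    cm <- counts[[l]]
    tot_per_deme <- rowSums(cm)
    present_demes <- colSums(cm > 0L)
    for (d in seq_len(nd)) {
      if (tot_per_deme[d] == 0L) next
      p <- cm[d, ] / tot_per_deme[d]
      p <- p[p > 0]
      per[d, l, "na"] <- length(p)
      per[d, l, "ne"] <- 1 / sum(p^2)
      per[d, l, "shannon"] <- -sum(p * log(p))
      per[d, l, "he"] <- 1 - sum(p^2)
      per[d, l, "private"] <- sum(cm[d, ] > 0L & present_demes == 1L)
    }
  }
  se <- function(x) sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  out <- data.frame(deme = demes,
                    n = vapply(demes, function(d) sum(gt$demes == d),
                               numeric(1L)),
                    n_polymorphic = apply(per[, , "na", drop = FALSE], 1L,
                                          function(x) sum(x > 1, na.rm = TRUE)))
  for (s in c("na", "ne", "shannon", "private", "he")) {
    out[[paste0(s, "_mean")]] <- apply(per[, , s, drop = FALSE], 1L, mean,
                                       na.rm = TRUE)
    out[[paste0(s, "_se")]] <- apply(per[, , s, drop = FALSE], 1L, se)
  }
  rownames(out) <- demes
  attr(out, "per_locus") <- per
  out
}

# ---- Fdist outlier scan ------------------------------------------------------

# per-locus (He_total, Nei G_ST over all demes) from a count matrix
.locus_he_fst <- function(cm) {
  tot <- rowSums(cm)
  use <- tot > 0L
  if (sum(use) < 2L || sum(cm) == 0L) return(c(he = NA_real_, fst = NA_real_))
  p <- cm[use, , drop = FALSE] / tot[use]
  hs <- mean(1 - rowSums(p^2))
  pbar <- colMeans(p)
  ht <- 1 - sum(pbar^2)
  c(he = ht, fst = if (ht > 0) (ht - hs) / ht else NA_real_)
}

#' Fdist-style F_ST outlier scan against an island-model null
#'
#' Simulates `reps` independent microsatellite loci under a finite island
#' model calibrated so that the realized mean F_ST matches the observed
#' multilocus mean, then compares each observed locus's (He, F_ST) to
#' conditional quantiles of the simulated F_ST given He (20 equal-count He
#' bins, envelope interpolated at the observed He).
#'
#' @param gt a [genotype_table()] with >= 2 demes.
#' @param reps simulated loci (>= 10000 for the production envelope).
#' @param seed optional RNG seed.
#' @param envelope lower/upper simulated quantiles (default 95% envelope).
#' @param n_bins number of equal-count He bins.
#' @param island_N deme size used for the null island model.
#' @return Data frame per locus: `he`, `fst`, `lower`, `median`, `upper`,
#'   `flag` in `{neutral, high-outlier, low-outlier}` (`NA` for monomorphic
#'   loci). Attributes: `target_fst`, `realized_fst`, `island_m`, `reps`.
#' @export
fdist_outlier_test <- function(gt, reps = 10000L, seed = NULL,
                               envelope = c(0.025, 0.975), n_bins = 20L,
                               island_N = 500) {
  stopifnot(inherits(gt, "genotype_table"))
  demes <- deme_labels(gt)
  d <- length(demes)
  if (d < 2L) stop("outlier scan needs at least two demes")
  if (!is.null(seed)) set.seed(seed)
  counts <- .allele_counts(gt)
  obs <- t(vapply(counts, .locus_he_fst, numeric(2L)))
  if (all(is.na(obs[, "fst"]))) stop("all loci monomorphic: no test possible")
  target <- mean(obs[, "fst"], na.rm = TRUE)
  target <- min(max(target, 0.01), 0.95)
  copies <- vapply(demes, function(x) 2L * sum(gt$demes == x), integer(1L))

  sim_batch <- function(m, k) {
    spec <- scenario_island(d, island_N, m)
    t(vapply(seq_len(k), function(i) {
      r <- simulate_locus(spec, copies, mu = .rlogunif(1L, 1e-5, 5e-3),
                          model = "smm")
      cm <- table(factor(r$deme, levels = spec$demes$label), factor(r$alleles))
      .locus_he_fst(matrix(as.integer(cm), nrow = d))
    }, numeric(2L)))
  }
  # calibrate the per-pair migration rate to the observed mean F_ST
  m <- (1 / target - 1) / (4 * (2 * island_N) * (d / (d - 1))^2) / (d - 1)
  realized <- NA_real_
  for (it in 1:4) {
    cal <- sim_batch(m, 400L)
    realized <- mean(cal[, "fst"], na.rm = TRUE)
    if (abs(realized - target) < 0.01) break
    adj <- (1 / target - 1) / (1 / realized - 1)
    m <- min(m * adj, 0.5)
  }
  sims <- sim_batch(m, reps)
  sims <- sims[stats::complete.cases(sims), , drop = FALSE]
  realized <- mean(sims[, "fst"])

  # equal-count He bins, envelope interpolated at observed He
  ord <- order(sims[, "he"])
  bins <- split(ord, cut(seq_along(ord), n_bins, labels = FALSE))
  bin_he <- vapply(bins, function(ix) median(sims[ix, "he"]), numeric(1L))
  bin_lo <- vapply(bins, function(ix) quantile(sims[ix, "fst"], envelope[1L]),
                   numeric(1L))
  bin_md <- vapply(bins, function(ix) median(sims[ix, "fst"]), numeric(1L))
  bin_hi <- vapply(bins, function(ix) quantile(sims[ix, "fst"], envelope[2L]),
                   numeric(1L))
  interp <- function(y, x0) approx(bin_he, y, xout = x0, rule = 2L)$y
  lower <- interp(bin_lo, obs[, "he"])
  med   <- interp(bin_md, obs[, "he"])
  upper <- interp(bin_hi, obs[, "he"])
  flag <- ifelse(is.na(obs[, "fst"]), NA_character_,
          ifelse(obs[, "fst"] > upper, "high-outlier",
          ifelse(obs[, "fst"] < lower, "low-outlier", "neutral")))
  out <- data.frame(locus = gt$loci, he = obs[, "he"], fst = obs[, "fst"],
                    lower = lower, median = med, upper = upper, flag = flag,
                    row.names = gt$loci)
  attr(out, "target_fst") <- target
  attr(out, "realized_fst") <- realized
  attr(out, "island_m") <- m
  attr(out, "reps") <- reps
  out
}
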