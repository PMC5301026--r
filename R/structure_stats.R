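# Hierarchical AMOVA on allele-identity distances between gene copies, Nei
# pairwise F_ST with Rousset linearization, and global fixation indices.
#
# With the 0/1 allele-identity metric, sums of squares reduce to allele
# counts: for a set X of n scored copies at one locus,
#   SS(X) = [C(n,2) - sum_a C(c_a,2)] / n,
# summed over loci. Loci are handled with complete-deletion per locus;
# degrees of freedom use the full gene-copy counts (exact for complete data).

.ss_from_counts <- function(cnt) {
  n <- sum(cnt)
  if (n < 2L) return(0)
  (choose(n, 2) - sum(choose(cnt, 2))) / n
}

# sum over pairs of squared repeat-size differences, over n:
# sum_{i<j}(a_i - a_j)^2 / n = sum(a^2) - (sum a)^2 / n
.ss_from_sizes <- function(a) {
  n <- length(a)
  if (n < 2L) return(0)
  sum(a^2) - sum(a)^2 / n
}

# variance components for one assignment (pop per individual, group per pop)
.amova_components <- function(acopy, pop_of_copy, group_of_pop,
                              metric = "identity") {
  pops <- levels(pop_of_copy)
  groups <- unique(group_of_pop[pops])
  P <- length(pops); G <- length(groups)
  Ncop <- length(pop_of_copy)
  grp_of_copy <- factor(group_of_pop[as.character(pop_of_copy)],
                        levels = groups)
  ss_wp <- ss_wg <- ss_t <- 0
  for (l in seq_len(ncol(acopy))) {
    a <- acopy[, l]
    keep <- !is.na(a)
    pp <- pop_of_copy[keep]; gg <- grp_of_copy[keep]
    if (metric == "identity") {
      af <- factor(a[keep])
      ss_wp <- ss_wp + sum(apply(table(pp, af), 1L, .ss_from_counts))
      ss_wg <- ss_wg + sum(apply(table(gg, af), 1L, .ss_from_counts))
      ss_t <- ss_t + .ss_from_counts(table(af))
    } else {                               # squared repeat-size differences
      av <- as.numeric(a[keep])
      ss_wp <- ss_wp + sum(tapply(av, pp, .ss_from_sizes), na.rm = TRUE)
      ss_wg <- ss_wg + sum(tapply(av, gg, .ss_from_sizes), na.rm = TRUE)
      ss_t <- ss_t + .ss_from_sizes(av)
    }
  }
  ss_ap <- ss_wg - ss_wp
  ss_ag <- ss_t - ss_wg
  n_p <- as.numeric(table(pop_of_copy))
  n_g <- as.numeric(table(grp_of_copy))
  grp_idx <- match(group_of_pop[pops], groups)
  sum_np2_over_ng <- sum(vapply(seq_len(G), function(g) {
    sum(n_p[grp_idx == g]^2) / n_g[g]
  }, numeric(1L)))
  df <- c(ag = G - 1, ap = P - G, wp = Ncop - P)
  n1 <- (Ncop - sum_np2_over_ng) / df["ap"]
  n2 <- if (G > 1) (sum_np2_over_ng - sum(n_p^2) / Ncop) / df["ag"] else NA_real_
  n3 <- if (G > 1) (Ncop - sum(n_g^2) / Ncop) / df["ag"] else NA_real_
  ms_wp <- ss_wp / df["wp"]
  ms_ap <- ss_ap / df["ap"]
  sig_c <- ms_wp
  sig_b <- (ms_ap - sig_c) / n1
  sig_a <- if (G > 1) (ss_ag / df["ag"] - sig_c - n2 * sig_b) / n3 else NA_real_
  list(ss = c(ag = unname(ss_ag), ap = unname(ss_ap), wp = unname(ss_wp)),
       df = df, sigma = c(a = unname(sig_a), b = unname(sig_b),
                          c = unname(sig_c)))
}

.amova_f <- function(sigma) {
  tot <- sum(sigma, na.rm = TRUE)
  c(f_ct = unname(sigma["a"] / tot),
    f_sc = unname(sigma["b"] / (sigma["b"] + sigma["c"])),
    f_st = unname((sum(sigma[c("a", "b")], na.rm = TRUE)) / tot))
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Decomposes allele-identity variance among groups (species), among demes
#' within groups, and within demes, over gene copies (2 per diploid
#' individual). Negative variance components are reported as-is, never
#' truncated. Permutation p-values (add-one convention) use the scheme
#' appropriate to each statistic: individuals among all demes for F_ST,
#' individuals among demes within groups for F_SC, whole demes among groups
#' for F_CT.
#'
#' @param gt a [genotype_table()] with >= 2 demes.
#' @param grouping named character vector mapping deme label -> group label.
#'   Defaults to one group (two-level AMOVA; among-group row dropped).
#' @param perms number of permutations (0 skips the tests).
#' @param seed optional RNG seed.
#' @param metric gene-copy distance: `"identity"` (0/1 allele identity, the
#'   F_ST-like default) or `"repeat_size"` (squared repeat-score
#'   differences, R_ST-like).
#' @return List of class `amova_result`: `table` (df, SS, variance component,
#'   percent variation per stratum), `f_statistics`, `p_values`.
#' @export
amova <- function(gt, grouping = NULL, perms = 10000L, seed = NULL,
                  metric = c("identity", "repeat_size")) {
  metric <- match.arg(metric)
  stopifnot(inherits(gt, "genotype_table"))
  demes <- deme_labels(gt)
  if (length(demes) < 2L) stop("AMOVA needs at least two demes")
  if (is.null(grouping)) grouping <- setNames(rep("all", length(demes)), demes)
  if (!all(demes %in% names(grouping)))
    stop("grouping must cover every deme")
  grouping <- grouping[demes]
  one_group <- length(unique(grouping)) == 1L
  single_deme_groups <- names(which(table(grouping)[grouping] == 1L))
  if (!one_group && any(table(grouping) == 1L))
    warning("group(s) with a single deme: among-group test is fragile")
  if (!is.null(seed)) set.seed(seed)

  n_ind <- length(gt$ids)
  acopy <- rbind(gt$a1, gt$a2)          # 2*n_ind x L, copy i and i+n pair up
  pop_ind <- gt$demes
  pop_of_copy <- factor(rep(pop_ind, 2L), levels = demes)

  obs <- .amova_components(acopy, pop_of_copy, grouping, metric)
  fobs <- .amova_f(obs$sigma)

  p <- c(f_ct = NA_real_, f_sc = NA_real_, f_st = NA_real_)
  if (perms > 0L) {
    exceed <- c(f_ct = 0L, f_sc = 0L, f_st = 0L)
    for (b in seq_len(perms)) {
      # F_ST: individuals among all demes
      perm_all <- sample(pop_ind)
      f1 <- .amova_f(.amova_components(
        acopy, factor(rep(perm_all, 2L), levels = demes), grouping,
        metric)$sigma)
      if (!is.na(f1["f_st"]) && f1["f_st"] >= fobs["f_st"])
        exceed["f_st"] <- exceed["f_st"] + 1L
      if (!one_group) {
        # F_SC: individuals among demes within their group
        perm_wg <- pop_ind
        for (g in unique(grouping)) {
          sel <- grouping[pop_ind] == g
          perm_wg[sel] <- sample(pop_ind[sel])
        }
        f2 <- .amova_f(.amova_components(
          acopy, factor(rep(perm_wg, 2L), levels = demes), grouping,
          metric)$sigma)
        if (!is.na(f2["f_sc"]) && f2["f_sc"] >= fobs["f_sc"])
          exceed["f_sc"] <- exceed["f_sc"] + 1L
        # F_CT: whole demes among groups
        perm_g <- setNames(sample(unname(grouping)), demes)
        f3 <- .amova_f(.amova_components(acopy, pop_of_copy, perm_g,
                                         metric)$sigma)
        if (!is.na(f3["f_ct"]) && f3["f_ct"] >= fobs["f_ct"])
          exceed["f_ct"] <- exceed["f_ct"] + 1L
      }
    }
    p <- (exceed + 1L) / (perms + 1L)
    if (one_group) p[c("f_ct", "f_sc")] <- NA_real_
  }

  tot <- sum(obs$sigma, na.rm = TRUE)
  strata <- c("among_groups", "among_demes_within_groups", "within_demes")
  tab <- data.frame(
    stratum = strata,
    df = as.numeric(obs$df),
    sum_sq = as.numeric(obs$ss),
    variance = as.numeric(obs$sigma),
    pct_variation = 100 * as.numeric(obs$sigma) / tot)
  if (one_group) tab <- tab[-1L, ]
  structure(list(table = tab, f_statistics = fobs, p_values = p,
                 total_variance = tot, perms = perms),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("F_CT=%.4f F_SC=%.4f F_ST=%.4f\n",
              x$f_statistics["f_ct"], x$f_statistics["f_sc"],
              x$f_statistics["f_st"]))
  invisible(x)
}

# ---- pairwise F_ST and linearization ----------------------------------------

#' Nei pairwise F_ST (G_ST) between demes
#'
#' For each deme pair and locus, `G_ST = (H_T - H_S) / H_T` with `H_S` the
#' mean within-deme gene diversity and `H_T` computed from the unweighted
#' mean allele frequencies of the pair; per-pair values average the loci
#' polymorphic in that pair.
#'
#' @param gt a [genotype_table()] with >= 2 demes.
#' @return A [dist_matrix()] of kind `"genetic"`.
#' @export
pairwise_fst_nei <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  demes <- deme_labels(gt)
  if (length(demes) < 2L) stop("need at least two demes")
  counts <- .allele_counts(gt)
  n <- length(demes)
  m <- matrix(0, n, n, dimnames = list(demes, demes))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    vals <- vapply(counts, function(cm) {
      sub <- cm[c(i, j), , drop = FALSE]
      tot <- rowSums(sub)
      if (any(tot == 0L)) return(NA_real_)
      p <- sub / tot
      hs <- mean(1 - rowSums(p^2))
      ht <- 1 - sum(colMeans(p)^2)
      if (ht <= 0) NA_real_ else (ht - hs) / ht
    }, numeric(1L))
    scored <- vapply(counts, function(cm) all(rowSums(cm[c(i, j), ,
                                                         drop = FALSE]) > 0L),
                     logical(1L))
    if (!any(scored))
      stop("deme pair with no jointly scored locus: ", demes[i], "-", demes[j])
    m[i, j] <- m[j, i] <- if (all(is.na(vals))) 0 else mean(vals, na.rm = TRUE)
  }
  dist_matrix(m, demes, kind = "genetic")
}

#' Rousset linearization F_ST / (1 - F_ST)
#'
#' Entries at or above 0.999 are clamped to a linearized value of 999 (with a
#' message) to avoid infinities on fixed pairs; negative entries pass
#' through unchanged.
#'
#' @param fst a [dist_matrix()] of pairwise F_ST.
#' @return A [dist_matrix()] of kind `"linearized_fst"`.
#' @export
rousset_linearize <- function(fst) {
  m <- as.matrix(fst)
  clamped <- m >= 0.999 & row(m) != col(m)
  if (any(clamped)) {
    message("rousset_linearize: ", sum(clamped) / 2,
            " pair(s) at F_ST >= 0.999 clamped to 999")
  }
  out <- ifelse(clamped, 999, m / (1 - m))
  diag(out) <- 0
  dist_matrix(out, rownames(m), kind = "linearized_fst")
}

#' Global fixation indices F_IS, F_ST, F_IT (Nei formulation)
#'
#' `H_O` is the observed heterozygote fraction (averaged over demes then
#' loci), `H_S` the mean within-deme gene diversity, `H_T` the gene diversity
#' of unweighted mean allele frequencies. The identity
#' `(1 - F_IT) = (1 - F_IS)(1 - F_ST)` holds exactly in this formulation.
#'
#' @param gt a [genotype_table()] with >= 2 demes.
#' @return Named vector `c(f_is, f_st, f_it)`; all `NA` when every locus is
#'   monomorphic (`H_T = 0`).
#' @export
global_f_statistics <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  demes <- deme_labels(gt)
  if (length(demes) < 2L) stop("need at least two demes")
  counts <- .allele_counts(gt)
  L <- length(gt$loci)
  ho <- hs <- ht <- numeric(L)
  for (l in seq_len(L)) {
    cm <- counts[[l]]
    tot <- rowSums(cm)
    use <- tot > 0L
    p <- cm[use, , drop = FALSE] / tot[use]
    hs[l] <- mean(1 - rowSums(p^2))
    ht[l] <- 1 - sum(colMeans(p)^2)
    het <- !is.na(gt$a1[, l]) & gt$a1[, l] != gt$a2[, l]
    scored <- !is.na(gt$a1[, l])
    ho_d <- vapply(demes, function(d) {
      sel <- gt$demes == d & scored
      if (!any(sel)) NA_real_ else mean(het[sel])
    }, numeric(1L))
    ho[l] <- mean(ho_d, na.rm = TRUE)
  }
  HO <- mean(ho); HS <- mean(hs); HT <- mean(ht)
  if (HT <= 0) return(c(f_is = NA_real_, f_st = NA_real_, f_it = NA_real_))
  c(f_is = 1 - HO / HS, f_st = 1 - HS / HT, f_it = 1 - HO / HT)
}
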