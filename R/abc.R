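# Rejection ABC over demographic scenarios: microsatellite summary
# statistics, optional PLS compression, MAD-standardized Euclidean rejection,
# GLM marginal densities for model choice, and posterior parameter summaries.

#' Microsatellite summary statistics for ABC
#'
#' A fixed-order named vector linking observed data to simulations: per-deme
#' mean number of alleles and mean expected heterozygosity, global
#' F_IS/F_ST/F_IT, mean Nei pairwise F_ST, total allele count over loci, and
#' the mean per-locus variance of allele (repeat) size. Undefined fixation
#' indices on (near-)monomorphic tables are null-coded as 0 and flagged by the
#' `"degenerate"` attribute.
#'
#' @param x a [genotype_table()] or the result of [simulate_coalescent()].
#' @return Named numeric vector; length depends only on the number of demes.
#' @export
compute_summaries <- function(x) {
  gt <- if (inherits(x, "sim_dataset")) x$genotypes else x
  stopifnot(inherits(gt, "genotype_table"))
  demes <- deme_labels(gt)
  nd <- length(demes)
  counts <- .allele_counts(gt)
  L <- length(gt$loci)

  na_dl <- he_dl <- matrix(NA_real_, nd, L)
  ho_l <- hs_l <- ht_l <- numeric(L)
  var_sz <- numeric(L)
  tot_alleles <- 0L
  for (l in seq_len(L)) {
    cm <- counts[[l]]
    tot <- rowSums(cm)
    use <- tot > 0L
    p <- cm[use, , drop = FALSE] / tot[use]
    na_dl[use, l] <- rowSums(cm[use, , drop = FALSE] > 0L)
    he_dl[use, l] <- 1 - rowSums(p^2)
    hs_l[l] <- mean(1 - rowSums(p^2))
    ht_l[l] <- 1 - sum(colMeans(p)^2)
    het <- !is.na(gt$a1[, l]) & gt$a1[, l] != gt$a2[, l]
    scored <- !is.na(gt$a1[, l])
    ho_l[l] <- mean(vapply(demes, function(d) {
      sel <- gt$demes == d & scored
      if (!any(sel)) NA_real_ else mean(het[sel])
    }, numeric(1L)), na.rm = TRUE)
    tot_alleles <- tot_alleles + sum(colSums(cm) > 0L)
    sizes <- rep(as.integer(colnames(cm)), colSums(cm))
    var_sz[l] <- if (length(sizes) > 1L) var(sizes) else 0
  }
  HO <- mean(ho_l); HS <- mean(hs_l); HT <- mean(ht_l)
  degenerate <- HT <= 0 || HS <= 0
  fis <- if (degenerate) 0 else 1 - HO / HS
  fst <- if (degenerate) 0 else 1 - HS / HT
  fit <- if (degenerate) 0 else 1 - HO / HT
  mean_pw <- sd_pw <- 0
  if (nd >= 2L) {
    pw <- unfold_upper(pairwise_fst_nei(gt))
    mean_pw <- mean(pw)
    # spread of pairwise differentiation separates heterogeneous from shared
    # founding histories; 0 when only one pair exists
    sd_pw <- if (length(pw) > 1L) sd(pw) else 0
  }
  out <- c(setNames(rowMeans(na_dl, na.rm = TRUE), paste0("na_", demes)),
           setNames(rowMeans(he_dl, na.rm = TRUE), paste0("he_", demes)),
           f_is = fis, f_st = fst, f_it = fit,
           mean_pairwise_fst = mean_pw, sd_pairwise_fst = sd_pw,
           total_alleles = as.numeric(tot_alleles),
           var_allele_size = mean(var_sz))
  if (any(!is.finite(out))) stop("non-finite summary statistic produced")
  attr(out, "degenerate") <- degenerate
  out
}

#' Simulate an ABC reference table for one scenario family
#'
#' Draws `n_sims` parameter vectors from the prior, simulates a dataset for
#' each, and records [compute_summaries()] per draw.
#'
#' @param kind scenario family (see [default_priors()]).
#' @param sample_sizes named individuals-per-deme vector (deme names of the
#'   family's scenarios).
#' @param n_sims number of prior draws.
#' @param priors prior list.
#' @param n_msat microsatellite loci per simulated dataset (no sequence locus
#'   is simulated: the summary set is microsatellite-based).
#' @param seed optional RNG seed.
#' @return List of class `abc_reference`: `kind`, `params` (n_sims x p),
#'   `summaries` (n_sims x s).
#' @export
abc_reference <- function(kind, sample_sizes, n_sims = 10000L,
                          priors = default_priors(kind), n_msat = 11L,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- NULL; summaries <- NULL
  for (i in seq_len(n_sims)) {
    spec <- draw_scenario(kind, priors, n_msat = n_msat, n_seq = 0L)
    ds <- simulate_coalescent(spec, sample_sizes)
    s <- compute_summaries(ds)
    if (is.null(params)) {
      params <- matrix(NA_real_, n_sims, length(spec$params),
                       dimnames = list(NULL, names(spec$params)))
      summaries <- matrix(NA_real_, n_sims, length(s),
                          dimnames = list(NULL, names(s)))
    }
    params[i, ] <- spec$params
    summaries[i, ] <- s
  }
  structure(list(kind = kind, params = params, summaries = summaries),
            class = "abc_reference")
}

# ---- PLS ---------------------------------------------------------------------

#' Partial least squares transform of summary statistics
#'
#' NIPALS PLS2 on standardized summaries (X) and parameters (Y): components
#' maximize covariance with the parameters. The fitted rotation can be
#' applied to new (e.g. observed) summary vectors via [pls_apply()].
#' Collinear/duplicate summary columns are tolerated.
#'
#' @param sim_summaries n x s matrix; `sim_params` n x p matrix; `k` number
#'   of components (`1 <= k <= s`).
#' @return List of class `pls_fit`: `scores` (n x k), `rotation`, `center`,
#'   `scale`, `k`.
#' @export
pls_transform <- function(sim_summaries, sim_params, k) {
  X <- as.matrix(sim_summaries); Y <- as.matrix(sim_params)
  if (k < 1L) stop("number of PLS components must be positive")
  if (k > ncol(X)) stop("k exceeds the number of summary statistics")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd); scl[scl == 0] <- 1
  X0 <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  Y0 <- scale(Y)
  Y0[, apply(Y, 2L, sd) == 0] <- 0
  W <- P <- NULL
  Xd <- X0
  for (cc in seq_len(k)) {
    u <- Y0[, which.max(apply(Y0, 2L, var))]
    w_old <- NULL
    for (it in 1:200) {
      w <- drop(crossprod(Xd, u))
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) { w <- rep(0, ncol(Xd)); break }
      w <- w / nw
      tt <- drop(Xd %*% w)
      q <- drop(crossprod(Y0, tt)) / sum(tt^2)
      nq <- sqrt(sum(q^2))
      u <- if (nq < 1e-12) tt else drop(Y0 %*% q) / sum(q^2)
      if (!is.null(w_old) && sum((w - w_old)^2) < 1e-12) break
      w_old <- w
    }
    if (sum(w^2) < 1e-12) break
    tt <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, tt)) / sum(tt^2)
    Xd <- Xd - tcrossprod(tt, p)
    W <- cbind(W, w); P <- cbind(P, p)
  }
  if (is.null(W)) stop("PLS found no informative component")
  R <- W %*% solve(crossprod(P, W))     # rotation: T = X0 %*% R
  fit <- structure(list(rotation = R, center = ctr, scale = scl,
                        k = ncol(R)), class = "pls_fit")
  fit$scores <- X0 %*% R
  fit
}

#' Apply a fitted PLS rotation to new summary vectors
#' @param fit a `pls_fit` from [pls_transform()].
#' @param newdata summary vector or matrix in the original statistic space.
#' @return Matrix of component scores.
#' @export
pls_apply <- function(fit, newdata) {
  stopifnot(inherits(fit, "pls_fit"))
  X <- if (is.null(dim(newdata))) matrix(newdata, 1L) else as.matrix(newdata)
  X0 <- sweep(sweep(X, 2L, fit$center), 2L, fit$scale, "/")
  X0 %*% fit$rotation
}

# ---- rejection and densities -------------------------------------------------

#' Rejection step: retain the simulations closest to the observed vector
#'
#' Distance is Euclidean on summaries standardized by the simulation-wide
#' median absolute deviation (statistics with zero MAD are excluded from the
#' distance). Ties are broken by simulation index, so the retained set is
#' deterministic.
#'
#' @param observed named summary vector.
#' @param simulations an [abc_reference()] (or list with `params`,
#'   `summaries`).
#' @param retain_k number of simulations to retain.
#' @param scale optional per-statistic scale overriding the table's own MAD
#'   (used to share one standardization across candidate models).
#' @return List: `params`, `summaries` (retained, ascending distance),
#'   `distances`, `index`, `scale`.
#' @export
abc_reject <- function(observed, simulations, retain_k, scale = NULL) {
  S <- simulations$summaries
  if (retain_k > nrow(S)) stop("retain_k exceeds the number of simulations")
  obs <- observed[colnames(S)]
  if (any(is.na(obs))) stop("observed vector lacks required statistics")
  if (is.null(scale)) scale <- apply(S, 2L, stats::mad)
  use <- scale > 0
  if (!any(use)) stop("all summary statistics are constant across simulations")
  D <- sweep(S[, use, drop = FALSE], 2L, obs[use])
  D <- sweep(D, 2L, scale[use], "/")
  d <- sqrt(rowSums(D^2))
  ord <- order(d, seq_along(d))
  keep <- ord[seq_len(retain_k)]
  list(params = simulations$params[keep, , drop = FALSE],
       summaries = S[keep, , drop = FALSE],
       distances = d[keep], index = keep, scale = scale)
}

.dmvnorm_chol <- function(x, mu_mat, sigma) {
  # mean over rows of mu_mat of N(x; mu, sigma)
  p <- length(x)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  eps <- 1e-8 * mean(diag(sigma))
  if (eps <= 0) eps <- 1e-12
  while (is.null(ch)) {
    sigma <- sigma + diag(eps, p)
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    eps <- eps * 10
  }
  logdet <- 2 * sum(log(diag(ch)))
  dev <- sweep(mu_mat, 2L, x)
  z <- forwardsolve(t(ch), t(dev))
  q <- colSums(z^2)
  mean(exp(-0.5 * (q + logdet + p * log(2 * pi))))
}

#' GLM-adjusted marginal density of a model at the observed summaries
#'
#' Fits a multivariate-normal linear regression of the retained summaries on
#' the retained parameters and evaluates the density of the observed summary
#' vector under the fitted model, averaged over the retained parameter sample
#' (a mixture evaluation of the model evidence local to the rejection
#' region). Deterministic given the retained set; a singular residual
#' covariance is ridge-regularized with a message.
#'
#' @param retained output of [abc_reject()] (>= 100 rows).
#' @param observed named summary vector.
#' @return The marginal density (non-negative scalar).
#' @export
glm_marginal_density <- function(retained, observed) {
  S <- retained$summaries; Th <- retained$params
  if (nrow(S) < 100L) stop("need at least 100 retained simulations")
  obs <- observed[colnames(S)]
  # densities are evaluated on the raw summary scale so that ratios across
  # models share one measure and toy problems match analytic evidences
  pv <- apply(Th, 2L, sd)       # drop parameters with no variation
  X <- cbind(1, scale(Th[, pv > 0, drop = FALSE]))
  fit <- lm.fit(X, S)
  res <- as.matrix(fit$residuals)
  dfree <- max(nrow(S) - ncol(X), 1L)
  sigma <- crossprod(res) / dfree
  mu <- as.matrix(X %*% fit$coefficients)
  .dmvnorm_chol(obs, mu, sigma)
}

#' Posterior model probabilities and Bayes factors from marginal densities
#'
#' @param densities named non-negative vector of per-scenario marginal
#'   densities (equal prior model weights).
#' @return List of class `model_comparison`: `densities`, `posterior`
#'   (sums to 1), `bayes_factors` (matrix `BF[i, j] = d_i / d_j`).
#' @export
model_posterior <- function(densities) {
  densities <- unlist(densities)
  if (length(densities) < 2L) stop("need at least two candidate scenarios")
  if (any(densities < 0)) stop("marginal densities must be non-negative")
  if (sum(densities) == 0) stop("all marginal densities are zero: no posterior")
  post <- densities / sum(densities)
  bf <- outer(densities, densities, "/")
  structure(list(densities = densities, posterior = post,
                 bayes_factors = bf), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  df <- data.frame(scenario = names(x$posterior),
                   density = signif(x$densities, 4),
                   posterior_pct = round(100 * x$posterior, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Posterior parameter summaries from a retained set
#'
#' Kernel-density mode and equal-tailed 2.5-97.5% interval per parameter,
#' optionally weighted.
#'
#' @param params retained parameter matrix (or `abc_reject()` output).
#' @param weights optional non-negative weights.
#' @return Data frame: `parameter`, `mode`, `lo95`, `hi95`.
#' @export
posterior_param_estimates <- function(params, weights = NULL) {
  if (is.list(params) && !is.null(params$params)) params <- params$params
  params <- as.matrix(params)
  if (nrow(params) < 1L) stop("retained set is empty")
  if (is.null(weights)) weights <- rep(1, nrow(params))
  w <- weights / sum(weights)
  wq <- function(x, probs) {
    o <- order(x)
    cw <- cumsum(w[o])
    vapply(probs, function(pr) x[o][which(cw >= pr)[1L]], numeric(1L))
  }
  rows <- lapply(colnames(params), function(nm) {
    x <- params[, nm]
    if (sd(x) == 0) {
      warning("parameter ", nm, " is constant in the retained set")
      return(data.frame(parameter = nm, mode = x[1L], lo95 = x[1L],
                        hi95 = x[1L]))
    }
    dd <- density(x, weights = w)
    q <- wq(x, c(0.025, 0.975))
    data.frame(parameter = nm, mode = dd$x[which.max(dd$y)],
               lo95 = q[1L], hi95 = q[2L])
  })
  do.call(rbind, rows)
}

#' End-to-end ABC model choice over scenario families
#'
#' Builds (or reuses) a reference table per candidate family, standardizes
#' all summaries by the pooled MAD across candidates, retains the `retain_k`
#' closest simulations per family, computes GLM marginal densities, and
#' returns the model comparison plus per-family retained sets.
#'
#' @param observed named summary vector ([compute_summaries()]).
#' @param references list of [abc_reference()] tables (one per family).
#' @param retain_k retained simulations per family.
#' @return List of class `abc_model_choice`: `comparison`
#'   ([model_posterior()]), `retained` (per family), `retain_k`.
#' @export
abc_model_choice <- function(observed, references, retain_k = 500L) {
  stopifnot(length(references) >= 2L)
  kinds <- vapply(references, `[[`, character(1L), "kind")
  names(references) <- kinds
  pooled <- do.call(rbind, lapply(references, `[[`, "summaries"))
  scale <- apply(pooled, 2L, stats::mad)
  retained <- lapply(references, function(ref)
    abc_reject(observed, ref, retain_k, scale = scale))
  dens <- vapply(retained, glm_marginal_density, numeric(1L),
                 observed = observed)
  structure(list(comparison = model_posterior(dens), retained = retained,
                 retain_k = retain_k), class = "abc_model_choice")
}
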