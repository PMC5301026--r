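# Distance construction and matrix association tests. Mantel statistics are
# one-tailed for positive association (the convention of the originating
# method); MMRR coefficient tests are two-tailed. All permutation p-values
# use the add-one convention p = (exceedances + 1) / (perms + 1).

#' Geographic distance between populations
#'
#' `mode = "projected"` (default) converts latitude/longitude to kilometres
#' on a local equirectangular projection and uses altitude in kilometres,
#' giving physically meaningful 3-D Euclidean distances. `mode = "paper_raw"`
#' reproduces the raw mixing of decimal degrees with altitude in metres used
#' by some published pipelines.
#'
#' @param sites site data frame ([read_site_table()]).
#' @param mode `"projected"` or `"paper_raw"`.
#' @return A [dist_matrix()] of kind `"geographic"`.
#' @export
geographic_distance <- function(sites, mode = c("projected", "paper_raw")) {
  mode <- match.arg(mode)
  if (any(is.na(sites$altitude))) stop("altitude required for 3-D distances")
  if (mode == "projected") {
    km_per_deg <- pi * 6371.0088 / 180
    lat0 <- mean(sites$latitude) * pi / 180
    x <- sites$longitude * km_per_deg * cos(lat0)
    y <- sites$latitude * km_per_deg
    z <- sites$altitude / 1000
  } else {
    x <- sites$longitude; y <- sites$latitude; z <- sites$altitude
  }
  m <- as.matrix(dist(cbind(x, y, z)))
  dist_matrix(m, sites$abbreviation, kind = "geographic")
}

#' Environmental (climatic) distance between populations
#'
#' Euclidean distance over the chosen bioclimatic variables, by default the
#' six retained ones, standardized to unit variance first (set
#' `standardize = FALSE` for raw-unit distances).
#'
#' @param sites site data frame.
#' @param variables climate columns to use.
#' @param standardize scale columns to unit variance before the distance.
#' @return A [dist_matrix()] of kind `"environmental"`.
#' @export
environmental_distance <- function(sites,
                                   variables = c("bio2", "bio8", "bio9",
                                                 "bio13", "bio18", "bio19"),
                                   standardize = TRUE) {
  missing_vars <- setdiff(variables, names(sites))
  if (length(missing_vars))
    stop("site table lacks variable(s): ", paste(missing_vars, collapse = ", "))
  X <- as.matrix(sites[variables])
  if (standardize) X <- scale(X)
  m <- as.matrix(dist(X))
  dist_matrix(m, sites$abbreviation, kind = "environmental")
}

.check_labels <- function(...) {
  mats <- list(...)
  labs <- rownames(mats[[1L]])
  for (m in mats[-1L])
    if (!identical(rownames(m), labs))
      stop("distance matrices must share one label order")
  labs
}

#' Mantel test between two distance matrices
#'
#' Correlation (Spearman by default) between the unfolded upper triangles;
#' the null distribution jointly permutes rows and columns of the second
#' matrix. One-tailed (greater) add-one p.
#'
#' @param mA,mB [dist_matrix()] objects with identical label order.
#' @param method correlation method.
#' @param perms number of permutations.
#' @param seed optional RNG seed.
#' @return List of class `matrix_test_result`: `statistic` (rho), `p`,
#'   `perms`, `method`.
#' @export
mantel_test <- function(mA, mB, method = c("spearman", "pearson"),
                        perms = 9999L, seed = NULL) {
  method <- match.arg(method)
  .check_labels(mA, mB)
  if (!is.null(seed)) set.seed(seed)
  vA <- unfold_upper(mA); vB <- unfold_upper(mB)
  if (sd(vA) == 0 || sd(vB) == 0)
    stop("constant distance matrix: correlation undefined")
  obs <- cor(vA, vB, method = method)
  n <- nrow(mA)
  B <- as.matrix(mB)
  exceed <- 0L
  for (b in seq_len(perms)) {
    p <- sample.int(n)
    if (cor(vA, unfold_upper(B[p, p]), method = method) >= obs)
      exceed <- exceed + 1L
  }
  structure(list(statistic = c(rho = obs), p = (exceed + 1L) / (perms + 1L),
                 perms = perms, method = method, kind = "mantel"),
            class = "matrix_test_result")
}

#' @export
print.matrix_test_result <- function(x, ...) {
  cat(x$kind, ": ", paste(names(x$statistic), "=",
                          signif(x$statistic, 4), collapse = ", "),
      "; p = ", signif(x$p, 4), " (", x$perms, " perms)\n", sep = "")
  invisible(x)
}

#' Partial Mantel test (A vs B, controlling C)
#'
#' First-order partial rank correlation of the unfolded triangles;
#' significance by permuting the matrix of residuals of A on C (rows and
#' columns jointly) and re-correlating with the residuals of B on C.
#'
#' @param mA,mB,mC [dist_matrix()] objects with identical label order.
#' @inheritParams mantel_test
#' @return A `matrix_test_result` with the partial rho.
#' @export
partial_mantel <- function(mA, mB, mC, perms = 9999L, seed = NULL) {
  .check_labels(mA, mB, mC)
  if (!is.null(seed)) set.seed(seed)
  rA <- rank(unfold_upper(mA)); rB <- rank(unfold_upper(mB))
  rC <- rank(unfold_upper(mC))
  r_ab <- cor(rA, rB); r_ac <- cor(rA, rC); r_bc <- cor(rB, rC)
  if (abs(r_ac) >= 1 - 1e-12 || abs(r_bc) >= 1 - 1e-12)
    stop("conditioning matrix collinear with an input: partial correlation degenerate")
  obs <- (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
  eA <- stats::resid(lm(rA ~ rC)); eB <- stats::resid(lm(rB ~ rC))
  RA <- refold_upper(eA)
  n <- nrow(mA)
  stat0 <- cor(eA, eB)
  exceed <- 0L
  for (b in seq_len(perms)) {
    p <- sample.int(n)
    if (cor(unfold_upper(RA[p, p]), eB) >= stat0) exceed <- exceed + 1L
  }
  structure(list(statistic = c(rho = obs), p = (exceed + 1L) / (perms + 1L),
                 perms = perms, method = "spearman-partial",
                 kind = "partial_mantel"),
            class = "matrix_test_result")
}

#' Multiple matrix regression with randomization (MMRR)
#'
#' OLS of the unfolded response matrix on the unfolded predictor matrices,
#' all standardized to zero mean and unit variance; significance of the
#' standardized betas (two-tailed, on |t|) and of the overall F by jointly
#' permuting rows and columns of the response matrix.
#'
#' @param response a [dist_matrix()]; `predictors` named list of
#'   [dist_matrix()] objects.
#' @inheritParams mantel_test
#' @return A `matrix_test_result` with `beta` (per predictor), `r_squared`,
#'   `f`, `p` (overall F), `p_beta` (per predictor).
#' @export
mmrr <- function(response, predictors, perms = 9999L, seed = NULL) {
  stopifnot(length(predictors) >= 1L)
  if (is.null(names(predictors)))
    names(predictors) <- paste0("X", seq_along(predictors))
  do.call(.check_labels, c(list(response), predictors))
  if (!is.null(seed)) set.seed(seed)
  zs <- function(v) (v - mean(v)) / sd(v)
  y <- zs(unfold_upper(response))
  X <- vapply(predictors, function(m) zs(unfold_upper(m)),
              numeric(length(y)))
  X <- as.matrix(X)
  if (qr(cbind(1, X))$rank < ncol(X) + 1L)
    stop("predictor matrices are collinear: MMRR design is rank-deficient")
  fit_stats <- function(yv) {
    f <- lm(yv ~ X)
    sm <- summary(f)
    list(beta = coef(f)[-1L], t = coef(sm)[-1L, "t value"],
         r2 = sm$r.squared,
         F = unname(sm$fstatistic[1L]))
  }
  obs <- fit_stats(y)
  n <- nrow(response)
  R <- as.matrix(response)
  exc_t <- rep(0L, ncol(X)); exc_f <- 0L
  for (b in seq_len(perms)) {
    p <- sample.int(n)
    pst <- fit_stats(zs(unfold_upper(R[p, p])))
    exc_t <- exc_t + (abs(pst$t) >= abs(obs$t))
    exc_f <- exc_f + (pst$F >= obs$F)
  }
  structure(list(statistic = setNames(obs$beta,
                                      paste0("beta_", names(predictors))),
                 r_squared = obs$r2, f = obs$F,
                 p = (exc_f + 1L) / (perms + 1L),
                 p_beta = setNames((exc_t + 1L) / (perms + 1L),
                                   names(predictors)),
                 perms = perms, method = "ols", kind = "mmrr"),
            class = "matrix_test_result")
}
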