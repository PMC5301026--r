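# Climate-variable pruning, climate PCA, partial distance-based RDA of the
# genetic components conditioned on geography, and per-variable GLMs on the
# ordination axes. The constrained ordination itself is delegated to vegan.

#' Iterative variance-inflation-factor pruning
#'
#' Repeatedly drops the variable with the largest VIF
#' (`VIF_j = 1 / (1 - R^2_j)` from regressing variable j on the rest) until
#' every remaining VIF is below the threshold. Perfectly collinear variables
#' get infinite VIF and are dropped first.
#'
#' @param climate data frame or matrix of candidate variables over sites.
#' @param threshold VIF threshold (default 10).
#' @return Character vector of retained variable names; the drop order is
#'   attached as attribute `"dropped"` and the final VIFs as `"vif"`.
#' @export
vif_prune <- function(climate, threshold = 10) {
  X <- as.data.frame(climate)
  if (ncol(X) < 2L) stop("need at least two candidate variables")
  vifs_of <- function(vars) {
    vapply(vars, function(v) {
      fit <- lm(stats::reformulate(vars[vars != v], response = v), data = X)
      r2 <- suppressWarnings(summary(fit)$r.squared)  # perfect fits expected
      if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
    }, numeric(1L))
  }
  vars <- names(X)
  dropped <- character(0)
  while (length(vars) > 1L) {
    v <- vifs_of(vars)
    if (max(v) < threshold) break
    worst <- names(which.max(v))
    dropped <- c(dropped, worst)
    vars <- setdiff(vars, worst)
  }
  final <- if (length(vars) > 1L) vifs_of(vars) else setNames(1, vars)
  structure(vars, dropped = dropped, vif = final)
}

#' Principal component analysis of (standardized) climate variables
#'
#' Correlation-matrix PCA with deterministic loading signs: each component is
#' flipped so its largest-magnitude loading is positive.
#'
#' @param sites site data frame (or any data frame holding the variables).
#' @param variables columns to analyse.
#' @return List of class `climate_pca`: `loadings`, `scores`, `explained`
#'   (fractions summing to 1).
#' @export
climate_pca <- function(sites, variables = c("bio2", "bio8", "bio9", "bio13",
                                             "bio18", "bio19")) {
  X <- as.matrix(as.data.frame(sites)[variables])
  sds <- apply(X, 2L, sd)
  if (any(sds == 0))
    stop("zero-variance variable(s): ",
         paste(variables[sds == 0], collapse = ", "))
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(list(loadings = pc$rotation, scores = pc$x,
                 explained = pc$sdev^2 / sum(pc$sdev^2)),
            class = "climate_pca")
}

#' Individual-level allele-sharing genetic distance
#'
#' `d_ij = 1 -` (mean over jointly scored loci of shared alleles / 2): 0 for
#' identical genotypes, 1 when no alleles are shared at any locus.
#'
#' @param gt a [genotype_table()].
#' @return Symmetric matrix over individuals.
#' @export
allele_sharing_distance <- function(gt) {
  n <- length(gt$ids)
  L <- length(gt$loci)
  d <- matrix(0, n, n, dimnames = list(gt$ids, gt$ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sh <- num <- 0
    for (l in seq_len(L)) {
      gi <- c(gt$a1[i, l], gt$a2[i, l]); gj <- c(gt$a1[j, l], gt$a2[j, l])
      if (anyNA(gi) || anyNA(gj)) next
      u <- unique(c(gi, gj))
      s <- sum(pmin(tabulate(match(gi, u), length(u)),
                    tabulate(match(gj, u), length(u))))
      sh <- sh + s / 2; num <- num + 1
    }
    d[i, j] <- d[j, i] <- if (num == 0) NA_real_ else 1 - sh / num
  }
  if (anyNA(d)) stop("individual pair with no jointly scored locus")
  d
}

#' Genetic components: principal coordinates of allele-sharing distance
#'
#' Metric PCoA (classical MDS) of [allele_sharing_distance()]; the first
#' `n_axes` coordinates represent the genetic components of individuals.
#'
#' @param gt a [genotype_table()].
#' @param n_axes number of retained axes (default 5).
#' @return Matrix (individuals x axes) with deme labels as attribute.
#' @export
genetic_components <- function(gt, n_axes = 5L) {
  d <- allele_sharing_distance(gt)
  pc <- cmdscale(as.dist(d), k = n_axes)
  colnames(pc) <- paste0("PC", seq_len(ncol(pc)))
  attr(pc, "demes") <- gt$demes
  pc
}

#' Partial distance-based redundancy analysis of genetic components
#'
#' Constrains the first `n_axes` genetic principal coordinates of the
#' individuals by the site climate variables, conditioning on geography
#' (latitude and longitude by default). Individuals carry the climate and
#' coordinates of their population's site. Per-predictor marginal pseudo-F
#' and permutation-of-residuals p-values, and the inertia partition
#' (conditional / constrained / unconstrained summing to the total), follow
#' the standard constrained-ordination machinery (vegan).
#'
#' @param gt a [genotype_table()] whose deme labels match
#'   `sites$abbreviation`, or a numeric response matrix with a `"demes"`
#'   attribute.
#' @param sites site data frame.
#' @param predictors climate columns used as constraints.
#' @param conditioners columns conditioned out (`NULL` for plain RDA).
#' @param n_axes genetic axes when `gt` is a genotype table.
#' @param perms permutations for the marginal ANOVA.
#' @param seed optional RNG seed.
#' @return List of class `dbrda_result`: `inertia` (data frame with the
#'   partition), `terms` (per-predictor inertia, proportion, F, p),
#'   `site_scores` (axes 1-2), `model` (the underlying vegan fit).
#' @export
partial_dbrda <- function(gt, sites,
                          predictors = c("bio2", "bio8", "bio9", "bio13",
                                         "bio18", "bio19"),
                          conditioners = c("latitude", "longitude"),
                          n_axes = 5L, perms = 999L, seed = NULL) {
  Y <- if (inherits(gt, "genotype_table")) genetic_components(gt, n_axes)
       else as.matrix(gt)
  demes <- attr(Y, "demes")
  if (is.null(demes)) stop("response needs a 'demes' attribute")
  if (!all(demes %in% sites$abbreviation))
    stop("deme label(s) missing from the site table: ",
         paste(setdiff(demes, sites$abbreviation), collapse = ", "))
  env <- sites[match(demes, sites$abbreviation),
               c(predictors, conditioners), drop = FALSE]
  if (length(c(predictors, conditioners)) > nrow(Y) - 1L)
    stop("more predictors plus conditioners than observations - 1")
  rhs <- paste(predictors, collapse = " + ")
  if (length(conditioners))
    rhs <- paste0(rhs, " + Condition(",
                  paste(conditioners, collapse = " + "), ")")
  fml <- stats::as.formula(paste("Y ~", rhs))
  if (!is.null(seed)) set.seed(seed)
  mod <- vegan::rda(fml, data = env)
  an <- vegan::anova.cca(mod, by = "margin", permutations = perms)

  tot <- mod$tot.chi
  inertia <- data.frame(
    component = c("conditional", "constrained", "unconstrained", "total"),
    inertia = c(if (is.null(mod$pCCA)) 0 else mod$pCCA$tot.chi,
                if (is.null(mod$CCA)) 0 else mod$CCA$tot.chi,
                mod$CA$tot.chi, tot))
  inertia$proportion <- inertia$inertia / tot
  terms <- data.frame(term = rownames(an)[seq_along(predictors)],
                      inertia = an$Variance[seq_along(predictors)],
                      proportion = an$Variance[seq_along(predictors)] / tot,
                      f = an$F[seq_along(predictors)],
                      p = an$`Pr(>F)`[seq_along(predictors)])
  sc <- vegan::scores(mod, display = "sites", choices = 1:2)
  structure(list(inertia = inertia, terms = terms, site_scores = sc,
                 model = mod), class = "dbrda_result")
}

#' @export
print.dbrda_result <- function(x, ...) {
  print(x$inertia, row.names = FALSE)
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' GLM of a climate variable on two ordination axes
#'
#' Ordinary least squares of the per-observation variable values on axis-1
#' and axis-2 scores: per-axis t statistics, adjusted R-squared, overall F
#' and its p-value.
#'
#' @param values numeric vector (one value per observation).
#' @param axis_scores two-column matrix of ordination scores.
#' @return List: `t` (per axis), `p_t`, `adj_r_squared`, `f`, `p`.
#' @export
axis_glm <- function(values, axis_scores) {
  axis_scores <- as.matrix(axis_scores)[, 1:2, drop = FALSE]
  if (length(values) != nrow(axis_scores)) stop("lengths differ")
  if (length(values) < 3L) stop("need at least three observations")
  if (sd(values) == 0) stop("constant variable: fit undefined")
  a1 <- axis_scores[, 1L]; a2 <- axis_scores[, 2L]
  fit <- lm(values ~ a1 + a2)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(t = setNames(coef(sm)[-1L, "t value"], c("axis1", "axis2")),
       p_t = setNames(coef(sm)[-1L, "Pr(>|t|)"], c("axis1", "axis2")),
       adj_r_squared = sm$adj.r.squared,
       f = unname(fstat[1L]),
       p = unname(pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)))
}
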