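# Repertoire-ecotype association statistics: 2x2 contingency test,
# family-size-ratio test, PCA of the species-by-subfamily matrix, ANOSIM on
# Euclidean distances, and phylogenetic logistic regression of a binary
# ecotype on repertoire size.

#' Pearson chi-square test for a 2x2 table
#'
#' Default is the uncorrected Pearson statistic
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with a chi-square(1) tail;
#' Yates continuity correction is available by flag.
#'
#' @param a,b,c,d Cell counts (row-wise: a,b / c,d).
#' @param correction `"off"` (default) or `"yates"`.
#' @return List with `stat` and `p`.
#' @export
chisq_2x2 <- function(a, b, c, d, correction = c("off", "yates")) {
  correction <- match.arg(correction)
  if (min(a, b, c, d) < 0) stop("counts must be >= 0")
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("degenerate table: zero row or column sum")
  num <- abs(a * d - b * c)
  if (correction == "yates") num <- max(0, num - n / 2)
  stat <- n * num^2 / prod(margins)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' One-sample t test of family-size ratios against a reference
#'
#' Two-sided one-sample Student's t test of `mean(ratios)` against
#' `reference`; optionally reports where a focal ratio sits in the empirical
#' distribution of ratios.
#'
#' @param ratios Per-family size ratios (length >= 2, finite).
#' @param reference Reference mean ratio.
#' @param focal Optional focal ratio (e.g. the receptor family's own ratio).
#' @return List with `t`, `df`, `p`, `mean`, and `focal_quantile` (fraction
#'   of ratios <= focal) when `focal` is given.
#' @export
family_size_ratio_test <- function(ratios, reference, focal = NULL) {
  if (length(ratios) < 2L || any(!is.finite(ratios))) {
    stop("need >= 2 finite ratios")
  }
  if (stats::sd(ratios) == 0) {
    # no dispersion: identical to the reference is no evidence of difference;
    # any other constant value leaves t undefined
    if (isTRUE(all.equal(mean(ratios), reference))) {
      return(list(t = 0, df = length(ratios) - 1, p = 1, mean = mean(ratios)))
    }
    stop("degenerate: zero variance in ratios")
  }
  tt <- stats::t.test(ratios, mu = reference)
  out <- list(t = unname(tt$statistic), df = unname(tt$parameter),
              p = tt$p.value, mean = mean(ratios))
  if (!is.null(focal)) out$focal_quantile <- mean(ratios <= focal)
  out
}

#' Principal component analysis of a repertoire matrix
#'
#' Centered (not scaled) PCA via singular value decomposition of the
#' species-by-subfamily matrix, on raw counts or row-proportions.
#'
#' @param m Numeric matrix (species x subfamilies), >= 3 rows, >= 2 columns.
#' @param view `"counts"` or `"proportions"` (rows normalized to sum 1).
#' @return List with `scores`, `loadings`, `var_explained` (percentages
#'   summing to 100), `sdev`.
#' @export
pca_repertoire <- function(m, view = c("counts", "proportions")) {
  view <- match.arg(view)
  if (nrow(m) < 3L || ncol(m) < 2L) stop("need >= 3 species and >= 2 subfamilies")
  x <- if (view == "proportions") m / rowSums(m) else m
  if (all(apply(x, 2, stats::var) == 0)) stop("degenerate: constant matrix")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ve <- 100 * p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, loadings = p$rotation, var_explained = ve, sdev = p$sdev)
}

#' Analysis of similarities (ANOSIM)
#'
#' Clarke's ANOSIM on Euclidean distances (or a supplied distance matrix):
#' distances are replaced by their global ranks (mean ranks for ties) and
#' `R = (mean_between - mean_within) / (n(n-1)/4)`. Significance is assessed
#' by permuting group labels; p-values use the add-one estimator and are
#' never exactly zero.
#'
#' @param x Data matrix (rows = observations) or a `dist` object.
#' @param grouping Group labels (>= 2 groups).
#' @param n_perm Number of label permutations.
#' @param seed RNG seed.
#' @return An `anosim_result` list: `R`, `p`, `n_perm`, `grouping`, `metric`,
#'   `unreliable` (TRUE when a group is a singleton).
#' @export
anosim_test <- function(x, grouping, n_perm = 999L, seed = 1L) {
  d <- if (inherits(x, "dist")) x else stats::dist(x, method = "euclidean")
  n <- attr(d, "Size")
  g <- as.factor(grouping)
  if (length(g) != n) stop("grouping length must match observations")
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  unreliable <- any(table(g) < 2L)
  if (unreliable) warning("singleton group: permutation p unreliable")
  r <- rank(as.vector(d))
  denom <- n * (n - 1) / 4
  lower <- lower.tri(matrix(0, n, n))
  same_of <- function(gg) outer(gg, gg, "==")[lower]
  stat <- function(same) (mean(r[!same]) - mean(r[same])) / denom
  obs <- stat(same_of(g))
  exceed <- 0L
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      if (stat(same_of(sample(g))) >= obs) exceed <- exceed + 1L
    }
  })
  structure(list(R = obs, p = (exceed + 1) / (n_perm + 1), n_perm = n_perm,
                 grouping = g, metric = "euclidean",
                 unreliable = unreliable),
            class = "anosim_result")
}

# Laplace-approximate marginal log-likelihood of a phylogenetic logistic
# GLMM at given estimates (used for the reported AIC).
pglmm_laplace_ll <- function(y, X, beta, s2, C) {
  eta_fix <- drop(X %*% beta)
  if (s2 < 1e-8) {
    p <- stats::plogis(eta_fix)
    return(sum(y * log(p) + (1 - y) * log1p(-p)))
  }
  Sigma <- s2 * C
  Sinv <- solve(Sigma)
  u <- rep(0, length(y))
  for (it in 1:100) {
    eta <- eta_fix + u
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    grad <- (y - p) - drop(Sinv %*% u)
    H <- diag(w) + Sinv
    u_new <- u + drop(solve(H, grad))
    if (max(abs(u_new - u)) < 1e-8) { u <- u_new; break }
    u <- u_new
  }
  eta <- eta_fix + u
  p <- stats::plogis(eta)
  w <- pmax(p * (1 - p), 1e-10)
  ll_cond <- sum(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
  ll_cond - 0.5 * drop(t(u) %*% Sinv %*% u) -
    0.5 * determinant(diag(length(y)) + Sigma %*% diag(w),
                      logarithm = TRUE)$modulus
}

# Laplace maximum likelihood for the binary phylogenetic GLMM: optimize
# (beta, log s2) of the marginal likelihood approximated by pglmm_laplace_ll.
laplace_ml_fit <- function(y, X, C) {
  nll <- function(par) {
    -pglmm_laplace_ll(y, X, par[seq_len(ncol(X))], exp(par[ncol(X) + 1L]), C)
  }
  p0 <- c(rep(0, ncol(X)), log(0.3))
  fit <- stats::nlminb(p0, nll,
                       lower = c(rep(-30, ncol(X)), log(1e-6)),
                       upper = c(rep(30, ncol(X)), log(100)))
  list(ll = -fit$objective, par = fit$par, converged = fit$convergence == 0,
       nll = nll)
}

#' Phylogenetic logistic regression of a binary trait
#'
#' Regresses a binary response (ecotype) on a continuous predictor (e.g.
#' intact-gene count) while accounting for phylogenetic dependence among
#' species, in the Ives-Garland binary-trait framework: a logistic model
#' whose latent liability carries a Brownian phylogenetic random effect with
#' signal variance `s2`, estimated jointly with the coefficients by Laplace
#' maximum likelihood. The slope test is a likelihood-ratio test against the
#' intercept-only model referred to an F(1, n - 3) distribution (a
#' small-sample correction; the chi-square reference is anti-conservative at
#' phylogeny-scale n). On a star phylogeny the fit reduces to ordinary
#' logistic regression. Complete separation triggers a ridge-penalized
#' non-phylogenetic fallback with a flag.
#'
#' @param tree [ape::phylo] whose tips match the data names.
#' @param response Named 0/1 vector per species.
#' @param predictor Named numeric vector per species.
#' @return A `phylo_glm` list: `coef` (intercept, slope), `se` (from the
#'   numerical Hessian), `p` (slope LRT p-value), `lrt_stat`, `s2`
#'   (phylogenetic signal variance), `aic`, `converged`, `separation`.
#' @export
phylo_logistic_regression <- function(tree, response, predictor) {
  sp <- tree$tip.label
  if (!all(sp %in% names(response)) || !all(sp %in% names(predictor))) {
    stop("response/predictor must be named by the tree's tip labels")
  }
  y <- as.numeric(response[sp])
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  if (length(unique(y)) < 2L) stop("constant response")
  x <- as.numeric(predictor[sp])
  n <- length(y)
  # screen for complete separation with an ordinary logistic fit
  glm0 <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  separated <- all(abs(stats::fitted(glm0) - y) < 1e-6)
  if (separated) {
    fit <- ridge_logistic(y, x, lambda = 1)
    return(structure(list(coef = fit$coef, se = fit$se, p = fit$p[2],
                          lrt_stat = NA_real_, s2 = NA_real_, aic = fit$aic,
                          converged = TRUE, separation = TRUE),
                     class = "phylo_glm"))
  }
  C <- ape::vcv(tree, corr = FALSE)
  C <- C / mean(diag(C))
  C <- C[sp, sp]
  X <- cbind("(Intercept)" = 1, x = x)
  full <- laplace_ml_fit(y, X, C)
  null <- laplace_ml_fit(y, X[, 1, drop = FALSE], C)
  stat <- max(0, 2 * (full$ll - null$ll))
  p_slope <- stats::pf(stat, 1, max(n - 3, 1), lower.tail = FALSE)
  hess <- tryCatch(stats::optimHess(full$par, full$nll), error = function(e) NULL)
  se <- rep(NA_real_, 2)
  if (!is.null(hess)) {
    vc <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vc) && all(diag(vc)[1:2] > 0)) se <- sqrt(diag(vc)[1:2])
  }
  coef <- stats::setNames(full$par[1:2], colnames(X))
  np <- 3L
  structure(list(coef = coef, se = se, p = p_slope, lrt_stat = stat,
                 s2 = exp(full$par[3]), aic = -2 * full$ll + 2 * np,
                 converged = full$converged && null$converged,
                 separation = FALSE), class = "phylo_glm")
}

# Weak-ridge logistic fallback for separated data: slope test is an LRT of
# the unpenalized log-likelihood at the ridge estimates against the
# intercept-only model, on the same small-sample F reference as the main fit.
ridge_logistic <- function(y, x, lambda = 0.5) {
  n <- length(y)
  fit_one <- function(X) {
    nll <- function(b) {
      eta <- drop(X %*% b)
      sum(log1p(exp(eta))) - sum(y * eta) + lambda / 2 * sum(b[-1]^2)
    }
    opt <- stats::optim(rep(0, ncol(X)), nll, method = "BFGS", hessian = TRUE)
    eta <- drop(X %*% opt$par)
    list(opt = opt, ll = sum(y * eta) - sum(log1p(exp(eta))))
  }
  X <- cbind(1, scale(x))
  full <- fit_one(X)
  null <- fit_one(X[, 1, drop = FALSE])
  stat <- max(0, 2 * (full$ll - null$ll))
  p_slope <- stats::pf(stat, 1, max(n - 3, 1), lower.tail = FALSE)
  se <- sqrt(diag(solve(full$opt$hessian)))
  # back-transform the slope to the predictor's original scale
  sdx <- stats::sd(x)
  coef <- c(full$opt$par[1] - full$opt$par[2] * mean(x) / sdx,
            full$opt$par[2] / sdx)
  list(coef = stats::setNames(coef, c("(Intercept)", "x")),
       se = se / c(1, sdx), p = c(NA_real_, p_slope), lrt_stat = stat,
       aic = 2 * full$opt$value + 2 * 2)
}
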