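# Maximum-likelihood fitting of GY94 site models (M0, M1a, M2a, M7, M8, M8a)
# and branch-site model A, likelihood-ratio tests, and empirical-Bayes
# identification of positively selected sites. Branch lengths are by default
# estimated under M0 and fixed for the mixture models (standard practice);
# the optimizer is bounded quasi-Newton (nlminb) with random restarts.

beta_bin_means <- function(p, q, K = 10L) {
  # Means of K equal-probability bins of Beta(p, q).
  edges <- stats::qbeta(seq(0, 1, length.out = K + 1), p, q)
  cum <- stats::pbeta(edges, p + 1, q) * p / (p + q)
  m <- diff(cum) * K
  pmin(pmax(m, 1e-8), 1 - 1e-8)
}

# Model definitions: free-parameter layout after kappa, and the map from a
# parameter vector to site classes. Proportion pairs use the (sum, ratio)
# parameterization so boxes stay rectangular.
site_model_def <- function(model, K = 10L) {
  switch(model,
    M0 = list(init = c(omega = 0.5), lower = 1e-4, upper = 20,
              classes = function(p) list(list(prop = 1, omega = p[["omega"]]))),
    M1a = list(init = c(p0 = 0.7, omega0 = 0.2),
               lower = c(1e-4, 1e-4), upper = c(1 - 1e-4, 1 - 1e-4),
               classes = function(p) list(
                 list(prop = p[["p0"]], omega = p[["omega0"]]),
                 list(prop = 1 - p[["p0"]], omega = 1))),
    M2a = list(init = c(q0 = 0.7, q1 = 0.8, omega0 = 0.2, omega2 = 2.5),
               lower = c(1e-4, 1e-4, 1e-4, 1), upper = c(1 - 1e-4, 1 - 1e-4, 1 - 1e-4, 30),
               classes = function(p) {
                 p0 <- p[["q0"]]; p1 <- (1 - p0) * p[["q1"]]
                 list(list(prop = p0, omega = p[["omega0"]]),
                      list(prop = p1, omega = 1),
                      list(prop = 1 - p0 - p1, omega = p[["omega2"]]))
               }),
    M7 = list(init = c(p = 0.5, q = 1.5), lower = c(0.005, 0.005),
              upper = c(99, 99),
              classes = function(p) {
                w <- beta_bin_means(p[["p"]], p[["q"]], K)
                lapply(w, function(x) list(prop = 1 / K, omega = x))
              }),
    M8 = list(init = c(p0 = 0.9, p = 0.5, q = 1.5, omega_s = 2),
              lower = c(1e-4, 0.005, 0.005, 1), upper = c(1 - 1e-4, 99, 99, 30),
              classes = function(p) {
                w <- beta_bin_means(p[["p"]], p[["q"]], K)
                c(lapply(w, function(x) list(prop = p[["p0"]] / K, omega = x)),
                  list(list(prop = 1 - p[["p0"]], omega = p[["omega_s"]])))
              }),
    M8a = list(init = c(p0 = 0.9, p = 0.5, q = 1.5),
               lower = c(1e-4, 0.005, 0.005), upper = c(1 - 1e-4, 99, 99),
               classes = function(p) {
                 w <- beta_bin_means(p[["p"]], p[["q"]], K)
                 c(lapply(w, function(x) list(prop = p[["p0"]] / K, omega = x)),
                   list(list(prop = 1 - p[["p0"]], omega = 1)))
               }),
    stop("unknown site model: ", model)
  )
}

fit_objective <- function(par_names, def, plan, pat, freqs, lengths, fg = NULL,
                          fixed_blen = TRUE) {
  nedge <- nrow(plan$edge)
  function(x) {
    kappa <- exp(x[1])
    mp <- x[seq_along(def$init) + 1]
    names(mp) <- names(def$init)
    classes <- def$classes(mp)
    len <- if (fixed_blen) lengths else exp(x[length(def$init) + 1 + seq_len(nedge)])
    ll <- try(class_site_logliks(plan, pat$states, kappa, classes, freqs,
                                 lengths = len, fg = fg), silent = TRUE)
    if (inherits(ll, "try-error") || any(!is.finite(ll))) return(1e10)
    props <- vapply(classes, `[[`, numeric(1), "prop")
    -mixture_loglik(props, ll, pat$weights)
  }
}

run_restarts <- function(obj, x0, lower, upper, starts, seed) {
  best <- NULL
  set.seed(seed)
  for (s in seq_len(max(1L, starts))) {
    x <- if (s == 1L) x0 else pmin(pmax(x0 + stats::rnorm(length(x0), 0, 0.5),
                                        lower + 1e-6), upper - 1e-6)
    fit <- try(stats::nlminb(x, obj, lower = lower, upper = upper,
                             control = list(rel.tol = 1e-8, iter.max = 500)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stop("optimizer failed in all starts")
  best
}

#' Fit a GY94 site model to a codon alignment
#'
#' Fits one of the standard site models by maximum likelihood using the
#' pruning algorithm over compressed site patterns. For mixture models the
#' branch lengths are first estimated under M0 and then held fixed (pass
#' `lengths` to override); for `model = "M0"` branch lengths are estimated
#' jointly with `kappa` and `omega` unless `fix_blen = TRUE`.
#'
#' @param seqs Named character vector: aligned coding sequences.
#' @param tree Tree ([ape::phylo]) with branch lengths covering all taxa.
#' @param model One of `"M0"`, `"M1a"`, `"M2a"`, `"M7"`, `"M8"`, `"M8a"`.
#' @param freqs Codon frequency vector, or a model name for
#'   [codon_frequencies()] (default `"F3X4"`).
#' @param starts Number of optimizer starts (first start is deterministic).
#' @param seed Seed for the random restarts.
#' @param lengths Optional fixed branch lengths (postorder edge order).
#' @param fix_blen For M0: keep the tree's branch lengths fixed.
#' @param K Number of beta discretization classes for M7/M8/M8a.
#' @return A `codon_fit` object: list with `model`, `lnL`, `np`, `kappa`,
#'   `params`, `classes` (proportions and omegas), `lengths`, `convergence`,
#'   and cached pattern/site-likelihood structures.
#' @export
fit_site_model <- function(seqs, tree, model = "M0", freqs = "F3X4",
                           starts = 3L, seed = 1L, lengths = NULL,
                           fix_blen = FALSE, K = 10L) {
  pat <- codon_patterns(seqs)
  plan <- tree_plan(tree, pat$labels)
  if (is.character(freqs)) freqs <- codon_frequencies(seqs, freqs)
  def <- site_model_def(model, K)
  nedge <- nrow(plan$edge)
  est_blen <- model == "M0" && !fix_blen && is.null(lengths)
  if (is.null(lengths)) {
    if (model != "M0" && !fix_blen) {
      m0 <- fit_site_model(seqs, tree, "M0", freqs = freqs, starts = 1L,
                           seed = seed)
      lengths <- m0$lengths
    } else lengths <- plan$len
  }
  x0 <- c(log(2), unname(def$init))
  lower <- c(log(0.05), def$lower)
  upper <- c(log(50), def$upper)
  if (est_blen) {
    x0 <- c(x0, log(pmax(plan$len, 1e-3)))
    lower <- c(lower, rep(log(1e-5), nedge))
    upper <- c(upper, rep(log(20), nedge))
  }
  obj <- fit_objective(names(def$init), def, plan, pat, freqs, lengths,
                       fixed_blen = !est_blen)
  best <- run_restarts(obj, x0, lower, upper, starts, seed)
  mp <- best$par[seq_along(def$init) + 1]
  names(mp) <- names(def$init)
  classes <- def$classes(mp)
  len_hat <- if (est_blen) exp(best$par[length(def$init) + 1 + seq_len(nedge)]) else lengths
  kappa <- exp(best$par[1])
  site_ll <- class_site_logliks(plan, pat$states, kappa, classes, freqs,
                                lengths = len_hat)
  structure(list(
    model = model, lnL = -best$objective,
    np = nedge + 1L + length(def$init),
    kappa = kappa, params = mp,
    classes = list(props = vapply(classes, `[[`, numeric(1), "prop"),
                   omegas = vapply(classes, `[[`, numeric(1), "omega")),
    lengths = len_hat, freqs = freqs, convergence = best$convergence == 0,
    site_ll = site_ll, patterns = pat, plan = plan, foreground = NULL
  ), class = "codon_fit")
}

# Branch-site model A class layout given (q0, q1, omega0, omega2):
# p0 = q0*q1-share etc.; classes 2a/2b split the remainder in p0:p1 ratio.
bs_classes <- function(q0, q1, omega0, omega2) {
  p0 <- q0 * q1
  p1 <- q0 * (1 - q1)
  p2a <- (1 - q0) * q1
  p2b <- (1 - q0) * (1 - q1)
  list(list(prop = p0, omega = omega0, omega_fg = omega0),
       list(prop = p1, omega = 1, omega_fg = 1),
       list(prop = p2a, omega = omega0, omega_fg = omega2),
       list(prop = p2b, omega = 1, omega_fg = omega2))
}

# Map foreground labels (tip or internal-node labels) to postorder edge flags.
foreground_edges <- function(plan, foreground) {
  tree <- plan$tree
  labels <- c(tree$tip.label,
              if (is.null(tree$node.label)) rep(NA_character_, tree$Nnode)
              else tree$node.label)
  nodes <- match(foreground, labels)
  if (anyNA(nodes)) stop("unknown foreground branch label(s): ",
                         paste(foreground[is.na(nodes)], collapse = ", "))
  fg <- plan$edge[, 2] %in% nodes
  if (!any(fg)) stop("no foreground branches resolved")
  if (all(fg)) stop("foreground cannot include every branch")
  fg
}

#' Fit branch-site model A (or its null)
#'
#' Model A has four site classes (0, 1, 2a, 2b); on the designated foreground
#' branches classes 2a/2b take `omega2 >= 1`, which the null model fixes at 1.
#' The alternative starts `omega2` at 1.5. Branch lengths are estimated under
#' M0 and fixed unless supplied.
#'
#' @inheritParams fit_site_model
#' @param foreground Character vector of tip/internal-node labels; the edges
#'   leading to them are the foreground set.
#' @param null Fit the null model (`omega2 = 1`)?
#' @return A `codon_fit` object (model `"bsA"` or `"bsA_null"`).
#' @export
fit_branch_site <- function(seqs, tree, foreground, null = FALSE,
                            freqs = "F3X4", starts = 3L, seed = 1L,
                            lengths = NULL) {
  pat <- codon_patterns(seqs)
  plan <- tree_plan(tree, pat$labels)
  if (is.character(freqs)) freqs <- codon_frequencies(seqs, freqs)
  fg <- foreground_edges(plan, foreground)
  if (is.null(lengths)) {
    m0 <- fit_site_model(seqs, tree, "M0", freqs = freqs, starts = 1L,
                         seed = seed)
    lengths <- m0$lengths
  }
  nm <- c("q0", "q1", "omega0", if (!null) "omega2")
  x0 <- c(log(2), 0.8, 0.8, 0.2, if (!null) 1.5)
  lower <- c(log(0.05), 1e-4, 1e-4, 1e-4, if (!null) 1)
  upper <- c(log(50), 1 - 1e-4, 1 - 1e-4, 1 - 1e-4, if (!null) 30)
  objfun <- function(x) {
    kappa <- exp(x[1])
    omega2 <- if (null) 1 else x[5]
    classes <- bs_classes(x[2], x[3], x[4], omega2)
    ll <- try(class_site_logliks(plan, pat$states, kappa, classes, freqs,
                                 lengths = lengths, fg = fg), silent = TRUE)
    if (inherits(ll, "try-error") || any(!is.finite(ll))) return(1e10)
    -mixture_loglik(vapply(classes, `[[`, numeric(1), "prop"), ll, pat$weights)
  }
  best <- run_restarts(objfun, x0, lower, upper, starts, seed)
  omega2 <- if (null) 1 else best$par[5]
  classes <- bs_classes(best$par[2], best$par[3], best$par[4], omega2)
  kappa <- exp(best$par[1])
  site_ll <- class_site_logliks(plan, pat$states, kappa, classes, freqs,
                                lengths = lengths, fg = fg)
  params <- best$par[-1]
  names(params) <- nm
  structure(list(
    model = if (null) "bsA_null" else "bsA", lnL = -best$objective,
    np = nrow(plan$edge) + 1L + length(nm),
    kappa = kappa, params = params,
    classes = list(props = vapply(classes, `[[`, numeric(1), "prop"),
                   omegas = vapply(classes, `[[`, numeric(1), "omega"),
                   omegas_fg = vapply(classes, function(c)
                     if (is.null(c$omega_fg)) c$omega else c$omega_fg,
                     numeric(1))),
    lengths = lengths, freqs = freqs, convergence = best$convergence == 0,
    site_ll = site_ll, patterns = pat, plan = plan, foreground = foreground
  ), class = "codon_fit")
}

#' Likelihood-ratio test between nested codon models
#'
#' @param lnl_alt,lnl_null Log-likelihoods of the alternative and null fits
#'   (numbers or `codon_fit` objects).
#' @param df Degrees of freedom (difference in free parameters).
#' @param tol Negative statistics larger than `-tol` are clamped to 0.
#' @return List with `stat` (2 delta lnL), `df`, `p`.
#' @export
likelihood_ratio_test <- function(lnl_alt, lnl_null, df, tol = 1e-6) {
  if (inherits(lnl_alt, "codon_fit")) lnl_alt <- lnl_alt$lnL
  if (inherits(lnl_null, "codon_fit")) lnl_null <- lnl_null$lnL
  if (df < 1) stop("df must be >= 1")
  stat <- 2 * (lnl_alt - lnl_null)
  if (stat < -tol) warning("negative LRT statistic: models may not be nested")
  stat <- max(stat, 0)
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Index (or indices) of the positive-selection class(es) of a fit.
positive_class_idx <- function(fit) {
  switch(fit$model,
    M2a = 3L,
    M8 = length(fit$classes$props),
    bsA = 3:4,
    stop("model ", fit$model, " has no positive-selection class")
  )
}

#' Posterior probabilities of the positive-selection site class
#'
#' NEB evaluates class posteriors at the maximum-likelihood estimates. BEB
#' averages the posteriors over a uniform 10-point grid per free mixing
#' parameter (class omegas held at their MLEs), weighting each grid point by
#' its marginal likelihood.
#'
#' @param fit A `codon_fit` from [fit_site_model()] (M2a/M8) or
#'   [fit_branch_site()] (alternative model).
#' @param method `"NEB"` or `"BEB"`.
#' @return Data frame with one row per codon site: `site`, `posterior`
#'   (positive class), and `flag` (posterior > 0.95).
#' @export
posterior_site_classes <- function(fit, method = c("NEB", "BEB")) {
  method <- match.arg(method)
  pos <- positive_class_idx(fit)
  site_ll <- fit$site_ll
  w <- fit$patterns$weights
  if (method == "NEB") {
    props <- fit$classes$props
    post <- neb_posterior(props, site_ll)
  } else {
    grid1 <- seq(0.05, 0.95, by = 0.1)
    if (fit$model == "M8") {
      grids <- lapply(grid1, function(p0) {
        p <- c(rep(p0 / 10, 10), 1 - p0)
      })
    } else {  # M2a and bsA share the (q0, q1) mixing parameterization
      grids <- list()
      for (a in grid1) for (b in grid1) {
        grids[[length(grids) + 1L]] <-
          if (fit$model == "M2a") c(a, (1 - a) * b, (1 - a) * (1 - b))
          else c(a * b, a * (1 - b), (1 - a) * b, (1 - a) * (1 - b))
      }
    }
    logw <- vapply(grids, function(props) {
      mixture_loglik(props, site_ll, w)
    }, numeric(1))
    wg <- exp(logw - max(logw))
    wg <- wg / sum(wg)
    post <- 0
    for (g in seq_along(grids)) {
      post <- post + wg[g] * neb_posterior(grids[[g]], site_ll)
    }
  }
  ppos <- colSums(post[pos, , drop = FALSE])
  ppos <- ppos[fit$patterns$index]
  data.frame(site = seq_along(ppos), posterior = ppos, flag = ppos > 0.95)
}

neb_posterior <- function(props, site_ll) {
  m <- apply(site_ll, 2, max)
  num <- props * exp(sweep(site_ll, 2, m))
  sweep(num, 2, colSums(num), "/")
}

#' Compare per-category conservation between gene sets
#'
#' Given conservation profiles (from [column_information()]) for two or more
#' gene sets over a shared column coordinate system, summarizes mean
#' information content per site category per set and rank-sum tests the
#' per-column IC of the first set against each other set within category.
#'
#' @param profiles Named list of conservation-profile data frames.
#' @param categories Optional character vector of per-column category labels
#'   applied to all profiles (overrides any `category` column).
#' @return List with `summary` (set x category mean IC) and `tests`
#'   (data frame of pairwise rank-sum p-values vs the first set).
#' @export
compare_site_variability <- function(profiles, categories = NULL) {
  if (is.null(names(profiles))) names(profiles) <- paste0("set", seq_along(profiles))
  profiles <- lapply(profiles, function(p) {
    if (!is.null(categories)) {
      if (length(categories) != nrow(p)) stop("category length mismatch")
      p$category <- categories
    }
    if (is.null(p$category)) stop("no site categories supplied")
    p
  })
  cats <- unique(unlist(lapply(profiles, function(p) p$category)))
  summ <- sapply(cats, function(cc) {
    vapply(profiles, function(p) mean(p$ic[p$category == cc], na.rm = TRUE),
           numeric(1))
  })
  summ <- matrix(summ, nrow = length(profiles),
                 dimnames = list(names(profiles), cats))
  tests <- NULL
  ref <- profiles[[1]]
  for (other in names(profiles)[-1]) {
    for (cc in cats) {
      a <- ref$ic[ref$category == cc]
      b <- profiles[[other]]$ic[profiles[[other]]$category == cc]
      if (!length(a) || !length(b)) next
      p <- if (length(unique(c(a, b))) == 1L) 1
        else stats::wilcox.test(a, b, exact = FALSE)$p.value
      tests <- rbind(tests, data.frame(set = other, category = cc,
                                       mean_ref = mean(a), mean_other = mean(b),
                                       p = p))
    }
  }
  list(summary = summ, tests = tests)
}
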