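# DuMouchel multi-item gamma-Poisson shrinker: empirical-Bayes prior fit and
# per-table EBGM / EB05.
#
# Model: the observed count a for a table with independence expectation E is
# Poisson(lambda * E) with lambda drawn from a two-component gamma mixture
# prior  w * Gamma(alpha1, beta1) + (1-w) * Gamma(alpha2, beta2)  (shape/rate).
# Marginally a is a mixture of negative binomials; the prior is fitted by
# maximizing the marginal likelihood over all tables at one level.

mgps_transform <- function(p) {
  c(log(p[1:4]), stats::qlogis(p[5]))
}

mgps_untransform <- function(th) {
  c(exp(th[1:4]), stats::plogis(th[5]))
}

# log marginal density of each count under the NB mixture
mgps_logmarg <- function(a, E, p) {
  l1 <- log(p[5]) + stats::dnbinom(a, size = p[1],
                                   prob = p[2] / (p[2] + E), log = TRUE)
  l2 <- log1p(-p[5]) + stats::dnbinom(a, size = p[3],
                                      prob = p[4] / (p[4] + E), log = TRUE)
  m <- pmax(l1, l2)
  list(logmix = m + log(exp(l1 - m) + exp(l2 - m)), l1 = l1, l2 = l2)
}

# fixed (non-random) multi-start set: DuMouchel's published start first
.MGPS_STARTS <- list(
  c(0.2, 0.1, 2, 4, 1 / 3),
  c(0.5, 0.5, 1, 1, 0.5),
  c(1, 2, 3, 1, 0.2),
  c(0.1, 0.05, 4, 8, 0.4),
  c(2, 4, 0.2, 0.1, 2 / 3)
)

#' Fit the MGPS two-gamma mixture prior
#'
#' Maximizes the summed log marginal likelihood of the observed counts (a
#' mixture of negative binomials) over the five hyperparameters
#' (alpha1, beta1, alpha2, beta2, w). Positivity and the unit-interval weight are
#' enforced by a log / logit transform; optimization is Nelder-Mead from
#' DuMouchel's published start plus four fixed alternates, so the fit is
#' deterministic and uses no random numbers. At least ten distinct tables are
#' recommended; fewer produce a warning.
#'
#' @param a observed counts, one per contingency table.
#' @param E independence expectations `(a+b)(a+c)/N`, same length.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param reltol convergence tolerance on the objective.
#' @return an `mgps_prior`: list with `alpha1`, `beta1`, `alpha2`, `beta2`,
#'   `w`, `loglik`, `n_cells` and a `convergence` data.table (one row per
#'   start).
#' @export
fit_mgps_prior <- function(a, E, maxit = 2000L, reltol = 1e-10) {
  stopifnot(length(a) == length(E))
  keep <- is.finite(a) & is.finite(E) & E > 0
  a <- a[keep]; E <- E[keep]
  if (length(a) == 0L || all(a == 0)) {
    fs_error("degenerate data for MGPS prior fit: no cells with positive counts",
             "mgps_fit_error")
  }
  if (length(a) < 10L) {
    warning("fewer than 10 tables for the MGPS prior fit; ",
            "hyperparameter estimates may be unstable")
  }
  nll <- function(th) {
    p <- mgps_untransform(th)
    v <- -sum(mgps_logmarg(a, E, p)$logmix)
    if (!is.finite(v)) v <- .Machine$double.xmax / 2
    v
  }
  fits <- lapply(.MGPS_STARTS, function(s) {
    stats::optim(mgps_transform(s), nll, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = reltol))
  })
  conv <- data.table::data.table(
    start = seq_along(fits),
    value = vapply(fits, `[[`, numeric(1), "value"),
    converged = vapply(fits, function(f) f$convergence == 0L, logical(1)))
  best <- fits[[which.min(conv$value)]]
  # polish: restart Nelder-Mead from the incumbent until it reports
  # convergence (restarting rebuilds the simplex, escaping premature stops)
  polish <- 0L
  while (best$convergence != 0L && polish < 5L) {
    best <- stats::optim(best$par, nll, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = reltol))
    polish <- polish + 1L
  }
  if (best$convergence != 0L) {
    fs_error(paste0("MGPS prior fit did not converge; objective trace: ",
                    paste(sprintf("start %d: %.6g (converged: %s)", conv$start,
                                  conv$value, conv$converged),
                          collapse = "; ")),
             "mgps_fit_error")
  }
  p <- mgps_untransform(best$par)
  structure(list(alpha1 = p[1], beta1 = p[2], alpha2 = p[3], beta2 = p[4],
                 w = p[5], loglik = -best$value, n_cells = length(a),
                 convergence = conv),
            class = "mgps_prior")
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat(sprintf(paste0("<mgps_prior> w=%.3f  Gamma(%.3g, %.3g) / Gamma(%.3g, %.3g)",
                     "  loglik=%.3f on %d cells\n"),
              x$w, x$alpha1, x$beta1, x$alpha2, x$beta2, x$loglik, x$n_cells))
  invisible(x)
}

#' Empirical-Bayes geometric mean and its lower 5th percentile
#'
#' Under the fitted prior the posterior of the relative reporting ratio lambda
#' is again a two-component gamma mixture, components
#' `Gamma(alpha1 + a, beta1 + E)` and `Gamma(alpha2 + a, beta2 + E)` with the
#' mixture weight updated by the marginal likelihoods.
#' `EBGM = 2^(E[log2 lambda])` uses the digamma closed form;
#' `EB05` is the posterior 5th percentile found by root-finding on the mixture
#' CDF (Brent, tolerance 1e-10, bracket `[1e-12, max(10*EBGM, 10)]` expanded
#' geometrically if needed). Tables with `E <= 0` are non-evaluable (`NA`).
#'
#' @param a observed counts.
#' @param E independence expectations.
#' @param prior an `mgps_prior` from [fit_mgps_prior()].
#' @return data.table with `ebgm`, `eb05`.
#' @export
ebgm_stat <- function(a, E, prior) {
  stopifnot(inherits(prior, "mgps_prior"))
  p <- c(prior$alpha1, prior$beta1, prior$alpha2, prior$beta2, prior$w)
  ok <- is.finite(a) & is.finite(E) & E > 0
  ebgm <- eb05 <- rep(NA_real_, length(a))
  if (!any(ok)) return(data.table::data.table(ebgm = ebgm, eb05 = eb05))
  lm <- mgps_logmarg(a[ok], E[ok], p)
  qn <- 1 / (1 + exp(lm$l2 - lm$l1)) # posterior weight of component 1
  s1 <- p[1] + a[ok]; r1 <- p[2] + E[ok]
  s2 <- p[3] + a[ok]; r2 <- p[4] + E[ok]
  eln <- qn * (digamma(s1) - log(r1)) + (1 - qn) * (digamma(s2) - log(r2))
  ebgm[ok] <- exp(eln)
  idx <- which(ok)
  for (k in seq_along(idx)) {
    cdf <- function(l) {
      qn[k] * stats::pgamma(l, shape = s1[k], rate = r1[k]) +
        (1 - qn[k]) * stats::pgamma(l, shape = s2[k], rate = r2[k])
    }
    up <- max(10 * ebgm[idx[k]], 10)
    while (cdf(up) < 0.05) up <- up * 10
    eb05[idx[k]] <- stats::uniroot(function(l) cdf(l) - 0.05,
                                   lower = 1e-12, upper = up,
                                   tol = 1e-10)$root
  }
  data.table::data.table(ebgm = ebgm, eb05 = eb05)
}
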