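# Four-parameter logistic (4PL) dose-response fitting for HTRF cAMP data.
#
# Model: y = bottom + (top - bottom) / (1 + (ec50/x)^hill), fitted by
# least squares with ec50 parameterized as log10(ec50) for stability.

#' HTRF emission ratio
#'
#' The kit-standard readout of an HTRF competition assay:
#' `ratio = em665 / em620 * 1e4`.
#'
#' @param em665 acceptor emission counts at 665 nm.
#' @param em620 donor emission counts at 620 nm (must be > 0).
#' @return numeric ratio(s).
#' @examples
#' htrf_ratio(330, 660)  # 5000
#' @export
htrf_ratio <- function(em665, em620) {
  if (any(em620 == 0)) stop("em620 must be non-zero", call. = FALSE)
  em665 / em620 * 1e4
}

#' 4PL parameter set
#'
#' @param bottom asymptotic response at zero dose.
#' @param top asymptotic response at saturating dose.
#' @param ec50 half-maximal effective concentration (same units as the
#'   doses, conventionally nM); must be > 0.
#' @param hill Hill slope (dimensionless; negative values describe
#'   descending curves equivalently to swapping top and bottom).
#' @return an object of class `fourpl_params`.
#' @export
fourpl_params <- function(bottom, top, ec50, hill = 1) {
  if (ec50 <= 0) stop("'ec50' must be > 0", call. = FALSE)
  structure(list(bottom = as.numeric(bottom), top = as.numeric(top),
                 ec50 = as.numeric(ec50), hill = as.numeric(hill)),
            class = "fourpl_params")
}

#' Evaluate the 4PL model
#'
#' @param x dose(s), > 0.
#' @param params a [fourpl_params()].
#' @return response(s) `bottom + (top - bottom)/(1 + (ec50/x)^hill)`.
#' @export
fourpl <- function(x, params) {
  with(params, bottom + (top - bottom) / (1 + (ec50 / x)^hill))
}

#' Simulate a dose-response curve
#'
#' Multiplicative Gaussian noise around the 4PL curve:
#' `response = 4PL(dose) * (1 + Normal(0, cv))`, per replicate.
#'
#' @param params a [fourpl_params()].
#' @param doses dose vector (> 0, conventionally nM).
#' @param cv coefficient of variation of the noise (>= 0).
#' @param n_replicates replicates per dose.
#' @param seed RNG seed (`NULL` = current stream).
#' @return data.frame with `concentration`, `replicate`, `response`.
#' @export
simulate_curve <- function(params, doses, cv = 0.05, n_replicates = 3L,
                           seed = NULL) {
  stopifnot(inherits(params, "fourpl_params"), all(doses > 0), cv >= 0)
  n_replicates <- stopifnot_scalar_int(n_replicates, "n_replicates", min = 1L)
  with_seed(seed, {
    d <- rep(doses, each = n_replicates)
    mu <- fourpl(d, params)
    data.frame(
      concentration = d,
      replicate = rep(seq_len(n_replicates), times = length(doses)),
      response = mu * (1 + rnorm(length(d), 0, cv))
    )
  })
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the 4PL model with EC50 parameterized on the
#' log10 scale, by Levenberg-Marquardt from multiple starts: bottom/top
#' seeded from the mean responses at the lowest and highest doses (both
#' orientations, so descending/inhibition curves fit without special
#' casing), log10(EC50) on a grid over the observed dose range, and Hill
#' slope in {0.5, 1, 2}. The best converged start by residual sum of
#' squares wins. log10(EC50) is bounded to the observed dose range
#' widened by 3 decades on each side.
#'
#' @param data data.frame with columns `concentration` (> 0, >= 5 distinct
#'   values) and `response`; a `replicate` column is allowed and ignored.
#' @param hill_starts Hill-slope starting values.
#' @param n_ec50_starts number of log10(EC50) grid starts.
#' @return an object of class `fit4pl`: list with `params`
#'   ([fourpl_params()]), `se` (named standard errors, EC50 by the delta
#'   method), `rss`, `converged`, `n`, `fitted_fun`.
#' @examples
#' truth <- fourpl_params(0, 100, ec50 = 10, hill = 1)
#' d <- simulate_curve(truth, 10^seq(-1, 3, length.out = 8), cv = 0, seed = 1)
#' fit_4pl(d)$params$ec50
#' @export
fit_4pl <- function(data, hill_starts = c(0.5, 1, 2), n_ec50_starts = 3L) {
  stopifnot(is.data.frame(data),
            all(c("concentration", "response") %in% names(data)))
  x <- data$concentration
  y <- data$response
  if (any(x <= 0)) stop("concentrations must be strictly positive", call. = FALSE)
  if (length(unique(x)) < 5L) {
    stop("need >= 5 distinct concentrations", call. = FALSE)
  }
  if (sd(y) == 0) stop("degenerate: responses are constant", call. = FALSE)

  lx <- log10(x)
  df <- data.frame(lx = lx, y = y)
  lo_mean <- mean(y[x == min(x)])
  hi_mean <- mean(y[x == max(x)])
  lec50_grid <- quantile(lx, probs = seq(0.2, 0.8, length.out = n_ec50_starts),
                         names = FALSE)
  lower <- c(bottom = -Inf, top = -Inf, lec50 = min(lx) - 3, hill = -50)
  upper <- c(bottom = Inf, top = Inf, lec50 = max(lx) + 3, hill = 50)

  best <- NULL
  for (orient in list(c(lo_mean, hi_mean), c(hi_mean, lo_mean))) {
    for (l0 in lec50_grid) {
      for (h0 in hill_starts) {
        fit <- tryCatch(
          minpack.lm::nlsLM(
            y ~ bottom + (top - bottom) / (1 + 10^(hill * (lec50 - lx))),
            data = df,
            start = list(bottom = orient[1], top = orient[2],
                         lec50 = l0, hill = h0),
            lower = lower, upper = upper,
            control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                                 ptol = 1e-14)
          ),
          error = function(e) NULL, warning = function(w) NULL
        )
        if (is.null(fit)) next
        rss <- sum(resid(fit)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
      }
    }
  }

  if (is.null(best)) {
    return(structure(list(params = NULL, se = NULL, rss = NA_real_,
                          converged = FALSE, n = length(y)),
                     class = "fit4pl"))
  }
  cf <- coef(best$fit)
  se <- tryCatch(sqrt(diag(vcov(best$fit))), error = function(e) {
    setNames(rep(NA_real_, 4), names(cf))
  })
  ec50 <- 10^cf[["lec50"]]
  se_out <- c(bottom = unname(se["bottom"]), top = unname(se["top"]),
              ec50 = unname(se["lec50"]) * log(10) * ec50,
              hill = unname(se["hill"]))
  params <- fourpl_params(cf[["bottom"]], cf[["top"]], ec50, cf[["hill"]])
  structure(list(
    params = params, se = se_out, rss = best$rss, converged = TRUE,
    n = length(y),
    fitted_fun = function(xx) fourpl(xx, params)
  ), class = "fit4pl")
}

#' @export
print.fit4pl <- function(x, ...) {
  if (!x$converged) {
    cat("4PL fit: did not converge\n")
    return(invisible(x))
  }
  p <- x$params
  cat(sprintf(
    "4PL fit (n=%d): EC50 = %.4g (SE %.3g), hill = %.3g, bottom = %.4g, top = %.4g, RSS = %.4g\n",
    x$n, p$ec50, x$se[["ec50"]], p$hill, p$bottom, p$top, x$rss))
  invisible(x)
}

#' Fit 4PL curves per group from a long-format table
#'
#' @param data data.frame with columns `group`, `concentration_nM` (or
#'   `concentration`), `response` (and optionally `replicate`).
#' @return named list of `fit4pl` objects, one per group.
#' @export
fit_4pl_by_group <- function(data) {
  if ("concentration_nM" %in% names(data) && !"concentration" %in% names(data)) {
    data$concentration <- data$concentration_nM
  }
  stopifnot("group" %in% names(data))
  lapply(split(data, data$group), fit_4pl)
}

#' EC50 recovery study
#'
#' Simulates `n_curves` noisy dose-response curves from a known 4PL truth
#' and refits each, returning the fitted EC50s. The default design is
#' 8 doses log-spaced over 4 decades centered on the generative EC50,
#' 3 replicates per dose, 5% multiplicative noise.
#'
#' @param ec50 generative EC50 (nM).
#' @param n_curves number of simulated curves.
#' @param bottom,top,hill remaining generative 4PL parameters.
#' @param cv noise coefficient of variation.
#' @param n_doses doses per curve.
#' @param decades total width of the dose range in log10 units.
#' @param n_replicates replicates per dose.
#' @param seed RNG seed for the whole study.
#' @return numeric vector of fitted EC50s (NA where a fit failed).
#' @export
ec50_recovery_study <- function(ec50, n_curves = 200L, bottom = 0, top = 100,
                                hill = 1, cv = 0.05, n_doses = 8L,
                                decades = 4, n_replicates = 3L, seed = 1L) {
  truth <- fourpl_params(bottom, top, ec50, hill)
  doses <- 10^seq(log10(ec50) - decades / 2, log10(ec50) + decades / 2,
                  length.out = n_doses)
  with_seed(seed, {
    vapply(seq_len(n_curves), function(i) {
      d <- simulate_curve(truth, doses, cv = cv, n_replicates = n_replicates,
                          seed = NULL)
      fit <- fit_4pl(d)
      if (fit$converged) fit$params$ec50 else NA_real_
    }, numeric(1))
  })
}
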