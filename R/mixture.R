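#' Poisson + Normal two-component mixture fit (bimodality model)
#'
#' Fits, by expectation-maximization, the mixture
#' \deqn{p(x) = \pi_1 Poisson(x | \lambda_1) + \pi_2 N(x | \mu_2, \sigma_2)}
#' used to detect bimodally expressed genes: a near-zero component (Poisson)
#' and a high-expression component (Normal, standing in for an NB). Values
#' are per-sample expression of one gene within one group, in RPM; the
#' Poisson density is evaluated at the rounded value as a continuous
#' extension of its discrete support.
#'
#' EM runs from two deterministic starts (responsibility split at the 25th
#' and 75th percentiles), two boundary starts (all mass on one component,
#' which guarantees the fit is at least as good as either single-component
#' model) and three seeded random starts; the best log-likelihood wins.
#' Updates are closed form; `sigma_2` is floored at `1e-3` to prevent
#' degeneracy, and the log-likelihood is non-decreasing across iterations.
#'
#' @param values Numeric vector (>= 6 values, non-negative expression).
#' @param lambda_max Upper bound on the Poisson mean `lambda_1` (default 1
#'   RPM): the Poisson component models the minimal-expression group, so its
#'   mean is constrained to the near-zero regime. Without the bound the
#'   mixture happily splits any overdispersed unimodal gene into two
#'   overlapping halves and calls it bimodal.
#' @param max_iter Maximum EM iterations per start.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param seed Seed for the random starts (local to this call).
#'
#' @return An object of class `pn_mixture`: `pi1`, `pi2`, `lambda1`, `mu2`,
#'   `sigma2`, `loglik`, `converged`, `n_iter`, `responsibilities`.
#' @seealso [is_bimodal()], [bimodal_fp_filter()]
#' @export
fit_poisson_normal_mixture <- function(values, lambda_max = 1, max_iter = 500,
                                       tol = 1e-8, seed = 1L) {
  if (length(values) < 6L) abort("at least 6 values are required.")
  if (any(!is.finite(values)) || any(values < 0)) {
    abort("`values` must be finite and non-negative.")
  }
  x <- as.numeric(values)
  xr <- round(x) # the Poisson component lives on the rounded values
  n <- length(x)
  sigma_floor <- 1e-3

  # all-equal data carry no mixture information: assign the single mode to
  # the minimal-expression (Poisson) component when it lies in that regime,
  # otherwise to the Normal component
  if (diff(range(x)) == 0) {
    poisson_mode <- mean(xr) <= lambda_max
    return(structure(
      list(pi1 = as.numeric(poisson_mode), pi2 = 1 - as.numeric(poisson_mode),
           lambda1 = if (poisson_mode) mean(xr) else 0,
           mu2 = mean(x), sigma2 = sigma_floor,
           loglik = if (poisson_mode) {
             sum(dpois(xr, pmax(mean(xr), 1e-12), log = TRUE))
           } else {
             sum(dnorm(x, mean(x), sigma_floor, log = TRUE))
           },
           converged = TRUE, n_iter = 0L,
           responsibilities = rep(as.numeric(poisson_mode), n), values = x),
      class = "pn_mixture"
    ))
  }

  run_em <- function(resp) {
    ll_old <- -Inf
    conv <- FALSE
    it <- 0L
    par <- NULL
    for (it in seq_len(max_iter)) {
      # M step
      w1 <- sum(resp)
      pi1 <- w1 / n
      lambda1 <- if (w1 > 1e-12) min(sum(resp * xr) / w1, lambda_max) else 0
      w2 <- n - w1
      if (w2 > 1e-12) {
        mu2 <- sum((1 - resp) * x) / w2
        sigma2 <- sqrt(sum((1 - resp) * (x - mu2)^2) / w2)
      } else {
        mu2 <- mean(x)
        sigma2 <- sigma_floor
      }
      sigma2 <- max(sigma2, sigma_floor)
      # E step
      d1 <- pi1 * dpois(xr, pmax(lambda1, 1e-12))
      d2 <- (1 - pi1) * dnorm(x, mu2, sigma2)
      tot <- d1 + d2
      tot[tot <= 0 | !is.finite(tot)] <- .Machine$double.xmin
      resp <- d1 / tot
      ll <- sum(log(tot))
      par <- list(pi1 = pi1, lambda1 = lambda1, mu2 = mu2, sigma2 = sigma2)
      if (is.finite(ll_old) && ll < ll_old - 1e-8) {
        # numerical guard; should not trigger for a correct EM
        break
      }
      if (is.finite(ll_old) && abs(ll - ll_old) / (abs(ll) + 1) < tol) {
        conv <- TRUE
        ll_old <- ll
        break
      }
      ll_old <- ll
    }
    c(par, list(loglik = ll_old, converged = conv, n_iter = it, resp = resp))
  }

  starts <- list()
  q25 <- quantile(x, 0.25, names = FALSE)
  q75 <- quantile(x, 0.75, names = FALSE)
  starts$split25 <- as.numeric(x <= q25)
  starts$split75 <- as.numeric(x <= q75)
  starts$all_poisson <- rep(1 - 1e-9, n)
  starts$all_normal <- rep(1e-9, n)
  withr::with_seed(seed, {
    for (r in seq_len(3)) starts[[paste0("random", r)]] <- runif(n)
  })

  fits <- purrr::map(starts, run_em)
  best <- fits[[which.max(purrr::map_dbl(fits, "loglik"))]]

  structure(
    list(pi1 = best$pi1, pi2 = 1 - best$pi1, lambda1 = best$lambda1,
         mu2 = best$mu2, sigma2 = best$sigma2, loglik = best$loglik,
         converged = best$converged, n_iter = best$n_iter,
         responsibilities = best$resp, values = x),
    class = "pn_mixture"
  )
}

#' @export
print.pn_mixture <- function(x, ...) {
  cat("<pn_mixture> pi1 * Poisson(lambda1) + pi2 * Normal(mu2, sigma2)\n")
  cat(sprintf("  pi1 = %.3f, lambda1 = %.3g | pi2 = %.3f, mu2 = %.3g, sigma2 = %.3g\n",
              x$pi1, x$lambda1, x$pi2, x$mu2, x$sigma2))
  cat(sprintf("  loglik = %.4g; converged: %s (%d iterations)\n",
              x$loglik, x$converged, x$n_iter))
  invisible(x)
}

#' @rdname fit_poisson_normal_mixture
#' @param x,object A `pn_mixture` fit.
#' @param ... Unused.
#' @export
tidy.pn_mixture <- function(x, ...) {
  tibble::tibble(
    component = c("poisson", "normal"),
    weight = c(x$pi1, x$pi2),
    mean = c(x$lambda1, x$mu2),
    sd = c(sqrt(x$lambda1), x$sigma2)
  )
}

#' @rdname fit_poisson_normal_mixture
#' @export
glance.pn_mixture <- function(x, ...) {
  tibble::tibble(log_lik = x$loglik, converged = x$converged,
                 n_iter = x$n_iter, nobs = length(x$values))
}

#' Histogram of values with fitted mixture components
#'
#' @param object A `pn_mixture` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pn_mixture <- function(object, ...) {
  x <- object$values
  grid <- seq(min(x), max(x), length.out = 400)
  dens <- tibble::tibble(
    x = rep(grid, 2),
    density = c(object$pi1 * dpois(round(grid), pmax(object$lambda1, 1e-12)),
                object$pi2 * dnorm(grid, object$mu2, object$sigma2)),
    component = rep(c("poisson", "normal"), each = length(grid))
  )
  ggplot2::ggplot(tibble::tibble(x = x), ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 30, fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density, colour = .data$component)) +
    ggplot2::labs(x = "expression (RPM)", y = "density") +
    ggplot2::theme_minimal()
}

#' Is a fitted mixture bimodal?
#'
#' A gene is called bimodal when the Poisson-component weight satisfies
#' `0.1 < pi1 < 0.9` (strict inequalities): a substantial share of samples in
#' each component. A non-converged fit is treated as not bimodal, with a
#' warning.
#'
#' @param fit A `pn_mixture` from [fit_poisson_normal_mixture()].
#' @return Logical scalar.
#' @export
is_bimodal <- function(fit) {
  stopifnot(inherits(fit, "pn_mixture"))
  if (!isTRUE(fit$converged)) {
    warn("mixture fit did not converge; treating as not bimodal.")
    return(FALSE)
  }
  fit$pi1 > 0.1 && fit$pi1 < 0.9
}
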