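#' Fit a continuous power law to degree data
#'
#' Maximum-likelihood fit of the tail model \eqn{P(k) \sim k^{-\alpha}} for
#' \eqn{k \ge x_{min}}, in the Clauset–Shalizi–Newman style: `xmin` is
#' chosen by minimising the Kolmogorov–Smirnov distance between the tail
#' data and the fitted law, and on the selected tail of size `n`
#' \deqn{\hat\alpha = 1 + n \Big/ \sum_i \ln(k_i / x_{min}),}
#' with the large-n 95% interval
#' \eqn{\hat\alpha \pm 1.96\,(\hat\alpha - 1)/\sqrt{n}}.
#'
#' The continuous estimator is the right one for weighted visibility-graph
#' degrees (strengths are real-valued); a discrete (zeta-normalised)
#' estimator for integer degrees is available with `discrete = TRUE`.
#'
#' @param x positive observations (e.g. pooled weighted degrees).
#' @param xmin optional fixed lower cut-off; when `NULL` (default) it is
#'   estimated by the KS scan.
#' @param discrete use the discrete MLE (numerically maximised zeta
#'   likelihood) instead of the continuous one.
#' @param max_xmin_candidates cap on the number of distinct candidate
#'   cut-offs scanned (quantile-thinned above this; default 250).
#' @return an object of class `vg_powerlaw` with fields `alpha`, `xmin`,
#'   `alpha_ci95`, `n_tail`, `n`, `ks_distance`, `discrete`, and the sorted
#'   data (for plotting). Has [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' set.seed(1)
#' fit <- fit_power_law(rpowerlaw(2000, alpha = 2.5, xmin = 1))
#' glance(fit)
#' @export
fit_power_law <- function(x, xmin = NULL, discrete = FALSE,
                          max_xmin_candidates = 250) {
  x <- x[is.finite(x)]
  if (length(x) < 2 || any(x <= 0)) {
    abort("need at least 2 positive finite observations",
          class = "vgfc_error_validation")
  }
  if (length(x) < 3) {
    abort("degenerate fit: cannot estimate a tail from 2 observations",
          class = "vgfc_error_degenerate")
  }
  if (length(unique(x)) == 1) {
    abort("degenerate fit: all observations identical",
          class = "vgfc_error_degenerate")
  }
  if (length(x) < 50) {
    warn("fewer than 50 observations; power-law fit will be unstable")
  }
  xs <- sort(x)
  if (is.null(xmin)) {
    cand <- unique(xs[-length(xs)])  # need >= 2 tail points
    if (length(cand) > max_xmin_candidates) {
      cand <- unique(stats::quantile(cand, probs = seq(0, 1,
                     length.out = max_xmin_candidates), names = FALSE,
                     type = 1))
    }
    best <- NULL
    for (xm in cand) {
      f <- pl_fit_at(xs, xm, discrete)
      if (is.null(best) || f$ks < best$ks) best <- f
    }
    fit <- best
  } else {
    check_scalar(xmin, "xmin", lower = 0, strict_lower = TRUE)
    fit <- pl_fit_at(xs, xmin, discrete)
  }
  if (fit$n < 2) {
    abort("degenerate fit: fewer than 2 tail observations",
          class = "vgfc_error_degenerate")
  }
  se <- (fit$alpha - 1) / sqrt(fit$n)
  structure(list(alpha = fit$alpha, xmin = fit$xmin,
                 alpha_ci95 = c(fit$alpha - 1.96 * se, fit$alpha + 1.96 * se),
                 n_tail = fit$n, n = length(xs), ks_distance = fit$ks,
                 discrete = discrete, data = xs),
            class = "vg_powerlaw")
}

# MLE + KS distance for a fixed cut-off on sorted data.
pl_fit_at <- function(xs, xm, discrete) {
  tail <- xs[xs >= xm]
  n <- length(tail)
  if (n < 2) return(list(alpha = NA_real_, xmin = xm, n = n, ks = Inf))
  if (discrete) {
    ll <- function(a) -n * log(pracma_zeta_trunc(a, xm)) - a * sum(log(tail))
    alpha <- stats::optimize(ll, c(1.01, 6), maximum = TRUE)$maximum
    kmax <- max(tail)
    ks_grid <- sort(unique(tail))
    z <- pracma_zeta_trunc(alpha, xm)
    pk <- vapply(ks_grid, function(k) sum((seq(xm, k))^(-alpha)) / z, numeric(1))
    emp <- vapply(ks_grid, function(k) mean(tail <= k), numeric(1))
    ks <- max(abs(emp - pk))
  } else {
    s <- sum(log(tail / xm))
    if (s <= 0) return(list(alpha = NA_real_, xmin = xm, n = n, ks = Inf))
    alpha <- 1 + n / s
    emp <- seq_len(n) / n
    theo <- 1 - (sort(tail) / xm)^(1 - alpha)
    # sup over both sides of each ECDF step
    ks <- max(pmax(abs(emp - theo), abs(c(0, emp[-n]) - theo)))
  }
  list(alpha = alpha, xmin = xm, n = n, ks = ks)
}

# Truncated Hurwitz-style normaliser sum_{k>=xmin} k^-a, summed to
# convergence (tolerance 1e-10).
pracma_zeta_trunc <- function(a, xmin) {
  k <- seq(ceiling(xmin), ceiling(xmin) + 1e5)
  sum(k^(-a))
}

#' Sample from a continuous power law
#'
#' Inverse-CDF sampler: \eqn{k = x_{min} u^{-1/(\alpha-1)}} with
#' \eqn{u \sim U(0,1)}. Used for parameter-recovery validation of
#' [fit_power_law()].
#'
#' @param n sample size.
#' @param alpha exponent (> 1).
#' @param xmin lower cut-off (> 0).
#' @return numeric vector of length `n`.
#' @export
rpowerlaw <- function(n, alpha, xmin = 1) {
  check_scalar(alpha, "alpha", lower = 1, strict_lower = TRUE)
  check_scalar(xmin, "xmin", lower = 0, strict_lower = TRUE)
  xmin * runif(n)^(-1 / (alpha - 1))
}

#' @export
print.vg_powerlaw <- function(x, ...) {
  cat(sprintf("<vg_powerlaw> alpha = %.3f [%.3f, %.3f], xmin = %.4g, tail n = %d / %d\n",
              x$alpha, x$alpha_ci95[1], x$alpha_ci95[2], x$xmin, x$n_tail, x$n))
  invisible(x)
}

#' @rdname fit_power_law
#' @param x a `vg_powerlaw` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.vg_powerlaw <- function(x, ...) {
  tibble(term = "alpha", estimate = x$alpha,
         conf.low = x$alpha_ci95[1], conf.high = x$alpha_ci95[2])
}

#' @rdname fit_power_law
#' @exportS3Method generics::glance
glance.vg_powerlaw <- function(x, ...) {
  tibble(alpha = x$alpha, xmin = x$xmin, n_tail = x$n_tail, n = x$n,
         ks_distance = x$ks_distance, discrete = x$discrete)
}

#' @rdname fit_power_law
#' @param object a `vg_powerlaw` object.
#' @exportS3Method ggplot2::autoplot
autoplot.vg_powerlaw <- function(object, ...) {
  dd <- degree_distribution_loglog(object$data)
  # density of the fitted tail, scaled by the fraction of data in the tail
  frac <- object$n_tail / object$n
  line <- dplyr::filter(dd, .data$k >= object$xmin) |>
    mutate(fit = frac * (object$alpha - 1) / object$xmin *
             (.data$k / object$xmin)^(-object$alpha))
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$k, y = .data$p)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, ggplot2::aes(y = .data$fit),
                       colour = "firebrick") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "P(k)",
                  title = sprintf("power-law fit: alpha = %.2f (xmin = %.3g)",
                                  object$alpha, object$xmin)) +
    ggplot2::theme_minimal()
}
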