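# One-dimensional Gaussian-mixture EM, initialised at PoDNano peak centres.
# Written in-package because the deconvolution contract pins the
# initialisation, the SD floor on degenerate components and the sorted-mean
# canonical order; mclust serves as an independent cross-check in the tests.

#' Fit a k-component Gaussian mixture by EM
#'
#' @param values Numeric vector (length >= 5k).
#' @param k Number of components (>= 1).
#' @param init Optional initial component means (e.g. PoDNano peak centres);
#'   defaults to evenly spaced quantiles.
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @param sd_floor Lower bound on component SDs; a component collapsing below
#'   it is refit at the floor with a warning.
#' @return Object of class `gmm_fit`: components tibble (`weight`, `mean`,
#'   `sd`, sorted by mean), log-likelihood, iteration count and data.
#' @examples
#' fit <- fit_gaussian_mixture(c(rnorm(100, 2), rnorm(100, 6)), k = 2)
#' tidy(fit)
#' @export
fit_gaussian_mixture <- function(values, k, init = NULL, max_iter = 500,
                                 tol = 1e-8, sd_floor = 0.05) {
  values <- sort(values[is.finite(values)])
  n <- length(values)
  if (k < 1) abort_config("`k` must be >= 1.")
  if (n < 5 * k) abort_data("Need at least 5 values per mixture component.")
  mu <- if (!is.null(init) && length(init) == k) sort(as.numeric(init)) else
    quantile(values, (seq_len(k) - 0.5) / k, names = FALSE)
  sig <- rep(max(sd(values) / max(k, 1), sd_floor), k)
  w <- rep(1 / k, k)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  floored <- FALSE
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(k), function(j) {
      log(w[j]) + dnorm(values, mu[j], sig[j], log = TRUE)
    }, numeric(n))
    logd <- matrix(logd, nrow = n)
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    resp <- exp(logd - lse)
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * values) / nk
    sig <- sqrt(colSums(resp * outer(values, mu, `-`)^2) / nk)
    if (any(sig < sd_floor)) {
      if (!floored) {
        warn("Degenerate mixture component; SD clamped to the floor.")
        floored <- TRUE
      }
      sig <- pmax(sig, sd_floor)
    }
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  ord <- order(mu)
  structure(
    list(components = tibble(weight = w[ord], mean = mu[ord], sd = sig[ord]),
         loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
         n = n, iters = length(ll_trace), data = values),
    class = "gmm_fit"
  )
}

#' Posterior component membership of a Gaussian mixture
#'
#' @param fit A `gmm_fit` object.
#' @param x Values at which to evaluate posteriors (default: the fitted data).
#' @return Matrix (length(x) by k) of posterior probabilities.
#' @export
gmm_posterior <- function(fit, x = fit$data) {
  co <- fit$components
  d <- vapply(seq_len(nrow(co)), function(j) {
    co$weight[j] * dnorm(x, co$mean[j], co$sd[j])
  }, numeric(length(x)))
  d <- matrix(d, nrow = length(x))
  sweep(d, 1, pmax(rowSums(d), .Machine$double.xmin), "/")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("<gmm_fit> k =", nrow(x$components), ", n =", x$n,
      ", logLik =", signif(x$loglik, 6), "\n")
  print(x$components)
  invisible(x)
}

#' @rdname fit_gaussian_mixture
#' @param x,object A `gmm_fit` object.
#' @param ... Unused.
#' @export
tidy.gmm_fit <- function(x, ...) {
  x$components |>
    dplyr::mutate(component = dplyr::row_number(), .before = 1)
}

#' @rdname fit_gaussian_mixture
#' @export
glance.gmm_fit <- function(x, ...) {
  tibble(k = nrow(x$components), n = x$n, loglik = x$loglik, iters = x$iters)
}
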