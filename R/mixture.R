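#' Deterministic two-component Gaussian mixture fit
#'
#' Fits a two-component univariate Gaussian mixture by
#' expectation-maximization with a deterministic, seed-free initialization:
#' component means start at the 25th and 75th percentiles of the data, both
#' standard deviations at the overall standard deviation, and equal weights.
#' Used for cutoff derivation on log hash counts and for dichotomizing
#' bimodal bulk peak intensities.
#'
#' @param x numeric vector (already on the scale to be modelled, e.g.
#'   `log1p(counts)` or `log(score)`).
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the log-likelihood.
#' @return a list of class `gmm2`: `mu`, `sigma`, `lambda` (component
#'   weights), `loglik`, `iter`, ordered so component 2 has the larger mean.
#' @export
fit_gmm2 <- function(x, max_iter = 500, tol = 1e-8) {
  x <- x[is.finite(x)]
  if (length(x) < 4) abort("too few observations for a mixture fit")
  mu <- unname(quantile(x, c(0.25, 0.75)))
  s0 <- max(sd(x), 1e-3)
  sigma <- c(s0, s0)
  lambda <- c(0.5, 0.5)
  ll_old <- -Inf
  iter <- 0
  for (iter in seq_len(max_iter)) {
    d1 <- lambda[1] * dnorm(x, mu[1], sigma[1])
    d2 <- lambda[2] * dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r2 <- d2 / tot
    r1 <- 1 - r2
    lambda <- c(mean(r1), mean(r2))
    mu <- c(sum(r1 * x) / sum(r1), sum(r2 * x) / sum(r2))
    sigma <- c(sqrt(sum(r1 * (x - mu[1])^2) / sum(r1)),
               sqrt(sum(r2 * (x - mu[2])^2) / sum(r2)))
    sigma <- pmax(sigma, 1e-4)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ord <- order(mu)
  structure(list(mu = mu[ord], sigma = sigma[ord], lambda = lambda[ord],
                 loglik = ll, iter = iter),
            class = "gmm2")
}

#' Posterior probability of the high component
#'
#' @param fit a [fit_gmm2()] object.
#' @param x numeric vector of points (same scale as the fit).
#' @return numeric vector of posterior probabilities that each point belongs
#'   to the higher-mean component.
#' @export
posterior_high <- function(fit, x) {
  d1 <- fit$lambda[1] * dnorm(x, fit$mu[1], fit$sigma[1])
  d2 <- fit$lambda[2] * dnorm(x, fit$mu[2], fit$sigma[2])
  out <- d2 / (d1 + d2)
  # far outside the support, fall back to nearest-mean assignment
  out[!is.finite(out)] <- as.numeric(
    abs(x[!is.finite(out)] - fit$mu[2]) < abs(x[!is.finite(out)] - fit$mu[1])
  )
  out
}

#' @export
print.gmm2 <- function(x, ...) {
  cat(sprintf("<gmm2> mu = (%.3f, %.3f), sigma = (%.3f, %.3f), lambda = (%.3f, %.3f)\n",
              x$mu[1], x$mu[2], x$sigma[1], x$sigma[2], x$lambda[1], x$lambda[2]))
  invisible(x)
}

#' @exportS3Method
tidy.gmm2 <- function(x, ...) {
  tibble(component = c("low", "high"), mu = x$mu, sigma = x$sigma,
         lambda = x$lambda)
}

#' @exportS3Method
glance.gmm2 <- function(x, ...) {
  tibble(loglik = x$loglik, iter = x$iter,
         separation = diff(x$mu) / sqrt(mean(x$sigma^2)))
}

# Mixture density at x.
gmm2_density <- function(fit, x) {
  fit$lambda[1] * dnorm(x, fit$mu[1], fit$sigma[1]) +
    fit$lambda[2] * dnorm(x, fit$mu[2], fit$sigma[2])
}

# Antimode (density minimum) between the two fitted means.
gmm2_dip <- function(fit) {
  if (diff(fit$mu) < 1e-9) return(list(at = fit$mu[1], density = gmm2_density(fit, fit$mu[1])))
  grid <- seq(fit$mu[1], fit$mu[2], length.out = 512)
  dens <- gmm2_density(fit, grid)
  i <- which.min(dens)
  list(at = grid[i], density = dens[i])
}
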