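#' Penalised-complexity prior for a standard deviation
#'
#' The PC prior for a standard deviation shrinks toward the base model
#' sigma = 0 (the random effect absent) with an exponential density on sigma,
#' rate lambda = -log(alpha)/u, so that P(sigma > u) = alpha.
#'
#' @param u threshold on the standard deviation scale (> 0)
#' @param alpha tail probability, 0 < alpha < 1
#' @return an object of class `pc_prior` with fields `kind`, `u`, `alpha`,
#'   `rate`, `support`, and `log_density(x)` evaluating the log prior density
#' @examples
#' pr <- pc_prior_sd(u = 0.1, alpha = 0.8)
#' exp(pr$log_density(0.1)) # density at the threshold
#' @export
pc_prior_sd <- function(u, alpha) {
  if (!is.finite(u) || u <= 0) stop("`u` must be > 0")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  rate <- -log(alpha) / u
  structure(list(kind = "sd", u = u, alpha = alpha, rate = rate,
                 support = c(0, Inf),
                 log_density = function(x) {
                   ifelse(x < 0, -Inf, log(rate) - rate * x)
                 }),
            class = "pc_prior")
}

#' Penalised-complexity prior for an AR(1) autocorrelation with base rho = 1
#'
#' Prior for the autocorrelation of a stationary first-order autoregressive
#' process that shrinks toward the base model rho = 1 (neighbouring effects
#' identical). The complexity distance from the base model is
#' d(rho) = sqrt(1 - rho); an exponential density with rate theta is placed on
#' d, truncated to d in (0, sqrt(2)) (i.e. rho in (-1, 1)) and transformed to
#' the rho scale. The rate is calibrated numerically so that
#' P(rho > u) = alpha. The admissible region is -1 < u < 1 together with
#' (1 - u)/2 < alpha < 1.
#'
#' @param u threshold on the correlation scale, -1 < u < 1
#' @param alpha tail probability for P(rho > u), (1 - u)/2 < alpha < 1
#' @return an object of class `pc_prior` with fields `kind`, `u`, `alpha`,
#'   `rate` (calibrated), `support`, and `log_density(rho)`
#' @examples
#' pr <- pc_prior_ar1(u = 0.7, alpha = 0.8)
#' integrate(function(r) exp(pr$log_density(r)), -1, 1)$value # ~1
#' @export
pc_prior_ar1 <- function(u, alpha) {
  if (!is.finite(u) || abs(u) >= 1) stop("`u` must satisfy -1 < u < 1")
  if (!is.finite(alpha) || alpha <= (1 - u) / 2 || alpha >= 1)
    stop("`alpha` must satisfy (1 - u)/2 < alpha < 1 for the base model rho = 1")
  s2 <- sqrt(2)
  du <- sqrt(1 - u)
  # P(rho > u) = P(d < du) = expm1(-theta*du)/expm1(-theta*s2); theta may be
  # negative (the truncated exponential on (0, sqrt 2) remains proper).
  tail_prob <- function(theta) {
    if (abs(theta) < 1e-12) return(du / s2)
    expm1(-theta * du) / expm1(-theta * s2)
  }
  f <- function(theta) tail_prob(theta) - alpha
  lo <- -1; hi <- 1
  while (f(lo) * f(hi) > 0 && hi < 1e6) { lo <- lo * 2; hi <- hi * 2 }
  if (f(lo) * f(hi) > 0) stop("PC prior calibration failed: no root for theta")
  theta <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  log_norm <- log(abs(theta)) - log(abs(expm1(-theta * s2)))
  structure(list(kind = "ar1_base1", u = u, alpha = alpha, rate = theta,
                 support = c(-1, 1),
                 log_density = function(x) {
                   d <- sqrt(pmax(1 - x, 0))
                   out <- log_norm - theta * d - log(2 * d)
                   out[x <= -1 | x >= 1] <- -Inf
                   out
                 }),
            class = "pc_prior")
}

#' @export
print.pc_prior <- function(x, ...) {
  cat("PC prior (", x$kind, "): P(x > ", x$u, ") = ", x$alpha,
      ", rate = ", signif(x$rate, 6), "\n", sep = "")
  invisible(x)
}

#' Default prior set for phenotype models
#'
#' Convenience bundle of the PC priors used throughout: exponential PC priors
#' on every standard deviation (default u = 0.1, alpha = 0.8) and the
#' base-one AR(1) PC prior on the autocorrelation (default u = 0.7,
#' alpha = 0.8). The fixed-effect prior is Gaussian with variance 1000.
#'
#' @param sd_u,sd_alpha threshold and tail probability for standard deviations
#' @param rho_u,rho_alpha threshold and tail probability for rho
#' @param fixed_prior_var Gaussian prior variance for fixed effects
#' @return list with elements `sd`, `rho`, `residual`, `fixed_prior_var`
#' @export
hn_priors <- function(sd_u = 0.1, sd_alpha = 0.8,
                      rho_u = 0.7, rho_alpha = 0.8,
                      fixed_prior_var = 1000) {
  list(sd = pc_prior_sd(sd_u, sd_alpha),
       rho = pc_prior_ar1(rho_u, rho_alpha),
       residual = pc_prior_sd(sd_u, sd_alpha),
       fixed_prior_var = fixed_prior_var)
}
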