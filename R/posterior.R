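#' Draw samples from the hyper-parameter posterior of a fit
#'
#' The grid posterior is a discrete mixture over atoms; samples are drawn by
#' picking an atom by weight and jittering uniformly within its grid cell (in
#' the standardised grid coordinates), which gives a piecewise-constant
#' continuous approximation of the posterior. Natural-scale columns are
#' returned (variances, and rho for haplotype network models).
#'
#' @param fit a `hapnet` object
#' @param n number of samples
#' @param seed integer seed (the draw is deterministic given the seed)
#' @return data frame of `n` rows with one column per hyper-parameter
#'   (`rho`, `s2_hap`, `s2_<term>`, `s2_e` as applicable)
#' @export
hyper_samples <- function(fit, n = 10000, seed = 1) {
  th_names <- fit$model$theta_names
  d <- length(fit$free)
  with_seed(seed, {
    idx <- sample.int(nrow(fit$hyper$z), n, replace = TRUE,
                      prob = fit$hyper$weights)
    th <- fit$hyper$theta[idx, , drop = FALSE]
    if (d > 0L && fit$step > 0) {
      jit <- matrix(stats::runif(n * d, -fit$step / 2, fit$step / 2), n, d)
      th[, fit$free] <- fit$hyper$theta[idx, fit$free, drop = FALSE] +
        jit %*% t(fit$B)
    }
    out <- data.frame(row.names = seq_len(n))
    for (j in seq_along(th_names)) {
      nm <- th_names[j]
      if (startsWith(nm, "rho.")) {
        out$rho <- tanh(th[, j] / 2)
      } else {
        key <- sub("^log_s2\\.", "s2_", nm)
        key <- sub("^s2_residual$", "s2_e", key)
        out[[key]] <- exp(th[, j])
      }
    }
    out
  })
}

#' Posterior of the conditional haplotype variance
#'
#' Transforms joint posterior samples of (rho, sigma2_hm) from a haplotype
#' network fit into the conditional variance sigma2_hc = sigma2_hm (1 -
#' rho^2) and summarises it.
#'
#' @param fit a `hapnet` object fitted with `haplotype = "hn"`
#' @param n_samples number of posterior samples (default 10000)
#' @param seed integer seed
#' @return list with `mean`, `ci` (central 95\% interval) and the `samples`
#' @export
conditional_variance_posterior <- function(fit, n_samples = 10000, seed = 1) {
  if (fit$model$haplotype != "hn")
    stop("conditional variance is defined for haplotype network fits")
  hs <- hyper_samples(fit, n_samples, seed)
  s2hc <- hs$s2_hap * (1 - hs$rho^2)
  list(mean = mean(s2hc),
       ci = stats::quantile(s2hc, c(0.025, 0.975), names = FALSE),
       samples = s2hc)
}

#' Central posterior interval for one hyper-parameter
#'
#' @param fit a `hapnet` object
#' @param which hyper-parameter name as in [hyper_samples()] output
#'   ("rho", "s2_hap", "s2_e", ...)
#' @param level interval level (default 0.95)
#' @param n,seed sampling settings passed to [hyper_samples()]
#' @return numeric vector of length two
#' @export
hyper_interval <- function(fit, which = "rho", level = 0.95,
                           n = 10000, seed = 1) {
  hs <- hyper_samples(fit, n, seed)
  if (!which %in% names(hs)) stop("no hyper-parameter `", which, "` in this fit")
  a <- (1 - level) / 2
  stats::quantile(hs[[which]], c(a, 1 - a), names = FALSE)
}

#' Posterior mutation effects back-solved from haplotype effects
#'
#' A haplotype-level fit (haplotype network or independent-haplotype model)
#' implies mutation effects through the least-squares map
#' v = (U'U)^-1 U' h over the scored (non-phantom) haplotypes. The map is
#' applied to each Gaussian conditional of the grid mixture, so the reported
#' variance is the diagonal of M Cov(h) M' under the full mixture.
#'
#' @param fit a `hapnet` object with an "hn" or "ih" haplotype term
#' @param U allele matrix (haplotypes x sites, 0/1, row names = haplotype
#'   labels) with full column rank over the scored haplotypes
#' @return data frame with columns `site`, `mean`, `sd`
#' @export
estimate_mutation_effects <- function(fit, U) {
  model <- fit$model
  if (model$haplotype == "mutation")
    stop("the mutation model estimates mutation effects directly; ",
         "use coef()/fit$latent")
  check_allele_matrix(U)
  scored <- model$node_ids[!model$is_phantom]
  missing <- setdiff(scored, rownames(U))
  if (length(missing)) stop("U is missing scored haplotype(s): ",
                            paste(utils::head(missing, 5), collapse = ", "))
  Us <- U[scored, , drop = FALSE]
  UtU <- crossprod(Us)
  qr_ <- qr(UtU)
  if (qr_$rank < ncol(Us)) {
    dep <- colnames(Us)[qr_$pivot[(qr_$rank + 1L):ncol(Us)]]
    stop("U'U is rank deficient; collinear site set includes: ",
         paste(utils::head(dep, 10), collapse = ", "))
  }
  M <- solve(UtU, t(Us)) # (U'U)^-1 U', sites x scored haplotypes
  L <- matrix(0, ncol(Us), model$blocks$hap$q)
  L[, match(scored, model$node_ids)] <- M
  out <- fit_lincomb(fit, L, block = "hap")
  data.frame(site = colnames(Us), mean = out$mean, sd = out$sd,
             stringsAsFactors = FALSE)
}

#' Mutation effects implied by a known haplotype-effect distribution
#'
#' Deterministic helper applying the least-squares map
#' M = (U'U)^-1 U' to a mean vector and (optionally) a covariance matrix of
#' haplotype effects.
#'
#' @param U allele matrix (haplotypes x sites)
#' @param mean haplotype-effect mean vector aligned with the rows of `U`
#' @param cov optional covariance matrix of the haplotype effects
#' @return list with `mean` and, when `cov` is given, `var` (per-site)
#' @export
mutation_effects_from_h <- function(U, mean, cov = NULL) {
  check_allele_matrix(U)
  M <- solve(crossprod(U), t(U))
  out <- list(mean = as.numeric(M %*% mean))
  if (!is.null(cov)) out$var <- diag(M %*% cov %*% t(M))
  out
}

#' Posterior haplotype effects of a fit
#'
#' For haplotype network and independent-haplotype fits these are the native
#' latent effects; for mutation-model fits the haplotype effects h = U v are
#' derived through the grid mixture.
#'
#' @param fit a `hapnet` object
#' @param include_phantom keep phantom haplotypes (default FALSE)
#' @return data frame with columns `id`, `mean`, `sd`, `is_phantom`
#' @export
haplotype_effects <- function(fit, include_phantom = FALSE) {
  model <- fit$model
  if (model$haplotype == "mutation") {
    Uh <- model$terms$hap$U
    out <- fit_lincomb(fit, Uh, block = "hap")
    res <- data.frame(id = rownames(Uh), mean = out$mean, sd = out$sd,
                      is_phantom = FALSE, stringsAsFactors = FALSE)
  } else {
    idx <- model$blocks$hap$idx
    res <- data.frame(id = model$node_ids,
                      mean = fit$latent_mean[idx],
                      sd = fit$latent_sd[idx],
                      is_phantom = unname(model$is_phantom),
                      stringsAsFactors = FALSE)
  }
  if (!include_phantom) res <- res[!res$is_phantom, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Evaluate and restore the RNG state around a seeded computation.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic sub-stream seed derivation: one global seed expands into
# per-stage seeds so stage-level reproducibility survives pipeline
# reordering. Kept below 2^31 - 1.
substream_seed <- function(seed, stage, index = 0L) {
  base <- as.numeric(seed) %% 2147483647
  sh <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((base * 48271 + sh * 7919 + as.numeric(index) * 104729) %% 2147483647)
}
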