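#' @export
print.hapnet <- function(x, ...) {
  cat("Haplotype phenotype model fit (", x$model$haplotype, " term)\n", sep = "")
  cat("  phenotypes:", x$model$p, " latent variables:", x$model$m, "\n")
  cat("  hyper-parameter grid:", nrow(x$hyper$theta), "retained points\n")
  cat("  converged:", x$converged, "\n")
  mode_nat <- theta_pars(x$model, x$mode)
  cat("  posterior mode:",
      paste(sprintf("%s = %.3g", names(mode_nat), unlist(mode_nat)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Summarise a haplotype model fit
#'
#' @param object a `hapnet` object
#' @param n_samples posterior samples used for hyper-parameter intervals
#' @param seed seed for the interval sampling
#' @param ... unused
#' @return a `summary.hapnet` list with hyper-parameter and haplotype-effect
#'   tables
#' @export
summary.hapnet <- function(object, n_samples = 10000, seed = 1, ...) {
  hs <- hyper_samples(object, n_samples, seed)
  hyper <- data.frame(parameter = names(hs),
                      mean = vapply(hs, mean, 0),
                      sd = vapply(hs, stats::sd, 0),
                      q025 = vapply(hs, stats::quantile, 0, probs = 0.025),
                      q975 = vapply(hs, stats::quantile, 0, probs = 0.975),
                      row.names = NULL)
  out <- list(call = object$call, converged = object$converged,
              haplotype = object$model$haplotype,
              p = object$model$p, m = object$model$m,
              hyper = hyper,
              effects = haplotype_effects(object, include_phantom = TRUE))
  class(out) <- "summary.hapnet"
  out
}

#' @export
print.summary.hapnet <- function(x, ...) {
  cat("Haplotype phenotype model (", x$haplotype, " term), p = ", x$p,
      ", latent size ", x$m, "\n", sep = "")
  cat("converged:", x$converged, "\n\nHyper-parameters:\n")
  print(cbind(x$hyper[1], signif(x$hyper[-1], 4)), row.names = FALSE)
  cat("\nHaplotype effects (first 6):\n")
  eh <- utils::head(x$effects, 6)
  eh$mean <- signif(eh$mean, 4); eh$sd <- signif(eh$sd, 4)
  print(eh, row.names = FALSE)
  invisible(x)
}

#' Posterior mean haplotype effects
#'
#' @param object a `hapnet` object
#' @param ... unused
#' @return named numeric vector of posterior mean haplotype effects
#'   (phantoms included for network fits)
#' @export
coef.hapnet <- function(object, ...) {
  he <- haplotype_effects(object, include_phantom = TRUE)
  stats::setNames(he$mean, he$id)
}

#' @export
fitted.hapnet <- function(object, ...) object$fitted

#' @export
residuals.hapnet <- function(object, ...) object$residuals

#' Predict haplotype effects
#'
#' Returns the posterior mean and standard deviation of the effect of each
#' requested haplotype, including haplotypes that carry no phenotyped
#' individuals (for the network model their estimates borrow strength from
#' phylogenetic neighbours).
#'
#' @param object a `hapnet` object
#' @param haplotypes character vector of haplotype labels (default: all
#'   non-phantom haplotypes)
#' @param include_phantom include phantom haplotypes when defaulting
#' @param ... unused
#' @return data frame with columns `id`, `mean`, `sd`
#' @export
predict.hapnet <- function(object, haplotypes = NULL,
                           include_phantom = FALSE, ...) {
  he <- haplotype_effects(object, include_phantom = TRUE)
  if (is.null(haplotypes)) {
    if (!include_phantom) he <- he[!he$is_phantom, , drop = FALSE]
    rownames(he) <- NULL
    return(he[, c("id", "mean", "sd")])
  }
  miss <- setdiff(haplotypes, he$id)
  if (length(miss)) stop("unknown haplotype(s): ", paste(miss, collapse = ", "))
  out <- he[match(haplotypes, he$id), c("id", "mean", "sd")]
  rownames(out) <- NULL
  out
}

#' Plot a haplotype model fit
#'
#' Draws the hyper-parameter posterior densities (sampled from the grid
#' mixture) and the haplotype effect estimates with 95\% intervals, ordered
#' by posterior mean.
#'
#' @param x a `hapnet` object
#' @param which "hyper", "effects" or "both"
#' @param n_samples samples for the density panels
#' @param seed sampling seed
#' @param ... passed to [graphics::plot()]
#' @return invisibly, `x`
#' @export
plot.hapnet <- function(x, which = c("both", "hyper", "effects"),
                        n_samples = 5000, seed = 1, ...) {
  which <- match.arg(which)
  hs <- hyper_samples(x, n_samples, seed)
  nh <- ncol(hs)
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  if (which == "both") {
    graphics::par(mfrow = c(1, nh + 1))
  } else if (which == "hyper") {
    graphics::par(mfrow = c(1, nh))
  }
  if (which != "effects") {
    for (nm in names(hs)) {
      d <- stats::density(hs[[nm]])
      graphics::plot(d, main = nm, xlab = nm, ...)
    }
  }
  if (which != "hyper") {
    he <- haplotype_effects(x, include_phantom = FALSE)
    o <- order(he$mean)
    graphics::plot(seq_along(o), he$mean[o], ylim = range(he$mean - 2 * he$sd,
                                                          he$mean + 2 * he$sd),
                   xlab = "haplotype (ordered)", ylab = "effect",
                   main = "haplotype effects", pch = 16, ...)
    graphics::segments(seq_along(o), he$mean[o] - 1.96 * he$sd[o],
                       seq_along(o), he$mean[o] + 1.96 * he$sd[o],
                       col = "grey50")
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}

#' Simulate from the posterior predictive distribution
#'
#' Draws phenotype vectors by sampling a hyper-parameter grid atom by weight,
#' drawing the latent field from its exact Gaussian conditional, and adding
#' residual noise.
#'
#' @param object a `hapnet` object
#' @param nsim number of simulated phenotype vectors
#' @param seed integer seed
#' @param ... unused
#' @return a p x nsim matrix of simulated phenotypes
#' @export
simulate.hapnet <- function(object, nsim = 1, seed = 1, ...) {
  model <- object$model
  with_seed(seed, {
    atoms <- sample.int(nrow(object$hyper$theta), nsim, replace = TRUE,
                        prob = object$hyper$weights)
    out <- matrix(0, model$p, nsim)
    for (s in seq_len(nsim)) {
      th <- object$hyper$theta[atoms[s], ]
      gc <- gaussian_conditional(model, th, full = TRUE)
      pars <- theta_pars(model, th)
      A <- build_Qx(model, pars)$Qx + model$WtW / pars$s2e
      R <- chol(A)
      xdraw <- gc$mu + backsolve(R, stats::rnorm(model$m))
      out[, s] <- as.numeric(model$W %*% xdraw) +
        stats::rnorm(model$p, 0, sqrt(pars$s2e))
    }
    out
  })
}
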