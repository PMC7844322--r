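# Exact Gaussian machinery for the phenotype model: for fixed hyper-parameters
# the latent field is Gaussian with precision A = Q_x(theta) + W'W / s2e and the
# marginal likelihood of y integrates out the latent field in closed form.
# Log-determinants of the prior precision are available in closed form for
# every block (T^-1 is unit-triangular, so the hn block contributes
# -n log s2hc + s log(1 - rho^2) + sum log k_i).

# Map an internal-scale hyper vector to natural-scale parameters.
theta_pars <- function(model, theta) {
  names(theta) <- model$theta_names
  pars <- list()
  for (nm in names(model$terms)) {
    tr <- model$terms[[nm]]
    if (tr$type == "hn") {
      phi <- theta[[paste0("rho.", nm)]]
      pars[[paste0("rho.", nm)]] <- tanh(phi / 2)
    }
    pars[[paste0("s2.", nm)]] <- exp(theta[[paste0("log_s2.", nm)]])
  }
  pars$s2e <- exp(theta[["log_s2.residual"]])
  pars
}

# Prior precision of the full latent field, dense, plus its log-determinant.
build_Qx <- function(model, pars) {
  m <- model$m
  Qx <- matrix(0, m, m)
  logdet <- 0
  for (bn in names(model$blocks)) {
    b <- model$blocks[[bn]]
    if (b$type == "fixed") {
      v <- model$priors$fixed_prior_var
      Qx[cbind(b$idx, b$idx)] <- 1 / v
      logdet <- logdet - b$q * log(v)
    } else if (b$type == "iid" || b$type == "mutation") {
      s2 <- pars[[paste0("s2.", bn)]]
      Qx[cbind(b$idx, b$idx)] <- 1 / s2
      logdet <- logdet - b$q * log(s2)
    } else if (b$type == "user_precision") {
      s2 <- pars[[paste0("s2.", bn)]]
      Qx[b$idx, b$idx] <- b$precision / s2
      logdet <- logdet + b$logdet_precision - b$q * log(s2)
    } else if (b$type == "hn") {
      rho <- pars[[paste0("rho.", bn)]]
      s2hm <- pars[[paste0("s2.", bn)]]
      s2hc <- s2hm * (1 - rho^2)
      Qx[model$hn_lin] <- template_values(b$template, rho) / s2hc
      logdet <- logdet - b$q * log(s2hc) +
        model$hn_nstart * log(1 - rho^2) + model$hn_sumlogk
    }
  }
  list(Qx = Qx, logdet = logdet)
}

# Joint latent precision A = Q_x + W'W/s2e built in place, with the prior
# log-determinant accumulated in closed form.
build_joint_precision <- function(model, pars) {
  A <- model$WtW * (1 / pars$s2e)
  m <- model$m
  dlin <- (seq_len(m) - 1L) * m + seq_len(m)
  logdet <- 0
  for (bn in names(model$blocks)) {
    b <- model$blocks[[bn]]
    if (b$type == "fixed") {
      v <- model$priors$fixed_prior_var
      A[dlin[b$idx]] <- A[dlin[b$idx]] + 1 / v
      logdet <- logdet - b$q * log(v)
    } else if (b$type == "iid" || b$type == "mutation") {
      s2 <- pars[[paste0("s2.", bn)]]
      A[dlin[b$idx]] <- A[dlin[b$idx]] + 1 / s2
      logdet <- logdet - b$q * log(s2)
    } else if (b$type == "user_precision") {
      s2 <- pars[[paste0("s2.", bn)]]
      A[b$idx, b$idx] <- A[b$idx, b$idx] + b$precision / s2
      logdet <- logdet + b$logdet_precision - b$q * log(s2)
    } else if (b$type == "hn") {
      rho <- pars[[paste0("rho.", bn)]]
      s2hm <- pars[[paste0("s2.", bn)]]
      s2hc <- s2hm * (1 - rho^2)
      tpl <- b$template
      A[model$hn_lin] <- A[model$hn_lin] +
        (tpl$a + tpl$b * rho + tpl$c * rho^2) / s2hc
      logdet <- logdet - b$q * log(s2hc) +
        model$hn_nstart * log(1 - rho^2) + model$hn_sumlogk
    }
  }
  list(A = A, logdet = logdet)
}

# Log marginal likelihood log p(y | theta) and, when full = TRUE, the latent
# conditional mean, marginal variances and optional linear-combination
# summaries. `lincomb` is a q x m matrix applied to the full latent field.
gaussian_conditional <- function(model, theta, full = FALSE, lincomb = NULL) {
  pars <- theta_pars(model, theta)
  if (!all(is.finite(unlist(pars)))) return(list(loglik = -Inf))
  qx <- build_joint_precision(model, pars)
  A <- qx$A
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(list(loglik = -Inf))
  b <- model$Wty / pars$s2e
  z <- backsolve(R, b, transpose = TRUE)
  loglik <- -model$p / 2 * log(2 * pi * pars$s2e) +
    0.5 * qx$logdet - sum(log(diag(R))) +
    0.5 * sum(z^2) - 0.5 * model$yty / pars$s2e
  out <- list(loglik = as.numeric(loglik), pars = pars)
  if (!full) return(out)
  mu <- backsolve(R, z)
  Ainv <- chol2inv(R)
  dv <- diag(Ainv)
  if (!is.null(model$constraint)) {
    cv <- model$constraint
    Ac <- Ainv %*% cv
    denom <- as.numeric(crossprod(cv, Ac))
    mu <- mu - as.numeric(Ac) * (sum(cv * mu) / denom)
    dv <- dv - as.numeric(Ac)^2 / denom
  }
  out$mu <- as.numeric(mu)
  out$diag_var <- pmax(dv, 0)
  if (!is.null(lincomb)) {
    S <- backsolve(R, t(lincomb), transpose = TRUE) # R^-T L'
    out$lin_mu <- as.numeric(lincomb %*% mu)
    out$lin_var <- pmax(colSums(S^2), 0)
    if (!is.null(model$constraint)) {
      cv <- model$constraint
      Ac <- Ainv %*% cv
      denom <- as.numeric(crossprod(cv, Ac))
      LAc <- as.numeric(lincomb %*% Ac)
      out$lin_mu <- as.numeric(lincomb %*% mu) # mu already corrected
      out$lin_var <- pmax(out$lin_var - LAc^2 / denom, 0)
    }
  }
  out
}

# Log prior density of the hyper-parameters on the internal scale
# (log variances; Fisher-type transform for rho), Jacobians included.
log_hyper_prior <- function(model, theta) {
  names(theta) <- model$theta_names
  lp <- 0
  for (nm in names(model$terms)) {
    tr <- model$terms[[nm]]
    if (tr$type == "hn") {
      phi <- theta[[paste0("rho.", nm)]]
      rho <- tanh(phi / 2)
      lp <- lp + tr$rho_prior$log_density(rho) + log((1 - rho^2) / 2)
    }
    lt <- theta[[paste0("log_s2.", nm)]]
    sig <- exp(lt / 2)
    lp <- lp + tr$prior$log_density(sig) + log(sig / 2)
  }
  lt <- theta[["log_s2.residual"]]
  sig <- exp(lt / 2)
  lp <- lp + model$priors$residual$log_density(sig) + log(sig / 2)
  as.numeric(lp)
}

#' Log marginal likelihood of the phenotype model at fixed hyper-parameters
#'
#' Integrates the Gaussian latent field out of the Gaussian likelihood in
#' closed form via one factorisation of the joint latent precision
#' Q_x(theta) + W'W / sigma2_e.
#'
#' @param model an `hn_model`
#' @param theta named list or vector of natural-scale hyper-parameters:
#'   `rho` (hn models), `s2_hap` (marginal variance of the haplotype term, or
#'   mutation-effect variance), `s2_e`, and `s2_<name>` for extra terms
#' @return log p(y | theta), a scalar
#' @export
log_marginal_likelihood <- function(model, theta) {
  gaussian_conditional(model, natural_to_internal(model, theta))$loglik
}

# Accepts list(rho=, s2_hap=, s2_e=, s2_<term>=) and builds the internal vector.
natural_to_internal <- function(model, theta) {
  th <- numeric(length(model$theta_names))
  names(th) <- model$theta_names
  for (nm in names(model$terms)) {
    tr <- model$terms[[nm]]
    key <- if (nm == "hap") "s2_hap" else paste0("s2_", nm)
    if (is.null(theta[[key]])) stop("theta needs `", key, "`")
    th[[paste0("log_s2.", nm)]] <- log(theta[[key]])
    if (tr$type == "hn") {
      if (is.null(theta$rho)) stop("theta needs `rho` for an hn model")
      if (abs(theta$rho) >= 1) stop("|rho| must be < 1 for stationarity")
      th[[paste0("rho.", nm)]] <- 2 * atanh(theta$rho)
    }
  }
  if (is.null(theta$s2_e)) stop("theta needs `s2_e`")
  th[["log_s2.residual"]] <- log(theta$s2_e)
  th
}
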