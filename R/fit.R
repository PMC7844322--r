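#' Control settings for the hyper-parameter grid
#'
#' The posterior over hyper-parameters is explored on a Cartesian grid in a
#' standardised coordinate system: the log posterior is maximised
#' numerically, the Hessian at the mode is inverted, and grid axes follow the
#' eigenvectors of the resulting covariance scaled by its eigenvalue square
#' roots. Points whose log posterior falls more than `prune_log` below the
#' mode are discarded before weight normalisation.
#'
#' @param n_points grid points per hyper-parameter dimension within the
#'   initial +/- `z_extent` range (odd, so the mode itself is a grid point);
#'   the spacing `2 z_extent / (n_points - 1)` is kept when a direction is
#'   extended
#' @param z_extent initial half-width of the grid in posterior standard
#'   deviations; each direction is extended beyond it while the log posterior
#'   stays within `prune_log` of the mode
#' @param prune_log log-weight drop at which grid points are pruned and the
#'   lattice exploration stops growing
#' @param max_steps hard cap on lattice steps per dimension and side
#' @param max_points hard cap on the number of explored lattice points
#' @param optim_maxit maximum iterations for the mode search
#' @return list of settings for [hapnet()]
#' @export
hn_control <- function(n_points = 7, z_extent = 3, prune_log = 10,
                       max_steps = 50, max_points = 6000,
                       optim_maxit = 2000) {
  stopifnot(n_points >= 3, z_extent > 0, prune_log > 0, max_steps >= 1,
            max_points >= 10)
  list(n_points = as.integer(n_points), z_extent = z_extent,
       prune_log = prune_log, max_steps = max_steps,
       max_points = as.integer(max_points),
       optim_maxit = as.integer(optim_maxit))
}

#' Fit a haplotype phenotype model
#'
#' Fits the Bayesian phenotype model assembled by [hn_model()] (all arguments
#' are forwarded there unless `model` is supplied directly). Because the
#' likelihood and the latent field are Gaussian, the latent conditionals at
#' fixed hyper-parameters are exact; the few hyper-parameters (variances, and
#' the autocorrelation rho for the haplotype network model) are integrated
#' numerically over an eigen-scaled Cartesian grid around the posterior mode.
#' Reported latent summaries are the mean and variance of the resulting
#' mixture of Gaussians.
#'
#' @inheritParams hn_model
#' @param model optionally a ready-made `hn_model` (then y/Z/... are ignored)
#' @param control grid settings from [hn_control()]
#' @param fixed named list of hyper-parameters to hold fixed at given
#'   natural-scale values, e.g. `list(rho = 0)`; fixed dimensions are removed
#'   from the grid
#' @param ... passed to [hn_model()]
#' @return an object of class `hapnet` with components `latent` (data frame
#'   of posterior means/sds per latent variable), `hyper` (grid atoms and
#'   weights), `converged`, and the model internals; use [summary.hapnet()],
#'   [coef.hapnet()], [predict.hapnet()], [hyper_samples()] on it
#' @examples
#' dag <- haplotype_dag(data.frame(child = c("i", "j", "k"),
#'                                 parent = c(NA, "i", "j")))
#' sim <- simulate_from_hn(dag, rho = 0.8, ve_over_vhc = 1, p = 9,
#'                         scenario = "all_observed", seed = 1)
#' fit <- hapnet(y = sim$y, Z = sim$Z, dag = dag, haplotype = "hn",
#'               control = hn_control(n_points = 5))
#' coef(fit)
#' @export
hapnet <- function(y = NULL, Z = NULL, dag = NULL, U = NULL,
                   haplotype = c("hn", "ih", "mutation"),
                   X = NULL, extra = list(), priors = hn_priors(),
                   model = NULL, control = hn_control(), fixed = list(), ...) {
  if (is.null(model)) {
    haplotype <- match.arg(haplotype)
    model <- hn_model(y = y, Z = Z, dag = dag, U = U, haplotype = haplotype,
                      X = X, extra = extra, priors = priors, ...)
  }
  if (!inherits(model, "hn_model")) stop("`model` must be an hn_model")

  fx <- fixed_theta(model, fixed)
  free <- fx$free
  d <- length(free)

  log_joint <- function(th_free) {
    th <- fx$full
    th[free] <- th_free
    gc <- gaussian_conditional(model, th)
    if (!is.finite(gc$loglik)) return(-1e10)
    lp <- log_hyper_prior(model, th)
    val <- gc$loglik + lp
    if (!is.finite(val)) -1e10 else val
  }

  converged <- TRUE
  if (d == 0L) {
    mode_free <- numeric(0)
    H <- matrix(0, 0, 0)
  } else {
    th0 <- init_theta(model)[free]
    opt <- tryCatch({
      if (d == 1L) {
        stats::optim(th0, function(t) -log_joint(t), method = "Brent",
                     lower = th0 - 25, upper = th0 + 25,
                     control = list(maxit = control$optim_maxit))
      } else {
        stats::optim(th0, function(t) -log_joint(t), method = "Nelder-Mead",
                     control = list(maxit = control$optim_maxit,
                                    reltol = 1e-10))
      }
    }, error = function(e) NULL)
    if (is.null(opt) || opt$convergence != 0) converged <- FALSE
    mode_free <- if (is.null(opt)) th0 else opt$par
    H <- tryCatch(stats::optimHess(mode_free, function(t) -log_joint(t)),
                  error = function(e) NULL)
    if (is.null(H) || any(!is.finite(H))) {
      converged <- FALSE
      H <- diag(d)
    }
  }

  # eigen-scaled grid directions; guard non-positive curvature
  if (d > 0L) {
    H <- (H + t(H)) / 2
    eh <- eigen(H, symmetric = TRUE)
    if (any(eh$values <= 0)) converged <- FALSE
    evals <- pmax(eh$values, 1e-6)
    B <- eh$vectors %*% diag(1 / sqrt(evals), d)
  } else B <- matrix(0, 0, 0)

  npt <- control$n_points
  step <- if (npt > 1) 2 * control$z_extent / (npt - 1) else 0
  # adaptive lattice exploration: starting from the mode, evaluate the log
  # posterior on the step-spaced lattice (in the eigen-standardised
  # coordinates) and grow the evaluated region outward until every boundary
  # point has dropped prune_log below the running maximum. This follows
  # skewed and ridge-shaped hyper posteriors (e.g. the rho -> 1 ridge) that
  # a fixed mode-centred box would truncate.
  if (d > 0L) {
    reg <- explore_lattice(log_joint, d, step, mode_free, B,
                           prune_log = control$prune_log,
                           max_coord = control$max_steps,
                           max_points = control$max_points)
    zgrid <- reg$z
    lp <- reg$lp
  } else {
    zgrid <- matrix(0, 1, 0)
    lp <- 0
  }
  G <- nrow(zgrid)
  theta_grid <- matrix(rep(fx$full, each = G), G, length(fx$full),
                       dimnames = list(NULL, model$theta_names))
  if (d > 0L)
    theta_grid[, free] <- matrix(mode_free, G, d, byrow = TRUE) + zgrid %*% t(B)
  if (!any(is.finite(lp))) stop("degenerate hyper-parameter grid: no finite posterior values")
  keep <- lp > max(lp) - control$prune_log
  zgrid <- zgrid[keep, , drop = FALSE]
  theta_grid <- theta_grid[keep, , drop = FALSE]
  lp <- lp[keep]
  w <- exp(lp - max(lp))
  w <- w / sum(w)

  # exact Gaussian conditional at every retained grid point
  m <- model$m
  G <- nrow(theta_grid)
  mu_mat <- matrix(0, G, m)
  dv_mat <- matrix(0, G, m)
  for (g in seq_len(G)) {
    gc <- gaussian_conditional(model, theta_grid[g, ], full = TRUE)
    mu_mat[g, ] <- gc$mu
    dv_mat[g, ] <- gc$diag_var
  }
  lat_mean <- as.numeric(crossprod(w, mu_mat))
  lat_var <- as.numeric(crossprod(w, dv_mat + mu_mat^2)) - lat_mean^2
  lat_var <- pmax(lat_var, 0)

  hap_idx <- model$blocks$hap$idx
  latent <- data.frame(id = model$latent_names,
                       mean = lat_mean, sd = sqrt(lat_var),
                       stringsAsFactors = FALSE)
  latent$block <- ""
  for (bn in names(model$blocks)) latent$block[model$blocks[[bn]]$idx] <- bn

  fitted_vals <- as.numeric(model$W %*% lat_mean)
  mode_full <- fx$full
  mode_full[free] <- mode_free
  structure(list(model = model, control = control,
                 converged = converged,
                 mode = stats::setNames(mode_full, model$theta_names),
                 mode_free = mode_free, free = free, B = B, step = step,
                 hyper = list(theta = theta_grid, z = zgrid,
                              log_post = lp, weights = w),
                 latent = latent,
                 latent_mean = stats::setNames(lat_mean, model$latent_names),
                 latent_sd = stats::setNames(sqrt(lat_var), model$latent_names),
                 mu_grid = mu_mat,
                 fitted = fitted_vals,
                 residuals = model$y - fitted_vals,
                 call = match.call()),
            class = "hapnet")
}

# Breadth-first exploration of the log posterior on an integer lattice in the
# standardised z-coordinates. A lattice point is "open" while its log value is
# within prune_log of the running maximum; neighbours (one step along each
# axis) of open points are evaluated until no open point has an unevaluated
# neighbour. Returns all evaluated points (the caller prunes).
explore_lattice <- function(log_joint, d, step, mode_free, B,
                            prune_log, max_coord, max_points) {
  cache <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(ix) paste(ix, collapse = ",")
  evalpt <- function(ix) {
    lp <- log_joint(mode_free + as.numeric(B %*% (ix * step)))
    assign(key(ix), lp, envir = cache)
    lp
  }
  coords <- list(rep(0L, d))
  lps <- evalpt(coords[[1L]])
  lpmax <- lps
  queue <- coords
  n_eval <- 1L
  repeat {
    lpmax_in <- lpmax
    frontier <- list()
    for (pt in queue) {
      if (get(key(pt), envir = cache) <= lpmax - prune_log) next
      for (dd in seq_len(d)) for (s in c(-1L, 1L)) {
        nb <- pt
        nb[dd] <- nb[dd] + s
        if (abs(nb[dd]) > max_coord) next
        k <- key(nb)
        if (!exists(k, envir = cache)) {
          lp <- evalpt(nb)
          n_eval <- n_eval + 1L
          if (lp > lpmax) lpmax <- lp
          coords[[length(coords) + 1L]] <- nb
          lps <- c(lps, lp)
          frontier[[length(frontier) + 1L]] <- nb
        }
      }
      if (n_eval >= max_points) break
    }
    if (n_eval >= max_points) break
    if (length(frontier)) {
      # continue from the newly opened shell; if the maximum rose enough to
      # change the cutoff materially, rescan everything once
      queue <- if (lpmax - lpmax_in > 0.1) coords else frontier
    } else if (lpmax - lpmax_in > 0.1) {
      queue <- coords
    } else break
  }
  list(z = matrix(unlist(coords), ncol = d, byrow = TRUE) * step,
       lp = lps)
}

# Resolve fixed hyper-parameters: returns the full internal vector with fixed
# slots filled and the indices of the free dimensions.
fixed_theta <- function(model, fixed) {
  full <- init_theta(model)
  free <- seq_along(full)
  if (length(fixed)) {
    names(full) <- model$theta_names
    drop <- integer(0)
    for (nm in names(fixed)) {
      slot <- switch(nm,
                     rho = "rho.hap",
                     s2_hap = "log_s2.hap",
                     s2_e = "log_s2.residual",
                     paste0("log_s2.", sub("^s2_", "", nm)))
      if (!slot %in% model$theta_names) stop("unknown fixed hyper-parameter: ", nm)
      val <- fixed[[nm]]
      full[[slot]] <- if (startsWith(slot, "rho.")) 2 * atanh(val) else log(val)
      drop <- c(drop, match(slot, model$theta_names))
    }
    free <- setdiff(free, drop)
  }
  list(full = as.numeric(full), free = free)
}

init_theta <- function(model) {
  vy <- if (model$p > 1) stats::var(model$y) else 1
  nterm <- length(model$terms) + 1L
  th <- numeric(length(model$theta_names))
  names(th) <- model$theta_names
  th[startsWith(model$theta_names, "log_s2.")] <- log(max(vy, 1e-3) / nterm)
  th[startsWith(model$theta_names, "rho.")] <- 2 * atanh(0.5)
  as.numeric(th)
}

# Recompute linear-combination posterior summaries over the stored grid.
# L maps the latents of `block` (columns named/ordered as that block) to q
# derived quantities; returns the mixture mean and sd per row of L.
fit_lincomb <- function(fit, L, block = "hap") {
  model <- fit$model
  b <- model$blocks[[block]]
  if (is.null(b)) stop("no block `", block, "` in the model")
  if (ncol(L) != b$q) stop("lincomb has ", ncol(L), " columns for block of size ", b$q)
  Lf <- matrix(0, nrow(L), model$m)
  Lf[, b$idx] <- as.matrix(L)
  th <- fit$hyper$theta
  w <- fit$hyper$weights
  G <- nrow(th)
  q <- nrow(L)
  mu <- matrix(0, G, q)
  vv <- matrix(0, G, q)
  for (g in seq_len(G)) {
    gc <- gaussian_conditional(model, th[g, ], full = TRUE, lincomb = Lf)
    mu[g, ] <- gc$lin_mu
    vv[g, ] <- gc$lin_var
  }
  mean <- as.numeric(crossprod(w, mu))
  var <- pmax(as.numeric(crossprod(w, vv + mu^2)) - mean^2, 0)
  data.frame(mean = mean, sd = sqrt(var))
}
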