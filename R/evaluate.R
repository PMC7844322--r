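#' Gaussian continuous ranked probability score
#'
#' Closed-form CRPS of a Gaussian predictive distribution N(mu, sigma^2)
#' against an observed value:
#' sigma * (z (2 Phi(z) - 1) + 2 phi(z) - 1/sqrt(pi)), z = (truth - mu)/sigma.
#' For sigma = 0 the score degenerates to the absolute error. Smaller is
#' better; the score is proper.
#'
#' @param mu predictive mean (vectorised)
#' @param sigma predictive standard deviation (>= 0)
#' @param truth realised value
#' @return numeric vector of scores
#' @examples
#' crps_gaussian(0, 1, 0) # 2 dnorm(0) - 1/sqrt(pi)
#' @export
crps_gaussian <- function(mu, sigma, truth) {
  k <- max(length(mu), length(sigma), length(truth))
  mu <- rep_len(mu, k); sigma <- rep_len(sigma, k); truth <- rep_len(truth, k)
  if (any(sigma < 0)) stop("sigma must be >= 0")
  out <- abs(truth - mu)
  pos <- sigma > 0
  if (any(pos)) {
    z <- (truth[pos] - mu[pos]) / sigma[pos]
    out[pos] <- sigma[pos] * (z * (2 * stats::pnorm(z) - 1) +
                                2 * stats::dnorm(z) - 1 / sqrt(pi))
  }
  out
}

#' Relative CRPS between two models
#'
#' Log of the ratio of summed CRPS of a model against a reference over the
#' same index set: negative values favour the model, and
#' rcrps(a, b) = -rcrps(b, a).
#'
#' @param crps_model CRPS values of the candidate model
#' @param crps_reference CRPS values of the reference model (same length,
#'   positive sum)
#' @return scalar log ratio
#' @export
rcrps <- function(crps_model, crps_reference) {
  if (length(crps_model) != length(crps_reference) || !length(crps_model))
    stop("CRPS vectors must have equal positive length")
  sr <- sum(crps_reference)
  if (sr <= 0) stop("reference CRPS sum must be > 0")
  log(sum(crps_model) / sr)
}

#' Root mean square error
#'
#' @param estimates estimated values
#' @param truths true values (same length)
#' @return sqrt(mean((estimates - truths)^2))
#' @export
rmse <- function(estimates, truths) {
  if (length(estimates) != length(truths) || !length(estimates))
    stop("vectors must have equal positive length")
  sqrt(mean((estimates - truths)^2))
}

#' Stratify haplotypes by phenotype-observation count
#'
#' @param Z incidence matrix with one column per haplotype
#' @param is_phantom optional logical flag per column; phantom haplotypes are
#'   always labelled "never"
#' @return factor with levels never/once/several, one per haplotype
#' @export
stratify_by_observation <- function(Z, is_phantom = NULL) {
  cs <- Matrix::colSums(Z)
  lab <- ifelse(cs == 0, "never", ifelse(cs == 1, "once", "several"))
  if (!is.null(is_phantom)) lab[is_phantom] <- "never"
  factor(lab, levels = c("never", "once", "several"))
}

#' Proportions of total variance explained
#'
#' Divides each named variance component (posterior means; use the marginal
#' haplotype variance for the network term) by the component total.
#'
#' @param components named numeric vector of variances (>= 0, at least two)
#' @return data frame with columns `component`, `variance`, `proportion`
#'   (proportions sum to one)
#' @export
variance_proportions <- function(components) {
  if (length(components) < 2) stop("need at least two components")
  if (any(components < 0)) stop("variances must be >= 0")
  tot <- sum(components)
  if (tot <= 0) stop("all components are zero")
  data.frame(component = names(components),
             variance = as.numeric(components),
             proportion = as.numeric(components) / tot,
             row.names = NULL)
}

# CRPS of fitted haplotype effects against truth, per haplotype.
hap_crps <- function(fit, truth, ids) {
  he <- haplotype_effects(fit, include_phantom = TRUE)
  he <- he[match(ids, he$id), ]
  crps_gaussian(he$mean, he$sd, truth[ids])
}

#' Replicate the simulation study
#'
#' Runs the full simulate-fit-score loop: for each parameter cell, generates
#' replicate datasets (from the haplotype network model or the mutation
#' model), fits the requested models, drops replicates where any fit failed
#' to converge, scores haplotype effects with the Gaussian CRPS stratified by
#' observation count, and aggregates the log CRPS-sum ratios (RCRPS) per
#' replicate and then across replicates. For the mutation-model design the
#' back-solved mutation effects of the network fit are also scored against
#' the mutation model's native estimates.
#'
#' One phylogeny of `n_haplotypes` is generated per study from `seed`;
#' replicates redraw effects, carrier assignments and residuals.
#'
#' @param generative "hn" or "mutation"
#' @param cells data frame of parameter cells; columns `rho` (hn) or `lam`
#'   (mutation) and `ve` (residual variance; relative to the conditional
#'   haplotype variance for "hn", absolute for "mutation" where the empirical
#'   haplotype variance is 1)
#' @param scenarios observation scenarios to run per cell
#' @param models models fitted to every dataset (subset of hn/ih/mutation)
#' @param n_haplotypes,p dimensions of each dataset
#' @param n_rep replicates per cell and scenario
#' @param priors prior bundle from [hn_priors()]
#' @param control grid settings from [hn_control()]
#' @param seed study seed; all randomness derives from it
#' @param score_mutation_effects also score back-solved mutation effects
#'   (requires both "hn" and "mutation" in `models`; default TRUE for the
#'   mutation-model design)
#' @return data frame in long format: one row per (cell, scenario, stratum,
#'   comparison) with the mean RCRPS across converged replicates, plus
#'   `n_converged`; mutation-effect rows use stratum "mutations"
#' @export
replicate_study <- function(generative = c("hn", "mutation"),
                            cells,
                            scenarios = c("all_observed", "some_unobserved"),
                            models = c("hn", "ih", "mutation"),
                            n_haplotypes = 107, p = 400, n_rep = 50,
                            priors = hn_priors(), control = hn_control(),
                            seed = 1,
                            score_mutation_effects = identical(generative, "mutation")) {
  generative <- match.arg(generative)
  models <- match.arg(models, c("hn", "ih", "mutation"), several.ok = TRUE)
  scenarios <- match.arg(scenarios, c("all_observed", "some_unobserved"),
                         several.ok = TRUE)
  phy <- generate_random_phylogeny(n_haplotypes,
                                   seed = substream_seed(seed, "phylogeny"))
  dag <- phy$dag; U <- phy$U
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    for (sc in scenarios) {
      per_rep <- list()
      n_conv <- 0L
      for (r in seq_len(n_rep)) {
        rseed <- substream_seed(seed, paste(generative, ci, sc), r)
        sim <- if (generative == "hn") {
          simulate_from_hn(dag, rho = cells$rho[ci], ve_over_vhc = cells$ve[ci],
                           p = p, scenario = sc, seed = rseed)
        } else {
          simulate_from_mutation_model(dag, U, lam = cells$lam[ci],
                                       sigma2_e = cells$ve[ci], p = p,
                                       scenario = sc, seed = rseed)
        }
        fits <- list()
        ok <- TRUE
        for (mdl in models) {
          ft <- tryCatch(hapnet(y = sim$y, Z = sim$Z, dag = dag, U = U,
                                haplotype = mdl, priors = priors,
                                control = control),
                         error = function(e) NULL)
          if (is.null(ft) || !ft$converged) { ok <- FALSE; break }
          fits[[mdl]] <- ft
        }
        if (!ok) next
        n_conv <- n_conv + 1L
        per_rep[[length(per_rep) + 1L]] <-
          score_replicate(sim, fits, dag, U, score_mutation_effects)
      }
      if (!length(per_rep)) {
        rows[[length(rows) + 1L]] <-
          data.frame(cell = ci, cells[ci, , drop = FALSE], scenario = sc,
                     stratum = NA, comparison = NA, mean_rcrps = NA,
                     n_converged = 0L, flagged = TRUE, row.names = NULL)
        next
      }
      agg <- do.call(rbind, per_rep)
      sp <- split(agg$rcrps, list(agg$stratum, agg$comparison), drop = TRUE)
      for (key in names(sp)) {
        parts <- strsplit(key, "\\.")[[1L]]
        rows[[length(rows) + 1L]] <-
          data.frame(cell = ci, cells[ci, , drop = FALSE], scenario = sc,
                     stratum = parts[1L], comparison = parts[2L],
                     mean_rcrps = mean(sp[[key]]),
                     n_converged = n_conv,
                     flagged = n_conv < n_rep / 2,
                     row.names = NULL)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Score one replicate: per-stratum RCRPS between fitted models on haplotype
# effects, and (optionally) RCRPS of mutation effects, HN vs mutation model.
score_replicate <- function(sim, fits, dag, U, score_mutation_effects) {
  scored <- dag$node_ids[!dag$is_phantom]
  truth <- sim$true_h[scored]
  strat <- stratify_by_observation(sim$Z[, scored, drop = FALSE])
  crps <- lapply(fits, hap_crps, truth = sim$true_h, ids = scored)
  out <- list()
  pair <- function(a, b) {
    if (!all(c(a, b) %in% names(fits))) return(NULL)
    res <- list()
    for (st in levels(strat)) {
      sel <- strat == st
      if (!any(sel)) next
      res[[st]] <- data.frame(stratum = st,
                              comparison = paste0(a, "_vs_", b),
                              rcrps = rcrps(crps[[a]][sel], crps[[b]][sel]))
    }
    res$all <- data.frame(stratum = "all", comparison = paste0(a, "_vs_", b),
                          rcrps = rcrps(crps[[a]], crps[[b]]))
    do.call(rbind, res)
  }
  out$hn_ih <- pair("hn", "ih")
  out$mut_ih <- pair("mutation", "ih")
  out$hn_mut <- pair("hn", "mutation")
  if (score_mutation_effects && !is.null(sim$true_v) &&
      all(c("hn", "mutation") %in% names(fits))) {
    vh <- estimate_mutation_effects(fits$hn, U)
    vm_idx <- fits$mutation$model$blocks$hap$idx
    vm_mean <- fits$mutation$latent_mean[vm_idx]
    vm_sd <- fits$mutation$latent_sd[vm_idx]
    cr_h <- crps_gaussian(vh$mean, vh$sd, sim$true_v[vh$site])
    cr_m <- crps_gaussian(vm_mean, vm_sd, sim$true_v)
    out$vmut <- data.frame(stratum = "mutations",
                           comparison = "hn_vs_mutation_effects",
                           rcrps = rcrps(cr_h, cr_m))
  }
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}
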