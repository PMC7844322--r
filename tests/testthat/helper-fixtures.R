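# Shared fixtures and independent oracles used across the suite.

# Worked-example phylogeny: ancestral haplotype i; two-mutation branches are
# pre-expanded with the intermediate haplotypes gp (g') and hp (h') so every
# edge carries one mutation. Conditional structure:
# i -> g' -> g -> {a, f, b, c};  i -> h' -> {h, d};  h -> e.
fig_example_dag <- function() {
  haplotype_dag(data.frame(
    child  = c("gp", "g", "a", "f", "b", "c", "hp", "h", "d", "e"),
    parent = c("i", "gp", "g", "g", "g", "g", "i", "hp", "hp", "h")))
}

# 5 haplotypes x 7 sites allele table of the worked example.
fig_example_U <- function() {
  U <- rbind(a = c(1, 0, 0, 1, 1, 0, 0),
             b = c(1, 0, 0, 0, 1, 1, 0),
             c = c(1, 0, 0, 0, 1, 1, 0),
             d = c(0, 1, 0, 0, 0, 0, 1),
             e = c(0, 1, 1, 0, 0, 0, 1))
  colnames(U) <- paste0("site", 1:7)
  U
}

# Random DAG with multi-parent structure: node 1 is a root; each later node
# is either an extra root (prob 0.15) or has 1-3 parents among earlier nodes.
random_dag <- function(n, seed) {
  set.seed(seed)
  child <- parent <- character(0)
  ids <- paste0("n", seq_len(n))
  child <- ids[1]; parent <- NA_character_
  for (i in 2:n) {
    if (stats::runif(1) < 0.15) {
      child <- c(child, ids[i]); parent <- c(parent, NA_character_)
    } else {
      k <- sample.int(min(3L, i - 1L), 1L)
      ps <- sample(ids[seq_len(i - 1L)], k)
      child <- c(child, rep(ids[i], k)); parent <- c(parent, ps)
    }
  }
  haplotype_dag(data.frame(child = child, parent = parent))
}

# Independent dense construction of T^-1 and D straight from the definitions
# (separate code path from the package internals).
dense_TD <- function(dag, rho) {
  ids <- dag$node_ids[dag$topo_order]
  n <- length(ids)
  Tinv <- diag(n); dimnames(Tinv) <- list(ids, ids)
  Ddiag <- numeric(n)
  for (i in seq_len(n)) {
    ps <- dag$parents[[ids[i]]]
    k <- length(ps)
    if (k == 0L) {
      Ddiag[i] <- 1 / (1 - rho^2)
    } else {
      Ddiag[i] <- 1 / k
      Tinv[i, ps] <- -rho / k
    }
  }
  list(Tinv = Tinv, Ddiag = Ddiag, ids = ids)
}

# Dense precision oracle (1/s2hc) T^-T D^-1 T^-1.
dense_precision_oracle <- function(dag, rho, sigma2_hm = 1) {
  td <- dense_TD(dag, rho)
  s2hc <- sigma2_hm * (1 - rho^2)
  t(td$Tinv) %*% diag(1 / td$Ddiag, length(td$Ddiag)) %*% td$Tinv / s2hc
}

# Dense marginal-likelihood oracle for a model with optional fixed effects
# and an hn/ih/mutation haplotype term: log N(y; 0, W V_x W' + s2e I).
dense_loglik_oracle <- function(model, theta) {
  Vxs <- list()
  if (!is.null(model$blocks$beta))
    Vxs$beta <- diag(model$priors$fixed_prior_var, model$blocks$beta$q)
  for (nm in names(model$terms)) {
    tr <- model$terms[[nm]]
    Vxs[[nm]] <- switch(tr$type,
      hn = hn_covariance(model$dag, theta$rho, theta$s2_hap),
      iid = diag(if (nm == "hap") theta$s2_hap else theta[[paste0("s2_", nm)]], tr$q),
      mutation = diag(theta$s2_hap, tr$q),
      user_precision = solve(tr$precision) *
        (if (nm == "hap") theta$s2_hap else theta[[paste0("s2_", nm)]]))
  }
  Vx <- as.matrix(Matrix::bdiag(Vxs))
  W <- model$W
  Vy <- W %*% Vx %*% t(W) + diag(theta$s2_e, model$p)
  p <- model$p
  as.numeric(-0.5 * (p * log(2 * pi) + determinant(Vy)$modulus +
                       t(model$y) %*% solve(Vy, model$y)))
}

# Dense latent posterior mean at fixed hyper-parameters.
dense_latent_mean_oracle <- function(model, theta) {
  Vxs <- list()
  if (!is.null(model$blocks$beta))
    Vxs$beta <- diag(model$priors$fixed_prior_var, model$blocks$beta$q)
  for (nm in names(model$terms)) {
    tr <- model$terms[[nm]]
    Vxs[[nm]] <- switch(tr$type,
      hn = hn_covariance(model$dag, theta$rho, theta$s2_hap),
      iid = diag(theta$s2_hap, tr$q),
      mutation = diag(theta$s2_hap, tr$q))
  }
  Vx <- as.matrix(Matrix::bdiag(Vxs))
  W <- model$W
  Vy <- W %*% Vx %*% t(W) + diag(theta$s2_e, model$p)
  as.numeric(Vx %*% t(W) %*% solve(Vy, model$y))
}

# Numerical-integration CRPS oracle: integral of (F(x) - 1{x >= y})^2 dx.
crps_numeric_oracle <- function(mu, sigma, truth) {
  f <- function(x) (stats::pnorm(x, mu, sigma) - as.numeric(x >= truth))^2
  lo <- min(mu - 12 * sigma, truth - 12 * sigma)
  hi <- max(mu + 12 * sigma, truth + 12 * sigma)
  stats::integrate(f, lo, hi, rel.tol = 1e-12, abs.tol = 1e-12)$value
}
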