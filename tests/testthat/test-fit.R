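small_fit_data <- function(seed = 3, n = 8, p = 24, rho = 0.8) {
  phy <- generate_random_phylogeny(n, seed = seed)
  sim <- simulate_from_hn(phy$dag, rho = rho, ve_over_vhc = 1, p = p,
                          scenario = "all_observed", seed = seed + 1)
  list(phy = phy, sim = sim)
}

test_that("posteriors are invariant to permuting individuals", {
  dd <- small_fit_data()
  f1 <- hapnet(y = dd$sim$y, Z = dd$sim$Z, dag = dd$phy$dag, haplotype = "hn",
               control = hn_control(n_points = 5))
  set.seed(9); perm <- sample(length(dd$sim$y))
  f2 <- hapnet(y = dd$sim$y[perm], Z = dd$sim$Z[perm, ], dag = dd$phy$dag,
               haplotype = "hn", control = hn_control(n_points = 5))
  expect_equal(f1$latent_mean, f2$latent_mean, tolerance = 1e-8)
  expect_equal(f1$latent_sd, f2$latent_sd, tolerance = 1e-8)
})

test_that("with no observations the posterior reduces to the prior", {
  d <- fig_example_dag()
  m <- hn_model(y = numeric(0), Z = character(0), dag = d, haplotype = "hn")
  f <- hapnet(model = m, control = hn_control(n_points = 5))
  expect_true(all(f$latent_mean == 0))
  # hyper posterior mass must track the prior: the rho tail statement of the
  # PC prior, P(rho > 0.7) = 0.8, should be reproduced by the grid posterior
  hs <- hyper_samples(f, 40000, seed = 8)
  expect_equal(mean(hs$rho > 0.7), 0.8, tolerance = 0.03)
})

test_that("fixing rho at zero reproduces the independent-haplotype model", {
  # on a tree (k = 1 everywhere) the network prior at rho = 0 is i.i.d.
  set.seed(21)
  dt <- haplotype_dag(data.frame(child = c("r", "a", "b", "c", "d"),
                                 parent = c(NA, "r", "a", "a", "b")))
  p <- 15
  Z <- sample(dt$node_ids, p, replace = TRUE)
  y <- rnorm(p)
  f0 <- hapnet(y = y, Z = Z, dag = dt, haplotype = "hn", fixed = list(rho = 0))
  fi <- hapnet(y = y, Z = Z, dag = dt, haplotype = "ih")
  # same latents up to node ordering (the two fits take independent
  # optimisation paths, so agreement is to numerical-integration accuracy)
  expect_equal(f0$latent_mean[dt$node_ids], fi$latent_mean[dt$node_ids],
               tolerance = 1e-4)
  expect_equal(f0$latent_sd[dt$node_ids], fi$latent_sd[dt$node_ids],
               tolerance = 1e-4)
})

test_that("doubling the grid resolution barely moves the latent summaries", {
  dd <- small_fit_data(seed = 3, n = 20, p = 100, rho = 0.7)
  f7 <- hapnet(y = dd$sim$y, Z = dd$sim$Z, dag = dd$phy$dag, haplotype = "hn",
               control = hn_control(n_points = 7))
  f13 <- hapnet(y = dd$sim$y, Z = dd$sim$Z, dag = dd$phy$dag, haplotype = "hn",
                control = hn_control(n_points = 13))
  rel <- abs(f7$latent_mean - f13$latent_mean) / pmax(f13$latent_sd, 1e-8)
  expect_lt(max(rel), 0.01)
})

test_that("the conditional-variance transform matches closed forms", {
  dd <- small_fit_data()
  # degenerate posteriors via fixed hyper-parameters
  f <- hapnet(y = dd$sim$y, Z = dd$sim$Z, dag = dd$phy$dag, haplotype = "hn",
              fixed = list(rho = 0, s2_hap = 2.5))
  cv <- conditional_variance_posterior(f, n_samples = 500, seed = 4)
  expect_equal(cv$mean, 2.5, tolerance = 1e-10)
  f2 <- hapnet(y = dd$sim$y, Z = dd$sim$Z, dag = dd$phy$dag, haplotype = "hn",
               fixed = list(rho = 0.5, s2_hap = 4))
  cv2 <- conditional_variance_posterior(f2, n_samples = 500, seed = 4)
  expect_equal(cv2$mean, 3, tolerance = 1e-10)

  # free fit: the sampled mean approaches the grid-exact expectation as the
  # cell width shrinks (the within-cell jitter adds O(step^2) smoothing bias)
  f3 <- hapnet(y = dd$sim$y, Z = dd$sim$Z, dag = dd$phy$dag, haplotype = "hn",
               control = hn_control(n_points = 13))
  th <- f3$hyper$theta
  rho <- tanh(th[, "rho.hap"] / 2); s2 <- exp(th[, "log_s2.hap"])
  exact <- sum(f3$hyper$weights * s2 * (1 - rho^2))
  cv3 <- conditional_variance_posterior(f3, n_samples = 20000, seed = 5)
  mcse <- stats::sd(cv3$samples) / sqrt(length(cv3$samples))
  expect_lt(abs(cv3$mean - exact), max(3 * mcse, 0.02 * exact))
})

test_that("back-solved mutation effects agree with dense least squares", {
  # left-inverse identity: exact h = U v recovers v (full-rank U)
  set.seed(5)
  U <- matrix(rbinom(60, 1, 0.4), 10, 6)
  while (qr(crossprod(U))$rank < 6) U <- matrix(rbinom(60, 1, 0.4), 10, 6)
  rownames(U) <- paste0("h", 1:10)
  v <- rnorm(6)
  out <- mutation_effects_from_h(U, as.numeric(U %*% v))
  expect_equal(out$mean, v, tolerance = 1e-10)
  # identity U: v == h
  Ui <- diag(1L, 4); rownames(Ui) <- paste0("h", 1:4)
  hm <- rnorm(4)
  expect_equal(mutation_effects_from_h(Ui, hm)$mean, hm, tolerance = 1e-12)
  # random full-rank U vs explicit dense solve, with covariance propagation
  U8 <- matrix(rbinom(32, 1, 0.5), 8, 4)
  while (qr(crossprod(U8))$rank < 4) U8 <- matrix(rbinom(32, 1, 0.5), 8, 4)
  rownames(U8) <- paste0("h", 1:8)
  hmean <- rnorm(8)
  S <- crossprod(matrix(rnorm(64), 8, 8)) / 8
  got <- mutation_effects_from_h(U8, hmean, S)
  M <- solve(crossprod(U8)) %*% t(U8)
  expect_equal(got$mean, as.numeric(M %*% hmean), tolerance = 1e-10)
  expect_equal(got$var, diag(M %*% S %*% t(M)), tolerance = 1e-10)
})

test_that("mutation-effect posteriors from a fit detect rank deficiency", {
  dd <- small_fit_data()
  f <- hapnet(y = dd$sim$y, Z = dd$sim$Z, dag = dd$phy$dag, haplotype = "hn",
              control = hn_control(n_points = 5))
  me <- estimate_mutation_effects(f, dd$phy$U)
  expect_equal(nrow(me), ncol(dd$phy$U))
  expect_true(all(me$sd > 0))
  # duplicated site column makes U'U singular
  Ubad <- cbind(dd$phy$U, dup = dd$phy$U[, 1])
  expect_error(estimate_mutation_effects(f, Ubad), "rank deficient")
})

test_that("methods expose coherent summaries and predictions", {
  dd <- small_fit_data()
  f <- hapnet(y = dd$sim$y, Z = dd$sim$Z, dag = dd$phy$dag, haplotype = "hn",
              control = hn_control(n_points = 5))
  expect_output(print(f), "converged")
  s <- summary(f)
  expect_true(all(c("rho", "s2_hap", "s2_e") %in% s$hyper$parameter))
  expect_equal(length(coef(f)), 8)
  expect_equal(fitted(f) + residuals(f), dd$sim$y, tolerance = 1e-12)
  pr <- predict(f, haplotypes = c("H3", "H1"))
  expect_identical(pr$id, c("H3", "H1"))
  expect_error(predict(f, haplotypes = "nope"), "unknown")
  ys <- simulate(f, nsim = 3, seed = 2)
  expect_equal(dim(ys), c(length(dd$sim$y), 3))
  # deterministic given the seed
  expect_identical(ys, simulate(f, nsim = 3, seed = 2))
})

test_that("non-positive-definite models raise informative inference errors", {
  d <- fig_example_dag()
  m <- hn_model(y = rnorm(3), Z = c("a", "b", "c"), dag = d, haplotype = "hn")
  expect_error(log_marginal_likelihood(m, list(rho = 1.2, s2_hap = 1, s2_e = 1)))
})
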