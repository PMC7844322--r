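test_that("the closed-form Gaussian CRPS matches numerical integration", {
  worst <- 0
  for (z in c(-3, -1, -0.2, 0, 0.5, 2)) {
    for (sg in c(0.2, 1, 3.7)) {
      mu <- 0.4; truth <- mu + z * sg
      worst <- max(worst, abs(crps_gaussian(mu, sg, truth) -
                                crps_numeric_oracle(mu, sg, truth)))
    }
  }
  expect_lt(worst, 1e-8)
  # calibrated point forecast: centred predictive with unit sd
  expect_equal(crps_gaussian(0, 1, 0), 2 * stats::dnorm(0) - 1 / sqrt(pi),
               tolerance = 1e-12)
  expect_equal(crps_gaussian(0, 1, 0), 0.23369, tolerance = 1e-4)
  # degenerate forecast and translation invariance
  expect_equal(crps_gaussian(1.3, 0, 1.3), 0)
  expect_equal(crps_gaussian(1.3, 0, 2), 0.7)
  expect_equal(crps_gaussian(0.2 + 5, 0.7, 1.1 + 5),
               crps_gaussian(0.2, 0.7, 1.1), tolerance = 1e-12)
  expect_error(crps_gaussian(0, -1, 0), "sigma")
})

test_that("RCRPS is a signed log ratio with exact antisymmetry", {
  a <- c(0.2, 0.4, 0.1)
  expect_equal(rcrps(a, a), 0)
  expect_equal(rcrps(a / 2, a), log(0.5), tolerance = 1e-12)
  set.seed(31)
  for (i in 1:100) {
    x <- stats::runif(7, 0.01, 2); y <- stats::runif(7, 0.01, 2)
    expect_equal(rcrps(x, y), -rcrps(y, x), tolerance = 1e-12)
    expect_identical(rcrps(x, y) < 0, mean(x) < mean(y))
  }
  expect_error(rcrps(a, c(0, 0, 0)), "reference")
  expect_error(rcrps(a, a[1:2]), "length")
})

test_that("RMSE matches its definition", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(1:5 + 2, 1:5), 2)
  set.seed(2)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(rmse(x, y), sqrt(mean((x - y)^2)), tolerance = 1e-12)
})

test_that("haplotypes stratify by phenotype-observation count", {
  Z <- matrix(0, 6, 3)
  Z[1, 2] <- 1; Z[2:6, 3] <- 1
  st <- stratify_by_observation(Z)
  expect_equal(as.character(st), c("never", "once", "several"))
  # phantoms are never scored as observed
  st2 <- stratify_by_observation(Z, is_phantom = c(FALSE, TRUE, FALSE))
  expect_equal(as.character(st2), c("never", "never", "several"))

  phy <- generate_random_phylogeny(40, seed = 3)
  s1 <- simulate_from_hn(phy$dag, 0.5, 1, p = 80, scenario = "all_observed",
                         seed = 1)
  expect_false(any(stratify_by_observation(s1$Z) == "never"))
  s2 <- simulate_from_hn(phy$dag, 0.5, 1, p = 80, scenario = "some_unobserved",
                         seed = 1)
  expect_equal(sum(stratify_by_observation(s2$Z) == "never"), round(0.15 * 40))
})

test_that("variance proportions normalise named components", {
  vp <- variance_proportions(c(a = 1, b = 1))
  expect_equal(vp$proportion, c(0.5, 0.5))
  vp2 <- variance_proportions(c(x = 1, y = 3))
  expect_equal(vp2$proportion, c(0.25, 0.75))
  set.seed(9)
  for (i in 1:20) {
    v <- stats::runif(4, 0, 5)
    names(v) <- letters[1:4]
    expect_equal(sum(variance_proportions(v)$proportion), 1, tolerance = 1e-12)
  }
  expect_error(variance_proportions(c(a = 0, b = 0)), "zero")
  expect_error(variance_proportions(c(a = 1)), "two")
})

test_that("a degenerate one-replicate study produces the full score table", {
  cells <- data.frame(rho = 0.7, ve = 1)
  tab <- replicate_study("hn", cells, scenarios = "all_observed",
                         models = c("hn", "ih", "mutation"),
                         n_haplotypes = 12, p = 20, n_rep = 1,
                         control = hn_control(n_points = 5), seed = 7)
  expect_true(all(c("stratum", "comparison", "mean_rcrps", "n_converged")
                  %in% names(tab)))
  expect_true(all(tab$n_converged == 1))
  expect_true(all(c("hn_vs_ih", "mutation_vs_ih", "hn_vs_mutation")
                  %in% tab$comparison))
  # all_observed: nothing in the never stratum
  expect_false("never" %in% tab$stratum)
  # aggregates are finite log ratios
  expect_true(all(is.finite(tab$mean_rcrps)))
})

test_that("study aggregation is invariant to haplotype ordering", {
  set.seed(4)
  phy <- generate_random_phylogeny(15, seed = 2)
  sim <- simulate_from_hn(phy$dag, 0.8, 1, p = 30, scenario = "all_observed",
                          seed = 5)
  f <- hapnet(y = sim$y, Z = sim$Z, dag = phy$dag, haplotype = "hn",
              control = hn_control(n_points = 5))
  he <- haplotype_effects(f)
  cr <- crps_gaussian(he$mean, he$sd, sim$true_h[he$id])
  perm <- sample(length(cr))
  expect_equal(rcrps(cr, 2 * cr), rcrps(cr[perm], 2 * cr[perm]),
               tolerance = 1e-12)
  expect_equal(rmse(he$mean, sim$true_h[he$id]),
               rmse(he$mean[perm], sim$true_h[he$id][perm]), tolerance = 1e-12)
})
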