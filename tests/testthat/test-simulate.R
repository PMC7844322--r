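test_that("random phylogenies have infinite-sites structure and are seeded", {
  p2 <- generate_random_phylogeny(2, seed = 1)
  expect_length(p2$dag$node_ids, 2)
  expect_equal(unname(p2$U), matrix(c(0L, 1L), 2, 1))
  expect_error(generate_random_phylogeny(1), "at least 2")

  phy <- generate_random_phylogeny(107, seed = 4)
  expect_length(phy$dag$node_ids, 107)
  expect_equal(dim(phy$U), c(107, 106))
  expect_true(all(unlist(phy$dag$edge_mutations) == 1L))
  expect_length(starting_haplotypes(phy$dag), 1)
  # each haplotype differs from its parent at exactly one site
  for (id in setdiff(phy$dag$node_ids, "H1")) {
    par <- phy$dag$parents[[id]]
    expect_equal(sum(phy$U[id, ] != phy$U[par, ]), 1)
  }
  phy2 <- generate_random_phylogeny(107, seed = 4)
  expect_identical(phy$U, phy2$U)
  expect_identical(phy$dag$parents, phy2$dag$parents)
  expect_false(identical(phy$U, generate_random_phylogeny(107, seed = 5)$U))
})

test_that("observation scenarios hit their quotas exactly", {
  phy <- generate_random_phylogeny(107, seed = 2)
  s1 <- simulate_from_hn(phy$dag, rho = 0.5, ve_over_vhc = 1, p = 400,
                         scenario = "all_observed", seed = 11)
  cs <- colSums(s1$Z)
  expect_equal(sum(cs == 1), round(0.15 * 107))
  expect_true(all(cs >= 1))
  expect_equal(sum(cs), 400)

  s2 <- simulate_from_hn(phy$dag, rho = 0.5, ve_over_vhc = 1, p = 400,
                         scenario = "some_unobserved", seed = 12)
  cs2 <- colSums(s2$Z)
  expect_equal(sum(cs2 == 0), round(0.15 * 107))
  expect_true(all(cs2[cs2 > 0] >= 1))
  expect_equal(sum(cs2), 400)

  expect_error(simulate_from_hn(phy$dag, 0.5, 1, p = 50,
                                scenario = "all_observed", seed = 1),
               "p >= n")
})

test_that("phenotypes decompose exactly as y = Z h + e", {
  phy <- generate_random_phylogeny(30, seed = 6)
  s <- simulate_from_hn(phy$dag, rho = 0.7, ve_over_vhc = 2, p = 60,
                        scenario = "all_observed", seed = 3)
  expect_equal(s$y, as.numeric(s$Z %*% s$true_h) + s$e, tolerance = 1e-12)
  expect_equal(s$params$sigma2_hc, 1)
  expect_equal(s$params$sigma2_e, 2)
  sm <- simulate_from_mutation_model(phy$dag, phy$U, lam = 0.5, sigma2_e = 1,
                                     p = 60, scenario = "all_observed", seed = 4)
  expect_equal(sm$y, as.numeric(sm$Z %*% sm$true_h) + sm$e, tolerance = 1e-12)
  # identical seeds give byte-identical data
  sm2 <- simulate_from_mutation_model(phy$dag, phy$U, lam = 0.5, sigma2_e = 1,
                                      p = 60, scenario = "all_observed", seed = 4)
  expect_identical(sm, sm2)
})

test_that("network-model draws match the analytic covariance", {
  # 3-node chain at rho = 0.5: sample moments over many draws against the
  # dense covariance oracle, within 5 Monte Carlo standard errors
  dc <- haplotype_dag(data.frame(child = c("i", "j", "k"),
                                 parent = c(NA, "i", "j")))
  rho <- 0.5
  V <- hn_covariance(dc, rho, 1 / (1 - rho^2)) # s2hc = 1
  R <- 20000
  H <- matrix(0, R, 3)
  for (r in seq_len(R)) {
    s <- simulate_from_hn(dc, rho = rho, ve_over_vhc = 1, p = 3,
                          scenario = "all_observed", seed = r)
    H[r, ] <- s$true_h[c("i", "j", "k")]
  }
  Sv <- stats::cov(H)
  # var of a sample (co)variance of Gaussians ~ (V_ii V_jj + V_ij^2)/R
  for (a in 1:3) for (b in 1:3) {
    se <- sqrt((V[a, a] * V[b, b] + V[a, b]^2) / R)
    expect_lt(abs(Sv[a, b] - V[a, b]), 5 * se)
  }
})

test_that("mutation-model draws respect the causal mixture and unit variance", {
  phy <- generate_random_phylogeny(107, seed = 8)
  s1 <- simulate_from_mutation_model(phy$dag, phy$U, lam = 1, sigma2_e = 1,
                                     p = 400, scenario = "all_observed", seed = 2)
  expect_true(all(s1$true_v != 0)) # every site causal at lam = 1
  expect_equal(stats::var(s1$true_h), 1, tolerance = 1e-12)

  # causal-site count is Binomial(106, 0.1): check the replicate mean
  R <- 400
  counts <- vapply(seq_len(R), function(r) {
    s <- simulate_from_mutation_model(phy$dag, phy$U, lam = 0.1, sigma2_e = 1,
                                      p = 100, scenario = "some_unobserved",
                                      seed = 1000 + r)
    sum(s$true_v != 0)
  }, numeric(1))
  mu <- 106 * 0.1
  se <- sqrt(106 * 0.1 * 0.9 / R)
  expect_lt(abs(mean(counts) - mu), 5 * se)
  expect_true(all(counts >= 1)) # resampling guarantees a non-empty mask
  expect_error(simulate_from_mutation_model(phy$dag, phy$U, lam = 0,
                                            sigma2_e = 1, p = 400,
                                            scenario = "all_observed"), "lam")
})
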