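# sigma2_hm chosen so that sigma2_hc = 1 makes the frozen matrices easy to read.
s2hm_for <- function(rho) 1 / (1 - rho^2)

test_that("frozen small-graph precisions match the worked algebra", {
  # single starting node: Q = (1 - rho^2)/s2hc = 1/s2hm
  d1 <- haplotype_dag(data.frame(child = "i", parent = NA))
  for (rho in c(-0.7, 0, 0.5, 0.9)) {
    Q <- as.matrix(hn_precision(d1, rho, s2hm_for(rho))$Q)
    expect_equal(Q[1, 1], 1 - rho^2, tolerance = 1e-12)
  }

  # chain i -> j -> k at rho = 0.5, s2hc = 1
  dc <- haplotype_dag(data.frame(child = c("i", "j", "k"),
                                 parent = c(NA, "i", "j")))
  Q <- as.matrix(hn_precision(dc, 0.5, s2hm_for(0.5))$Q)
  expect_equal(Q, matrix(c(1, -0.5, 0, -0.5, 1.25, -0.5, 0, -0.5, 1), 3, 3,
                         dimnames = list(c("i", "j", "k"), c("i", "j", "k"))),
               tolerance = 1e-12)

  # star: d with independent parents a, b, c at rho = 0.6, s2hc = 1
  ds <- haplotype_dag(data.frame(child = c("a", "b", "c", "d", "d", "d"),
                                 parent = c(NA, NA, NA, "a", "b", "c")))
  Q <- as.matrix(hn_precision(ds, 0.6, s2hm_for(0.6))$Q)
  expect_equal(unname(diag(Q)[c("a", "b", "c")]), rep(0.76, 3), tolerance = 1e-12)
  expect_equal(unname(Q["d", "d"]), 3, tolerance = 1e-12)
  expect_equal(unname(Q["d", c("a", "b", "c")]), rep(-0.6, 3), tolerance = 1e-12)
  expect_equal(unname(c(Q["a", "b"], Q["a", "c"], Q["b", "c"])), rep(0.12, 3),
               tolerance = 1e-12)
})

test_that("sparse assembly equals the dense T/D oracle and inverts the covariance", {
  worst_q <- 0; worst_inv <- 0; min_eig <- Inf
  for (i in 1:200) {
    set.seed(i)
    n <- sample(2:12, 1)
    rho <- stats::runif(1, -0.99, 0.99)
    s2hm <- stats::runif(1, 0.2, 3)
    d <- random_dag(n, seed = i * 13)
    Q <- as.matrix(hn_precision(d, rho, s2hm)$Q)
    Qo <- dense_precision_oracle(d, rho, s2hm)
    worst_q <- max(worst_q, max(abs(Q - Qo)))
    V <- hn_covariance(d, rho, s2hm)
    worst_inv <- max(worst_inv, max(abs(Q %*% V - diag(nrow(Q)))))
    min_eig <- min(min_eig, min(eigen(Q, symmetric = TRUE)$values))
  }
  expect_lt(worst_q, 1e-10)
  expect_lt(worst_inv, 1e-8)
  expect_gt(min_eig, 0)
})

test_that("single-parent trees are stationary: every marginal variance is s2hm", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(3:12, 1)
    # random tree: exactly one parent per non-root node
    parent <- c(NA, sapply(2:n, function(i) sample(i - 1, 1)))
    ids <- paste0("t", 1:n)
    d <- haplotype_dag(data.frame(child = ids,
                                  parent = c(NA, ids[parent[-1]])))
    rho <- stats::runif(1, -0.95, 0.95)
    s2hm <- stats::runif(1, 0.5, 2)
    V <- hn_covariance(d, rho, s2hm)
    expect_equal(unname(diag(V)), rep(s2hm, n), tolerance = 1e-10)
  }
})

test_that("rho = 0 gives independent effects on any DAG topology (tree case)", {
  # the covariance collapses to s2hm * I when no dependency flows along edges
  dc <- haplotype_dag(data.frame(child = c("i", "j", "k"),
                                 parent = c(NA, "i", "j")))
  V <- hn_covariance(dc, 0, 1.7)
  expect_equal(V, diag(1.7, 3, 3) + 0 * V, tolerance = 1e-12, ignore_attr = TRUE)
  Q <- as.matrix(hn_precision(dc, 0, 1.7)$Q)
  expect_equal(Q, diag(1 / 1.7, 3), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the multi-parent conditional law is recoverable from Q", {
  # childless node with k parents: h | parents ~ N(rho/k * sum, s2hc/k)
  ds <- haplotype_dag(data.frame(child = c("a", "b", "c", "d", "d", "d"),
                                 parent = c(NA, NA, NA, "a", "b", "c")))
  rho <- 0.6; s2hm <- 2.5; s2hc <- s2hm * (1 - rho^2)
  Q <- as.matrix(hn_precision(ds, rho, s2hm)$Q)
  coefs <- -Q["d", c("a", "b", "c")] / Q["d", "d"]
  expect_equal(unname(coefs), rep(rho / 3, 3), tolerance = 1e-12)
  expect_equal(1 / Q["d", "d"], s2hc / 3, tolerance = 1e-12, ignore_attr = TRUE)
  # general (non-childless) nodes: regression on ancestors via T^-1 rows
  prec <- hn_precision(ds, rho, s2hm)
  Ti <- as.matrix(prec$T_inv)
  expect_equal(unname(Ti["d", c("a", "b", "c")]), rep(-rho / 3, 3), tolerance = 1e-12)
})

test_that("multi-region precision is block diagonal with exact determinant", {
  dc <- haplotype_dag(data.frame(child = c("i", "j", "k"),
                                 parent = c(NA, "i", "j")))
  rho <- 0.5; s2hm <- s2hm_for(rho)
  one <- hn_precision(dc, rho, s2hm)
  two <- hn_precision_multiregion(list(dc, dc), rho, s2hm)
  expect_equal(as.matrix(two$Q[1:3, 1:3]), as.matrix(one$Q), ignore_attr = TRUE)
  expect_equal(as.matrix(two$Q[4:6, 4:6]), as.matrix(one$Q), ignore_attr = TRUE)
  expect_true(all(as.matrix(two$Q[1:3, 4:6]) == 0))
  expect_error(hn_precision_multiregion(list(), rho), "at least one")

  # joint density normalisation: det(s2hc * Q) = (1 - rho^2)^m * prod(k_i)
  # with one starting haplotype per region (m regions)
  for (m in 1:3) {
    dags <- rep(list(dc), m)
    pm <- hn_precision_multiregion(dags, rho, s2hm)
    ld <- as.numeric(Matrix::determinant(pm$Q * pm$sigma2_hc)$modulus)
    expect_equal(ld, m * log(1 - rho^2), tolerance = 1e-10)
  }
})

test_that("a multi-mutation edge is rejected until phantoms are inserted", {
  d <- haplotype_dag(data.frame(child = "g", parent = "i", n_mutations = 3))
  expect_error(hn_precision(d, 0.5), "phantom")
  expect_silent(hn_precision(insert_phantom_haplotypes(d), 0.5))
  expect_error(hn_precision(fig_example_dag(), 1.2), "rho")
})

test_that("precision matrices export to MatrixMarket text", {
  f <- withr::local_tempfile(fileext = ".mtx")
  write_precision_mm(hn_precision(fig_example_dag(), 0.7), f)
  M <- Matrix::readMM(f)
  expect_equal(dim(M), c(11, 11))
})
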