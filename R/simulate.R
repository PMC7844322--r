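#' Generate a random haplotype phylogeny under infinite sites
#'
#' Builds a single-root tree by sequential random attachment: each new
#' haplotype copies a uniformly chosen existing haplotype and gains one new
#' mutated site, so n haplotypes segregate n - 1 biallelic sites and every
#' edge carries exactly one mutation. This emulates the shape of a
#' coalescent-derived haplotype genealogy at the dimensions used in the
#' simulation study (107 haplotypes, 106 mutations) without requiring an
#' external coalescent engine.
#'
#' @param n_haplotypes number of unique haplotypes (>= 2)
#' @param seed integer seed; the same seed gives an identical phylogeny
#' @return list with `dag` (a `haplotype_dag`) and `U` (n x (n-1) 0/1 allele
#'   matrix, haplotype ids `H1..Hn`, site ids `s1..s(n-1)`)
#' @examples
#' phy <- generate_random_phylogeny(5, seed = 1)
#' phy$dag
#' @export
generate_random_phylogeny <- function(n_haplotypes, seed = 1) {
  n <- as.integer(n_haplotypes)
  if (n < 2L) stop("need at least 2 haplotypes")
  with_seed(seed, {
    ids <- paste0("H", seq_len(n))
    parent <- c(NA_integer_, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
    U <- matrix(0L, n, n - 1L, dimnames = list(ids, paste0("s", seq_len(n - 1L))))
    for (i in 2:n) {
      U[i, ] <- U[parent[i], ]
      U[i, i - 1L] <- 1L
    }
    dag <- haplotype_dag(data.frame(child = ids,
                                    parent = c(NA_character_, ids[parent[-1L]]),
                                    n_mutations = 1L))
    list(dag = dag, U = U)
  })
}

# Assign p individuals to haplotypes under the two observation scenarios.
# all_observed: round(0.15 n) haplotypes carry exactly one individual each,
#   every other haplotype carries at least one, remainder uniform.
# some_unobserved: round(0.15 n) haplotypes carry no individuals; the rest
#   carry at least one, remainder uniform.
# Returns the individual -> haplotype index assignment (into `nodes`).
assign_carriers <- function(nodes, p, scenario) {
  n <- length(nodes)
  s <- round(0.15 * n)
  if (scenario == "all_observed") {
    if (p < n) stop("all_observed scenario needs p >= n (every haplotype a carrier)")
    singles <- sample.int(n, s)
    rest <- setdiff(seq_len(n), singles)
    # the designated 15% carry exactly one individual; when capacity allows,
    # every other haplotype starts with two carriers so the "once" stratum is
    # exactly the designated set, then the remainder is assigned uniformly
    base <- if (p - s >= 2 * length(rest)) rep(rest, 2) else rest
    fill <- p - s - length(base)
    assign <- c(singles, base,
                if (fill > 0) rest[sample.int(length(rest), fill, replace = TRUE)])
  } else if (scenario == "some_unobserved") {
    unobs <- sample.int(n, s)
    rest <- setdiff(seq_len(n), unobs)
    if (p < length(rest)) stop("too few individuals to observe all non-hidden haplotypes")
    fill <- p - length(rest)
    assign <- c(rest, if (fill > 0) rest[sample.int(length(rest), fill, replace = TRUE)])
  } else stop("unknown scenario: ", scenario)
  assign[sample.int(length(assign))] # shuffle individual order
}

#' Simulate phenotypes from the haplotype network model
#'
#' Draws haplotype effects by ancestral recursion on the DAG (a starting
#' haplotype from the stationary N(0, sigma2_hm); a node with k parents from
#' N(rho/k * sum(parent effects), sigma2_hc / k)), with the conditional
#' variance fixed at sigma2_hc = 1 so the residual-to-conditional variance
#' ratio maps directly to the residual variance. Phenotypes are y = Z h + e
#' for haploid individuals assigned to haplotypes under one of two
#' observation scenarios: `"all_observed"` (15\% of haplotypes carried by
#' exactly one individual, the rest spread over the remainder with at least
#' one carrier each) or `"some_unobserved"` (15\% of haplotypes with no
#' phenotyped carrier).
#'
#' @param dag a `haplotype_dag` with single-mutation edges
#' @param rho autocorrelation of the haplotype process, |rho| < 1
#' @param ve_over_vhc residual variance relative to the conditional haplotype
#'   variance (> 0); equals sigma2_e because sigma2_hc = 1
#' @param p number of haploid phenotyped individuals
#' @param scenario `"all_observed"` or `"some_unobserved"`
#' @param seed integer seed
#' @return list of class `hn_simulation`: `y`, `Z` (p x n incidence over all
#'   nodes in dag order), `true_h` (all nodes, phantoms included),
#'   `epsilon` (innovations), `e` (residuals), `dag`, `scenario`, `params`,
#'   `seed`
#' @export
simulate_from_hn <- function(dag, rho, ve_over_vhc, p,
                             scenario = c("all_observed", "some_unobserved"),
                             seed = 1) {
  scenario <- match.arg(scenario)
  validate_dag(dag)
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (ve_over_vhc <= 0) stop("ve_over_vhc must be > 0")
  sigma2_hc <- 1
  sigma2_hm <- sigma2_hc / (1 - rho^2)
  sigma2_e <- ve_over_vhc * sigma2_hc
  ids <- dag$node_ids
  n <- length(ids)
  with_seed(seed, {
    h <- stats::setNames(numeric(n), ids)
    eps <- stats::setNames(numeric(n), ids)
    for (i in dag$topo_order) {
      id <- ids[i]
      ps <- dag$parents[[id]]
      k <- length(ps)
      if (k == 0L) {
        eps[id] <- stats::rnorm(1, 0, sqrt(sigma2_hm))
        h[id] <- eps[id]
      } else {
        eps[id] <- stats::rnorm(1, 0, sqrt(sigma2_hc / k))
        h[id] <- rho * mean(h[ps]) + eps[id]
      }
    }
    carriers <- ids[!dag$is_phantom]
    assign <- assign_carriers(carriers, p, scenario)
    hap_of_ind <- carriers[assign]
    Z <- matrix(0, p, n, dimnames = list(NULL, ids))
    Z[cbind(seq_len(p), match(hap_of_ind, ids))] <- 1
    e <- stats::rnorm(p, 0, sqrt(sigma2_e))
    y <- as.numeric(Z %*% h) + e
    structure(list(y = y, Z = Z, true_h = h, epsilon = eps, e = e,
                   dag = dag, scenario = scenario,
                   params = list(rho = rho, sigma2_hm = sigma2_hm,
                                 sigma2_hc = sigma2_hc, sigma2_e = sigma2_e),
                   seed = seed),
              class = "hn_simulation")
  })
}

#' Simulate phenotypes from the mutation model
#'
#' Each site is causal with probability `lam`; causal effects are i.i.d.
#' Gaussian. The haplotype effects h = U v are rescaled (by scaling v) so the
#' empirical variance of h across haplotypes is exactly 1, making the
#' residual variance directly comparable across parameter sets. Phenotypes
#' are y = Z h + e with the same observation scenarios as
#' [simulate_from_hn()].
#'
#' @param dag a `haplotype_dag` (used for the carrier set and bookkeeping)
#' @param U allele matrix over the non-phantom haplotypes of `dag`
#' @param lam probability that a site is causal, 0 < lam <= 1
#' @param sigma2_e residual variance
#' @param p number of haploid phenotyped individuals
#' @inheritParams simulate_from_hn
#' @return list of class `hn_simulation` with `true_v` (per-site effects
#'   after rescaling) in addition to the fields of [simulate_from_hn()];
#'   `true_h` covers the non-phantom haplotypes
#' @export
simulate_from_mutation_model <- function(dag, U, lam, sigma2_e, p,
                                         scenario = c("all_observed", "some_unobserved"),
                                         seed = 1) {
  scenario <- match.arg(scenario)
  validate_dag(dag)
  if (lam <= 0 || lam > 1) stop("lam must be in (0, 1]")
  if (sigma2_e <= 0) stop("sigma2_e must be > 0")
  carriers <- dag$node_ids[!dag$is_phantom]
  Us <- align_alleles(U, dag$node_ids, dag$is_phantom)
  q <- ncol(Us)
  with_seed(seed, {
    v <- NULL
    for (attempt in seq_len(100L)) {
      mask <- stats::runif(q) < lam
      if (any(mask)) { v <- ifelse(mask, stats::rnorm(q), 0); break }
    }
    if (is.null(v)) stop("all-causal-mask draws were empty after 100 attempts")
    h <- as.numeric(Us %*% v)
    sdh <- stats::sd(h)
    if (sdh == 0) stop("degenerate mutation draw: constant haplotype effects")
    v <- v / sdh
    h <- h / sdh
    names(h) <- rownames(Us)
    assign <- assign_carriers(carriers, p, scenario)
    hap_of_ind <- carriers[assign]
    Z <- matrix(0, p, length(carriers), dimnames = list(NULL, carriers))
    Z[cbind(seq_len(p), match(hap_of_ind, carriers))] <- 1
    e <- stats::rnorm(p, 0, sqrt(sigma2_e))
    y <- as.numeric(Z %*% h) + e
    structure(list(y = y, Z = Z, true_h = h, true_v = stats::setNames(v, colnames(Us)),
                   e = e, dag = dag, U = Us, scenario = scenario,
                   params = list(lam = lam, sigma2_e = sigma2_e),
                   seed = seed),
              class = "hn_simulation")
  })
}

#' @export
print.hn_simulation <- function(x, ...) {
  cat("Simulated haplotype-phenotype dataset (", x$scenario, ")\n", sep = "")
  cat("  individuals:", length(x$y), " haplotypes:", length(x$true_h), "\n")
  cat("  params:", paste(sprintf("%s = %.3g", names(x$params),
                                 unlist(x$params)), collapse = ", "), "\n")
  invisible(x)
}
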