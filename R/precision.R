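#' Hyper-parameters of the haplotype network process
#'
#' The process is parameterised by the autocorrelation rho (|rho| < 1 for
#' stationarity) and the marginal variance sigma2_hm of a starting haplotype;
#' the conditional (innovation) variance is derived as
#' sigma2_hc = sigma2_hm * (1 - rho^2).
#'
#' @param rho autocorrelation between a haplotype effect and its parent,
#'   |rho| < 1
#' @param sigma2_hm marginal variance (>= 0)
#' @return list with components `rho`, `sigma2_hm`, `sigma2_hc`
#' @export
ar_hyperparams <- function(rho, sigma2_hm = 1) {
  if (abs(rho) >= 1) stop("|rho| must be < 1 for stationarity")
  if (sigma2_hm < 0) stop("sigma2_hm must be >= 0")
  list(rho = rho, sigma2_hm = sigma2_hm, sigma2_hc = sigma2_hm * (1 - rho^2))
}

# Precompute the sparsity pattern of the haplotype precision for a DAG.
# Every non-zero entry of sigma2_hc * Q is a polynomial a + b*rho + c*rho^2;
# the pattern and coefficients do not depend on the hyper-parameters, so a
# template is built once per DAG and filled per rho. Triplets with equal
# (row, col) are aggregated. Indices are in topological node order.
precision_template <- function(dag) {
  validate_dag(dag)
  ids <- dag$node_ids[dag$topo_order]
  n <- length(ids)
  pos <- stats::setNames(seq_len(n), ids)
  ii <- jj <- integer(0)
  aa <- bb <- cc <- numeric(0)
  add <- function(i, j, a = 0, b = 0, c = 0) {
    ii <<- c(ii, i); jj <<- c(jj, j)
    aa <<- c(aa, a); bb <<- c(bb, b); cc <<- c(cc, c)
  }
  d_inv <- numeric(n) # D(rho)^{-1} diagonal: 1 - rho^2 coded via is_start, k otherwise
  is_start <- logical(n)
  kvec <- integer(n)
  for (id in ids) {
    i <- pos[[id]]
    ps <- dag$parents[[id]]
    k <- length(ps)
    kvec[i] <- k
    if (k == 0L) {
      is_start[i] <- TRUE
      add(i, i, a = 1, c = -1)            # 1 - rho^2 on the diagonal
      next
    }
    if (any(dag$edge_mutations[[id]] != 1L))
      stop("DAG has a multi-mutation edge; call insert_phantom_haplotypes() first")
    add(i, i, a = k)                       # k_i on the diagonal
    pidx <- pos[ps]
    for (j in pidx) {
      add(i, j, b = -1); add(j, i, b = -1) # -rho to each parent (symmetric)
      add(j, j, c = 1 / k)                 # + rho^2/k on each parent diagonal
    }
    if (k > 1L) {
      prs <- utils::combn(pidx, 2L)
      for (q in seq_len(ncol(prs))) {      # + rho^2/k between parents sharing the child
        add(prs[1L, q], prs[2L, q], c = 1 / k)
        add(prs[2L, q], prs[1L, q], c = 1 / k)
      }
    }
  }
  key <- (ii - 1) * n + jj
  grp <- match(key, unique(key)) # 1..m in first-occurrence order
  A <- rowsum(cbind(aa, bb, cc), grp) # rowsum sorts groups, i.e. 1..m
  first <- !duplicated(key)
  list(i = ii[first], j = jj[first],
       a = A[, 1L], b = A[, 2L], c = A[, 3L],
       n = n, node_order = ids, is_start = is_start, k = kvec)
}

template_values <- function(tpl, rho) {
  tpl$a + tpl$b * rho + tpl$c * rho^2
}

#' Sparse precision matrix of haplotype effects
#'
#' Builds the precision matrix of the stationary first-order autoregressive
#' Gaussian Markov random field on a haplotype DAG:
#' Q = (1/sigma2_hc) * T^-T D^-1 T^-1, assembled directly from the graph in
#' one pass over the nodes. A starting haplotype contributes 1 - rho^2 to its
#' diagonal; a node with k parents contributes k to its own diagonal, -rho to
#' each (node, parent) entry, rho^2/k to each parent diagonal and rho^2/k
#' between every pair of parents sharing that node. All edges must carry
#' exactly one mutation (see [insert_phantom_haplotypes()]).
#'
#' @param dag a `haplotype_dag` with single-mutation edges
#' @param rho autocorrelation, |rho| < 1
#' @param sigma2_hm marginal variance of a starting haplotype (> 0); the
#'   conditional variance sigma2_hc = sigma2_hm (1 - rho^2) scales the matrix
#' @return an object of class `hn_precision`: list with the sparse symmetric
#'   matrix `Q` (nodes in topological order), `node_order`, and the components
#'   `T_inv` (unit lower-triangular, entries -rho/k at (child, parent)) and
#'   `d_inv` (diagonal of D^-1: 1 - rho^2 for starting nodes, k otherwise)
#' @examples
#' d <- haplotype_dag(data.frame(child = c("i", "j", "k"),
#'                               parent = c(NA, "i", "j")))
#' hn_precision(d, rho = 0.5)$Q
#' @export
hn_precision <- function(dag, rho, sigma2_hm = 1) {
  hp <- ar_hyperparams(rho, sigma2_hm)
  if (hp$sigma2_hc <= 0) stop("sigma2_hc must be > 0")
  tpl <- precision_template(dag)
  hn_precision_from_template(tpl, rho, hp$sigma2_hc)
}

hn_precision_from_template <- function(tpl, rho, sigma2_hc) {
  x <- template_values(tpl, rho) / sigma2_hc
  Q <- Matrix::sparseMatrix(i = tpl$i, j = tpl$j, x = x,
                            dims = c(tpl$n, tpl$n),
                            dimnames = list(tpl$node_order, tpl$node_order))
  d_inv <- ifelse(tpl$is_start, 1 - rho^2, pmax(tpl$k, 1))
  # T^-1: unit diagonal, -rho/k at (child, parent)
  ti <- tpl$i[tpl$b != 0 & tpl$i > tpl$j] # child rows of parent entries
  tj <- tpl$j[tpl$b != 0 & tpl$i > tpl$j]
  T_inv <- Matrix::sparseMatrix(i = c(seq_len(tpl$n), ti), j = c(seq_len(tpl$n), tj),
                                x = c(rep(1, tpl$n), -rho / tpl$k[ti]),
                                dims = c(tpl$n, tpl$n),
                                dimnames = list(tpl$node_order, tpl$node_order))
  structure(list(Q = Q, node_order = tpl$node_order,
                 T_inv = T_inv, d_inv = d_inv,
                 rho = rho, sigma2_hc = sigma2_hc),
            class = "hn_precision")
}

#' @export
print.hn_precision <- function(x, ...) {
  cat("Haplotype network precision matrix\n")
  cat("  nodes:", length(x$node_order),
      " non-zeros:", Matrix::nnzero(x$Q), "\n")
  cat("  rho:", x$rho, " sigma2_hc:", x$sigma2_hc, "\n")
  invisible(x)
}

#' Dense covariance of haplotype effects (test oracle)
#'
#' Explicitly constructs V = T D T' sigma2_hc by inverting the unit
#' lower-triangular T^-1. Intended for small graphs as an independent check of
#' [hn_precision()]; it densifies and should not be used at scale.
#'
#' @inheritParams hn_precision
#' @return dense symmetric covariance matrix in topological node order
#' @export
hn_covariance <- function(dag, rho, sigma2_hm = 1) {
  hp <- ar_hyperparams(rho, sigma2_hm)
  prec <- hn_precision(dag, rho, sigma2_hm)
  Tinv <- as.matrix(prec$T_inv)
  Tm <- backsolve(t(Tinv), diag(nrow(Tinv)), upper.tri = TRUE)
  Tm <- t(Tm) # T = (T^-1)^-1, lower triangular
  V <- Tm %*% (diag(1 / prec$d_inv, nrow(Tinv)) * hp$sigma2_hc) %*% t(Tm)
  dimnames(V) <- list(prec$node_order, prec$node_order)
  (V + t(V)) / 2
}

#' Block-diagonal precision across multiple haplotype regions
#'
#' Regions (for example non-recombining segments with separate phylogenies)
#' share the hyper-parameters (rho, sigma2_hm); the joint precision is block
#' diagonal with one haplotype-network block per region, ordered by the
#' concatenation of the per-region topological orders.
#'
#' @param dags list of `haplotype_dag` objects, one per region
#' @inheritParams hn_precision
#' @return an `hn_precision` whose `Q` is block diagonal; `region` gives the
#'   region index of each node
#' @export
hn_precision_multiregion <- function(dags, rho, sigma2_hm = 1) {
  if (!length(dags)) stop("need at least one region DAG")
  parts <- lapply(dags, hn_precision, rho = rho, sigma2_hm = sigma2_hm)
  Q <- Matrix::bdiag(lapply(parts, `[[`, "Q"))
  T_inv <- Matrix::bdiag(lapply(parts, `[[`, "T_inv"))
  nodes <- unlist(lapply(parts, `[[`, "node_order"))
  if (anyDuplicated(nodes))
    nodes <- paste0("r", rep(seq_along(parts), vapply(parts, function(p)
      length(p$node_order), 1L)), ".", nodes)
  dimnames(Q) <- list(nodes, nodes)
  structure(list(Q = Q, node_order = nodes, T_inv = T_inv,
                 d_inv = unlist(lapply(parts, `[[`, "d_inv")),
                 rho = rho, sigma2_hc = parts[[1L]]$sigma2_hc,
                 region = rep(seq_along(parts),
                              vapply(parts, function(p) length(p$node_order), 1L))),
            class = "hn_precision")
}
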