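#' Assemble a phenotype model with a haplotype term
#'
#' Builds and validates the Gaussian phenotype model
#' y = X beta + f_1 + ... + f_s + Z h + e, where `h` carries the haplotype
#' effects under one of three structures: the haplotype network model
#' (`"hn"`, autoregressive on the phylogeny DAG), independent haplotype
#' effects (`"ih"`, i.i.d. Gaussian), or a mutation model (`"mutation"`,
#' h = U v with i.i.d. mutation effects v). Fixed effects have Gaussian
#' priors with variance `priors$fixed_prior_var`; there is no global
#' intercept, because an intercept and the haplotype-effect level are not
#' jointly identifiable as rho approaches 1 (the mean level is absorbed by
#' the haplotype effects).
#'
#' @param y numeric phenotype vector (centred and scaled), length p
#' @param Z haplotype incidence: either a p x n 0/1 matrix (column names =
#'   haplotype labels; row sums 1 for haploid, 2 for diploid) or a character
#'   vector of length p naming the haplotype carried by each individual
#'   (haploid shorthand)
#' @param dag a `haplotype_dag` (required for `haplotype = "hn"`; optional
#'   for `"ih"`); all edges must carry one mutation
#' @param U haplotype-by-site 0/1 allele matrix with haplotype row names
#'   (required for `haplotype = "mutation"`)
#' @param haplotype structure of the haplotype term: "hn", "ih" or "mutation"
#' @param X optional p x r fixed-effect design matrix (no constant column)
#' @param extra named list of additional random-effect terms; each element is
#'   a list with `design` (p x q matrix) and optionally `type` ("iid", the
#'   default, or "user_precision"), `precision` (q x q positive-definite
#'   matrix for `"user_precision"`; the effect prior is
#'   N(0, sigma2 * precision^-1)) and `prior` (a [pc_prior_sd()] for the
#'   term's standard deviation)
#' @param priors prior bundle from [hn_priors()]
#' @param sum_to_zero constrain the haplotype effects to sum to zero
#'   (off by default; changes interpretation when rho is near 1)
#' @param check_intercept reject a constant column in `X` (default TRUE)
#' @return an object of class `hn_model` used by [hapnet()]
#' @export
hn_model <- function(y, Z, dag = NULL, U = NULL,
                     haplotype = c("hn", "ih", "mutation"),
                     X = NULL, extra = list(), priors = hn_priors(),
                     sum_to_zero = FALSE, check_intercept = TRUE) {
  haplotype <- match.arg(haplotype)
  y <- as.numeric(y)
  p <- length(y)

  if (haplotype == "hn" && is.null(dag)) stop("the hn model needs a `dag`")
  if (haplotype == "mutation" && is.null(U)) stop("the mutation model needs `U`")
  if (!is.null(dag)) validate_dag(dag)

  node_ids <- hap_node_ids(Z, dag, U)
  Zm <- build_incidence(Z, node_ids, p)
  is_phantom <- if (!is.null(dag)) dag$is_phantom[node_ids] else
    stats::setNames(rep(FALSE, length(node_ids)), node_ids)

  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != p) stop("X must have one row per phenotype")
    if (check_intercept && ncol(X) > 0 &&
        any(apply(X, 2, function(col) length(unique(col)) == 1L)))
      stop("X contains a constant column; the model has no global intercept ",
           "(the haplotype effects absorb the mean level). ",
           "Drop the column or set check_intercept = FALSE.")
  }

  terms <- list()
  for (nm in names(extra)) {
    tr <- extra[[nm]]
    D <- as.matrix(tr$design)
    if (nrow(D) != p) stop("design for term `", nm, "` must have ", p, " rows")
    type <- if (is.null(tr$type)) "iid" else match.arg(tr$type, c("iid", "user_precision"))
    prior <- if (is.null(tr$prior)) priors$sd else tr$prior
    P <- NULL; ldP <- 0
    if (type == "user_precision") {
      P <- as.matrix(tr$precision)
      if (is.null(P) || nrow(P) != ncol(D)) stop("term `", nm, "`: precision must be q x q")
      ldP <- as.numeric(determinant(P, logarithm = TRUE)$modulus)
    }
    terms[[nm]] <- list(name = nm, type = type, design = D, q = ncol(D),
                        prior = prior, precision = P, logdet_precision = ldP)
  }

  # haplotype term always last in the latent ordering
  hap <- switch(haplotype,
    hn = list(name = "hap", type = "hn", design = Zm, q = length(node_ids),
              prior = priors$sd, rho_prior = priors$rho,
              template = precision_template(dag)),
    ih = list(name = "hap", type = "iid", design = Zm, q = length(node_ids),
              prior = priors$sd),
    mutation = {
      if (any(Zm[, is_phantom, drop = FALSE] != 0))
        stop("individuals cannot carry phantom haplotypes")
      carried <- node_ids[Matrix::colSums(Zm) > 0]
      Uh <- align_alleles(U, node_ids, is_phantom, carried)
      list(name = "hap", type = "mutation",
           design = Zm[, rownames(Uh), drop = FALSE] %*% Uh, q = ncol(Uh),
           prior = priors$sd, U = Uh)
    })
  if (haplotype == "hn") {
    # template is in topological order; reorder Z columns to match
    ord <- hap$template$node_order
    hap$design <- Zm[, ord, drop = FALSE]
    node_ids <- ord
    is_phantom <- if (!is.null(dag)) dag$is_phantom[ord] else is_phantom[ord]
  }
  terms$hap <- hap

  model <- structure(list(y = y, p = p, X = X,
                          terms = terms, haplotype = haplotype,
                          node_ids = node_ids, is_phantom = is_phantom,
                          Z = Zm, dag = dag,
                          priors = priors, sum_to_zero = sum_to_zero),
                     class = "hn_model")
  model_internals(model)
}

# Resolve the haplotype label set from Z / dag / U.
hap_node_ids <- function(Z, dag, U) {
  if (!is.null(dag)) return(dag$node_ids)
  if (is.matrix(Z) || inherits(Z, "Matrix")) {
    if (is.null(colnames(Z))) return(paste0("h", seq_len(ncol(Z))))
    return(colnames(Z))
  }
  if (!is.null(U)) return(rownames(U))
  sort(unique(as.character(Z)))
}

build_incidence <- function(Z, node_ids, p) {
  if (is.character(Z) || is.factor(Z)) {
    Z <- as.character(Z)
    if (length(Z) != p) stop("haplotype assignment must have length p")
    bad <- setdiff(unique(Z), node_ids)
    if (length(bad)) stop("unknown haplotype label(s) in Z: ", paste(bad, collapse = ", "))
    M <- matrix(0, p, length(node_ids), dimnames = list(NULL, node_ids))
    if (p > 0) M[cbind(seq_len(p), match(Z, node_ids))] <- 1
    return(M)
  }
  Z <- as.matrix(Z)
  if (nrow(Z) != p) stop("Z must have one row per phenotype")
  if (is.null(colnames(Z))) {
    if (ncol(Z) != length(node_ids)) stop("Z has ", ncol(Z), " columns for ",
                                          length(node_ids), " haplotypes")
    colnames(Z) <- node_ids
  }
  M <- matrix(0, p, length(node_ids), dimnames = list(NULL, node_ids))
  keep <- intersect(colnames(Z), node_ids)
  if (length(keep) < ncol(Z)) stop("Z columns not in the haplotype set: ",
                                   paste(setdiff(colnames(Z), node_ids), collapse = ", "))
  M[, keep] <- Z[, keep]
  if (p > 0 && !all(rowSums(M) %in% c(1, 2)))
    stop("each individual must carry one (haploid) or two (diploid) haplotypes")
  M
}

align_alleles <- function(U, node_ids, is_phantom, required = NULL) {
  check_allele_matrix(U)
  named <- node_ids[!is_phantom]
  if (is.null(required)) required <- named
  missing <- setdiff(required, rownames(U))
  if (length(missing)) stop("allele matrix is missing haplotype(s): ",
                            paste(utils::head(missing, 5), collapse = ", "))
  # model the haplotypes whose sequences are known
  U <- U[intersect(named, rownames(U)), , drop = FALSE]
  if (is.null(colnames(U))) colnames(U) <- paste0("s", seq_len(ncol(U)))
  U
}

# Precompute quantities reused at every hyper-parameter evaluation.
model_internals <- function(model) {
  p <- model$p
  blocks <- list()
  Ws <- list()
  off <- 0L
  if (!is.null(model$X) && ncol(model$X) > 0) {
    r <- ncol(model$X)
    blocks$beta <- list(name = "beta", type = "fixed", idx = off + seq_len(r),
                        q = r)
    Ws$beta <- model$X
    off <- off + r
  }
  for (nm in names(model$terms)) {
    tr <- model$terms[[nm]]
    blocks[[nm]] <- c(tr[setdiff(names(tr), "design")],
                      list(idx = off + seq_len(tr$q)))
    Ws[[nm]] <- tr$design
    off <- off + tr$q
  }
  m <- off
  W <- do.call(cbind, Ws)
  model$W <- as.matrix(W)
  model$m <- m
  model$blocks <- blocks
  model$WtW <- crossprod(model$W)
  model$Wty <- as.numeric(crossprod(model$W, model$y))
  model$yty <- sum(model$y^2)

  # hyper-parameter layout: per-term hypers in term order, residual variance last
  theta_names <- character(0)
  for (nm in names(model$terms)) {
    tr <- model$terms[[nm]]
    if (tr$type == "hn") theta_names <- c(theta_names, paste0("rho.", nm))
    theta_names <- c(theta_names, paste0("log_s2.", nm))
  }
  theta_names <- c(theta_names, "log_s2.residual")
  model$theta_names <- theta_names

  # latent names
  lat <- character(m)
  if (!is.null(blocks$beta)) lat[blocks$beta$idx] <- paste0("beta", seq_len(blocks$beta$q))
  for (nm in names(model$terms)) {
    b <- blocks[[nm]]
    lat[b$idx] <- if (nm == "hap" && model$haplotype == "mutation")
      paste0("v.", colnames(model$terms$hap$U))
    else if (nm == "hap") model$node_ids
    else paste0(nm, seq_len(b$q))
  }
  model$latent_names <- lat

  # precompute dense linear indices for the hn template inside the full matrix
  hb <- blocks$hap
  if (!is.null(hb$template)) {
    tpl <- hb$template
    o <- hb$idx[1L] - 1L
    model$hn_lin <- (o + tpl$j - 1L) * m + o + tpl$i
    model$hn_nstart <- sum(tpl$is_start)
    model$hn_sumlogk <- sum(log(tpl$k[!tpl$is_start]))
  }
  if (model$sum_to_zero) {
    cvec <- numeric(m)
    cvec[hb$idx] <- 1
    model$constraint <- cvec
  }
  model
}

#' @export
print.hn_model <- function(x, ...) {
  cat("Phenotype model (", x$haplotype, " haplotype term)\n", sep = "")
  cat("  phenotypes:", x$p, " latent size:", x$m, "\n")
  cat("  hyper-parameters:", paste(x$theta_names, collapse = ", "), "\n")
  invisible(x)
}
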