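#' Construct a haplotype phylogeny DAG
#'
#' Builds and validates the directed acyclic graph of haplotypes used by the
#' haplotype network model. Nodes are haplotypes, edges connect a haplotype to
#' the parental haplotype(s) it arose from by mutation. Haplotypes without a
#' parent form the non-empty "starting" set and receive the stationary marginal
#' distribution in the model.
#'
#' @param edges a data frame with columns `child`, `parent` and optionally
#'   `n_mutations` (positive integers, default 1). `parent` may be `NA` or `""`
#'   for starting haplotypes. A child with several parents occupies several
#'   rows.
#' @return an object of class `haplotype_dag` with components
#'   \describe{
#'     \item{node_ids}{haplotype labels in first-appearance order}
#'     \item{parents}{named list mapping each node to its parent labels
#'       (character(0) for starting haplotypes)}
#'     \item{edge_mutations}{named list, per node, of mutation counts aligned
#'       with `parents`}
#'     \item{is_phantom}{logical flag per node}
#'     \item{topo_order}{integer permutation of nodes such that every parent
#'       precedes its children}
#'   }
#' @examples
#' d <- haplotype_dag(data.frame(child = c("i", "g", "a"),
#'                               parent = c(NA, "i", "g"),
#'                               n_mutations = c(1, 2, 1)))
#' d
#' @seealso [read_dag()], [insert_phantom_haplotypes()], [dag_from_tree()]
#' @export
haplotype_dag <- function(edges) {
  if (!is.data.frame(edges)) stop("`edges` must be a data frame")
  if (nrow(edges) == 0L) stop("empty edge table: no starting haplotype")
  if (!all(c("child", "parent") %in% names(edges)))
    stop("edge table needs columns `child` and `parent`")
  child <- as.character(edges$child)
  parent <- as.character(edges$parent)
  parent[is.na(parent) | parent == ""] <- NA_character_
  if (anyNA(child) || any(child == ""))
    stop("every row must name a child haplotype")
  nmut <- if ("n_mutations" %in% names(edges)) edges$n_mutations else rep(1L, nrow(edges))
  nmut[is.na(nmut)] <- 1
  if (any(nmut != round(nmut)) || any(nmut <= 0))
    stop("`n_mutations` must be positive integers")
  nmut <- as.integer(nmut)

  # first-appearance node order over children then any parent-only labels
  node_ids <- unique(c(child, parent[!is.na(parent)]))
  # parent-only labels become starting haplotypes implicitly
  parents <- stats::setNames(vector("list", length(node_ids)), node_ids)
  emut <- stats::setNames(vector("list", length(node_ids)), node_ids)
  for (id in node_ids) {
    parents[[id]] <- character(0)
    emut[[id]] <- integer(0)
  }
  for (r in seq_along(child)) {
    if (is.na(parent[r])) next
    if (parent[r] %in% parents[[child[r]]])
      stop("duplicated edge ", child[r], " -> ", parent[r])
    parents[[child[r]]] <- c(parents[[child[r]]], parent[r])
    emut[[child[r]]] <- c(emut[[child[r]]], nmut[r])
  }
  unknown <- setdiff(unlist(parents), node_ids)
  if (length(unknown))
    stop("unknown parent label(s): ", paste(unknown, collapse = ", "))

  dag <- structure(list(node_ids = node_ids,
                        parents = parents,
                        edge_mutations = emut,
                        is_phantom = stats::setNames(rep(FALSE, length(node_ids)), node_ids),
                        topo_order = NULL),
                   class = "haplotype_dag")
  dag$topo_order <- topo_sort(dag)
  validate_dag(dag)
  dag
}

#' @export
print.haplotype_dag <- function(x, ...) {
  n <- length(x$node_ids)
  np <- sum(x$is_phantom)
  starts <- starting_haplotypes(x)
  nedge <- sum(lengths(x$parents))
  cat("Haplotype phylogeny DAG\n")
  cat("  nodes:", n, if (np) paste0("(", np, " phantom)") else "", "\n")
  cat("  edges:", nedge, "\n")
  cat("  starting haplotypes:", paste(utils::head(starts, 8), collapse = ", "),
      if (length(starts) > 8) "..." else "", "\n")
  invisible(x)
}

#' Starting haplotypes of a DAG
#'
#' @param dag a `haplotype_dag`
#' @return character vector of node labels with no parents
#' @export
starting_haplotypes <- function(dag) {
  dag$node_ids[lengths(dag$parents[dag$node_ids]) == 0L]
}

#' Number of parental haplotypes per node
#'
#' @param dag a `haplotype_dag`
#' @return named integer vector, in node order
#' @export
parent_counts <- function(dag) {
  k <- lengths(dag$parents[dag$node_ids])
  stats::setNames(as.integer(k), dag$node_ids)
}

# Kahn topological sort; errors naming one cycle if the graph is cyclic.
topo_sort <- function(dag) {
  ids <- dag$node_ids
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  indeg <- integer(n) # number of unresolved parents per node
  children <- vector("list", n)
  for (i in seq_len(n)) {
    ps <- dag$parents[[ids[i]]]
    indeg[i] <- length(ps)
    for (p in ps) children[[idx[p]]] <- c(children[[idx[p]]], i)
  }
  queue <- which(indeg == 0L)
  if (!length(queue)) stop("no starting haplotype: every node has a parent (cycle)")
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    left <- setdiff(seq_len(n), out)
    cyc <- find_cycle(dag, ids[left])
    stop("cycle detected in haplotype DAG: ", paste(cyc, collapse = " -> "))
  }
  out
}

# Walk parent pointers from an unresolved node until a label repeats.
find_cycle <- function(dag, candidates) {
  cur <- candidates[1L]
  seen <- character(0)
  while (!(cur %in% seen)) {
    seen <- c(seen, cur)
    ps <- intersect(dag$parents[[cur]], candidates)
    cur <- ps[1L]
  }
  c(seen[which(seen == cur):length(seen)], cur)
}

validate_dag <- function(dag) {
  ids <- dag$node_ids
  stopifnot(length(ids) > 0, !anyDuplicated(ids))
  if (!length(starting_haplotypes(dag)))
    stop("no starting haplotype: every node has a parent")
  ord <- dag$topo_order
  pos <- integer(length(ids)); pos[ord] <- seq_along(ord)
  idx <- stats::setNames(seq_along(ids), ids)
  for (id in ids) {
    for (p in dag$parents[[id]]) {
      if (pos[idx[p]] >= pos[idx[id]]) stop("topo_order is not topological")
    }
    if (length(dag$parents[[id]]) != length(dag$edge_mutations[[id]]))
      stop("edge mutation counts misaligned for node ", id)
  }
  invisible(dag)
}

#' Insert phantom haplotypes so every edge carries exactly one mutation
#'
#' An edge separating two haplotypes by m > 1 mutations is replaced by a chain
#' of m - 1 unobserved ("phantom") intermediate haplotypes, each edge then
#' carrying one mutation. The order of mutations along such an edge is not
#' identifiable from counts; the chain is an arbitrary linear order, which does
#' not affect the model because only the path length enters the precision.
#' The operation is idempotent.
#'
#' Phantom labels are deterministic: `<child>.p1`, `<child>.p2`, ... ordered
#' from the parent toward the child. When a child has several parents the
#' parent label is included (`<child>.<parent>.p1`, ...) to keep labels unique.
#'
#' @param dag a `haplotype_dag`
#' @return a `haplotype_dag` in which every edge has mutation count one
#' @examples
#' d <- haplotype_dag(data.frame(child = "g", parent = "i", n_mutations = 2))
#' insert_phantom_haplotypes(d)$node_ids # i -> g.p1 -> g
#' @export
insert_phantom_haplotypes <- function(dag) {
  validate_dag(dag)
  rows <- list()
  phantom <- character(0)
  multi <- parent_counts(dag) > 1L
  for (id in dag$node_ids) {
    ps <- dag$parents[[id]]
    ms <- dag$edge_mutations[[id]]
    if (!length(ps)) {
      rows[[length(rows) + 1L]] <- data.frame(child = id, parent = NA_character_,
                                              n_mutations = 1L)
      next
    }
    for (j in seq_along(ps)) {
      m <- ms[j]
      if (m == 1L) {
        rows[[length(rows) + 1L]] <- data.frame(child = id, parent = ps[j],
                                                n_mutations = 1L)
      } else {
        base <- if (multi[id]) paste0(id, ".", ps[j]) else id
        mids <- paste0(base, ".p", seq_len(m - 1L))
        chain <- c(ps[j], mids, id)
        for (s in seq_len(m)) {
          rows[[length(rows) + 1L]] <- data.frame(child = chain[s + 1L],
                                                  parent = chain[s],
                                                  n_mutations = 1L)
        }
        phantom <- c(phantom, mids)
      }
    }
  }
  tab <- do.call(rbind, rows)
  # keep original first-appearance order for named nodes, phantoms appear where created
  out <- haplotype_dag(tab)
  out$is_phantom[phantom] <- TRUE
  out$is_phantom[dag$node_ids] <- dag$is_phantom[dag$node_ids]
  out
}

#' Convert a bifurcating/multifurcating tree to a haplotype DAG
#'
#' Interprets a Newick string (or an [ape::phylo] object) as a haplotype
#' phylogeny: the root and internal nodes become haplotypes alongside the
#' tips, and integer branch lengths are read as mutation counts (1 when
#' absent). The model counts discrete mutations, so non-integer branch
#' lengths are an error.
#'
#' @param tree a Newick string or an `ape` `phylo` object
#' @return a `haplotype_dag` with the root as the starting haplotype
#' @examples
#' dag_from_tree("((a:1,b:1):1);")
#' @export
dag_from_tree <- function(tree) {
  if (is.character(tree)) {
    phy <- tryCatch(suppressWarnings(ape::read.tree(text = tree)),
                    error = function(e) stop("malformed Newick: ", conditionMessage(e)))
    if (is.null(phy)) stop("malformed Newick string")
  } else if (inherits(tree, "phylo")) {
    phy <- tree
  } else stop("`tree` must be a Newick string or a phylo object")
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  labs <- character(ntip + nnode)
  labs[seq_len(ntip)] <- phy$tip.label
  inner <- if (!is.null(phy$node.label) && all(nzchar(phy$node.label)))
    phy$node.label else paste0("node", seq_len(nnode))
  labs[ntip + seq_len(nnode)] <- inner
  if (anyDuplicated(labs)) stop("duplicated node labels in tree")
  len <- phy$edge.length
  if (is.null(len)) len <- rep(1, nrow(phy$edge))
  len[is.na(len)] <- 1
  if (any(abs(len - round(len)) > 1e-9) || any(len < 1))
    stop("branch lengths must be positive integer mutation counts")
  root <- ntip + 1L
  tab <- data.frame(child = c(labs[root], labs[phy$edge[, 2L]]),
                    parent = c(NA_character_, labs[phy$edge[, 1L]]),
                    n_mutations = c(1L, as.integer(round(len))))
  haplotype_dag(tab)
}
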