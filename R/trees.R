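#' Dated tree container
#'
#' Wraps a rooted `ape::phylo` tree with node ages in Ma (mega-annum before
#' present). Edge lengths of the wrapped tree are kept equal to the age
#' difference between parent and child; tips sit at age 0 unless stated.
#'
#' @param tree A rooted `phylo` object. Internal nodes are labelled
#'   (`n<k>` labels are added when missing).
#' @param ages Numeric vector of ages in Ma, one per node, ordered by ape
#'   node id (tips `1..Ntip`, then internals), or named by node label.
#' @return Object of class `dated_tree` with elements `tree` (phylo, edge
#'   lengths in Ma) and `ages` (numeric, ape node-id order, names = labels).
#' @export
dated_tree <- function(tree, ages) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  tree <- ensure_node_labels(tree)
  n_all <- ape::Ntip(tree) + tree$Nnode
  labs <- node_labels(tree)
  if (!is.null(names(ages))) {
    miss <- setdiff(labs, names(ages))
    if (length(miss)) stop("ages missing for node(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    ages <- ages[labs]
  }
  stopifnot(length(ages) == n_all)
  ages <- stats::setNames(as.numeric(ages), labs)
  parent_age <- ages[tree$edge[, 1]]
  child_age <- ages[tree$edge[, 2]]
  if (any(parent_age <= child_age - 1e-9)) {
    bad <- labs[tree$edge[which(parent_age <= child_age - 1e-9)[1], 2]]
    stop("age monotonicity violated at node ", bad, call. = FALSE)
  }
  tree$edge.length <- as.numeric(parent_age - child_age)
  structure(list(tree = tree, ages = ages), class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat("dated_tree:", ape::Ntip(x$tree), "tips,",
      x$tree$Nnode, "internal nodes, root age",
      format(root_age(x), digits = 6), "Ma\n")
  invisible(x)
}

#' @rdname dated_tree
#' @param x A `dated_tree`.
#' @export
root_age <- function(x) {
  stopifnot(inherits(x, "dated_tree"))
  unname(x$ages[ape::Ntip(x$tree) + 1L])
}

# vector of labels in ape node-id order (tips then internals)
node_labels <- function(tree) c(tree$tip.label, tree$node.label)

ensure_node_labels <- function(tree) {
  nn <- tree$Nnode
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label)) ||
      anyDuplicated(tree$node.label)) {
    tree$node.label <- paste0("n", seq_len(nn))
  }
  if (anyDuplicated(c(tree$tip.label, tree$node.label)))
    tree$node.label <- paste0("n", seq_len(nn), "_")
  tree
}

# ape node id for a label (tip or internal)
node_id <- function(tree, label) {
  id <- match(label, node_labels(tree))
  if (anyNA(id)) stop("unknown node label(s): ",
                      paste(label[is.na(id)], collapse = ", "), call. = FALSE)
  id
}

#' Most recent common ancestor of a leaf set
#'
#' @param tree A rooted `phylo`.
#' @param leaves Character vector of tip labels (length >= 1).
#' @return ape node id of the LCA (the tip itself for a single leaf).
#' @export
lca_node <- function(tree, leaves) {
  miss <- setdiff(leaves, tree$tip.label)
  if (length(miss)) stop("unknown leaf(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  ids <- match(leaves, tree$tip.label)
  if (length(ids) == 1L) return(ids)
  ape::getMRCA(tree, ids)
}

# tip labels descending from a node id
clade_leaves <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- children_map(tree)
  stack <- node
  out <- integer(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v <= ntip) out <- c(out, v) else stack <- c(stack, kids[[v - ntip]])
  }
  tree$tip.label[sort(out)]
}

# children of each internal node as a list indexed by (node - ntip)
children_map <- function(tree) {
  split(tree$edge[, 2], factor(tree$edge[, 1] - ape::Ntip(tree),
                               levels = seq_len(tree$Nnode)))
}

# parent vector indexed by node id (root -> 0)
parent_map <- function(tree) {
  p <- integer(ape::Ntip(tree) + tree$Nnode)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

#' Test whether a leaf subset is monophyletic on a rooted tree
#'
#' True iff the smallest clade containing all subset leaves contains no
#' other leaves.
#'
#' @param tree A rooted `phylo`.
#' @param leaves Character vector of tip labels.
#' @return Logical scalar.
#' @export
monophyly_check <- function(tree, leaves) {
  miss <- setdiff(leaves, tree$tip.label)
  if (length(miss)) stop("unknown leaf(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  mrca <- lca_node(tree, leaves)
  setequal(clade_leaves(tree, mrca), leaves)
}

#' Patristic distance from every node to a reference node
#'
#' Sums branch lengths along the unique path between each node (tips and
#' internals) and the reference.
#'
#' @param tree A `phylo` with branch lengths.
#' @param reference Node label (tip or internal) or ape node id.
#' @return Named numeric vector over all node labels; the reference maps to 0.
#' @export
distance_to_reference <- function(tree, reference) {
  tree <- ensure_node_labels(tree)
  ref <- if (is.character(reference)) node_id(tree, reference) else as.integer(reference)
  n_all <- ape::Ntip(tree) + tree$Nnode
  if (ref < 1 || ref > n_all) stop("unknown node: ", reference, call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  adj <- vector("list", n_all)
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]; b <- tree$edge[i, 2]; w <- tree$edge.length[i]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  dist <- rep(NA_real_, n_all)
  dist[ref] <- 0
  queue <- ref
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    nb <- adj[[v]]
    if (is.null(nb)) next
    for (j in seq_len(nrow(nb))) {
      u <- nb[j, 1]
      if (is.na(dist[u])) {
        dist[u] <- dist[v] + nb[j, 2]
        queue <- c(queue, u)
      }
    }
  }
  stats::setNames(dist, node_labels(tree))
}

#' Write / read node ages as TSV
#'
#' @param x A `dated_tree`.
#' @param path Output path.
#' @return `write_ages_tsv` invisibly returns `path`; `read_ages_tsv`
#'   returns a data.frame (node_label, age_ma).
#' @export
write_ages_tsv <- function(x, path) {
  stopifnot(inherits(x, "dated_tree"))
  df <- data.frame(node_label = names(x$ages), age_ma = as.numeric(x$ages))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ages_tsv
#' @export
read_ages_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Rebuild a dated tree from a Newick file plus an ages TSV
#'
#' @param newick Path to a Newick file (node labels preserved).
#' @param ages_tsv Path to the node-age TSV written by [write_ages_tsv()].
#' @return A `dated_tree`.
#' @export
read_dated_tree <- function(newick, ages_tsv) {
  tr <- ape::read.tree(newick)
  ag <- read_ages_tsv(ages_tsv)
  dated_tree(tr, stats::setNames(ag$age_ma, ag$node_label))
}
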