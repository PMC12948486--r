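#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining (taxa are sorted lexicographically first, so
#' the result is invariant to input order). Negative branch estimates are
#' clamped to zero with the deficit moved onto the adjacent sibling branch,
#' keeping path lengths between the joined pair's neighbours.
#'
#' @param d Symmetric distance matrix with row/col names (>= 3 taxa).
#' @return Unrooted `phylo`; attribute `clamped` counts adjusted branches.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
  if (nrow(d) < 3) stop("need at least 3 taxa", call. = FALSE)
  ord <- order(rownames(d))
  d <- d[ord, ord]
  tr <- ape::nj(d)
  n_clamped <- 0L
  for (iter in 1:10) {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    i <- neg[order(tr$edge.length[neg])][1]
    p <- tr$edge[i, 1]
    sibs <- setdiff(which(tr$edge[, 1] == p | tr$edge[, 2] == p), i)
    sibs <- sibs[order(tr$edge[sibs, 2])]
    tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + tr$edge.length[i]
    tr$edge.length[i] <- 0
    n_clamped <- n_clamped + 1L
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- n_clamped
  tr
}

#' Root a tree with a named outgroup
#'
#' @param tree A `phylo`.
#' @param outgroup Character vector of tip labels forming the outgroup.
#' @return Rooted `phylo`.
#' @export
outgroup_root <- function(tree, outgroup) {
  miss <- setdiff(outgroup, tree$tip.label)
  if (length(miss)) stop("unknown outgroup leaf/leaves: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Paralogous rooting via pooled pre-duplication subunits
#'
#' Builds a joint tree of the pooled (non-concatenated) A and B subunit
#' alignments, roots it on the branch separating the A clade from the B
#' clade, identifies within each subunit clade the taxon group branching
#' most basally, and roots the concatenated tree with that group as the
#' outgroup.
#'
#' @param concat_tree Unrooted `phylo` of the concatenated A+B sequences
#'   (tips = taxa).
#' @param a_seqs,b_seqs Alignment matrices of the two subunits (same taxa,
#'   mutually aligned, equal column count).
#' @param dist_model Distance model for the joint tree (see
#'   [distance_matrix()]).
#' @param shape Gamma shape when `dist_model = "gamma"`.
#' @return Rooted `phylo`; attributes `basal_group` (taxa nominated by the
#'   A clade), `basal_group_b`, `agreement` (logical).
#' @export
paralogous_root <- function(concat_tree, a_seqs, b_seqs,
                            dist_model = "poisson", shape = NULL) {
  a_seqs <- as_alignment(a_seqs); b_seqs <- as_alignment(b_seqs)
  if (ncol(a_seqs) != ncol(b_seqs))
    stop("A and B subunit alignments must share columns (be mutually aligned)",
         call. = FALSE)
  rownames(a_seqs) <- paste0(rownames(a_seqs), "|A")
  rownames(b_seqs) <- paste0(rownames(b_seqs), "|B")
  joint <- rbind(a_seqs, b_seqs)
  jt <- nj_tree(distance_matrix(joint, dist_model, shape = shape))
  a_labs <- rownames(a_seqs)
  rooted_joint <- tryCatch(
    ape::root(jt, outgroup = a_labs, resolve.root = TRUE),
    error = function(e) NULL)
  if (is.null(rooted_joint)) {
    mr <- ape::getMRCA(ape::root(jt, outgroup = jt$tip.label[1],
                                 resolve.root = TRUE), a_labs)
    stop("A and B subunits are not reciprocally monophyletic in the joint ",
         "tree; conflicting leaves: ",
         paste(setdiff(clade_leaves(ensure_node_labels(
           ape::root(jt, outgroup = jt$tip.label[1], resolve.root = TRUE)), mr),
           a_labs), collapse = ", "),
         call. = FALSE)
  }
  basal_of <- function(rt, labs) {
    rt <- ensure_node_labels(rt)
    sub_root <- lca_node(rt, labs)
    kids <- children_map(rt)[[sub_root - ape::Ntip(rt)]]
    groups <- lapply(kids, function(k) clade_leaves(rt, k))
    sizes <- lengths(groups)
    pick <- order(sizes, vapply(groups, function(g) sort(g)[1], ""))[1]
    sort(sub("\\|[AB]$", "", groups[[pick]]))
  }
  basal_a <- basal_of(rooted_joint, a_labs)
  basal_b <- basal_of(ape::root(jt, outgroup = rownames(b_seqs),
                                resolve.root = TRUE), rownames(b_seqs))
  out <- outgroup_root(concat_tree, intersect(basal_a, concat_tree$tip.label))
  attr(out, "basal_group") <- basal_a
  attr(out, "basal_group_b") <- basal_b
  attr(out, "agreement") <- identical(basal_a, basal_b)
  out
}

#' Nonparametric bootstrap replicate trees
#'
#' Resamples alignment columns with replacement, re-running the
#' distance + neighbor-joining build per replicate (optionally followed by
#' maximum-likelihood branch lengths).
#'
#' @param aln Alignment matrix.
#' @param n_replicates Number of replicates (>= 1).
#' @param seed Integer seed; replicate `i` uses `seed + i`.
#' @param dist_model,shape Passed to [distance_matrix()].
#' @param refit_model Optional [subst_model()]; when given, branch lengths
#'   of every replicate are refit by [fit_branch_lengths()].
#' @param resample Diagnostic flag; `FALSE` reuses the original columns.
#' @return List of `phylo` trees; attribute `seeds`.
#' @export
bootstrap_trees <- function(aln, n_replicates, seed, dist_model = "poisson",
                            shape = NULL, refit_model = NULL,
                            resample = TRUE) {
  aln <- as_alignment(aln)
  stopifnot(n_replicates >= 1)
  seeds <- seed + seq_len(n_replicates)
  trees <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    set.seed(seeds[i])
    cols <- if (resample) sample.int(ncol(aln), ncol(aln), replace = TRUE)
            else seq_len(ncol(aln))
    rep_aln <- aln[, cols, drop = FALSE]
    tr <- nj_tree(distance_matrix(rep_aln, dist_model, shape = shape))
    if (!is.null(refit_model)) {
      tr <- fit_branch_lengths(tr, rep_aln, refit_model, tol = 1e-4,
                               max_cycles = 5L)
    }
    trees[[i]] <- tr
  }
  attr(trees, "seeds") <- seeds
  trees
}

#' Bootstrap support for the clades of a reference tree
#'
#' @param ref Rooted or unrooted reference `phylo`.
#' @param trees Replicate trees (e.g. from [bootstrap_trees()]).
#' @return `ref` with internal-node labels set to percent support.
#' @export
clade_support <- function(ref, trees) {
  pp <- ape::prop.clades(ref, trees, rooted = FALSE)
  pp[is.na(pp)] <- 0
  ref$node.label <- round(100 * pp / length(trees))
  ref
}
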