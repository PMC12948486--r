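#' Build a calibration constraint table
#'
#' Nodes are identified by leaf sets (LCA semantics), robust to node
#' relabeling. Either bound may be `NA` (one-sided constraint).
#'
#' @param leafset List of character vectors (or a single vector for one
#'   constraint); comma-joined in the table.
#' @param min_ma,max_ma Lower / upper age bounds in Ma (`NA` = absent).
#' @param target_ma Optional scale-fit target age; when absent, two-sided
#'   constraints target their interval midpoint. Transfer-projected
#'   constraints target the interval's younger endpoint, since the
#'   calibrated node's age is the first divergence after the transfer,
#'   i.e. the speciation closing the recipient branch.
#' @param provenance Free-text origin tags.
#' @return Data.frame of class `calibration_set`.
#' @export
calibration <- function(leafset, min_ma = NA_real_, max_ma = NA_real_,
                        provenance = "", target_ma = NA_real_) {
  if (is.character(leafset)) leafset <- list(leafset)
  n <- length(leafset)
  min_ma <- rep_len(as.numeric(min_ma), n)
  max_ma <- rep_len(as.numeric(max_ma), n)
  target_ma <- rep_len(as.numeric(target_ma), n)
  bad <- !is.na(min_ma) & !is.na(max_ma) & min_ma > max_ma
  if (any(bad)) stop("min_age > max_age in constraint ", which(bad)[1],
                     call. = FALSE)
  if (any(!lengths(leafset))) stop("empty leaf set", call. = FALSE)
  structure(data.frame(
    leafset = vapply(leafset, paste, "", collapse = ","),
    min_ma = min_ma, max_ma = max_ma, target_ma = target_ma,
    provenance = rep_len(provenance, n), stringsAsFactors = FALSE),
    class = c("calibration_set", "data.frame"))
}

#' @rdname calibration
#' @param path TSV path (columns leafset, min_ma, max_ma, provenance).
#' @export
read_calibrations_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  calibration(strsplit(df$leafset, ","), df$min_ma, df$max_ma,
              df$provenance %||% "", df$target_ma %||% NA_real_)
}

#' @rdname calibration
#' @param x A `calibration_set`.
#' @export
write_calibrations_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Relative-rate dating: relative node heights and branch rates
#'
#' Clock-free post-order recursion: each internal node's relative height is
#' the mean of its two child path estimates (`branch + child height`), and
#' each lineage's relative rate is its realized path divided by the
#' clock-expected path. Heights are normalised to root = 1 and are strictly
#' decreasing toward the tips (violations from extreme rate contrasts are
#' clamped and flagged).
#'
#' @param tree Rooted binary `phylo` with branch lengths in subst/site.
#' @return List of class `relative_dating`: `tree`, `rel_heights` (named,
#'   root = 1), `raw_heights` (subst/site scale), `rates` (per-branch
#'   relative rates, named by child label), `clamped` (labels).
#' @export
relative_dating <- function(tree) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  tree <- ensure_node_labels(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  ntip <- ape::Ntip(tree)
  n_all <- ntip + tree$Nnode
  labs <- node_labels(tree)
  elen <- numeric(n_all)
  elen[tree$edge[, 2]] <- tree$edge.length
  kids <- children_map(tree)
  h <- numeric(n_all)
  clamped <- character(0)
  ord <- ape::reorder.phylo(tree, "postorder")
  for (p in unique(ord$edge[, 1])) {
    ch <- kids[[p - ntip]]
    est <- mean(elen[ch] + h[ch])
    floor_h <- max(h[ch])
    if (est <= floor_h) {
      est <- floor_h * (1 + 1e-9) + 1e-12
      clamped <- c(clamped, labs[p])
    }
    h[p] <- est
  }
  root <- ntip + 1L
  H <- h[root]
  if (H <= 0) stop("tree has zero total depth; cannot date", call. = FALSE)
  rates <- stats::setNames(rep(NA_real_, n_all), labs)
  flagged <- character(0)
  ord2 <- rev(seq_len(nrow(ord$edge)))
  for (i in ord2) {   # preorder
    p <- ord$edge[i, 1]; v <- ord$edge[i, 2]
    expected <- h[p] - h[v]
    if (expected > 0) {
      rates[v] <- elen[v] / expected
    } else {
      rates[v] <- if (p == root || is.na(rates[p])) 1 else rates[p]
      flagged <- c(flagged, labs[v])
    }
  }
  structure(list(tree = tree, rel_heights = stats::setNames(h / H, labs),
                 raw_heights = stats::setNames(h, labs),
                 rates = rates[tree$edge[, 2]],
                 clamped = clamped, rate_inherited = flagged),
            class = "relative_dating")
}

resolve_constraint_nodes <- function(tree, constraints) {
  vapply(strsplit(constraints$leafset, ","), function(ls) {
    lca_node(tree, ls)
  }, integer(1))
}

#' Scale relative heights to absolute ages under calibration constraints
#'
#' A single global scale factor is fit by least squares to the calibrated
#' nodes' targets (interval midpoints; one-sided constraints join the fit
#' only when no two-sided constraint exists, using the bound itself).
#' Nodes violating a bound are then clamped to the bound, their descendants
#' rescaled proportionally (preserving relative order) and ancestors raised
#' minimally where needed; the result satisfies every constraint, with tips
#' at 0.
#'
#' @param rd A [relative_dating()] result (or a rooted tree, which is run
#'   through `relative_dating` first).
#' @param constraints A [calibration()] table.
#' @return A [dated_tree()]; attributes `scale`, `clamped_nodes`.
#' @export
apply_calibrations <- function(rd, constraints) {
  if (inherits(rd, "phylo")) rd <- relative_dating(rd)
  stopifnot(inherits(rd, "relative_dating"))
  if (!nrow(constraints)) stop("no calibration constraints given", call. = FALSE)
  tree <- rd$tree
  ntip <- ape::Ntip(tree)
  labs <- node_labels(tree)
  nodes <- resolve_constraint_nodes(tree, constraints)
  lo <- ifelse(is.na(constraints$min_ma), -Inf, constraints$min_ma)
  hi <- ifelse(is.na(constraints$max_ma), Inf, constraints$max_ma)
  # joint satisfiability: an ancestor's max must not undercut a descendant's min
  par <- parent_map(tree)
  anc_of <- function(v) {
    out <- integer(0)
    while (par[v] != 0) { v <- par[v]; out <- c(out, v) }
    out
  }
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i == j) next
      if (nodes[j] %in% anc_of(nodes[i]) && is.finite(hi[j]) &&
          is.finite(lo[i]) && hi[j] < lo[i]) {
        stop("unsatisfiable constraints: ancestor node ", labs[nodes[j]],
             " max ", hi[j], " < descendant node ", labs[nodes[i]],
             " min ", lo[i], call. = FALSE)
      }
    }
  }
  h <- rd$rel_heights
  explicit <- if ("target_ma" %in% names(constraints))
    constraints$target_ma else rep(NA_real_, nrow(constraints))
  two_sided <- (is.finite(lo) & is.finite(hi)) | !is.na(explicit)
  if (any(two_sided)) {
    tgt <- ifelse(!is.na(explicit[two_sided]), explicit[two_sided],
                  (lo[two_sided] + hi[two_sided]) / 2)
    hh <- h[nodes[two_sided]]
  } else {
    tgt <- ifelse(is.finite(hi), hi, lo)
    hh <- h[nodes]
  }
  scale <- sum(hh * tgt) / sum(hh^2)
  ages <- stats::setNames(as.numeric(scale * h), labs)
  ages[seq_len(ntip)] <- 0
  # clamp violations root-ward first
  kids <- children_map(tree)
  desc_internal <- function(v) {
    out <- integer(0); stack <- v
    while (length(stack)) {
      x <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (x > ntip) {
        out <- c(out, x)
        stack <- c(stack, kids[[x - ntip]])
      }
    }
    out
  }
  clamped_nodes <- character(0)
  ordc <- order(-ages[nodes])
  for (ii in ordc) {
    v <- nodes[ii]
    a <- ages[v]
    if (a > hi[ii] + 1e-9) {
      f <- hi[ii] / a
      dd <- desc_internal(v)
      ages[dd] <- ages[dd] * f
      clamped_nodes <- c(clamped_nodes, labs[v])
    } else if (a < lo[ii] - 1e-9) {
      f <- lo[ii] / a
      dd <- desc_internal(v)
      ages[dd] <- ages[dd] * f
      clamped_nodes <- c(clamped_nodes, labs[v])
      # raise ancestors minimally to preserve monotonicity
      up <- v
      while (par[up] != 0) {
        upp <- par[up]
        if (ages[upp] <= ages[up]) {
          ages[upp] <- ages[up] * (1 + 1e-9)
          cidx <- match(upp, nodes)
          if (!is.na(cidx) && ages[upp] > hi[cidx] + 1e-9) {
            stop("unsatisfiable constraints at node ", labs[upp], call. = FALSE)
          }
        }
        up <- upp
      }
    }
  }
  out <- dated_tree(tree, ages)
  # post-hoc assertion: every constraint satisfied
  for (ii in seq_along(nodes)) {
    a <- out$ages[nodes[ii]]
    if (a < lo[ii] - 1e-6 || a > hi[ii] + 1e-6) {
      stop("internal error: constraint on ", labs[nodes[ii]],
           " not satisfied (age ", a, ")", call. = FALSE)
    }
  }
  attr(out, "scale") <- scale
  attr(out, "clamped_nodes") <- unique(clamped_nodes)
  out
}

# least-squares branch lengths for a fixed topology from a distance matrix;
# negative estimates clamped to zero
ols_branch_lengths <- function(tree, d) {
  d <- as.matrix(d)
  tips <- tree$tip.label
  ntip <- length(tips)
  n_edge <- nrow(tree$edge)
  # edges on the path between each tip pair, via node paths to root
  par <- parent_map(tree)
  edge_of_child <- match(seq_along(par), tree$edge[, 2])
  path_up <- function(v) {
    out <- integer(0)
    while (par[v] != 0) { out <- c(out, edge_of_child[v]); v <- par[v] }
    out
  }
  paths <- lapply(seq_len(ntip), path_up)
  pairs <- utils::combn(ntip, 2)
  A <- matrix(0, ncol(pairs), n_edge)
  y <- numeric(ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1, q]; j <- pairs[2, q]
    shared <- intersect(paths[[i]], paths[[j]])
    A[q, c(setdiff(paths[[i]], shared), setdiff(paths[[j]], shared))] <- 1
    y[q] <- d[tips[i], tips[j]]
  }
  b <- stats::lm.fit(A, y)$coefficients
  b[!is.finite(b) | b < 0] <- 0
  # the split of path length across the two root edges is unidentifiable
  # from distances; redistribute it in the reference tree's proportion
  root_edges <- which(tree$edge[, 1] == ntip + 1L)
  if (length(root_edges) == 2 && !is.null(tree$edge.length)) {
    tot <- sum(b[root_edges])
    ref <- tree$edge.length[root_edges]
    w <- if (sum(ref) > 0) ref / sum(ref) else c(0.5, 0.5)
    b[root_edges] <- tot * w
  }
  tree$edge.length <- as.numeric(b)
  tree
}

#' Bootstrap confidence intervals for calibrated node ages
#'
#' Alignment columns are resampled with replacement; per replicate, branch
#' lengths are refit on the fixed topology (least-squares from the
#' replicate's distance matrix, or maximum likelihood), then
#' [relative_dating()] + [apply_calibrations()] are re-run. CIs are the
#' 2.5/97.5 percentiles across replicates, widened if needed so the point
#' estimate lies inside (flagged).
#'
#' @param aln Alignment matrix.
#' @param topology Rooted binary `phylo` (point-estimate branch lengths are
#'   used as the warm start / point estimate).
#' @param constraints A [calibration()] table.
#' @param n_boot Number of replicates (>= 2).
#' @param seed Integer seed.
#' @param method `"ols"` (distance-based refit on the fixed topology;
#'   default), `"ml"` (maximum-likelihood refit, fixed topology), or
#'   `"full"` (the whole distance + neighbor-joining + rooting build is
#'   re-run per replicate and nodes are matched by leaf set, so the CI
#'   also reflects topology and rooting uncertainty).
#' @param model A [subst_model()] (required for `method = "ml"`).
#' @param dist_model,shape Distance settings for `method = "ols"`.
#' @param level CI level (default 0.95).
#' @param point_tree Optional tree (same topology) whose branch lengths
#'   define the point estimate, e.g. a maximum-likelihood fit; by default
#'   the point estimate is refit from `aln` with the same estimator as the
#'   replicates.
#' @return List: `dated` (point-estimate [dated_tree()]), `ci` (data.frame:
#'   node, age_ma, ci_lo, ci_hi), `widened` (labels).
#' @export
bootstrap_cis <- function(aln, topology, constraints, n_boot, seed,
                          method = c("ols", "ml", "full"), model = NULL,
                          dist_model = "poisson", shape = NULL,
                          level = 0.95, point_tree = NULL,
                          reroot = phangorn::midpoint) {
  method <- match.arg(method)
  stopifnot(n_boot >= 2)
  aln <- as_alignment(aln)
  topology <- ensure_node_labels(topology)
  refit <- function(a) {
    if (method == "ml") {
      fit_branch_lengths(topology, a, model, tol = 1e-4, max_cycles = 5L)
    } else if (method == "full") {
      ensure_node_labels(reroot(nj_tree(distance_matrix(a, dist_model,
                                                        shape = shape))))
    } else {
      ols_branch_lengths(topology, distance_matrix(a, dist_model,
                                                   shape = shape))
    }
  }
  # point estimate through the same branch-length estimator as the
  # replicates (so a zero-variation alignment collapses the CI exactly),
  # unless a dedicated point tree, e.g. an ML fit, is supplied
  pt <- if (is.null(point_tree)) refit(aln) else ensure_node_labels(point_tree)
  point <- apply_calibrations(relative_dating(pt), constraints)
  labs <- node_labels(topology)
  reps <- matrix(NA_real_, n_boot, length(labs), dimnames = list(NULL, labs))
  ntip <- ape::Ntip(topology)
  leafsets <- lapply(seq_along(labs), function(v) clade_leaves(topology, v))
  for (b in seq_len(n_boot)) {
    set.seed(seed + b)
    cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
    tr <- refit(aln[, cols, drop = FALSE])
    dated <- tryCatch(apply_calibrations(relative_dating(tr), constraints),
                      error = function(e) NULL)
    if (is.null(dated)) next
    if (method == "full") {
      # replicate topologies differ: match every point-tree node by the
      # LCA of its leaf set in the replicate
      reps[b, ] <- vapply(leafsets, function(ls)
        as.numeric(dated$ages[lca_node(dated$tree, ls)]), numeric(1))
    } else {
      reps[b, ] <- as.numeric(dated$ages[labs])
    }
  }
  alpha <- (1 - level) / 2
  qs <- apply(reps, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  pt_age <- as.numeric(point$ages[labs])
  if (!is.null(point_tree)) {
    # the point estimator differs from the replicate estimator (e.g. ML
    # point over distance-based replicates): recenter the replicate
    # deviations on the point estimate (basic bootstrap), so the interval
    # inherits the replicates' spread but the point's center
    ctr <- apply(reps, 2, stats::median, na.rm = TRUE)
    lo_ci <- pmax(pt_age + (qs[1, ] - ctr), 0)
    hi_ci <- pt_age + (qs[2, ] - ctr)
  } else {
    lo_ci <- qs[1, ]
    hi_ci <- qs[2, ]
  }
  ci <- data.frame(node = labs, age_ma = pt_age,
                   ci_lo = lo_ci, ci_hi = hi_ci,
                   stringsAsFactors = FALSE, row.names = NULL)
  widened <- ci$node[ci$age_ma < ci$ci_lo | ci$age_ma > ci$ci_hi]
  ci$ci_lo <- pmin(ci$ci_lo, ci$age_ma)
  ci$ci_hi <- pmax(ci$ci_hi, ci$age_ma)
  list(dated = point, ci = ci, widened = widened,
       n_failed = sum(is.na(reps[, 1])))
}

#' Project dated transfer events onto gene-tree calibration constraints
#'
#' For each retained transfer event, the recipient species branch's age
#' interval becomes a calibration constraint on the LCA of the gene-tree
#' clade of recipient-descendant homologs — provided that clade has at
#' least `min_clade_size` leaves and is monophyletic in the gene tree.
#'
#' @param dated_species_tree A [dated_tree()].
#' @param events Data.frame with columns donor, recipient (species branch
#'   labels) and optionally frequency.
#' @param gene_tree Rooted `phylo` of the gene family.
#' @param leaf_map Named character vector gene leaf -> species leaf.
#' @param min_clade_size Minimum gene-clade size (default 3).
#' @return A [calibration()] table; attribute `skipped` (data.frame with
#'   reasons).
#' @export
transfer_calibrations <- function(dated_species_tree, events, gene_tree,
                                  leaf_map, min_clade_size = 3L) {
  stopifnot(inherits(dated_species_tree, "dated_tree"))
  sp <- dated_species_tree$tree
  ages <- dated_species_tree$ages
  par <- parent_map(sp)
  gene_tree <- ensure_node_labels(gene_tree)
  out <- NULL
  skipped <- NULL
  skip <- function(i, why) {
    skipped <<- rbind(skipped, data.frame(recipient = events$recipient[i],
                                          reason = why,
                                          stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(events))) {
    rec <- events$recipient[i]
    rid <- match(rec, node_labels(sp))
    if (is.na(rid)) { skip(i, "unknown recipient branch"); next }
    if (par[rid] == 0) { skip(i, "recipient is the root"); next }
    a_lo <- as.numeric(ages[rid])
    a_hi <- as.numeric(ages[par[rid]])
    sp_leaves <- clade_leaves(sp, rid)
    gl <- names(leaf_map)[leaf_map %in% sp_leaves]
    gl <- intersect(gl, gene_tree$tip.label)
    if (length(gl) < min_clade_size) { skip(i, "gene clade too small"); next }
    if (!monophyly_check(gene_tree, gl)) {
      skip(i, "gene clade not monophyletic"); next
    }
    prov <- sprintf("transfer %s->%s%s", events$donor[i], rec,
                    if (!is.null(events$frequency))
                      sprintf(" freq=%.2f", events$frequency[i]) else "")
    out <- rbind(out, calibration(list(gl), min_ma = a_lo, max_ma = a_hi,
                                  provenance = prov, target_ma = a_lo))
  }
  if (is.null(out)) {
    out <- calibration(list("placeholder"), NA, NA, "")[0, ]

    class(out) <- c("calibration_set", "data.frame")
  }
  attr(out, "skipped") <- skipped
  out
}
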