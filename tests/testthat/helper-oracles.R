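# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (full enumeration, explicit path walks) so they check
# the optimized implementations from a different route.

AA <- paleoclock:::AA20

rand_aa_seq <- function(n, exclude = NULL) {
  paste(sample(setdiff(AA, exclude), n, replace = TRUE), collapse = "")
}

rand_aln <- function(ntaxa, nsites, names = paste0("t", seq_len(ntaxa))) {
  m <- matrix(sample(AA, ntaxa * nsites, replace = TRUE), ntaxa, nsites)
  rownames(m) <- names
  m
}

# full enumeration of internal states, per site, averaged over gamma
# categories
brute_loglik <- function(tree, aln, model) {
  tree <- paleoclock:::ensure_node_labels(tree)
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  codes <- matrix(match(aln, AA), nrow(aln), ncol(aln))
  rownames(codes) <- rownames(aln)
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(1:20), nint)))
  for (site in seq_len(ncol(aln))) {
    site_lik <- 0
    for (cc in seq_len(model$k)) {
      Ps <- lapply(seq_len(nrow(tree$edge)), function(i)
        transition_prob(model, tree$edge.length[i] * model$rates[cc]))
      s <- 0
      for (r in seq_len(nrow(grid))) {
        st <- c(codes[tree$tip.label, site], grid[r, ])
        pr <- model$pi[grid[r, 1]]
        for (i in seq_len(nrow(tree$edge))) {
          a <- st[tree$edge[i, 1]]; b <- st[tree$edge[i, 2]]
          if (is.na(b)) next   # gap tip: sum over states = 1 handled below
          pr <- pr * Ps[[i]][a, b]
        }
        s <- s + pr
      }
      site_lik <- site_lik + s / model$k
    }
    total <- total + log(site_lik)
  }
  total
}

# joint enumeration of all internal states -> marginal posterior of `node`
# at `site`
brute_asr_posterior <- function(tree, aln, model, node_label, site) {
  tree <- paleoclock:::ensure_node_labels(tree)
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  labs <- paleoclock:::node_labels(tree)
  target <- match(node_label, labs) - ntip
  codes <- matrix(match(aln, AA), nrow(aln), ncol(aln))
  rownames(codes) <- rownames(aln)
  grid <- as.matrix(expand.grid(rep(list(1:20), nint)))
  post <- numeric(20)
  for (cc in seq_len(model$k)) {
    Ps <- lapply(seq_len(nrow(tree$edge)), function(i)
      transition_prob(model, tree$edge.length[i] * model$rates[cc]))
    for (r in seq_len(nrow(grid))) {
      st <- c(codes[tree$tip.label, site], grid[r, ])
      pr <- model$pi[grid[r, 1]] / model$k
      for (i in seq_len(nrow(tree$edge))) {
        pr <- pr * Ps[[i]][st[tree$edge[i, 1]], st[tree$edge[i, 2]]]
      }
      post[grid[r, target]] <- post[grid[r, target]] + pr
    }
  }
  post / sum(post)
}

# exhaustive DTL: minimum scenario cost over all placements of gene
# internal nodes onto species nodes
brute_dtl <- function(gene_tree, species_tree, leaf_map, costs) {
  gt <- paleoclock:::ensure_node_labels(gene_tree)
  sp <- paleoclock:::ensure_node_labels(species_tree)
  gntip <- ape::Ntip(gt); sntip <- ape::Ntip(sp)
  n_s <- sntip + sp$Nnode
  spar <- paleoclock:::parent_map(sp)
  anc <- matrix(FALSE, n_s, n_s)   # anc[i, j]: i ancestor-or-self of j
  for (v in seq_len(n_s)) {
    u <- v
    while (u != 0) { anc[u, v] <- TRUE; u <- spar[u] }
  }
  depth <- integer(n_s)
  for (v in seq_len(n_s)) {
    u <- v
    while (spar[u] != 0) { u <- spar[u]; depth[v] <- depth[v] + 1L }
  }
  edist <- function(a, b) depth[b] - depth[a]    # a ancestor of b
  skids <- paleoclock:::children_map(sp)
  gkids <- paleoclock:::children_map(gt)
  sigma <- match(leaf_map[gt$tip.label], sp$tip.label)
  n_int <- gt$Nnode
  ord <- ape::reorder.phylo(gt, "postorder")
  gpost <- c(ord$edge[, 2], gntip + 1L)
  gpost <- gpost[gpost > gntip]
  D <- unname(costs["duplication"]); Tc <- unname(costs["transfer"])
  L <- unname(costs["loss"])
  grid <- as.matrix(expand.grid(rep(list(seq_len(n_s)), n_int)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    phi <- c(sigma, grid[r, ])
    cost <- 0
    for (g in gpost) {
      s <- phi[g]
      ch <- gkids[[g - gntip]]
      s1 <- phi[ch[1]]; s2 <- phi[ch[2]]
      opts <- c()
      in1 <- anc[s, s1]; in2 <- anc[s, s2]
      if (in1 && in2) {
        if (s > sntip) {
          k2 <- skids[[s - sntip]]
          if (anc[k2[1], s1] && anc[k2[2], s2]) {
            opts <- c(opts, L * (edist(k2[1], s1) + edist(k2[2], s2)))
          }
          if (anc[k2[2], s1] && anc[k2[1], s2]) {
            opts <- c(opts, L * (edist(k2[2], s1) + edist(k2[1], s2)))
          }
        }
        opts <- c(opts, D + L * (edist(s, s1) + edist(s, s2)))
      }
      incomp1 <- !anc[s, s1] && !anc[s1, s]
      incomp2 <- !anc[s, s2] && !anc[s2, s]
      if (in1 && incomp2) opts <- c(opts, Tc + L * edist(s, s1))
      if (in2 && incomp1) opts <- c(opts, Tc + L * edist(s, s2))
      if (!length(opts)) { cost <- Inf; break }
      cost <- cost + min(opts)
    }
    best <- min(best, cost)
  }
  best
}

# clade enumeration by explicit edge walking (independent of clade_leaves)
all_clades <- function(tree) {
  ntip <- ape::Ntip(tree)
  out <- list()
  for (v in (ntip + 1):(ntip + tree$Nnode)) {
    members <- c()
    stack <- v
    while (length(stack)) {
      x <- stack[1]; stack <- stack[-1]
      kk <- tree$edge[tree$edge[, 1] == x, 2]
      for (y in kk) {
        if (y <= ntip) members <- c(members, tree$tip.label[y]) else stack <- c(stack, y)
      }
    }
    out[[length(out) + 1]] <- sort(members)
  }
  out
}

# dated two-leaf tree helper
toy_dated_tree <- function(root_age = 1000, tip_names = c("a", "b")) {
  tr <- ape::read.tree(text = sprintf("(%s:%g,%s:%g)r;", tip_names[1],
                                      root_age, tip_names[2], root_age))
  dated_tree(tr, c(stats::setNames(c(0, 0), tip_names), r = root_age))
}

ivywrel_fraction <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  mean(s %in% c("I", "V", "Y", "W", "R", "E", "L"))
}

# resample simulate_truth until the gene family size falls in a window
sample_truth_by_size <- function(make_cfg, min_leaves, max_leaves,
                                 max_tries = 200) {
  for (k in seq_len(max_tries)) {
    cfg <- make_cfg(k)
    t2 <- tryCatch(suppressMessages(simulate_truth(cfg)),
                   error = function(e) NULL)
    if (!is.null(t2)) {
      nt <- ape::Ntip(t2$gene_tree$tree)
      if (nt >= min_leaves && nt <= max_leaves) return(t2)
    }
  }
  stop("no dataset in the size window after ", max_tries, " tries")
}
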