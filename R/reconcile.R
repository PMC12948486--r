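#' Duplication-transfer-loss event costs
#'
#' Speciation costs 0. Defaults (duplication 2, transfer 3, loss 1) follow
#' common parsimony DTL practice.
#'
#' @param duplication,transfer,loss Non-negative costs.
#' @return Named numeric vector of class `dtl_costs`.
#' @export
dtl_costs <- function(duplication = 2, transfer = 3, loss = 1) {
  stopifnot(duplication >= 0, transfer >= 0, loss >= 0)
  structure(c(duplication = duplication, transfer = transfer, loss = loss),
            class = "dtl_costs")
}

# species-tree bookkeeping for the DP: ancestry matrix, depths, children
species_index <- function(stree) {
  stree <- ensure_node_labels(stree)
  ntip <- ape::Ntip(stree)
  n <- ntip + stree$Nnode
  labs <- node_labels(stree)
  par <- parent_map(stree)
  depth <- integer(n)
  ord <- (ntip + 1L):n
  # ancestor-or-self matrix by walking up from every node
  anc <- matrix(FALSE, n, n)
  for (v in seq_len(n)) {
    u <- v
    while (u != 0) {
      anc[u, v] <- TRUE
      u <- par[u]
    }
  }
  root <- which(par == 0)
  for (v in seq_len(n)) {
    u <- v; dvar <- 0L
    while (u != root) { u <- par[u]; dvar <- dvar + 1L }
    depth[v] <- dvar
  }
  kids <- children_map(stree)
  list(tree = stree, n = n, ntip = ntip, labs = labs, parent = par,
       depth = depth, anc = anc, kids = kids, root = root,
       post = order(depth, decreasing = TRUE))
}

#' Parsimony duplication-transfer-loss reconciliation
#'
#' Maps a rooted binary gene tree into a rooted binary species tree by a
#' dynamic program over (gene node x species branch), minimising total
#' duplication + transfer + loss cost (speciations free). One optimal
#' scenario is returned, with deterministic tie-breaking (speciation over
#' duplication over transfer, then smallest species-branch label). In dated
#' mode, transfers are restricted to species branches whose age intervals
#' overlap the donor's.
#'
#' @param gene_tree Rooted binary `phylo`.
#' @param species_tree Rooted binary `phylo`, or a [dated_tree()] (required
#'   for `dated = TRUE`).
#' @param leaf_map Named character vector gene leaf -> species leaf.
#' @param costs A [dtl_costs()].
#' @param dated Restrict transfers to age-overlapping branches.
#' @return List: `min_cost`, `events` (data.frame: type, gene_node, donor,
#'   recipient), `root_mapping` (species label), `n_cooptimal_roots`.
#' @export
reconcile <- function(gene_tree, species_tree, leaf_map,
                      costs = dtl_costs(), dated = FALSE) {
  sp_ages <- NULL
  if (inherits(species_tree, "dated_tree")) {
    sp_ages <- species_tree$ages
    species_tree <- species_tree$tree
  }
  if (dated && is.null(sp_ages))
    stop("dated mode needs a dated species tree", call. = FALSE)
  if (!ape::is.binary(gene_tree) || !ape::is.binary(species_tree))
    stop("both trees must be binary", call. = FALSE)
  if (!ape::is.rooted(gene_tree) || !ape::is.rooted(species_tree))
    stop("both trees must be rooted", call. = FALSE)
  gene_tree <- ensure_node_labels(gene_tree)
  si <- species_index(species_tree)
  unmapped <- setdiff(gene_tree$tip.label, names(leaf_map))
  if (length(unmapped)) stop("unmapped gene leaf/leaves: ",
                             paste(unmapped, collapse = ", "), call. = FALSE)
  sigma <- match(leaf_map[gene_tree$tip.label], si$labs[seq_len(si$ntip)])
  if (anyNA(sigma)) {
    bad <- gene_tree$tip.label[is.na(sigma)]
    stop("gene leaf/leaves map to unknown species: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  D <- unname(costs["duplication"]); Tc <- unname(costs["transfer"])
  L <- unname(costs["loss"])
  n_s <- si$n
  gntip <- ape::Ntip(gene_tree)
  n_g <- gntip + gene_tree$Nnode
  gkids <- children_map(gene_tree)
  glabs <- node_labels(gene_tree)

  # transfer compatibility: incomparable species branches (+ age overlap)
  incomp <- !(si$anc | t(si$anc))
  if (dated) {
    lo <- as.numeric(sp_ages[si$labs])
    hi <- ifelse(si$parent == 0, Inf, as.numeric(sp_ages[si$labs[pmax(si$parent, 1)]]))
    ovl <- outer(lo, hi, "<") & t(outer(lo, hi, "<"))
    incomp <- incomp & ovl
  }

  # children always precede parents when walking postorder edge children,
  # with the root appended last
  ord <- ape::reorder.phylo(gene_tree, "postorder")
  gene_post <- c(ord$edge[, 2], gntip + 1L)

  INF <- 1e18
  Cm <- matrix(INF, n_g, n_s)      # c(g, s)
  Im <- matrix(INF, n_g, n_s)      # in(g, s)
  choice <- vector("list", n_g)    # per gene node: list over s of decisions

  in_pass <- function(g) {
    # given Cm[g, ], fill Im[g, ] bottom-up over species postorder
    for (s in si$post) {
      v <- Cm[g, s]
      if (s > si$ntip) {
        for (ch in si$kids[[s - si$ntip]]) v <- min(v, Im[g, ch] + L)
      }
      Im[g, s] <<- v
    }
  }

  for (g in gene_post) {
    if (g <= gntip) {
      Cm[g, sigma[g]] <- 0
      in_pass(g)
      next
    }
    ch <- gkids[[g - gntip]]
    g1 <- ch[1]; g2 <- ch[2]
    dec <- vector("list", n_s)
    for (s in seq_len(n_s)) {
      best <- INF; bdec <- NULL
      if (s > si$ntip) {
        k2 <- si$kids[[s - si$ntip]]
        v <- Im[g1, k2[1]] + Im[g2, k2[2]]
        if (v < best) { best <- v; bdec <- list(ev = "speciation", s1 = k2[1], s2 = k2[2]) }
        v <- Im[g1, k2[2]] + Im[g2, k2[1]]
        if (v < best) { best <- v; bdec <- list(ev = "speciation", s1 = k2[2], s2 = k2[1]) }
      }
      v <- D + Im[g1, s] + Im[g2, s]
      if (v < best) { best <- v; bdec <- list(ev = "duplication", s1 = s, s2 = s) }
      cand <- which(incomp[s, ])
      if (length(cand)) {
        # child 2 transferred
        r2 <- cand[order(Cm[g2, cand], si$labs[cand])][1]
        v <- Tc + Im[g1, s] + Cm[g2, r2]
        if (v < best) { best <- v; bdec <- list(ev = "transfer", s1 = s, s2 = r2, moved = 2L) }
        r1 <- cand[order(Cm[g1, cand], si$labs[cand])][1]
        v <- Tc + Cm[g1, r1] + Im[g2, s]
        if (v < best) { best <- v; bdec <- list(ev = "transfer", s1 = r1, s2 = s, moved = 1L) }
      }
      Cm[g, s] <- best
      dec[[s]] <- bdec
    }
    choice[[g]] <- dec
    in_pass(g)
  }

  groot <- gntip + 1L
  min_cost <- min(Cm[groot, ])
  opt_roots <- which(Cm[groot, ] <= min_cost + 1e-9)
  s_root <- opt_roots[order(si$labs[opt_roots])][1]

  # backtrack one optimal scenario
  events <- list()
  add_event <- function(type, gnode, donor, recipient = NA_character_) {
    events[[length(events) + 1L]] <<- data.frame(
      type = type, gene_node = gnode, donor = donor, recipient = recipient,
      stringsAsFactors = FALSE)
  }
  descend_in <- function(g, s) {
    # follow the in() chain from s down to where c(g, .) is achieved,
    # recording a loss on each sibling branch passed
    while (Cm[g, s] > Im[g, s] + 1e-9) {
      k2 <- si$kids[[s - si$ntip]]
      nxt <- k2[order(Im[g, k2], si$labs[k2])][1]
      add_event("loss", glabs[g], si$labs[setdiff(k2, nxt)])
      s <- nxt
    }
    s
  }
  walk <- function(g, s, via_in = TRUE) {
    if (via_in) s <- descend_in(g, s)
    if (g <= gntip) return(invisible())
    dd <- choice[[g]][[s]]
    ch <- gkids[[g - gntip]]
    if (dd$ev == "speciation") {
      add_event("speciation", glabs[g], si$labs[s])
      walk(ch[1], dd$s1); walk(ch[2], dd$s2)
    } else if (dd$ev == "duplication") {
      add_event("duplication", glabs[g], si$labs[s])
      walk(ch[1], s); walk(ch[2], s)
    } else if (dd$moved == 2L) {
      add_event("transfer", glabs[g], si$labs[s], si$labs[dd$s2])
      walk(ch[1], s); walk(ch[2], dd$s2, via_in = FALSE)
    } else {
      add_event("transfer", glabs[g], si$labs[s], si$labs[dd$s1])
      walk(ch[2], s); walk(ch[1], dd$s1, via_in = FALSE)
    }
  }
  walk(groot, s_root, via_in = FALSE)
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(0), gene_node = character(0),
               donor = character(0), recipient = character(0),
               stringsAsFactors = FALSE)
  list(min_cost = min_cost, events = ev,
       root_mapping = si$labs[s_root],
       n_cooptimal_roots = length(opt_roots))
}

#' Bootstrap transfer frequencies with a retention filter
#'
#' Reconciles every replicate gene tree against the species tree; a
#' transfer's identity is its (donor branch, recipient branch) pair and its
#' frequency is the fraction of replicates containing it. Events below
#' `min_freq` are dropped.
#'
#' @param bootstrap_gene_trees List of rooted binary `phylo` replicates.
#' @param species_tree `phylo` or [dated_tree()].
#' @param leaf_map Named character vector gene leaf -> species leaf.
#' @param costs A [dtl_costs()].
#' @param min_freq Retention threshold (default 0.3).
#' @param dated Passed to [reconcile()].
#' @return Data.frame: donor, recipient, frequency (descending), with the
#'   full unfiltered table in attribute `all_events`.
#' @export
transfer_frequency <- function(bootstrap_gene_trees, species_tree, leaf_map,
                               costs = dtl_costs(), min_freq = 0.3,
                               dated = FALSE) {
  stopifnot(length(bootstrap_gene_trees) >= 1)
  n <- length(bootstrap_gene_trees)
  seen <- list()
  for (tr in bootstrap_gene_trees) {
    rec <- reconcile(tr, species_tree, leaf_map, costs, dated = dated)
    tv <- rec$events[rec$events$type == "transfer", , drop = FALSE]
    keys <- unique(paste(tv$donor, tv$recipient, sep = "\r"))
    for (kk in keys) seen[[kk]] <- (seen[[kk]] %||% 0L) + 1L
  }
  if (!length(seen)) {
    out <- data.frame(donor = character(0), recipient = character(0),
                      frequency = numeric(0), stringsAsFactors = FALSE)
    attr(out, "all_events") <- out
    return(out)
  }
  parts <- strsplit(names(seen), "\r", fixed = TRUE)
  all_ev <- data.frame(donor = vapply(parts, `[`, "", 1),
                       recipient = vapply(parts, `[`, "", 2),
                       frequency = unlist(seen) / n,
                       stringsAsFactors = FALSE)
  all_ev <- all_ev[order(-all_ev$frequency, all_ev$donor, all_ev$recipient), ]
  rownames(all_ev) <- NULL
  out <- all_ev[all_ev$frequency >= min_freq, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_events") <- all_ev
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
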