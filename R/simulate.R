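#' Simulation configuration
#'
#' Bundles every parameter of the ground-truthed generator. Ages are in Ma
#' before present; all rates are per lineage per Ma. Defaults describe the
#' scaled-down study system the package is validated on: a dated archaeal-like
#' species tree (root 3460 Ma), a sulfite-reductase-like gene family moving
#' between lineages mainly by horizontal transfer, and a hot ancestral
#' optimum cooling slowly toward the present.
#'
#' @param seed Integer seed; together with the config it fully determines
#'   every output.
#' @param n_species Number of extant species (>= 3).
#' @param birth_rate,death_rate Birth-death rates (per lineage per Ma),
#'   `birth_rate > death_rate >= 0`.
#' @param root_age Species root age in Ma.
#' @param dtl_rates Named numeric: `duplication`, `transfer`, `loss` rates
#'   (per gene lineage per Ma).
#' @param seq_length Alignment columns.
#' @param subst_model_id `"poisson"` or an empirical model id (e.g. `"LG"`).
#' @param gamma_shape Gamma shape for among-site rate variation (`NULL` for
#'   rate homogeneity).
#' @param clock_rate Expected substitutions per site per Ma.
#' @param rate_sdlog Lognormal sd of per-branch rate multipliers (0 = strict
#'   clock).
#' @param topt_root Root optimal temperature, degrees C.
#' @param topt_sigma Brownian-motion scale, degrees C per sqrt(Ma).
#' @param topt_trend Drift, degrees C per Ma (negative = cooling).
#' @param beta_comp Composition-temperature coupling (per degree C, logit
#'   space); 0 decouples sequences from the thermal trait.
#' @param comp_ref Composition pivot temperature (degrees C): the
#'   temperature at which the family's equilibrium composition equals the
#'   substitution model's base frequencies. Defaults to 60, the typical
#'   operating temperature of the simulated system, keeping compositions
#'   in the quasi-linear regime of the logit tilt across the simulated
#'   temperature range.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_species = 12L,
                       birth_rate = 1e-3,
                       death_rate = 2.5e-4,
                       root_age = 3460,
                       dtl_rates = c(duplication = 2.5e-5, transfer = 3e-4,
                                     loss = 4e-4),
                       seq_length = 300L,
                       subst_model_id = "LG",
                       gamma_shape = 1,
                       clock_rate = 2e-4,
                       rate_sdlog = 0,
                       topt_root = 73,
                       topt_sigma = 0.4,
                       topt_trend = -0.005,
                       beta_comp = 0.025,
                       comp_ref = 60) {
  dtl <- as.numeric(dtl_rates)
  if (length(dtl) != 3) stop("dtl_rates must have 3 entries", call. = FALSE)
  names(dtl) <- c("duplication", "transfer", "loss")
  cfg <- list(seed = as.integer(seed), n_species = as.integer(n_species),
              birth_rate = birth_rate, death_rate = death_rate,
              root_age = root_age, dtl_rates = dtl,
              seq_length = as.integer(seq_length),
              subst_model_id = subst_model_id, gamma_shape = gamma_shape,
              clock_rate = clock_rate, rate_sdlog = rate_sdlog,
              topt_root = topt_root, topt_sigma = topt_sigma,
              topt_trend = topt_trend, beta_comp = beta_comp,
              comp_ref = comp_ref)
  with(cfg, {
    stopifnot(n_species >= 3, root_age > 0, seq_length >= 1,
              birth_rate > death_rate, death_rate >= 0, all(dtl >= 0),
              clock_rate > 0, rate_sdlog >= 0, topt_sigma >= 0,
              beta_comp >= 0 || beta_comp < 0)
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a dated birth-death species tree
#'
#' Forward (Gillespie) birth-death simulation from a single lineage, stopped
#' at the first moment `n_species` lineages are simultaneously extant (plus a
#' short random overhang so pendant branches are never zero); extinct
#' lineages are pruned and the reconstructed tree is rescaled so the root
#' sits at `root_age`, tips at 0.
#'
#' @param config A [sim_config()].
#' @param max_retries Retry cap when the process dies out (default 100).
#' @return A [dated_tree()] with `n_species` tips labelled `s1..sN`.
#' @export
simulate_species_tree <- function(config, max_retries = 100L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lambda <- config$birth_rate; mu <- config$death_rate
  n_target <- config$n_species
  for (try in seq_len(max_retries)) {
    # lineage records: split time + children, or death time
    split_t <- list(); split_kids <- list(); dead <- integer(0)
    alive <- 1L; n_lin <- 1L
    t <- 0
    ok <- FALSE
    while (length(alive) > 0) {
      k <- length(alive)
      if (k >= n_target) {
        t <- t + stats::runif(1) * stats::rexp(1, k * (lambda + mu))
        ok <- TRUE
        break
      }
      t <- t + stats::rexp(1, k * (lambda + mu))
      who <- alive[sample.int(k, 1)]
      if (stats::runif(1) < lambda / (lambda + mu)) {
        c1 <- n_lin + 1L; c2 <- n_lin + 2L; n_lin <- n_lin + 2L
        split_t[[who]] <- t; split_kids[[who]] <- c(c1, c2)
        alive <- c(setdiff(alive, who), c1, c2)
      } else {
        dead <- c(dead, who)
        alive <- setdiff(alive, who)
      }
    }
    if (ok) {
      nwk <- bd_newick(1L, 0, t, split_t, split_kids, alive)
      if (is.null(nwk)) next
      tr <- ape::read.tree(text = paste0(nwk$str, ";"))
      if (ape::Ntip(tr) != n_target) next
      depths <- ape::node.depth.edgelength(tr)
      h <- max(depths)
      tr$edge.length <- tr$edge.length * (config$root_age / h)
      tr$tip.label <- paste0("s", seq_len(ape::Ntip(tr)))
      tr <- ensure_node_labels(tr)
      depths <- ape::node.depth.edgelength(tr)
      ages <- pmax(config$root_age - depths, 0)
      ages[seq_len(ape::Ntip(tr))] <- 0
      return(dated_tree(tr, stats::setNames(ages, node_labels(tr))))
    }
  }
  stop("birth-death simulation went extinct in all ", max_retries,
       " retries before reaching ", n_target, " species", call. = FALSE)
}

# recursive newick builder over the forward-simulation records; collapses
# extinct subtrees and pass-through lineages. Returns NULL if no extant
# descendant, else list(str) where str carries the branch length from t0.
bd_newick <- function(lin, t0, t_end, split_t, split_kids, extant) {
  has_split <- lin <= length(split_t) && !is.null(split_t[[lin]])
  if (!has_split) {
    if (!(lin %in% extant)) return(NULL)
    return(list(str = sprintf("t%d:%.10g", lin, t_end - t0)))
  }
  ts <- split_t[[lin]]
  kids <- split_kids[[lin]]
  a <- bd_newick(kids[1], ts, t_end, split_t, split_kids, extant)
  b <- bd_newick(kids[2], ts, t_end, split_t, split_kids, extant)
  if (is.null(a) && is.null(b)) return(NULL)
  if (is.null(a) || is.null(b)) {
    surv <- if (is.null(a)) b else a
    # pass-through: extend the surviving child's pendant branch
    parts <- sub(":([0-9.eE+-]+)$", "", surv$str)
    len <- as.numeric(sub("^.*:", "", surv$str))
    return(list(str = sprintf("%s:%.10g", parts, len + (ts - t0))))
  }
  list(str = sprintf("(%s,%s):%.10g", a$str, b$str, ts - t0))
}

# species edges of a dated tree as a data.frame: child id, label, age range
species_edges <- function(sp) {
  tr <- sp$tree
  labs <- node_labels(tr)
  data.frame(child = tr$edge[, 2],
             label = labs[tr$edge[, 2]],
             age_lo = as.numeric(sp$ages[tr$edge[, 2]]),
             age_hi = as.numeric(sp$ages[tr$edge[, 1]]),
             stringsAsFactors = FALSE)
}

#' Simulate a gene tree inside a dated species tree
#'
#' The gene lineage starts at the species root and evolves tipward.
#' Duplication, transfer and loss events occur as Poisson processes at the
#' configured rates; a transfer's recipient is drawn uniformly among species
#' branches alive at the event's age, excluding the donor. Lost lineages are
#' pruned and pass-through nodes collapsed.
#'
#' @param species_tree A [dated_tree()].
#' @param config A [sim_config()].
#' @param max_lineages Guard against duplication blow-up (default 1000).
#' @return List: `gene_tree` (a `dated_tree`; leaves `"<species>_g<k>"`),
#'   `events` (data.frame: type, age_ma, donor, recipient, gene_node,
#'   observable).
#' @export
simulate_gene_tree <- function(species_tree, config, max_lineages = 1000L) {
  stopifnot(inherits(species_tree, "dated_tree"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  tr <- species_tree$tree
  ntip <- ape::Ntip(tr)
  labs <- node_labels(tr)
  ages <- species_tree$ages
  kids <- children_map(tr)
  edges <- species_edges(species_tree)
  rates <- config$dtl_rates
  rho <- sum(rates)

  env <- new.env()
  env$events <- list()
  env$n_lin <- 0L

  record <- function(type, age, donor, recipient = NA_character_) {
    env$events[[length(env$events) + 1L]] <-
      list(type = type, age_ma = age, donor = donor, recipient = recipient,
           node = NULL, observable = NA)
    length(env$events)
  }

  combine <- function(a, b, age, ev_idx = NA_integer_) {
    if (!is.na(ev_idx)) {
      env$events[[ev_idx]]$observable <- !is.null(a) && !is.null(b)
    }
    if (is.null(a) && is.null(b)) return(NULL)
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    list(kind = "node", age = age, children = list(a, b), ev = ev_idx)
  }

  sim_edge <- function(sid, age_from) {
    env$n_lin <- env$n_lin + 1L
    if (env$n_lin > max_lineages * 50L)
      stop("gene-tree simulation exceeded lineage budget", call. = FALSE)
    a_end <- as.numeric(ages[sid])
    a <- age_from
    repeat {
      step <- if (rho > 0) stats::rexp(1, rho) else Inf
      if (a - step <= a_end) {
        if (sid <= ntip) {
          return(list(kind = "tip", age = 0, species = labs[sid]))
        }
        ch <- kids[[sid - ntip]]
        return(combine(sim_edge(ch[1], a_end), sim_edge(ch[2], a_end), a_end))
      }
      a <- a - step
      type <- sample(c("duplication", "transfer", "loss"), 1, prob = rates)
      if (type == "loss") {
        record("loss", a, labs[sid])
        return(NULL)
      }
      if (type == "duplication") {
        idx <- record("duplication", a, labs[sid])
        return(combine(sim_edge(sid, a), sim_edge(sid, a), a, idx))
      }
      cand <- edges$child[edges$age_lo < a & a < edges$age_hi &
                          edges$child != sid]
      if (!length(cand)) next  # no contemporaneous recipient; redraw
      rec <- cand[sample.int(length(cand), 1)]
      idx <- record("transfer", a, labs[sid], labs[rec])
      return(combine(sim_edge(sid, a), sim_edge(rec, a), a, idx))
    }
  }

  rs <- ntip + 1L
  ch <- kids[[1L]]
  root <- combine(sim_edge(ch[1], as.numeric(ages[rs])),
                  sim_edge(ch[2], as.numeric(ages[rs])),
                  as.numeric(ages[rs]))
  if (is.null(root)) stop("all gene lineages were lost", call. = FALSE)
  if (root$kind == "tip") stop("only one gene lineage survived", call. = FALSE)

  # flatten to newick + ages; label nodes g1.. in preorder, tips per species
  env$tipn <- integer(length(labs)); names(env$tipn) <- labs
  env$gn <- 0L
  env$node_age <- numeric(0)
  # build newick without lengths; dated_tree() derives lengths from ages
  build2 <- function(nd) {
    if (nd$kind == "tip") {
      env$tipn[nd$species] <- env$tipn[nd$species] + 1L
      lab <- paste0(nd$species, "_g", env$tipn[nd$species])
      env$node_age[lab] <- 0
      return(lab)
    }
    env$gn <- env$gn + 1L
    lab <- paste0("g", env$gn)
    env$node_age[lab] <- nd$age
    if (!is.null(nd$ev) && !is.na(nd$ev)) env$events[[nd$ev]]$node <- lab
    a <- build2(nd$children[[1]]); b <- build2(nd$children[[2]])
    sprintf("(%s,%s)%s", a, b, lab)
  }
  env$tipn[] <- 0L
  nwk <- build2(root)
  gt <- ape::read.tree(text = paste0(nwk, ";"))
  gd <- dated_tree(gt, env$node_age[node_labels(gt)])

  ev <- env$events
  events <- data.frame(
    type = vapply(ev, `[[`, "", "type"),
    age_ma = vapply(ev, `[[`, 0, "age_ma"),
    donor = vapply(ev, `[[`, "", "donor"),
    recipient = vapply(ev, `[[`, "", "recipient"),
    gene_node = vapply(ev, function(e) if (is.null(e$node)) NA_character_ else e$node, ""),
    observable = vapply(ev, function(e) isTRUE(e$observable), NA),
    stringsAsFactors = FALSE)
  if (!nrow(events)) {
    events <- data.frame(type = character(0), age_ma = numeric(0),
                         donor = character(0), recipient = character(0),
                         gene_node = character(0), observable = logical(0))
  }
  list(gene_tree = gd, events = events)
}

#' Map gene leaves to species leaves
#'
#' Gene leaves are named `"<species>_g<copy>"` by the generator; this strips
#' the copy suffix.
#'
#' @param gene_leaves Character vector of gene leaf labels.
#' @return Named character vector (gene leaf -> species leaf).
#' @export
leaf_species_map <- function(gene_leaves) {
  stats::setNames(sub("_g[0-9]+$", "", gene_leaves), gene_leaves)
}

#' Simulate a Brownian thermal trait on a dated tree
#'
#' Root value `topt_root`; each child is parent `+ trend * dt +
#' Normal(0, sigma^2 * dt)`. Values are clipped to `[0, 110]` degrees C and
#' clipping is reported via a message and the `clipped` attribute.
#'
#' @param gene_tree A [dated_tree()].
#' @param config A [sim_config()].
#' @return Named numeric vector of temperatures over all node labels.
#' @export
simulate_thermal_trait <- function(gene_tree, config) {
  stopifnot(inherits(gene_tree, "dated_tree"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  tr <- gene_tree$tree
  ages <- gene_tree$ages
  labs <- node_labels(tr)
  topt <- stats::setNames(rep(NA_real_, length(labs)), labs)
  topt[ape::Ntip(tr) + 1L] <- config$topt_root
  edges <- tr$edge[order(-as.numeric(ages[tr$edge[, 2]]), tr$edge[, 2]), ,
                   drop = FALSE]
  # preorder: parents always before children because parent age > child age
  clipped <- character(0)
  for (i in seq_len(nrow(edges))) {
    p <- edges[i, 1]; c <- edges[i, 2]
    dt <- as.numeric(ages[p] - ages[c])
    v <- topt[p] + config$topt_trend * dt +
      stats::rnorm(1, 0, config$topt_sigma * sqrt(max(dt, 0)))
    if (v < 0 || v > 110) {
      clipped <- c(clipped, labs[c])
      v <- min(max(v, 0), 110)
    }
    topt[c] <- v
  }
  if (length(clipped)) {
    message("thermal trait clipped to [0, 110] C at node(s): ",
            paste(clipped, collapse = ", "))
  }
  attr(topt, "clipped") <- clipped
  topt
}

#' Simulate thermally coupled protein sequences on a dated gene tree
#'
#' Site-independent reversible evolution. Each branch uses equilibrium
#' frequencies tilted by the mean of the parent and child temperatures (see
#' [thermal_freqs()]); branch lengths in substitutions/site are
#' `dt * clock_rate * m`, with `m` a lognormal per-branch multiplier
#' (sd `rate_sdlog`, mean 1). Site rates follow the model's discrete-gamma
#' categories. No indels: the output is an alignment.
#'
#' @param gene_tree A [dated_tree()].
#' @param node_topt Named temperatures covering every node label.
#' @param config A [sim_config()].
#' @return Leaf alignment matrix. Attributes: `node_sequences` (named
#'   character vector of true internal-node sequences), `subs_tree` (the
#'   gene `phylo` with branch lengths in substitutions/site), `site_rates`.
#' @export
simulate_sequences <- function(gene_tree, node_topt, config) {
  stopifnot(inherits(gene_tree, "dated_tree"), inherits(config, "sim_config"))
  tr <- gene_tree$tree
  labs <- node_labels(tr)
  miss <- setdiff(labs, names(node_topt))
  if (length(miss)) stop("node_topt missing node(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  set.seed(config$seed + 3L)
  model <- subst_model(config$subst_model_id, shape = config$gamma_shape)
  L <- config$seq_length
  ntip <- ape::Ntip(tr)
  n_all <- ntip + tr$Nnode
  ages <- gene_tree$ages
  root <- ntip + 1L

  cat_of_site <- sample.int(model$k, L, replace = TRUE)
  rates <- model$rates

  ref <- config$comp_ref %||% 60
  pi_at <- function(T) thermal_freqs(model$pi, T, config$beta_comp, ref = ref)
  states <- matrix(NA_integer_, n_all, L)
  states[root, ] <- sample.int(20, L, replace = TRUE,
                               prob = pi_at(node_topt[labs[root]]))
  edges <- tr$edge[order(-as.numeric(ages[tr$edge[, 2]]), tr$edge[, 2]), ,
                   drop = FALSE]
  subs_len <- stats::setNames(numeric(length(labs)), labs)
  for (i in seq_len(nrow(edges))) {
    p <- edges[i, 1]; ch <- edges[i, 2]
    dt <- as.numeric(ages[p] - ages[ch])
    m <- if (config$rate_sdlog > 0) {
      stats::rlnorm(1, meanlog = -config$rate_sdlog^2 / 2,
                    sdlog = config$rate_sdlog)
    } else 1
    blen <- dt * config$clock_rate * m
    subs_len[labs[ch]] <- blen
    Tm <- (node_topt[labs[p]] + node_topt[labs[ch]]) / 2
    pib <- pi_at(Tm)
    Qb <- build_generator(model$S, pib)
    eig <- reversible_eigen(Qb, pib)
    mb <- list(eig = eig)
    child <- states[p, ]
    if (blen > 0) {
      for (cc in seq_len(model$k)) {
        sites <- which(cat_of_site == cc)
        if (!length(sites)) next
        P <- transition_prob(mb, blen * rates[cc])
        ps <- states[p, sites]
        for (s in sort(unique(ps))) {
          idx <- sites[ps == s]
          child[idx] <- sample.int(20, length(idx), replace = TRUE,
                                   prob = P[s, ])
        }
      }
    }
    states[ch, ] <- child
  }
  seq_of <- function(i) paste(AA20[states[i, ]], collapse = "")
  aln <- do.call(rbind, lapply(seq_len(ntip), function(i) AA20[states[i, ]]))
  rownames(aln) <- tr$tip.label
  node_seqs <- vapply((ntip + 1L):n_all, seq_of, character(1))
  names(node_seqs) <- labs[(ntip + 1L):n_all]
  st <- tr
  st$edge.length <- as.numeric(subs_len[labs[tr$edge[, 2]]])
  attr(aln, "node_sequences") <- node_seqs
  attr(aln, "subs_tree") <- st
  attr(aln, "site_rates") <- rates[cat_of_site]
  aln
}

#' Simulate a complete ground-truthed dataset
#'
#' Chains [simulate_species_tree()], [simulate_gene_tree()],
#' [simulate_thermal_trait()] and [simulate_sequences()].
#'
#' @param config A [sim_config()].
#' @return List of class `synthetic_truth`: `config`, `species_tree`,
#'   `gene_tree`, `events`, `node_topt`, `alignment`, `leaf_map`.
#' @export
simulate_truth <- function(config) {
  sp <- simulate_species_tree(config)
  g <- simulate_gene_tree(sp, config)
  topt <- suppressMessages(simulate_thermal_trait(g$gene_tree, config))
  aln <- simulate_sequences(g$gene_tree, topt, config)
  structure(list(config = config, species_tree = sp,
                 gene_tree = g$gene_tree, events = g$events,
                 node_topt = topt, alignment = aln,
                 leaf_map = leaf_species_map(g$gene_tree$tree$tip.label)),
            class = "synthetic_truth")
}

#' Truth-level projectable transfer calibrations
#'
#' Lists the observable true transfers whose recipient species branch
#' subtends a monophyletic gene clade of at least `min_clade_size` leaves —
#' i.e. the transfers a reconciliation-based calibration projection could
#' in principle recover.
#'
#' @param truth A `synthetic_truth`.
#' @param min_clade_size Minimum gene-clade size (default 3).
#' @param dense Require every species below the recipient branch to carry
#'   the gene (the taxonomically dense configuration in which a
#'   reconciliation can pinpoint the recipient; default `FALSE`).
#' @return Data.frame: recipient, donor, age_ma (event), age_lo, age_hi
#'   (recipient branch interval), n_leaves, lca_label, lca_age_ma.
#' @export
truth_transfer_calibrations <- function(truth, min_clade_size = 3L,
                                        dense = FALSE) {
  sp <- truth$species_tree
  gt <- truth$gene_tree
  par <- parent_map(sp$tree)
  ev <- truth$events
  ev <- ev[ev$type == "transfer" & ev$observable, , drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(ev))) {
    rid <- match(ev$recipient[i], node_labels(sp$tree))
    if (is.na(rid) || par[rid] == 0) next
    spl <- clade_leaves(sp$tree, rid)
    gl <- names(truth$leaf_map)[truth$leaf_map %in% spl]
    if (length(gl) < min_clade_size) next
    if (dense && !all(spl %in% truth$leaf_map)) next
    if (!monophyly_check(gt$tree, gl)) next
    lca <- lca_node(gt$tree, gl)
    out <- rbind(out, data.frame(
      recipient = ev$recipient[i], donor = ev$donor[i],
      age_ma = ev$age_ma[i],
      age_lo = as.numeric(sp$ages[rid]),
      age_hi = as.numeric(sp$ages[par[rid]]),
      n_leaves = length(gl),
      lca_label = node_labels(gt$tree)[lca],
      lca_age_ma = as.numeric(gt$ages[lca]),
      stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    out <- data.frame(recipient = character(0), donor = character(0),
                      age_ma = numeric(0), age_lo = numeric(0),
                      age_hi = numeric(0), n_leaves = integer(0),
                      lca_label = character(0), lca_age_ma = numeric(0),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Simulate a calibratable ground-truthed dataset
#'
#' Draws [simulate_truth()] datasets (advancing the seed deterministically)
#' until one is analyzable by the transfer-calibrated dating chain: the gene
#' family survives with at least `min_leaves` leaves and at least one
#' observable transfer projects onto a monophyletic gene clade of
#' `min_clade_size`+ leaves. Mirrors the fact that the dating strategy
#' applies to gene families that possess dated transfer calibrations.
#'
#' @param config A [sim_config()]; its seed determines the whole search.
#' @param min_leaves,max_leaves Window on surviving gene leaves (defaults
#'   8-24, bracketing the nominal scaled condition of ~16 leaves).
#' @param min_clade_size See [truth_transfer_calibrations()].
#' @param dense See [truth_transfer_calibrations()]; default `TRUE`.
#' @param max_tries Attempt cap (default 500).
#' @return A `synthetic_truth`; attributes `n_tries`,
#'   `truth_calibrations`.
#' @export
simulate_calibratable_truth <- function(config, min_leaves = 8L,
                                        max_leaves = 24L,
                                        min_clade_size = 3L,
                                        dense = TRUE,
                                        max_tries = 500L) {
  for (k in seq_len(max_tries)) {
    cfg_k <- config
    cfg_k$seed <- as.integer((config$seed + 7919 * (k - 1)) %% .Machine$integer.max)
    truth <- tryCatch(suppressMessages(simulate_truth(cfg_k)),
                      error = function(e) NULL)
    if (is.null(truth)) next
    nt <- ape::Ntip(truth$gene_tree$tree)
    if (nt < min_leaves || nt > max_leaves) next
    tc <- truth_transfer_calibrations(truth, min_clade_size, dense = dense)
    if (nrow(tc) >= 1) {
      attr(truth, "n_tries") <- k
      attr(truth, "truth_calibrations") <- tc
      return(truth)
    }
  }
  stop("no calibratable dataset found in ", max_tries, " attempts",
       call. = FALSE)
}

#' Labelled fixture for the homolog screen
#'
#' Emits a mixture of (i) true adjacent A/B pairs whose A subunit carries
#' both the siroheme-binding and the Fe4S4-binding motif, (ii) pairs whose A
#' subunit misses one motif, and (iii) motif-positive pairs that are not
#' adjacent on their contig, with truth labels in the metadata.
#'
#' @param seed Integer seed.
#' @param n_true,n_motif_fail,n_adj_fail Counts per category.
#' @param seq_len Length of each subunit sequence (>= 60).
#' @return List: `sequences` (named character vector), `meta` (data.frame:
#'   id, genome_id, contig_id, gene_index, subunit, label, pair_id).
#' @export
make_screen_fixture <- function(seed = 1L, n_true = 10L, n_motif_fail = 5L,
                                n_adj_fail = 5L, seq_len = 120L) {
  set.seed(seed)
  stopifnot(seq_len >= 60)
  no_c <- setdiff(AA20, "C")
  rand_seq <- function(n, alphabet = no_c) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
  }
  siro <- function() paste0("C", rand_seq(5), "C", rand_seq(5), "C",
                            rand_seq(3), "C")
  fe4s4 <- function() paste0("C", rand_seq(2), "C", rand_seq(2), "C")
  with_motifs <- function(which = c("both", "siro", "fe")) {
    which <- match.arg(which)
    core <- switch(which,
      both = paste0(siro(), rand_seq(8), fe4s4()),
      siro = siro(),
      fe = fe4s4())
    pad <- seq_len - nchar(core)
    paste0(rand_seq(max(pad %/% 2, 3)), core, rand_seq(max(pad - pad %/% 2, 3)))
  }
  seqs <- character(0); meta <- NULL
  add <- function(pair_id, label, a_seq, b_seq, idx_a, idx_b, contig_b = NULL) {
    genome <- sprintf("G%03d", pair_id)
    contig <- paste0(genome, "_c1")
    ida <- paste0(genome, "_dsrA"); idb <- paste0(genome, "_dsrB")
    seqs[[ida]] <<- a_seq; seqs[[idb]] <<- b_seq
    meta <<- rbind(meta, data.frame(
      id = c(ida, idb), genome_id = genome,
      contig_id = c(contig, if (is.null(contig_b)) contig else contig_b),
      gene_index = c(idx_a, idx_b), subunit = c("A", "B"),
      label = label, pair_id = pair_id, stringsAsFactors = FALSE))
  }
  pid <- 0L
  for (i in seq_len(n_true)) {
    pid <- pid + 1L
    add(pid, "true_pair", with_motifs("both"), rand_seq(seq_len), 4L, 5L)
  }
  for (i in seq_len(n_motif_fail)) {
    pid <- pid + 1L
    add(pid, "motif_fail", with_motifs(if (i %% 2) "siro" else "fe"),
        rand_seq(seq_len), 4L, 5L)
  }
  for (i in seq_len(n_adj_fail)) {
    pid <- pid + 1L
    add(pid, "adjacency_fail", with_motifs("both"), rand_seq(seq_len), 4L, 6L)
  }
  if (is.null(meta)) {
    meta <- data.frame(id = character(0), genome_id = character(0),
                       contig_id = character(0), gene_index = integer(0),
                       subunit = character(0), label = character(0),
                       pair_id = integer(0), stringsAsFactors = FALSE)
  }
  list(sequences = seqs, meta = meta)
}

#' Write a synthetic truth bundle to disk
#'
#' Emits aligned FASTA, Newick trees, node-age TSVs, the true event table
#' and a manifest naming every artifact with its md5 digest and the config
#' hash.
#'
#' @param truth A `synthetic_truth` from [simulate_truth()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest as a list.
#' @export
write_truth_bundle <- function(truth, dir) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(dir, x)
  write_alignment(truth$alignment, f("alignment.fasta"))
  ape::write.tree(truth$species_tree$tree, f("species_tree.nwk"))
  ape::write.tree(truth$gene_tree$tree, f("gene_tree.nwk"))
  write_ages_tsv(truth$species_tree, f("species_ages.tsv"))
  write_ages_tsv(truth$gene_tree, f("gene_ages.tsv"))
  utils::write.table(truth$events, f("events.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(node = names(truth$node_topt),
               topt_c = as.numeric(truth$node_topt)),
    f("node_topt.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  cfgfile <- f("config.yaml")
  yaml::write_yaml(unclass(truth$config), cfgfile)
  arts <- c("alignment.fasta", "species_tree.nwk", "gene_tree.nwk",
            "species_ages.tsv", "gene_ages.tsv", "events.tsv",
            "node_topt.tsv", "config.yaml")
  manifest <- list(config_hash = unname(tools::md5sum(cfgfile)),
                   artifacts = as.list(stats::setNames(
                     unname(tools::md5sum(file.path(dir, arts))), arts)))
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
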