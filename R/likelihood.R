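# ---- internal pruning machinery -------------------------------------------
# Alignments are converted to integer codes (1..20, NA = gap/X/missing) and
# compressed to unique site patterns with weights. Partial likelihoods are
# 20 x S matrices per node and gamma category, rescaled per column with the
# cumulative log-scale carried alongside (numerically safe for deep trees).

aln_codes <- function(aln) {
  aln <- as_alignment(aln)
  m <- matrix(match(aln, AA20), nrow(aln), ncol(aln),
              dimnames = dimnames(aln))
  m
}

compress_patterns <- function(codes) {
  key <- apply(codes, 2, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[first])))
  list(codes = codes[, first, drop = FALSE], weights = w,
       index = match(key, key[first]))
}

# tip partial: indicator columns, all-ones for missing
tip_partial <- function(code_row) {
  S <- length(code_row)
  M <- matrix(0, 20, S)
  obs <- !is.na(code_row)
  M[cbind(code_row[obs], which(obs))] <- 1
  M[, !obs] <- 1
  M
}

check_leaves_match <- function(tree, aln) {
  miss <- setdiff(tree$tip.label, rownames(aln))
  if (length(miss)) stop("alignment missing leaf/leaves: ",
                         paste(miss, collapse = ", "), call. = FALSE)
}

# Downward (post-order) conditional likelihoods for every node and category.
# Returns down[[node]][[cat]] (20 x S) and dslog[[node]][[cat]] (length-S
# cumulative log scalers).
pruning_down <- function(tree, pat, model) {
  ntip <- length(tree$tip.label)
  n_all <- ntip + tree$Nnode
  k <- model$k
  S <- length(pat$weights)
  elen <- numeric(n_all)
  elen[tree$edge[, 2]] <- tree$edge.length
  down <- vector("list", n_all)
  dslog <- vector("list", n_all)
  for (i in seq_len(ntip)) {
    tp <- tip_partial(pat$codes[match(tree$tip.label[i], rownames(pat$codes)), ])
    down[[i]] <- rep(list(tp), k)
    dslog[[i]] <- rep(list(numeric(S)), k)
  }
  ord <- ape::reorder.phylo(tree, "postorder")
  parents <- unique(ord$edge[, 1])
  kids_of <- split(ord$edge[, 2], factor(ord$edge[, 1], levels = parents))
  for (p in parents) {
    down[[p]] <- vector("list", k)
    dslog[[p]] <- vector("list", k)
    for (cc in seq_len(k)) {
      M <- matrix(1, 20, S)
      slog <- numeric(S)
      for (ch in kids_of[[as.character(p)]]) {
        P <- transition_prob(model, elen[ch] * model$rates[cc])
        M <- M * (P %*% down[[ch]][[cc]])
        slog <- slog + dslog[[ch]][[cc]]
      }
      sc <- col_max(M)
      sc[sc <= 0] <- 1
      down[[p]][[cc]] <- sweep(M, 2, sc, "/")
      dslog[[p]][[cc]] <- slog + log(sc)
    }
  }
  list(down = down, dslog = dslog, elen = elen,
       root = parents[length(parents)])
}

# Above-partials: G[[v]] is the conditional likelihood of everything outside
# the subtree of v, expressed at v's *parent* (pre-transition across v's
# branch); the root prior pi is folded in at the root. aslog carries scalers.
pruning_above <- function(tree, dn, model) {
  ntip <- length(tree$tip.label)
  n_all <- ntip + tree$Nnode
  k <- model$k
  S <- length(dn$dslog[[1]][[1]])
  root <- dn$root
  G <- vector("list", n_all)
  gslog <- vector("list", n_all)
  ord <- ape::reorder.phylo(tree, "postorder")
  parents <- unique(ord$edge[, 1])
  kids_of <- split(ord$edge[, 2], factor(ord$edge[, 1], levels = parents))
  # A[[v]]: above-partial AT node v (post-transition); root gets pi
  A <- vector("list", n_all)
  aslog <- vector("list", n_all)
  A[[root]] <- rep(list(matrix(model$pi, 20, S)), k)
  aslog[[root]] <- rep(list(numeric(S)), k)
  for (p in rev(parents)) {   # preorder
    kids <- kids_of[[as.character(p)]]
    for (cc in seq_len(k)) {
      contrib <- lapply(kids, function(ch) {
        P <- transition_prob(model, dn$elen[ch] * model$rates[cc])
        P %*% dn$down[[ch]][[cc]]
      })
      for (j in seq_along(kids)) {
        ch <- kids[j]
        M <- A[[p]][[cc]]
        slog <- aslog[[p]][[cc]]
        for (l in seq_along(kids)) {
          if (l == j) next
          M <- M * contrib[[l]]
          slog <- slog + dn$dslog[[kids[l]]][[cc]]
        }
        sc <- col_max(M)
        sc[sc <= 0] <- 1
        M <- sweep(M, 2, sc, "/")
        slog <- slog + log(sc)
        if (is.null(G[[ch]])) { G[[ch]] <- vector("list", k); gslog[[ch]] <- vector("list", k) }
        G[[ch]][[cc]] <- M
        gslog[[ch]][[cc]] <- slog
        if (ch > ntip) {
          P <- transition_prob(model, dn$elen[ch] * model$rates[cc])
          if (is.null(A[[ch]])) { A[[ch]] <- vector("list", k); aslog[[ch]] <- vector("list", k) }
          A[[ch]][[cc]] <- crossprod(P, M)
          aslog[[ch]][[cc]] <- slog
        }
      }
    }
  }
  list(G = G, gslog = gslog, A = A, aslog = aslog, root = root)
}

col_max <- function(M) {
  out <- M[1, ]
  for (i in 2:nrow(M)) out <- pmax.int(out, M[i, ])
  out
}

logsumexp <- function(m) {
  # rows = components, cols = sites
  mx <- apply(m, 2, max)
  mx + log(colSums(exp(sweep(m, 2, mx, "-"))))
}

loglik_from_down <- function(dn, model, weights) {
  k <- model$k
  comp <- vapply(seq_len(k), function(cc) {
    lik <- colSums(model$pi * dn$down[[dn$root]][[cc]])
    log(pmax(lik, 1e-300)) + dn$dslog[[dn$root]][[cc]] - log(k)
  }, numeric(length(weights)))
  sll <- logsumexp(t(matrix(comp, ncol = k)))
  sum(weights * sll)
}

#' Phylogenetic log-likelihood by the pruning algorithm
#'
#' Felsenstein pruning over sites with a discrete-gamma rate mixture
#' (equal-weight categories averaged per site). Gaps and `X` are treated as
#' missing data. Works on rooted or unrooted trees; for reversible models
#' the value is invariant to root placement.
#'
#' @param tree A `phylo` with branch lengths in substitutions/site.
#' @param aln Alignment matrix (rows named by the tree's tips).
#' @param model A [subst_model()].
#' @return Log-likelihood (scalar).
#' @export
log_likelihood <- function(tree, aln, model) {
  aln <- as_alignment(aln)
  if (ncol(aln) == 0) stop("zero-length alignment", call. = FALSE)
  check_leaves_match(tree, aln)
  pat <- compress_patterns(aln_codes(aln))
  dn <- pruning_down(tree, pat, model)
  loglik_from_down(dn, model, pat$weights)
}

# per-edge log-likelihood profile: given above/below partials, the total
# log-likelihood as a function of one branch length
edge_loglik_fun <- function(dn, ab, model, weights, v) {
  k <- model$k
  S <- length(weights)
  function(t) {
    comp <- vapply(seq_len(k), function(cc) {
      P <- transition_prob(model, t * model$rates[cc])
      lik <- colSums(ab$G[[v]][[cc]] * (P %*% dn$down[[v]][[cc]]))
      log(pmax(lik, 1e-300)) + dn$dslog[[v]][[cc]] + ab$gslog[[v]][[cc]] - log(k)
    }, numeric(S))
    sum(weights * logsumexp(t(matrix(comp, ncol = k))))
  }
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Coordinate-wise 1-D optimisation of every branch (bounded `[0, 20]`
#' substitutions/site), cycled until the total log-likelihood improves by
#' less than `tol`. The likelihood never decreases between cycles; proposals
#' that do not improve are rejected.
#'
#' @param tree A `phylo` with starting branch lengths (zero/missing lengths
#'   are started at 0.05).
#' @param aln Alignment matrix.
#' @param model A [subst_model()].
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_cycles Cycle cap (default 100); non-convergence returns the
#'   current tree with a warning and `converged = FALSE` attribute.
#' @param max_blen Upper bound per branch (default 20).
#' @return The tree with fitted `edge.length`; attributes `loglik`,
#'   `converged`, `cycles`.
#' @export
fit_branch_lengths <- function(tree, aln, model, tol = 1e-6,
                               max_cycles = 100L, max_blen = 20) {
  aln <- as_alignment(aln)
  check_leaves_match(tree, aln)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.05, nrow(tree$edge))
  tree$edge.length[!is.finite(tree$edge.length) | tree$edge.length < 0] <- 0.05
  pat <- compress_patterns(aln_codes(aln))
  ll <- log_likelihood_pat(tree, pat, model)
  converged <- FALSE
  cycles <- 0L
  for (cyc in seq_len(max_cycles)) {
    cycles <- cyc
    ll0 <- ll
    for (ei in seq_len(nrow(tree$edge))) {
      v <- tree$edge[ei, 2]
      dn <- pruning_down(tree, pat, model)
      ab <- pruning_above(tree, dn, model)
      f <- edge_loglik_fun(dn, ab, model, pat$weights, v)
      opt <- stats::optimize(f, interval = c(0, max_blen), maximum = TRUE,
                             tol = 1e-6)
      cand <- opt$maximum
      if (opt$objective > ll + 1e-12) {
        tree$edge.length[ei] <- if (cand < 1e-8) 0 else cand
        ll <- f(tree$edge.length[ei])
      }
    }
    if (ll - ll0 < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("branch-length optimisation did not converge within ",
            max_cycles, " cycles")
  }
  attr(tree, "loglik") <- ll
  attr(tree, "converged") <- converged
  attr(tree, "cycles") <- cycles
  tree
}

log_likelihood_pat <- function(tree, pat, model) {
  dn <- pruning_down(tree, pat, model)
  loglik_from_down(dn, model, pat$weights)
}
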