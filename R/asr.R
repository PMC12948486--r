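#' Marginal empirical-Bayes ancestral sequence reconstruction
#'
#' Per internal node and site, the marginal posterior over the 20 residues
#' is proportional to the product of the conditional likelihood of the data
#' below the node and the likelihood of the rest of the tree above it,
#' mixed over the discrete-gamma categories. Branch lengths are taken as
#' fixed; no molecular clock is assumed. The maximum-posterior residue is
#' reported per site, ties broken alphabetically.
#'
#' @param tree Rooted `phylo` with branch lengths in subst/site.
#' @param aln Alignment matrix (rows cover the tree's tips).
#' @param model A [subst_model()].
#' @return List of class `ancestral_states`: `map_sequences` (named
#'   character vector per internal node), `posterior` (list of site x 20
#'   matrices per internal node), `mean_pp` (mean per-site posterior of the
#'   MAP residue per node).
#' @export
marginal_asr <- function(tree, aln, model) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  tree <- ensure_node_labels(tree)
  aln <- as_alignment(aln)
  check_leaves_match(tree, aln)
  pat <- compress_patterns(aln_codes(aln))
  dn <- pruning_down(tree, pat, model)
  ab <- pruning_above(tree, dn, model)
  ntip <- ape::Ntip(tree)
  n_all <- ntip + tree$Nnode
  labs <- node_labels(tree)
  k <- model$k
  S <- length(pat$weights)
  posterior <- list()
  map_seqs <- character(0)
  mean_pp <- numeric(0)
  for (v in (ntip + 1L):n_all) {
    num <- matrix(0, 20, S)
    # per-site log weights differ across categories; combine on a common scale
    lw <- vapply(seq_len(k), function(cc) dn$dslog[[v]][[cc]] + ab$aslog[[v]][[cc]],
                 numeric(S))
    lw <- matrix(lw, nrow = S)
    mx <- apply(lw, 1, max)
    for (cc in seq_len(k)) {
      num <- num + sweep(dn$down[[v]][[cc]] * ab$A[[v]][[cc]], 2,
                         exp(lw[, cc] - mx), "*")
    }
    tot <- colSums(num)
    post_pat <- t(sweep(num, 2, tot, "/"))   # S x 20
    post <- post_pat[pat$index, , drop = FALSE]
    colnames(post) <- AA20
    # MAP with alphabetical tie-break
    map_idx <- apply(post, 1, function(p) {
      cand <- which(p >= max(p) - 1e-12)
      cand[order(AA20[cand])][1]
    })
    lab <- labs[v]
    posterior[[lab]] <- post
    map_seqs[lab] <- paste(AA20[map_idx], collapse = "")
    mean_pp[lab] <- mean(post[cbind(seq_len(nrow(post)), map_idx)])
  }
  structure(list(map_sequences = map_seqs, posterior = posterior,
                 mean_pp = mean_pp),
            class = "ancestral_states")
}

#' Residue composition of a protein sequence
#'
#' Frequencies over the 20 amino acids, ignoring gaps and `X`.
#'
#' @param sequence Amino-acid string.
#' @return Named numeric 20-vector summing to 1.
#' @export
composition <- function(sequence) {
  s <- strsplit(toupper(sequence), "")[[1]]
  s <- s[s %in% AA20]
  if (!length(s)) stop("no countable residues in sequence", call. = FALSE)
  tab <- table(factor(s, levels = AA20))
  stats::setNames(as.numeric(tab) / length(s), AA20)
}

#' Fit a linear optimal-temperature model on residue composition
#'
#' Ridge-regularised least squares of Topt on the 20 residue frequencies
#' (penalty on the coefficients, none on the intercept; the objective is
#' mean squared error + lambda * ||coef||^2, so the fit is invariant to
#' duplicating the training set). A transparent stand-in for learned
#' sequence-based Topt predictors; real predictor output can be imported
#' instead via [predict_topt()]'s override mode.
#'
#' @param compositions Matrix (n x 20) of residue frequencies, or a list of
#'   sequences/compositions.
#' @param topt Numeric vector of training temperatures (degrees C).
#' @param lambda Ridge penalty (default 1e-3).
#' @return Object of class `topt_model`: `intercept`, `coefficients`
#'   (named 20-vector), `lambda`.
#' @export
fit_topt_model <- function(compositions, topt, lambda = 1e-3) {
  X <- compositions_matrix(compositions)
  stopifnot(nrow(X) == length(topt))
  if (nrow(X) < 22) stop("need at least 22 training pairs", call. = FALSE)
  # standardized ridge: penalty applies to unit-variance coefficients, so
  # lambda is a dimensionless shrinkage fraction and the fit is invariant
  # to duplicating the training set
  n <- nrow(X)
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2, mu, "-")^2))   # population scale:
  sdv[sdv == 0] <- 1                              # duplication-invariant
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  ybar <- mean(topt)
  M <- crossprod(Xs) / n + diag(lambda, 20)
  bs <- tryCatch(solve(M, crossprod(Xs, topt - ybar) / n),
                 error = function(e)
                   stop("degenerate design; increase lambda", call. = FALSE))
  b <- as.numeric(bs) / sdv
  structure(list(intercept = ybar - sum(b * mu),
                 coefficients = stats::setNames(b, AA20),
                 lambda = lambda),
            class = "topt_model")
}

compositions_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 20)
    colnames(x) <- AA20
    return(x)
  }
  if (is.character(x)) x <- as.list(x)
  do.call(rbind, lapply(x, function(el) {
    if (is.character(el)) composition(el) else {
      stopifnot(length(el) == 20)
      as.numeric(el)
    }
  }))
}

#' Predict optimal temperature from sequence composition
#'
#' Either applies a fitted [fit_topt_model()], or (override mode) reads
#' per-node predictions from an external TSV (columns `node`, `topt_c`),
#' e.g. the output of a learned predictor.
#'
#' @param x Sequence string(s), composition vector, or composition matrix;
#'   in override mode, the node name(s) to look up.
#' @param model A `topt_model` (ignored in override mode).
#' @param override Path to a node -> Topt TSV, or a data.frame with columns
#'   `node` and `topt_c`.
#' @return Numeric vector of temperatures (degrees C).
#' @export
predict_topt <- function(x, model = NULL, override = NULL) {
  if (!is.null(override)) {
    df <- if (is.character(override)) {
      utils::read.table(override, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    } else override
    idx <- match(x, df$node)
    if (anyNA(idx)) stop("override table missing node(s): ",
                         paste(x[is.na(idx)], collapse = ", "), call. = FALSE)
    return(stats::setNames(df$topt_c[idx], x))
  }
  stopifnot(inherits(model, "topt_model"))
  X <- compositions_matrix(x)
  out <- as.numeric(model$intercept + X %*% model$coefficients)
  if (is.character(x) && !is.null(names(x))) names(out) <- names(x)
  if (!is.null(rownames(X))) names(out) <- rownames(X)
  out
}

#' Linear regression of Topt on evolutionary distance
#'
#' Ordinary least squares of optimal temperature against distance from a
#' reference ancestor, with the two-sided slope p-value from the t
#' distribution on n - 2 degrees of freedom.
#'
#' @param distance,topt Numeric vectors (>= 3 points).
#' @return List: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
topt_distance_regression <- function(distance, topt) {
  stopifnot(length(distance) == length(topt))
  if (length(distance) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::var(distance) == 0)
    stop("zero distance variance; slope undefined", call. = FALSE)
  if (stats::var(topt) == 0)
    stop("constant Topt; R-squared undefined", call. = FALSE)
  fit <- stats::lm(topt ~ distance)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       n = length(distance))
}

#' Thermal profile of every tree node
#'
#' Combines ancestral MAP sequences with the extant leaves, predicts Topt
#' for each, and measures each node's patristic distance to a reference
#' node.
#'
#' @param tree Rooted `phylo` with branch lengths in subst/site.
#' @param aln Leaf alignment.
#' @param asr An [marginal_asr()] result for `tree`/`aln` (computed if
#'   `NULL`).
#' @param model_subst A [subst_model()] (used only if `asr` is `NULL`).
#' @param topt_model A `topt_model`, or `NULL` with `override`.
#' @param reference Node label of the reference ancestor.
#' @param override Optional override table/path (see [predict_topt()]).
#' @return Data.frame: node, topt_c, distance, is_leaf.
#' @export
thermal_profile <- function(tree, aln, topt_model, reference,
                            asr = NULL, model_subst = NULL, override = NULL) {
  tree <- ensure_node_labels(tree)
  aln <- as_alignment(aln)
  if (is.null(asr) && is.null(override)) {
    asr <- marginal_asr(tree, aln, model_subst)
  }
  dist <- distance_to_reference(tree, reference)
  labs <- node_labels(tree)
  is_leaf <- labs %in% tree$tip.label
  if (!is.null(override)) {
    topt <- predict_topt(labs, override = override)
  } else {
    seqs <- c(stats::setNames(apply(aln[tree$tip.label, , drop = FALSE], 1,
                                    paste, collapse = ""), tree$tip.label),
              asr$map_sequences)
    topt <- predict_topt(seqs[labs], model = topt_model)
  }
  data.frame(node = labs, topt_c = as.numeric(topt),
             distance = as.numeric(dist[labs]), is_leaf = is_leaf,
             stringsAsFactors = FALSE)
}
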