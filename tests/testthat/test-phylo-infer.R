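test_that("neighbor joining recovers additive trees exactly", {
  tt <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):1);")
  D <- ape::cophenetic.phylo(tt)
  nj1 <- nj_tree(D)
  expect_equal(as.matrix(ape::cophenetic.phylo(nj1))[rownames(D), colnames(D)],
               D, tolerance = 1e-10)
  expect_equal(phangorn::RF.dist(ape::unroot(nj1), ape::unroot(tt)), 0)
})

test_that("three taxa give the closed-form star lengths", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  len <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(len["a"]), (3 + 5 - 6) / 2)
  expect_equal(unname(len["b"]), (3 + 6 - 5) / 2)
  expect_equal(unname(len["c"]), (5 + 6 - 3) / 2)
})

test_that("neighbor joining is invariant to input order and rejects bad input", {
  set.seed(1)
  tt <- ape::rtree(7)
  D <- ape::cophenetic.phylo(tt)
  perm <- sample(7)
  t1 <- nj_tree(D)
  t2 <- nj_tree(D[perm, perm])
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  D2 <- D; D2[1, 2] <- Inf
  expect_error(nj_tree(D2), "finite")
})

test_that("pruning likelihood matches closed forms and is root-invariant", {
  m <- subst_model("poisson")
  aln1 <- rbind(a = "A", b = "A")
  tr2 <- ape::read.tree(text = "(a:0,b:0);")
  expect_equal(log_likelihood(tr2, aln1, m), log(1 / 20), tolerance = 1e-12)

  set.seed(2)
  aln <- rand_aln(5, 30, names = paste0("t", 1:5))
  tr <- ape::rtree(5)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.5)
  mg <- subst_model("LG", shape = 0.8)
  ll0 <- log_likelihood(tr, aln, mg)
  for (og in c("t2", "t4")) {
    rr <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE)
    expect_lt(abs(log_likelihood(rr, aln, mg) - ll0), 1e-8)
  }
  expect_error(log_likelihood(tr, aln[, 0, drop = FALSE], m), "zero-length")
})

test_that("branch-length fitting handles degenerate and fixed-point cases", {
  m <- subst_model("poisson")
  aln <- matrix("A", 4, 50,
                dimnames = list(paste0("t", 1:4), NULL))
  aln[] <- sample(AA, 50, replace = TRUE)[col(aln)]  # identical rows
  tr <- ape::rtree(4)
  tr$edge.length <- rep(0.3, nrow(tr$edge))
  ft <- fit_branch_lengths(tr, aln, m)
  expect_true(all(ft$edge.length <= 1e-6))

  set.seed(3)
  aln2 <- rand_aln(4, 60, names = paste0("t", 1:4))
  f1 <- fit_branch_lengths(tr, aln2, m)
  f2 <- fit_branch_lengths(f1, aln2, m)
  expect_lt(abs(attr(f2, "loglik") - attr(f1, "loglik")), 1e-5)
})

test_that("fitted branch lengths are consistent on simulated data", {
  cfg <- sim_config(seed = 17, n_species = 6, seq_length = 20000,
                    dtl_rates = c(0, 0, 0), beta_comp = 0,
                    subst_model_id = "poisson", gamma_shape = NULL)
  tru <- suppressMessages(simulate_truth(cfg))
  st <- attr(tru$alignment, "subs_tree")
  ft <- fit_branch_lengths(st, tru$alignment, subst_model("poisson"),
                           tol = 1e-5)
  # compare unrooted path lengths (the root split is unidentifiable)
  p_true <- ape::cophenetic.phylo(st)
  p_fit <- as.matrix(ape::cophenetic.phylo(ft))[rownames(p_true), colnames(p_true)]
  rel <- abs(p_fit - p_true) / pmax(p_true, 1e-9)
  expect_lt(max(rel[upper.tri(rel)]), 0.05)
})

test_that("paralogous rooting recovers the duplication-rooted topology", {
  cfg <- sim_config(seed = 23, n_species = 6, dtl_rates = c(0, 0, 0),
                    beta_comp = 0, seq_length = 400, topt_sigma = 0)
  sp <- simulate_species_tree(cfg)
  gA <- simulate_gene_tree(sp, cfg)
  cfgB <- cfg; cfgB$seed <- 101L
  topt <- stats::setNames(rep(55, length(gA$gene_tree$ages)),
                          names(gA$gene_tree$ages))
  alnA <- simulate_sequences(gA$gene_tree, topt, cfg)
  alnB <- simulate_sequences(gA$gene_tree, topt, cfgB)
  rownames(alnA) <- sub("_g1$", "", rownames(alnA))
  rownames(alnB) <- sub("_g1$", "", rownames(alnB))
  concat <- cbind(alnA, alnB)
  ct <- nj_tree(distance_matrix(concat, "poisson"))
  rooted <- paralogous_root(ct, alnA, alnB)
  # nominated basal group must be one of the true root-child clades
  kids <- paleoclock:::children_map(sp$tree)[[1]]
  root_clades <- lapply(kids, function(k) paleoclock:::clade_leaves(sp$tree, k))
  bg <- attr(rooted, "basal_group")
  expect_true(any(vapply(root_clades, setequal, TRUE, y = bg)))
  expect_true(ape::is.rooted(rooted))
  # outgroup mode on a toy tree: root lands on the pendant branch
  toy <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  rt <- outgroup_root(ape::unroot(toy), "a")
  expect_true(monophyly_check(rt, c("b", "c", "d")))
})

test_that("bootstrap replicates are seeded and support strong clades", {
  set.seed(4)
  aln <- rand_aln(6, 80)
  b1 <- bootstrap_trees(aln, 5, seed = 7)
  b2 <- bootstrap_trees(aln, 5, seed = 7)
  expect_identical(lapply(b1, ape::write.tree), lapply(b2, ape::write.tree))
  b0 <- bootstrap_trees(aln, 1, seed = 7, resample = FALSE)
  point <- nj_tree(distance_matrix(aln, "poisson"))
  expect_identical(ape::write.tree(b0[[1]]), ape::write.tree(point))

  # two 4-leaf clades separated by a long internal branch
  nwk <- "(((a:200,b:200):100,(c:200,d:200):100):2700,((e:200,f:200):100,(g:200,h:200):100):2700)r;"
  tr <- ape::read.tree(text = nwk)
  ages <- c(stats::setNames(rep(0, 8), letters[1:8]))
  dep <- ape::node.depth.edgelength(tr)
  all_ages <- max(dep) - dep
  names(all_ages) <- paleoclock:::node_labels(paleoclock:::ensure_node_labels(tr))
  td <- dated_tree(paleoclock:::ensure_node_labels(tr), all_ages)
  cfg <- sim_config(seed = 10, seq_length = 300, topt_sigma = 0)
  topt <- stats::setNames(rep(55, length(td$ages)), names(td$ages))
  aln2 <- simulate_sequences(td, topt, cfg)
  boots <- bootstrap_trees(aln2, 100, seed = 11, dist_model = "gamma",
                           shape = 1)
  ref <- clade_support(td$tree, boots)
  node <- ape::getMRCA(ref, c("a", "b", "c", "d"))
  supp <- as.numeric(ref$node.label[node - ape::Ntip(ref)])
  expect_gte(supp, 95)
})
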