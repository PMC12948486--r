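test_that("birth-death species trees are dated, binary and ultrametric", {
  cfg <- sim_config(seed = 3, n_species = 3)
  sp <- simulate_species_tree(cfg)
  expect_equal(ape::Ntip(sp$tree), 3)
  expect_equal(sp$tree$Nnode, 2)
  expect_true(ape::is.binary(sp$tree))
  expect_equal(unname(sp$ages[sp$tree$tip.label]), c(0, 0, 0))
  expect_equal(root_age(sp), cfg$root_age)
  expect_true(all(sp$ages >= 0 & sp$ages <= cfg$root_age))

  # pure birth: internal node count is always n - 1
  for (s in 1:10) {
    cfg2 <- sim_config(seed = s, n_species = 50, birth_rate = 1e-3,
                       death_rate = 0)
    sp2 <- simulate_species_tree(cfg2)
    expect_equal(sp2$tree$Nnode, 49)
  }
})

test_that("species tree ages respect parent > child everywhere", {
  sp <- simulate_species_tree(sim_config(seed = 11, n_species = 15))
  pa <- sp$ages[paleoclock:::parent_map(sp$tree)[sp$tree$edge[, 2]]]
  ca <- sp$ages[sp$tree$edge[, 2]]
  expect_true(all(pa > ca))
})

test_that("gene tree with zero DTL rates is congruent with the species tree", {
  cfg <- sim_config(seed = 5, n_species = 8, dtl_rates = c(0, 0, 0))
  sp <- simulate_species_tree(cfg)
  g <- simulate_gene_tree(sp, cfg)
  expect_equal(nrow(g$events), 0)
  expect_equal(ape::Ntip(g$gene_tree$tree), 8)
  relab <- g$gene_tree$tree
  relab$tip.label <- sub("_g1$", "", relab$tip.label)
  expect_equal(phangorn::RF.dist(ape::unroot(relab), ape::unroot(sp$tree)), 0)
  # node ages carry over exactly
  expect_equal(root_age(g$gene_tree), root_age(sp))
})

test_that("transfer count matches the Poisson thinning oracle", {
  # transfer-only process: expected count = rate x total gene-tree length
  rate <- 5e-4
  counts <- numeric(0)
  lens <- numeric(0)
  for (s in 1:200) {
    cfg <- sim_config(seed = s, n_species = 6,
                      dtl_rates = c(0, rate, 0))
    sp <- simulate_species_tree(cfg)
    g <- simulate_gene_tree(sp, cfg)
    counts <- c(counts, sum(g$events$type == "transfer"))
    lens <- c(lens, sum(g$gene_tree$tree$edge.length))
  }
  # direct-counting oracle: each event is a Poisson point on the realized
  # gene-tree branches (length includes post-event lineages, so compare
  # rate estimates, not raw Poisson mean)
  expected <- rate * mean(lens)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 0.15 * expected)
})

test_that("recorded transfers land on species branches alive at the event age", {
  for (s in c(2, 7, 15)) {
    cfg <- sim_config(seed = s, n_species = 10)
    sp <- simulate_species_tree(cfg)
    g <- simulate_gene_tree(sp, cfg)
    tv <- g$events[g$events$type == "transfer", , drop = FALSE]
    if (!nrow(tv)) next
    par <- paleoclock:::parent_map(sp$tree)
    for (i in seq_len(nrow(tv))) {
      for (br in c(tv$donor[i], tv$recipient[i])) {
        id <- match(br, paleoclock:::node_labels(sp$tree))
        lo <- as.numeric(sp$ages[id])
        hi <- as.numeric(sp$ages[par[id]])
        expect_true(lo < tv$age_ma[i] && tv$age_ma[i] < hi)
      }
    }
  }
})

test_that("thermal trait follows the Brownian-with-drift contract", {
  td <- toy_dated_tree(1000)
  cfg0 <- sim_config(seed = 1, topt_sigma = 0, topt_trend = 0)
  t0 <- simulate_thermal_trait(td, cfg0)
  expect_equal(as.numeric(t0), rep(cfg0$topt_root, 3))

  cfgd <- sim_config(seed = 1, topt_sigma = 0, topt_trend = -0.01)
  t1 <- simulate_thermal_trait(td, cfgd)
  expect_equal(as.numeric(t1["a"] - t1["r"]), -10)

  # BM variance over dt = 4 by Monte-Carlo
  td4 <- toy_dated_tree(4)
  incr <- vapply(1:1000, function(s) {
    tt <- simulate_thermal_trait(td4, sim_config(seed = s, topt_sigma = 5,
                                                 topt_trend = 0))
    unname(tt["a"] - tt["r"])
  }, numeric(1))
  v <- var(incr)
  se_v <- sqrt(2 / (length(incr) - 1)) * 100   # var of sample variance, normal
  expect_lt(abs(v - 100), 3 * se_v)
})

test_that("thermal trait clipping is reported, never silent", {
  td <- toy_dated_tree(4000)
  cfg <- sim_config(seed = 4, topt_sigma = 0, topt_trend = -0.05,
                    topt_root = 50)
  expect_message(tt <- simulate_thermal_trait(td, cfg), "clipped")
  expect_true(all(tt >= 0))
  expect_true(length(attr(tt, "clipped")) > 0)
})

test_that("decoupled sequences show no composition-temperature slope", {
  cfg <- sim_config(seed = 8, n_species = 20, beta_comp = 0,
                    dtl_rates = c(0, 0, 0), topt_sigma = 0.6)
  tru <- suppressMessages(simulate_truth(cfg))
  fr <- apply(tru$alignment, 1, function(r) mean(r %in% c("I","V","Y","W","R","E","L")))
  topt <- as.numeric(tru$node_topt[rownames(tru$alignment)])
  fit <- summary(lm(fr ~ topt))
  expect_lt(abs(fit$coefficients[2, 1]), 2 * fit$coefficients[2, 2] + 1e-4)
})

test_that("coupled sequences shift composition with temperature", {
  # long branches to two leaves held at 90 vs 20 degrees C
  td <- toy_dated_tree(60000)
  cfg <- sim_config(seed = 2, beta_comp = 0.025, seq_length = 400)
  topt <- c(r = 55, a = 90, b = 20)
  aln <- simulate_sequences(td, topt, cfg)
  fa <- mean(aln["a", ] %in% c("I","V","Y","W","R","E","L"))
  fb <- mean(aln["b", ] %in% c("I","V","Y","W","R","E","L"))
  expect_gt(fa, fb)
  # stationary-frequency oracle from the pi(T) formula (branch regime is
  # the parent/child midpoint)
  m <- subst_model(cfg$subst_model_id, cfg$gamma_shape)
  up <- c("I","V","Y","W","R","E","L")
  pred_a <- sum(thermal_freqs(m$pi, (55 + 90) / 2, 0.025, ref = cfg$comp_ref)[up])
  pred_b <- sum(thermal_freqs(m$pi, (55 + 20) / 2, 0.025, ref = cfg$comp_ref)[up])
  expect_lt(abs(fa - pred_a), 3 * sqrt(pred_a * (1 - pred_a) / 400))
  expect_lt(abs(fb - pred_b), 3 * sqrt(pred_b * (1 - pred_b) / 400))
})

test_that("zero-length branches copy the parent sequence", {
  tr <- ape::read.tree(text = "(a:0,b:500)r;")
  td <- dated_tree(tr, c(a = 0, b = 0, r = 0))  # degenerate: root at 0
  expect_true(all(td$tree$edge.length == 0))
  cfg <- sim_config(seed = 6, seq_length = 80)
  aln <- simulate_sequences(td, c(a = 50, b = 50, r = 50), cfg)
  root_seq <- strsplit(attr(aln, "node_sequences")[["r"]], "")[[1]]
  expect_equal(unname(aln["a", ]), root_seq)
  expect_equal(unname(aln["b", ]), root_seq)
})

test_that("identical config and seed give identical outputs", {
  cfg <- sim_config(seed = 14)
  t1 <- suppressMessages(simulate_truth(cfg))
  t2 <- suppressMessages(simulate_truth(cfg))
  expect_identical(t1$alignment, t2$alignment)
  expect_identical(ape::write.tree(t1$gene_tree$tree),
                   ape::write.tree(t2$gene_tree$tree))
  expect_identical(t1$events, t2$events)
  expect_identical(t1$node_topt, t2$node_topt)
})

test_that("neutral generator reduces to clock-free sequence simulation", {
  # dtl = 0 and beta = 0: pairwise distances recoverable within 10%
  cfg <- sim_config(seed = 9, n_species = 6, dtl_rates = c(0, 0, 0),
                    beta_comp = 0, seq_length = 10000,
                    subst_model_id = "poisson", gamma_shape = NULL)
  tru <- suppressMessages(simulate_truth(cfg))
  truth_d <- ape::cophenetic.phylo(attr(tru$alignment, "subs_tree"))
  est_d <- distance_matrix(tru$alignment, "poisson")
  ids <- rownames(est_d)
  rel <- abs(est_d[ids, ids] - truth_d[ids, ids]) /
    pmax(truth_d[ids, ids], 1e-9)
  expect_lt(max(rel[upper.tri(rel)]), 0.10)
})

test_that("calibratable sampler returns a projectable transfer", {
  truth <- simulate_calibratable_truth(sim_config(seed = 21))
  tc <- attr(truth, "truth_calibrations")
  expect_gte(nrow(tc), 1)
  expect_true(all(tc$n_leaves >= 3))
  expect_true(all(tc$age_lo <= tc$age_ma & tc$age_ma <= tc$age_hi))
  nt <- ape::Ntip(truth$gene_tree$tree)
  expect_true(nt >= 8 && nt <= 24)
})

test_that("truth bundles round-trip through disk", {
  truth <- suppressMessages(simulate_truth(sim_config(seed = 14)))
  dir <- withr::local_tempdir()
  man <- write_truth_bundle(truth, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  sp2 <- read_dated_tree(file.path(dir, "species_tree.nwk"),
                         file.path(dir, "species_ages.tsv"))
  expect_equal(root_age(sp2), root_age(truth$species_tree))
  aln2 <- read_alignment(file.path(dir, "alignment.fasta"))
  expect_equal(aln2[rownames(truth$alignment), ],
               `attributes<-`(truth$alignment,
                              list(dim = dim(truth$alignment),
                                   dimnames = dimnames(truth$alignment))))
})
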