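test_that("strict-clock input yields equal rates and depth-proportional heights", {
  sp <- simulate_species_tree(sim_config(seed = 2, n_species = 10))
  rd <- relative_dating(sp$tree)   # edge lengths in Ma: a perfect clock
  expect_lt(sd(rd$rates) / mean(rd$rates), 1e-9)
  true_rel <- as.numeric(sp$ages[names(rd$rel_heights)]) / root_age(sp)
  expect_equal(unname(rd$rel_heights), true_rel, tolerance = 1e-9)
})

test_that("two-lineage rates follow the closed form", {
  tr <- ape::read.tree(text = "(a:1,b:3)r;")
  rd <- relative_dating(tr)
  r <- stats::setNames(rd$rates, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(r["b"] / r["a"]), 3)
  expect_equal(unname(rd$rel_heights["r"]), 1)
})

test_that("mild rate noise preserves the age ranking", {
  cors <- c()
  for (s in 1:6) {
    cfg <- sim_config(seed = 200 + s, n_species = 10, seq_length = 2000,
                      dtl_rates = c(0, 0, 0), beta_comp = 0, rate_sdlog = 0.2)
    tru <- suppressMessages(simulate_truth(cfg))
    st <- attr(tru$alignment, "subs_tree")
    rd <- relative_dating(st)
    tt <- tru$gene_tree
    ta <- as.numeric(tt$ages)
    ea <- as.numeric(rd$rel_heights[names(tt$ages)])
    cors <- c(cors, cor(ta, ea))
  }
  expect_true(all(cors >= 0.95))
})

test_that("calibration scaling and clamping honour the constraints", {
  sp <- simulate_species_tree(sim_config(seed = 4, n_species = 8))
  rd <- relative_dating(sp$tree)

  # single two-sided root window: root lands at its midpoint, inside
  cons <- calibration(list(sp$tree$tip.label), 3460, 4380, "root window")
  dated <- apply_calibrations(rd, cons)
  expect_equal(root_age(dated), (3460 + 4380) / 2)
  expect_true(root_age(dated) >= 3460 && root_age(dated) <= 4380)

  # constraint equal to the unconstrained scaled age: ages unchanged
  base <- apply_calibrations(rd, calibration(list(sp$tree$tip.label),
                                             3460, 3460))
  some_node <- names(base$ages)[ape::Ntip(sp$tree) + 3L]
  a0 <- as.numeric(base$ages[some_node])
  ls0 <- paleoclock:::clade_leaves(sp$tree,
                                   match(some_node,
                                         paleoclock:::node_labels(sp$tree)))
  cons2 <- rbind(calibration(list(sp$tree$tip.label), 3460, 3460),
                 calibration(list(ls0), a0, a0))
  dated2 <- apply_calibrations(rd, cons2)
  expect_equal(as.numeric(dated2$ages), as.numeric(base$ages),
               tolerance = 1e-6)

  # max-only clamp drags the node to the bound and its descendants below it
  target <- names(base$ages)[ape::Ntip(sp$tree) + 2L]
  tid <- match(target, paleoclock:::node_labels(sp$tree))
  tage <- as.numeric(base$ages[target])
  cap <- 0.8 * tage
  cons3 <- rbind(calibration(list(sp$tree$tip.label), 3460, 3460),
                 calibration(list(paleoclock:::clade_leaves(sp$tree, tid)),
                             NA, cap))
  dated3 <- apply_calibrations(rd, cons3)
  expect_equal(as.numeric(dated3$ages[target]), cap, tolerance = 1e-6)
  desc <- paleoclock:::clade_leaves(sp$tree, tid)
  inner <- setdiff(names(dated3$ages)[vapply(seq_along(dated3$ages),
    function(v) all(paleoclock:::clade_leaves(sp$tree, v) %in% desc), TRUE)],
    target)
  expect_true(all(dated3$ages[inner] < cap + 1e-6))

  # unsatisfiable: descendant min above ancestor max
  bad <- rbind(calibration(list(sp$tree$tip.label), NA, 1000),
               calibration(list(ls0), 2000, NA))
  expect_error(apply_calibrations(rd, bad), "unsatisfiable")
})

test_that("dated output is always age-monotone with constraints satisfied", {
  for (s in 1:5) {
    truth <- simulate_calibratable_truth(sim_config(seed = 300 + s))
    tc <- attr(truth, "truth_calibrations")
    gt <- truth$gene_tree$tree
    cons <- rbind(
      transfer_calibrations(truth$species_tree,
                            data.frame(donor = tc$donor,
                                       recipient = tc$recipient,
                                       stringsAsFactors = FALSE),
                            gt, truth$leaf_map),
      calibration(list(gt$tip.label), NA, 1.25 * root_age(truth$species_tree)))
    st <- attr(truth$alignment, "subs_tree")
    dated <- apply_calibrations(relative_dating(st), cons)
    pa <- dated$ages[paleoclock:::parent_map(dated$tree)[dated$tree$edge[, 2]]]
    ca <- dated$ages[dated$tree$edge[, 2]]
    expect_true(all(pa > ca - 1e-6))
    for (i in seq_len(nrow(cons))) {
      a <- as.numeric(dated$ages[lca_node(dated$tree,
                                          strsplit(cons$leafset[i], ",")[[1]])])
      if (!is.na(cons$min_ma[i])) expect_gte(a, cons$min_ma[i] - 1e-6)
      if (!is.na(cons$max_ma[i])) expect_lte(a, cons$max_ma[i] + 1e-6)
    }
  }
})

test_that("bootstrap CIs collapse on zero-variation data and are seeded", {
  # alignment of identical repeated columns: every resample is identical
  col <- sample(AA, 6)
  aln <- matrix(rep(col, 40), 6, 40,
                dimnames = list(paste0("t", 1:6), NULL))
  aln[1, ] <- AA[1]  # make two groups so distances are not all zero
  tr <- ape::read.tree(text = "(((t1:1,t2:1):1,(t3:1,t4:1):1):1,(t5:1,t6:1):2);")
  cons <- calibration(list(tr$tip.label), 1000, 1000)
  b1 <- bootstrap_cis(aln, tr, cons, n_boot = 10, seed = 5)
  expect_true(all(abs(b1$ci$ci_hi - b1$ci$ci_lo) < 1e-6))
  b2 <- bootstrap_cis(aln, tr, cons, n_boot = 10, seed = 5)
  expect_identical(b1$ci, b2$ci)
  # CI always contains the point estimate
  expect_true(all(b1$ci$ci_lo - 1e-9 <= b1$ci$age_ma &
                    b1$ci$age_ma <= b1$ci$ci_hi + 1e-9))
})

test_that("transfer calibrations project recipient branch intervals onto gene clades", {
  # species branch 1993-1229 Ma hosting a transfer; 4-leaf recipient clade
  spn <- "(((p1:800,p2:800)P:429,(q1:600,q2:600)Q:629)X:764,o1:1993)R;"
  sptr <- ape::read.tree(text = spn)
  dep <- ape::node.depth.edgelength(sptr)
  sp <- dated_tree(sptr, stats::setNames(max(dep) - dep,
                                         c(sptr$tip.label, sptr$node.label)))
  gn <- "(((p1_g1:3,p2_g1:3):4,(q1_g1:3,q2_g1:3):4):5,o1_g1:12)gr;"
  gtr <- ape::read.tree(text = gn)
  lm0 <- leaf_species_map(gtr$tip.label)
  ev <- data.frame(donor = "o1", recipient = "X", frequency = 0.8,
                   stringsAsFactors = FALSE)
  cons <- transfer_calibrations(sp, ev, gtr, lm0, min_clade_size = 3)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$min_ma, 1229)
  expect_equal(cons$max_ma, 1993)
  expect_equal(cons$target_ma, 1229)
  expect_setequal(strsplit(cons$leafset, ",")[[1]],
                  c("p1_g1", "p2_g1", "q1_g1", "q2_g1"))

  # a 2-leaf recipient clade emits nothing
  ev2 <- data.frame(donor = "o1", recipient = "P", frequency = 0.8,
                    stringsAsFactors = FALSE)
  cons2 <- transfer_calibrations(sp, ev2, gtr, lm0, min_clade_size = 3)
  expect_equal(nrow(cons2), 0)
  expect_equal(attr(cons2, "skipped")$reason, "gene clade too small")
})

test_that("calibration tables round-trip through TSV", {
  cons <- rbind(calibration(list(c("a", "b", "c")), 1229, 1993,
                            "transfer X", target_ma = 1229),
                calibration(list(c("a", "b", "c", "d")), NA, 4380, "root"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_calibrations_tsv(cons, path)
  back <- read_calibrations_tsv(path)
  expect_equal(back$leafset, cons$leafset)
  expect_equal(back$min_ma, cons$min_ma)
  expect_equal(back$max_ma, cons$max_ma)
  expect_equal(back$target_ma, cons$target_ma)
})
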