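test_that("ASR on identical leaves returns the leaf sequence everywhere", {
  seqv <- sample(AA, 12, replace = TRUE)
  aln <- matrix(rep(seqv, each = 4), 4, 12,
                dimnames = list(paste0("t", 1:4), NULL))
  tr <- ape::read.tree(text = "((t1:0.1,t2:0.1):0.1,(t3:0.1,t4:0.1):0.1)r;")
  asr <- marginal_asr(tr, aln, subst_model("poisson", shape = 1))
  for (nm in names(asr$map_sequences)) {
    expect_equal(asr$map_sequences[[nm]], paste(seqv, collapse = ""))
    pp <- asr$posterior[[nm]]
    expect_true(all(pp[cbind(seq_len(nrow(pp)), match(seqv, AA))] ==
                      apply(pp, 1, max)))
  }
})

test_that("ASR posteriors normalise and saturate to the equilibrium", {
  set.seed(1)
  aln <- rand_aln(4, 20, names = paste0("t", 1:4))
  tr <- ape::read.tree(text = "((t1:0.2,t2:0.4):0.3,(t3:0.1,t4:0.6):0.2)r;")
  m <- subst_model("LG", shape = 1)
  asr <- marginal_asr(tr, aln, m)
  sums <- unlist(lapply(asr$posterior, rowSums))
  expect_true(all(abs(sums - 1) < 1e-9))

  # long branches: posterior approaches the equilibrium frequencies
  # (rate-homogeneous model, so every site is genuinely saturated)
  m <- subst_model("LG")
  tr_long <- tr
  tr_long$edge.length <- rep(25, nrow(tr$edge))
  asr_long <- marginal_asr(tr_long, aln, m)
  root_lab <- paleoclock:::node_labels(paleoclock:::ensure_node_labels(tr_long))[5]
  pp <- asr_long$posterior[[root_lab]]
  expect_lt(max(abs(sweep(pp, 2, m$pi, "-"))), 1e-3)
})

test_that("composition counts residues and rejects empty input", {
  expect_equal(unname(composition("AAAA")[c("A", "C")]), c(1, 0))
  expect_equal(unname(composition("ACAC")[c("A", "C")]), c(0.5, 0.5))
  expect_equal(unname(composition("A-C-")[c("A", "C")]), c(0.5, 0.5))
  expect_error(composition("--XX"), "no countable residues")
})

test_that("the composition model recovers a known linear truth", {
  set.seed(2)
  up <- c("I", "V", "Y", "W", "R", "E", "L")
  make_comp <- function(f_up) {
    x <- stats::setNames(runif(20, 0.5, 1.5), AA)
    x[up] <- x[up] / sum(x[up]) * f_up
    x[setdiff(AA, up)] <- x[setdiff(AA, up)] / sum(x[setdiff(AA, up)]) * (1 - f_up)
    x
  }
  fr <- runif(40, 0.25, 0.55)
  X <- t(vapply(fr, make_comp, numeric(20)))
  y <- 37 + 200 * (fr - 0.4)
  mod <- fit_topt_model(X[1:30, ], y[1:30])
  pred <- predict_topt(X[31:40, ], model = mod)
  expect_lt(max(abs(pred - y[31:40])), 0.5)

  # fraction 0.5 maps to 57 under the known truth
  x50 <- make_comp(0.5)
  expect_lt(abs(predict_topt(matrix(x50, 1), model = mod) - 57), 0.5)

  # constant training labels predict that constant
  mod73 <- fit_topt_model(X[1:30, ], rep(73, 30))
  expect_equal(unname(predict_topt(X[31:40, ], model = mod73)),
               rep(73, 10), tolerance = 1e-6)

  # duplicated training set leaves the fit unchanged
  mod2 <- fit_topt_model(rbind(X[1:30, ], X[1:30, ]), c(y[1:30], y[1:30]))
  expect_equal(mod2$coefficients, mod$coefficients, tolerance = 1e-8)
  expect_error(fit_topt_model(X[1:10, ], y[1:10]), "22")
})

test_that("zero-coefficient models and override tables pass through", {
  mod <- structure(list(intercept = 73,
                        coefficients = stats::setNames(numeric(20), AA),
                        lambda = 0), class = "topt_model")
  expect_equal(unname(predict_topt("MKVLAW", model = mod)), 73)

  ov <- data.frame(node = c("n1", "n2", "n3"), topt_c = c(55, 60.5, 41))
  expect_equal(unname(predict_topt(c("n2", "n1"), override = ov)),
               c(60.5, 55))
  expect_error(predict_topt("nope", override = ov), "nope")
})

test_that("distances to a reference node are exact path sums", {
  tr <- ape::read.tree(text = "((a:0.2,x:0.3)b:0.3,c:0.4)root;")
  d <- distance_to_reference(tr, "root")
  expect_equal(unname(d["root"]), 0)
  expect_equal(unname(d["a"]), 0.5)
  expect_equal(unname(d["x"]), 0.6)

  # brute-force path walk on random trees
  set.seed(3)
  for (rep in 1:5) {
    tr <- paleoclock:::ensure_node_labels(ape::rtree(8))
    labs <- paleoclock:::node_labels(tr)
    ref <- sample(labs, 1)
    d <- distance_to_reference(tr, ref)
    # oracle: path through MRCA via node depths
    dd <- ape::dist.nodes(tr)
    ids <- match(labs, labs)
    expect_equal(unname(d[labs]),
                 unname(dd[match(ref, labs), seq_along(labs)]),
                 tolerance = 1e-10)
  }
  expect_error(distance_to_reference(tr, "zz"), "zz")
})

test_that("the Topt-distance regression matches the hand-computed OLS", {
  x <- 0:4; y <- c(1, 2, 2, 4, 4)
  r <- topt_distance_regression(x, y)
  expect_equal(r$slope, 0.8)
  expect_equal(r$intercept, 1.0)
  expect_equal(r$r_squared, 1 - 0.8 / 7.2)
  expect_lt(r$p_value, 0.05)

  rp <- topt_distance_regression(1:5, 2 * (1:5) + 3)
  expect_equal(rp$r_squared, 1)
  expect_lt(rp$p_value, 1e-10)

  expect_error(topt_distance_regression(rep(1, 4), 1:4), "distance")
  expect_error(topt_distance_regression(1:4, rep(7, 4)), "R-squared")
  expect_error(topt_distance_regression(1:2, 1:2), "3 points")
})

test_that("thermal profiles combine ASR, prediction and distances", {
  truth <- sample_truth_by_size(function(k)
    sim_config(seed = (77 + 7919 * k) %% 2147483647, n_species = 24), 22, 40)
  aln <- truth$alignment
  gt <- attr(aln, "subs_tree")
  asr <- marginal_asr(gt, aln, subst_model("LG", shape = 1))
  tm <- fit_topt_model(apply(aln, 1, paste, collapse = ""),
                       as.numeric(truth$node_topt[rownames(aln)]))
  rootlab <- paleoclock:::node_labels(gt)[ape::Ntip(gt) + 1L]
  prof <- thermal_profile(gt, aln, tm, reference = rootlab, asr = asr)
  expect_equal(nrow(prof), ape::Ntip(gt) + gt$Nnode)
  expect_equal(prof$distance[prof$node == rootlab], 0)
  expect_true(all(prof$distance >= 0))
  expect_true(all(is.finite(prof$topt_c)))
})
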