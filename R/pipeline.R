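#' Default analysis parameters for the pipeline
#'
#' Thresholds mirror the reference workflow: gap occupancy 0.95 with a 0.50
#' retention floor, redundancy clustering at 0.75 identity, clade
#' delineation at 0.60, transfer-frequency filter 0.3, minimum calibration
#' clade size 3.
#'
#' @param ... Overrides of any default.
#' @return Named list of analysis parameters.
#' @export
pipeline_defaults <- function(...) {
  out <- list(
    trim_occupancy = 0.95, trim_min_fraction = 0.50,
    prune_fraction = 0,
    dist_model = "gamma", dist_shape = 1,
    rooting = "midpoint", outgroup = NULL,
    ml_branch_lengths = TRUE,
    n_boot = 50L, seed = 1L,
    dtl_costs = dtl_costs(), min_transfer_freq = 0.3,
    dated_reconciliation = FALSE,
    min_clade_size = 3L,
    root_max_ma = NA_real_, root_min_ma = NA_real_,
    ci_level = 0.95, ci_method = "full",
    require_transfer_calibrations = FALSE,
    run_asr = TRUE, topt_lambda = 1e-3, topt_import = NULL,
    clade_identity = 0.60,
    subst_model_id = "LG", gamma_shape = 1)
  ov <- list(...)
  out[names(ov)] <- ov
  out
}

root_gene_tree <- function(tree, params) {
  if (identical(params$rooting, "outgroup")) {
    outgroup_root(tree, params$outgroup)
  } else {
    phangorn::midpoint(tree)
  }
}

#' Run the two-stage dating and thermal-reconstruction pipeline
#'
#' Executes, on a synthetic ground-truthed dataset, the full inference
#' chain: alignment filtering, distance + neighbor-joining tree with
#' rooting, bootstrap replication, parsimony DTL reconciliation with
#' transfer-frequency filtering, projection of dated recipient branches
#' onto gene-tree calibration constraints, relative-rate dating with
#' bootstrap CIs, marginal ancestral reconstruction, and per-clade
#' Topt-versus-distance regressions. Any stage's input can instead be
#' supplied from files by replacing the corresponding element of the
#' returned structure in downstream calls.
#'
#' @param sim A [sim_config()] (the synthetic study conditions), or a
#'   `synthetic_truth` from [simulate_truth()].
#' @param params Analysis parameters from [pipeline_defaults()].
#' @param out_dir Optional output directory; when given, all artifacts and
#'   a manifest are written.
#' @return List of class `paleoclock_run` with the artifacts of every
#'   stage (see elements `truth`, `aln`, `gene_tree`, `transfers`,
#'   `constraints`, `dating`, `asr`, `thermal`, `regressions`, `manifest`).
#' @export
run_pipeline <- function(sim, params = pipeline_defaults(), out_dir = NULL) {
  truth <- if (inherits(sim, "synthetic_truth")) sim else simulate_truth(sim)
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))

  # -- alignment filtering ---------------------------------------------------
  aln <- trim_gaps(truth$alignment, params$trim_occupancy,
                   params$trim_min_fraction)
  if (params$prune_fraction > 0) {
    aln <- prune_heterogeneous_sites(aln, params$prune_fraction)
  }

  # -- gene tree build + rooting --------------------------------------------
  d <- distance_matrix(aln, params$dist_model, shape = params$dist_shape)
  gtree <- root_gene_tree(nj_tree(d), params)
  gtree <- ensure_node_labels(gtree)

  # -- bootstrap + reconciliation -------------------------------------------
  boots <- bootstrap_trees(aln, params$n_boot, params$seed,
                           dist_model = params$dist_model,
                           shape = params$dist_shape)
  boots_rooted <- lapply(boots, function(tr)
    ensure_node_labels(root_gene_tree(tr, params)))
  leaf_map <- truth$leaf_map
  rec_point <- reconcile(gtree, truth$species_tree$tree, leaf_map,
                         params$dtl_costs)
  transfers <- transfer_frequency(boots_rooted, truth$species_tree, leaf_map,
                                  params$dtl_costs,
                                  min_freq = params$min_transfer_freq,
                                  dated = params$dated_reconciliation)

  # -- calibration projection + dating --------------------------------------
  constraints <- transfer_calibrations(truth$species_tree, transfers, gtree,
                                       leaf_map, params$min_clade_size)
  root_max <- if (is.na(params$root_max_ma)) {
    1.25 * root_age(truth$species_tree)
  } else params$root_max_ma
  constraints <- rbind(constraints,
                       calibration(list(gtree$tip.label),
                                   min_ma = params$root_min_ma,
                                   max_ma = root_max,
                                   provenance = "root upper bound"))
  class(constraints) <- c("calibration_set", "data.frame")
  n_transfer_cal <- sum(!is.na(constraints$target_ma))
  if (params$require_transfer_calibrations && n_transfer_cal == 0) {
    stop(errorCondition(
      "no transfer-derived calibrations were emitted; the family cannot be dated",
      class = c("paleoclock_uncalibrated", "error")))
  }
  # saturation-robust point estimate: ML branch lengths on the fixed
  # rooted topology (the replicate refits stay distance-based)
  point_tree <- NULL
  if (params$ml_branch_lengths) {
    point_tree <- withCallingHandlers(
      fit_branch_lengths(
        gtree, aln, subst_model(params$subst_model_id, params$gamma_shape),
        tol = 1e-3, max_cycles = 5L),
      warning = function(w) {
        note("branch-length fit: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  dating <- bootstrap_cis(aln, gtree, constraints,
                          n_boot = params$n_boot, seed = params$seed + 1000L,
                          method = params$ci_method,
                          dist_model = params$dist_model,
                          shape = params$dist_shape,
                          level = params$ci_level, point_tree = point_tree)
  if (params$ml_branch_lengths) gtree <- dating$dated$tree

  # -- ancestral reconstruction + thermal analysis ---------------------------
  asr <- NULL; thermal <- NULL; regressions <- NULL; topt_model <- NULL
  if (params$run_asr) {
    mdl <- subst_model(params$subst_model_id, params$gamma_shape)
    asr <- marginal_asr(gtree, aln, mdl)
    leaf_seqs <- apply(aln[gtree$tip.label, , drop = FALSE], 1, paste,
                       collapse = "")
    if (is.null(params$topt_import)) {
      if (length(leaf_seqs) >= 22) {
        leaf_topt <- truth$node_topt[gtree$tip.label]
        topt_model <- fit_topt_model(leaf_seqs, as.numeric(leaf_topt),
                                     lambda = params$topt_lambda)
        thermal <- thermal_profile(gtree, aln, topt_model,
                                   reference = node_labels(gtree)[ape::Ntip(gtree) + 1L],
                                   asr = asr)
      } else {
        note("thermal stage skipped: %d leaves < 22 needed to calibrate the composition model",
             length(leaf_seqs))
      }
    } else {
      thermal <- thermal_profile(gtree, aln, NULL,
                                 reference = node_labels(gtree)[ape::Ntip(gtree) + 1L],
                                 override = params$topt_import)
    }
    # per-clade regressions (clades from pairwise identity at the threshold)
    if (!is.null(thermal)) {
    idm <- 1 - distance_matrix(aln, "p")
    diag(idm) <- 1
    clades <- assign_clades(idm, params$clade_identity)
    regressions <- list()
    for (cl in unique(clades)) {
      members <- names(clades)[clades == cl]
      if (length(members) < 2) next
      sub_nodes <- if (length(members) < length(clades)) {
        internals <- (ape::Ntip(gtree) + 1L):(ape::Ntip(gtree) + gtree$Nnode)
        inside <- internals[vapply(internals, function(v)
          all(clade_leaves(gtree, v) %in% members), TRUE)]
        c(members, node_labels(gtree)[inside])
      } else node_labels(gtree)
      pts <- thermal[thermal$node %in% sub_nodes, , drop = FALSE]
      if (nrow(pts) >= 3 && stats::var(pts$distance) > 0 &&
          stats::var(pts$topt_c) > 0) {
        regressions[[cl]] <- c(list(clade = cl),
                               topt_distance_regression(pts$distance,
                                                        pts$topt_c))
      }
    }
    regressions <- if (length(regressions))
      do.call(rbind, lapply(regressions, as.data.frame)) else NULL
    }
  }

  run <- structure(list(
    truth = truth, params = params, aln = aln, dist = d,
    gene_tree = gtree, bootstrap_trees = boots_rooted,
    reconciliation = rec_point, transfers = transfers,
    constraints = constraints, dating = dating,
    asr = asr, topt_model = topt_model, thermal = thermal,
    regressions = regressions, warnings = warnings_log),
    class = "paleoclock_run")
  if (!is.null(out_dir)) run$manifest <- write_run(run, out_dir)
  run
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(dir, x)
  write_truth_bundle(run$truth, file.path(dir, "truth"))
  write_alignment(run$aln, f("alignment_filtered.fasta"))
  ape::write.tree(run$gene_tree, f("gene_tree_inferred.nwk"))
  utils::write.table(run$transfers, f("transfers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_calibrations_tsv(run$constraints, f("constraints.tsv"))
  ape::write.tree(run$dating$dated$tree, f("gene_tree_dated.nwk"))
  utils::write.table(run$dating$ci, f("gene_dated_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(run$thermal)) {
    utils::write.table(run$thermal, f("thermal_profile.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$regressions)) {
    utils::write.table(run$regressions, f("regressions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  arts <- list.files(dir, recursive = TRUE)
  arts <- setdiff(arts, "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("paleoclock")),
    seed = run$params$seed,
    params = lapply(run$params[vapply(run$params, function(x)
      is.numeric(x) || is.character(x) || is.logical(x), TRUE)], unclass),
    warnings = run$warnings,
    artifacts = as.list(stats::setNames(
      unname(tools::md5sum(file.path(dir, arts))), arts)))
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  manifest
}

#' Validate the cross-stage invariants of a pipeline run
#'
#' Checks age monotonicity of the dated gene tree, satisfaction of every
#' calibration constraint, posterior normalisation of the ancestral
#' reconstruction, CI containment of point estimates, and monophyly of
#' every constraint leaf set.
#'
#' @param run A `paleoclock_run`, or a run directory written by
#'   [run_pipeline()].
#' @return Data.frame: check, pass, detail. Attribute `ok` (all passed).
#' @export
validate_outputs <- function(run) {
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }
  if (is.character(run)) {
    dir <- run
    if (!file.exists(file.path(dir, "manifest.json"))) {
      stop("missing manifest.json in ", dir, call. = FALSE)
    }
    nodes <- utils::read.table(file.path(dir, "gene_dated_nodes.tsv"),
                               header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    tr <- ape::read.tree(file.path(dir, "gene_tree_dated.nwk"))
    tr <- ensure_node_labels(tr)
    ages <- stats::setNames(nodes$age_ma, nodes$node)
    bad <- character(0)
    for (i in seq_len(nrow(tr$edge))) {
      p <- node_labels(tr)[tr$edge[i, 1]]; ch <- node_labels(tr)[tr$edge[i, 2]]
      if (!is.na(ages[p]) && !is.na(ages[ch]) && ages[p] <= ages[ch] - 1e-6) {
        bad <- c(bad, ch)
      }
    }
    add("age_monotonicity", !length(bad), paste(bad, collapse = ", "))
    cons <- utils::read.table(file.path(dir, "constraints.tsv"),
                              header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE,
                              na.strings = c("NA", ""))
    viol <- character(0)
    for (i in seq_len(nrow(cons))) {
      ls <- strsplit(cons$leafset[i], ",")[[1]]
      nd <- node_labels(tr)[lca_node(tr, ls)]
      a <- ages[nd]
      if ((!is.na(cons$min_ma[i]) && a < cons$min_ma[i] - 1e-6) ||
          (!is.na(cons$max_ma[i]) && a > cons$max_ma[i] + 1e-6)) {
        viol <- c(viol, nd)
      }
    }
    add("constraints_satisfied", !length(viol), paste(viol, collapse = ", "))
    ok_ci <- all(nodes$ci_lo - 1e-9 <= nodes$age_ma &
                   nodes$age_ma <= nodes$ci_hi + 1e-9)
    add("ci_contains_point", ok_ci)
  } else {
    stopifnot(inherits(run, "paleoclock_run"))
    dt <- run$dating$dated
    pa <- dt$ages[parent_map(dt$tree)[dt$tree$edge[, 2]]]
    ca <- dt$ages[dt$tree$edge[, 2]]
    add("age_monotonicity", all(pa > ca - 1e-6))
    tips0 <- all(abs(dt$ages[seq_len(ape::Ntip(dt$tree))]) < 1e-9)
    add("tips_at_zero", tips0)
    cons <- run$constraints
    viol <- 0L
    for (i in seq_len(nrow(cons))) {
      ls <- strsplit(cons$leafset[i], ",")[[1]]
      a <- dt$ages[lca_node(dt$tree, ls)]
      if ((!is.na(cons$min_ma[i]) && a < cons$min_ma[i] - 1e-6) ||
          (!is.na(cons$max_ma[i]) && a > cons$max_ma[i] + 1e-6)) viol <- viol + 1L
    }
    add("constraints_satisfied", viol == 0L, as.character(viol))
    ci <- run$dating$ci
    add("ci_contains_point",
        all(ci$ci_lo - 1e-9 <= ci$age_ma & ci$age_ma <= ci$ci_hi + 1e-9))
    if (!is.null(run$asr)) {
      sums <- unlist(lapply(run$asr$posterior, rowSums))
      add("asr_posteriors_normalised", all(abs(sums - 1) < 1e-9))
    }
    mono <- all(vapply(seq_len(nrow(cons)), function(i)
      monophyly_check(run$gene_tree, strsplit(cons$leafset[i], ",")[[1]]) ||
        setequal(strsplit(cons$leafset[i], ",")[[1]], run$gene_tree$tip.label),
      TRUE))
    add("constraint_clades_monophyletic", mono)
  }
  out <- do.call(rbind, checks)
  attr(out, "ok") <- all(out$pass)
  out
}
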