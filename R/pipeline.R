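# Orchestration: run the full analysis (preprocessing -> delimitation ->
# reconciliation -> congruence -> diversification -> calibration) from one
# validated configuration, with a single master seed fanned out to stages.

#' Pipeline configuration
#'
#' Defaults are the conventional settings of this analysis: 1% ITS and 2%
#' COI delimitation thresholds, bootstrap-support collapse at 70, 1e4
#' sampled cost sets, 1e4 randomized tree pairs for the topological
#' congruence test, 9999 permutations for the distance-based test, 5000
#' null trees for the rate-shift test and a 2.4 Mya host-radiation age for
#' rate calibration. Input paths are optional; stages whose inputs are
#' missing are skipped.
#'
#' @param host_tree,parasite_tree,links,alignment_its,alignment_coi,ultrametric_tree,host_distances,parasite_distances
#'   optional input file paths (Newick / TSV / FASTA).
#' @param theta_its,theta_coi delimitation thresholds (fractions).
#' @param support_collapse bootstrap threshold below which parasite nodes
#'   are collapsed.
#' @param alpha_its,alpha_coi gamma shapes for the JC+G distances.
#' @param n_cost_sets,n_rand_topology,n_perm_parafit,n_null_trees Monte Carlo
#'   sizes of the four stochastic stages.
#' @param calibration_age host clade age in Mya used for rate calibration.
#' @param calibration_range pairwise divergence range (percent) to calibrate.
#' @param seed master seed.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(host_tree = NULL, parasite_tree = NULL, links = NULL,
                            alignment_its = NULL, alignment_coi = NULL,
                            ultrametric_tree = NULL,
                            host_distances = NULL, parasite_distances = NULL,
                            theta_its = 0.01, theta_coi = 0.02,
                            support_collapse = 70,
                            alpha_its = 0.40, alpha_coi = 0.11,
                            n_cost_sets = 10000, n_rand_topology = 10000,
                            n_perm_parafit = 9999, n_null_trees = 5000,
                            calibration_age = 2.4, calibration_range = c(2, 7),
                            seed = 1L) {
  cfg <- list(host_tree = host_tree, parasite_tree = parasite_tree,
              links = links, alignment_its = alignment_its,
              alignment_coi = alignment_coi,
              ultrametric_tree = ultrametric_tree,
              host_distances = host_distances,
              parasite_distances = parasite_distances,
              theta_its = theta_its, theta_coi = theta_coi,
              support_collapse = support_collapse,
              alpha_its = alpha_its, alpha_coi = alpha_coi,
              n_cost_sets = n_cost_sets, n_rand_topology = n_rand_topology,
              n_perm_parafit = n_perm_parafit, n_null_trees = n_null_trees,
              calibration_age = calibration_age,
              calibration_range = calibration_range,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match the [pipeline_config()] arguments.
#' @return a `"pipeline_config"`.
#' @export
pipeline_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop2("unknown configuration key(s): ",
                             paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

validate_config <- function(cfg) {
  errs <- character(0)
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  for (th in c("theta_its", "theta_coi")) {
    chk(is.numeric(cfg[[th]]) && cfg[[th]] > 0 && cfg[[th]] < 1,
        paste0(th, " must lie in (0, 1)"))
  }
  for (nn in c("n_cost_sets", "n_rand_topology", "n_perm_parafit", "n_null_trees")) {
    chk(is.numeric(cfg[[nn]]) && cfg[[nn]] >= 1, paste0(nn, " must be >= 1"))
  }
  chk(is.numeric(cfg$calibration_age) && cfg$calibration_age > 0,
      "calibration_age must be > 0")
  for (p in c("host_tree", "parasite_tree", "links", "alignment_its",
              "alignment_coi", "ultrametric_tree", "host_distances",
              "parasite_distances")) {
    if (!is.null(cfg[[p]])) chk(file.exists(cfg[[p]]),
                                paste0(p, ": file not found: ", cfg[[p]]))
  }
  if (length(errs)) stop2("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  invisible(TRUE)
}

#' Run the full cophylogenetic pipeline
#'
#' Stages run in dependency order; all label cross-references are checked
#' up front so a malformed input aborts before any computation. Every
#' stochastic stage gets its own seed derived from the master seed, so a
#' report is reproducible from the configuration alone.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, the report is written to
#'   `report.json` plus TSV summaries there.
#' @return list of class `"run_report"`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  t0 <- Sys.time()
  log_stage <- function(...) message("[cophyr] ", sprintf(...))

  # ---- pre-flight: parse everything, aggregate label mismatches -----------
  inputs <- list()
  errs <- character(0)
  grab <- function(name, reader) {
    if (is.null(config[[name]])) return(NULL)
    tryCatch(reader(config[[name]]),
             error = function(e) {
               errs <<- c(errs, paste0(name, ": ", conditionMessage(e)))
               NULL
             })
  }
  inputs$host_tree <- grab("host_tree", function(p) parse_newick(readLines(p, warn = FALSE)[1]))
  inputs$parasite_tree <- grab("parasite_tree", function(p) parse_newick(readLines(p, warn = FALSE)[1]))
  inputs$links <- grab("links", read_links)
  inputs$alignment_its <- grab("alignment_its", read_alignment)
  inputs$alignment_coi <- grab("alignment_coi", read_alignment)
  inputs$ultrametric_tree <- grab("ultrametric_tree", function(p) parse_newick(readLines(p, warn = FALSE)[1]))
  inputs$host_distances <- grab("host_distances", read_distance_matrix)
  inputs$parasite_distances <- grab("parasite_distances", read_distance_matrix)
  if (!is.null(inputs$links)) {
    if (!is.null(inputs$parasite_tree)) {
      miss <- setdiff(inputs$parasite_tree$tip.label, rownames(inputs$links))
      if (length(miss)) errs <- c(errs, paste0("parasite leaves unlinked: ",
                                               paste(miss, collapse = ", ")))
      miss <- setdiff(rownames(inputs$links), inputs$parasite_tree$tip.label)
      if (length(miss)) errs <- c(errs, paste0("linked parasites absent from tree: ",
                                               paste(miss, collapse = ", ")))
    }
    if (!is.null(inputs$host_tree)) {
      miss <- setdiff(colnames(inputs$links), inputs$host_tree$tip.label)
      if (length(miss)) errs <- c(errs, paste0("linked hosts absent from host tree: ",
                                               paste(miss, collapse = ", ")))
    }
    if (!is.null(inputs$host_distances)) {
      miss <- setdiff(colnames(inputs$links), rownames(inputs$host_distances))
      if (length(miss)) errs <- c(errs, paste0("hosts missing from distance matrix: ",
                                               paste(miss, collapse = ", ")))
    }
    if (!is.null(inputs$parasite_distances)) {
      miss <- setdiff(rownames(inputs$links), rownames(inputs$parasite_distances))
      if (length(miss)) errs <- c(errs, paste0("parasites missing from distance matrix: ",
                                               paste(miss, collapse = ", ")))
    }
  }
  if (length(errs)) {
    stop2("pre-flight validation failed:\n  ", paste(errs, collapse = "\n  "))
  }

  report <- list(config = unclass(config),
                 seeds = list(),
                 stages = list(),
                 warnings = character(0))

  run_stage <- function(name, enabled, fn) {
    if (!enabled) return(invisible())
    st <- Sys.time()
    log_stage("stage %s ...", name)
    res <- tryCatch(fn(), error = function(e) {
      stop2("stage '", name, "' failed: ", conditionMessage(e))
    })
    log_stage("stage %s done (%.1fs)", name,
              as.numeric(difftime(Sys.time(), st, units = "secs")))
    report$stages[[name]] <<- res
    invisible()
  }

  # ---- delimitation -------------------------------------------------------
  delimit_one <- function(aln, theta, alpha, marker) {
    stats <- alignment_stats(aln)
    haps <- collapse_haplotypes(aln)
    D <- alignment_distances(haps, model = "JC+G", alpha = alpha)
    del <- delimit_species(D, theta, units = "fraction")
    list(marker = marker, alignment = stats,
         n_sequences = sum(haps$multiplicity),
         n_haplotypes = length(haps$sequences),
         theta = theta, gamma_shape = alpha,
         n_species = del$n_species,
         clusters = as.list(del$clusters))
  }
  run_stage("delimitation_its", !is.null(inputs$alignment_its), function() {
    delimit_one(inputs$alignment_its, config$theta_its, config$alpha_its, "ITS")
  })
  run_stage("delimitation_coi", !is.null(inputs$alignment_coi), function() {
    delimit_one(inputs$alignment_coi, config$theta_coi, config$alpha_coi, "COI")
  })

  # ---- reconciliation -----------------------------------------------------
  recon_ready <- !is.null(inputs$host_tree) && !is.null(inputs$parasite_tree) &&
    !is.null(inputs$links)
  run_stage("reconciliation", recon_ready, function() {
    ptree <- inputs$parasite_tree
    links <- inputs$links
    if (!is.null(node_supports(ptree))) {
      ptree <- collapse_low_support(ptree, config$support_collapse)
    }
    coll <- collapse_terminal_host_clades(ptree, links)
    seed <- stage_seed(config$seed, 1L)
    report$seeds$reconciliation <<- seed
    est <- estimate_costs(inputs$host_tree, coll$tree, coll$links,
                          n_sets = config$n_cost_sets, seed = seed,
                          options = reconcile_options(allow_polytomies = TRUE))
    plaus <- flag_implausible(est$reconciliation)
    chron <- check_chronology(inputs$host_tree, est$reconciliation)
    seed2 <- stage_seed(config$seed, 2L)
    report$seeds$topology_randomization <<- seed2
    cosp <- cospeciation_significance(inputs$host_tree, coll$tree, coll$links,
                                      n_rand = config$n_rand_topology, seed = seed2,
                                      options = reconcile_options(allow_polytomies = TRUE))
    list(event_table = event_table(est$reconciliation),
         ranked = est$ranked,
         quality = est$quality,
         implausible = plaus,
         chronologically_consistent = chron,
         cospeciation_test = cosp[c("observed", "p_value", "n_rand")])
  })

  # ---- congruence ---------------------------------------------------------
  congr_ready <- !is.null(inputs$links) &&
    !is.null(inputs$host_distances) && !is.null(inputs$parasite_distances)
  run_stage("congruence", congr_ready, function() {
    seed <- stage_seed(config$seed, 3L)
    report$seeds$congruence <<- seed
    res <- parafit_links(inputs$host_distances, inputs$parasite_distances,
                         inputs$links, n_perm = config$n_perm_parafit,
                         seed = seed)
    list(statistic = res$statistic, p_value = res$p_value,
         n_perm = res$n_perm,
         n_links = nrow(res$links),
         n_links_significant = sum(res$links$p_value <= 0.05),
         links = res$links)
  })

  # ---- diversification ----------------------------------------------------
  run_stage("diversification", !is.null(inputs$ultrametric_tree), function() {
    times <- branching_times(inputs$ultrametric_tree)
    seed <- stage_seed(config$seed, 4L)
    report$seeds$diversification <<- seed
    fits <- fit_models(times)
    shift <- rate_shift_test(times, n_null = config$n_null_trees, seed = seed)
    list(n_tips = attr(times, "n_tips"),
         ltt = ltt_series(times),
         fits = fits[, c("model", "logL", "k", "AIC")],
         delta_aic = shift$delta_aic,
         p_value = shift$p_value,
         n_null = shift$n_null)
  })

  # ---- rate calibration ---------------------------------------------------
  run_stage("calibration", TRUE, function() {
    r <- calibrate_rate(config$calibration_range[1], config$calibration_range[2],
                        config$calibration_age)
    list(divergence_range_percent = config$calibration_range,
         age_mya = config$calibration_age,
         rate_percent_per_my = as.list(r))
  })

  report$elapsed_seconds <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(report) <- "run_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, out_dir)
  }
  report
}

#' Write a run report to disk
#'
#' @param report a `"run_report"`.
#' @param dir output directory (`report.json` plus TSV summaries).
#' @export
write_report <- function(report, dir) {
  ser <- rapply(unclass(report), function(x) {
    if (is.data.frame(x)) x else x
  }, how = "replace")
  jsonlite::write_json(ser, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  if (!is.null(report$stages$reconciliation)) {
    utils::write.table(report$stages$reconciliation$event_table,
                       file.path(dir, "event_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$stages$congruence)) {
    utils::write.table(report$stages$congruence$links,
                       file.path(dir, "link_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$stages$diversification)) {
    utils::write.table(report$stages$diversification$ltt,
                       file.path(dir, "ltt.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file.path(dir, "report.json"))
}

#' @export
print.run_report <- function(x, ...) {
  cat("cophyr run report:", length(x$stages), "stage(s),",
      sprintf("%.1fs elapsed\n", x$elapsed_seconds))
  for (nm in names(x$stages)) cat("  -", nm, "\n")
  invisible(x)
}
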