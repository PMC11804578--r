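#' Default pipeline configuration
#'
#' A full configuration is a list with components `analysis` (fields of
#' [analysis_config()]), `simulation` (fields of [simulation_config()];
#' used when no input paths are given), optional `inputs` (paths
#' `salt_counts`, `zinc_counts`, `sheet`, and optionally `fst_w`,
#' `fst_e`) and `out_dir`. Any omitted field takes its documented
#' default; a YAML file with the same structure can be used instead.
#'
#' @param config list or path to a YAML file; `NULL` for all defaults.
#' @return normalized configuration list.
#' @export
pipeline_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  ana <- do.call(analysis_config, config$analysis %||% list())
  sim_args <- config$simulation %||% list()
  if (is.null(sim_args$seed)) sim_args$seed <- ana$seed
  if (!is.null(sim_args$class_proportions))
    sim_args$class_proportions <- unlist(sim_args$class_proportions)
  sim <- do.call(simulation_config, sim_args)
  list(analysis = ana, simulation = sim, inputs = config$inputs,
       out_dir = config$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic child seeds fanned out from the global seed
child_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L + stage * 7919L) %% 2147483647L
}

#' Run the complete analysis pipeline
#'
#' Executes simulate (or load) -> filter -> contrast catalog ->
#' classification -> randomization and proportion tests -> PST-FST
#' screening, and (when `out_dir` is set) writes every result table plus
#' a YAML run manifest. With simulated input the planted truth is scored
#' with [score_recovery()]. The run is fully deterministic under the
#' configured seed.
#'
#' @param config list or YAML path, see [pipeline_config()].
#' @return list of class `plastiscan_run` with elements `config`,
#'   `catalog`, `report`, `summary`, `randomization`, `proportion`,
#'   `pst_fst`, `recovery` (NULL for real input), `truth`, `data`,
#'   `manifest`.
#' @export
run_full <- function(config = NULL) {
  cfg <- pipeline_config(config)
  ana <- cfg$analysis
  truth <- NULL
  fst <- NULL
  if (!is.null(cfg$inputs)) {
    salt <- read_experiment(cfg$inputs$salt_counts, cfg$inputs$sheet)
    zinc <- read_experiment(cfg$inputs$zinc_counts, cfg$inputs$sheet)
    sheet <- salt$sheet
    salt <- salt$counts; zinc <- zinc$counts
    if (!is.null(cfg$inputs$fst_w))
      fst <- list(W = read_fst(cfg$inputs$fst_w, "W"),
                  E = read_fst(cfg$inputs$fst_e, "E"))
  } else {
    sim <- simulate_experiments(cfg$simulation)
    salt <- sim$salt; zinc <- sim$zinc; sheet <- sim$sheet
    truth <- sim$truth
  }
  if (is.null(fst))
    fst <- list(
      W = simulate_fst_null(10000L, seed = child_seed(ana$seed, 1L),
                            pair = "W"),
      E = simulate_fst_null(10000L, seed = child_seed(ana$seed, 2L),
                            pair = "E"))

  catalog <- build_contrast_catalog(salt, zinc, sheet, ana)
  report <- classify_genes(catalog)
  sizes <- attr(report, "sizes")
  summary_tab <- summarize_report(report)

  # randomization tests: shared salt plasticity across the two coasts
  # and across the two mines
  rand <- list(
    coast_salt = overlap_randomization(
      catalog$P[["salt.Coast-W"]], catalog$P[["salt.Coast-E"]],
      catalog$universe, ana$n_permutations, child_seed(ana$seed, 3L)),
    mine_salt = overlap_randomization(
      catalog$P[["salt.Mine-W"]], catalog$P[["salt.Mine-E"]],
      catalog$universe, ana$n_permutations, child_seed(ana$seed, 4L)))

  # proportion tests against permutation-estimated chance expectations
  prop <- list()
  for (cat_nm in c("cue_transfer", "genetic_adoption")) {
    den <- if (cat_nm == "cue_transfer")
      sizes[["changed_zinc_plasticity"]] else sizes[["constitutive_ec"]]
    n_perm <- min(ana$n_permutations, 200L)
    p0 <- chance_proportion(catalog, cat_nm, n_permutations = n_perm,
                            seed = child_seed(ana$seed, 5L))
    # chance probability that a gene in the denominator set meets the
    # rule: rescale the per-universe-gene rate to the denominator; a
    # zero permutation estimate is floored at the add-one bound
    floor0 <- 1 / (n_perm * length(catalog$universe) + 1)
    p0_cond <- min(max(p0$p0 * length(catalog$universe) /
                         max(den, 1L), floor0), 1 - 1e-12)
    prop[[cat_nm]] <- if (den > 0)
      proportion_chisq(sizes[[cat_nm]], den, p0_cond) else NULL
    prop[[paste0(cat_nm, "_p0")]] <- p0
  }

  # PST-FST screening of the constitutive and mine-zinc-plastic sets
  zinc_f <- low_count_filter(zinc, ana$min_count)
  zinc_f <- zinc_f[intersect(rownames(zinc_f), catalog$universe), ,
                   drop = FALSE]
  class(zinc_f) <- c("count_matrix", "matrix", "array")
  sheet_z <- sheet[sheet$experiment == "zinc_expt", ]
  ec_genes <- constitutive_ec_set(catalog)$gene_id
  mz <- catalog_evidence(catalog)
  plastic_genes <- mz$genes[mz$mine_zinc != "none"]
  pst_fst <- list()
  for (pr in PAIRS) {
    con <- pst_genes(zinc_f, sheet_z, ec_genes, pr, "control",
                     ana$c_over_h2)
    pla <- pst_genes(zinc_f, sheet_z, plastic_genes, pr,
                     "zinc_over_control", ana$c_over_h2)
    pst_fst[[pr]] <- list(
      constitutive = con, plastic = pla,
      constitutive_exceed = fraction_exceeding(con$pst, fst[[pr]],
                                               ana$alpha),
      plastic_exceed = fraction_exceeding(pla$pst, fst[[pr]],
                                          ana$alpha))
  }

  recovery <- if (!is.null(truth)) score_recovery(truth, report) else NULL

  run <- structure(list(config = cfg, catalog = catalog, report = report,
                        summary = summary_tab, randomization = rand,
                        proportion = prop, pst_fst = pst_fst,
                        recovery = recovery, truth = truth,
                        data = list(salt = salt, zinc = zinc,
                                    sheet = sheet, fst = fst),
                        manifest = NULL),
                   class = "plastiscan_run")
  if (!is.null(cfg$out_dir)) run$manifest <- write_run(run, cfg$out_dir)
  run
}

# serialize the run's tables; returns the file manifest
write_run <- function(run, out_dir) {
  sizes <- attr(run$report, "sizes")
  tables <- list(
    classification_report = as.data.frame(run$report),
    summary = run$summary,
    set_sizes = data.frame(set = names(sizes), size = as.integer(sizes)),
    test_summaries = data.frame(
      test = c("randomization_coast_salt", "randomization_mine_salt",
               "proportion_cue_transfer", "proportion_genetic_adoption"),
      statistic = c(run$randomization$coast_salt$observed_overlap,
                    run$randomization$mine_salt$observed_overlap,
                    run$proportion$cue_transfer$chi2 %||% NA_real_,
                    run$proportion$genetic_adoption$chi2 %||% NA_real_),
      p_value = c(run$randomization$coast_salt$p_value,
                  run$randomization$mine_salt$p_value,
                  run$proportion$cue_transfer$p_value %||% NA_real_,
                  run$proportion$genetic_adoption$p_value %||% NA_real_)))
  for (pr in names(run$pst_fst)) {
    tables[[paste0("pst_constitutive_", pr)]] <-
      run$pst_fst[[pr]]$constitutive
    tables[[paste0("pst_plastic_", pr)]] <- run$pst_fst[[pr]]$plastic
  }
  if (!is.null(run$recovery))
    tables$recovery <- as.data.frame(run$recovery)
  write_results(tables, out_dir, run$config$analysis)
}

#' Re-threshold and reclassify at a different significance level
#'
#' Rebuilds the contrast catalog and classification from the run's
#' stored count matrices at a relaxed (or tightened) `alpha2` without
#' re-simulating, and reports per-category count deltas.
#'
#' @param run a `plastiscan_run`.
#' @param alpha2 new significance level in (0, 1).
#' @return list: `report2`, `sizes2`, `deltas` (data.frame of per-set
#'   size changes, new minus old).
#' @export
relaxed_fdr_rerun <- function(run, alpha2) {
  if (alpha2 <= 0 || alpha2 >= 1)
    stop("alpha2 must be strictly between 0 and 1", call. = FALSE)
  ana <- run$config$analysis
  ana2 <- analysis_config(alpha = alpha2, min_count = ana$min_count,
                          n_permutations = ana$n_permutations,
                          bootstrap_reps = ana$bootstrap_reps,
                          c_over_h2 = ana$c_over_h2, seed = ana$seed)
  catalog2 <- build_contrast_catalog(run$data$salt, run$data$zinc,
                                     run$data$sheet, ana2)
  report2 <- classify_genes(catalog2)
  s1 <- attr(run$report, "sizes"); s2 <- attr(report2, "sizes")
  deltas <- data.frame(set = names(s1),
                       old = as.integer(s1),
                       new = as.integer(s2[names(s1)]),
                       delta = as.integer(s2[names(s1)] - s1),
                       stringsAsFactors = FALSE, row.names = NULL)
  list(report2 = report2, sizes2 = s2, deltas = deltas)
}

#' @export
print.plastiscan_run <- function(x, ...) {
  sizes <- attr(x$report, "sizes")
  cat("plastiscan run:", sizes[["universe"]], "comparable genes\n")
  for (nm in c("coast_salt_plastic", "mine_salt_plastic",
               "evolved_zinc_plasticity", "constitutive_ec",
               "preadaptive", "cue_transfer", "genetic_adoption",
               "genetic_assimilation"))
    cat(sprintf("  %-26s %d\n", nm, sizes[[nm]]))
  invisible(x)
}
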