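#' Simulation configuration for the paired salt/zinc design
#'
#' Defines the synthetic study: two experiments (salt and zinc, 24 pooled
#' samples each) over two coast/mine population pairs with
#' `n_individuals` biological replicates per population per treatment,
#' negative-binomial counts with a `alpha(mu) = a0 + a1/mu` dispersion
#' trend, log-normal baseline expression, multiplicative library-depth
#' noise, and planted gene classes with known effect directions.
#'
#' Recognized classes and their planted mean structure (`e` the effect in
#' log2 units, `d` a random per-gene sign):
#' \describe{
#'   \item{null}{no effects anywhere.}
#'   \item{coast_salt_plastic}{salt response `d*e` in both coasts only.}
#'   \item{preadaptive}{salt and zinc responses `d*e` in all four
#'     populations, no constitutive change.}
#'   \item{cue_transfer}{coastal (and retained mine) salt response `d*e`;
#'     coastal zinc response absent or opposite; mine zinc response
#'     `d*e`.}
#'   \item{genetic_adoption}{coastal salt response `d*e`; constitutive
#'     mine shift `d*e`; no mine zinc plasticity; coastal zinc response
#'     absent or opposite.}
#'   \item{genetic_assimilation}{coastal zinc response `d*e`;
#'     constitutive mine shift `d*e`; mine zinc response canalized to
#'     zero.}
#'   \item{evolved_plasticity_other}{mine-only zinc response `d*e`
#'     (evolved zinc plasticity that is not cue transfer).}
#'   \item{lineage_specific}{responses in a single population only
#'     (never shared across the pair).}
#' }
#'
#' @param n_genes number of genes.
#' @param class_proportions named fractions over the classes above,
#'   summing to 1.
#' @param base_mean_log_mu,base_mean_log_sd log-normal parameters of the
#'   baseline mean expression.
#' @param dispersion_a0,dispersion_a1 dispersion trend coefficients.
#' @param effect_log2fc magnitude of planted effects (log2 units).
#' @param library_size_sd sdlog of the per-sample depth factor.
#' @param n_individuals replicates per population per treatment.
#' @param seed integer seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 10000L,
                              class_proportions = c(
                                null = 0.88,
                                coast_salt_plastic = 0.02,
                                preadaptive = 0.02,
                                cue_transfer = 0.02,
                                genetic_adoption = 0.02,
                                genetic_assimilation = 0.02,
                                evolved_plasticity_other = 0.01,
                                lineage_specific = 0.01),
                              base_mean_log_mu = log(400),
                              base_mean_log_sd = 1,
                              dispersion_a0 = 0.05,
                              dispersion_a1 = 0,
                              effect_log2fc = 2,
                              library_size_sd = 0.2,
                              n_individuals = 3L,
                              seed = 1L) {
  known <- c("null", "coast_salt_plastic", "preadaptive", "cue_transfer",
             "genetic_adoption", "genetic_assimilation",
             "evolved_plasticity_other", "lineage_specific")
  bad <- setdiff(names(class_proportions), known)
  if (length(bad))
    stop("unknown gene class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1", call. = FALSE)
  if (any(class_proportions < 0))
    stop("class_proportions must be non-negative", call. = FALSE)
  pos <- class_proportions[class_proportions > 0]
  if (any(n_genes * pos < 1))
    stop("n_genes x smallest positive class fraction is below 1 gene",
         call. = FALSE)
  stopifnot(effect_log2fc >= 0, dispersion_a0 >= 0, dispersion_a1 >= 0,
            base_mean_log_sd >= 0, library_size_sd >= 0,
            n_individuals >= 2, n_genes >= 2)
  structure(list(n_genes = as.integer(n_genes),
                 class_proportions = class_proportions,
                 base_mean_log_mu = base_mean_log_mu,
                 base_mean_log_sd = base_mean_log_sd,
                 dispersion_a0 = dispersion_a0,
                 dispersion_a1 = dispersion_a1,
                 effect_log2fc = effect_log2fc,
                 library_size_sd = library_size_sd,
                 n_individuals = as.integer(n_individuals),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# evaluate expr with a private, seeded RNG stream; restores global state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# the 16 design cells: experiment x population x treatment
design_cells <- function() {
  rbind(
    expand.grid(experiment = "salt_expt", population = POPULATIONS,
                treatment = c("control", "salt"),
                stringsAsFactors = FALSE),
    expand.grid(experiment = "zinc_expt", population = POPULATIONS,
                treatment = c("control", "zinc"),
                stringsAsFactors = FALSE))
}

cell_key <- function(experiment, population, treatment) {
  paste(experiment, population, treatment, sep = ".")
}

# per-gene log2 offsets for every design cell given class and signs
planted_offsets <- function(class, d, e, zinc_opposite) {
  cells <- design_cells()
  off <- stats::setNames(numeric(nrow(cells)),
                         cell_key(cells$experiment, cells$population,
                                  cells$treatment))
  coast <- c("Coast-W", "Coast-E"); mine <- c("Mine-W", "Mine-E")
  add <- function(ex, pops, trt, amount) {
    k <- cell_key(ex, pops, trt)
    off[k] <<- off[k] + amount
  }
  salt_resp_coast <- 0; salt_resp_mine <- 0
  zinc_resp_coast <- 0; zinc_resp_mine <- 0
  constitutive <- 0
  if (class == "coast_salt_plastic") {
    salt_resp_coast <- d * e
  } else if (class == "preadaptive") {
    salt_resp_coast <- salt_resp_mine <- d * e
    zinc_resp_coast <- zinc_resp_mine <- d * e
  } else if (class == "cue_transfer") {
    salt_resp_coast <- salt_resp_mine <- d * e
    zinc_resp_coast <- if (zinc_opposite) -d * e else 0
    zinc_resp_mine <- d * e
  } else if (class == "genetic_adoption") {
    salt_resp_coast <- d * e
    zinc_resp_coast <- if (zinc_opposite) -d * e else 0
    constitutive <- d * e
  } else if (class == "genetic_assimilation") {
    zinc_resp_coast <- d * e
    constitutive <- d * e
  } else if (class == "evolved_plasticity_other") {
    zinc_resp_mine <- d * e
  } else if (class == "lineage_specific") {
    add("salt_expt", "Coast-W", "salt", d * e)
    add("zinc_expt", "Mine-W", "zinc", d * e)
  }
  if (salt_resp_coast != 0) add("salt_expt", coast, "salt", salt_resp_coast)
  if (salt_resp_mine != 0) add("salt_expt", mine, "salt", salt_resp_mine)
  if (zinc_resp_coast != 0) add("zinc_expt", coast, "zinc", zinc_resp_coast)
  if (zinc_resp_mine != 0) add("zinc_expt", mine, "zinc", zinc_resp_mine)
  if (constitutive != 0)
    for (trt in c("control", "salt", "zinc"))
      for (ex in EXPERIMENTS) {
        k <- cell_key(ex, mine, trt)
        k <- k[k %in% names(off)]
        if (length(k)) off[k] <- off[k] + constitutive
      }
  list(offsets = off,
       dir_salt_coast = sign(salt_resp_coast),
       dir_salt_mine = sign(salt_resp_mine),
       dir_zinc_coast = sign(zinc_resp_coast),
       dir_zinc_mine = sign(zinc_resp_mine),
       dir_constitutive = sign(constitutive))
}

# sample sheet for one experiment
experiment_sheet <- function(experiment, n_individuals) {
  cue <- if (experiment == "salt_expt") "salt" else "zinc"
  g <- expand.grid(individual = paste0("ind", seq_len(n_individuals)),
                   treatment = c("control", cue),
                   population = POPULATIONS,
                   stringsAsFactors = FALSE)
  g$ecotype <- ifelse(grepl("^Coast", g$population), "coast", "mine")
  g$pair <- sub("^.*-", "", g$population)
  g$experiment <- experiment
  g$sample_id <- paste(g$population, g$individual, g$treatment,
                       sub("_expt$", "", experiment), sep = ".")
  g[, c("sample_id", "population", "ecotype", "pair", "individual",
        "treatment", "experiment")]
}

#' Simulate the paired salt and zinc experiments
#'
#' Draws the two genes-by-24-samples count matrices with planted gene
#' classes. Counts are NB with mean `s_j * mu_gc` (sample depth factor
#' times the gene's cell mean) and gene dispersion from the configured
#' trend; a zero dispersion gives Poisson counts. The same baseline,
#' class and direction assignments underlie both experiments, so
#' cross-experiment control expression is equal by construction (up to a
#' constitutive mine shift that applies to both experiments alike).
#'
#' @param cfg a `simulation_config`.
#' @return list with `salt` and `zinc` count matrices, `sheet` (both
#'   experiments' samples), and `truth` (a `planted_truth` data.frame:
#'   class, planted directions and the 16 per-cell true means per gene).
#' @export
simulate_experiments <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_genes
    props <- cfg$class_proportions[cfg$class_proportions > 0]
    n_per <- floor(props * n)
    left <- n - sum(n_per)
    if (left > 0) {
      top <- order(props * n - n_per, decreasing = TRUE)
      n_per[top[seq_len(left)]] <- n_per[top[seq_len(left)]] + 1L
    }
    classes <- rep(names(n_per), n_per)
    gene_ids <- sprintf("g%05d", seq_len(n))
    mu0 <- stats::rlnorm(n, cfg$base_mean_log_mu, cfg$base_mean_log_sd)
    alpha_g <- cfg$dispersion_a0 + cfg$dispersion_a1 / mu0
    d <- sample(c(-1, 1), n, replace = TRUE)
    zinc_opp <- stats::runif(n) < 0.5
    cells <- design_cells()
    keys <- cell_key(cells$experiment, cells$population, cells$treatment)
    offmat <- matrix(0, n, length(keys), dimnames = list(gene_ids, keys))
    dirs <- matrix(0L, n, 5L, dimnames = list(gene_ids,
      c("dir_salt_coast", "dir_salt_mine", "dir_zinc_coast",
        "dir_zinc_mine", "dir_constitutive")))
    for (i in seq_len(n)) {
      po <- planted_offsets(classes[i], d[i], cfg$effect_log2fc,
                            zinc_opp[i])
      offmat[i, ] <- po$offsets[keys]
      dirs[i, ] <- c(po$dir_salt_coast, po$dir_salt_mine,
                     po$dir_zinc_coast, po$dir_zinc_mine,
                     po$dir_constitutive)
    }
    means <- mu0 * 2^offmat  # genes x 16 true cell means
    sheets <- lapply(EXPERIMENTS, experiment_sheet,
                     n_individuals = cfg$n_individuals)
    names(sheets) <- EXPERIMENTS
    mats <- list()
    for (ex in EXPERIMENTS) {
      sh <- sheets[[ex]]
      depth <- stats::rlnorm(nrow(sh), 0, cfg$library_size_sd)
      m <- matrix(0L, n, nrow(sh), dimnames = list(gene_ids, sh$sample_id))
      for (j in seq_len(nrow(sh))) {
        mu_j <- means[, cell_key(ex, sh$population[j], sh$treatment[j])] *
          depth[j]
        m[, j] <- if (all(alpha_g == 0)) {
          stats::rpois(n, mu_j)
        } else {
          stats::rnbinom(n, mu = mu_j, size = 1 / pmax(alpha_g, 1e-12))
        }
      }
      mats[[ex]] <- count_matrix(m)
    }
    sheet <- do.call(rbind, sheets)
    rownames(sheet) <- NULL
    validate_sample_sheet(sheet)
    truth <- data.frame(gene_id = gene_ids, class = classes,
                        base_mean = mu0, dispersion = alpha_g,
                        dirs, means, check.names = FALSE,
                        stringsAsFactors = FALSE, row.names = NULL)
    class(truth) <- c("planted_truth", "data.frame")
    if (cfg$effect_log2fc > 0) validate_planted_truth(truth)
    list(salt = mats$salt_expt, zinc = mats$zinc_expt, sheet = sheet,
         truth = truth)
  })
}

#' Check internal consistency of a planted truth table
#'
#' Asserts the sign constraints that define each class, e.g. cue-transfer
#' genes must have a mine zinc direction equal to the coastal salt
#' direction and a coastal zinc direction different from it.
#'
#' @param truth a `planted_truth` data.frame.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_planted_truth <- function(truth) {
  chk <- function(cond, msg) {
    if (!all(cond)) stop("planted truth inconsistency: ", msg,
                         call. = FALSE)
  }
  for (cl in unique(truth$class)) {
    t <- truth[truth$class == cl, ]
    switch(cl,
      null = chk(t$dir_salt_coast == 0 & t$dir_zinc_mine == 0 &
                   t$dir_constitutive == 0, "null genes carry effects"),
      coast_salt_plastic = chk(t$dir_salt_coast != 0 &
                                 t$dir_zinc_mine == 0,
                               "coast_salt_plastic signs"),
      preadaptive = chk(t$dir_salt_coast != 0 &
                          t$dir_salt_coast == t$dir_salt_mine &
                          t$dir_salt_coast == t$dir_zinc_coast &
                          t$dir_salt_coast == t$dir_zinc_mine &
                          t$dir_constitutive == 0, "preadaptive signs"),
      cue_transfer = chk(t$dir_salt_coast != 0 &
                           t$dir_zinc_mine == t$dir_salt_coast &
                           t$dir_zinc_coast != t$dir_salt_coast,
                         "cue_transfer signs"),
      genetic_adoption = chk(t$dir_salt_coast != 0 &
                               t$dir_constitutive == t$dir_salt_coast &
                               t$dir_zinc_mine == 0 &
                               t$dir_zinc_coast != t$dir_salt_coast,
                             "genetic_adoption signs"),
      genetic_assimilation = chk(t$dir_zinc_coast != 0 &
                                   t$dir_constitutive == t$dir_zinc_coast &
                                   t$dir_zinc_mine == 0,
                                 "genetic_assimilation signs"),
      evolved_plasticity_other = chk(t$dir_zinc_mine != 0 &
                                       t$dir_zinc_coast == 0 &
                                       t$dir_salt_coast == 0,
                                     "evolved_plasticity_other signs"),
      lineage_specific = NULL)
  }
  invisible(TRUE)
}

#' Simulate a neutral genome-wide FST distribution
#'
#' Beta-distributed stand-in for an empirical neutral differentiation
#' distribution.
#'
#' @param n_loci number of loci (>= 1).
#' @param shape_a,shape_b positive Beta shapes.
#' @param seed integer seed.
#' @param pair pair label attached to the result.
#' @return an `fst_distribution`.
#' @export
simulate_fst_null <- function(n_loci, shape_a = 0.5, shape_b = 5,
                              seed = 1L, pair = "W") {
  if (n_loci < 1) stop("n_loci must be >= 1", call. = FALSE)
  stopifnot(shape_a > 0, shape_b > 0)
  with_seed(seed, fst_distribution(pair, stats::rbeta(n_loci, shape_a,
                                                      shape_b)))
}

#' Score classification recovery against the planted truth
#'
#' Compares assigned categories with planted classes over the analyzed
#' gene universe (the genes present in the report; report genes must be a
#' subset of the truth). For each of the four headline classes
#' (preadaptive, cue_transfer, genetic_adoption, genetic_assimilation)
#' reports precision, recall and F1; genes planted in a class but absent
#' from the report (filtered upstream) are counted in `n_filtered`, not
#' against recall.
#'
#' @param truth `planted_truth` table.
#' @param report classification report with `gene_id` and `category`.
#' @return data.frame of class `confusion_table` with one row per scored
#'   class, plus attributes `accuracy` (over genes planted in scored
#'   classes), `false_assignments` (genes planted outside a class but
#'   assigned one) and `n_unclassified`.
#' @export
score_recovery <- function(truth, report) {
  extra <- setdiff(report$gene_id, truth$gene_id)
  if (length(extra))
    stop("report contains genes absent from truth: ",
         paste(utils::head(extra, 3), collapse = ", "), call. = FALSE)
  scored <- c("preadaptive", "cue_transfer", "genetic_adoption",
              "genetic_assimilation")
  tr_class <- stats::setNames(truth$class, truth$gene_id)
  assigned <- stats::setNames(report$category, report$gene_id)
  planted_in <- tr_class[names(assigned)]
  rows <- lapply(scored, function(cl) {
    tp <- sum(planted_in == cl & assigned == cl)
    fp <- sum(planted_in != cl & assigned == cl)
    n_in <- sum(planted_in == cl)
    n_filtered <- sum(tr_class == cl) - n_in
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (n_in > 0) tp / n_in else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    data.frame(class = cl, n_planted = sum(tr_class == cl),
               n_in_universe = n_in, n_filtered = n_filtered,
               tp = tp, fp = fp, precision = precision, recall = recall,
               f1 = f1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  in_scored <- planted_in %in% scored
  attr(out, "accuracy") <- if (any(in_scored))
    mean(assigned[in_scored] == planted_in[in_scored]) else NA_real_
  attr(out, "false_assignments") <-
    sum(!in_scored & assigned %in% scored)
  attr(out, "n_unclassified") <- sum(assigned == "none")
  class(out) <- c("confusion_table", "data.frame")
  out
}
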