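#' Within-population plasticity contrast (treatment vs control)
#'
#' Tests cue-treatment vs control expression inside one population, with
#' individuals as a pairing block (the paired-design analogue of a
#' population-by-individual nested model). Positive log2fc means higher
#' expression under the cue treatment.
#'
#' @param cm experiment count matrix (already filtered).
#' @param sheet sample sheet rows for that experiment.
#' @param nf size factors for `cm`'s samples.
#' @param disp dispersion table (or scalar).
#' @param population one of `Coast-W`, `Mine-W`, `Coast-E`, `Mine-E`.
#' @param cue `"salt"` or `"zinc"`.
#' @param alpha significance level for the direction calls.
#' @param paired mean-center within individual before contrasting.
#' @return `direction_call` data.frame (BH adjusted over tested genes).
#' @export
plasticity_contrast <- function(cm, sheet, nf, disp, population, cue,
                                alpha = 0.05, paired = TRUE) {
  idx <- sheet$population == population & sheet$treatment %in%
    c("control", cue)
  sub <- sheet[idx, ]
  if (!all(c("control", cue) %in% sub$treatment))
    stop("population ", population, " lacks control or ", cue,
         " samples", call. = FALSE)
  ctrl_ind <- sort(sub$individual[sub$treatment == "control"])
  cue_ind <- sort(sub$individual[sub$treatment == cue])
  if (!identical(ctrl_ind, cue_ind))
    stop("individuals unmatched across treatments in ", population,
         call. = FALSE)
  cols <- match(sub$sample_id, colnames(cm))
  res <- nb_wald_contrast(cm[, cols, drop = FALSE], nf[cols], disp,
                          design = sub$treatment,
                          contrast = c(cue, "control"),
                          block = if (paired) sub$individual else NULL)
  call_genes(res, alpha)
}

#' Mine-vs-coast divergence contrast within one treatment
#'
#' Tests mine vs coast expression for one population pair within one
#' treatment. Positive log2fc means higher expression in the mine
#' population.
#'
#' @inheritParams plasticity_contrast
#' @param pair `"W"` or `"E"`.
#' @param treatment `"control"`, `"salt"` or `"zinc"`.
#' @return `direction_call` data.frame.
#' @export
divergence_contrast <- function(cm, sheet, nf, disp, pair, treatment,
                                alpha = 0.05) {
  idx <- sheet$pair == pair & sheet$treatment == treatment
  sub <- sheet[idx, ]
  if (length(unique(sub$ecotype)) < 2L)
    stop("pair ", pair, " lacks both ecotypes in treatment ", treatment,
         call. = FALSE)
  cols <- match(sub$sample_id, colnames(cm))
  res <- nb_wald_contrast(cm[, cols, drop = FALSE], nf[cols], disp,
                          design = sub$ecotype,
                          contrast = c("mine", "coast"))
  call_genes(res, alpha)
}

# X(pop): control(salt_expt) vs control(zinc_expt) for one population,
# on the combined control-sample matrix
cross_experiment_contrast <- function(cm, sheet, nf, disp, population,
                                      alpha = 0.05) {
  idx <- sheet$population == population & sheet$treatment == "control"
  sub <- sheet[idx, ]
  cols <- match(sub$sample_id, colnames(cm))
  res <- nb_wald_contrast(cm[, cols, drop = FALSE], nf[cols], disp,
                          design = sub$experiment,
                          contrast = c("salt_expt", "zinc_expt"))
  call_genes(res, alpha)
}

#' Cross-experiment comparability filter
#'
#' Returns genes with no significant control-vs-control expression
#' difference between the two experiments. Mode `"all"` (default,
#' strictest) demands a non-significant call in every one of the four
#' populations; mode `"pooled"` tests all control samples of one
#' experiment against the other's in a single contrast.
#'
#' @param x_calls named list of the four per-population `direction_call`
#'   tables (mode `"all"`), or a single table (mode `"pooled"`).
#' @param mode `"all"` or `"pooled"`.
#' @return character vector of comparable gene ids.
#' @export
cross_experiment_filter <- function(x_calls, mode = c("all", "pooled")) {
  mode <- match.arg(mode)
  if (mode == "pooled") {
    if (is.data.frame(x_calls)) x_calls <- list(x_calls)
    x_calls <- x_calls[1]
  }
  ok <- Reduce(`&`, lapply(x_calls, function(tab) tab$call == "ns"))
  genes <- x_calls[[1]]$gene_id[ok]
  if (!length(genes))
    stop("cross-experiment filter removed every gene", call. = FALSE)
  genes
}

#' Direction-matched shared calls between two populations
#'
#' A gene is shared with direction `d` when both call tables assign it
#' the same non-`ns` direction.
#'
#' @param calls_a,calls_b `direction_call` tables over the same genes.
#' @return data.frame `gene_id`, `shared` (`"up"`, `"down"` or `"none"`)
#'   with attribute `size`, the number of shared genes.
#' @export
shared_call <- function(calls_a, calls_b) {
  if (!setequal(calls_a$gene_id, calls_b$gene_id))
    stop("call tables cover different gene universes", call. = FALSE)
  b <- calls_b[match(calls_a$gene_id, calls_b$gene_id), ]
  shared <- ifelse(calls_a$call != "ns" & calls_a$call == b$call,
                   calls_a$call, "none")
  out <- data.frame(gene_id = calls_a$gene_id, shared = shared,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "size") <- sum(shared != "none")
  out
}

#' Build the full contrast catalog for the paired experiments
#'
#' Runs the complete contrast set on the comparable gene universe:
#' \itemize{
#'   \item `P`: treatment-vs-control plasticity within each of the four
#'     populations, for the salt cue (salt experiment) and the zinc cue
#'     (zinc experiment) — 8 contrasts, individual-paired.
#'   \item `D`: mine-vs-coast divergence per pair in control, salt and
#'     zinc treatments — 6 contrasts (the control divergence is taken
#'     from the zinc experiment's control samples by default, matching
#'     the constitutive-change definition; set
#'     `control_divergence_from = "salt_expt"` for the alternative).
#'   \item `X`: control-vs-control between experiments per population —
#'     4 contrasts, which define the comparable universe (genes
#'     non-significant in all four, or in a pooled test with
#'     `comparability = "pooled"`).
#' }
#' Each contrast is BH-adjusted over exactly its tested gene set; P and D
#' contrasts are computed on the comparable universe.
#'
#' @param salt,zinc count matrices for the two experiments.
#' @param sheet combined sample sheet covering both experiments.
#' @param config an [analysis_config()].
#' @param comparability `"all"` or `"pooled"` (see
#'   [cross_experiment_filter()]).
#' @param control_divergence_from experiment supplying the control
#'   divergence contrast.
#' @param paired use individual pairing in plasticity contrasts.
#' @return list of class `contrast_catalog`: `universe` (comparable gene
#'   ids), `P` (list by `<cue>.<population>`), `D` (list by
#'   `<treatment>.<pair>`), `X` (list by population), `n_before_filter`,
#'   `alpha`.
#' @export
build_contrast_catalog <- function(salt, zinc, sheet,
                                   config = analysis_config(),
                                   comparability = c("all", "pooled"),
                                   control_divergence_from = "zinc_expt",
                                   paired = TRUE) {
  comparability <- match.arg(comparability)
  validate_sample_sheet(sheet)
  alpha <- config$alpha
  salt_f <- low_count_filter(salt, config$min_count)
  zinc_f <- low_count_filter(zinc, config$min_count)
  genes <- intersect(rownames(salt_f), rownames(zinc_f))
  if (length(genes) < 2L)
    stop("fewer than 2 genes shared by the filtered experiments",
         call. = FALSE)
  salt_f <- salt_f[genes, , drop = FALSE]
  zinc_f <- zinc_f[genes, , drop = FALSE]
  sheet_s <- sheet[sheet$experiment == "salt_expt", ]
  sheet_z <- sheet[sheet$experiment == "zinc_expt", ]
  sheet_s <- sheet_s[match(colnames(salt_f), sheet_s$sample_id), ]
  sheet_z <- sheet_z[match(colnames(zinc_f), sheet_z$sample_id), ]

  # cross-experiment stage: combined control samples
  ctrl_s <- sheet_s[sheet_s$treatment == "control", ]
  ctrl_z <- sheet_z[sheet_z$treatment == "control", ]
  comb <- cbind(salt_f[, ctrl_s$sample_id, drop = FALSE],
                zinc_f[, ctrl_z$sample_id, drop = FALSE])
  sheet_c <- rbind(ctrl_s, ctrl_z)
  nf_c <- median_ratio_size_factors(comb)
  grp_c <- paste(sheet_c$population, sheet_c$experiment, sep = ".")
  disp_c <- estimate_dispersions(comb, nf_c, grp_c)
  X <- if (comparability == "pooled") {
    res <- nb_wald_contrast(comb, nf_c, disp_c, design = sheet_c$experiment,
                            contrast = c("salt_expt", "zinc_expt"))
    list(pooled = call_genes(res, alpha))
  } else {
    stats::setNames(lapply(POPULATIONS, function(p)
      cross_experiment_contrast(comb, sheet_c, nf_c, disp_c, p, alpha)),
      POPULATIONS)
  }
  universe <- cross_experiment_filter(X, comparability)

  salt_u <- salt_f[universe, , drop = FALSE]
  zinc_u <- zinc_f[universe, , drop = FALSE]
  nf_s <- median_ratio_size_factors(salt_u)
  nf_z <- median_ratio_size_factors(zinc_u)
  disp_s <- estimate_dispersions(salt_u, nf_s,
    paste(sheet_s$population, sheet_s$treatment, sep = "."))
  disp_z <- estimate_dispersions(zinc_u, nf_z,
    paste(sheet_z$population, sheet_z$treatment, sep = "."))

  P <- list()
  for (p in POPULATIONS) {
    P[[paste0("salt.", p)]] <- plasticity_contrast(
      salt_u, sheet_s, nf_s, disp_s, p, "salt", alpha, paired)
    P[[paste0("zinc.", p)]] <- plasticity_contrast(
      zinc_u, sheet_z, nf_z, disp_z, p, "zinc", alpha, paired)
  }
  D <- list()
  ctl <- if (control_divergence_from == "zinc_expt")
    list(cm = zinc_u, sh = sheet_z, nf = nf_z, di = disp_z)
  else list(cm = salt_u, sh = sheet_s, nf = nf_s, di = disp_s)
  for (pr in PAIRS) {
    D[[paste0("control.", pr)]] <- divergence_contrast(
      ctl$cm, ctl$sh, ctl$nf, ctl$di, pr, "control", alpha)
    D[[paste0("salt.", pr)]] <- divergence_contrast(
      salt_u, sheet_s, nf_s, disp_s, pr, "salt", alpha)
    D[[paste0("zinc.", pr)]] <- divergence_contrast(
      zinc_u, sheet_z, nf_z, disp_z, pr, "zinc", alpha)
  }
  structure(list(universe = universe, P = P, D = D, X = X,
                 n_before_filter = length(genes), alpha = alpha),
            class = "contrast_catalog")
}

#' @export
print.contrast_catalog <- function(x, ...) {
  cat("contrast_catalog:", length(x$universe), "comparable genes (of",
      x$n_before_filter, "filtered), alpha =", x$alpha, "\n")
  cat("  P contrasts:", paste(names(x$P), collapse = ", "), "\n")
  cat("  D contrasts:", paste(names(x$D), collapse = ", "), "\n")
  invisible(x)
}
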