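# named call vector (gene_id -> up/down/ns) from a direction_call table
call_vec <- function(tab) stats::setNames(tab$call, tab$gene_id)

# shared direction between two call tables: up/down/none per gene
shared_vec <- function(tab_a, tab_b) {
  s <- shared_call(tab_a, tab_b)
  stats::setNames(s$shared, s$gene_id)
}

# all shared/evidence vectors the decision rules need, aligned on universe
catalog_evidence <- function(catalog) {
  u <- catalog$universe
  P <- catalog$P; D <- catalog$D
  al <- function(v) v[u]
  list(
    genes = u,
    coast_salt = al(shared_vec(P[["salt.Coast-W"]], P[["salt.Coast-E"]])),
    mine_salt = al(shared_vec(P[["salt.Mine-W"]], P[["salt.Mine-E"]])),
    coast_zinc = al(shared_vec(P[["zinc.Coast-W"]], P[["zinc.Coast-E"]])),
    mine_zinc = al(shared_vec(P[["zinc.Mine-W"]], P[["zinc.Mine-E"]])),
    ec = al(shared_vec(D[["control.W"]], D[["control.E"]])),
    d_zinc_sig = al(call_vec(D[["zinc.W"]]) != "ns") &
      al(call_vec(D[["zinc.E"]]) != "ns"),
    mine_zinc_ns = al(call_vec(P[["zinc.Mine-W"]]) == "ns") &
      al(call_vec(P[["zinc.Mine-E"]]) == "ns"),
    p_salt = lapply(P[paste0("salt.", POPULATIONS)],
                    function(t) al(call_vec(t))),
    p_zinc = lapply(P[paste0("zinc.", POPULATIONS)],
                    function(t) al(call_vec(t))))
}

#' Genes with evolved zinc plasticity
#'
#' Genes zinc-plastic in both mine populations with the same direction
#' and differentially expressed between mine and coast in the zinc
#' treatment in both pairs.
#'
#' @param catalog a `contrast_catalog`.
#' @return character vector of gene ids.
#' @export
evolved_zinc_plasticity_set <- function(catalog) {
  ev <- catalog_evidence(catalog)
  ev$genes[ev$mine_zinc != "none" & ev$d_zinc_sig]
}

#' Genes with a shared constitutive evolutionary change
#'
#' Genes differentially expressed between mine and coast under control
#' conditions in both pairs, with the same direction.
#'
#' @param catalog a `contrast_catalog`.
#' @return data.frame `gene_id`, `direction` (the shared mine-vs-coast
#'   sign).
#' @export
constitutive_ec_set <- function(catalog) {
  ev <- catalog_evidence(catalog)
  keep <- ev$ec != "none"
  data.frame(gene_id = ev$genes[keep], direction = unname(ev$ec[keep]),
             stringsAsFactors = FALSE, row.names = NULL)
}

# rule kernels operating on an evidence list -------------------------------

rule_preadaptive <- function(ev) {
  allcalls <- c(ev$p_salt, ev$p_zinc)
  sig <- Reduce(`&`, lapply(allcalls, function(v) v != "ns"))
  same <- Reduce(`&`, lapply(allcalls[-1],
                             function(v) v == allcalls[[1]]))
  sig & same
}

rule_cue_transfer <- function(ev) {
  ds <- ev$coast_salt
  ds != "none" & ev$coast_zinc != ds &
    ev$mine_zinc != "none" & ev$d_zinc_sig & ev$mine_zinc == ds
}

rule_genetic_adoption <- function(ev) {
  ds <- ev$coast_salt
  ds != "none" & ev$ec == ds & ev$mine_zinc_ns & ev$coast_zinc != ds
}

rule_genetic_assimilation <- function(ev) {
  ev$ec != "none" & ev$coast_zinc == ev$ec & ev$mine_zinc_ns
}

rule_changed_plasticity <- function(ev) {
  ev$mine_zinc != "none" & ev$d_zinc_sig & ev$coast_zinc != ev$mine_zinc
}

#' Genes with preadaptive plasticity
#'
#' Significant same-direction responses to both cues in all four
#' populations: the salt call and zinc call of every population share one
#' common direction.
#' @param catalog a `contrast_catalog`.
#' @return character vector of gene ids.
#' @export
classify_preadaptive <- function(catalog) {
  ev <- catalog_evidence(catalog)
  ev$genes[rule_preadaptive(ev)]
}

#' Genes showing cue transfer
#'
#' Coastal salt-plastic genes (shared direction `d`) whose shared coastal
#' zinc response is not `d`, that belong to the evolved-zinc-plasticity
#' set, and whose shared mine zinc direction equals `d`: the derived zinc
#' response resembles the ancestral salt response.
#' @param catalog a `contrast_catalog`.
#' @return character vector of gene ids.
#' @export
classify_cue_transfer <- function(catalog) {
  ev <- catalog_evidence(catalog)
  ev$genes[rule_cue_transfer(ev)]
}

#' Genes showing genetic adoption
#'
#' Coastal salt-plastic genes with a shared constitutive mine-vs-coast
#' change in the salt-response direction, no zinc plasticity in either
#' mine, and a shared coastal zinc response different from the salt
#' direction: the ancestral salt-response value became constitutive.
#' @param catalog a `contrast_catalog`.
#' @return character vector of gene ids.
#' @export
classify_genetic_adoption <- function(catalog) {
  ev <- catalog_evidence(catalog)
  ev$genes[rule_genetic_adoption(ev)]
}

#' Genes showing genetic assimilation
#'
#' Constitutively changed genes whose shared coastal zinc response
#' matches the constitutive direction while mine zinc plasticity is
#' absent: ancestral zinc plasticity canalized into constitutive
#' expression.
#' @param catalog a `contrast_catalog`.
#' @return character vector of gene ids.
#' @export
classify_genetic_assimilation <- function(catalog) {
  ev <- catalog_evidence(catalog)
  ev$genes[rule_genetic_assimilation(ev)]
}

#' Classify every comparable gene
#'
#' Applies the four decision rules to the contrast catalog. The rules are
#' mutually exclusive by construction; a gene matching two categories
#' (impossible under the rule logic, guarded anyway) aborts with a
#' diagnostic. Genes matching no rule fall back to
#' `evolved_plasticity_unclassified` (member of the evolved zinc
#' plasticity set), `constitutive_unclassified` (shared constitutive
#' change) or `none`.
#'
#' @param catalog a `contrast_catalog`.
#' @return data.frame of class `classification_report`: `gene_id`,
#'   `category` and the evidence columns (shared coast/mine salt and zinc
#'   directions, constitutive direction, zinc-divergence and mine-zinc-ns
#'   flags, changed-plasticity flag). Set sizes are attached as the
#'   `sizes` attribute.
#' @export
classify_genes <- function(catalog) {
  ev <- catalog_evidence(catalog)
  hits <- cbind(preadaptive = rule_preadaptive(ev),
                cue_transfer = rule_cue_transfer(ev),
                genetic_adoption = rule_genetic_adoption(ev),
                genetic_assimilation = rule_genetic_assimilation(ev))
  multi <- rowSums(hits) > 1L
  if (any(multi))
    stop("gene(s) matched multiple exclusive categories: ",
         paste(utils::head(ev$genes[multi], 5), collapse = ", "),
         call. = FALSE)
  category <- rep("none", length(ev$genes))
  for (cl in colnames(hits)) category[hits[, cl]] <- cl
  evolved <- ev$mine_zinc != "none" & ev$d_zinc_sig
  category[category == "none" & evolved] <- "evolved_plasticity_unclassified"
  category[category == "none" & ev$ec != "none"] <-
    "constitutive_unclassified"
  report <- data.frame(
    gene_id = ev$genes, category = category,
    coast_salt_shared = unname(ev$coast_salt),
    mine_salt_shared = unname(ev$mine_salt),
    coast_zinc_shared = unname(ev$coast_zinc),
    mine_zinc_shared = unname(ev$mine_zinc),
    constitutive_shared = unname(ev$ec),
    d_zinc_sig_both = unname(ev$d_zinc_sig),
    mine_zinc_ns_both = unname(ev$mine_zinc_ns),
    changed_zinc_plasticity = unname(rule_changed_plasticity(ev)),
    stringsAsFactors = FALSE, row.names = NULL)
  sizes <- c(
    universe = length(ev$genes),
    coast_salt_plastic = sum(ev$coast_salt != "none"),
    mine_salt_plastic = sum(ev$mine_salt != "none"),
    coast_zinc_plastic = sum(ev$coast_zinc != "none"),
    mine_zinc_plastic = sum(ev$mine_zinc != "none"),
    salt_plastic_overlap = sum(ev$coast_salt != "none" &
                                 ev$mine_salt != "none" &
                                 ev$coast_salt == ev$mine_salt),
    evolved_zinc_plasticity = sum(evolved),
    changed_zinc_plasticity = sum(rule_changed_plasticity(ev)),
    constitutive_ec = sum(ev$ec != "none"),
    preadaptive = sum(hits[, "preadaptive"]),
    cue_transfer = sum(hits[, "cue_transfer"]),
    genetic_adoption = sum(hits[, "genetic_adoption"]),
    genetic_assimilation = sum(hits[, "genetic_assimilation"]))
  attr(report, "sizes") <- sizes
  class(report) <- c("classification_report", "data.frame")
  report
}

#' Summarize a classification into the headline counts and percentages
#'
#' Computes, from gene-set sizes, the quantities reported for the study
#' system: the cue-transfer share of genes with changed zinc plasticity,
#' the genetic-adoption share of constitutively changed genes, the
#' retention and loss of salt plasticity in mine populations, and
#' transcriptome fractions. Integer percentages are rounded half away
#' from zero; two-decimal percentages use standard two-decimal rounding.
#' Ratios with a zero denominator yield `NA` and are flagged in the
#' `defined` column.
#'
#' @param report a `classification_report`, or a named list/vector of set
#'   sizes with entries `cue_transfer`, `changed_zinc_plasticity`,
#'   `genetic_adoption`, `constitutive_ec`, `salt_plastic_overlap`,
#'   `coast_salt_plastic`, `mine_salt_plastic` (and optionally
#'   `coast_zinc_plastic`).
#' @param universe_size denominator for transcriptome fractions; defaults
#'   to the report's universe.
#' @return data.frame `quantity`, `numerator`, `denominator`, `value`,
#'   `defined`.
#' @export
summarize_report <- function(report, universe_size = NULL) {
  sizes <- if (inherits(report, "classification_report"))
    as.list(attr(report, "sizes")) else as.list(report)
  if (is.null(universe_size)) universe_size <- sizes$universe
  if (is.null(universe_size))
    stop("universe_size is required", call. = FALSE)
  g <- function(nm) if (is.null(sizes[[nm]])) NA_real_ else
    as.numeric(sizes[[nm]])
  pct_int <- function(num, den) if (is.na(den) || den == 0) NA_real_ else
    round_half_up(100 * num / den)
  pct2 <- function(num, den) if (is.na(den) || den == 0) NA_real_ else
    round_half_up(100 * num / den, 2L)
  rows <- list(
    list("cue_transfer_pct", g("cue_transfer"),
         g("changed_zinc_plasticity"),
         pct_int(g("cue_transfer"), g("changed_zinc_plasticity"))),
    list("genetic_adoption_pct", g("genetic_adoption"),
         g("constitutive_ec"),
         pct_int(g("genetic_adoption"), g("constitutive_ec"))),
    list("salt_plasticity_retention_pct", g("salt_plastic_overlap"),
         g("mine_salt_plastic"),
         pct_int(g("salt_plastic_overlap"), g("mine_salt_plastic"))),
    list("salt_plasticity_loss_pct",
         g("coast_salt_plastic") - g("salt_plastic_overlap"),
         g("coast_salt_plastic"),
         if (is.na(g("coast_salt_plastic")) ||
             g("coast_salt_plastic") == 0) NA_real_ else
           round_half_up(100 * (1 - g("salt_plastic_overlap") /
                                  g("coast_salt_plastic")), 2L)),
    list("coast_salt_transcriptome_pct", g("coast_salt_plastic"),
         universe_size, pct2(g("coast_salt_plastic"), universe_size)),
    list("mine_salt_transcriptome_pct", g("mine_salt_plastic"),
         universe_size, pct2(g("mine_salt_plastic"), universe_size)),
    list("coast_zinc_transcriptome_pct", g("coast_zinc_plastic"),
         universe_size, pct2(g("coast_zinc_plastic"), universe_size)))
  out <- data.frame(
    quantity = vapply(rows, function(r) r[[1L]], ""),
    numerator = vapply(rows, function(r) as.numeric(r[[2L]]), 0),
    denominator = vapply(rows, function(r) as.numeric(r[[3L]]), 0),
    value = vapply(rows, function(r) as.numeric(r[[4L]]), 0),
    stringsAsFactors = FALSE, row.names = NULL)
  out$defined <- !is.na(out$value)
  out
}
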