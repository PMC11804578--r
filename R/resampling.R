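#' Randomization test for direction-matched shared DE genes
#'
#' Observed statistic: the number of genes called in the same non-`ns`
#' direction by both call sets. Null: hold A fixed and reassign B's up
#' and down labels to uniformly random distinct genes of the universe,
#' recounting the direction-matched overlap each time. The p-value uses
#' the add-one permutation convention
#' `(1 + #{perm >= observed}) / (n_permutations + 1)`.
#'
#' @param calls_a,calls_b `direction_call` tables covering the universe.
#' @param universe character vector of gene ids.
#' @param n_permutations number of label reassignments (>= 1).
#' @param seed integer seed.
#' @return list of class `randomization_result`: `observed_overlap`,
#'   `expected_overlap`, `p_value`, `n_permutations`.
#' @export
overlap_randomization <- function(calls_a, calls_b, universe,
                                  n_permutations = 10000L, seed = 1L) {
  stopifnot(n_permutations >= 1)
  a <- stats::setNames(calls_a$call, calls_a$gene_id)[universe]
  if (anyNA(a))
    stop("calls must be defined on every universe gene", call. = FALSE)
  n_up <- sum(calls_b$call == "up"); n_dn <- sum(calls_b$call == "down")
  if (n_up + n_dn > length(universe))
    stop("universe smaller than B's significant set", call. = FALSE)
  b <- stats::setNames(calls_b$call, calls_b$gene_id)[universe]
  b[is.na(b)] <- "ns"
  observed <- sum(a != "ns" & a == b)
  a_up <- which(a == "up"); a_dn <- which(a == "down")
  n <- length(universe)
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      pick <- sample.int(n, n_up + n_dn)
      sum(pick[seq_len(n_up)] %in% a_up) +
        sum(pick[n_up + seq_len(n_dn)] %in% a_dn)
    }, 0L)
  })
  structure(list(observed_overlap = observed,
                 expected_overlap = mean(perm),
                 p_value = (1 + sum(perm >= observed)) /
                   (n_permutations + 1),
                 n_permutations = as.integer(n_permutations)),
            class = "randomization_result")
}

#' One-sample proportion chi-square test
#'
#' Tests `x` successes in `n` trials against the null proportion `p0`
#' with the 1-df chi-square statistic
#' `(x - n p0)^2 / (n p0 (1 - p0))` (Yates continuity subtracts 0.5 from
#' the absolute deviation first). Delegates to [stats::prop.test()].
#'
#' @param x successes (0 <= x <= n).
#' @param n trials.
#' @param p0 null proportion, strictly inside (0, 1).
#' @param continuity apply the continuity correction.
#' @param alternative passed to [stats::prop.test()].
#' @return list of class `proportion_test_result`: `x`, `n`, `p0`,
#'   `chi2`, `df`, `p_value`.
#' @export
proportion_chisq <- function(x, n, p0, continuity = FALSE,
                             alternative = "two.sided") {
  stopifnot(x >= 0, x <= n, n >= 1)
  if (p0 <= 0 || p0 >= 1)
    stop("p0 must be strictly between 0 and 1", call. = FALSE)
  ht <- suppressWarnings(stats::prop.test(x, n, p = p0,
                                          correct = continuity,
                                          alternative = alternative))
  structure(list(x = x, n = n, p0 = p0,
                 chi2 = unname(ht$statistic), df = 1L,
                 p_value = ht$p.value),
            class = "proportion_test_result")
}

#' Chance probability of meeting a category rule
#'
#' Estimates the probability that a random gene satisfies a
#' classification rule when every contrast's direction calls are
#' permuted independently across genes, breaking all between-contrast
#' dependence while preserving each contrast's up/down/ns margins.
#'
#' @param catalog a `contrast_catalog`.
#' @param category rule name (`"preadaptive"`, `"cue_transfer"`,
#'   `"genetic_adoption"`, `"genetic_assimilation"`) or a function taking
#'   a catalog and returning a gene-id vector.
#' @param n_permutations number of independent catalog shuffles.
#' @param seed integer seed.
#' @return list: `p0` (mean fraction of genes meeting the rule), `se`
#'   (Monte-Carlo standard error), `n_permutations`.
#' @export
chance_proportion <- function(catalog, category, n_permutations = 200L,
                              seed = 1L) {
  rule_fun <- if (is.function(category)) category else
    switch(category,
           preadaptive = classify_preadaptive,
           cue_transfer = classify_cue_transfer,
           genetic_adoption = classify_genetic_adoption,
           genetic_assimilation = classify_genetic_assimilation,
           stop("unknown category rule: ", category, call. = FALSE))
  n <- length(catalog$universe)
  shuffle_tab <- function(tab) {
    idx <- sample.int(nrow(tab))
    out <- tab[idx, ]
    out$gene_id <- tab$gene_id
    out
  }
  fracs <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      perm <- catalog
      perm$P <- lapply(catalog$P, shuffle_tab)
      perm$D <- lapply(catalog$D, shuffle_tab)
      length(rule_fun(perm)) / n
    }, 0)
  })
  list(p0 = mean(fracs), se = stats::sd(fracs) / sqrt(n_permutations),
       n_permutations = as.integer(n_permutations))
}

#' PST point estimate for one trait across two populations
#'
#' Decomposes the trait into the between-population component (variance
#' of the two population means about their grand mean) and the pooled
#' within-population variance, then
#' `PST = (c/h2 * s2_B) / (c/h2 * s2_B + 2 * s2_W)`.
#'
#' @param values numeric trait values, one per sample.
#' @param population two-level label per value (>= 2 samples each).
#' @param c_over_h2 scalar c/h^2 (default 1).
#' @return list of class `pst_result`: `sigma2_between`, `sigma2_within`,
#'   `c_over_h2`, `pst` (`NA` with `defined = FALSE` when both
#'   components vanish).
#' @export
pst_statistic <- function(values, population, c_over_h2 = 1) {
  population <- as.character(population)
  lev <- unique(population)
  if (length(lev) != 2L)
    stop("exactly two populations required", call. = FALSE)
  if (any(table(population) < 2L))
    stop("at least 2 samples per population required", call. = FALSE)
  stopifnot(c_over_h2 > 0)
  means <- tapply(values, population, mean)
  s2_b <- stats::var(as.numeric(means))
  s2_w <- sum(tapply(values, population,
                     function(v) sum((v - mean(v))^2))) /
    (length(values) - 2L)
  denom <- c_over_h2 * s2_b + 2 * s2_w
  pst <- if (denom > 0) c_over_h2 * s2_b / denom else NA_real_
  structure(list(sigma2_between = s2_b, sigma2_within = s2_w,
                 c_over_h2 = c_over_h2, pst = pst,
                 defined = denom > 0),
            class = "pst_result")
}

#' Bootstrap percentile interval for PST
#'
#' Resamples within each population with replacement and reports the
#' 2.5/97.5 percentile interval of the PST estimate.
#'
#' @inheritParams pst_statistic
#' @param reps bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @return `pst_result` with added `ci_low`, `ci_high`, `reps`.
#' @export
pst_bootstrap <- function(values, population, c_over_h2 = 1, reps = 200L,
                          seed = 1L) {
  if (reps < 100L) stop("reps must be >= 100", call. = FALSE)
  if (any(table(population) < 2L))
    stop("each population needs more than one sample", call. = FALSE)
  point <- pst_statistic(values, population, c_over_h2)
  idx_by_pop <- split(seq_along(values), population)
  boots <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      take <- unlist(lapply(idx_by_pop, function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]))
      pst_statistic(values[take], population[take], c_over_h2)$pst
    }, 0)
  })
  boots <- boots[!is.na(boots)]
  ci <- if (length(boots)) stats::quantile(boots, c(0.025, 0.975),
                                           names = FALSE)
  else c(NA_real_, NA_real_)
  point$ci_low <- min(ci[1L], point$pst, na.rm = TRUE)
  point$ci_high <- max(ci[2L], point$pst, na.rm = TRUE)
  point$reps <- as.integer(reps)
  point
}

#' Fraction of genes whose PST exceeds the neutral FST quantile
#'
#' @param pst numeric vector of per-gene PST point estimates.
#' @param fst an `fst_distribution`.
#' @param alpha tail level; the threshold is the empirical
#'   `1 - alpha` quantile of the FST values.
#' @return list: `fraction` (`NA` for an empty gene set, flagged by
#'   `defined`), `threshold`, `n_genes`.
#' @export
fraction_exceeding <- function(pst, fst, alpha = 0.05) {
  stopifnot(inherits(fst, "fst_distribution"))
  thr <- stats::quantile(fst$values, 1 - alpha, names = FALSE)
  pst <- pst[!is.na(pst)]
  if (!length(pst))
    return(list(fraction = NA_real_, threshold = thr, n_genes = 0L,
                defined = FALSE))
  list(fraction = mean(pst > thr), threshold = thr,
       n_genes = length(pst), defined = TRUE)
}

#' Per-gene PST for an expression trait over a gene set
#'
#' Builds the trait per sample/individual and population, then computes
#' per-gene PST within one population pair. Trait `"control"` is
#' `log2(normalized control count + 0.5)`; trait `"zinc_over_control"`
#' is the per-individual log2 ratio of zinc over control normalized
#' counts (individuals paired across treatments), the log-scale version
#' of the zinc/control expression fraction. Set `log_ratio = FALSE` for
#' the untransformed ratio.
#'
#' @param cm count matrix of the zinc experiment (filtered).
#' @param sheet its sample sheet.
#' @param genes gene ids to score.
#' @param pair `"W"` or `"E"`.
#' @param trait `"control"` or `"zinc_over_control"`.
#' @param c_over_h2 scalar c/h^2.
#' @param log_ratio log-transform the zinc/control ratio.
#' @return data.frame `gene_id`, `pst`, `sigma2_between`,
#'   `sigma2_within`.
#' @export
pst_genes <- function(cm, sheet, genes, pair,
                      trait = c("control", "zinc_over_control"),
                      c_over_h2 = 1, log_ratio = TRUE) {
  trait <- match.arg(trait)
  genes <- intersect(genes, rownames(cm))
  if (!length(genes))
    return(data.frame(gene_id = character(0), pst = numeric(0),
                      sigma2_between = numeric(0),
                      sigma2_within = numeric(0)))
  sub <- sheet[sheet$pair == pair, ]
  nf <- median_ratio_size_factors(cm)
  y <- sweep(unclass(cm), 2L, nf, "/")
  if (trait == "control") {
    sm <- sub[sub$treatment == "control", ]
    vals <- log2(y[genes, sm$sample_id, drop = FALSE] + 0.5)
    pops <- sm$population
  } else {
    ctl <- sub[sub$treatment == "control", ]
    zn <- sub[sub$treatment == "zinc", ]
    zn <- zn[match(paste(ctl$population, ctl$individual),
                   paste(zn$population, zn$individual)), ]
    if (anyNA(zn$sample_id))
      stop("individuals unmatched across zinc/control", call. = FALSE)
    ratio <- (y[genes, zn$sample_id, drop = FALSE] + 0.5) /
      (y[genes, ctl$sample_id, drop = FALSE] + 0.5)
    vals <- if (log_ratio) log2(ratio) else ratio
    pops <- ctl$population
  }
  res <- t(vapply(seq_along(genes), function(i) {
    p <- pst_statistic(vals[i, ], pops, c_over_h2)
    c(p$pst, p$sigma2_between, p$sigma2_within)
  }, numeric(3L)))
  data.frame(gene_id = genes, pst = res[, 1L],
             sigma2_between = res[, 2L], sigma2_within = res[, 3L],
             stringsAsFactors = FALSE, row.names = NULL)
}
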