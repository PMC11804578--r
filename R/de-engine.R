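#' Median-of-ratios size factors
#'
#' Standard library-size normalization for count matrices: each sample's
#' factor is the median, over reference genes, of that sample's counts
#' divided by the gene's geometric mean across samples. Reference genes
#' are those with no zero count; with `pseudo_reference = TRUE` a 0.5
#' pseudocount makes every gene usable when no all-positive gene exists.
#'
#' @param cm a `count_matrix` (or plain counts matrix).
#' @param pseudo_reference fall back to pseudocounted geometric means.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
median_ratio_size_factors <- function(cm, pseudo_reference = FALSE) {
  m <- unclass(cm)
  if (pseudo_reference) {
    logg <- rowMeans(log(m + 0.5))
    ref <- rep(TRUE, nrow(m))
  } else {
    ref <- rowSums(m == 0) == 0L
    if (!any(ref))
      stop("no gene has all counts positive; rerun with ",
           "pseudo_reference = TRUE", call. = FALSE)
    logg <- rowMeans(log(m[ref, , drop = FALSE]))
  }
  ratios <- log(m[ref, , drop = FALSE] + if (pseudo_reference) 0.5 else 0) -
    logg
  sf <- exp(apply(ratios, 2L, stats::median))
  stats::setNames(sf, colnames(m))
}

#' Per-gene negative-binomial dispersion estimates
#'
#' Method-of-moments gene estimates on normalized counts pooled within
#' condition groups, a fitted mean-dispersion trend
#' `alpha(mu) = a0 + a1/mu`, and a shrunk final estimate
#' `w * gene + (1 - w) * trend` with `w = df / (df + shrink)` where `df`
#' is the residual degrees of freedom. The NB parameterization is
#' `Var = mu + alpha * mu^2`.
#'
#' @param cm counts matrix.
#' @param nf size factors from [median_ratio_size_factors()].
#' @param groups per-sample condition labels; each group needs >= 2
#'   samples.
#' @param shrink prior weight pulling gene estimates toward the trend
#'   (default 4, tuned for 3-replicate designs).
#' @return data.frame `gene_id`, `alpha_gene`, `alpha_trend`, `alpha`.
#' @export
estimate_dispersions <- function(cm, nf, groups, shrink = 4) {
  m <- unclass(cm)
  groups <- as.character(groups)
  if (length(groups) != ncol(m))
    stop("one group label per sample required", call. = FALSE)
  tab <- table(groups)
  if (any(tab < 2L))
    stop("every group needs at least 2 samples; offending: ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  y <- sweep(m, 2L, nf, "/")
  glev <- names(tab)
  ss <- matrix(0, nrow(m), 1L)  # pooled within-group sum of squares
  poisson_part <- 0              # E[1/s] adjustment of the Poisson term
  for (g in glev) {
    idx <- groups == g
    yg <- y[, idx, drop = FALSE]
    mu_g <- rowMeans(yg)
    ss <- ss + rowSums((yg - mu_g)^2)
    poisson_part <- poisson_part + sum(1 / nf[idx])
  }
  df <- ncol(m) - length(glev)
  s2 <- ss[, 1L] / df
  mu <- rowMeans(y)
  inv_s <- poisson_part / ncol(m)  # mean of 1/size factor
  alpha_gene <- pmax(0, (s2 - mu * inv_s) / mu^2)
  alpha_gene[!is.finite(alpha_gene)] <- 0
  # least-squares trend on genes with a positive raw estimate
  pos <- alpha_gene > 0 & mu > 0
  if (sum(pos) >= 10L) {
    fit <- stats::lm.fit(cbind(1, 1 / mu[pos]), alpha_gene[pos])
    a0 <- max(fit$coefficients[1L], 1e-4)
    a1 <- max(fit$coefficients[2L], 0)
  } else {
    a0 <- max(stats::median(alpha_gene[pos]), 1e-4)
    if (!is.finite(a0)) a0 <- 1e-4
    a1 <- 0
  }
  alpha_trend <- pmax(a0 + a1 / pmax(mu, 1e-8), 1e-6)
  w <- df / (df + shrink)
  alpha <- w * alpha_gene + (1 - w) * alpha_trend
  out <- data.frame(gene_id = rownames(m), alpha_gene = alpha_gene,
                    alpha_trend = alpha_trend, alpha = alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "resid_df") <- df
  attr(out, "prior_df") <- shrink
  out
}

#' Negative-binomial Wald contrast between two design cells
#'
#' Fits per-gene cell means on normalized counts and tests
#' `log2(mu_num / mu_den)` with a Wald statistic whose standard error
#' comes from the NB variance function `Var = mu + alpha * mu^2`. Cell
#' means are floored at 0.5 normalized counts so fold changes stay
#' finite; genes with all-zero counts in both cells get `log2fc = 0`,
#' `p = 1`. An optional `block` factor (e.g. individual) mean-centers
#' expression within block before the contrast, removing block baseline
#' shifts in paired designs.
#'
#' Because the dispersion entering the standard error is itself
#' estimated, the Wald statistic is referred to a t distribution with
#' moderated degrees of freedom (the dispersion-estimation residual df
#' plus the shrinkage prior df, read from the `estimate_dispersions()`
#' attributes); with a known scalar dispersion the reference is normal.
#' This keeps null p-values uniform down to the far tail in
#' few-replicate designs.
#'
#' @param cm counts matrix.
#' @param nf size factors.
#' @param disp dispersion table from [estimate_dispersions()] (matched by
#'   gene id) or a single numeric dispersion.
#' @param design per-sample condition labels.
#' @param contrast length-2 character: numerator then denominator cell.
#' @param block optional per-sample blocking labels for paired centering.
#' @return data.frame of class `de_result`: `gene_id`, `log2fc`, `se`,
#'   `pvalue`, `padj` (BH-adjusted over all tested genes).
#' @export
nb_wald_contrast <- function(cm, nf, disp, design, contrast, block = NULL) {
  m <- unclass(cm)
  design <- as.character(design)
  if (length(design) != ncol(m))
    stop("design must label every sample", call. = FALSE)
  if (length(contrast) != 2L || !all(contrast %in% design))
    stop("both contrast conditions must be present in the design",
         call. = FALSE)
  if (is.numeric(disp) && length(disp) %in% c(1L, nrow(m))) {
    alpha_g <- rep_len(disp, nrow(m))
    t_df <- Inf  # dispersion treated as known
  } else {
    alpha_g <- disp$alpha[match(rownames(m), disp$gene_id)]
    t_df <- if (!is.null(attr(disp, "resid_df")))
      attr(disp, "resid_df") + attr(disp, "prior_df") else Inf
  }
  if (anyNA(alpha_g))
    stop("dispersion estimates missing for some genes", call. = FALSE)
  y <- sweep(m, 2L, nf, "/")
  if (!is.null(block)) {
    block <- as.character(block)
    grand <- rowMeans(y)
    for (b in unique(block)) {
      idx <- block == b
      y[, idx] <- y[, idx, drop = FALSE] -
        rowMeans(y[, idx, drop = FALSE]) + grand
    }
    y[y < 0] <- 0
  }
  cell <- function(cond) {
    idx <- design == cond
    mu_hat <- rowMeans(y[, idx, drop = FALSE])
    mu_fl <- pmax(mu_hat, 0.5)
    # Var(mean of normalized counts) = (1/n^2) sum_j (mu/s_j + alpha mu^2)
    v <- (mu_fl * sum(1 / nf[idx]) + alpha_g * mu_fl^2 * sum(idx)) /
      sum(idx)^2
    list(mu = mu_hat, mu_fl = mu_fl, var_log2 = v / (mu_fl * log(2))^2)
  }
  num <- cell(contrast[1L]); den <- cell(contrast[2L])
  log2fc <- log2(num$mu_fl / den$mu_fl)
  se <- sqrt(num$var_log2 + den$var_log2)
  z <- log2fc / se
  pvalue <- 2 * stats::pt(-abs(z), df = t_df)
  both_zero <- num$mu == 0 & den$mu == 0
  log2fc[both_zero] <- 0
  pvalue[both_zero] <- 1
  out <- data.frame(gene_id = rownames(m), log2fc = log2fc, se = se,
                    pvalue = pvalue, padj = bh_adjust(pvalue),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, returned in input order and
#' capped at 1 (delegates to [stats::p.adjust()]).
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Ternary direction calls from a DE result
#'
#' `up` when `padj <= alpha` and `log2fc > 0`, `down` when `padj <= alpha`
#' and `log2fc < 0`, otherwise `ns` (a zero fold change is never
#' significant).
#'
#' @param res `de_result` data.frame.
#' @param alpha significance threshold (boundary counts as significant).
#' @return data.frame of class `direction_call`: `gene_id`, `call`,
#'   `log2fc`, `padj`.
#' @export
call_genes <- function(res, alpha = 0.05) {
  call <- rep("ns", nrow(res))
  sig <- res$padj <= alpha & res$log2fc != 0
  call[sig & res$log2fc > 0] <- "up"
  call[sig & res$log2fc < 0] <- "down"
  out <- data.frame(gene_id = res$gene_id, call = call,
                    log2fc = res$log2fc, padj = res$padj,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("direction_call", "data.frame")
  out
}
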