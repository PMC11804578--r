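# shared fixture builders (all fixtures are generated in code)

# tiny count matrix with a matching single-experiment sample sheet
tiny_experiment <- function() {
  m <- matrix(c(12L, 15L, 11L, 30L,
                100L, 90L, 110L, 95L),
              nrow = 2L, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3", "s4")))
  sheet <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    population = c("Coast-W", "Coast-W", "Mine-W", "Mine-W"),
    ecotype = c("coast", "coast", "mine", "mine"),
    pair = "W",
    individual = c("ind1", "ind1", "ind1", "ind1"),
    treatment = c("control", "salt", "control", "salt"),
    experiment = "salt_expt",
    stringsAsFactors = FALSE)
  list(counts = count_matrix(m), sheet = sheet)
}

# direction_call table from a named vector of calls (up/down/ns)
call_table <- function(calls, genes = names(calls)) {
  call <- unname(calls[genes])
  data.frame(
    gene_id = genes,
    call = call,
    log2fc = ifelse(call == "up", 1, ifelse(call == "down", -1, 0)),
    padj = ifelse(call == "ns", 0.5, 0.01),
    stringsAsFactors = FALSE)
}

# hand-built contrast catalog; unspecified contrasts default to all-ns.
# P entries are named "<cue>.<population>", D entries "<treatment>.<pair>",
# X entries by population.
make_catalog <- function(universe, P = list(), D = list(), alpha = 0.05) {
  pops <- c("Coast-W", "Mine-W", "Coast-E", "Mine-E")
  ns <- setNames(rep("ns", length(universe)), universe)
  fill <- function(spec) {
    calls <- ns
    if (!is.null(spec)) calls[names(spec)] <- spec
    call_table(calls)
  }
  P_full <- list()
  for (cue in c("salt", "zinc"))
    for (p in pops)
      P_full[[paste0(cue, ".", p)]] <- fill(P[[paste0(cue, ".", p)]])
  D_full <- list()
  for (trt in c("control", "salt", "zinc"))
    for (pr in c("W", "E"))
      D_full[[paste0(trt, ".", pr)]] <- fill(D[[paste0(trt, ".", pr)]])
  X_full <- setNames(lapply(pops, function(p) fill(NULL)), pops)
  structure(list(universe = universe, P = P_full, D = D_full, X = X_full,
                 n_before_filter = length(universe), alpha = alpha),
            class = "contrast_catalog")
}

# brute-force BH step-up: sort, m*p/rank, cumulative min from the right
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, m * p[o] / seq_len(m))
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- adj
  out
}

# simulate a two-group NB count matrix; lfc applied to group b for the
# first n_de genes (all genes when n_de is NULL) so that median-of-ratios
# normalization retains a null majority
nb_two_group <- function(n_genes, n_per = 3L, mu_meanlog = log(400),
                         mu_sdlog = 1, dispersion = 0.05, lfc = 0,
                         n_de = NULL, seed = 1L) {
  set.seed(seed)
  mu <- rlnorm(n_genes, mu_meanlog, mu_sdlog)
  lfc_vec <- rep(lfc, n_genes)
  if (!is.null(n_de)) lfc_vec[-seq_len(n_de)] <- 0
  mu_mat <- cbind(matrix(mu, n_genes, n_per),
                  matrix(mu * 2^lfc_vec, n_genes, n_per))
  m <- matrix(rnbinom(length(mu_mat), mu = mu_mat,
                      size = 1 / dispersion),
              n_genes, 2L * n_per,
              dimnames = list(sprintf("g%05d", seq_len(n_genes)),
                              paste0("s", seq_len(2L * n_per))))
  list(counts = count_matrix(m),
       groups = rep(c("a", "b"), each = n_per),
       de_genes = if (is.null(n_de)) seq_len(n_genes) else seq_len(n_de))
}

# exhaustive-enumeration oracle for the direction-matched overlap null:
# B's up/down labels land on every ordered arrangement of distinct genes
exact_overlap_null <- function(calls_a, n_up, n_dn, universe) {
  a <- setNames(calls_a$call, calls_a$gene_id)[universe]
  n <- length(universe)
  idx <- seq_len(n)
  picks <- combn(idx, n_up + n_dn, simplify = FALSE)
  counts <- integer(0)
  for (p in picks) {
    if (n_up + n_dn > 1) {
      # all splits of the chosen genes into up vs down labels
      ups <- combn(p, n_up, simplify = FALSE)
      if (n_up == 0) ups <- list(integer(0))
      for (u in ups) {
        d <- setdiff(p, u)
        counts <- c(counts, sum(a[u] == "up") + sum(a[d] == "down"))
      }
    } else {
      counts <- c(counts, if (n_up == 1) sum(a[p] == "up") else
        sum(a[p] == "down"))
    }
  }
  counts
}
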