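genes5 <- c("g1", "g2", "g3", "g4", "g5")

test_that("evolved zinc plasticity set follows the membership rule", {
  cat <- make_catalog(
    genes5,
    P = list("zinc.Mine-W" = c(g1 = "up", g2 = "up", g3 = "down"),
             "zinc.Mine-E" = c(g1 = "up", g2 = "ns", g3 = "down")),
    D = list("zinc.W" = c(g1 = "up", g3 = "down"),
             "zinc.E" = c(g1 = "up", g3 = "up")))
  # g1: shared mine zinc + divergence in both pairs -> in
  # g2: mines disagree (up, ns) -> out; g3 qualifies (direction of the
  # divergence is not constrained)
  expect_setequal(evolved_zinc_plasticity_set(cat), c("g1", "g3"))
})

test_that("constitutive EC set requires shared-direction divergence", {
  cat <- make_catalog(
    genes5,
    D = list("control.W" = c(g1 = "up", g2 = "up", g3 = "down"),
             "control.E" = c(g1 = "up", g2 = "down", g3 = "down")))
  ec <- constitutive_ec_set(cat)
  expect_setequal(ec$gene_id, c("g1", "g3"))
  expect_identical(ec$direction[ec$gene_id == "g3"], "down")
})

test_that("preadaptive rule needs all eight same-direction calls", {
  allpops <- c("Coast-W", "Mine-W", "Coast-E", "Mine-E")
  up_everywhere <- setNames(rep("up", 5), genes5)
  P <- list()
  for (cue in c("salt", "zinc"))
    for (p in allpops)
      P[[paste0(cue, ".", p)]] <- up_everywhere
  # g2 flips direction in the zinc responses; g3 loses one salt call
  for (p in allpops) P[[paste0("zinc.", p)]][["g2"]] <- "down"
  P[["salt.Mine-E"]][["g3"]] <- "ns"
  cat <- make_catalog(genes5, P = P)
  expect_setequal(classify_preadaptive(cat), c("g1", "g4", "g5"))
})

test_that("cue transfer and genetic adoption instantiate the rule panels", {
  # g1: coastal salt down, coastal zinc up, mine zinc down with
  #   divergence -> cue transfer
  # g2: as g1 but mine zinc up (matches coastal zinc, not salt) -> not
  # g3: coastal salt down, EC down, mine zinc ns, coastal zinc up ->
  #   genetic adoption
  # g4: as g3 but EC up -> neither
  P <- list(
    "salt.Coast-W" = c(g1 = "down", g2 = "down", g3 = "down",
                       g4 = "down"),
    "salt.Coast-E" = c(g1 = "down", g2 = "down", g3 = "down",
                       g4 = "down"),
    "zinc.Coast-W" = c(g1 = "up", g2 = "up", g3 = "up", g4 = "down"),
    "zinc.Coast-E" = c(g1 = "up", g2 = "up", g3 = "up", g4 = "down"),
    "zinc.Mine-W" = c(g1 = "down", g2 = "up"),
    "zinc.Mine-E" = c(g1 = "down", g2 = "up"))
  D <- list(
    "zinc.W" = c(g1 = "down", g2 = "down"),
    "zinc.E" = c(g1 = "down", g2 = "down"),
    "control.W" = c(g3 = "down", g4 = "up"),
    "control.E" = c(g3 = "down", g4 = "up"))
  cat <- make_catalog(genes5, P = P, D = D)
  expect_identical(classify_cue_transfer(cat), "g1")
  expect_identical(classify_genetic_adoption(cat), "g3")
  report <- classify_genes(cat)
  expect_identical(report$category[report$gene_id == "g1"],
                   "cue_transfer")
  expect_identical(report$category[report$gene_id == "g2"],
                   "evolved_plasticity_unclassified")
  expect_identical(report$category[report$gene_id == "g4"],
                   "constitutive_unclassified")
  expect_identical(report$category[report$gene_id == "g5"], "none")
})

test_that("genetic assimilation is recognized and excludes adoption", {
  # g1: coastal zinc up, EC up, mine zinc ns -> assimilation
  # g2: adoption pattern (coastal salt down, EC down, coastal zinc up)
  P <- list(
    "zinc.Coast-W" = c(g1 = "up", g2 = "up"),
    "zinc.Coast-E" = c(g1 = "up", g2 = "up"),
    "salt.Coast-W" = c(g2 = "down"),
    "salt.Coast-E" = c(g2 = "down"))
  D <- list("control.W" = c(g1 = "up", g2 = "down"),
            "control.E" = c(g1 = "up", g2 = "down"))
  cat <- make_catalog(genes5, P = P, D = D)
  expect_identical(classify_genetic_assimilation(cat), "g1")
  expect_identical(classify_genetic_adoption(cat), "g2")
  report <- classify_genes(cat)
  expect_identical(report$category[report$gene_id == "g1"],
                   "genetic_assimilation")
  expect_identical(report$category[report$gene_id == "g2"],
                   "genetic_adoption")
})

test_that("classifier output is invariant to gene order", {
  sim <- simulate_experiments(simulation_config(n_genes = 500L,
                                                seed = 23L))
  cat <- build_contrast_catalog(sim$salt, sim$zinc, sim$sheet,
                                analysis_config(seed = 23L))
  rep1 <- classify_genes(cat)
  perm <- cat
  set.seed(1)
  perm$universe <- sample(cat$universe)
  shuffle <- function(tab) tab[sample(nrow(tab)), ]
  perm$P <- lapply(cat$P, shuffle)
  perm$D <- lapply(cat$D, shuffle)
  rep2 <- classify_genes(perm)
  rep2 <- rep2[match(rep1$gene_id, rep2$gene_id), ]
  expect_identical(rep1$category, rep2$category)
})

test_that("exclusive categories never overlap on simulated data", {
  sim <- simulate_experiments(simulation_config(n_genes = 2000L,
                                                seed = 29L))
  cat <- build_contrast_catalog(sim$salt, sim$zinc, sim$sheet,
                                analysis_config(seed = 29L))
  sets <- list(pre = classify_preadaptive(cat),
               ct = classify_cue_transfer(cat),
               ga = classify_genetic_adoption(cat),
               gs = classify_genetic_assimilation(cat))
  for (i in seq_along(sets))
    for (j in seq_along(sets))
      if (i < j) expect_length(intersect(sets[[i]], sets[[j]]), 0L)
  expect_true(all(sets$ct %in% evolved_zinc_plasticity_set(cat)))
  expect_true(all(sets$ga %in% constitutive_ec_set(cat)$gene_id))
})

test_that("summary percentages follow the stated rounding rules", {
  sizes <- list(cue_transfer = 28, changed_zinc_plasticity = 91,
                genetic_adoption = 30, constitutive_ec = 124,
                salt_plastic_overlap = 132, coast_salt_plastic = 957,
                mine_salt_plastic = 155, coast_zinc_plastic = 10933)
  s <- summarize_report(sizes, universe_size = 23093)
  val <- setNames(s$value, s$quantity)
  expect_identical(val[["cue_transfer_pct"]], 31)
  expect_identical(val[["genetic_adoption_pct"]], 24)
  expect_identical(val[["salt_plasticity_retention_pct"]], 85)
  expect_identical(val[["salt_plasticity_loss_pct"]], 86.21)
  expect_identical(val[["coast_salt_transcriptome_pct"]], 4.14)
  expect_identical(val[["mine_salt_transcriptome_pct"]], 0.67)
  expect_identical(val[["coast_zinc_transcriptome_pct"]], 47.34)
  # zero denominators are flagged, not errors
  s0 <- summarize_report(list(cue_transfer = 0,
                              changed_zinc_plasticity = 0,
                              genetic_adoption = 0, constitutive_ec = 0,
                              salt_plastic_overlap = 0,
                              coast_salt_plastic = 0,
                              mine_salt_plastic = 0),
                         universe_size = 100)
  expect_false(s0$defined[s0$quantity == "cue_transfer_pct"])
  # integer percentages round half away from zero
  s2 <- summarize_report(list(cue_transfer = 61,
                              changed_zinc_plasticity = 200,
                              genetic_adoption = 0, constitutive_ec = 1,
                              salt_plastic_overlap = 0,
                              coast_salt_plastic = 1,
                              mine_salt_plastic = 1),
                         universe_size = 100)
  expect_identical(s2$value[s2$quantity == "cue_transfer_pct"], 31)
})
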