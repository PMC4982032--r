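small_model <- function(seed = 5)
  background_model(n_genes = 400, mean_variants_per_exome = 150, seed = seed)

test_that("exome pools are deterministic and match the model's means", {
  model <- small_model()
  a <- generate_exome_pool(model, 2, seed = 7)
  b <- generate_exome_pool(model, 2, seed = 7)
  expect_identical(a, b)

  pool <- generate_exome_pool(model, 50, seed = 8)
  counts <- vapply(pool, function(p) nrow(p$variants), numeric(1))
  mu <- sum(model$intensity)
  se <- sqrt(mu / 50)  # Poisson totals
  expect_lt(abs(mean(counts) - mu), 3 * se)

  # effect-class frequencies match the multinomial within 3 SE
  eff <- unlist(lapply(pool, function(p) p$variants$effect))
  for (cl in names(model$effect_probs)) {
    p0 <- model$effect_probs[[cl]]
    se_cl <- sqrt(p0 * (1 - p0) / length(eff))
    expect_lt(abs(mean(eff == cl) - p0), 3 * se_cl + 1e-9)
  }

  # novel variants carry frequency exactly zero on both criteria
  af <- unlist(lapply(pool, function(p) p$variants$evs_af))
  expect_gt(mean(af == 0), 0.01)
})

test_that("recombination conserves per-chromosome variant multisets", {
  model <- small_model()
  pool <- generate_exome_pool(model, 6, seed = 9)
  out <- recombine_exomes(pool, 6, seed = 10)
  vid <- function(xs) sort(unlist(lapply(xs, function(p) p$variants$variant_id)))
  expect_equal(vid(out), vid(pool))
  # per chromosome, block conservation
  chrom_ids <- function(xs, ch)
    sort(unlist(lapply(xs, function(p)
      p$variants$variant_id[p$variants$chrom == ch])))
  for (ch in c("chr1", "chr5", "chr22"))
    expect_equal(chrom_ids(out, ch), chrom_ids(pool, ch))
  expect_error(recombine_exomes(pool, 7), "pool size")

  # single pool exome per output: with n_out = pool size each chromosome's
  # blocks are a permutation of the pool's
  counts_by_chrom <- function(xs, ch)
    sort(vapply(xs, function(p) sum(p$variants$chrom == ch), numeric(1)))
  for (ch in paste0("chr", c(2, 11)))
    expect_equal(counts_by_chrom(out, ch), counts_by_chrom(pool, ch))
})

test_that("spike-gene probabilities follow the heterogeneity model", {
  sc <- simulation_scenario(2, u = 0.2, balanced = FALSE, mode = "AR")
  expect_equal(spike_probabilities(sc), c(0.6, 0.2, 0.2))
  sc3 <- simulation_scenario(3, u = 0.4, balanced = FALSE)
  expect_equal(spike_probabilities(sc3), c(0.3, 0.15, 0.15, 0.4))
  sc4 <- simulation_scenario(4, u = 0.1, balanced = FALSE)
  expect_equal(spike_probabilities(sc4), c(0.45, 0.15, 0.15, 0.15, 0.1))
  scb <- simulation_scenario(3, u = 0, balanced = TRUE)
  expect_equal(spike_probabilities(scb), c(rep(1 / 3, 3), 0))

  # empirical check on a moderate draw
  genes <- paste0("G", 1:50)
  cases <- lapply(1:2000, function(i)
    exome_profile(paste0("c", i),
                  data.frame(variant_id = paste0("c", i, "_b"), gene = "G50",
                             zygosity = "het", evs_af = 0.5, kg_af = 0.5,
                             effect = "synonymous"), role = "case"))
  sp <- spike_study(cases, c("G1", "G2"), sc, gene_universe = genes, seed = 3)
  freq <- table(factor(ifelse(sp$log$captured, sp$log$gene, "other"),
                       levels = c("G1", "G2", "other"))) / 2000
  expect_lt(abs(freq[["G1"]] - 0.6), 3 * sqrt(0.6 * 0.4 / 2000))
  expect_lt(abs(freq[["G2"]] - 0.2), 3 * sqrt(0.2 * 0.8 / 2000))

  # u = 0 balanced: every case captured, shares roughly equal
  spb <- spike_study(cases, c("G1", "G2", "G3"),
                     simulation_scenario(3, u = 0, balanced = TRUE),
                     gene_universe = genes, seed = 4)
  expect_true(all(spb$log$captured))
  expect_true(all(spb$log$gene %in% c("G1", "G2", "G3")))

  expect_error(spike_study(cases[1:2], c("G1", "NOPE"), sc,
                           gene_universe = genes), "absent")
})

test_that("spiked zygosity patterns follow the mode with 10% error", {
  sc_ar <- simulation_scenario(2, u = 0, mode = "AR", n_cases = 1)
  set.seed(21)
  pats <- replicate(4000, hetrank:::draw_zygosity_pattern(sc_ar))
  p <- table(factor(pats, levels = c("hom", "compound_het", "het"))) / 4000
  expect_lt(abs(p[["hom"]] - 0.45), 3 * sqrt(0.45 * 0.55 / 4000))
  expect_lt(abs(p[["compound_het"]] - 0.45), 3 * sqrt(0.45 * 0.55 / 4000))
  expect_lt(abs(p[["het"]] - 0.10), 3 * sqrt(0.1 * 0.9 / 4000))

  sc_ad <- simulation_scenario(2, u = 0, mode = "AD", n_cases = 1)
  set.seed(22)
  pats_ad <- replicate(4000, hetrank:::draw_zygosity_pattern(sc_ad))
  expect_lt(abs(mean(pats_ad == "het") - 0.9), 3 * sqrt(0.9 * 0.1 / 4000))

  # compound het adds two distinct heterozygous variants to the same gene
  cases <- list(exome_profile("c1", data.frame(
    variant_id = "b1", gene = "G9", zygosity = "het", evs_af = 0.3,
    kg_af = 0.3, effect = "synonymous")))
  set.seed(30)
  repeat {
    sp <- spike_study(cases, c("G1", "G2"),
                      simulation_scenario(2, u = 0, mode = "AR", n_cases = 1),
                      gene_universe = paste0("G", 1:10))
    if (sp$log$pattern == "compound_het") break
  }
  v <- sp$cases[[1]]$variants
  spiked <- v[grepl("_spike", v$variant_id), ]
  expect_equal(nrow(spiked), 2)
  expect_equal(unique(spiked$gene), sp$log$gene)
  expect_true(all(spiked$zygosity == "heterozygous"))
})

test_that("scenario runs are deterministic and well shaped", {
  model <- small_model()
  net <- simulate_network(model, n_nodes = 120, seed = 2)
  catal <- sample_connected_subsets(net, 3, 10, seed = 3)
  sc <- simulation_scenario(3, u = 0.2, balanced = TRUE, mode = "AR",
                            n_cases = 6, n_controls = 8, n_replicates = 2,
                            seed = 77)
  m1 <- run_scenario(sc, model, net, catal)
  m2 <- run_scenario(sc, model, net, catal)
  expect_identical(m1, m2)
  # rows = replicates x methods x spiked genes
  expect_equal(nrow(m1), 2 * 3 * 3)
  expect_setequal(unique(m1$method),
                  c("hetrank", "hetrank_nonet", "intersection"))
  expect_true(all(m1$rank >= 1))

  # cases and controls never share a recombined exome within a replicate
  # (disjoint by construction: positions 1..n_cases vs the rest)
  study <- recombine_exomes(generate_exome_pool(model, 20, seed = 1), 14,
                            seed = 2)
  ids <- vapply(study, `[[`, "", "sample_id")
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("strong signal with u = 0 puts spiked genes at the top", {
  model <- small_model()
  net <- simulate_network(model, n_nodes = 120, seed = 4)
  catal <- sample_connected_subsets(net, 3, 10, seed = 5)
  sc <- simulation_scenario(3, u = 0, balanced = TRUE, mode = "AR",
                            n_cases = 10, n_controls = 10, n_replicates = 3,
                            seed = 99)
  m <- run_scenario(sc, model, net, catal)
  het <- m[m$method == "hetrank", ]
  expect_gte(mean(het$rank <= 10), 0.8)
})
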