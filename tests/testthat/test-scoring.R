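test_that("average-tie ranking resolves ties and missing policies", {
  crit <- af_criteria()[[1]]
  ex <- af_exome(c(0.0, 0.0, 0.5))
  expect_equal(unname(rank_by_criterion(ex, crit)), c(1.5, 1.5, 3))

  expect_equal(unname(rank_by_criterion(af_exome(0.1), crit)), 1)

  # ordered categories with ties, against the brute-force oracle
  eff <- criterion("effect", "ordered_categories",
                   category_order = c("truncating", "protein_altering",
                                      "synonymous"))
  ex2 <- toy_exome("s1", paste0("g", 1:4), af = rep(0, 4),
                   effect = c("truncating", "protein_altering", "synonymous",
                              "protein_altering"))
  keys <- match(ex2$variants$effect, eff$category_order)
  expect_equal(unname(rank_by_criterion(ex2, eff)),
               oracle_avg_rank(keys))
  expect_equal(unname(rank_by_criterion(ex2, eff)), c(1, 2.5, 4, 2.5))

  # worst: missing tied at the bottom; all-missing -> all tied at (n+1)/2
  ex3 <- af_exome(c(NA, NA, NA))
  expect_equal(unname(rank_by_criterion(ex3, crit)), rep(2, 3))
  ex4 <- af_exome(c(0.1, NA, NA))
  expect_equal(unname(rank_by_criterion(ex4, crit)), c(1, 2.5, 2.5))

  # skip: missing excluded entirely
  crit_skip <- af_criteria(missing_policy = "skip")[[1]]
  r <- rank_by_criterion(af_exome(c(0.1, NA, 0.2)), crit_skip)
  expect_named(r, c("s1_v1", "s1_v3"))
  expect_equal(unname(r), c(1, 2))

  # empty exome -> empty map
  expect_length(rank_by_criterion(exome_profile("e", NULL), crit), 0)
})

test_that("rank_to_score has the reciprocal, top-tier and filter anchors", {
  # top tier scores exactly 1 regardless of tie width
  expect_equal(rank_to_score(1.5, top_rank = 1.5), 1)
  expect_equal(rank_to_score(3, top_rank = 3, filter_rank = 10), 1)
  # pure reciprocal without a filter anchor
  expect_equal(rank_to_score(4, 1), 0.25)
  # filter-equivalent boundary scores exactly 0.5 on a grid
  for (top in c(1, 1.5, 2, 5)) {
    for (fr in c(10, 40, 100)) {
      if (fr < 2 * top) next
      expect_equal(rank_to_score(fr, top, fr), 0.5)
      expect_gte(rank_to_score(fr - 1, top, fr), 0.5)
      expect_lt(rank_to_score(fr + 1, top, fr), 0.5)
    }
  }
  expect_equal(rank_to_score(100, 1, 100), 0.5)
  # monotone non-increasing in rank
  s <- rank_to_score(seq(2, 50, by = 0.5), top_rank = 2, filter_rank = 12)
  expect_true(all(diff(s) <= 1e-12))
  expect_error(rank_to_score(1, top_rank = 2), "top_rank")
})

test_that("filter-equivalent phantom rank matches the insertion oracle", {
  crit <- af_criteria(filter_equivalent = 0.001)[[1]]
  ex <- af_exome(c(0.0001, 0.002, 0.05))
  expect_equal(compute_filter_rank(ex, crit), 2)

  # threshold better than every variant
  expect_equal(compute_filter_rank(af_exome(c(0.3, 0.5)), crit), 1)

  # threshold tied with an existing value shares an averaged tie
  ex_tied <- af_exome(c(0.001, 0.1))
  expect_equal(compute_filter_rank(ex_tied, crit), 1.5)

  # general insertion oracle: rank the augmented vector, read the phantom off
  set.seed(42)
  for (i in 1:25) {
    vals <- round(stats::runif(sample(3:12, 1), 0, 0.01), 3)
    thr <- round(stats::runif(1, 0, 0.01), 3)
    cr <- af_criteria(filter_equivalent = thr)[[1]]
    aug <- oracle_avg_rank(c(vals, thr))
    expect_equal(compute_filter_rank(af_exome(vals), cr),
                 aug[length(aug)])
  }
})

test_that("variant totals sum per-criterion scores and stay in [0, m]", {
  criteria <- toy_criteria()
  # m = 3: a variant best on all criteria totals exactly m
  criteria3 <- list(
    criterion("af", "numeric_lower_better"),
    criterion("af2", "numeric_lower_better"),
    criterion("effect", "ordered_categories",
              category_order = c("truncating_splicing", "protein_altering",
                                 "synonymous")))
  ex <- exome_profile("s1", data.frame(
    variant_id = c("v1", "v2"), gene = c("A", "B"), zygosity = "het",
    af = c(0, 0.1), af2 = c(0, 0.2),
    effect = c("truncating_splicing", "synonymous")))
  vs <- score_variants(ex, criteria3)
  expect_equal(vs$total[vs$variant_id == "v1"], 3)
  expect_equal(vs$total,
               vs$score.af + vs$score.af2 + vs$score.effect)
  expect_true(all(vs$total >= 0 & vs$total <= 3))

  # worked 4-variant 2-criterion toy against a hand computation:
  # af ranks (filter 0.001): keys [0,0,.2,.0005] -> ranks [1.5,1.5,4,3],
  #   phantom rank 4, scale max(1.5,2)=2 -> scores [1,1,.5,2/3]
  # effect ranks (filter protein_altering): keys [1,2,3,2] -> [1,2.5,4,2.5],
  #   phantom rank 3, scale max(1,1.5)=1.5 -> scores [1,.6,.375,.6]
  ex4 <- toy_exome("s1", c("A", "A", "B", "C"),
                   af = c(0, 0, 0.2, 0.0005),
                   effect = c("truncating_splicing", "protein_altering",
                              "synonymous", "protein_altering"),
                   zyg = c("het", "het", "hom", "het"))
  vs4 <- score_variants(ex4, criteria)
  expect_equal(vs4$score.af, c(1, 1, 0.5, 2 / 3))
  expect_equal(vs4$score.effect, c(1, 0.6, 0.375, 0.6))
  expect_equal(vs4$total, c(2, 1.6, 0.875, 0.6 + 2 / 3))
})

test_that("gene scores follow the inheritance-mode rules", {
  # gene with het totals {1.8, 1.2} and hom total 1.4
  vs <- data.frame(variant_id = c("v1", "v2", "v3"), gene = "A",
                   zygosity = c("heterozygous", "heterozygous", "homozygous"),
                   total = c(1.8, 1.2, 1.4), stringsAsFactors = FALSE)
  expect_equal(unname(gene_scores(vs, "AR")), 1.5)   # max(1.4, (1.8+1.2)/2)
  expect_equal(unname(gene_scores(vs, "AD")), 1.8)
  expect_equal(unname(gene_scores(vs, "neutral")), 1.8)

  # single hom variant: invisible to AD
  vs_hom <- data.frame(variant_id = "v1", gene = "A",
                       zygosity = "homozygous", total = 2.0)
  expect_length(gene_scores(vs_hom, "AD"), 0)
  expect_equal(unname(gene_scores(vs_hom, "AR")), 2.0)

  # single het under AR contributes half its own total
  vs_het <- data.frame(variant_id = "v1", gene = "A",
                       zygosity = "heterozygous", total = 1.0)
  expect_equal(unname(gene_scores(vs_het, "AR")), 0.5)

  # cross-check against brute-force enumeration over random exomes
  set.seed(7)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    vs_r <- data.frame(
      variant_id = paste0("v", 1:n),
      gene = paste0("g", sample.int(3, n, replace = TRUE)),
      zygosity = sample(c("heterozygous", "homozygous"), n, replace = TRUE),
      total = round(stats::runif(n, 0, 2), 3), stringsAsFactors = FALSE)
    for (g in unique(vs_r$gene)) {
      het <- vs_r$total[vs_r$gene == g & vs_r$zygosity == "heterozygous"]
      hom <- vs_r$total[vs_r$gene == g & vs_r$zygosity == "homozygous"]
      exp_ad <- if (length(het)) max(het) else 0
      exp_ar <- max(if (length(hom)) max(hom) else 0,
                    sum(sort(het, decreasing = TRUE)[1:2], na.rm = TRUE) / 2)
      exp_neu <- max(c(het, hom))
      got <- function(mode) {
        s <- gene_scores(vs_r, mode)
        if (g %in% names(s)) unname(s[g]) else 0
      }
      expect_equal(got("AD"), exp_ad)
      expect_equal(got("AR"), exp_ar)
      expect_equal(got("neutral"), exp_neu)
    }
  }
})

test_that("scores are invariant to variant order and bounded by m", {
  cfg <- study_config("AR", criteria = toy_criteria())
  set.seed(11)
  for (i in 1:10) {
    ex <- random_exome(sample(5:25, 1))
    perm <- sample(nrow(ex$variants))
    ex_p <- exome_profile(ex$sample_id, ex$variants[perm, ], role = "case")
    for (mode in c("AD", "AR", "neutral")) {
      cfg$mode <- mode
      a <- score_exome(ex, cfg)
      b <- score_exome(ex_p, cfg)
      expect_equal(a[order(names(a))], b[order(names(b))])
      expect_true(all(a >= 0 & a <= length(cfg$criteria)))
    }
  }
})

test_that("AD and AR gene scores never exceed the neutral score", {
  cfg <- study_config(criteria = toy_criteria())
  set.seed(13)
  for (i in 1:20) {
    ex <- random_exome(sample(5:30, 1))
    vs <- score_variants(ex, cfg$criteria)
    neu <- gene_scores(vs, "neutral")
    for (mode in c("AD", "AR")) {
      s <- gene_scores(vs, mode)
      if (length(s))
        expect_true(all(s <= neu[names(s)] + 1e-12))
    }
  }
})
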