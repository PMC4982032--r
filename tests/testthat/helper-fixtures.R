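# Shared fixtures: tiny criteria sets, exomes, and networks built in code.

toy_criteria <- function() {
  list(criterion("af", "numeric_lower_better", filter_equivalent = 0.001),
       criterion("effect", "ordered_categories",
                 category_order = c("truncating_splicing", "protein_altering",
                                    "synonymous"),
                 filter_equivalent = "protein_altering"))
}

toy_exome <- function(id = "s1", genes, af, effect,
                      zyg = rep("het", length(genes)), role = "case") {
  exome_profile(id, data.frame(
    variant_id = paste0(id, "_v", seq_along(genes)), gene = genes,
    zygosity = zyg, af = af, effect = effect, stringsAsFactors = FALSE),
    role = role)
}

# exome with a single numeric criterion "af"
af_criteria <- function(filter_equivalent = NULL, missing_policy = "worst") {
  list(criterion("af", "numeric_lower_better",
                 filter_equivalent = filter_equivalent,
                 missing_policy = missing_policy))
}

af_exome <- function(af, id = "s1", genes = paste0("g", seq_along(af)),
                     zyg = rep("het", length(af))) {
  exome_profile(id, data.frame(
    variant_id = paste0(id, "_v", seq_along(af)), gene = genes,
    zygosity = zyg, af = af, stringsAsFactors = FALSE))
}

# path graph A-B-C-D-...
path_network <- function(nodes) {
  make_network(nodes[-length(nodes)], nodes[-1])
}

# random exome generator for property tests
random_exome <- function(n_variants, n_genes = max(2, n_variants %/% 2),
                         id = "r1", p_missing = 0.1) {
  genes <- paste0("g", sample.int(n_genes, n_variants, replace = TRUE))
  af <- round(stats::runif(n_variants, 0, 0.01), 5)
  af[stats::runif(n_variants) < 0.3] <- 0
  af[stats::runif(n_variants) < p_missing] <- NA
  effect <- sample(c("truncating_splicing", "protein_altering", "synonymous"),
                   n_variants, replace = TRUE)
  zyg <- sample(c("het", "hom"), n_variants, replace = TRUE, prob = c(0.8, 0.2))
  toy_exome(id, genes, af, effect, zyg)
}

# brute-force average-tie ranking oracle (independent of rank())
oracle_avg_rank <- function(keys) {
  n <- length(keys)
  vapply(seq_len(n), function(i) {
    less <- sum(keys < keys[i])
    eq <- sum(keys == keys[i])
    mean(seq(less + 1, less + eq))
  }, numeric(1))
}

# exhaustive hypergeometric-tail oracle: enumerate all C(n,k) subsets
oracle_tail_enum <- function(n, t, k) {
  subsets <- utils::combn(n, k, simplify = FALSE)
  mean(vapply(subsets, function(s) any(s <= t), logical(1)))
}

# Monte-Carlo tail oracle
oracle_tail_mc <- function(n, t, k, draws = 1e5) {
  hits <- vapply(seq_len(draws),
                 function(i) any(sample.int(n, k) <= t), logical(1))
  mean(hits)
}
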