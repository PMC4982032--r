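#' Baseline gene ranking by intersection filtering
#'
#' The classical hard-filtering comparator. Per exome, variants failing any
#' criterion's filter-equivalent threshold are dropped (e.g. allele
#' frequency above 0.1%, effect worse than protein-altering; missing
#' annotations fail). Zygosity is then applied per mode: AD drops
#' homozygous variants; AR requires a gene to retain one homozygous or two
#' heterozygous variants; neutral applies no zygosity rule. Genes whose
#' post-filtering variants appear in at least `config$control_count_threshold`
#' control exomes are excluded everywhere. Remaining genes are ranked by
#' descending number of case gene lists containing them (average ties);
#' excluded and zero-count genes sit at `config$default_rank`.
#'
#' @param cases List of case [exome_profile()] objects.
#' @param controls List of control [exome_profile()] objects.
#' @param config A [study_config()]; uses `criteria` thresholds, `mode`,
#'   `control_count_threshold` and `default_rank`.
#' @return An object of class `"hetrank_baseline"`: list with `counts`
#'   (named, descending), `ranks`, `excluded` (control-filtered genes),
#'   `n_cases` and `config`.
#' @export
intersection_filter <- function(cases, controls = list(), config = study_config()) {
  case_lists <- lapply(cases, filtered_gene_list, config = config,
                       gene_rule = TRUE)
  ctrl_lists <- lapply(controls, filtered_gene_list, config = config,
                       gene_rule = FALSE)
  ctrl_counts <- table(unlist(ctrl_lists, use.names = FALSE))
  excluded <- names(ctrl_counts)[ctrl_counts >= config$control_count_threshold]
  case_lists <- lapply(case_lists, setdiff, y = excluded)
  counts <- table(unlist(case_lists, use.names = FALSE))
  counts <- sort(stats::setNames(as.integer(counts), names(counts)),
                 decreasing = TRUE)
  ranks <- if (length(counts)) rank(-counts, ties.method = "average") else
    stats::setNames(numeric(), character())
  names(ranks) <- names(counts)
  structure(list(counts = counts, ranks = ranks, excluded = excluded,
                 n_cases = length(cases), config = config),
            class = "hetrank_baseline")
}

# Genes of one exome that survive the hard variant filters (and, when
# gene_rule = TRUE, the AR one-hom-or-two-het gene requirement).
filtered_gene_list <- function(exome, config, gene_rule = TRUE) {
  v <- exome$variants
  if (!nrow(v)) return(character())
  pass <- rep(TRUE, nrow(v))
  for (cr in config$criteria) {
    fk <- criterion_filter_key(cr)
    if (is.null(fk)) next
    key <- criterion_key(v[[cr$name]], cr)
    pass <- pass & !is.na(key) & key <= fk
  }
  if (config$mode == "AD") pass <- pass & v$zygosity == "heterozygous"
  v <- v[pass, , drop = FALSE]
  if (!nrow(v)) return(character())
  if (config$mode == "AR" && gene_rule) {
    hom <- table(v$gene[v$zygosity == "homozygous"])
    het <- table(v$gene[v$zygosity == "heterozygous"])
    genes <- union(names(hom)[hom >= 1], names(het)[het >= 2])
  } else {
    genes <- unique(v$gene)
  }
  genes
}

#' @export
print.hetrank_baseline <- function(x, n = 10L, ...) {
  cat("Intersection-filtering ranking (", x$config$mode, " mode, ",
      x$n_cases, " cases; ", length(x$excluded),
      " genes control-excluded)\n", sep = "")
  print(utils::head(ranking(x), n), row.names = FALSE)
  invisible(x)
}

#' @export
ranking.hetrank_baseline <- function(fit, ...) {
  data.frame(gene = names(fit$counts), count = unname(fit$counts),
             rank = unname(fit$ranks), stringsAsFactors = FALSE)
}

#' Recovery metrics for a set of spiked disease genes
#'
#' Measures how well a ranking recovers known disease genes, in the style of
#' spike-in benchmark summaries: the achieved rank of each spiked gene
#' (ordered best to worst, so "gene 1" is the best-recovered), whether all
#' spiked genes land in the top s places (s = number of spiked genes), and
#' how many land in the top 10 and top 100. Genes absent from the ranking
#' are assigned the configured default rank.
#'
#' @param fit A `"hetrank"` or `"hetrank_baseline"` object.
#' @param spiked_genes Non-empty character vector of true disease genes.
#' @param default_rank Optional override for absent genes.
#' @return List with `gene_ranks` (named, sorted ascending), `all_in_top_s`,
#'   `top10`, `top100`.
#' @export
evaluate_ranking <- function(fit, spiked_genes, default_rank = NULL) {
  stopifnot(length(spiked_genes) >= 1)
  r <- gene_rank(fit, spiked_genes, default_rank = default_rank)
  r <- sort(r)
  s <- length(spiked_genes)
  list(gene_ranks = r,
       all_in_top_s = all(r <= s),
       top10 = sum(r <= 10),
       top100 = sum(r <= 100))
}
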