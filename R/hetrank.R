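#' Combine per-case gene scores into a final ranking
#'
#' Phase 4: network-adjusted gene scores are summed across the N case
#' exomes, so each gene's final score lies in [0, m * N]. Genes are ranked
#' by descending final score with average-tie ranks. Genes absent from every
#' table are implicitly 0 and omitted.
#'
#' @param case_tables List of named numeric vectors: network-adjusted gene
#'   scores, one per case exome.
#' @return List with `scores` (named numeric, descending), `ranks` (named
#'   numeric, average ties) and `n_cases`.
#' @export
combine_scores <- function(case_tables) {
  if (!length(case_tables)) stop("no case score tables to combine")
  genes <- unique(unlist(lapply(case_tables, names), use.names = FALSE))
  total <- stats::setNames(numeric(length(genes)), genes)
  for (tb in case_tables) {
    if (length(tb)) total[names(tb)] <- total[names(tb)] + unname(tb)
  }
  total <- sort(total, decreasing = TRUE)
  ranks <- rank(-total, ties.method = "average")
  list(scores = total, ranks = ranks, n_cases = length(case_tables))
}

#' Network-informed gene ranking for an exome-sequencing study
#'
#' Fits the full four-phase ranking: (1) per-exome reciprocal-rank variant
#' scoring collapsed to gene scores under the inheritance mode; (2) penalty
#' against control exomes, S'g = Sg/(1+K); (3) score sharing through the
#' interaction network d-neighborhoods (d <= `config$max_d`), gated by an
#' exact hypergeometric chance probability; (4) summation across case
#' exomes into final scores in [0, m*N] and an average-tie ranking. Setting
#' `config$max_d = 0` or passing `network = NULL` omits the network phase.
#'
#' @param cases List of case [exome_profile()] objects.
#' @param controls List of control [exome_profile()] objects (may be empty;
#'   phase 2 is then the identity).
#' @param network An `igraph` interaction network, or `NULL`.
#' @param config A [study_config()].
#' @param audit If `TRUE`, keep the per-case neighborhood-adjustment audit
#'   trail (see [network_adjust()]).
#' @return An object of class `"hetrank"`: a list with `scores` (final gene
#'   scores, descending), `ranks`, `n_cases`, `m` (number of criteria),
#'   `config`, `phase_tables` (per-case raw / control-adjusted /
#'   network-adjusted score vectors) and optionally `adjustments`.
#' @examples
#' crit <- list(criterion("af", "numeric_lower_better", filter_equivalent = 0.001))
#' cfg <- study_config("neutral", criteria = crit)
#' ex <- exome_profile("s1", data.frame(
#'   variant_id = c("v1", "v2"), gene = c("A", "B"),
#'   zygosity = c("het", "het"), af = c(0, 0.2)))
#' fit <- hetrank(list(ex), config = cfg)
#' ranking(fit)
#' @export
hetrank <- function(cases, controls = list(), network = NULL,
                    config = study_config(), audit = FALSE) {
  stopifnot(length(cases) >= 1)
  if (is.null(network)) {
    network <- igraph::make_empty_graph(0, directed = FALSE)
  }
  raw_cases <- lapply(cases, score_exome, config = config)
  raw_controls <- lapply(controls, score_exome, config = config)
  adjusted <- lapply(raw_cases, control_adjust, control_tables = raw_controls)
  nbr <- if (config$max_d > 0L && igraph::vcount(network) > 0L)
    neighborhood_index(network, config$max_d) else NULL
  final_tables <- lapply(adjusted, network_adjust, network = network,
                         config = config, nbr_index = nbr, audit = audit)
  fin <- combine_scores(final_tables)
  structure(list(
    scores = fin$scores, ranks = fin$ranks, n_cases = fin$n_cases,
    m = length(config$criteria), config = config,
    phase_tables = list(raw = raw_cases, control_adjusted = adjusted,
                        network_adjusted = lapply(final_tables, function(x) {
                          attr(x, "adjustments") <- NULL; x
                        })),
    adjustments = if (audit)
      lapply(final_tables, attr, which = "adjustments") else NULL,
    network_size = igraph::vcount(network)),
    class = "hetrank")
}

#' @export
print.hetrank <- function(x, n = 10L, ...) {
  cat("Network-informed gene ranking (", x$config$mode, " mode, ",
      x$n_cases, " cases, m = ", x$m, " criteria)\n", sep = "")
  cat("Final scores in [0, ", x$m * x$n_cases, "]; top genes:\n", sep = "")
  top <- utils::head(ranking(x), n)
  print(top, row.names = FALSE)
  invisible(x)
}

#' @export
summary.hetrank <- function(object, ...) {
  r <- ranking(object)
  structure(list(mode = object$config$mode, n_cases = object$n_cases,
                 m = object$m, n_genes = nrow(r),
                 network_size = object$network_size,
                 score_summary = summary(r$final_score),
                 top = utils::head(r, 10L)),
            class = "summary.hetrank")
}

#' @export
print.summary.hetrank <- function(x, ...) {
  cat("Gene ranking over", x$n_genes, "scored genes;", x$n_cases,
      "cases; mode", x$mode, "; network of", x$network_size, "genes\n")
  cat("Final score distribution:\n")
  print(x$score_summary)
  cat("Top 10 genes:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @export
coef.hetrank <- function(object, ...) object$scores

#' Extract the final ranking table
#'
#' @param fit A `"hetrank"` fit (or the baseline's `"hetrank_baseline"`).
#' @param ... Unused.
#' @return Data frame with columns `gene`, `final_score` (or `count` for the
#'   baseline) and `rank`, ordered best first.
#' @export
ranking <- function(fit, ...) UseMethod("ranking")

#' @export
ranking.hetrank <- function(fit, ...) {
  data.frame(gene = names(fit$scores), final_score = unname(fit$scores),
             rank = unname(fit$ranks), stringsAsFactors = FALSE)
}

#' @export
plot.hetrank <- function(x, n = 20L, ...) {
  r <- utils::head(ranking(x), n)
  op <- graphics::par(mar = c(5, 7, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(r$final_score), names.arg = rev(r$gene),
                    horiz = TRUE, las = 1, xlab = "final score",
                    main = paste0("Top ", nrow(r), " ranked genes"), ...)
  invisible(x)
}

#' Gene rank lookup with a default for absent genes
#'
#' @param fit A `"hetrank"` or `"hetrank_baseline"` object.
#' @param genes Character vector of gene symbols.
#' @param default_rank Rank for genes absent from the ranking; defaults to
#'   the fit's configured default (10000 unless changed).
#' @return Numeric vector of ranks, one per requested gene.
#' @export
gene_rank <- function(fit, genes, default_rank = NULL) {
  r <- if (inherits(fit, "hetrank")) fit$ranks else fit$ranks
  if (is.null(default_rank))
    default_rank <- if (!is.null(fit$config)) fit$config$default_rank else 10000
  out <- r[genes]
  out[is.na(out)] <- default_rank
  stats::setNames(as.numeric(out), genes)
}

#' Write a ranking table as TSV
#'
#' @param fit A `"hetrank"` or `"hetrank_baseline"` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(fit, path) {
  utils::write.table(ranking(fit), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
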