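#' Rank an exome's variants by one criterion
#'
#' All variants in the exome are ranked together on one annotation (1 = best
#' evidence for disease involvement), with tied values receiving the
#' arithmetic mean of the rank positions they span. Variants missing the
#' annotation are tied at the bottom under `missing_policy = "worst"`, or
#' excluded from this criterion under `"skip"`.
#'
#' @param exome An [exome_profile()].
#' @param cr A [criterion()].
#' @return Named numeric vector of average-tie ranks, named by `variant_id`;
#'   variants skipped for missingness are absent. Empty exome gives an empty
#'   vector.
#' @export
rank_by_criterion <- function(exome, cr) {
  v <- exome$variants
  if (!nrow(v)) return(stats::setNames(numeric(), character()))
  key <- criterion_key(v[[cr$name]], cr)
  if (cr$missing_policy == "worst") {
    key[is.na(key)] <- Inf
    idx <- seq_along(key)
  } else {
    idx <- which(!is.na(key))
    key <- key[idx]
  }
  stats::setNames(rank(key, ties.method = "average"), v$variant_id[idx])
}

#' Transform an average rank into a score
#'
#' The reciprocal-rank transform: without a filter-equivalent anchor,
#' `score = top_rank / rank`, so every member of the joint top tier scores
#' exactly 1 and scores decay with rank. With a filter-equivalent anchor at
#' phantom rank `filter_rank`, `score = min(1, max(top_rank, filter_rank/2) /
#' rank)`, which keeps the top tier at 1 and guarantees a score of at least
#' 0.5 for every rank at or better than `filter_rank`.
#'
#' @param rank Average-tie rank(s) (vectorized).
#' @param top_rank Average rank of the best tier (min of all ranks).
#' @param filter_rank Optional phantom rank of the filter-equivalent value
#'   (see [compute_filter_rank()]).
#' @return Score(s) in (0, 1].
#' @export
rank_to_score <- function(rank, top_rank, filter_rank = NULL) {
  if (any(rank < top_rank - 1e-9))
    stop("rank < top_rank: ranks must be bounded below by the top tier")
  scale <- if (is.null(filter_rank)) top_rank else {
    if (filter_rank < top_rank - 1e-9)
      stop("filter_rank must be >= top_rank")
    max(top_rank, filter_rank / 2)
  }
  pmin(1, scale / rank)
}

#' Phantom rank of a criterion's filter-equivalent value
#'
#' The average-tie rank a phantom variant carrying exactly the
#' filter-equivalent annotation would receive if inserted among the exome's
#' variants for this criterion. The phantom is then discarded: real ranks
#' are computed without it.
#'
#' @param exome An [exome_profile()].
#' @param cr A [criterion()] with a `filter_equivalent` value.
#' @return The phantom rank (numeric scalar).
#' @export
compute_filter_rank <- function(exome, cr) {
  fk <- criterion_filter_key(cr)
  if (is.null(fk)) stop("criterion '", cr$name, "' has no filter_equivalent")
  v <- exome$variants
  key <- if (nrow(v)) criterion_key(v[[cr$name]], cr) else numeric()
  if (cr$missing_policy == "worst") key[is.na(key)] <- Inf
  else key <- key[!is.na(key)]
  phantom_rank(key, fk)
}

# Average-tie rank of value fk inserted among keys (phantom discarded after).
phantom_rank <- function(keys, fk) {
  sum(keys < fk) + 1 + sum(keys == fk) / 2
}

#' Score all variants of an exome across the ranking criteria
#'
#' For each criterion, variants are ranked ([rank_by_criterion()]) and ranks
#' transformed into scores ([rank_to_score()]) anchored at the criterion's
#' filter-equivalent phantom rank when one is declared. A variant's total is
#' the sum of its per-criterion scores, so totals lie in [0, m] for m
#' criteria.
#'
#' @param exome An [exome_profile()].
#' @param criteria List of [criterion()] objects.
#' @return Data frame with columns `variant_id`, `gene`, `zygosity`, one
#'   score column per criterion (named `score.<criterion>`), and `total`.
#' @export
score_variants <- function(exome, criteria) {
  stopifnot(length(criteria) >= 1)
  v <- exome$variants
  out <- data.frame(variant_id = v$variant_id, gene = v$gene,
                    zygosity = v$zygosity, stringsAsFactors = FALSE)
  total <- numeric(nrow(v))
  for (cr in criteria) {
    ranks <- rank_by_criterion(exome, cr)
    s <- numeric(nrow(v))
    if (length(ranks)) {
      top <- min(ranks)
      fr <- if (is.null(cr$filter_equivalent)) NULL else
        compute_filter_rank(exome, cr)
      sc <- rank_to_score(ranks, top, fr)
      s[match(names(ranks), v$variant_id)] <- sc
    }
    out[[paste0("score.", cr$name)]] <- s
    total <- total + s
  }
  out$total <- total
  out
}

#' Per-gene evidence scores for one exome
#'
#' Collapses variant totals to gene scores under an inheritance mode. In AD
#' mode a gene's score is the maximum total of any heterozygous variant it
#' contains (homozygous variants are ignored). In AR mode it is the larger
#' of the best homozygous total and half the sum of the top two heterozygous
#' totals (a single heterozygous variant contributes half its own total,
#' covering compound heterozygosity). In neutral mode it is the maximum
#' total regardless of zygosity. Genes with no qualifying variant score 0
#' and are omitted (no evidence).
#'
#' @param variant_scores Output of [score_variants()].
#' @param mode `"AD"`, `"AR"` or `"neutral"`.
#' @return Named numeric vector of raw gene scores (phase "raw"), names are
#'   gene symbols; only genes with positive score appear.
#' @export
gene_scores <- function(variant_scores, mode = c("AD", "AR", "neutral")) {
  mode <- match.arg(mode)
  vs <- variant_scores
  if (!nrow(vs)) return(stats::setNames(numeric(), character()))
  het <- vs$zygosity == "heterozygous"
  scores <- switch(mode,
    AD = group_max(vs$gene[het], vs$total[het]),
    neutral = group_max(vs$gene, vs$total),
    AR = {
      hom_max <- group_max(vs$gene[!het], vs$total[!het])
      het2 <- group_top2_halfsum(vs$gene[het], vs$total[het])
      genes <- union(names(hom_max), names(het2))
      stats::setNames(pmax(ifelse(is.na(hom_max[genes]), 0, hom_max[genes]),
                           ifelse(is.na(het2[genes]), 0, het2[genes])),
                      genes)
    })
  scores[scores > 0]
}

group_max <- function(g, x) {
  if (!length(g)) return(stats::setNames(numeric(), character()))
  m <- tapply(x, g, max)
  stats::setNames(as.numeric(m), names(m))
}

# Half the sum of the two largest values per group (missing second = 0).
group_top2_halfsum <- function(g, x) {
  if (!length(g)) return(stats::setNames(numeric(), character()))
  o <- order(g, -x)
  g <- g[o]; x <- x[o]
  first <- !duplicated(g)
  pos <- seq_along(g) - rep(which(first), diff(c(which(first), length(g) + 1L)))
  top2 <- tapply(x[pos < 2], g[pos < 2], sum) / 2
  stats::setNames(as.numeric(top2), names(top2))
}

#' Raw gene-score table for one exome
#'
#' Convenience wrapper chaining [score_variants()] and [gene_scores()].
#'
#' @param exome An [exome_profile()].
#' @param config A [study_config()].
#' @return Named numeric vector of raw gene scores.
#' @export
score_exome <- function(exome, config) {
  gene_scores(score_variants(exome, config$criteria), config$mode)
}
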