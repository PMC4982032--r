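# Scores are compared after rounding to 12 decimal places so that tie
# counting (K in phase 2, t in phase 3) is platform-stable.
.score_round <- function(x) round(x, 12)

#' Penalize genes that score as well in control exomes
#'
#' For each gene g with raw case score Sg, let K be the number of control
#' exomes in which g's raw score is at least Sg (ties count). The adjusted
#' score is S'g = Sg / (1 + K), so a gene matched or surpassed in no control
#' keeps its score, while long and variant-tolerating genes that score well
#' in many controls are penalized. With zero controls this is the identity.
#'
#' @param raw Named numeric vector of raw gene scores for one case exome.
#' @param control_tables List of named numeric vectors: raw gene scores of
#'   the control exomes, computed with the same criteria and mode.
#' @return Named numeric vector of control-adjusted scores (same names).
#' @export
control_adjust <- function(raw, control_tables = list()) {
  if (!length(raw) || !length(control_tables)) return(raw)
  genes <- names(raw)
  # genes x controls matrix of control raw scores (absent gene = 0)
  ctrl <- vapply(control_tables, function(tb) {
    x <- tb[genes]
    x[is.na(x)] <- 0
    unname(x)
  }, numeric(length(genes)))
  ctrl <- matrix(ctrl, nrow = length(genes))
  K <- rowSums(.score_round(ctrl) >= .score_round(raw))
  stats::setNames(raw / (1 + K), genes)
}

#' Probability that a random gene set contains an equally good score
#'
#' Given the distribution of scores over all n network genes, the exact
#' probability that a uniformly random set of k network genes contains at
#' least one gene with score >= `threshold_score`. With t genes at or above
#' the threshold this is the hypergeometric tail
#' p = 1 - C(n - t, k) / C(n, k), evaluated in log space.
#'
#' @param score_pool Numeric vector of scores for all network genes (genes
#'   without variants contribute 0).
#' @param k Neighborhood size (1 <= k <= length(score_pool)).
#' @param threshold_score The score to be matched or beaten.
#' @return Probability in [0, 1].
#' @export
chance_probability <- function(score_pool, k, threshold_score) {
  n <- length(score_pool)
  if (k > n) stop("neighborhood size k exceeds number of network genes")
  t <- sum(.score_round(score_pool) >= .score_round(threshold_score))
  chance_probability_nt(n, t, k)
}

# Tail probability from the counts alone; vectorized over t and k.
chance_probability_nt <- function(n, t, k) {
  p <- 1 - exp(lchoose(n - t, k) - lchoose(n, k))
  p[t == 0] <- 0
  p[k > n - t] <- 1 # fewer threshold-free genes than the set size
  pmin(pmax(p, 0), 1)
}

#' Share scores through the interaction network
#'
#' Phase 3 of the ranking pipeline. For every gene g in the network and each
#' distance d = 1..max_d, the best control-adjusted score S'h in the
#' d-neighborhood Nd(g) (which includes g) is found. If the chance
#' probability that |Nd(g)| randomly chosen network genes include a score
#' >= S'h is below the configured gate (default 0.1), the neighborhood
#' proposes the distance-penalized score Sg(d) = S'h / (1 + d); otherwise it
#' proposes nothing (Sg(d) = 0). The network-adjusted score is
#' S''g = max(S'g, Sg(1), Sg(2)). Genes absent from the network keep S'g, so
#' genes outside the network remain rankable.
#'
#' @param control_adjusted Named numeric vector of control-adjusted gene
#'   scores for one case exome.
#' @param network An `igraph` interaction network (vertex names = genes).
#' @param config A [study_config()]; uses `max_d` and
#'   `neighborhood_p_threshold`. `max_d = 0` disables the adjustment.
#' @param nbr_index Optional precomputed [neighborhood_index()] for
#'   `network` (saves recomputation across exomes).
#' @param audit If `TRUE`, attach an `"adjustments"` attribute: a data frame
#'   with one row per (gene, d) whose gate opened, recording the best
#'   neighbor, its score, the neighborhood size, the chance probability and
#'   the proposed score.
#' @return Named numeric vector of network-adjusted scores covering all
#'   genes that end with a positive score.
#' @export
network_adjust <- function(control_adjusted, network, config,
                           nbr_index = NULL, audit = FALSE) {
  sprime <- control_adjusted
  n <- igraph::vcount(network)
  if (config$max_d == 0L || n == 0L) {
    if (audit) attr(sprime, "adjustments") <- empty_adjustments()
    return(sprime)
  }
  vnames <- igraph::V(network)$name
  # score pool over all network genes; non-mutated genes contribute 0
  pool <- stats::setNames(numeric(n), vnames)
  hit <- intersect(names(sprime), vnames)
  pool[hit] <- sprime[hit]
  pool_r <- .score_round(pool)
  pool_sorted <- sort(pool_r, decreasing = TRUE)
  if (is.null(nbr_index)) nbr_index <- neighborhood_index(network, config$max_d)
  best_final <- pool # start from S'g for network genes
  adjustments <- if (audit) list() else NULL
  for (d in seq_len(config$max_d)) {
    nbrs <- nbr_index[[d]]
    k <- lengths(nbrs)
    best <- vapply(nbrs, function(ix) max(pool[ix]), numeric(1))
    best_holder <- if (audit)
      vapply(nbrs, function(ix) {
        b <- max(pool[ix])
        min(vnames[ix][pool[ix] == b])
      }, character(1)) else NULL
    # t = number of pool genes at or above each neighborhood's best score
    t <- vapply(.score_round(best), function(b) sum(pool_sorted >= b),
                numeric(1))
    p <- chance_probability_nt(n, t, k)
    open <- p < config$neighborhood_p_threshold & best > 0
    proposed <- ifelse(open, best / (1 + d), 0)
    best_final <- pmax(best_final, proposed)
    if (audit && any(open))
      adjustments[[d]] <- data.frame(
        gene = vnames[open], d = d, best_neighbor = best_holder[open],
        best_score = best[open], neighborhood_size = k[open],
        chance_p = p[open], proposed = proposed[open],
        stringsAsFactors = FALSE)
  }
  out <- sprime
  upd <- best_final[best_final > 0]
  extra <- setdiff(names(upd), names(out))
  out[names(upd)[names(upd) %in% names(out)]] <-
    pmax(out[names(upd)[names(upd) %in% names(out)]],
         upd[names(upd) %in% names(out)])
  out <- c(out, upd[extra])
  if (audit)
    attr(out, "adjustments") <- if (length(adjustments))
      do.call(rbind, adjustments) else empty_adjustments()
  out
}

empty_adjustments <- function() {
  data.frame(gene = character(), d = integer(), best_neighbor = character(),
             best_score = numeric(), neighborhood_size = integer(),
             chance_p = numeric(), proposed = numeric(),
             stringsAsFactors = FALSE)
}
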