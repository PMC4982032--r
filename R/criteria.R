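#' Declare a variant-ranking criterion
#'
#' A criterion is one variant annotation used for ranking: a numeric value
#' where lower (e.g. alternative allele frequency) or higher (e.g. a
#' deleteriousness score) is better, or an ordered categorical annotation
#' (e.g. variant effect class) with the best category first.
#'
#' @param name Column name of the annotation in the variant table.
#' @param kind One of `"numeric_lower_better"`, `"numeric_higher_better"`,
#'   `"ordered_categories"`.
#' @param category_order Character vector of category labels, best first.
#'   Required iff `kind = "ordered_categories"`.
#' @param filter_equivalent Optional value on the criterion's scale: the
#'   threshold an intersection filter would use. When supplied, the
#'   rank-to-score transform anchors variants ranking at or better than this
#'   value to scores >= 0.5, and the baseline ranker uses it as a hard filter.
#' @param missing_policy How to treat variants missing this annotation:
#'   `"worst"` (tied at the bottom of the ranking; the default, so that
#'   absence of evidence never looks like strong evidence) or `"skip"`
#'   (excluded from this criterion, contributing a score of 0).
#' @return An object of class `"hetrank_criterion"`.
#' @examples
#' criterion("evs_af", "numeric_lower_better", filter_equivalent = 0.001)
#' criterion("effect", "ordered_categories",
#'   category_order = c("truncating_splicing", "protein_altering", "synonymous"),
#'   filter_equivalent = "protein_altering")
#' @export
criterion <- function(name, kind = c("numeric_lower_better",
                                     "numeric_higher_better",
                                     "ordered_categories"),
                      category_order = NULL, filter_equivalent = NULL,
                      missing_policy = c("worst", "skip")) {
  kind <- match.arg(kind)
  missing_policy <- match.arg(missing_policy)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("criterion 'name' must be a non-empty string")
  if (kind == "ordered_categories") {
    if (is.null(category_order) || !length(category_order))
      stop("criterion '", name, "': category_order is required for ordered_categories")
    category_order <- as.character(category_order)
    if (anyDuplicated(category_order))
      stop("criterion '", name, "': duplicate labels in category_order")
    if (!is.null(filter_equivalent) &&
        !as.character(filter_equivalent) %in% category_order)
      stop("criterion '", name, "': filter_equivalent '", filter_equivalent,
           "' is not a declared category")
  } else {
    category_order <- NULL
    if (!is.null(filter_equivalent)) {
      filter_equivalent <- as.numeric(filter_equivalent)
      if (is.na(filter_equivalent))
        stop("criterion '", name, "': filter_equivalent must be numeric")
    }
  }
  structure(list(name = name, kind = kind, category_order = category_order,
                 filter_equivalent = filter_equivalent,
                 missing_policy = missing_policy),
            class = "hetrank_criterion")
}

#' @export
print.hetrank_criterion <- function(x, ...) {
  cat("<criterion>", x$name, "(", x$kind, ")\n")
  if (!is.null(x$category_order))
    cat("  order:", paste(x$category_order, collapse = " > "), "\n")
  if (!is.null(x$filter_equivalent))
    cat("  filter-equivalent:", as.character(x$filter_equivalent), "\n")
  cat("  missing:", x$missing_policy, "\n")
  invisible(x)
}

#' Default ranking criteria
#'
#' Two alternative-allele-frequency criteria (lower is better, novel variants
#' at frequency zero) and an ordered variant-effect criterion
#' (truncating/splicing > protein-altering > synonymous), each with the
#' filter-equivalent thresholds a hard intersection filter would use
#' (frequency 0.1%, protein-altering effect).
#'
#' @return List of [criterion()] objects.
#' @export
default_criteria <- function() {
  list(
    criterion("evs_af", "numeric_lower_better", filter_equivalent = 0.001),
    criterion("kg_af",  "numeric_lower_better", filter_equivalent = 0.001),
    criterion("effect", "ordered_categories",
              category_order = c("truncating_splicing", "protein_altering",
                                 "synonymous"),
              filter_equivalent = "protein_altering")
  )
}

criteria_names <- function(criteria) {
  vapply(criteria, function(cr) cr$name, character(1))
}

# Map a criterion's annotation column to a numeric key where smaller = better
# evidence; NA marks a missing annotation. Unknown category labels error.
criterion_key <- function(values, cr) {
  if (cr$kind == "ordered_categories") {
    values <- as.character(values)
    values[!is.na(values) & !nzchar(values)] <- NA_character_
    key <- match(values, cr$category_order)
    bad <- !is.na(values) & is.na(key)
    if (any(bad))
      stop("criterion '", cr$name, "': unknown category label(s) ",
           paste(unique(values[bad]), collapse = ", "),
           " at row(s) ", paste(utils::head(which(bad), 5), collapse = ", "))
    as.numeric(key)
  } else {
    key <- suppressWarnings(as.numeric(values))
    if (cr$kind == "numeric_higher_better") key <- -key
    key
  }
}

# Filter-equivalent value on the key scale.
criterion_filter_key <- function(cr) {
  if (is.null(cr$filter_equivalent)) return(NULL)
  if (cr$kind == "ordered_categories")
    match(as.character(cr$filter_equivalent), cr$category_order)
  else if (cr$kind == "numeric_higher_better") -cr$filter_equivalent
  else cr$filter_equivalent
}

#' Study configuration
#'
#' Bundles the inheritance mode, ranking criteria and the tuning constants of
#' the ranking pipeline.
#'
#' @param mode Inheritance mode: `"AD"` (autosomal dominant: one heterozygous
#'   variant suffices), `"AR"` (autosomal recessive: a homozygous variant or a
#'   compound heterozygote), or `"neutral"` (zygosity ignored).
#' @param criteria List of [criterion()] objects (length m >= 1).
#' @param neighborhood_p_threshold Chance-probability gate for the network
#'   adjustment; a neighbor's score is shared only when the probability of a
#'   random gene set of the neighborhood's size containing an equally good
#'   score is below this (default 0.1).
#' @param max_d Maximum network distance over which scores are shared
#'   (0, 1 or 2; default 2; 0 disables the network step).
#' @param default_rank Rank assigned to genes absent from a ranking
#'   (default 10000).
#' @param control_count_threshold Baseline gene filter: genes with
#'   post-filtering variants in at least this many control exomes are excluded
#'   (default 5).
#' @param seed Integer seed recorded for stochastic subcommands.
#' @return An object of class `"hetrank_config"`.
#' @export
study_config <- function(mode = c("AD", "AR", "neutral"),
                         criteria = default_criteria(),
                         neighborhood_p_threshold = 0.1,
                         max_d = 2L,
                         default_rank = 10000L,
                         control_count_threshold = 5L,
                         seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(criteria) >= 1,
            all(vapply(criteria, inherits, logical(1), "hetrank_criterion")),
            neighborhood_p_threshold > 0, neighborhood_p_threshold <= 1,
            max_d %in% 0:2, default_rank >= 1, control_count_threshold >= 1)
  structure(list(mode = mode, criteria = criteria,
                 neighborhood_p_threshold = neighborhood_p_threshold,
                 max_d = as.integer(max_d),
                 default_rank = as.integer(default_rank),
                 control_count_threshold = as.integer(control_count_threshold),
                 seed = as.integer(seed)),
            class = "hetrank_config")
}

#' @export
print.hetrank_config <- function(x, ...) {
  cat("<hetrank config> mode:", x$mode, " m =", length(x$criteria),
      "criteria\n  p-gate <", x$neighborhood_p_threshold,
      " max_d =", x$max_d, " default rank =", x$default_rank, "\n")
  invisible(x)
}

#' Read a study configuration from a YAML file
#'
#' The file may declare `mode`, `neighborhood_p_threshold`, `max_d`,
#' `default_rank`, `control_count_threshold`, `seed` and a `criteria` list,
#' each entry with `name`, `kind`, and optional `category_order`,
#' `filter_equivalent`, `missing_policy`.
#'
#' @param path Path to a YAML configuration file.
#' @return A [study_config()] object.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  criteria <- if (is.null(y$criteria)) default_criteria() else
    lapply(y$criteria, function(e)
      criterion(e$name, e$kind,
                category_order = e$category_order,
                filter_equivalent = e$filter_equivalent,
                missing_policy = if (is.null(e$missing_policy)) "worst"
                                 else e$missing_policy))
  args <- y[intersect(names(y), c("mode", "neighborhood_p_threshold", "max_d",
                                  "default_rank", "control_count_threshold",
                                  "seed"))]
  do.call(study_config, c(args, list(criteria = criteria)))
}
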