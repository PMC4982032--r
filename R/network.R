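#' Read an interaction network from an edge list
#'
#' Parses a two-column tab-separated edge list of gene symbols into an
#' undirected simple igraph graph. Lines starting with `#` are ignored.
#' Self-loops are dropped with a warning; duplicate edges (either
#' orientation) are collapsed. Endpoints of dropped self-loops are retained
#' as isolated nodes.
#'
#' @param path Path to the edge-list file (TSV/SIF two-column).
#' @return An undirected simple `igraph` graph whose vertex names are gene
#'   symbols.
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines))
    return(igraph::make_empty_graph(0, directed = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("'", path, "': line ", bad[1], " does not have exactly 2 columns")
  a <- trimws(vapply(parts, `[`, character(1), 1L))
  b <- trimws(vapply(parts, `[`, character(1), 2L))
  make_network(a, b)
}

#' Build an interaction network from endpoint vectors
#'
#' @param from,to Character vectors of gene symbols (equal length).
#' @return An undirected simple `igraph` graph.
#' @export
make_network <- function(from, to) {
  stopifnot(length(from) == length(to))
  loops <- from == to
  if (any(loops))
    warning(sum(loops), " self-loop(s) dropped from network")
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a network as a two-column edge list
#'
#' @param network An `igraph` graph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  el <- igraph::as_edgelist(network, names = TRUE)
  iso <- setdiff(igraph::V(network)$name,
                 if (nrow(el)) unique(c(el[, 1], el[, 2])) else character())
  con <- file(path, "w")
  on.exit(close(con))
  if (length(iso))
    writeLines(paste0("# isolated: ", paste(iso, collapse = ",")), con)
  if (nrow(el))
    writeLines(paste(el[, 1], el[, 2], sep = "\t"), con)
  invisible(path)
}

#' Network d-neighborhood of a gene
#'
#' The set of genes reachable from `gene` via at most `d` interactions,
#' always including `gene` itself. A gene absent from the network has the
#' singleton neighborhood containing only itself.
#'
#' @param network An `igraph` graph with vertex names.
#' @param gene Gene symbol.
#' @param d Radius (non-negative integer; the pipeline uses 1 and 2).
#' @return Character vector of gene symbols.
#' @export
neighborhood <- function(network, gene, d) {
  stopifnot(d >= 0)
  if (!gene %in% igraph::V(network)$name) return(gene)
  nb <- igraph::ego(network, order = d, nodes = gene)[[1]]
  sort(igraph::V(network)$name[as.integer(nb)])
}

# Precompute neighborhood index lists for every vertex at d = 1..max_d.
# Returns list of lists: nbr[[d]][[v]] = integer vertex indices of N_d(v).
neighborhood_index <- function(network, max_d) {
  n <- igraph::vcount(network)
  out <- vector("list", max_d)
  if (n == 0) return(out)
  for (d in seq_len(max_d)) {
    eg <- igraph::ego(network, order = d, nodes = igraph::V(network))
    out[[d]] <- lapply(eg, as.integer)
  }
  out
}
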