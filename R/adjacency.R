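#' Read a spatial adjacency structure
#'
#' Reads first-order ("queen") contiguity neighbours either from a GeoDa GAL
#' spatial-weights file or from a two-column edge-list CSV, and returns a
#' validated symmetric adjacency object for the CAR priors and Moran's I.
#' Edges present in only one direction are symmetrised. Isolated regions
#' (e.g. island provinces with no queen neighbour) are refused: supply the
#' bridging edge explicitly in the input file so runs stay reproducible.
#'
#' @param path Path to a `.gal` file (1-based GeoDa dialect, header line
#'   carrying the node count) or a CSV with columns `from,to` (header
#'   optional). Node labels in a GAL file may be region names or 1-based
#'   integer indices into `regions`.
#' @param regions Ordered character vector of region identifiers the graph
#'   must cover exactly (usually `unique(panel$region)`).
#' @return A `bstm_graph`: list with `nodes` (the region order), `neighbours`
#'   (named list of character vectors) and `m` (named integer neighbour
#'   counts).
#' @export
read_adjacency <- function(path, regions) {
  if (!file.exists(path)) stop("adjacency file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  edges <- if (ext == "gal") parse_gal(path, regions) else parse_edge_csv(path)
  adjacency_from_edges(edges, regions)
}

# GAL dialect: optional comment lines, a header line whose last plausible
# token is the node count, then per node a "id k" line followed by a line of
# k neighbour ids. Ids may be 1-based indices or literal region names.
parse_gal <- function(path, regions) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "!") & !startsWith(lines, "#")]
  if (length(lines) < 1) stop("empty GAL file: ", path, call. = FALSE)
  header <- strsplit(lines[1], "\\s+")[[1]]
  n <- if (length(header) == 1) as.integer(header[1]) else as.integer(header[2])
  if (is.na(n) || n < 1) stop("unparseable GAL header: ", lines[1], call. = FALSE)
  resolve <- function(tok) {
    if (tok %in% regions) return(tok)
    i <- suppressWarnings(as.integer(tok))
    if (!is.na(i) && i >= 1 && i <= length(regions)) return(regions[i])
    stop("unknown region id in GAL file: ", tok, call. = FALSE)
  }
  from <- character(0); to <- character(0)
  pos <- 2L
  for (k in seq_len(n)) {
    if (pos > length(lines)) stop("truncated GAL file: ", path, call. = FALSE)
    head_k <- strsplit(lines[pos], "\\s+")[[1]]
    node <- resolve(head_k[1])
    deg <- as.integer(head_k[length(head_k)])
    if (is.na(deg)) stop("unparseable GAL node line: ", lines[pos], call. = FALSE)
    if (deg == 0) {
      stop("isolated node '", node, "' in GAL file; add a manual bridging ",
           "link (e.g. an island's nearest mainland neighbour)", call. = FALSE)
    }
    nb <- strsplit(lines[pos + 1L], "\\s+")[[1]]
    if (length(nb) != deg) {
      stop(sprintf("GAL node '%s' declares %d neighbours but lists %d",
                   node, deg, length(nb)), call. = FALSE)
    }
    from <- c(from, rep(node, deg))
    to <- c(to, vapply(nb, resolve, character(1), USE.NAMES = FALSE))
    pos <- pos + 2L
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

parse_edge_csv <- function(path) {
  df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 2) stop("edge-list CSV needs two columns (from,to)", call. = FALSE)
  df <- df[, 1:2]
  names(df) <- c("from", "to")
  # tolerate a header row
  if (identical(tolower(df$from[1]), "from")) df <- df[-1, , drop = FALSE]
  df
}

#' Build an adjacency object from an edge list
#'
#' @param edges A data frame with columns `from` and `to` (region
#'   identifiers); direction is ignored and the edge set symmetrised.
#' @param regions Ordered character vector of region identifiers.
#' @return A `bstm_graph` (see [read_adjacency()]).
#' @export
adjacency_from_edges <- function(edges, regions) {
  regions <- as.character(regions)
  if (anyDuplicated(regions)) stop("duplicate region identifiers", call. = FALSE)
  from <- as.character(edges$from); to <- as.character(edges$to)
  unknown <- setdiff(unique(c(from, to)), regions)
  if (length(unknown) > 0) {
    stop("edge list references unknown region(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(from == to)) stop("self-loops are not allowed", call. = FALSE)
  nb <- stats::setNames(vector("list", length(regions)), regions)
  for (r in regions) {
    nb[[r]] <- sort(unique(c(to[from == r], from[to == r])))
  }
  isolated <- regions[lengths(nb) == 0]
  if (length(isolated) > 0) {
    stop("isolated region(s) with no neighbour: ",
         paste(isolated, collapse = ", "),
         "; add a manual bridging edge to the adjacency input", call. = FALSE)
  }
  structure(list(nodes = regions, neighbours = nb,
                 m = stats::setNames(lengths(nb), regions)),
            class = "bstm_graph")
}

#' @export
print.bstm_graph <- function(x, ...) {
  cat(sprintf("<bstm_graph> %d nodes, %d edges, degrees %d-%d\n",
              length(x$nodes), sum(x$m) / 2, min(x$m), max(x$m)))
  invisible(x)
}

# Internal: binary adjacency matrix in node order.
adjacency_matrix <- function(graph) {
  n <- length(graph$nodes)
  W <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  for (i in seq_len(n)) W[i, graph$neighbours[[graph$nodes[i]]]] <- 1
  W
}

# Internal: sanity-check symmetry / self-loops (used by tests and simulate).
validate_graph <- function(graph) {
  W <- adjacency_matrix(graph)
  stopifnot(isSymmetric(W), all(diag(W) == 0), all(rowSums(W) >= 1))
  invisible(graph)
}

#' Write a posterior summary table to CSV
#'
#' @param summary_tbl A non-empty data frame of per-parameter summaries, as
#'   produced by [tidy.bstm_fit()] (columns such as `term`, `estimate`,
#'   `conf.low`, `conf.high`, `rhat`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary_tbl, path) {
  if (!is.data.frame(summary_tbl) || nrow(summary_tbl) == 0) {
    stop("summary table must be a non-empty data frame", call. = FALSE)
  }
  readr::write_csv(as.data.frame(summary_tbl), path, progress = FALSE)
  invisible(path)
}

#' Read a posterior summary table written by [write_summary()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_summary <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
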