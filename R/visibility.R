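#' Build the natural visibility graph of a time series
#'
#' Maps a univariate series to an undirected graph with one node per frame.
#' Two frames `i < j` are connected when the straight line between
#' `(i, x[i])` and `(j, x[j])` clears every intermediate sample: for all
#' `i < k < j`,
#' \deqn{x_k < x_j + (x_i - x_j)\,\frac{j - k}{j - i}.}
#' The inequality is strict, so a sample lying exactly on the sight line
#' blocks visibility (a linear ramp maps to a path graph). Time is the
#' 0-based frame index; the edge set is invariant under positive affine
#' transforms of the amplitudes.
#'
#' Every adjacent pair `(i, i+1)` is always visible, so the graph is
#' connected and contains the Hamiltonian path of consecutive frames.
#'
#' @param x numeric series (length >= 2, finite).
#' @param weighted if `TRUE`, each edge carries the reciprocal Euclidean
#'   distance weight \eqn{w_{ij} = 1/\sqrt{(j-i)^2 + (x_j-x_i)^2}} between
#'   its endpoints in the (frame, amplitude) plane. With frame-indexed time
#'   all weights are <= 1.
#' @return an [igraph::igraph] object with vertex attribute `frame`
#'   (0-based) and, when `weighted`, edge attribute `weight`.
#' @seealso [vg_oracle()] for the brute-force reference implementation,
#'   [degree_sequence()], [vg_features()].
#' @examples
#' g <- visibility_graph(c(2, 3, 1, 4))
#' igraph::ecount(g)           # 4 edges
#' degree_sequence(g)          # 1 3 2 2
#' @export
visibility_graph <- function(x, weighted = FALSE) {
  x <- check_series(x)
  e <- vg_edges_cpp(x, weighted)
  g <- igraph::make_graph(rbind(e$i + 1L, e$j + 1L), n = length(x),
                          directed = FALSE)
  igraph::V(g)$frame <- seq_along(x) - 1L
  if (weighted) igraph::E(g)$weight <- e$w
  g
}

#' Brute-force visibility-graph oracle
#'
#' Literal O(T^3) evaluation of the visibility criterion over every pair and
#' every intermediate point. Exists as an independent reference for the fast
#' sweep in [visibility_graph()]; the two must agree exactly on any input.
#'
#' @inheritParams visibility_graph
#' @return an igraph object, as [visibility_graph()].
#' @export
vg_oracle <- function(x, weighted = FALSE) {
  x <- check_series(x)
  n <- length(x)
  t <- seq_len(n) - 1
  ei <- integer(0); ej <- integer(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ks <- if (j - i > 1) (i + 1):(j - 1) else integer(0)
      visible <- all(x[ks] < x[j] + (x[i] - x[j]) * (t[j] - t[ks]) / (t[j] - t[i]))
      if (visible) {
        ei <- c(ei, i); ej <- c(ej, j)
      }
    }
  }
  g <- igraph::make_graph(rbind(ei, ej), n = n, directed = FALSE)
  igraph::V(g)$frame <- t
  if (weighted) {
    igraph::E(g)$weight <- 1 / sqrt((ej - ei)^2 + (x[ej] - x[ei])^2)
  }
  g
}

#' Visibility degree sequence
#'
#' Per-frame connectivity of a visibility graph, ordered by frame index.
#' The degree sequence is itself a time series — each node is a time point —
#' and is the raw material of degree-synchrony connectivity.
#'
#' @param g a visibility graph from [visibility_graph()] (any igraph works).
#' @param weighted if `TRUE`, return the incident-weight sum (strength)
#'   instead of the edge count; requires edge weights.
#' @return numeric vector of length `vcount(g)`.
#' @export
degree_sequence <- function(g, weighted = FALSE) {
  if (weighted) {
    if (is.null(igraph::E(g)$weight)) {
      abort("graph has no weights; build with weighted = TRUE",
            class = "vgfc_error_validation")
    }
    as.numeric(igraph::strength(g))
  } else {
    as.numeric(igraph::degree(g))
  }
}

#' Edge table of a visibility graph
#'
#' @param g an igraph object.
#' @return a tibble with 0-based frame columns `i`, `j` (i < j) and `weight`
#'   (1 for unweighted graphs).
#' @export
vg_edge_table <- function(g) {
  e <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight %||% rep(1, nrow(e))
  tibble(i = pmin(e[, 1], e[, 2]) - 1L,
         j = pmax(e[, 1], e[, 2]) - 1L,
         weight = w) |>
    arrange(.data$i, .data$j)
}

#' Export a visibility graph
#'
#' Writes either a tab-separated edge list (columns `i`, `j`, `weight`,
#' 0-based frames) or GraphML for interoperability with external tooling.
#'
#' @param g an igraph object.
#' @param path output file.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_vg <- function(g, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    readr::write_tsv(vg_edge_table(g), path)
  } else {
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
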