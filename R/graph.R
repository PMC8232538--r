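#' @name region_graph
#' @title Region adjacency graphs for spatial smoothing
#'
#' @description
#' The spatial term of the model is defined on an undirected contiguity
#' graph over administrative regions: the effect of region `s` given its
#' neighbours is Gaussian with mean the neighbour average and variance
#' `tau2 / N_s`, where `N_s` is the number of neighbours.  A graph is a
#' named neighbour list; symmetry and absence of self-loops are enforced
#' at construction.
NULL

#' Construct a region graph from a neighbour list
#'
#' @param nb named list; `nb[[s]]` is the character vector of neighbours
#'   of region `s`.  Must be symmetric and self-loop free.
#' @return object of class `region_graph` with fields `ids`, `nb` and
#'   neighbour counts `n_nb`.
#' @export
region_graph <- function(nb) {
  ids <- names(nb)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("neighbour list must have unique region names", call. = FALSE)
  }
  nb <- lapply(nb, as.character)
  for (s in ids) {
    if (s %in% nb[[s]]) stop("self-loop at region ", s, call. = FALSE)
    for (t in nb[[s]]) {
      if (!t %in% ids) stop("unknown neighbour '", t, "' of ", s, call. = FALSE)
      if (!s %in% nb[[t]]) {
        stop("asymmetric adjacency: ", s, " -> ", t, " only", call. = FALSE)
      }
    }
  }
  structure(list(ids = ids, nb = nb, n_nb = lengths(nb)),
            class = "region_graph")
}

#' @export
print.region_graph <- function(x, ...) {
  cat("region_graph:", length(x$ids), "regions,",
      sum(x$n_nb) / 2, "edges,",
      length(graph_components(x)), "component(s)\n")
  invisible(x)
}

#' Rook-adjacency lattice graph
#'
#' Regular `rows` by `cols` grid where each cell neighbours the cells it
#' shares an edge with.  Used as the default test geography standing in
#' for a real administrative contiguity map.
#'
#' @param rows,cols positive integers with `rows * cols >= 2`.
#' @return a [region_graph()] with ids `"r<i>c<j>"`, connected.
#' @export
make_lattice_graph <- function(rows, cols) {
  if (rows < 1 || cols < 1 || rows * cols < 2) {
    stop("need rows * cols >= 2", call. = FALSE)
  }
  id <- function(i, j) sprintf("r%dc%d", i, j)
  nb <- list()
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      nbr <- character(0)
      if (i > 1) nbr <- c(nbr, id(i - 1, j))
      if (i < rows) nbr <- c(nbr, id(i + 1, j))
      if (j > 1) nbr <- c(nbr, id(i, j - 1))
      if (j < cols) nbr <- c(nbr, id(i, j + 1))
      nb[[id(i, j)]] <- nbr
    }
  }
  region_graph(nb)
}

# connected components as a list of id vectors (breadth-first search)
graph_components <- function(graph) {
  ids <- graph$ids
  seen <- setNames(rep(FALSE, length(ids)), ids)
  comps <- list()
  for (s in ids) {
    if (seen[[s]]) next
    queue <- s
    comp <- character(0)
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      if (seen[[v]]) next
      seen[[v]] <- TRUE
      comp <- c(comp, v)
      queue <- c(queue, graph$nb[[v]][!seen[graph$nb[[v]]]])
    }
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

#' ICAR precision structure of a region graph
#'
#' Returns `Q = diag(N_s) - A` with `A` the 0/1 adjacency matrix.  Under
#' the intrinsic conditional autoregressive prior with variance `tau2`,
#' the full conditional of region `s` given the rest is Gaussian with
#' mean the average of its neighbours and variance `tau2 / N_s`; `Q`
#' encodes exactly that Markov structure.  Row sums are zero and
#' `rank(Q) = regions - components`.
#'
#' @param graph a [region_graph()].
#' @return symmetric matrix with dimnames the region ids.
#' @export
icar_precision <- function(graph) {
  stopifnot(inherits(graph, "region_graph"))
  ids <- graph$ids
  R <- length(ids)
  Q <- matrix(0, R, R, dimnames = list(ids, ids))
  for (s in ids) Q[s, graph$nb[[s]]] <- -1
  diag(Q) <- graph$n_nb[ids]
  Q
}

#' Write a graph as a plain-text neighbour list
#'
#' One region per line: `region_id: n_neighbors id id ...`.
#'
#' @param graph a [region_graph()].
#' @param path output file path.
#' @export
write_neighbor_list <- function(graph, path) {
  lines <- vapply(graph$ids, function(s) {
    paste0(s, ": ", length(graph$nb[[s]]),
           if (length(graph$nb[[s]])) paste0(" ", paste(graph$nb[[s]], collapse = " ")) else "")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text neighbour list
#'
#' @param path file written by [write_neighbor_list()] (or hand-prepared
#'   for a real geography).
#' @return a [region_graph()].
#' @export
read_neighbor_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  nb <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed neighbour line: ", ln, call. = FALSE)
    id <- trimws(parts[[1]])
    toks <- strsplit(trimws(parts[[2]]), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    n <- as.integer(toks[[1]])
    nbr <- if (n > 0) toks[-1] else character(0)
    if (length(nbr) != n) {
      stop("neighbour count mismatch for region ", id, call. = FALSE)
    }
    nb[[id]] <- nbr
  }
  region_graph(nb)
}
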