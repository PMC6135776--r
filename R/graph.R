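#' Canonical index of an unordered cell-type pair
#'
#' With 4 cell classes there are 10 unordered pairs of cell-cell connection
#' types. Identifying (M, I, S, N) with 1..4, pairs are ordered
#' (1,1), (2,1), (2,2), (3,1), (3,2), (3,3), (4,1), (4,2), (4,3), (4,4);
#' `pair_index()` returns the 1-based position of an unordered pair in this
#' order, so `pair_index(a, b) == pair_index(b, a)`.
#'
#' @param type_a,type_b Cell types (elements of [cell_types()]); vectorized.
#' @return Integer position(s) in 1..10.
#' @seealso [pair_names()] for the component labels in the same order.
#' @export
pair_index <- function(type_a, type_b) {
  a <- match(type_a, cell_types())
  b <- match(type_b, cell_types())
  if (anyNA(a) || anyNA(b)) {
    stop("unknown cell type; expected one of ",
         paste(cell_types(), collapse = ", "))
  }
  i <- pmax(a, b)
  j <- pmin(a, b)
  as.integer(i * (i - 1L) / 2L + j)
}

#' @rdname pair_index
#' @export
pair_names <- function() {
  types <- cell_types()
  out <- character(10L)
  for (i in 1:4) for (j in 1:i) {
    out[i * (i - 1L) / 2L + j] <- paste0(types[j], types[i])
  }
  out
}

#' Delaunay cell network of one tile
#'
#' Builds the cell network of a tile: vertices are the tile's cells and
#' edges are the Delaunay triangulation edges, so an edge joins a pair of
#' neighboring cells. Edges never cross tile boundaries because each tile is
#' triangulated on its own.
#'
#' Degenerate inputs follow the natural one-dimensional limit of the
#' triangulation: a single cell gives no edges, two cells give one edge, and
#' three or more collinear cells are joined by consecutive-neighbor path
#' edges along the line. Exactly coincident coordinates are merged to one
#' vertex keeping the first record's type, with a warning.
#'
#' @param tile A tile from [tile_cells()], or a cell data frame.
#' @return Object of class `cell_network`: list with `vertices` (data frame
#'   with `x_um`, `y_um`, `cell_type`) and `edges` (two-column integer
#'   matrix of vertex indices, each unordered pair once).
#' @export
delaunay_network <- function(tile) {
  cells <- if (is.data.frame(tile)) tile else tile$cells
  cells <- validate_cells(cells, require_case_id = FALSE)
  if (nrow(cells) == 0L) stop("cannot build a network for an empty tile")

  dup <- duplicated(cells[, c("x_um", "y_um")])
  if (any(dup)) {
    warning(sum(dup), " coincident cell coordinate(s) merged, keeping the ",
            "first record's type")
    cells <- cells[!dup, , drop = FALSE]
  }
  rownames(cells) <- NULL
  n <- nrow(cells)
  x <- cells$x_um
  y <- cells$y_um

  edges <- if (n == 1L) {
    matrix(integer(0), ncol = 2L)
  } else if (n == 2L) {
    matrix(c(1L, 2L), ncol = 2L)
  } else if (is_collinear(x, y)) {
    # order along the line through the farthest point and join consecutive
    # neighbors
    dx <- x - x[1]
    dy <- y - y[1]
    far <- which.max(dx^2 + dy^2)
    ord <- order(dx * dx[far] + dy * dy[far])
    cbind(ord[-n], ord[-1L])
  } else {
    d <- deldir::deldir(x, y, suppressMsge = TRUE)
    as.matrix(d$delsgs[, c("ind1", "ind2")])
  }
  if (nrow(edges) > 0L) {
    edges <- t(apply(edges, 1L, sort))
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  dimnames(edges) <- NULL
  storage.mode(edges) <- "integer"
  structure(list(vertices = cells, edges = edges), class = "cell_network")
}

# all points within tol of a single line?
is_collinear <- function(x, y, tol = 1e-9) {
  dx <- x - x[1]
  dy <- y - y[1]
  scale <- max(abs(c(dx, dy)), 1)
  cross <- dx * dy[which.max(dx^2 + dy^2)] - dy * dx[which.max(dx^2 + dy^2)]
  all(abs(cross) <= tol * scale^2)
}

#' @export
print.cell_network <- function(x, ...) {
  cat("cell network:", nrow(x$vertices), "cells,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Cell-cell connection frequency vector of a network
#'
#' Summarises a tile's cell network by the proportion of its edges joining
#' each unordered pair of cell types: a 10-component vector `h` on the
#' simplex (components sum to 1 whenever the network has any edge), indexed
#' in the canonical [pair_index()] order.
#'
#' @param network A `cell_network` from [delaunay_network()].
#' @return Object of class `conn_freq`: list with `h` (named numeric vector
#'   of length 10) and `n_edges` (edge count used for normalisation). An
#'   edgeless network yields the zero vector with `n_edges = 0`.
#' @export
connection_frequencies <- function(network) {
  stopifnot(inherits(network, "cell_network"))
  h <- numeric(10L)
  names(h) <- pair_names()
  m <- nrow(network$edges)
  if (m > 0L) {
    types <- network$vertices$cell_type
    idx <- pair_index(types[network$edges[, 1L]], types[network$edges[, 2L]])
    counts <- tabulate(idx, nbins = 10L)
    h <- counts / m
    names(h) <- pair_names()
  }
  structure(list(h = h, n_edges = m), class = "conn_freq")
}

#' Per-tile connection-frequency table for one or more slides
#'
#' Runs the full local-characterisation stage: tiles each case's cell map,
#' builds the Delaunay network of every tile, and records the tile's
#' 10-component connection-frequency vector. Tiles with fewer than
#' `min_cells` cells are retained in the table but flagged unphenotyped
#' (`phenotyped = FALSE`): their frequency vectors are too unstable to
#' cluster.
#'
#' @param cells Cell map data frame (may contain several `case_id`s).
#' @param tile_size_um Tile side in micrometres (default 200).
#' @param min_cells Minimum cells for a tile to enter phenotyping
#'   (default 5).
#' @return Data frame with one row per non-empty tile: `case_id`, `row`,
#'   `col`, `n_cells`, `n_edges`, `phenotyped`, and frequency columns named
#'   after [pair_names()].
#' @export
tile_frequencies <- function(cells, tile_size_um = 200, min_cells = 5) {
  cells <- validate_cells(cells)
  by_case <- split(cells, cells$case_id)
  rows <- lapply(names(by_case), function(cid) {
    tiles <- tile_cells(by_case[[cid]], tile_size_um = tile_size_um)
    if (length(tiles) == 0L) return(NULL)
    recs <- lapply(tiles, function(tl) {
      n <- nrow(tl$cells)
      if (n >= 2L) {
        cf <- connection_frequencies(delaunay_network(tl))
        h <- cf$h
        m <- cf$n_edges
      } else {
        h <- stats::setNames(numeric(10L), pair_names())
        m <- 0L
      }
      data.frame(case_id = cid, row = tl$row, col = tl$col, n_cells = n,
                 n_edges = m, phenotyped = n >= min_cells && m > 0L,
                 as.list(h), check.names = FALSE,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(case_id = character(0), row = integer(0),
                      col = integer(0), n_cells = integer(0),
                      n_edges = integer(0), phenotyped = logical(0))
    for (nm in pair_names()) out[[nm]] <- numeric(0)
  }
  rownames(out) <- NULL
  out
}

#' Extract the frequency-vector matrix from a tile table
#'
#' @param tile_table Output of [tile_frequencies()].
#' @param phenotyped_only Keep only tiles flagged for phenotyping.
#' @return Numeric matrix, one row per tile, 10 columns in [pair_names()]
#'   order.
#' @export
frequency_matrix <- function(tile_table, phenotyped_only = TRUE) {
  if (phenotyped_only) tile_table <- tile_table[tile_table$phenotyped, , drop = FALSE]
  as.matrix(tile_table[, pair_names(), drop = FALSE])
}
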