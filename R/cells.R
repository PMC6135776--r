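#' The four cell classes
#'
#' Cells are classified into four types on nuclear appearance:
#' malignant epithelial (`"M"`), inflammatory (`"I"`), spindle-shaped
#' (`"S"`, fibroblasts and smooth-muscle cells) and necrotic debris (`"N"`).
#'
#' @return Character vector `c("M", "I", "S", "N")`, in canonical order.
#' @export
cell_types <- function() c("M", "I", "S", "N")

#' Validate a cell map
#'
#' A cell map is a data frame with one row per detected cell: columns
#' `case_id`, `x_um`, `y_um` (centroid coordinates in micrometres, origin at
#' the top-left of the slide, y increasing downward) and `cell_type`
#' (one of [cell_types()]).
#'
#' @param cells Data frame to validate.
#' @param require_case_id Require the `case_id` column (default `TRUE`).
#' @return The validated data frame, invisibly coerced (cell_type as
#'   character).
#' @export
validate_cells <- function(cells, require_case_id = TRUE) {
  stopifnot(is.data.frame(cells))
  needed <- c("x_um", "y_um", "cell_type")
  if (require_case_id) needed <- c("case_id", needed)
  missing_cols <- setdiff(needed, names(cells))
  if (length(missing_cols) > 0L) {
    stop("cell map is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  cells$cell_type <- as.character(cells$cell_type)
  if (nrow(cells) > 0L) {
    if (!all(is.finite(cells$x_um)) || !all(is.finite(cells$y_um))) {
      stop("cell coordinates must be finite")
    }
    bad <- setdiff(unique(cells$cell_type), cell_types())
    if (length(bad) > 0L) {
      stop("unknown cell type(s): ", paste(bad, collapse = ", "))
    }
  }
  invisible(cells)
}

#' Read or write a cell map table
#'
#' Plain-text comma-separated table with header columns
#' `case_id,x_um,y_um,cell_type`. The same schema is accepted for cell maps
#' exported from external cell detection/classification tools.
#'
#' @param path File path.
#' @param cells Cell map data frame (see [validate_cells()]).
#' @return `read_cell_map()` returns the validated data frame;
#'   `write_cell_map()` returns `path` invisibly.
#' @export
read_cell_map <- function(path) {
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cells(cells)
  cells
}

#' @rdname read_cell_map
#' @export
write_cell_map <- function(cells, path) {
  validate_cells(cells)
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a slide's cells into non-overlapping square tiles
#'
#' The slide is partitioned into axis-aligned square tiles of side
#' `tile_size_um` (default 200 micrometres, within the limit of effective
#' intercellular communication). Tile `(row, col)` covers the half-open
#' square `[col * w, (col + 1) * w) x [row * w, (row + 1) * w)`, so each
#' cell belongs to exactly one tile. Tiles containing no cells are omitted.
#'
#' @param cells Cell map data frame for a single slide.
#' @param tile_size_um Tile side length in micrometres; must be positive.
#' @return List of tiles; each tile is a list with elements `row`, `col`,
#'   `bounds` (xmin, xmax, ymin, ymax; upper bounds exclusive) and `cells`
#'   (the contained rows of `cells`).
#' @export
tile_cells <- function(cells, tile_size_um = 200) {
  stopifnot(is.numeric(tile_size_um), length(tile_size_um) == 1L,
            tile_size_um > 0)
  cells <- validate_cells(cells, require_case_id = FALSE)
  if (nrow(cells) == 0L) return(list())
  if (any(cells$x_um < 0) || any(cells$y_um < 0)) {
    stop("negative coordinates: cell maps use a top-left origin with ",
         "x_um, y_um >= 0")
  }
  col <- floor(cells$x_um / tile_size_um)
  row <- floor(cells$y_um / tile_size_um)
  key <- paste(row, col, sep = "_")
  groups <- split(seq_len(nrow(cells)), key)
  tiles <- lapply(groups, function(idx) {
    r <- row[idx[1L]]
    cc <- col[idx[1L]]
    list(
      row = r, col = cc,
      bounds = c(xmin = cc * tile_size_um, xmax = (cc + 1) * tile_size_um,
                 ymin = r * tile_size_um, ymax = (r + 1) * tile_size_um),
      cells = cells[idx, , drop = FALSE]
    )
  })
  ord <- order(vapply(tiles, `[[`, 0, "row"), vapply(tiles, `[[`, 0, "col"))
  unname(tiles[ord])
}
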