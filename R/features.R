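#' Per-case phenotype-ratio features
#'
#' The signature feature of a case is, for each connection-frequency (CF)
#' phenotype, the ratio of the area covered by tiles of that phenotype to
#' the total tissue area:
#' `phenotype ratio = area of the tissue phenotype / total tissue area`.
#'
#' With a tissue mask (the default denominator, `"tissue_area"`), the
#' numerator is the tissue-pixel area of the mask inside the tiles assigned
#' to the phenotype and the denominator is [tissue_area()] of the mask, so
#' non-tissue pixels (normal, fat, background) inside a tile do not count
#' and the ratios sum to at most 1. Without a mask
#' (`denominator = "phenotyped_tiles"`), tile counts over the number of
#' phenotyped tiles are used and the ratios sum to exactly 1.
#'
#' @param tile_table Per-tile table of one case ([tile_frequencies()] rows).
#' @param labels Phenotype label (1..k) per phenotyped tile, in the order
#'   of the phenotyped rows of `tile_table` (as from [assign_phenotypes()]
#'   on [frequency_matrix()]).
#' @param k Number of phenotypes.
#' @param mask Optional [tissue_mask()] of the case's slide.
#' @param tile_size_um Tile side used to build `tile_table`.
#' @param denominator `"tissue_area"` (requires `mask`) or
#'   `"phenotyped_tiles"`.
#' @return Named numeric vector `cf_ratio_1 .. cf_ratio_k`; all `NA` with a
#'   warning when the denominator is zero.
#' @export
cf_phenotype_ratios <- function(tile_table, labels, k, mask = NULL,
                                tile_size_um = 200,
                                denominator = c("tissue_area",
                                                "phenotyped_tiles")) {
  denominator <- match.arg(denominator)
  if (denominator == "tissue_area" && is.null(mask)) {
    stop("denominator = \"tissue_area\" requires a tissue mask; ",
         "use denominator = \"phenotyped_tiles\" for maskless runs")
  }
  ph <- tile_table[tile_table$phenotyped, , drop = FALSE]
  stopifnot(length(labels) == nrow(ph))
  out <- stats::setNames(rep(NA_real_, k), paste0("cf_ratio_", seq_len(k)))

  if (denominator == "phenotyped_tiles") {
    if (nrow(ph) == 0L) {
      warning("no phenotyped tiles; phenotype ratios undefined")
      return(out)
    }
    counts <- tabulate(labels, nbins = k)
    return(stats::setNames(counts / nrow(ph), names(out)))
  }

  denom <- tissue_area(mask)
  if (denom == 0) {
    warning("zero tissue area; phenotype ratios undefined")
    return(out)
  }
  tissue_px <- tissue_pixels_per_tile(mask, tile_size_um)
  num <- numeric(k)
  if (nrow(ph) > 0L) {
    key <- paste(ph$row, ph$col, sep = "_")
    px <- tissue_px[key]
    px[is.na(px)] <- 0
    for (p in seq_len(k)) num[p] <- sum(px[labels == p])
  }
  stats::setNames(num * mask$um_per_pixel^2 / denom, names(out))
}

# tissue-pixel count per tile (named "row_col"), assigning each pixel to
# the tile containing its center
tissue_pixels_per_tile <- function(mask, tile_size_um) {
  cls <- matrix(mask$class_map[as.character(mask$labels)],
                nrow = nrow(mask$labels))
  is_tissue <- !(cls %in% non_tissue_classes())
  dim(is_tissue) <- dim(mask$labels)
  upp <- mask$um_per_pixel
  px_row <- floor(((row(mask$labels) - 0.5) * upp) / tile_size_um)
  px_col <- floor(((col(mask$labels) - 0.5) * upp) / tile_size_um)
  key <- paste(px_row[is_tissue], px_col[is_tissue], sep = "_")
  counts <- table(key)
  stats::setNames(as.numeric(counts), names(counts))
}

#' Morisita-Horn colocalization of inflammatory and malignant cells
#'
#' Measures the spatial coexistence of two cell populations by the
#' Morisita-Horn overlap of their quadrat counts. With per-quadrat counts
#' `x_q` (inflammatory) and `y_q` (malignant), totals `X` and `Y`:
#' `MH = 2 * sum(x_q * y_q) / ((sum(x_q^2)/X^2 + sum(y_q^2)/Y^2) * X * Y)`.
#' The index lies in `[0, 1]`: 1 for proportionally identical counts in
#' every quadrat, 0 for fully disjoint occupancy. Quadrats are squares
#' aligned with the tile grid (default 200 micrometres).
#'
#' @param cells Cell map of one case.
#' @param quadrat_size_um Quadrat side in micrometres.
#' @param type_x,type_y The two cell types compared (defaults `"I"`,
#'   `"M"`).
#' @return Scalar in `[0, 1]`, or `NA` with a warning when either type is
#'   absent.
#' @export
morisita_index <- function(cells, quadrat_size_um = 200, type_x = "I",
                           type_y = "M") {
  stopifnot(quadrat_size_um > 0)
  cells <- validate_cells(cells, require_case_id = FALSE)
  qkey <- paste(floor(cells$y_um / quadrat_size_um),
                floor(cells$x_um / quadrat_size_um), sep = "_")
  quadrats <- unique(qkey)
  x <- as.numeric(table(factor(qkey[cells$cell_type == type_x],
                               levels = quadrats)))
  y <- as.numeric(table(factor(qkey[cells$cell_type == type_y],
                               levels = quadrats)))
  morisita_horn(x, y)
}

#' Morisita-Horn overlap of two count vectors
#'
#' @param x,y Nonnegative counts over the same quadrats.
#' @return Scalar in `[0, 1]`, or `NA` with a warning if either total is 0.
#' @export
morisita_horn <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  X <- sum(x)
  Y <- sum(y)
  if (X == 0 || Y == 0) {
    warning("one population is empty; Morisita-Horn undefined")
    return(NA_real_)
  }
  2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
}

#' Full feature vector of one case
#'
#' Combines the CF phenotype ratios, the appearance-mask features and the
#' Morisita-Horn index into the case's one-row feature record. Features
#' whose denominator is empty (e.g. necrosis-tumor ratio on a slide with
#' no tumor pixels) are `NA` and the row is retained.
#'
#' @param case_id Case identifier.
#' @param tile_table Per-tile table of the case.
#' @param labels Phenotype labels of the case's phenotyped tiles.
#' @param k Number of phenotypes.
#' @param cells The case's cell map (for the Morisita index).
#' @param mask Optional [tissue_mask()]; without it the appearance features
#'   are `NA` and CF ratios use the `"phenotyped_tiles"` denominator.
#' @param tile_size_um Tile side in micrometres.
#' @return One-row data frame with the fixed feature schema.
#' @export
case_features <- function(case_id, tile_table, labels, k, cells,
                          mask = NULL, tile_size_um = 200) {
  cf <- cf_phenotype_ratios(
    tile_table, labels, k, mask = mask, tile_size_um = tile_size_um,
    denominator = if (is.null(mask)) "phenotyped_tiles" else "tissue_area")
  if (!is.null(mask)) {
    ap <- ap_ratios(mask)
    st <- stroma_tumor_ratio(mask)
    nt <- necrosis_tumor_ratio(mask)
    area <- tissue_area(mask)
  } else {
    ap <- c(ap_smooth_muscle_ratio = NA_real_,
            ap_inflammation_ratio = NA_real_)
    st <- NA_real_
    nt <- NA_real_
    area <- NA_real_
  }
  mi <- suppressWarnings(morisita_index(cells, quadrat_size_um = tile_size_um))
  data.frame(case_id = case_id, as.list(cf), as.list(ap),
             stroma_tumor_ratio = st, necrosis_tumor_ratio = nt,
             morisita_index = mi, tissue_area_um2 = area,
             stringsAsFactors = FALSE)
}

#' Assemble the per-case feature table
#'
#' @param cases List of one-row data frames from [case_features()].
#' @param k Number of phenotypes (fixes the column schema when `cases` is
#'   empty).
#' @return Data frame with one row per case and a stable column order;
#'   duplicate `case_id`s are rejected.
#' @export
build_feature_table <- function(cases, k = NULL) {
  if (length(cases) == 0L) {
    stopifnot(!is.null(k))
    out <- data.frame(case_id = character(0))
    for (nm in paste0("cf_ratio_", seq_len(k))) out[[nm]] <- numeric(0)
    for (nm in c("ap_smooth_muscle_ratio", "ap_inflammation_ratio",
                 "stroma_tumor_ratio", "necrosis_tumor_ratio",
                 "morisita_index", "tissue_area_um2")) {
      out[[nm]] <- numeric(0)
    }
    return(out)
  }
  out <- do.call(rbind, cases)
  if (anyDuplicated(out$case_id)) {
    stop("duplicate case_id in feature table: ",
         paste(unique(out$case_id[duplicated(out$case_id)]), collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Read or write a feature table
#'
#' Comma-separated with header, one row per case; missing features are
#' empty fields.
#'
#' @param features Feature table data frame.
#' @param path File path.
#' @return `read_feature_table()` returns the data frame.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}
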