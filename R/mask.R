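#' The nine appearance classes of the tissue mask
#'
#' Appearance-based segmentation labels every mask pixel with one of nine
#' categories. `background` (non-tissue), `normal` (normal mucosa) and
#' `fat` (adipose) never count as tissue when areas are computed; the other
#' six do.
#'
#' @return Character vector of the nine class names.
#' @export
ap_classes <- function() {
  c("background", "normal", "loose_connective", "fat", "stroma",
    "inflammation", "necrosis", "smooth_muscle", "tumor")
}

# classes excluded from every tissue-area denominator
non_tissue_classes <- function() c("background", "normal", "fat")

#' Construct a tissue mask
#'
#' A tissue mask is a categorical raster over the slide: an integer label
#' matrix (rows = y, columns = x, matching the top-left image origin), a
#' map from label values to appearance classes, and the pixel size in
#' micrometres.
#'
#' @param labels Integer matrix of label values.
#' @param class_map Named character vector mapping label value (name) to a
#'   class in [ap_classes()].
#' @param um_per_pixel Positive pixel size in micrometres.
#' @return Object of class `tissue_mask`.
#' @export
tissue_mask <- function(labels, class_map, um_per_pixel) {
  stopifnot(is.matrix(labels), um_per_pixel > 0)
  storage.mode(labels) <- "integer"
  class_map <- stats::setNames(as.character(class_map), names(class_map))
  bad_class <- setdiff(class_map, ap_classes())
  if (length(bad_class) > 0L) {
    stop("unknown appearance class(es): ", paste(bad_class, collapse = ", "))
  }
  present <- unique(as.vector(labels))
  unmapped <- setdiff(as.character(present), names(class_map))
  if (length(unmapped) > 0L) {
    stop("mask labels without a class-map entry: ",
         paste(unmapped, collapse = ", "))
  }
  structure(list(labels = labels, class_map = class_map,
                 um_per_pixel = um_per_pixel), class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat("tissue mask:", nrow(x$labels), "x", ncol(x$labels), "px at",
      x$um_per_pixel, "um/px\n")
  invisible(x)
}

# per-class pixel counts, named by class
class_pixel_counts <- function(mask) {
  stopifnot(inherits(mask, "tissue_mask"))
  counts <- table(factor(mask$class_map[as.character(mask$labels)],
                         levels = ap_classes()))
  stats::setNames(as.numeric(counts), names(counts))
}

#' Area of one appearance class, in square micrometres
#'
#' @param mask A [tissue_mask()].
#' @param class An appearance class name.
#' @return Area in square micrometres.
#' @export
class_area <- function(mask, class) {
  stopifnot(class %in% ap_classes())
  class_pixel_counts(mask)[[class]] * mask$um_per_pixel^2
}

#' Total tissue area of a mask
#'
#' The tissue area counts all appearance classes except normal mucosa,
#' fat and non-tissue background, times the squared pixel size.
#'
#' @param mask A [tissue_mask()].
#' @return Area in square micrometres.
#' @export
tissue_area <- function(mask) {
  counts <- class_pixel_counts(mask)
  tissue <- setdiff(ap_classes(), non_tissue_classes())
  sum(counts[tissue]) * mask$um_per_pixel^2
}

#' Appearance-class ratio features
#'
#' Ratio of the smooth-muscle (resp. inflammation) class area to the total
#' tissue area of the mask.
#'
#' @param mask A [tissue_mask()].
#' @return Named numeric vector `ap_smooth_muscle_ratio`,
#'   `ap_inflammation_ratio`; `NA` with a warning when the mask has no
#'   tissue.
#' @export
ap_ratios <- function(mask) {
  denom <- tissue_area(mask)
  if (denom == 0) {
    warning("mask has zero tissue area; appearance ratios undefined")
    return(c(ap_smooth_muscle_ratio = NA_real_,
             ap_inflammation_ratio = NA_real_))
  }
  c(ap_smooth_muscle_ratio = class_area(mask, "smooth_muscle") / denom,
    ap_inflammation_ratio = class_area(mask, "inflammation") / denom)
}

#' Stroma-tumor and necrosis-tumor ratios
#'
#' `stroma_tumor_ratio = stroma area / (stroma area + tumor area)` and
#' `necrosis_tumor_ratio = necrosis area / (necrosis area + tumor area)`,
#' on the appearance-mask class areas.
#'
#' @param mask A [tissue_mask()].
#' @return Scalar ratio, or `NA` with a warning when the denominator is 0.
#' @export
stroma_tumor_ratio <- function(mask) {
  s <- class_area(mask, "stroma")
  t <- class_area(mask, "tumor")
  if (s + t == 0) {
    warning("no stroma or tumor pixels; stroma-tumor ratio undefined")
    return(NA_real_)
  }
  s / (s + t)
}

#' @rdname stroma_tumor_ratio
#' @export
necrosis_tumor_ratio <- function(mask) {
  nn <- class_area(mask, "necrosis")
  t <- class_area(mask, "tumor")
  if (nn + t == 0) {
    warning("no necrosis or tumor pixels; necrosis-tumor ratio undefined")
    return(NA_real_)
  }
  nn / (nn + t)
}

#' Read or write a tissue mask
#'
#' The raster is stored as a single-channel 8-bit PNG (label values 0-255)
#' with a plain-text sidecar (`<path>.labels.txt`) recording
#' `um_per_pixel` and one `label=class` line per label value.
#'
#' @param mask A [tissue_mask()].
#' @param path PNG file path.
#' @return `write_tissue_mask()` returns `path` invisibly;
#'   `read_tissue_mask()` returns the mask.
#' @export
write_tissue_mask <- function(mask, path) {
  stopifnot(inherits(mask, "tissue_mask"))
  if (max(mask$labels) > 255L || min(mask$labels) < 0L) {
    stop("mask labels must fit 8 bits (0-255)")
  }
  png::writePNG(mask$labels / 255, path)
  sidecar <- paste0(path, ".labels.txt")
  lines <- c(paste0("um_per_pixel=", format(mask$um_per_pixel, digits = 15)),
             paste0(names(mask$class_map), "=", mask$class_map))
  writeLines(lines, sidecar)
  invisible(path)
}

#' @rdname write_tissue_mask
#' @export
read_tissue_mask <- function(path) {
  raster <- png::readPNG(path)
  if (length(dim(raster)) == 3L) raster <- raster[, , 1L]
  labels <- matrix(as.integer(round(raster * 255)), nrow = nrow(raster))
  lines <- readLines(paste0(path, ".labels.txt"))
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  upp <- as.numeric(vals[keys == "um_per_pixel"])
  class_map <- stats::setNames(vals[keys != "um_per_pixel"],
                               keys[keys != "um_per_pixel"])
  tissue_mask(labels, class_map, upp)
}
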