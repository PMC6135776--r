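#' Chi-squared distance between two frequency vectors
#'
#' `d(h, m) = sum_k (h_k - m_k)^2 / (h_k + m_k)`, the standard histogram
#' dissimilarity. Terms with `h_k + m_k = 0` contribute 0. For two vectors
#' on the simplex the distance is bounded by 2, attained by disjoint unit
#' masses.
#'
#' @param h,m Nonnegative numeric vectors of equal length.
#' @return Nonnegative scalar; 0 iff `h == m`.
#' @export
chisq_distance <- function(h, m) {
  if (length(h) != length(m)) stop("vectors must have equal length")
  if (any(h < 0) || any(m < 0)) stop("frequency vectors must be nonnegative")
  s <- h + m
  ok <- s > 0
  sum((h[ok] - m[ok])^2 / s[ok])
}

#' Pairwise chi-squared distance matrix
#'
#' @param x Numeric matrix, one frequency vector per row.
#' @param y Optional second matrix; if supplied, the cross-distance matrix
#'   `nrow(x) x nrow(y)` is returned.
#' @return Distance matrix.
#' @export
chisq_distance_matrix <- function(x, y = NULL) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("frequency vectors must be nonnegative")
  symmetric <- is.null(y)
  y <- if (symmetric) x else as.matrix(y)
  if (any(y < 0)) stop("frequency vectors must be nonnegative")
  if (ncol(x) != ncol(y)) stop("vectors must have equal length")
  d <- matrix(0, nrow(x), nrow(y))
  for (k in seq_len(ncol(x))) {
    s <- outer(x[, k], y[, k], "+")
    num <- outer(x[, k], y[, k], "-")^2
    contrib <- num / s
    contrib[s == 0] <- 0
    d <- d + contrib
  }
  if (symmetric) d[cbind(seq_len(nrow(x)), seq_len(nrow(x)))] <- 0
  d
}

#' k-medoids clustering of connection-frequency vectors
#'
#' Partition-around-medoids-style clustering under the chi-squared distance.
#' Each restart draws k distinct medoids uniformly at random, then
#' alternates (i) assignment of every vector to its nearest medoid and (ii)
#' replacement of each cluster's medoid by the member minimising the total
#' within-cluster distance, until the medoid set is stable (a local
#' optimum; the total cost never increases across iterations). The model
#' returned is the restart with the smallest total sum of distances between
#' the vectors and their medoids. The default of 100 restarts reproduces
#' the protocol used to derive the published phenotypes.
#'
#' @param x Numeric matrix, one frequency vector per row.
#' @param k Number of phenotypes; `1 <= k <= ` number of distinct rows.
#' @param n_restarts Random restarts (ignored when `init` is given).
#' @param seed Integer seed; all randomness is local to the call.
#' @param init Optional list of integer vectors, each a set of k starting
#'   medoid row indices (e.g. every k-subset, for exhaustive verification);
#'   overrides random initialisation.
#' @param max_iter Iteration cap per restart.
#' @return Object of class `phenotype_model`: `k`, `medoid_index`,
#'   `medoids` (k x 10 matrix, rows of `x`), `cost`, `replicate_costs`,
#'   `labels` (training assignment), `seed`, and `names` (optional semantic
#'   phenotype names, `NULL` until [name_phenotypes()]).
#' @export
kmedoids <- function(x, k, n_restarts = 100, seed = NULL, init = NULL,
                     max_iter = 100) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(k >= 1, n >= 1)
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) {
    stop("k = ", k, " exceeds the number of distinct vectors (", n_distinct, ")")
  }
  d <- chisq_distance_matrix(x)

  starts <- if (!is.null(init)) {
    lapply(init, function(s) {
      s <- as.integer(s)
      stopifnot(length(s) == k, all(s >= 1), all(s <= n), !anyDuplicated(s))
      s
    })
  } else {
    rng <- local_rng(seed)
    lapply(seq_len(n_restarts), function(i) rng$sample(n, k))
  }

  best <- NULL
  replicate_costs <- numeric(length(starts))
  for (r in seq_along(starts)) {
    fit <- kmedoids_once(d, starts[[r]], max_iter)
    replicate_costs[r] <- fit$cost
    if (is.null(best) || fit$cost < best$cost) best <- fit
  }

  medoid_index <- best$medoids
  structure(list(
    k = as.integer(k),
    medoid_index = medoid_index,
    medoids = x[medoid_index, , drop = FALSE],
    cost = best$cost,
    replicate_costs = replicate_costs,
    labels = best$labels,
    seed = seed,
    names = NULL
  ), class = "phenotype_model")
}

# one restart: alternate assignment and per-cluster medoid update on a
# precomputed distance matrix
kmedoids_once <- function(d, medoids, max_iter) {
  n <- nrow(d)
  k <- length(medoids)
  for (iter in seq_len(max_iter)) {
    labels <- max.col(-d[, medoids, drop = FALSE], ties.method = "first")
    new_medoids <- medoids
    for (cl in seq_len(k)) {
      members <- which(labels == cl)
      if (length(members) == 0L) next  # empty cluster keeps its medoid
      within <- colSums(d[members, members, drop = FALSE])
      new_medoids[cl] <- members[which.min(within)]
    }
    if (all(new_medoids == medoids)) break
    medoids <- new_medoids
  }
  labels <- max.col(-d[, medoids, drop = FALSE], ties.method = "first")
  cost <- sum(d[cbind(seq_len(n), medoids[labels])])
  list(medoids = medoids, labels = labels, cost = cost)
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat("phenotype model: k =", x$k, " cost =", format(x$cost, digits = 6),
      " (best of", length(x$replicate_costs), "restarts)\n")
  if (!is.null(x$names)) cat("phenotypes:", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Assign tiles to their nearest phenotype medoid
#'
#' Each vector is labeled by the chi-squared-nearest medoid of a fitted
#' model; ties are broken toward the lowest medoid index.
#'
#' @param model A `phenotype_model` from [kmedoids()].
#' @param x Frequency-vector matrix (rows on the same 10 components).
#' @return Integer vector of phenotype labels in `1..k`, with the distance
#'   to the assigned medoid in attribute `"distance"`.
#' @export
assign_phenotypes <- function(model, x) {
  stopifnot(inherits(model, "phenotype_model"))
  x <- as.matrix(x)
  d <- chisq_distance_matrix(x, model$medoids)
  labels <- max.col(-d, ties.method = "first")
  attr(labels, "distance") <- d[cbind(seq_len(nrow(x)), labels)]
  labels
}

#' Select the number of phenotypes
#'
#' Fits [kmedoids()] for every k in `k_range` and applies the two published
#' admissibility criteria: phenotypes must stay mutually distinct (minimum
#' pairwise chi-squared distance between medoids at least `dist_threshold`)
#' and the per-case phenotype-ratio features they induce must not be
#' redundant (maximum pairwise Spearman correlation at most
#' `corr_threshold`). The selected k is the largest admissible value; a
#' distance below 0.2 or a correlation above 0.8 is considered undesirable.
#'
#' Correlations are computed on per-case phenotype ratios (tile counts per
#' phenotype over phenotyped tiles per case), the features the criterion
#' guards. The signed maximum is used: strongly positively correlated
#' features are redundant, whereas the negative correlations inherent to
#' compositional ratios are not.
#'
#' @param x Frequency-vector matrix of pooled tiles.
#' @param case_ids Case identifier per row of `x` (for the per-case ratio
#'   features).
#' @param k_range Candidate phenotype counts (default `2:10`).
#' @param dist_threshold Minimum admissible medoid-pair distance
#'   (default 0.2).
#' @param corr_threshold Maximum admissible feature correlation
#'   (default 0.8).
#' @param n_restarts,seed Passed to [kmedoids()] (one derived seed per k).
#' @return Object of class `k_selection`: `selected_k` (integer, or `NA`
#'   with `status = "no admissible k"`), `status`, `diagnostics` (one row
#'   per k: `k`, `cost`, `min_medoid_distance`, `max_feature_correlation`,
#'   `admissible`), and `models` (the fitted models, named by k).
#' @export
select_k <- function(x, case_ids, k_range = 2:10, dist_threshold = 0.2,
                     corr_threshold = 0.8, n_restarts = 100, seed = NULL) {
  x <- as.matrix(x)
  stopifnot(length(case_ids) == nrow(x))
  rng <- local_rng(seed)
  diagnostics <- data.frame(k = integer(0), cost = numeric(0),
                            min_medoid_distance = numeric(0),
                            max_feature_correlation = numeric(0),
                            admissible = logical(0))
  models <- list()
  for (k in sort(k_range)) {
    fit <- kmedoids(x, k, n_restarts = n_restarts, seed = rng$int())
    labels <- fit$labels
    dm <- chisq_distance_matrix(fit$medoids)
    min_dist <- min(dm[upper.tri(dm)])
    ratios <- per_case_ratios(labels, case_ids, k)
    max_corr <- if (nrow(ratios) >= 3L) {
      cm <- suppressWarnings(stats::cor(ratios, method = "spearman"))
      diag(cm) <- NA
      cm[!is.finite(cm)] <- NA
      if (all(is.na(cm))) -Inf else max(cm, na.rm = TRUE)
    } else -Inf
    admissible <- min_dist >= dist_threshold && max_corr <= corr_threshold
    diagnostics <- rbind(diagnostics, data.frame(
      k = k, cost = fit$cost, min_medoid_distance = min_dist,
      max_feature_correlation = max_corr, admissible = admissible))
    models[[as.character(k)]] <- fit
  }
  ok <- diagnostics$k[diagnostics$admissible]
  selected <- if (length(ok) > 0L) max(ok) else NA_integer_
  structure(list(
    selected_k = selected,
    status = if (is.na(selected)) "no admissible k" else "ok",
    diagnostics = diagnostics,
    models = models
  ), class = "k_selection")
}

# per-case phenotype tile-count ratios (maskless), cases x k
per_case_ratios <- function(labels, case_ids, k) {
  tab <- table(factor(case_ids), factor(labels, levels = seq_len(k)))
  tot <- rowSums(tab)
  tot[tot == 0] <- 1
  as.matrix(sweep(unclass(tab), 1, tot, "/"))
}

#' @export
print.k_selection <- function(x, ...) {
  cat("phenotype-count selection:",
      if (is.na(x$selected_k)) x$status else paste("k =", x$selected_k), "\n")
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

#' Semantic phenotype names from medoid connection spectra
#'
#' Optionally labels each phenotype by the tissue it resembles, using the
#' dominant connections of its medoid: per-type incident mass
#' `w_t = h_tt + sum_{u != t} h_tu / 2` decides the dominant cell class,
#' with S-dominant medoids split into `smooth_muscle` (S-S connections
#' prevail strongly) versus `stroma`, and balanced M/S medoids labeled
#' `tumor_stroma_interface`. Purely cosmetic: names never affect any
#' downstream number.
#'
#' @param model A `phenotype_model`.
#' @param mapping Optional character vector of length k; returned verbatim
#'   (overrides the heuristic).
#' @return The model with `names` set; names are also returned in attribute
#'   form via `model$names`.
#' @export
name_phenotypes <- function(model, mapping = NULL) {
  stopifnot(inherits(model, "phenotype_model"))
  if (!is.null(mapping)) {
    stopifnot(length(mapping) == model$k)
    model$names <- as.character(mapping)
    return(model)
  }
  model$names <- unname(apply(model$medoids, 1L, medoid_name))
  model
}

medoid_name <- function(h) {
  types <- cell_types()
  w <- stats::setNames(numeric(4L), types)
  nm <- pair_names()
  for (p in seq_along(nm)) {
    a <- substr(nm[p], 1L, 1L)
    b <- substr(nm[p], 2L, 2L)
    if (a == b) w[a] <- w[a] + h[p]
    else {
      w[a] <- w[a] + h[p] / 2
      w[b] <- w[b] + h[p] / 2
    }
  }
  dom <- names(which.max(w))
  if (dom == "N") return("necrosis")
  if (dom == "I") return("inflammation")
  if (w["M"] > 0.3 && w["S"] > 0.3) return("tumor_stroma_interface")
  if (dom == "M") return("tumor")
  if (h[pair_index("S", "S")] >= 0.6) return("smooth_muscle")
  "stroma"
}

#' Serialize or restore a phenotype model
#'
#' Models are stored as human-readable JSON holding k, the medoid vectors,
#' the seed, the best cost and the restart costs, so a fitted model can be
#' reused on new slides.
#'
#' @param model A `phenotype_model`.
#' @param path File path.
#' @return `write_phenotype_model()` returns `path` invisibly;
#'   `read_phenotype_model()` returns the model.
#' @export
write_phenotype_model <- function(model, path) {
  stopifnot(inherits(model, "phenotype_model"))
  obj <- list(
    k = model$k,
    pair_names = pair_names(),
    medoids = apply(model$medoids, 1L, function(r) unname(r), simplify = FALSE),
    medoid_index = model$medoid_index,
    cost = model$cost,
    replicate_costs = model$replicate_costs,
    seed = model$seed,
    names = model$names
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_phenotype_model
#' @export
read_phenotype_model <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"),
                            simplifyMatrix = FALSE)
  medoids <- do.call(rbind, obj$medoids)
  colnames(medoids) <- obj$pair_names
  structure(list(
    k = as.integer(obj$k),
    medoid_index = as.integer(obj$medoid_index),
    medoids = medoids,
    cost = obj$cost,
    replicate_costs = unlist(obj$replicate_costs),
    labels = NULL,
    seed = obj$seed,
    names = if (is.null(obj$names)) NULL else unlist(obj$names)
  ), class = "phenotype_model")
}
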