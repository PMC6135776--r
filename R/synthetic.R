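#' Expected connection frequencies of an independent cell mixture
#'
#' For a homogeneous point pattern whose cells carry independent type marks
#' with proportions `p`, the probability that an edge joins types `i` and
#' `j` is `2 * p_i * p_j` for distinct types and `p_i^2` for equal types,
#' whatever the edge structure. This closed form ties a region's cell
#' mixture to its expected connection-frequency vector and makes planted
#' archetypes analytically checkable.
#'
#' @param mixture Nonnegative length-4 vector over [cell_types()]; need not
#'   be normalised.
#' @return 10-component simplex vector in [pair_names()] order.
#' @export
expected_pair_frequencies <- function(mixture) {
  stopifnot(length(mixture) == 4L, all(mixture >= 0), sum(mixture) > 0)
  p <- mixture / sum(mixture)
  h <- numeric(10L)
  for (i in 1:4) for (j in 1:i) {
    h[i * (i - 1L) / 2L + j] <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
  }
  stats::setNames(h / sum(h), pair_names())
}

#' The six planted tissue archetypes
#'
#' Default archetype profiles used by the generators, one per tissue
#' phenotype the clustering stage is expected to discover: smooth muscle,
#' inflammation, tumor-stroma interface, tumor, stroma and necrosis. Each
#' profile carries a 4-component cell mixture over (M, I, S, N), the
#' implied target connection-frequency vector
#' ([expected_pair_frequencies()]), a cell density (cells per 200 um tile)
#' and the appearance class its regions take in generated masks. The
#' default mixtures give pairwise chi-squared distances of at least 0.6
#' between target vectors, comfortably above the 0.2 phenotype-similarity
#' threshold.
#'
#' @param names Which archetypes to return (default all six).
#' @return Named list of `archetype_profile` objects with fields `name`,
#'   `cell_mixture`, `target_frequencies`, `density`, `ap_class`.
#' @export
archetype_profiles <- function(names = NULL) {
  spec <- list(
    smooth_muscle = list(mix = c(M = 0.02, I = 0.03, S = 0.95, N = 0.00),
                         density = 150, ap_class = "smooth_muscle"),
    inflammation = list(mix = c(M = 0.10, I = 0.80, S = 0.10, N = 0.00),
                        density = 300, ap_class = "inflammation"),
    tumor_stroma_interface = list(mix = c(M = 0.45, I = 0.08, S = 0.45,
                                          N = 0.02),
                                  density = 200, ap_class = "tumor"),
    tumor = list(mix = c(M = 0.85, I = 0.05, S = 0.08, N = 0.02),
                 density = 250, ap_class = "tumor"),
    stroma = list(mix = c(M = 0.10, I = 0.22, S = 0.60, N = 0.08),
                  density = 120, ap_class = "stroma"),
    necrosis = list(mix = c(M = 0.20, I = 0.05, S = 0.05, N = 0.70),
                    density = 100, ap_class = "necrosis")
  )
  if (is.null(names)) names <- base::names(spec)
  missing_names <- setdiff(names, base::names(spec))
  if (length(missing_names) > 0L) {
    stop("unknown archetype(s): ", paste(missing_names, collapse = ", "))
  }
  profiles <- lapply(names, function(nm) {
    s <- spec[[nm]]
    structure(list(
      name = nm,
      cell_mixture = s$mix / sum(s$mix),
      target_frequencies = expected_pair_frequencies(s$mix),
      density = s$density,
      ap_class = s$ap_class
    ), class = "archetype_profile")
  })
  stats::setNames(profiles, names)
}

#' Sample labeled connection-frequency vectors around archetype targets
#'
#' Draws vectors from a Dirichlet distribution on the 10-simplex with mean
#' equal to each profile's target frequencies and a single concentration
#' scalar controlling cluster tightness (`alpha = concentration * target`);
#' `concentration = Inf` returns each target exactly. This bypasses the
#' slide geometry and feeds the clustering stage directly.
#'
#' @param profiles List of `archetype_profile`s (non-empty).
#' @param n_per_profile Vectors per profile (>= 1).
#' @param concentration Positive Dirichlet concentration (default 150;
#'   `Inf` for degenerate sampling at the targets).
#' @param seed Integer seed.
#' @return List with `h` (matrix, `n_per_profile * length(profiles)` rows)
#'   and `label` (factor of true profile names, aligned with rows).
#' @export
sample_frequency_vectors <- function(profiles, n_per_profile,
                                     concentration = 150, seed = NULL) {
  if (length(profiles) == 0L) stop("at least one archetype profile required")
  stopifnot(n_per_profile >= 1, concentration > 0)
  rng <- local_rng(seed)
  blocks <- lapply(profiles, function(pr) {
    target <- pr$target_frequencies
    if (is.infinite(concentration)) {
      matrix(rep(target, each = n_per_profile), nrow = n_per_profile,
             dimnames = list(NULL, names(target)))
    } else {
      rng$draw(function() rdirichlet(n_per_profile, concentration * target))
    }
  })
  h <- do.call(rbind, blocks)
  colnames(h) <- pair_names()
  label <- factor(rep(vapply(profiles, `[[`, "", "name"),
                      each = n_per_profile),
                  levels = vapply(profiles, `[[`, "", "name"))
  list(h = h, label = label)
}

# Dirichlet draws via normalised gammas; alpha components equal to 0 give
# exact zeros
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Define a synthetic slide layout
#'
#' A layout is the slide's bounding box plus a set of non-overlapping
#' axis-aligned rectangular regions, each filled by one archetype.
#'
#' @param width_um,height_um Positive slide dimensions in micrometres.
#' @param regions Data frame with columns `xmin`, `xmax`, `ymin`, `ymax`
#'   (micrometres) and `archetype` (a name known to
#'   [archetype_profiles()]).
#' @param mask_resolution_um Pixel size of emitted tissue masks
#'   (default 2.2).
#' @return Object of class `slide_layout`.
#' @export
slide_layout <- function(width_um, height_um, regions,
                         mask_resolution_um = 2.2) {
  stopifnot(width_um > 0, height_um > 0, mask_resolution_um > 0,
            is.data.frame(regions), nrow(regions) > 0L)
  needed <- c("xmin", "xmax", "ymin", "ymax", "archetype")
  stopifnot(all(needed %in% names(regions)))
  if (any(regions$xmin < 0 | regions$ymin < 0 |
          regions$xmax > width_um | regions$ymax > height_um |
          regions$xmin >= regions$xmax | regions$ymin >= regions$ymax)) {
    stop("regions must be non-degenerate rectangles inside the slide bounds")
  }
  archetype_profiles(unique(regions$archetype))  # validates names
  structure(list(width_um = width_um, height_um = height_um,
                 regions = regions,
                 mask_resolution_um = mask_resolution_um),
            class = "slide_layout")
}

#' Generate a synthetic slide: cell map plus tissue mask
#'
#' Within each region of the layout, cells are placed by a homogeneous
#' Poisson point process at the region archetype's density, with
#' independent type marks drawn from its cell mixture. The tissue mask
#' labels each pixel (by pixel-center containment) with the appearance
#' class of its region, and background elsewhere.
#'
#' @param layout A [slide_layout()].
#' @param case_id Case identifier written into the cell map.
#' @param seed Integer seed.
#' @param tile_size_um Tile side the densities refer to (default 200).
#' @param density_scale Nonnegative multiplier on every archetype density
#'   (0 gives an empty cell map).
#' @return List with `cells` (cell map data frame; zero rows, with a
#'   message, if every density is 0) and `mask` (a [tissue_mask()]).
#' @export
generate_slide <- function(layout, case_id = "case_1", seed = NULL,
                           tile_size_um = 200, density_scale = 1) {
  stopifnot(density_scale >= 0)
  stopifnot(inherits(layout, "slide_layout"))
  rng <- local_rng(seed)
  profiles <- archetype_profiles(unique(layout$regions$archetype))
  parts <- lapply(seq_len(nrow(layout$regions)), function(i) {
    reg <- layout$regions[i, ]
    pr <- profiles[[reg$archetype]]
    area <- (reg$xmax - reg$xmin) * (reg$ymax - reg$ymin)
    intensity <- density_scale * pr$density / tile_size_um^2
    n <- rng$draw(function() stats::rpois(1L, intensity * area))
    if (n == 0L) return(NULL)
    rng$draw(function() data.frame(
      case_id = case_id,
      x_um = stats::runif(n, reg$xmin, reg$xmax),
      y_um = stats::runif(n, reg$ymin, reg$ymax),
      cell_type = sample(cell_types(), n, replace = TRUE,
                         prob = pr$cell_mixture),
      stringsAsFactors = FALSE))
  })
  cells <- do.call(rbind, parts)
  if (is.null(cells)) {
    message("generated slide has no cells (zero density everywhere)")
    cells <- data.frame(case_id = character(0), x_um = numeric(0),
                        y_um = numeric(0), cell_type = character(0),
                        stringsAsFactors = FALSE)
  }
  mask <- layout_mask(layout, profiles)
  list(cells = cells, mask = mask)
}

# rasterise the layout's regions into a label matrix; label values are the
# fixed positions of ap_classes() minus one (background = 0)
layout_mask <- function(layout, profiles) {
  upp <- layout$mask_resolution_um
  nc <- ceiling(layout$width_um / upp)
  nr <- ceiling(layout$height_um / upp)
  labels <- matrix(0L, nrow = nr, ncol = nc)
  cx <- (seq_len(nc) - 0.5) * upp
  cy <- (seq_len(nr) - 0.5) * upp
  class_codes <- stats::setNames(seq_along(ap_classes()) - 1L, ap_classes())
  for (i in seq_len(nrow(layout$regions))) {
    reg <- layout$regions[i, ]
    code <- class_codes[[profiles[[reg$archetype]]$ap_class]]
    rows <- which(cy >= reg$ymin & cy < reg$ymax)
    cols <- which(cx >= reg$xmin & cx < reg$xmax)
    labels[rows, cols] <- code
  }
  tissue_mask(labels, stats::setNames(ap_classes(), class_codes), upp)
}

#' Configuration for the synthetic clinical cohort
#'
#' @param n_cases Number of cases (>= 0).
#' @param beta Named numeric vector: planted logistic coefficient per
#'   feature, on the per-interquartile-range scale (an interquartile change
#'   of the feature multiplies the odds of 5-year metastasis by
#'   `exp(beta)`).
#' @param log_hazard Named numeric vector: planted Cox coefficient per
#'   feature, per interquartile range.
#' @param beta0 Logistic intercept (default `qlogis(0.26)`, matching a
#'   roughly 26% metastasis prevalence).
#' @param baseline_hazard Events per year under a zero linear predictor
#'   (default 0.1; must be positive).
#' @param censor_time_years Administrative censoring horizon (default 5).
#' @param missing_rate Per-variable completely-at-random missingness
#'   probability in `[0, 1)` applied to feature columns (default 0).
#' @param seed Integer seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_cases, beta = numeric(0),
                          log_hazard = numeric(0),
                          beta0 = stats::qlogis(0.26),
                          baseline_hazard = 0.1, censor_time_years = 5,
                          missing_rate = 0, seed = NULL) {
  stopifnot(n_cases >= 0, baseline_hazard > 0,
            missing_rate >= 0, missing_rate < 1, censor_time_years >= 0)
  if (!all(is.finite(c(beta, log_hazard, beta0)))) {
    stop("planted coefficients must be finite")
  }
  structure(list(n_cases = as.integer(n_cases), beta = beta,
                 log_hazard = log_hazard, beta0 = beta0,
                 baseline_hazard = baseline_hazard,
                 censor_time_years = censor_time_years,
                 missing_rate = missing_rate, seed = seed),
            class = "cohort_config")
}

#' Generate a synthetic clinical cohort with planted effects
#'
#' Produces a cohort table with clinical covariates (two-institute cohort
#' indicator, differentiation, histological type, T stage, drawn with
#' marginals resembling a two-centre colorectal series), a binary 5-year
#' metastasis outcome drawn from a logistic model with the planted
#' per-interquartile coefficients `beta`, and distant-metastasis-free
#' survival from an exponential proportional-hazards model with
#' coefficients `log_hazard`, administratively censored at
#' `censor_time_years`. Missingness is injected completely at random at
#' `missing_rate` into the feature columns.
#'
#' Planted coefficients are interpreted per interquartile range of the
#' realised feature, so the interquartile effect-factor estimates of the
#' analysis stage (`exp(beta_hat * (Q3 - Q1))`) are directly comparable to
#' `exp(beta)`.
#'
#' @param config A [cohort_config()].
#' @param feature_table Optional data frame of features with `n_cases`
#'   rows (a `case_id` column is aligned if present); by default every
#'   feature named in `beta`/`log_hazard` is drawn i.i.d. Beta(2, 5), a
#'   right-skewed ratio-like distribution on `[0, 1]`.
#' @return Cohort data frame: `case_id`, `cohort`, `differentiation`,
#'   `histological_type`, `t_stage`, feature columns, `metastasis_5yr`,
#'   `dmfs_time_years`, `dmfs_event`.
#' @export
generate_cohort <- function(config, feature_table = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_cases
  rng <- local_rng(config$seed)
  feature_names <- union(names(config$beta), names(config$log_hazard))

  if (is.null(feature_table)) {
    feature_table <- as.data.frame(stats::setNames(
      lapply(feature_names,
             function(f) rng$draw(function() stats::rbeta(n, 2, 5))),
      feature_names))
    if (n == 0L && length(feature_names) == 0L) {
      feature_table <- data.frame(row.names = integer(0))
    }
  } else {
    if (nrow(feature_table) != n) {
      stop("feature_table must have n_cases = ", n, " rows")
    }
    missing_features <- setdiff(feature_names, names(feature_table))
    if (length(missing_features) > 0L) {
      stop("feature_table lacks planted-effect columns: ",
           paste(missing_features, collapse = ", "))
    }
  }
  case_id <- if (!is.null(feature_table$case_id)) {
    feature_table$case_id
  } else {
    sprintf("case_%04d", seq_len(n))
  }
  feats <- feature_table[, setdiff(names(feature_table), "case_id"),
                         drop = FALSE]

  clinical <- rng$draw(function() data.frame(
    cohort = sample(c("site_A", "site_B"), n, replace = TRUE,
                    prob = c(72, 30)),
    differentiation = sample(c("WD/MD", "PD"), n, replace = TRUE,
                             prob = c(69, 20)),
    histological_type = sample(c("adenocarcinoma", "mucinous"), n,
                               replace = TRUE, prob = c(89, 12)),
    t_stage = sample(c("pT3", "pT4"), n, replace = TRUE, prob = c(82, 20)),
    stringsAsFactors = FALSE))

  lp_logit <- rep(config$beta0, n)
  for (f in names(config$beta)) {
    lp_logit <- lp_logit + per_iqr_coef(config$beta[[f]], feats[[f]]) * feats[[f]]
  }
  metastasis_5yr <- rng$draw(function() {
    stats::rbinom(n, 1L, stats::plogis(lp_logit))
  })

  lp_surv <- rep(0, n)
  for (f in names(config$log_hazard)) {
    lp_surv <- lp_surv + per_iqr_coef(config$log_hazard[[f]], feats[[f]]) * feats[[f]]
  }
  t_event <- rng$draw(function() {
    stats::rexp(n, rate = config$baseline_hazard * exp(lp_surv))
  })
  dmfs_time_years <- pmin(t_event, config$censor_time_years)
  dmfs_event <- as.integer(t_event <= config$censor_time_years)

  out <- data.frame(case_id = case_id, clinical, feats,
                    metastasis_5yr = metastasis_5yr,
                    dmfs_time_years = dmfs_time_years,
                    dmfs_event = dmfs_event,
                    stringsAsFactors = FALSE)
  if (config$missing_rate > 0 && ncol(feats) > 0L) {
    for (f in names(feats)) {
      drop_idx <- rng$draw(function() {
        which(stats::runif(n) < config$missing_rate)
      })
      out[[f]][drop_idx] <- NA
    }
  }
  out
}

# convert a per-IQR coefficient to the raw feature scale
per_iqr_coef <- function(coef_iqr, x) {
  iqr <- stats::IQR(x, na.rm = TRUE)
  if (iqr == 0) stop("feature has zero interquartile range; ",
                     "a per-IQR coefficient cannot be planted")
  coef_iqr / iqr
}

#' Generate an end-to-end synthetic study
#'
#' Builds per-case slides whose archetype composition varies across cases
#' (each case's tile grid is filled with archetypes drawn from a
#' case-specific Dirichlet share vector) and draws clinical outcomes whose
#' planted coefficients act on the true per-case archetype shares. The
#' result exercises the whole pipeline: the phenotype ratios recovered from
#' the cell maps estimate the true shares, and the effect estimates of the
#' analysis stage should recover the planted directions.
#'
#' @param n_cases Number of cases.
#' @param beta,log_hazard Named by archetype: planted per-IQR coefficients
#'   on the true archetype shares (see [generate_cohort()]).
#' @param slide_tiles_x,slide_tiles_y Tile-grid dimensions of each slide
#'   (default 4 x 4 tiles of 200 um).
#' @param share_concentration Dirichlet concentration of the per-case
#'   archetype shares (default 2; smaller = more between-case contrast).
#' @param tile_size_um Tile side in micrometres.
#' @param seed Integer seed.
#' @param baseline_hazard,censor_time_years,missing_rate,beta0 Passed to
#'   [cohort_config()].
#' @return List with `cells` (pooled cell map of all cases), `clinical`
#'   (cohort table joined with the true shares as `share_<archetype>`
#'   columns), and `truth` (matrix of true shares).
#' @export
generate_study <- function(n_cases, beta = numeric(0),
                           log_hazard = numeric(0), slide_tiles_x = 4,
                           slide_tiles_y = 4, share_concentration = 2,
                           tile_size_um = 200, seed = NULL,
                           baseline_hazard = 0.1, censor_time_years = 5,
                           missing_rate = 0, beta0 = stats::qlogis(0.26)) {
  profiles <- archetype_profiles()
  arch_names <- names(profiles)
  rng <- local_rng(seed)
  shares <- rng$draw(function() {
    rdirichlet(n_cases, rep(share_concentration, length(arch_names)))
  })
  colnames(shares) <- arch_names

  cell_parts <- vector("list", n_cases)
  n_tiles <- slide_tiles_x * slide_tiles_y
  for (i in seq_len(n_cases)) {
    tile_arch <- rng$draw(function() {
      sample(arch_names, n_tiles, replace = TRUE, prob = shares[i, ])
    })
    grid <- expand.grid(col = seq_len(slide_tiles_x) - 1L,
                        row = seq_len(slide_tiles_y) - 1L)
    regions <- data.frame(
      xmin = grid$col * tile_size_um, xmax = (grid$col + 1L) * tile_size_um,
      ymin = grid$row * tile_size_um, ymax = (grid$row + 1L) * tile_size_um,
      archetype = tile_arch, stringsAsFactors = FALSE)
    layout <- slide_layout(slide_tiles_x * tile_size_um,
                           slide_tiles_y * tile_size_um, regions)
    slide <- generate_slide(layout, case_id = sprintf("case_%04d", i),
                            seed = rng$int(), tile_size_um = tile_size_um)
    cell_parts[[i]] <- slide$cells
  }
  cells <- do.call(rbind, cell_parts)

  share_df <- as.data.frame(shares)
  names(share_df) <- paste0("share_", arch_names)
  rename <- function(v) {
    if (length(v) == 0L) return(v)
    stats::setNames(v, paste0("share_", names(v)))
  }
  config <- cohort_config(n_cases, beta = rename(beta),
                          log_hazard = rename(log_hazard), beta0 = beta0,
                          baseline_hazard = baseline_hazard,
                          censor_time_years = censor_time_years,
                          missing_rate = missing_rate, seed = rng$int())
  share_df$case_id <- sprintf("case_%04d", seq_len(n_cases))
  clinical <- generate_cohort(config, feature_table = share_df)
  list(cells = cells, clinical = clinical, truth = shares)
}
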