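#' Resolved run configuration
#'
#' Collects every tunable of an end-to-end run, with defaults matching the
#' published analysis constants: 200 um tiles, chi-squared k-medoids with
#' 100 restarts, phenotype-count thresholds 0.2 (distance) and 0.8
#' (correlation), 10-90% cutoff window, 100 imputations and 100 bootstrap
#' replicates.
#'
#' @param cells Cell-map table path or data frame.
#' @param clinical Optional clinical table path or data frame (columns
#'   `case_id`, optional `metastasis_5yr`, `dmfs_time_years`,
#'   `dmfs_event`, adjusters).
#' @param masks_dir Optional directory of per-case tissue masks
#'   (`<case_id>.png` plus sidecars).
#' @param tile_size_um,min_cells Tiling parameters.
#' @param k Phenotype count; `NULL` selects k by [select_k()] over
#'   `k_range`.
#' @param k_range,dist_threshold,corr_threshold k-selection parameters.
#' @param restarts k-medoids restarts.
#' @param quantile_window Cutoff-scan window.
#' @param m Imputation count (used when the clinical table has missing
#'   values).
#' @param n_boot Bootstrap replicates for Cox AUCs.
#' @param seed Root seed; every stage derives its own stream from it.
#' @param out_dir Output directory; `NULL` keeps results in memory only.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cells, clinical = NULL, masks_dir = NULL,
                       tile_size_um = 200, min_cells = 5, k = NULL,
                       k_range = 2:10, dist_threshold = 0.2,
                       corr_threshold = 0.8, restarts = 100,
                       quantile_window = c(0.1, 0.9), m = 100,
                       n_boot = 100, seed = 1L, out_dir = NULL) {
  structure(list(cells = cells, clinical = clinical, masks_dir = masks_dir,
                 tile_size_um = tile_size_um, min_cells = min_cells,
                 k = k, k_range = k_range, dist_threshold = dist_threshold,
                 corr_threshold = corr_threshold, restarts = restarts,
                 quantile_window = quantile_window, m = m, n_boot = n_boot,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Write or read a run configuration as plain text
#'
#' Scalar and vector fields are stored as `key=value` lines
#' (comma-separated for vectors); table inputs given as data frames are
#' not serialised and must be re-supplied.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  fields <- config[!vapply(config, is.data.frame, logical(1L))]
  fields <- fields[!vapply(fields, is.null, logical(1L))]
  lines <- vapply(names(fields), function(k) {
    paste0(k, "=", paste(fields[[k]], collapse = ","))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, function(p) {
    v <- strsplit(p[[2L]], ",", fixed = TRUE)[[1L]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  }), vapply(kv, `[[`, "", 1L))
  defaults <- formals(run_config)
  args <- vals[names(vals) %in% names(defaults)]
  do.call(run_config, args)
}

#' Run the full tissue-phenotyping pipeline
#'
#' Executes, in order: cell-map loading, tiling and per-tile connection
#' frequencies, phenotype clustering (fixed k or automatic selection),
#' tile assignment, per-case feature computation (with appearance masks
#' when available), and — when a clinical table is supplied — the
#' prognostic analyses: univariate and adjusted logistic effects per CF
#' feature when the metastasis outcome is present, and univariate Cox
#' effects when the survival outcome is present. Any stage failure aborts
#' with a stage-prefixed error.
#'
#' @param config A [run_config()].
#' @return List with `config`, `tile_table`, `model` (named
#'   `phenotype_model`), `selection` (the `k_selection`, or `NULL` when k
#'   was fixed), `features` (per-case feature table), `cohort` (features
#'   joined with clinical), and `effects` (data frame of effect
#'   estimates, or `NULL`). When `config$out_dir` is set, the resolved
#'   config, tables, model and a run manifest are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rng <- local_rng(config$seed)
  stage <- function(name, expr_fun) {
    tryCatch(expr_fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cells <- stage("input", function() {
    if (is.character(config$cells)) read_cell_map(config$cells)
    else validate_cells(config$cells)
  })
  clinical <- stage("input", function() {
    if (is.null(config$clinical)) NULL
    else if (is.character(config$clinical)) {
      utils::read.csv(config$clinical, stringsAsFactors = FALSE,
                      na.strings = "")
    } else config$clinical
  })

  tile_table <- stage("network", function() {
    tile_frequencies(cells, tile_size_um = config$tile_size_um,
                     min_cells = config$min_cells)
  })
  x <- frequency_matrix(tile_table)
  case_ids <- tile_table$case_id[tile_table$phenotyped]

  selection <- NULL
  model <- stage("phenotype", function() {
    if (!is.null(config$k)) {
      kmedoids(x, config$k, n_restarts = config$restarts, seed = rng$int())
    } else {
      selection <<- select_k(x, case_ids, k_range = config$k_range,
                             dist_threshold = config$dist_threshold,
                             corr_threshold = config$corr_threshold,
                             n_restarts = config$restarts, seed = rng$int())
      if (is.na(selection$selected_k)) {
        stop("no admissible phenotype count in the range tried")
      }
      selection$models[[as.character(selection$selected_k)]]
    }
  })
  model <- name_phenotypes(model)
  labels <- assign_phenotypes(model, x)

  features <- stage("features", function() {
    rows <- lapply(split(seq_len(nrow(tile_table)), tile_table$case_id),
                   function(idx) {
      tt <- tile_table[idx, , drop = FALSE]
      cid <- tt$case_id[1L]
      lab <- labels[match(idx[tile_table$phenotyped[idx]],
                          which(tile_table$phenotyped))]
      mask <- NULL
      if (!is.null(config$masks_dir)) {
        mask_path <- file.path(config$masks_dir, paste0(cid, ".png"))
        if (file.exists(mask_path)) mask <- read_tissue_mask(mask_path)
      }
      case_features(cid, tt, lab, model$k,
                    cells[cells$case_id == cid, , drop = FALSE],
                    mask = mask, tile_size_um = config$tile_size_um)
    })
    build_feature_table(unname(rows), k = model$k)
  })

  cohort <- NULL
  effects <- NULL
  if (!is.null(clinical)) {
    cohort <- stage("join", function() {
      merge(features, clinical, by = "case_id", sort = TRUE)
    })
    effects <- stage("stats", function() {
      pipeline_effects(cohort, model, n_boot = config$n_boot,
                       seed = rng$int())
    })
  }

  result <- list(config = config, tile_table = tile_table, model = model,
                 selection = selection, features = features,
                 cohort = cohort, effects = effects)
  if (!is.null(config$out_dir)) {
    stage("output", function() write_pipeline_outputs(result))
  }
  result
}

# univariate + adjusted effect table over the CF ratio features
pipeline_effects <- function(cohort, model, n_boot = 100, seed = NULL) {
  rng <- local_rng(seed)
  feats <- grep("^cf_ratio_", names(cohort), value = TRUE)
  adjusters <- intersect(c("differentiation", "histological_type",
                           "t_stage"), names(cohort))
  adjusters <- adjusters[vapply(adjusters, function(a) {
    length(unique(stats::na.omit(cohort[[a]]))) > 1L
  }, logical(1L))]
  rows <- list()
  has_logistic <- "metastasis_5yr" %in% names(cohort) &&
    length(unique(stats::na.omit(cohort$metastasis_5yr))) == 2L
  has_cox <- all(c("dmfs_time_years", "dmfs_event") %in% names(cohort)) &&
    sum(cohort$dmfs_event, na.rm = TRUE) >= 1
  for (f in feats) {
    if (all(is.na(cohort[[f]])) || stats::var(cohort[[f]], na.rm = TRUE) == 0) next
    if (has_logistic) {
      rows <- c(rows, list(effect_row(
        logistic_iqr_effect(cohort, f), "logistic_univariate")))
      if (length(adjusters) > 0L) {
        rows <- c(rows, list(effect_row(
          logistic_iqr_effect(cohort, f, adjusters),
          "logistic_multivariate")))
      }
    }
    if (has_cox) {
      rows <- c(rows, list(effect_row(
        cox_iqr_effect(cohort, f, n_boot = n_boot, seed = rng$int()),
        "cox_univariate")))
    }
  }
  do.call(rbind, rows)
}

effect_row <- function(est, analysis) {
  data.frame(feature = est$feature, analysis = analysis,
             baseline_value = as.character(est$baseline_value),
             changed_value = as.character(est$changed_value),
             ratio_factor = est$ratio_factor, ci_low = est$ci_low,
             ci_high = est$ci_high, p_value = est$p_value,
             p_type = est$p_type, auc = est$auc, n = est$n,
             status = est$status, stringsAsFactors = FALSE)
}

write_pipeline_outputs <- function(result) {
  out <- result$config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_run_config(result$config, file.path(out, "resolved_config.txt"))
  utils::write.csv(result$tile_table, file.path(out, "tile_table.csv"),
                   row.names = FALSE, quote = FALSE)
  write_feature_table(result$features, file.path(out, "feature_table.csv"))
  write_phenotype_model(result$model, file.path(out, "phenotype_model.json"))
  if (!is.null(result$effects)) {
    utils::write.csv(result$effects, file.path(out, "effects.csv"),
                     row.names = FALSE, na = "")
  }
  manifest <- list(
    package = "phenotile",
    version = as.character(utils::packageVersion("phenotile")),
    r_version = R.version.string,
    seed = result$config$seed,
    n_cases = length(unique(result$tile_table$case_id)),
    n_tiles = nrow(result$tile_table),
    k = result$model$k,
    input_digest = if (is.character(result$config$cells)) {
      unname(tools::md5sum(result$config$cells))
    } else NA,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out, "run_manifest.json"))
  invisible(out)
}
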