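# End-to-end pipeline: simulate (or load) -> morphological features ->
# dynamic features -> statistical report, with a reproducibility manifest.
# Every stage writes plain CSV/NIfTI to disk so any stage can be rerun
# standalone.

#' Read a pipeline configuration (JSON or YAML)
#'
#' A config either requests synthetic generation
#' (`synthetic: {n_metastatic, n_nonmetastatic, reader2_jitter}`) or points
#' at external inputs (`masks_dir`, `curves_csv`, `labels_csv`; any subset).
#' Analysis settings: `folds`, `operating_point`, `entropy_bins`.
#'
#' @param path `.json`, `.yaml`/`.yml` file.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Extract morphological features for a directory of masks
#'
#' @param masks_dir Directory of `.nii`/`.nii.gz` masks named
#'   `<node_id>_<reader_id>.nii[.gz]` (or `<node_id>.nii[.gz]`, read as
#'   reader1).
#' @param out_csv Output CSV path (17 canonical feature columns + node_id,
#'   reader_id + radial_length_mm).
#' @param bins Entropy bins.
#' @return The feature data.frame, invisibly written to `out_csv`.
#' @export
extract_morph_dir <- function(masks_dir, out_csv, bins = 128L) {
  files <- list.files(masks_dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  if (!length(files)) stop("no NIfTI masks in ", masks_dir)
  masks <- lapply(files, function(f) {
    stem <- sub("\\.nii(\\.gz)?$", "", basename(f))
    parts <- strsplit(stem, "_")[[1]]
    if (length(parts) >= 2 && grepl("^reader", parts[length(parts)])) {
      read_mask(f, node_id = paste(parts[-length(parts)], collapse = "_"),
                reader_id = parts[length(parts)])
    } else {
      read_mask(f, node_id = stem)
    }
  })
  feats <- batch_morph(masks, bins = bins)
  utils::write.csv(feats, out_csv, row.names = FALSE, quote = FALSE)
  invisible(feats)
}

#' Extract dynamic features for a curves CSV
#'
#' @param curves_csv CSV with columns `node_id,time_s,signal`.
#' @param out_csv Output CSV path (9 canonical feature columns + node_id).
#' @return The feature data.frame, invisibly written to `out_csv`.
#' @export
extract_dyn_csv <- function(curves_csv, out_csv) {
  curves <- read_curves_csv(curves_csv)
  feats <- batch_dynamic(curves)
  utils::write.csv(feats, out_csv, row.names = FALSE, quote = FALSE)
  invisible(feats)
}

#' Statistical analysis stage
#'
#' Joins feature tables with labels and writes the four report tables
#' (`table2.csv` morphological group stats, `table3.csv` dynamic group
#' stats, `table4.csv` per-feature ROC, `table5.csv` LDA) plus
#' `analysis_meta.json`.
#'
#' @param features Data.frame (or CSV path) with node_id + feature columns;
#'   morphological, dynamic or both.
#' @param labels Data.frame (or CSV path) `node_id,label`.
#' @param out_dir Report directory.
#' @param folds,seed,operating_point Cross-validation / ROC settings.
#' @return The [report_tables()] list, invisibly.
#' @export
analyze_cohort <- function(features, labels, out_dir, folds = 10L,
                           seed = 17L,
                           operating_point = c("youden", "accuracy")) {
  operating_point <- match.arg(operating_point)
  if (is.character(features)) features <- utils::read.csv(features, stringsAsFactors = FALSE)
  if (is.character(labels)) labels <- read_labels_csv(labels)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- merge(features, labels[, c("node_id", "label")], by = "node_id")
  if (!nrow(tab)) stop("no overlap between feature table and labels")
  rep <- report_tables(tab, k = folds, seed = seed,
                       operating_point = operating_point)
  if (!is.null(rep$group_morph)) {
    utils::write.csv(rep$group_morph, file.path(out_dir, "table2.csv"),
                     row.names = FALSE)
  }
  if (!is.null(rep$group_dyn)) {
    utils::write.csv(rep$group_dyn, file.path(out_dir, "table3.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(rep$roc, file.path(out_dir, "table4.csv"), row.names = FALSE)
  utils::write.csv(rep$lda, file.path(out_dir, "table5.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(folds = folds, seed = seed, operating_point = operating_point,
         n_rows = nrow(tab),
         significant_features = rep$significant_features),
    file.path(out_dir, "analysis_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(rep)
}

#' Run the full pipeline
#'
#' simulate (or load external inputs) -> extract-morph -> extract-dyn ->
#' analyze, writing feature CSVs, report tables and a run manifest
#' (`manifest.json`: config hash, seed, package version, per-stage timings,
#' output checksums, warnings).
#'
#' @param config Path to a JSON/YAML config, or an equivalent named list.
#' @param out_dir Output directory.
#' @param seed Seed overriding the config's (optional).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed %||% cfg$seed %||% 17L)
  folds <- as.integer(cfg$folds %||% 10L)
  op <- cfg$operating_point %||% "youden"
  bins <- as.integer(cfg$entropy_bins %||% 128L)
  warnings_log <- character(0)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- as.numeric(Sys.time() - t0, units = "secs")
    res
  }

  masks_dir <- cfg$masks_dir
  curves_csv <- cfg$curves_csv
  labels_csv <- cfg$labels_csv
  if (!is.null(cfg$synthetic)) {
    sim <- stage("simulate", {
      sc <- cohort_config(
        n_metastatic = cfg$synthetic$n_metastatic %||% 48L,
        n_nonmetastatic = cfg$synthetic$n_nonmetastatic %||% 46L,
        seed = seed,
        reader2_jitter = cfg$synthetic$reader2_jitter %||% 0.08)
      cohort <- generate_cohort(sc)
      write_cohort(cohort, file.path(out_dir, "cohort"))
      cohort
    })
    masks_dir <- file.path(out_dir, "cohort", "masks")
    curves_csv <- file.path(out_dir, "cohort", "curves.csv")
    labels_csv <- file.path(out_dir, "cohort", "labels.csv")
  }
  if (is.null(labels_csv)) stop("config must provide labels (or synthetic generation)")
  labels <- read_labels_csv(labels_csv)

  feats <- NULL
  if (!is.null(masks_dir)) {
    morph <- stage("extract_morph", {
      extract_morph_dir(masks_dir, file.path(out_dir, "features_morph.csv"),
                        bins = bins)
    })
    feats <- morph[morph$reader_id == sort(unique(morph$reader_id))[1],
                   setdiff(names(morph), c("reader_id", "radial_length_mm")),
                   drop = FALSE]
  } else {
    warnings_log <- c(warnings_log,
                      "no masks provided: morphological features skipped")
  }
  if (!is.null(curves_csv)) {
    dyn <- stage("extract_dyn", {
      extract_dyn_csv(curves_csv, file.path(out_dir, "features_dyn.csv"))
    })
    feats <- if (is.null(feats)) dyn else merge(feats, dyn, by = "node_id")
  } else {
    warnings_log <- c(warnings_log,
                      "no curves provided: dynamic features skipped")
  }
  if (is.null(feats)) stop("config must provide masks and/or curves")

  n_missing <- sum(!is.finite(as.matrix(feats[, setdiff(names(feats), "node_id")])))
  if (n_missing > 0) {
    warnings_log <- c(warnings_log,
                      sprintf("%d missing-coded feature values", n_missing))
  }

  stage("analyze", {
    analyze_cohort(feats, labels, file.path(out_dir, "report"),
                   folds = folds, seed = seed, operating_point = op)
  })

  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  checksums <- as.list(tools::md5sum(outputs))
  names(checksums) <- sub(paste0("^", gsub("([^A-Za-z0-9])", "\\\\\\1", out_dir), "/?"),
                          "", names(checksums))
  manifest <- list(
    package_version = as.character(utils::packageVersion("noderadiomics")),
    seed = seed,
    config_hash = {
      tf <- tempfile()
      jsonlite::write_json(cfg, tf, auto_unbox = TRUE)
      unname(tools::md5sum(tf))
    },
    timings_s = timings,
    warnings = warnings_log,
    outputs = checksums)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
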