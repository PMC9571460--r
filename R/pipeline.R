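#' Resolved pipeline configuration
#'
#' Collects every tunable constant of the pipeline with the standard
#' defaults (37.79528 px/cm, 60 fps, likelihood cutoff 0.95, swing
#' threshold 10 cm/s, misstep depth 0.5 cm, 75/25 split, 100 trees,
#' top-20 overlap, 5 PCA features). A YAML file, when given, overrides
#' individual entries; per-view `px_per_cm` overrides are supported
#' under `calibration$px_per_cm_by_view`.
#'
#' @param path Optional YAML config file.
#' @param ... Named overrides applied after the file (e.g.
#'   `segmentation = list(speed_threshold = 12)`).
#' @return Object of class `pipeline_config` (nested list with blocks
#'   `calibration`, `segmentation`, `ladder`, `ml`).
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    calibration = list(px_per_cm = 37.79528, fps = 60,
                       likelihood_threshold = 0.95, confidence_dist_px = 17,
                       px_per_cm_by_view = NULL),
    segmentation = list(speed_threshold = 10, smooth = 3L, min_phase = 3L),
    ladder = list(depth_cm = 0.5, rung_y = NULL, merge_gap = 5L,
                  min_len = 2L),
    ml = list(split = 0.75, trees = 100L, top_k = 20L, pca_features = 5L,
              seed = 1L))
  merge <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        base[[nm]] <- merge(base[[nm]], upd[[nm]])
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  if (!is.null(path)) cfg <- merge(cfg, yaml::read_yaml(path))
  cfg <- merge(cfg, list(...))
  structure(cfg, class = "pipeline_config")
}

.config_calibration <- function(config, view = NULL) {
  cb <- config$calibration
  ppc <- cb$px_per_cm
  if (!is.null(view) && !is.null(cb$px_per_cm_by_view) &&
      !is.null(cb$px_per_cm_by_view[[view]]))
    ppc <- cb$px_per_cm_by_view[[view]]
  gait_calibration(px_per_cm = ppc, fps = cb$fps,
                   likelihood_threshold = cb$likelihood_threshold,
                   confidence_dist_px = cb$confidence_dist_px)
}

# parse <animal>_<timepoint>_<run>_<view>.csv
.parse_run_filename <- function(f) {
  base <- sub("\\.csv$", "", basename(f))
  parts <- strsplit(base, "_")[[1L]]
  if (length(parts) < 4L) return(NULL)
  view <- parts[length(parts)]
  if (!view %in% c("left", "right", "bottom")) return(NULL)
  list(animal = parts[1L],
       timepoint = paste(parts[2:(length(parts) - 2L)], collapse = "_"),
       run = parts[length(parts) - 1L], view = view,
       key = paste(parts[-length(parts)], collapse = "_"))
}

#' Extract features from a directory of keypoint tables
#'
#' Scans `input_dir` for files named `<animal>_<timepoint>_<run>_<view>.csv`
#' in the DeepLabCut dialect, computes the per-run gait parameters and
#' aggregates them into the labelled feature table. Unreadable runs are
#' skipped with a logged reason. When `output_dir` is given, writes
#' `features.csv`, `runs.csv` (per-run rows), `qc_log.txt` and the
#' resolved configuration (`config.yaml`, including the package
#' version).
#'
#' @param input_dir Directory of per-run view tables.
#' @param config A [pipeline_config()].
#' @param output_dir Optional output directory.
#' @return A `gait_feature_table`; attribute `"log"` carries the
#'   per-run QC lines, attribute `"skipped"` the skipped run keys.
#' @export
run_extract <- function(input_dir, config = pipeline_config(),
                        output_dir = NULL) {
  files <- list.files(input_dir, pattern = "\\.csv$", full.names = TRUE)
  meta <- lapply(files, .parse_run_filename)
  keep <- !vapply(meta, is.null, logical(1))
  files <- files[keep]; meta <- meta[keep]
  if (!length(files)) stop("no run tables found in ", input_dir, call. = FALSE)
  keys <- vapply(meta, `[[`, character(1), "key")
  log <- character(0)
  skipped <- character(0)
  rows <- list()
  for (k in unique(keys)) {
    idx <- which(keys == k)
    m <- meta[[idx[1L]]]
    views <- list()
    ok <- TRUE
    for (i in idx) {
      v <- meta[[i]]$view
      r <- tryCatch(
        read_dlc_table(files[i], view = v,
                       calibration = .config_calibration(config, v),
                       metadata = m[c("animal", "timepoint", "run")]),
        error = function(e) e)
      if (inherits(r, "error")) {
        log <- c(log, sprintf("SKIP %s: %s", k, conditionMessage(r)))
        skipped <- c(skipped, k)
        ok <- FALSE
        break
      }
      views[[v]] <- r
    }
    if (!ok) next
    par <- tryCatch(
      run_parameters(bottom = views$bottom, left = views$left,
                     right = views$right,
                     calibration = .config_calibration(config),
                     speed_threshold = config$segmentation$speed_threshold,
                     likelihood_threshold = config$calibration$likelihood_threshold),
      error = function(e) e)
    if (inherits(par, "error")) {
      log <- c(log, sprintf("SKIP %s: %s", k, conditionMessage(par)))
      skipped <- c(skipped, k)
      next
    }
    qc <- attr(par, "qc")
    ret <- unlist(qc[grepl("retained", names(qc))])
    log <- c(log, sprintf("OK %s: retained %.2f-%.2f, cycles %s", k,
                          min(ret), max(ret),
                          paste(qc$cycle_counts, collapse = "/")))
    rows[[length(rows) + 1L]] <-
      c(list(animal = m$animal, label = m$timepoint, run = m$run), par)
  }
  if (!length(rows)) stop("no readable run in ", input_dir, call. = FALSE)
  tab <- build_feature_table(rows)
  attr(tab, "log") <- log
  attr(tab, "skipped") <- unique(skipped)
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    utils::write.csv(as.data.frame(tab), file.path(output_dir, "features.csv"),
                     row.names = FALSE)
    writeLines(log, file.path(output_dir, "qc_log.txt"))
    cfg <- unclass(config)
    cfg$package_version <- as.character(utils::packageVersion("gaitprofiler"))
    yaml::write_yaml(cfg, file.path(output_dir, "config.yaml"))
  }
  tab
}

#' Profile a feature table: random forest + PCA report
#'
#' @param table A `gait_feature_table` (e.g. from [run_extract()]).
#' @param config A [pipeline_config()]; the `ml` block supplies split,
#'   tree count, PCA feature count and seed.
#' @param labels Optional label subset (subgroup profiling).
#' @param output_dir Optional directory for `importance.csv`,
#'   `confusion.csv`, `pca_scores.csv` and the resolved config.
#' @return List with `report` (a `classifier_report`) and `pca` (a
#'   `gait_pca`).
#' @export
run_report <- function(table, config = pipeline_config(), labels = NULL,
                       output_dir = NULL) {
  stopifnot(inherits(table, "gait_feature_table"))
  if (!is.null(labels)) table <- filter_labels(table, labels)
  ml <- config$ml
  rep <- rf_profile(table, split = ml$split, n_trees = ml$trees,
                    seed = ml$seed)
  pca <- pca_top(table, rep$importance, n_features = ml$pca_features)
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    imp <- sort(rep$importance, decreasing = TRUE)
    utils::write.csv(data.frame(feature = names(imp), importance = imp,
                                row.names = NULL),
                     file.path(output_dir, "importance.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(rep$confusion),
                     file.path(output_dir, "confusion.csv"),
                     row.names = FALSE)
    utils::write.csv(pca$scores, file.path(output_dir, "pca_scores.csv"),
                     row.names = FALSE)
    cfg <- unclass(config)
    cfg$package_version <- as.character(utils::packageVersion("gaitprofiler"))
    yaml::write_yaml(cfg, file.path(output_dir, "config.yaml"))
  }
  list(report = rep, pca = pca)
}
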