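#' Configure an end-to-end phantom pipeline run
#'
#' Bundles every knob of the offline workflow: phantom generation,
#' simulated network-failure corruption, refinement, labeling approach(es)
#' and evaluation. The bundled corruption model plays the role of the
#' network plug-in, so the whole pipeline runs without scans or weights; a
#' real inference command mapping a volume to the two labelmaps can be
#' substituted upstream and its outputs fed to [sequential_approach()] /
#' [combined_approach()] directly.
#'
#' @param out_dir Output directory (created if needed).
#' @param phantom A [phantom_spec()].
#' @param corruption A [corruption_spec()].
#' @param refine A [refine_config()].
#' @param approaches Subset of `c("sequential", "combined")`.
#' @param target_spacing_mm Working isotropic voxel size, mm.
#' @param exclude_partial Exclude edge-contacting vertebrae from scoring.
#' @param write_volumes Also write the phantom volume and labelmaps as
#'   NIfTI.
#' @param seed Master seed; reseeds the phantom (`seed`) and the corruption
#'   (`seed + 1`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, phantom = phantom_spec(),
                            corruption = corruption_spec(),
                            refine = refine_config(),
                            approaches = c("sequential", "combined"),
                            target_spacing_mm = 1, exclude_partial = TRUE,
                            write_volumes = TRUE, seed = 1) {
  approaches <- match.arg(approaches, several.ok = TRUE)
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(corruption, "corruption_spec"),
            inherits(refine, "refine_config"), target_spacing_mm > 0)
  phantom$seed <- as.integer(seed)
  corruption$seed <- as.integer(seed) + 1L
  structure(list(out_dir = out_dir, phantom = phantom,
                 corruption = corruption, refine = refine,
                 approaches = approaches,
                 target_spacing_mm = target_spacing_mm,
                 exclude_partial = exclude_partial,
                 write_volumes = isTRUE(write_volumes),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end phantom pipeline
#'
#' Phantom generation, corruption into simulated network predictions,
#' refinement, level assignment by the selected approach(es), per-vertebra
#' scoring, and (when both approaches run) a paired Wilcoxon comparison of
#' their Dice and Hausdorff values. Writes labelmaps (NIfTI), instance and
#' metrics tables (CSV) and a JSON run log embedding the resolved
#' configuration, its hash, and every destructive refinement action.
#' Deterministic given the configuration.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list: `metrics` (named list of `metrics_tbl`),
#'   `accuracy` (tibble per approach), `comparison` (tibble or `NULL`),
#'   `paths` (written files).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  ph <- generate_phantom(config$phantom)
  pred <- corrupt_prediction(ph$instances, ph$levels, config$corruption)

  t <- config$target_spacing_mm
  gt <- resample_isotropic(ph$instances, t)
  binary <- resample_isotropic(pred$binary, t)
  level <- resample_isotropic(pred$level, t)

  if (config$write_volumes) {
    for (nm in c("volume", "gt_instances", "pred_binary", "pred_level")) {
      p <- file.path(config$out_dir, paste0(nm, ".nii.gz"))
      obj <- switch(nm, volume = resample_isotropic(ph$volume, t),
                    gt_instances = gt, pred_binary = binary,
                    pred_level = level)
      write_nifti(obj, p)
      paths <- c(paths, p)
    }
    p <- file.path(config$out_dir, "gt_levels.csv")
    utils::write.csv(ph$levels, p, row.names = FALSE)
    paths <- c(paths, p)
  }

  metrics <- list()
  accuracy <- list()
  logs <- list()
  for (ap in config$approaches) {
    lseg <- if (ap == "sequential") {
      sequential_approach(binary, level, config$refine)
    } else {
      combined_approach(level, config$refine)
    }
    out_lm <- as_level_labelmap(lseg)
    p1 <- file.path(config$out_dir, paste0(ap, "_labels.nii.gz"))
    write_nifti(out_lm, p1)
    p2 <- file.path(config$out_dir, paste0(ap, "_instances.csv"))
    utils::write.csv(lseg$table, p2, row.names = FALSE)
    m <- match_and_score(lseg, gt, ph$levels,
                         exclude_partial = config$exclude_partial)
    p3 <- file.path(config$out_dir, paste0(ap, "_metrics.csv"))
    utils::write.csv(as.data.frame(m), p3, row.names = FALSE)
    paths <- c(paths, p1, p2, p3)
    metrics[[ap]] <- m
    accuracy[[ap]] <- dplyr::mutate(labeling_accuracy(m), approach = ap,
                                    .before = 1)
    logs[[ap]] <- lseg$log
  }

  comparison <- NULL
  if (length(config$approaches) == 2L) {
    a <- metrics[["sequential"]]; b <- metrics[["combined"]]
    shared <- intersect(a$true_level_code, b$true_level_code)
    a <- a[match(shared, a$true_level_code), ]
    b <- b[match(shared, b$true_level_code), ]
    comparison <- dplyr::bind_rows(
      dplyr::mutate(compare_paired(a$dsc, b$dsc), metric = "dsc", .before = 1),
      if (all(!a$hd_missing) && all(!b$hd_missing)) {
        dplyr::mutate(compare_paired(a$hd_mm, b$hd_mm), metric = "hd_mm",
                      .before = 1)
      }
    )
    p <- file.path(config$out_dir, "approach_comparison.csv")
    utils::write.csv(comparison, p, row.names = FALSE)
    paths <- c(paths, p)
  }

  resolved <- serialize_config(config)
  run_log <- list(
    config = resolved,
    config_hash = rlang::hash(resolved),
    accuracy = dplyr::bind_rows(accuracy),
    refinement_log = lapply(logs, as.data.frame)
  )
  plog <- file.path(config$out_dir, "run_log.json")
  jsonlite::write_json(run_log, plog, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  paths <- c(paths, plog)

  invisible(list(metrics = metrics, accuracy = dplyr::bind_rows(accuracy),
                 comparison = comparison, paths = paths))
}

serialize_config <- function(config) {
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(e) if (inherits(e, c("phantom_spec", "corruption_spec",
                                            "refine_config"))) strip(e) else e)
  }
  strip(config)
}
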