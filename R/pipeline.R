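#' Pipeline configuration
#'
#' One structured configuration object drives [run_pipeline()]. Every
#' numeric default that the underlying method leaves open (QC thresholds,
#' watershed separation, speck size, SVM cost, split fraction) is surfaced
#' here and round-trips losslessly through YAML via [write_config()] /
#' [read_config()].
#'
#' The default scene is a reduced demonstration scale (640 x 480 fields at
#' 1 px/um with ~10 cells per field, 2 fields per patient and 4 patients
#' per class) so a full simulate-to-evaluate run completes in well under a
#' minute; the class-specific atypical-cell probabilities give the cascade
#' real signal to learn. Production-size frames (2592 x 1936 at 1.9 px/um)
#' are a matter of changing `scene`.
#'
#' @param seed Master seed for the whole run.
#' @param scene Named list of [scene_spec()] overrides (scalar fields only).
#' @param atypia_by_class Named per-class probability that a generated cell
#'   is atypical.
#' @param n_patients_per_class,fields_per_patient,cells_per_field Cohort
#'   scale of the simulated study.
#' @param qc Named list of [qc_criteria()] overrides.
#' @param scorer List: `kind` (`"reference_morphometric"`) and `lambda`.
#' @param split_fraction Training fraction for the cascade.
#' @param segmentation Named list of [segment_params()] overrides.
#' @param rounding Percent rounding mode for reports.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            scene = list(image_width = 640, image_height = 480,
                                         fov_radius = 220, pixel_scale = 1,
                                         noise_sd = 5),
                            atypia_by_class = c(BNG = 0.05, LGD = 0.15,
                                                HGD = 0.35, OSCC = 0.65),
                            n_patients_per_class = 4L,
                            fields_per_patient = 2L,
                            cells_per_field = 10L,
                            qc = list(),
                            scorer = list(kind = "reference_morphometric",
                                          lambda = 0.01),
                            split_fraction = 0.5,
                            segmentation = list(),
                            rounding = "integer") {
  cfg <- list(seed = as.integer(seed), scene = scene,
              atypia_by_class = as.list(atypia_by_class),
              n_patients_per_class = as.integer(n_patients_per_class),
              fields_per_patient = as.integer(fields_per_patient),
              cells_per_field = as.integer(cells_per_field),
              qc = qc, scorer = scorer,
              split_fraction = split_fraction,
              segmentation = segmentation, rounding = rounding)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

scene_for_patient <- function(config, class, seed) {
  args <- config$scene
  args$p_atypical <- config$atypia_by_class[[class]]
  args$n_cells <- config$cells_per_field
  args$seed <- seed
  do.call(scene_spec, args)
}

#' Run the full simulate-to-evaluate pipeline
#'
#' Executes simulate -> segment -> qc -> score -> aggregate -> stratify ->
#' evaluate on a synthetic study cohort, writing per-stage artifacts into a
#' run directory: field PNGs, ground-truth and ROI manifests, a QC report,
#' per-cell scores, per-patient features, the serialised cascade model,
#' hold-out predictions, evaluation metrics and a machine-readable run
#' manifest (package version, seeds, per-stage counts, timings). Re-running
#' with the same configuration and seed reproduces every CSV/JSON artifact
#' exactly. Stage failures abort naming the stage.
#'
#' The per-cell scorer is trained inside the run: segmented, QC-passing
#' ROIs are matched back to the generator's ground-truth atypia labels and
#' the morphometric reference scorer is fitted on them, exactly as an
#' image-trained scorer would be slotted into the same contract.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created; must not already contain a run).
#' @return The run directory path, invisibly. The evaluation summary is in
#'   `metrics.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (missing(out_dir)) abort("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "fields"), showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    ts <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            parent = e)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), ts, units = "secs"))
    inform(sprintf("[%s] done in %.1fs", name, timings[[name]]))
    out
  }

  classes <- names(config$atypia_by_class)
  patients <- tibble(
    patient_id = sprintf("P%03d", seq_len(config$n_patients_per_class *
                                            length(classes))),
    class = rep(classes, each = config$n_patients_per_class)
  )

  # ---- simulate -------------------------------------------------------------
  sim <- stage("simulate", {
    fields <- list()
    truth_manifest <- list()
    k <- 0L
    for (i in seq_len(nrow(patients))) {
      for (f in seq_len(config$fields_per_patient)) {
        k <- k + 1L
        seed_k <- derive_seed(config$seed, k)
        spec <- scene_for_patient(config, patients$class[i], seed_k)
        fi <- generate_field_image(spec)
        fi$image$source_id <- sprintf("%s_f%02d", patients$patient_id[i], f)
        write_field_image(fi$image,
                          file.path(out_dir, "fields",
                                    paste0(fi$image$source_id, ".png")))
        fields[[k]] <- list(patient_id = patients$patient_id[i],
                            class = patients$class[i],
                            field = fi)
        truth_manifest[[k]] <- list(
          source_id = fi$image$source_id,
          patient_id = patients$patient_id[i],
          fov = unclass(fi$truth$fov),
          cells = as.list(fi$truth$cells[, c("cell_id", "cx", "cy", "area_px",
                                             "aspect", "atypical")])
        )
      }
    }
    write_manifest(list(fields = truth_manifest),
                   file.path(out_dir, "ground_truth.json"))
    fields
  })

  # ---- segment --------------------------------------------------------------
  seg <- stage("segment", {
    params <- do.call(segment_params, config$segmentation)
    lapply(sim, function(entry) {
      rois <- segment_field(entry$field$image, params)
      rois$patient_id <- rep(entry$patient_id, nrow(rois))
      rois$source_id <- rep(entry$field$image$source_id, nrow(rois))
      list(entry = entry, rois = rois)
    })
  })
  roi_manifest <- bind_rows(lapply(seg, function(s)
    s$rois[, c("patient_id", "source_id", "roi_id", "x0", "y0", "x1", "y1",
               "area_px", "area_um2", "aspect", "mean_r", "mean_g", "mean_b")]))
  write_manifest(list(rois = as.list(roi_manifest)),
                 file.path(out_dir, "rois.json"))

  # ---- qc -------------------------------------------------------------------
  qc_out <- stage("qc", {
    criteria <- do.call(qc_criteria, config$qc)
    lapply(seg, function(s) {
      q <- apply_qc(s$rois, criteria)
      q$results$patient_id <- rep(s$entry$patient_id, nrow(q$results))
      q$results$source_id <- rep(s$entry$field$image$source_id, nrow(q$results))
      list(entry = s$entry, rois = q$rois, results = q$results)
    })
  })
  qc_report <- bind_rows(lapply(qc_out, `[[`, "results"))
  write_table_csv(qc_report[, c("patient_id", "source_id", "roi_id",
                                "size_aspect", "shadow", "hematoxylin_area",
                                "nucleus", "pass", "failure_reason")],
                  file.path(out_dir, "qc_report.csv"))

  # ---- score ----------------------------------------------------------------
  scores <- stage("score", {
    if (is.null(config$scorer) || is.null(config$scorer$kind)) {
      abort("no scorer configured")
    }
    if (config$scorer$kind != "reference_morphometric") {
      abort(sprintf("unknown scorer kind '%s'", config$scorer$kind))
    }
    labelled <- list()
    for (s in qc_out) {
      if (nrow(s$rois) == 0) next
      m <- match_rois_to_truth(s$rois, s$entry$field$truth)
      if (nrow(m$matches) == 0) next
      matched <- left_join(m$matches, s$entry$field$truth$cells[, c("cell_id", "atypical")],
                           by = "cell_id")
      rois_m <- s$rois[match(matched$roi_id, s$rois$roi_id), , drop = FALSE]
      rois_m$truth_atypical <- matched$atypical
      labelled[[length(labelled) + 1]] <- rois_m
    }
    train_rois <- bind_rows(labelled)
    scorer <- train_reference_scorer(train_rois, train_rois$truth_atypical,
                                     seed = derive_seed(config$seed, 9001L),
                                     lambda = config$scorer$lambda %||% 0.01)
    all_scores <- bind_rows(lapply(qc_out, function(s) {
      if (nrow(s$rois) == 0) return(NULL)
      sc <- score_cells(s$rois, scorer)
      sc$patient_id <- rep(s$entry$patient_id, nrow(sc))
      sc$source_id <- rep(s$entry$field$image$source_id, nrow(sc))
      sc
    }))
    list(scorer = scorer, table = all_scores)
  })
  write_table_csv(scores$table[, c("patient_id", "source_id", "roi_id",
                                   "score", "atypical", "bin")],
                  file.path(out_dir, "scores.csv"))

  # ---- aggregate ------------------------------------------------------------
  features <- stage("aggregate", {
    tbl <- left_join(scores$table, patients, by = "patient_id")
    aggregate_cohort(tbl[, c("patient_id", "class", "score")])
  })
  write_table_csv(features, file.path(out_dir, "features.csv"))

  # ---- stratify -------------------------------------------------------------
  strat <- stage("stratify", {
    split <- split_cohort(features, fraction = config$split_fraction,
                          seed = derive_seed(config$seed, 7001L))
    model <- fit_cascade(split$train, seed = config$seed)
    preds <- cascade_predict(split$test, model)
    preds$class <- split$test$class
    list(split = split, model = model, preds = preds)
  })
  write_table_csv(strat$preds[, c("patient_id", "class", "stratum",
                                  "test1_margin", "mean_atypical")],
                  file.path(out_dir, "predictions.csv"))
  write_manifest(
    list(model = list(
      test1 = list(weights = as.list(strat$model$test1$weights),
                   intercept = strat$model$test1$intercept,
                   center = as.list(strat$model$test1$center),
                   scale = as.list(strat$model$test1$scale),
                   positive_class = strat$model$test1$positive_class),
      test2 = list(cutoff = strat$model$test2$cutoff, j = strat$model$test2$j),
      seed = strat$model$seed,
      train_ids = strat$model$test1$train_ids)),
    file.path(out_dir, "model.json"))

  # ---- evaluate -------------------------------------------------------------
  metrics <- stage("evaluate", {
    preds <- strat$preds
    truth_hi <- preds$class %in% c("OSCC", "HGD")
    pred_hi <- preds$stratum != "LGD_or_benign"
    overall <- metrics_from_counts(
      count_confusion(truth_hi, pred_hi, positive = "OSCC/HGD vs LGD/BNG"),
      rounding = config$rounding)
    t1 <- metrics_from_counts(
      count_confusion(preds$class == "OSCC", preds$stratum == "OSCC_risk",
                      positive = "OSCC vs rest"),
      rounding = config$rounding)
    neg1 <- preds[preds$stratum != "OSCC_risk", , drop = FALSE]
    t2 <- if (nrow(neg1) > 0 && length(unique(neg1$class %in% c("OSCC", "HGD"))) == 2) {
      metrics_from_counts(
        count_confusion(neg1$class %in% c("OSCC", "HGD"),
                        neg1$stratum == "HGD_risk",
                        positive = "HGD vs LGD/BNG (Test-1 negatives)"),
        rounding = config$rounding)
    } else NULL
    list(overall = overall, test1 = t1, test2 = t2)
  })
  metrics_json <- lapply(metrics, function(m) {
    if (is.null(m)) return(NULL)
    setNames(as.list(m$percent_rounded), m$metric)
  })
  write_manifest(list(metrics = metrics_json,
                      rounding = config$rounding),
                 file.path(out_dir, "metrics.json"))

  # ---- run manifest ---------------------------------------------------------
  write_manifest(list(
    package_version = as.character(utils::packageVersion("oralcyto")),
    seed = config$seed,
    config = unclass(config),
    counts = list(
      patients = nrow(patients),
      fields = length(sim),
      rois = nrow(roi_manifest),
      rois_passing_qc = sum(qc_report$pass),
      cells_scored = nrow(scores$table),
      scorer_validation_accuracy = scores$scorer$validation_accuracy
    ),
    timings_sec = timings,
    total_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), file.path(out_dir, "run_manifest.json"))

  invisible(out_dir)
}
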