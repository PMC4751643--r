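#' Run configuration for the end-to-end pipeline
#'
#' Bundles every stage parameter: the simulated study design, the per-image
#' segmentation settings, the analysis level and the output locations.
#' Readable from a YAML file with [read_run_config()]; any field may be
#' overridden programmatically (or by CLI flags, which win over the file).
#'
#' @param out_dir Directory for all outputs (created if missing).
#' @param stages Character vector, a subset of
#'   `c("simulate", "quantify", "score", "analyze")`.
#' @param study A [study_gen_config()] or a plain list of its arguments.
#' @param images `NULL` to skip image simulation/quantification, or a list
#'   with `width`, `height`, `n_cells` (and any other [image_gen_config()]
#'   argument) used for one synthetic Ki-67 image per proliferation-role
#'   section.
#' @param min_object_area,opening_radius,um_per_px Segmentation settings,
#'   see [segment_cells()] and [quantify_image()].
#' @param alpha Significance level for the analysis stage.
#' @param outcomes Annotation outcomes to score and analyze.
#' @param save_masks Whether to write per-image segmentation masks.
#' @param seed Master seed; every stochastic stage derives its stream from
#'   it, so identical configs give byte-identical outputs.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = "ovcortex_run",
                       stages = c("simulate", "quantify", "score", "analyze"),
                       study = list(), images = list(),
                       min_object_area = 20, opening_radius = 1,
                       um_per_px = 0.46, alpha = 0.01,
                       outcomes = c("total_primordial", "normal_primordial",
                                    "proliferative_primordial"),
                       save_masks = FALSE, seed = 1L) {
  known <- c("simulate", "quantify", "score", "analyze")
  if (!all(stages %in% known))
    stop_config("unknown stage(s): %s", paste(setdiff(stages, known), collapse = ", "))
  structure(list(out_dir = out_dir, stages = known[known %in% stages],
                 study = study, images = images,
                 min_object_area = min_object_area,
                 opening_radius = opening_radius, um_per_px = um_per_px,
                 alpha = alpha, outcomes = outcomes,
                 save_masks = isTRUE(save_masks), seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file whose top-level keys are `run_config()` arguments.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  vals <- yaml::read_yaml(path) %||% list()
  bad <- setdiff(names(vals), names(formals(run_config)))
  if (length(bad))
    stop_config("unknown config key(s): %s", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

log_msg <- function(...) message(sprintf(...))

#' Execute the pipeline stages
#'
#' Runs, in order and as selected: `simulate` (write the synthetic
#' annotation table and, when image parameters are given, one synthetic
#' Ki-67 section image per proliferation section), `quantify` (segment
#' every image and append `global_proliferation` observations),
#' `score` (annotation outcomes to the observation table) and `analyze`
#' (one mixed-model fit per outcome, contrasts to CSV and a plain-text
#' summary). All intermediate tables are CSV files under `cfg$out_dir`.
#'
#' @param cfg A [run_config()].
#' @return A `run_summary` list: per-stage record counts and output paths.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) stop_config("cfg must be a run_config")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(annotations = file.path(cfg$out_dir, "annotations.csv"),
                images = file.path(cfg$out_dir, "images"),
                image_quant = file.path(cfg$out_dir, "image_quant.csv"),
                observations = file.path(cfg$out_dir, "observations.csv"),
                contrasts = file.path(cfg$out_dir, "contrasts.csv"),
                summary = file.path(cfg$out_dir, "model_summary.txt"))
  counts <- list()
  seeds <- derive_seeds(cfg$seed, 2L)
  do_images <- !is.null(cfg$images)

  if ("simulate" %in% cfg$stages) {
    log_msg("[simulate] seed %d", seeds[1])
    study_cfg <- cfg$study
    if (!inherits(study_cfg, "study_gen_config"))
      study_cfg <- do.call(study_gen_config, study_cfg)
    study_cfg$seed <- seeds[1]
    ann <- generate_follicle_dataset(study_cfg)
    write_annotations(ann, paths$annotations)
    counts$annotations <- nrow(ann)
    log_msg("[simulate] wrote %d annotation rows -> %s", nrow(ann),
            paths$annotations)
    if (do_images) {
      dir.create(paths$images, showWarnings = FALSE)
      secs <- unique(ann[ann$analysis_role == "proliferation",
                         c("section_id", "fragment_id", "arm", "condition")])
      img_seeds <- derive_seeds(seeds[2], max(1L, nrow(secs)))
      for (i in seq_len(nrow(secs))) {
        icfg <- do.call(image_gen_config,
                        c(cfg$images, list(seed = img_seeds[i])))
        g <- generate_ihc_image(icfg)
        write_rgb_image(g$image,
                        file.path(paths$images, paste0(secs$section_id[i], ".png")))
      }
      counts$images <- nrow(secs)
      log_msg("[simulate] wrote %d section images -> %s", nrow(secs),
              paths$images)
    }
  }

  obs <- NULL
  if ("quantify" %in% cfg$stages && do_images) {
    if (!dir.exists(paths$images))
      stop_config("quantify stage needs images under %s (run simulate first)",
                  paths$images)
    files <- list.files(paths$images, pattern = "\\.png$", full.names = TRUE)
    if (length(files) == 0) stop_config("no PNG images found in %s", paths$images)
    ann <- read_annotations(paths$annotations)
    sec_meta <- unique(ann[, c("section_id", "fragment_id", "arm", "condition")])
    rows <- lapply(files, function(f) {
      id <- sub("\\.png$", "", basename(f))
      q <- quantify_image(read_rgb_image(f), cfg$min_object_area,
                          cfg$opening_radius, cfg$um_per_px)
      if (cfg$save_masks) {
        mdir <- file.path(cfg$out_dir, "masks")
        dir.create(mdir, showWarnings = FALSE)
        write_mask(q$cell_mask, file.path(mdir, paste0(id, "_cells.png")))
        write_mask(q$tissue_mask, file.path(mdir, paste0(id, "_tissue.png")))
      }
      data.frame(image_id = id,
                 threshold_used = q$density$threshold_used,
                 cell_area_px = q$density$cell_area,
                 tissue_area_px = q$density$tissue_area,
                 density = q$density$density, stringsAsFactors = FALSE)
    })
    quant <- do.call(rbind, rows)
    utils::write.csv(quant, paths$image_quant, row.names = FALSE)
    counts$image_quant <- nrow(quant)
    log_msg("[quantify] %d images -> %s", nrow(quant), paths$image_quant)
    m <- match(quant$image_id, sec_meta$section_id)
    keep <- !is.na(m)
    if (any(keep)) {
      obs_img <- data.frame(fragment_id = sec_meta$fragment_id[m[keep]],
                            arm = sec_meta$arm[m[keep]],
                            condition = sec_meta$condition[m[keep]],
                            outcome = "global_proliferation",
                            raw_per_mm2 = quant$density[keep],
                            log_value = log10p1(quant$density[keep]),
                            section_id = quant$image_id[keep],
                            stringsAsFactors = FALSE)
      obs <- obs_img
    }
  }

  if ("score" %in% cfg$stages) {
    if (!file.exists(paths$annotations))
      stop_config("score stage needs %s (run simulate first)", paths$annotations)
    ann <- read_annotations(paths$annotations)
    obs_ann <- score_study(ann, outcomes = cfg$outcomes, level = "section")
    obs <- rbind(obs_ann, obs)
    utils::write.csv(obs, paths$observations, row.names = FALSE)
    counts$observations <- nrow(obs)
    log_msg("[score] %d observations -> %s", nrow(obs), paths$observations)
  }

  if ("analyze" %in% cfg$stages) {
    if (is.null(obs)) {
      if (!file.exists(paths$observations))
        stop_config("analyze stage needs %s (run score first)", paths$observations)
      obs <- utils::read.csv(paths$observations, stringsAsFactors = FALSE)
    }
    fits <- lapply(unique(obs$outcome), function(oc) {
      fit_mixed_model(obs, model_spec(response = oc, alpha = cfg$alpha))
    })
    ctr <- do.call(rbind, lapply(fits, function(f)
      cbind(outcome = f$response, f$contrasts)))
    utils::write.csv(ctr, paths$contrasts, row.names = FALSE)
    counts$contrasts <- nrow(ctr)
    txt <- utils::capture.output(for (f in fits) { print(f); cat("\n") })
    writeLines(txt, paths$summary)
    log_msg("[analyze] %d contrasts -> %s", nrow(ctr), paths$contrasts)
  }

  structure(list(counts = counts, paths = paths, stages = cfg$stages,
                 seed = cfg$seed),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("pipeline run (seed %d): %s\n", x$seed,
              paste(x$stages, collapse = " -> ")))
  for (nm in names(x$counts))
    cat(sprintf("  %-14s %6d records\n", nm, x$counts[[nm]]))
  invisible(x)
}
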