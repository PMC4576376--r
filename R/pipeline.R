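# End-to-end pipeline: chains import, fix merge, calibration, attitude,
# energetics, dead-reckoning, correction, classification and export behind
# one validated configuration, mirroring the modular wizard steps. Each
# stage is also runnable on its own through the exported functions; the
# pipeline simply sequences them, so a pipeline run is bit-identical to the
# stage-by-stage equivalent.

.pipeline_keys <- list(
  input = c("path", "delimiter", "rate"),
  fixes = c("path", "delimiter", "tolerance_ms"),
  calibration = c("model_path", "fit"),
  axis_map = c("mag", "mount"),
  attitude = c("window", "declination"),
  vedba = c("window"),
  speed = c("m", "c", "t", "constant"),
  deadreckon = c("start"),
  correct = c("max_iter", "heading_tol", "speed_tol"),
  classify = c("template_paths", "threshold", "normalized", "class_name"),
  export = c("path", "labels_path"),
  report = c("path"))

#' Validate a pipeline configuration
#'
#' A configuration is a named list of per-stage parameter blocks (or a YAML
#' file holding one). Unknown stages or unknown keys within a stage are
#' rejected outright, so a typo cannot silently disable a step.
#'
#' @param config named list or path to a YAML file.
#' @return the validated config, classed `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(.pipeline_keys))
  if (length(unknown)) {
    stop("unknown pipeline stage(s) in config: ", paste(unknown, collapse = ", "))
  }
  for (st in names(config)) {
    if (!is.list(config[[st]])) next
    bad <- setdiff(names(config[[st]]), .pipeline_keys[[st]])
    if (length(bad)) {
      stop("unknown key(s) in stage '", st, "': ", paste(bad, collapse = ", "))
    }
  }
  if (!is.null(config$attitude) && is.null(config$attitude$declination)) {
    stop("config stage 'attitude' is missing required field 'declination'")
  }
  class(config) <- c("pipeline_config", "list")
  config
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order on one deployment: import (or an
#' in-memory table), fix merge, magnetometer calibration, axis alignment,
#' attitude + heading, VeDBA, speed, dead-reckoning, fix correction,
#' template classification and merged export. Original channels — including
#' environmental ones such as temperature — pass through untouched, so every
#' exported row links behaviour, energetics and position to the conditions
#' the animal experienced. The run report records every parameter and
#' per-stage row counts. Any stage failure aborts with the stage name and
#' cause.
#'
#' @param config a [pipeline_config] (or list / YAML path coercible to one).
#' @param table optional in-memory [sensor_table] (replaces the `input`
#'   stage).
#' @param fixes optional in-memory [fix_set] (replaces the `fixes` path).
#' @param templates optional list of [dd_template]s for classification
#'   (replaces `template_paths`).
#' @param calibration optional in-memory `calibration_model`.
#' @return list with the final `table` (all derived channels appended),
#'   `track`, `corrected`, `labels`, `model` and the `report` list.
#' @export
run_pipeline <- function(config, table = NULL, fixes = NULL,
                         templates = NULL, calibration = NULL) {
  config <- pipeline_config(unclass(config))
  report <- list(config = config, stages = list())
  note <- function(name, rows, ...) {
    report$stages[[name]] <<- c(list(rows = rows), list(...))
  }

  if (is.null(table)) {
    if (is.null(config$input)) stop("no input table: provide config$input or 'table'")
    table <- run_stage("input", do.call(load_table, config$input))
  }
  note("input", nrow(table))

  if (is.null(fixes) && !is.null(config$fixes)) {
    fixes <- run_stage("fixes", do.call(
      load_fixes, config$fixes[setdiff(names(config$fixes), "tolerance_ms")]))
  }
  if (!is.null(fixes)) {
    tol <- if (!is.null(config$fixes$tolerance_ms)) config$fixes$tolerance_ms else 0
    table <- run_stage("fixes", merge_fixes(table, fixes, tolerance_ms = tol))
    note("fixes", nrow(fixes))
  }

  if (!is.null(config$axis_map)) {
    table <- run_stage("axis_map", {
      mk <- function(v) if (is.null(v)) diag(3) else matrix(as.numeric(v), 3, 3, byrow = TRUE)
      apply_axis_map(table, axis_map(mk(config$axis_map$mag),
                                     mk(config$axis_map$mount)))
    })
    note("axis_map", nrow(table))
  }

  mag_channels <- NULL
  model <- calibration
  if (is.null(model) && !is.null(config$calibration)) {
    model <- run_stage("calibration", {
      if (!is.null(config$calibration$model_path)) {
        load_model(config$calibration$model_path)
      } else if (isTRUE(config$calibration$fit)) {
        fit_ellipsoid(sensor_matrix(table, "mag"))
      } else stop("calibration stage needs 'model_path' or 'fit: true'")
    })
  }
  if (!is.null(model)) {
    table <- run_stage("calibration", apply_calibration(table, model))
    mag_channels <- c("mag_x_cal", "mag_y_cal", "mag_z_cal")
    note("calibration", nrow(table), cv = model$cv)
  }

  if (!is.null(config$attitude)) {
    table <- run_stage("attitude", derive_attitude(
      table, window = config$attitude$window,
      declination = config$attitude$declination,
      mag_channels = mag_channels))
    note("attitude", nrow(table), window = config$attitude$window,
         declination = config$attitude$declination)
  }

  if (!is.null(config$vedba)) {
    table <- run_stage("vedba", {
      dba <- dynamic_acceleration(sensor_matrix(table, "accel"),
                                  config$vedba$window)
      append_channels(table, list(VeDBA = dba$VeDBA, ODBA = dba$ODBA))
    })
    note("vedba", nrow(table), window = config$vedba$window)
  }

  if (!is.null(config$speed)) {
    smod <- run_stage("speed", {
      sp <- config$speed
      if (!is.null(sp$constant)) {
        speed_model(mode = "constant", constant = sp$constant)
      } else {
        speed_model(m = sp$m, c = if (is.null(sp$c)) 0 else sp$c,
                    t = if (is.null(sp$t)) 0 else sp$t)
      }
    })
    table <- run_stage("speed", append_channels(
      table, list(speed = speed_from_vedba(table$VeDBA, smod))))
    note("speed", nrow(table), mode = smod$mode)
  }

  track <- NULL
  corrected <- NULL
  if (!is.null(config$deadreckon)) {
    track <- run_stage("deadreckon", {
      start <- config$deadreckon$start
      if (is.null(start)) {
        if (is.null(fixes) || !nrow(fixes)) {
          stop("no start position: give config$deadreckon$start or fixes")
        }
        start <- c(fixes$lat[1], fixes$lon[1])
      }
      dt <- 1 / attr(table, "rate")
      dead_reckon(table$heading, table$speed, dt, start, time_ms = time_ms(table))
    })
    table <- run_stage("deadreckon", append_channels(
      table, list(dr_lat = track$lat, dr_lon = track$lon)))
    note("deadreckon", nrow(track))
    if (!is.null(config$correct) && !is.null(fixes) && nrow(fixes) >= 2) {
      corrected <- run_stage("correct", {
        cc <- config$correct
        correct_track(table$heading, table$speed, 1 / attr(table, "rate"),
                      time_ms(table), fixes,
                      max_iter = if (is.null(cc$max_iter)) 10 else cc$max_iter,
                      heading_tol = if (is.null(cc$heading_tol)) 0.1 else cc$heading_tol,
                      speed_tol = if (is.null(cc$speed_tol)) 0.001 else cc$speed_tol)
      })
      table <- run_stage("correct", append_channels(
        table, list(cor_lat = corrected$track$lat, cor_lon = corrected$track$lon)))
      note("correct", nrow(corrected$track),
           segments = nrow(corrected$corrections))
    }
  }

  labels <- NULL
  if (!is.null(config$classify)) {
    if (is.null(templates)) {
      templates <- run_stage("classify", lapply(config$classify$template_paths,
                                                read_template))
    }
    labels <- run_stage("classify", {
      thr <- if (is.null(config$classify$threshold)) 80 else config$classify$threshold
      nrm <- if (is.null(config$classify$normalized)) TRUE else config$classify$normalized
      ls <- label_set(nrow(table))
      nm <- if (is.null(config$classify$class_name)) {
        vapply(templates, function(tp) tp$behaviour, character(1))
      } else rep_len(config$classify$class_name, length(templates))
      for (ti in seq_along(templates)) {
        cname <- nm[ti]
        if (!(cname %in% ls$classes$name)) ls <- add_class(ls, cname)
        cid <- ls$classes$id[ls$classes$name == cname]
        res <- extract_matches(
          sliding_similarity(table, templates[[ti]], normalized = nrm),
          thr, length(templates[[ti]]$channels[[1]]), template = ti)
        ls <- propose_matches(ls, res, cid)
        ls <- accept_reject(ls, accept = ls$pending$id)
      }
      ls
    })
    note("classify", nrow(labels$intervals))
  }

  if (!is.null(config$export)) {
    run_stage("export", export_merged(table, config$export$path, labels))
    if (!is.null(config$export$labels_path) && !is.null(labels)) {
      run_stage("export", write_labels(labels, config$export$labels_path,
                                       time_ms(table)))
    }
    note("export", nrow(table), path = config$export$path)
  }

  if (!is.null(config$report) && !is.null(config$report$path)) {
    writeLines(utils::capture.output(utils::str(report, max.level = 3)),
               config$report$path)
  }

  list(table = table, track = track, corrected = corrected,
       labels = labels, model = model, report = report)
}
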