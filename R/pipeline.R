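#' Read and validate a pipeline run configuration
#'
#' The run configuration is a single declarative YAML file (or an equivalent
#' R list) describing one full analysis: the channel map, gate settings,
#' reporter sample manifest, autofluorescence manifest with day/replicate
#' labels and explicit exclusions, bead manifest, an optional external
#' cell-volume noise `cv2_v`, an output directory and a seed. All referenced
#' paths are checked up front so a misconfigured run fails before any
#' computation.
#'
#' @param config path to a YAML file, or a named list with the same
#'   structure.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list", call. = FALSE)

  defaults <- list(
    seed = 1L, cv2_v = 0, output_dir = NULL,
    channel_map = NULL,
    gate = list(threshold = 0.5, tol = 1e-8, max_iter = 500L, min_events = 50L,
                log_transform = FALSE),
    expression = list(tol = 1e-8, max_iter = 500L, min_events = 50L),
    samples = list(),
    autofluorescence = list(samples = list(), exclude = character()),
    beads = list(paths = character(), method = "shared_cv2", delta = NULL,
                 offset_O = NULL)
  )
  # shallow, name-wise merge (one level into option sections): sample
  # manifests and path lists are unnamed lists and must replace wholesale
  shallow_merge <- function(d, v) {
    for (nm in names(v)) d[[nm]] <- v[[nm]]
    d
  }
  cfg <- defaults
  for (nm in names(config)) {
    if (nm %in% c("gate", "expression", "autofluorescence", "beads") &&
        is.list(config[[nm]])) {
      cfg[[nm]] <- shallow_merge(defaults[[nm]], config[[nm]])
    } else {
      cfg[[nm]] <- config[[nm]]
    }
  }
  if (length(cfg$samples) == 0L) stop("config lists no reporter samples", call. = FALSE)
  thr <- cfg$gate$threshold
  if (!is.numeric(thr) || thr < 0 || thr > 1) {
    stop("gate threshold must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(cfg$channel_map)) {
    cfg$channel_map <- do.call(channel_map, as.list(cfg$channel_map))
  }

  paths <- c(vapply(cfg$samples, `[[`, character(1), "path"),
             vapply(cfg$autofluorescence$samples, `[[`, character(1), "path"),
             unlist(cfg$beads$paths))
  missing_paths <- paths[!file.exists(paths)]
  if (length(missing_paths) > 0L) {
    stop("config references missing file(s): ",
         paste(missing_paths, collapse = ", "), call. = FALSE)
  }
  manual_shot <- !is.null(cfg$beads$delta)
  if (length(cfg$beads$paths) == 0L && !manual_shot) {
    stop("config must give bead files or an explicit beads: {delta, offset_O}",
         call. = FALSE)
  }
  if (length(cfg$autofluorescence$samples) == 0L && is.null(cfg$autofluorescence$mean)) {
    stop("config must give autofluorescence samples or explicit ",
         "autofluorescence: {mean, var}", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Run the full expression-analysis pipeline
#'
#' For every reporter sample: gate on the 4D scatter mixture, filter at the
#' configured posterior threshold, fit the log-fluorescence mixture, and
#' correct the linear-scale moments for autofluorescence and shot noise.
#' Autofluorescence samples are pushed through the same gate-and-fit path and
#' aggregated over replicates and days; bead files are summarized and used to
#' calibrate the shot-noise strength and offset. Calibration failures abort
#' the run (corrections are meaningless without them) unless an explicit
#' pass-through calibration (`beads: {delta: 0, offset_O: 0}` or
#' `autofluorescence: {mean: 0, var: 0}`) is configured.
#'
#' When `output_dir` is set, writes `summary.tsv` (one row per sample) and
#' the fitted calibration models as JSON.
#'
#' @param config a [read_run_config()] result, a config list, or a YAML path.
#' @return A list with `summary` (tibble, one row per reporter sample),
#'   `autofluorescence`, `shot_noise`, `gate_models` and `estimates`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  gate_cfg <- em_config(tol = cfg$gate$tol, max_iter = cfg$gate$max_iter,
                        min_events = cfg$gate$min_events,
                        log_transform = isTRUE(cfg$gate$log_transform))
  expr_cfg <- em_config(tol = cfg$expression$tol, max_iter = cfg$expression$max_iter,
                        min_events = cfg$expression$min_events)

  gate_fit_one <- function(path, sample_id, day_id = NA, replicate_id = NA) {
    ev <- read_events(path, channel_map = cfg$channel_map, sample_id = sample_id,
                      day_id = as.character(day_id),
                      replicate_id = as.character(replicate_id))
    model <- fit_scatter_mixture(ev, config = gate_cfg)
    p <- gate_posteriors(model, ev)
    flt <- filter_events(ev, p, threshold = cfg$gate$threshold)
    est <- fit_log_fluor_mixture(flt$events, config = expr_cfg)
    list(model = model, estimate = est, retained = flt$retained_fraction)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # --- autofluorescence ---
  autofluor <- stage("autofluorescence", {
    if (length(cfg$autofluorescence$samples) > 0L) {
      ests <- lapply(cfg$autofluorescence$samples, function(s) {
        gate_fit_one(s$path, sample_id = s$sample_id %||% basename(s$path),
                     day_id = s$day_id, replicate_id = s$replicate_id)$estimate
      })
      aggregate_autofluorescence(ests, exclusions = cfg$autofluorescence$exclude)
    } else {
      manual_autofluor_model(cfg$autofluorescence$mean, cfg$autofluorescence$var,
                             cfg$autofluorescence$se_mean %||% 0,
                             cfg$autofluorescence$se_var %||% 0)
    }
  })

  # --- shot-noise calibration ---
  shot <- stage("shot_noise", {
    if (!is.null(cfg$beads$delta)) {
      shot_noise_model(delta = cfg$beads$delta,
                       offset_O = cfg$beads$offset_O %||% 0)
    } else {
      pops <- lapply(cfg$beads$paths, read_events, channel_map = cfg$channel_map)
      names(pops) <- basename(unlist(cfg$beads$paths))
      summaries <- summarize_beads(pops, config = expr_cfg)
      if (identical(cfg$beads$method, "simple")) {
        fit_shot_noise_simple(summaries)
      } else {
        fit_shot_noise_shared_cv2(summaries, events = pops, seed = cfg$seed)
      }
    }
  })

  # --- per-sample gate, fit, correct ---
  gate_models <- list()
  estimates <- list()
  rows <- lapply(cfg$samples, function(s) {
    sid <- s$sample_id %||% basename(s$path)
    res <- stage(paste0("sample:", sid), gate_fit_one(s$path, sample_id = sid))
    gate_models[[sid]] <<- res$model
    estimates[[sid]] <<- res$estimate
    corr <- stage(paste0("correct:", sid),
                  correct_expression(res$estimate, autofluor, shot))
    cv2_C <- if (!is.na(corr$cv2_I) && corr$cv2_I >= 0) {
      suppressWarnings(concentration_cv2(corr$cv2_I, cfg$cv2_v))
    } else NA_real_
    tibble(sample_id = sid, n_events = res$estimate$n_used,
           retained_fraction = res$retained,
           mu_log = res$estimate$mu, v_log = res$estimate$v,
           mean_M = res$estimate$mean_lin, var_M = res$estimate$var_lin,
           mean_T = corr$mean_T, sigma_mean_T = corr$sigma_mean_T,
           var_T = corr$var_T, sigma_var_T = corr$sigma_var_T,
           cv2_I = corr$cv2_I, sigma_cv2_I = corr$sigma_cv2,
           cv2_C = cv2_C,
           flags = paste(corr$flags, collapse = ";"))
  })
  summary <- do.call(rbind, rows)

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(summary, file.path(cfg$output_dir, "summary.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(shot_noise = unclass(shot)[c("delta", "offset_O", "sigma_delta",
                                        "sigma_offset", "shared_cv2", "method")],
           autofluorescence = list(overall_mean = autofluor$overall_mean,
                                   se_overall_mean = autofluor$se_overall_mean,
                                   overall_var = autofluor$overall_var,
                                   se_overall_var = autofluor$se_overall_var,
                                   excluded = autofluor$excluded)),
      file.path(cfg$output_dir, "calibration.json"),
      auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  }

  list(summary = summary, autofluorescence = autofluor, shot_noise = shot,
       gate_models = gate_models, estimates = estimates, config = cfg)
}

# explicit pass-through autofluorescence (no measured samples)
manual_autofluor_model <- function(mean, var, se_mean = 0, se_var = 0) {
  structure(list(per_replicate = tibble(), per_day = tibble(),
                 overall_mean = mean, se_overall_mean = se_mean,
                 overall_var = var, se_overall_var = se_var,
                 excluded = character()),
            class = "autofluorescence_model")
}
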