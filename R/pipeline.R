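#' Read and validate a pipeline run configuration
#'
#' A YAML (or JSON) config drives [run_slice()]. Exactly one input mode is
#' allowed: `phantom` (a [phantom_spec()] block) or `input` (a file path
#' for [load_stack()]). Optional blocks: `frames` (`n_select`,
#' `pre_contrast_count`), `roi` (`polygon` path and/or `ring_width_mm`),
#' `estimation` ([estimation_options()] fields), `viz` (`decimate`,
#' `streamline_spacing`, `render` on/off), plus `patient_id`, `slice_id`,
#' `resection_stage`, `seed`, `outdir`.
#'
#' @param path YAML/JSON file path, or a list to validate directly.
#' @return An object of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  has_phantom <- !is.null(cfg$phantom)
  has_input <- !is.null(cfg$input)
  if (has_phantom == has_input)
    stop("config must specify exactly one input mode: 'phantom' or 'input'")
  if (has_input && !file.exists(cfg$input$path))
    stop("input file does not exist: ", cfg$input$path)
  if (!is.null(cfg$roi$polygon) && !file.exists(cfg$roi$polygon))
    stop("ROI polygon file does not exist: ", cfg$roi$polygon)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$outdir)) stop("config must set 'outdir'")
  if (is.null(cfg$patient_id)) cfg$patient_id <- "P00"
  if (is.null(cfg$slice_id)) cfg$slice_id <- "s1"
  if (is.null(cfg$resection_stage)) cfg$resection_stage <- "pre"
  structure(cfg, class = "run_config")
}

log_line <- function(con, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
  invisible(line)
}

## deterministic sub-seed derivation in double arithmetic (stays exact and
## well below 2^31 even when chained)
derive_seed <- function(seed, i)
  as.integer(((as.numeric(seed) %% 2000003) * 7919 +
                as.numeric(i) * 104729) %% 2000000011)

#' Run the full single-slice analysis
#'
#' Executes the stage chain load (or simulate) -> frame selection ->
#' background subtraction -> transport estimation -> region summaries ->
#' rose histogram -> figures, writing every artifact plus a JSON manifest
#' (file list with MD5 hashes and the resolved config) into the output
#' directory. Any stage failure aborts with the stage name in the error.
#' Identical config and seed give byte-identical CSV/JSON artifacts.
#'
#' @param config a [read_run_config()] result, a path, or a list.
#' @return Invisibly, the manifest as a list.
#' @export
run_slice <- function(config) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(config$outdir, "run.log"), open = "wt")
  on.exit(close(logf))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  files <- character(0)
  add <- function(...) files <<- c(files, ...)

  ## --- acquire -----------------------------------------------------------
  phantom <- NULL
  stk <- stage("acquire", {
    if (!is.null(config$phantom)) {
      spec_args <- config$phantom
      spec_args$seed <- derive_seed(config$seed, 1L)
      spec <- do.call(phantom_spec, spec_args)
      ft <- config$frames$frame_times
      if (is.null(ft)) ft <- 0:4
      pre <- config$frames$pre_contrast_count
      if (is.null(pre)) pre <- 1L
      ## the stage expression is evaluated in this function frame, so a
      ## plain assignment updates run_slice's 'phantom'
      phantom <- simulate_phantom(spec, frame_times = ft,
                                  pre_contrast_count = pre,
                                  micro_dt = config$frames$micro_dt)
      log_line(logf, "acquire", paste0("phantom '", spec$kind, "' ",
                                       paste(spec$shape, collapse = "x")))
      phantom$stack
    } else {
      s <- load_stack(config$input$path,
                      slice_index = config$input$slice_index,
                      pre_contrast_count =
                        if (is.null(config$frames$pre_contrast_count)) 1L
                      else config$frames$pre_contrast_count)
      if (!is.null(config$frames$n_select)) {
        idx <- select_spanning_frames(n_frames(s),
                                      config$frames$n_select,
                                      s$pre_contrast_count)
        s <- conc_stack(s$frames[, , idx, drop = FALSE],
                        s$frame_times[idx], s$pixel_spacing,
                        sum(idx <= s$pre_contrast_count))
      }
      log_line(logf, "acquire", paste0(config$input$path, ": ",
                                       n_frames(s), " frames"))
      s
    }
  })

  ## --- background --------------------------------------------------------
  sub <- stage("background_subtraction", subtract_background(stk))
  log_line(logf, "background_subtraction",
           sprintf("noise sd estimate %.4g", sub$noise_sd))

  ## --- masks -------------------------------------------------------------
  masks <- stage("roi", {
    tumor <- if (!is.null(config$roi$polygon)) {
      rasterize_polygon(read_roi_json(config$roi$polygon),
                        dim(sub$frames)[1:2])
    } else if (!is.null(phantom$tumor_mask)) {
      phantom$tumor_mask
    } else {
      ## fallback: threshold the mean enhancement at 20% of its maximum
      mf <- apply(sub$frames, c(1L, 2L), mean)
      region_mask(mf > 0.2 * max(mf), "tumor")
    }
    ring <- if (!is.null(config$roi$parenchyma_polygon)) {
      rasterize_polygon(read_roi_json(config$roi$parenchyma_polygon),
                        dim(sub$frames)[1:2])
    } else {
      w <- config$roi$ring_width_mm
      if (is.null(w)) w <- 3 * sub$pixel_spacing
      make_parenchyma_ring(tumor, w, sub$pixel_spacing)
    }
    list(tumor = tumor, ring = ring)
  })
  log_line(logf, "roi", sprintf("tumor %d px, parenchyma %d px",
                                masks$tumor$count, masks$ring$count))

  ## --- estimate ----------------------------------------------------------
  fit <- stage("estimation", {
    opts <- do.call(estimation_options,
                    if (is.null(config$estimation)) list()
                    else config$estimation)
    both <- region_mask(masks$tumor$mask | masks$ring$mask, "analysis")
    estimate_transport(sub, both, opts)
  })
  sm <- summary(fit)
  log_line(logf, "estimation",
           sprintf("valid %d, degenerate %d, ill-conditioned %d",
                   sum(fit$valid_mask),
                   sm$status_counts[["degenerate"]],
                   sm$status_counts[["ill_conditioned"]]))
  if (sm$n_clipped > 0)
    log_line(logf, "estimation",
             sprintf("WARN %d pixels with negative D clipped to 0",
                     sm$n_clipped))

  ## --- summaries ---------------------------------------------------------
  summaries <- stage("summaries", rbind(
    summarize_region(fit, masks$tumor, config$patient_id, config$slice_id),
    summarize_region(fit, masks$ring, config$patient_id, config$slice_id)))
  sum_path <- file.path(config$outdir, "region_summaries.csv")
  write.csv(summaries, sum_path, row.names = FALSE)
  add(sum_path)

  ## --- rose --------------------------------------------------------------
  rose <- stage("rose", rose_histogram(fit, masks$tumor))
  rose_path <- file.path(config$outdir, "rose_tumor.csv")
  write.csv(rose_to_table(rose), rose_path, row.names = FALSE)
  add(rose_path)

  ## --- maps and figures --------------------------------------------------
  add(stage("maps", write_field_maps(fit, config$outdir)))
  render <- is.null(config$viz$render) || isTRUE(config$viz$render)
  if (render) {
    figs <- stage("figures", {
      sp <- velocity_magnitude(fit)
      bgm <- apply(sub$frames, c(1L, 2L), mean)
      p1 <- file.path(config$outdir, "heatmap_speed.png")
      render_heatmap(sp, background = bgm, out_path = p1)
      p2 <- file.path(config$outdir, "heatmap_D.png")
      render_heatmap(fit$diffusion_map, background = bgm, out_path = p2)
      seeds <- streamline_seeds(masks$tumor,
                                spacing = config$viz$streamline_spacing %||% 4)
      sl <- if (nrow(seeds)) compute_streamlines(fit, seeds, step = 0.5,
                                                 max_steps = 200)
      else list()
      p3 <- file.path(config$outdir, "quiver_streamlines.png")
      render_quiver_streamlines(fit, background = bgm, streamlines = sl,
                                out_path = p3,
                                decimate = config$viz$decimate %||% 2L)
      c(p1, paste0(p1, ".json"), p2, paste0(p2, ".json"), p3)
    })
    add(figs)
    log_line(logf, "figures", paste(length(figs), "files"))
  }

  ## --- manifest ----------------------------------------------------------
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  log_line(logf, "done", sprintf("%.2f s", elapsed))
  manifest <- list(
    config = unclass(config),
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))),
    n_valid_pixels = sum(fit$valid_mask),
    degenerate_fraction = sm$degenerate_fraction)
  man_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a cohort of slice analyses and the cohort statistics
#'
#' Runs [run_slice()] for each patient/slice config (seeds derived
#' deterministically from `seed`), aggregates slices to patients,
#' left-joins the clinical table and writes the cohort summary CSVs plus a
#' JSON statistics report covering region comparisons, clinical
#' correlations, group tests and (when both stages are present) the paired
#' pre/post-resection analysis. Patients lacking a required stage are
#' excluded from the affected analysis with a logged reason; with fewer
#' than 3 patients the correlation analyses are skipped but summaries are
#' still produced.
#'
#' @param configs list of [run_config] lists (one per patient slice); each
#'   needs distinct `outdir` and shared `patient_id` per patient.
#' @param clinical clinical covariate table (CSV path or data.frame).
#' @param outdir cohort output directory.
#' @param seed global seed; per-slice seeds are derived from it.
#' @return Invisibly, a list with `cohort` (the joined table), `stats`,
#'   and `manifest`.
#' @export
run_cohort <- function(configs, clinical, outdir, seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  all_summaries <- list()
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    cfg$seed <- derive_seed(seed, i)
    cfg <- read_run_config(cfg)
    man <- run_slice(cfg)
    s <- read.csv(file.path(cfg$outdir, "region_summaries.csv"))
    s$resection_stage <- cfg$resection_stage
    all_summaries[[i]] <- s
  }
  slices <- do.call(rbind, all_summaries)
  patients <- do.call(rbind, lapply(
    split(slices,
          list(slices$patient_id, slices$region, slices$resection_stage),
          drop = TRUE),
    function(s) aggregate_patient(
      s[, setdiff(names(s), "resection_stage")],
      resection_stage = s$resection_stage[1L])))
  rownames(patients) <- NULL
  cohort <- build_cohort_table(patients, clinical)
  stats <- cohort_stats(cohort)
  paths <- c(file.path(outdir, "cohort_slices.csv"),
             file.path(outdir, "cohort_patients.csv"),
             file.path(outdir, "cohort_table.csv"),
             file.path(outdir, "stats_report.json"))
  write.csv(slices, paths[1L], row.names = FALSE)
  write.csv(patients, paths[2L], row.names = FALSE)
  write.csv(cohort, paths[3L], row.names = FALSE)
  jsonlite::write_json(stats, paths[4L], auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest <- list(
    seed = seed, n_slices = nrow(slices),
    n_patients = length(unique(patients$patient_id)),
    outputs = lapply(paths, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, stats = stats, manifest = manifest))
}
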