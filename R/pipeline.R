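#' Demo pipeline configuration
#'
#' A complete desk-scale configuration for [run_pipeline]: a synthetic
#' two-pesticide apple scene over the standard 10-point time course with a
#' reduced spatial grid, all six stages enabled.
#'
#' @param out_dir output directory.
#' @param seed top-level seed; all stage randomness derives from it.
#' @return nested configuration list.
#' @export
demo_config <- function(out_dir = tempfile("serspen_run_"), seed = 1L) {
  list(
    out_dir = out_dir,
    seed = seed,
    scene = list(axis = list(start_cm1 = 400, stop_cm1 = 1800, n_channels = 161),
                 n_depth = 25, n_lateral = 12,
                 depth_step_um = 8, lateral_step_um = 8,
                 times_h = c(2, 4, 6, 8, 10, 12, 24, 48, 72, 96)),
    pipeline = list(pesticide_threshold = 0.8, suspected_threshold = 0.5,
                    train_fraction = 0.7, n_endmembers = 3),
    map = list(metric = "pearson", ref_source = "vca"),
    profile = list(bin_um = NULL, spline_df = 6),
    classify = list(n_per_class = 120, families = c("lda", "logistic"),
                    n_groups = 4))
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop_domain("config error: expected a list or a JSON path")
  for (field in c("out_dir", "seed", "scene"))
    if (is.null(config[[field]]))
      stop_domain("config error at `", field, "`: field is required")
  config
}

stage_run <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(expr, error = function(e)
    stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE))
  list(value = value, elapsed_s = proc.time()[["elapsed"]] - t0)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> unmix -> quantify -> map -> profile -> classify on a
#' synthetic scene, writing delimited tables and a JSON run manifest under
#' `out_dir`. All randomness flows from the single top-level seed; re-running
#' with the same configuration reproduces the outputs.
#'
#' @param config a configuration list (see [demo_config]) or a path to a
#'   JSON file with the same structure.
#' @return a `sers_run` object: list with `manifest` (config snapshot, seed,
#'   per-stage outputs and timings), and the in-memory stage results
#'   (`scene`, `cubes`, `endmembers`, `mcr`, `maps`, `profiles`, `curve`,
#'   `reports`).
#' @export
run_pipeline <- function(config = demo_config()) {
  config <- read_pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)

  pl_args <- config$pipeline %||% list()
  pl_args$seed <- seed
  cfg <- do.call(pipeline_config, pl_args)

  manifest <- list(config = config, seed = seed, tool = "serspen",
                   version = as.character(utils::packageVersion("serspen")),
                   stages = list())
  outputs <- character(0)
  note <- function(stage, paths, elapsed) {
    manifest$stages[[stage]] <<- list(outputs = paths, elapsed_s = round(elapsed, 3))
    outputs <<- c(outputs, paths)
  }

  ## -- simulate -------------------------------------------------------------
  st <- stage_run("simulate", {
    sc_args <- config$scene
    if (!is.null(sc_args$axis) && is.list(sc_args$axis))
      sc_args$axis <- build_axis(sc_args$axis$start_cm1, sc_args$axis$stop_cm1,
                                 sc_args$axis$n_channels)
    sc_args$seed <- seed
    scene <- do.call(scene_config, sc_args)
    fields <- lapply(seq_along(scene$components), function(j)
      simulate_penetration_field(scene, j))
    cubes <- lapply(scene$times_h, function(t)
      assemble_hypermap(scene, t, fields = fields))
    paths <- character(0)
    for (i in seq_along(cubes)) {
      p <- file.path(out_dir, sprintf("cube_t%03dh.tsv", scene$times_h[i]))
      write_hypermap(cubes[[i]]$map, p)
      paths <- c(paths, p, paste0(p, ".json"))
    }
    for (j in seq_along(fields)) {
      p <- file.path(out_dir, sprintf("truth_concentration_%s.tsv",
                                      scene$components[[j]]$name))
      utils::write.table(fields[[j]]$values, p, sep = "\t",
                         row.names = FALSE, col.names = FALSE)
      paths <- c(paths, p)
    }
    list(scene = scene, fields = fields, cubes = cubes, paths = paths)
  })
  scene <- st$value$scene; cubes <- st$value$cubes; fields <- st$value$fields
  note("simulate", st$value$paths, st$elapsed_s)

  refs <- lapply(scene$components, function(comp)
    make_reference_spectrum(comp$peaks, scene$axis,
                            shape = comp$shape %||% "lorentzian",
                            name = comp$name))
  ccubes <- NULL

  ## -- unmix (on baseline-corrected cubes, as the raw data were in the
  ## acquisition software) ---------------------------------------------------
  st <- stage_run("unmix", {
    ccubes <- lapply(cubes, function(cb)
      baseline_correct_cube(cb$map, cfg$baseline_smoothness,
                            cfg$baseline_asymmetry, cfg$baseline_iter))
    ems <- lapply(seq_along(ccubes), function(i) {
      E <- run_vca(ccubes[[i]], p = cfg$n_endmembers,
                   seed = sub_seed(seed, 10L + i))
      match_endmembers(E, refs)
    })
    p <- file.path(out_dir, "endmembers_t002h.tsv")
    utils::write.table(cbind(cm1 = as.numeric(scene$axis), t(ems[[1L]]$S)),
                       p, sep = "\t", row.names = FALSE, quote = FALSE)
    list(ems = ems, paths = p)
  })
  ems <- st$value$ems
  note("unmix", st$value$paths, st$elapsed_s)

  ## -- quantify -------------------------------------------------------------
  st <- stage_run("quantify", {
    ref_names <- vapply(refs, function(r) r$name, "")
    fits <- lapply(seq_along(ccubes), function(i) {
      em <- ems[[i]]
      if (!all(ref_names %in% em$names)) {
        ## heavily mixed cube (no pure pixels): initialize from the library
        ## references plus a flat background component
        S_init <- rbind(do.call(rbind, lapply(refs, function(r)
          r$spectrum$intensities)), rep(1, length(scene$axis)))
        em <- endmember_set(S_init, names = c(ref_names, "background"))
      }
      run_mcr_als(ccubes[[i]], em)
    })
    p <- file.path(out_dir, "mcr_lof.tsv")
    utils::write.table(
      data.frame(time_h = scene$times_h,
                 lof_final = vapply(fits, function(f) utils::tail(f$lof_trace, 1L), 0),
                 n_iter = vapply(fits, function(f) f$n_iter, 0L)),
      p, sep = "\t", row.names = FALSE, quote = FALSE)
    list(fits = fits, paths = p)
  })
  fits <- st$value$fits
  note("quantify", st$value$paths, st$elapsed_s)

  ## -- map ------------------------------------------------------------------
  st <- stage_run("map", {
    metric <- (config$map %||% list())$metric %||% "pearson"
    ref_source <- (config$map %||% list())$ref_source %||% "vca"
    maps1 <- lapply(seq_along(ccubes), function(i) {
      em <- ems[[i]]
      tgt <- refs[[1L]]$name
      ref_use <- if (ref_source == "vca" && tgt %in% em$names)
        new_spectrum(scene$axis, em$S[match(tgt, em$names), ]) else refs[[1L]]
      sm <- similarity_map(ccubes[[i]], ref_use, metric = metric)
      list(sim = sm, labels = classify_similarity(sm, cfg))
    })
    paths <- file.path(out_dir, c("similarity_t002h.tsv", "labels_t002h.tsv"))
    utils::write.table(maps1[[1L]]$sim$values, paths[1L], sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(maps1[[1L]]$labels$color_values, paths[2L], sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    overlap <- NULL
    if (length(refs) >= 2L) {
      overlap <- lapply(ccubes, function(cb)
        mixed_overlap_map(cb, refs[[1L]], refs[[2L]], cfg))
      p <- file.path(out_dir, "overlap_t002h.tsv")
      utils::write.table(overlap[[1L]]$color_values, p, sep = "\t",
                         row.names = FALSE, col.names = FALSE)
      paths <- c(paths, p)
    }
    list(maps = maps1, overlap = overlap, paths = paths)
  })
  maps_out <- st$value
  note("map", maps_out$paths, st$elapsed_s)

  ## -- profile --------------------------------------------------------------
  st <- stage_run("profile", {
    prof_cfg <- config$profile %||% list()
    target <- refs[[1L]]$name
    profiles <- lapply(seq_along(cubes), function(i) {
      f <- fits[[i]]
      j <- match(target, f$names)
      if (is.na(j)) j <- 1L
      depth_profile(f$C[, j], cubes[[i]]$map,
                    bin_um = prof_cfg$bin_um)
    })
    curve <- curve_with_trend(total_content_curve(profiles),
                              df = prof_cfg$spline_df %||% 6L)
    paths <- file.path(out_dir, c("depth_profiles.tsv", "content_curve.tsv"))
    utils::write.table(
      data.frame(time_h = rep(scene$times_h,
                              each = nrow(profiles[[1L]]$depth_bins)),
                 depth_lower_um = rep(profiles[[1L]]$depth_bins[, 1L],
                                      length(profiles)),
                 mean_content = unlist(lapply(profiles, function(p) p$mean_content))),
      paths[1L], sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(time_h = curve$times_h, total_content = curve$total_content),
      paths[2L], sep = "\t", row.names = FALSE, quote = FALSE)
    list(profiles = profiles, curve = curve, paths = paths)
  })
  profiles <- st$value$profiles; curve <- st$value$curve
  note("profile", st$value$paths, st$elapsed_s)

  ## -- classify -------------------------------------------------------------
  st <- stage_run("classify", {
    cl_cfg <- config$classify %||% list()
    n_per_class <- cl_cfg$n_per_class %||% 120L
    families <- cl_cfg$families %||% c("lda", "logistic")
    ds_raw <- make_labeled_spectra(scene, n_per_class,
                                   seed = sub_seed(seed, 40L),
                                   n_groups = cl_cfg$n_groups %||% NULL)
    ## curate against the matched VCA endmembers; on heavily mixed cubes
    ## without pure pixels fall back to the library references
    em_cur <- if (any(ems[[1L]]$names != "background")) ems[[1L]]
    else endmember_set(do.call(rbind, lapply(refs, function(r)
      r$spectrum$intensities)),
      names = vapply(refs, function(r) r$name, ""))
    curated <- curate_training_set(ds_raw, em_cur, cfg,
                                   seed = sub_seed(seed, 41L))
    sp <- split_dataset(curated, cfg$train_fraction, seed = sub_seed(seed, 42L))
    reports <- lapply(families, function(fam) {
      model <- train_classifier(sp$train, fam, seed = sub_seed(seed, 43L))
      evaluate(model, sp$test)
    })
    names(reports) <- families
    p <- file.path(out_dir, "auc_summary.tsv")
    auc_tab <- do.call(rbind, lapply(families, function(fam)
      data.frame(family = fam, class = names(reports[[fam]]$auc),
                 auc = unname(reports[[fam]]$auc))))
    utils::write.table(auc_tab, p, sep = "\t", row.names = FALSE, quote = FALSE)
    list(reports = reports, split = sp, paths = p)
  })
  reports <- st$value$reports
  note("classify", st$value$paths, st$elapsed_s)

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  structure(list(manifest = manifest, manifest_path = manifest_path,
                 out_dir = out_dir, scene = scene, cubes = cubes,
                 fields = fields, endmembers = ems, mcr = fits,
                 maps = maps_out$maps, overlap = maps_out$overlap,
                 profiles = profiles, curve = curve, reports = reports),
            class = "sers_run")
}

#' @export
print.sers_run <- function(x, ...) {
  cat(sprintf("<sers_run> %d stage(s) in %s\n", length(x$manifest$stages), x$out_dir))
  for (nm in names(x$manifest$stages))
    cat(sprintf("  %-9s %6.2f s, %d output(s)\n", nm,
                x$manifest$stages[[nm]]$elapsed_s,
                length(x$manifest$stages[[nm]]$outputs)))
  invisible(x)
}

#' Export the standard figure panels of a run
#'
#' Writes PNG renderings: similarity heat map (red = similar), depth-content
#' heat map (blue = high content), mixed-pesticide overlap map (categorical,
#' at most 4 colors), the content-change curve with its B-spline trend, and
#' per-family ROC curves.
#'
#' @param run a `sers_run` from [run_pipeline].
#' @param out_dir output directory; default the run's directory.
#' @param width,height device size in pixels.
#' @return character vector of written file paths, invisibly.
#' @export
export_figures <- function(run, out_dir = run$out_dir,
                           width = 640, height = 480) {
  stopifnot(inherits(run, "sers_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  draw <- function(file, expr) {
    p <- file.path(out_dir, file)
    grDevices::png(p, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
    force(expr)
    paths <<- c(paths, p)
  }
  if (is.null(run$maps)) stop_domain("run is missing the map stage output")
  draw("fig_similarity.png", plot(run$maps[[1L]]$sim))
  draw("fig_depth_content.png", {
    prof_mat <- vapply(run$profiles, function(p) p$mean_content,
                       numeric(nrow(run$profiles[[1L]]$depth_bins)))
    graphics::image(run$curve$times_h, rowMeans(run$profiles[[1L]]$depth_bins),
                    t(prof_mat),
                    col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                    xlab = "Time (h)", ylab = "Depth (um)",
                    main = "Penetration content (MCR-ALS)")
  })
  if (!is.null(run$overlap)) {
    draw("fig_overlap.png", {
      om <- run$overlap[[1L]]
      graphics::image(seq_len(ncol(om$color_values)),
                      seq_len(nrow(om$color_values)),
                      t(om$color_values)[, rev(seq_len(nrow(om$color_values))),
                                         drop = FALSE],
                      breaks = c(-0.5, sort(om$code_set) + 0.5),
                      col = c("white", "#d95f02", "#7570b3", "#1b9e77"),
                      xlab = "Lateral pixel", ylab = "Depth pixel",
                      main = sprintf("Overlap map (%s)", om$reference))
    })
  }
  draw("fig_content_curve.png", plot(run$curve,
                                     main = "Total content change"))
  for (fam in names(run$reports))
    draw(sprintf("fig_roc_%s.png", fam), plot(run$reports[[fam]]))
  invisible(paths)
}
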