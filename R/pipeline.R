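#' Run a multi-stage analysis pipeline from a config
#'
#' Drives the standard workflow — simulate a synthetic wing, calibrate the
#' model weights, export the predicted orientation field, and compute the
#' directional statistics — from a single configuration (a YAML file or an
#' equivalent named list). Each requested stage writes CSV outputs into
#' `out_dir`, and a JSON manifest recording inputs, parameters, package
#' version and seed is written at the end so any output can be reproduced.
#'
#' Config keys (all optional unless a stage needs them):
#' \describe{
#'   \item{stages}{character vector drawn from `simulate`, `fit`,
#'     `predict`, `stats`.}
#'   \item{out_dir}{output directory (default `"."`).}
#'   \item{seed}{integer seed for `simulate`.}
#'   \item{scale}{um per pixel for the CSV readers (default 56/75).}
#'   \item{geometry, ridges, quadrats, orientations}{input CSV paths
#'     (outputs of `simulate` are used automatically when present).}
#'   \item{fit}{list with `w1_min`, `w1_max`, `w1_step`, `w2_min`,
#'     `w2_max`, `w2_step` (defaults: the calibration ranges 0–2 by 0.001
#'     and 0–1493 by 0.75 um).}
#'   \item{predict}{list with `w1`, `w2`, `spacing` (defaults to the fit
#'     optimum when `fit` ran, else required).}
#'   \item{simulate}{list of [synthetic_config()] fields.}
#' }
#'
#' @param config Path to a YAML file, or a named list.
#' @param verbose Print per-stage progress? Default `TRUE`.
#' @return A list with the per-stage results and the manifest, invisibly.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  stages <- config$stages %||% "fit"
  bad <- setdiff(stages, c("simulate", "fit", "predict", "stats"))
  if (length(bad)) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scale <- config$scale %||% DEFAULT_SCALE_UM_PER_PX
  say <- function(...) if (verbose) message(sprintf(...))

  results <- list()
  manifest <- list(
    package = "trichor",
    version = as.character(utils::packageVersion("trichor")),
    scale_um_per_px = scale, stages = stages,
    seed = config$seed, inputs = list(), outputs = list()
  )
  geom <- NULL
  quadrats <- NULL

  stage <- function(name, code) {
    t0 <- Sys.time()
    res <- tryCatch(code, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    say("stage %s done in %.2fs", name,
        as.numeric(Sys.time() - t0, units = "secs"))
    res
  }

  load_inputs <- function() {
    if (is.null(geom)) {
      if (is.null(config$geometry)) abort("no geometry input configured.")
      geom <<- read_geometry_csv(config$geometry,
                                 ridges_path = config$ridges,
                                 scale = scale)
      manifest$inputs$geometry <<- config$geometry
    }
    if (is.null(quadrats)) {
      if (is.null(config$quadrats) || is.null(config$orientations)) {
        abort("no quadrat/orientation inputs configured.")
      }
      quadrats <<- read_quadrat_data(config$quadrats, config$orientations,
                                     geom, scale = scale)
      manifest$inputs$quadrats <<- config$quadrats
      manifest$inputs$orientations <<- config$orientations
      say("loaded %d quadrats (%d in wing), %d hairs",
          nrow(quadrats), sum(quadrats$in_wing), sum(quadrats$n_hairs))
    }
  }

  if ("simulate" %in% stages) {
    results$simulate <- stage("simulate", {
      sim_args <- config$simulate %||% list()
      if (!is.null(config$seed)) sim_args$seed <- config$seed
      cfg <- do.call(synthetic_config, sim_args)
      geom <- generate_wing(cfg)
      quadrats <- sample_quadrats(geom, cfg)
      gpath <- file.path(out_dir, "geometry.csv")
      qpath <- file.path(out_dir, "quadrats.csv")
      opath <- file.path(out_dir, "orientations.csv")
      write_geometry_csv(geom, gpath)
      write_quadrats_csv(quadrats, qpath, scale = geom$scale)
      write_orientations_csv(
        tidyr::unnest(quadrats[c("quadrat", "angles")],
                      "angles") |>
          dplyr::rename(phi_deg = "angles"), opath)
      truth_path <- file.path(out_dir, "truth.json")
      jsonlite::write_json(
        list(w1 = cfg$truth$w1, w2 = cfg$truth$w2, seed = cfg$seed,
             noise_sd_deg = cfg$noise_sd_deg),
        truth_path, auto_unbox = TRUE, digits = NA)
      manifest$outputs <- c(manifest$outputs,
                            list(geometry = gpath, quadrats = qpath,
                                 orientations = opath, truth = truth_path))
      config$geometry <- gpath
      list(config = cfg)
    })
  }

  if ("fit" %in% stages) {
    results$fit <- stage("fit", {
      load_inputs()
      f <- config$fit %||% list()
      w1 <- seq(f$w1_min %||% 0, f$w1_max %||% 2, by = f$w1_step %||% 0.001)
      w2 <- seq(f$w2_min %||% 0, f$w2_max %||% 1493,
                by = f$w2_step %||% 0.75)
      say("grid search: %d x %d = %d SSR evaluations over %d quadrats",
          length(w1), length(w2), length(w1) * length(w2),
          sum(quadrats$in_wing))
      surf <- grid_search(quadrats, geom, w1, w2)
      fpath <- file.path(out_dir, "fit.csv")
      readr::write_csv(glance(surf), fpath)
      manifest$outputs$fit <- fpath
      if (isTRUE(config$write_surface)) {
        spath <- file.path(out_dir, "ssr_surface.csv")
        readr::write_csv(tidy(surf), spath)
        manifest$outputs$ssr_surface <- spath
      }
      manifest$fit <- list(w1_grid = length(w1), w2_grid = length(w2),
                           w1 = surf$params$w1, w2 = surf$params$w2,
                           min_ssr = surf$min_ssr)
      surf
    })
  }

  if ("predict" %in% stages) {
    results$predict <- stage("predict", {
      load_inputs()
      pr <- config$predict %||% list()
      params <- if (!is.null(pr$w1)) {
        model_params(pr$w1, pr$w2)
      } else if (!is.null(results$fit)) {
        results$fit$params
      } else {
        abort("predict needs `predict: {w1, w2}` or a prior fit stage.")
      }
      fld <- field_on_grid(geom, params, spacing = pr$spacing %||% 100)
      ppath <- file.path(out_dir, "field.csv")
      readr::write_csv(
        dplyr::mutate(fld, x_px = .data$x / scale, y_px = -.data$y / scale,
                      .before = 1) |>
          dplyr::rename(x_um = "x", y_um = "y"), ppath)
      manifest$outputs$field <- ppath
      fld
    })
  }

  if ("stats" %in% stages) {
    results$stats <- stage("stats", {
      load_inputs()
      st <- direction_stats(quadrats, geom,
                            params = if (!is.null(results$fit)) {
                              results$fit$params
                            })
      spath <- file.path(out_dir, "direction_stats.csv")
      readr::write_csv(st$bias, spath)
      manifest$outputs$direction_stats <- spath
      st
    })
  }

  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  say("manifest written to %s", mpath)
  invisible(c(results, list(manifest = manifest)))
}

#' Directional-bias and fidelity statistics for a quadrat dataset
#'
#' Classifies every quadrat (upslope / edgeward) and every hair (distal),
#' attaches the exact binomial tail probability to each bias count, and —
#' when model parameters are supplied — the model-fidelity summary of
#' predicted versus observed mean orientations over the in-wing quadrats.
#' Upslope classification uses all quadrats with a defined upslope
#' direction; edge-related statistics use in-wing quadrats only.
#'
#' @param quadrats A quadrat tibble (see [quadrat_samples()]).
#' @param geom A [wing_geometry()].
#' @param params Optional [model_params()] for the fidelity block.
#' @return A list: `per_quadrat` (classification flags), `bias` (one row
#'   per analysis: counts, fraction, exact tail probability), and — with
#'   `params` — `fidelity` (see [model_fidelity()]) and
#'   `residual_distance` (see [residual_distance_fit()]).
#' @export
direction_stats <- function(quadrats, geom, params = NULL) {
  per_q <- classify_upslope(quadrats, geom)
  per_q <- classify_edgeward(per_q, geom)
  hairs <- tidyr::unnest(quadrats[c("quadrat", "in_wing", "angles")],
                         "angles")
  up <- per_q$upslope[!is.na(per_q$upslope)]
  ed <- per_q$edgeward[per_q$in_wing]
  di <- classify_distal(hairs$angles)
  bias <- dplyr::bind_rows(
    dplyr::mutate(bias_summary(sum(up), length(up)), analysis = "upslope",
                  unit = "quadrats", .before = 1),
    dplyr::mutate(bias_summary(sum(ed), length(ed)), analysis = "edgeward",
                  unit = "quadrats", .before = 1),
    dplyr::mutate(bias_summary(sum(di), length(di)), analysis = "distal",
                  unit = "hairs", .before = 1)
  )
  out <- list(per_quadrat = per_q, bias = bias)
  if (!is.null(params)) {
    q <- quadrats[quadrats$in_wing, ]
    pred <- model_orientation(q[c("x", "y")], params, geom)
    out$fidelity <- model_fidelity(
      tibble(quadrat = q$quadrat, phi_deg = pred$phi_deg),
      tibble(quadrat = q$quadrat, phi_deg = q$mean_phi_deg))
    out$residual_distance <- residual_distance_fit(quadrats, geom)
  }
  out
}
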