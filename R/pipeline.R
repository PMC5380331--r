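# Configuration, provenance, and the end-to-end pipeline driver. All file
# formats are plain text: PGM image stacks, CSV tables, JSON fits and
# reports. Every run writes the resolved configuration verbatim next to its
# results together with a config hash, the seed and the package version.

#' Pipeline configuration
#'
#' Bundles the sub-configurations of every stage and validates them. The
#' resolved configuration is written verbatim (JSON) next to all results.
#'
#' @param optics an [optical_model()].
#' @param scene a [scene_params()].
#' @param n_theta angular bins for amplitude maps.
#' @param mode_range integer (lo, hi) summed into the total power.
#' @param h_max,std_max tight-adhesion thresholds (nm).
#' @param segmentation list of [extract_contour()] parameters
#'   (`threshold_frac`, `min_area_px`, `closing_radius`).
#' @param seed integer master seed.
#' @param outdir output directory.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(optics = optical_model(), scene = scene_params(),
                            n_theta = 360L, mode_range = c(2L, 10L),
                            h_max = 40, std_max = 10,
                            segmentation = list(threshold_frac = 0.25,
                                                min_area_px = 25L,
                                                closing_radius = 2L),
                            seed = 1L, outdir = tempfile("hscadhesion_")) {
  stopifnot(inherits(optics, "optical_model"), inherits(scene, "scene_params"))
  if (n_theta < 16L) stop_param("n_theta must be >= 16")
  if (length(mode_range) != 2L || mode_range[1] > mode_range[2] ||
      mode_range[2] >= n_theta / 2)
    stop_param("mode_range must be (lo, hi) with hi < n_theta/2")
  if (h_max <= 0 || std_max <= 0) stop_param("thresholds must be > 0")
  need <- c("threshold_frac", "min_area_px", "closing_radius")
  if (!all(need %in% names(segmentation)))
    stop_param("segmentation config missing fields: %s",
               paste(setdiff(need, names(segmentation)), collapse = ", "))
  structure(list(optics = optics, scene = scene, n_theta = as.integer(n_theta),
                 mode_range = as.integer(mode_range), h_max = h_max,
                 std_max = std_max, segmentation = segmentation,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

config_json <- function(config) {
  jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = NA,
                   pretty = TRUE)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

provenance <- function(config) {
  list(config_hash = fnv1a(as.character(config_json(config))),
       seed = config$seed,
       package_version = as.character(utils::packageVersion("hscadhesion")))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run a pipeline stage
#'
#' Deterministic end-to-end drivers over plain-text artifacts in
#' `config$outdir`:
#'
#' * `simulate`: one synthetic cell per motion class (contours as CSV), an
#'   RICM interferogram stack (PGM) with its ground truth, adhesion counts,
#'   detachment counts and calibration pairs (CSV).
#' * `ricm`: illumination-correct and reconstruct `ricm_stack.pgm`, measure
#'   the tight-adhesion area, write `ricm_result.json` + height map PGM.
#' * `modes`: amplitude map, autocorrelation, mode spectrum, and motion
#'   label for every `contours_*.csv`; writes per-cell CSV matrices and a
#'   JSON feature report.
#' * `hill`: Hill fit of `adhesion_counts.csv`, written to `hill_fit.json`.
#' * `detach`: calibration fit of `calibration.csv` and P* estimate from
#'   `detachment_counts.csv`, written to `detachment_fit.json`.
#' * `report`: aggregate all per-cell mode reports into `report.csv`
#'   (means +- SD per motion class).
#'
#' Every JSON artifact embeds provenance (config hash, seed, package
#' version); the resolved config is stored as `config_used.json`.
#'
#' @param command one of `"simulate"`, `"ricm"`, `"modes"`, `"hill"`,
#'   `"detach"`, `"report"`.
#' @param config a [pipeline_config()].
#' @return invisibly, a list of paths written (and for analysis stages the
#'   key results).
#' @export
run_pipeline <- function(command = c("simulate", "ricm", "modes", "hill",
                                     "detach", "report"),
                         config = pipeline_config()) {
  command <- match.arg(command)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  writeLines(as.character(config_json(config)),
             file.path(config$outdir, "config_used.json"))
  switch(command,
         simulate = pipeline_simulate(config),
         ricm = pipeline_ricm(config),
         modes = pipeline_modes(config),
         hill = pipeline_hill(config),
         detach = pipeline_detach(config),
         report = pipeline_report(config))
}

pipeline_simulate <- function(config) {
  out <- config$outdir
  paths <- character(0)
  classes <- c("rotational", "oscillatory", "translational")
  for (i in seq_along(classes)) {
    cs <- make_contour_series(motion_params(classes[i], seed = config$seed + i))
    df <- data.frame(frame = rep(seq_along(cs$polygons), each = nrow(cs$polygons[[1]])),
                     time = rep(cs$time, each = nrow(cs$polygons[[1]])),
                     x = unlist(lapply(cs$polygons, function(p) p[, 1])),
                     y = unlist(lapply(cs$polygons, function(p) p[, 2])))
    p <- file.path(out, sprintf("contours_%s.csv", classes[i]))
    utils::write.csv(df, p, row.names = FALSE)
    write_json_file(c(provenance(config),
                      list(motion_class = classes[i], n_frames = length(cs$polygons))),
                    file.path(out, sprintf("contours_%s.json", classes[i])))
    paths <- c(paths, p)
  }
  # RICM scene: tight-adhesion disc of radius 2.26 um with a steep 100 nm rim
  profile <- function(rho) ifelse(rho <= 2.26, 0, 100)
  sc <- make_ricm_scene(profile, config$optics, config$scene,
                        seed = config$seed + 101L)
  p <- file.path(out, "ricm_stack.pgm")
  write_pgm_stack(sc$images, p)
  write_pgm_stack(sc$height, file.path(out, "ricm_truth_height.pgm"))
  paths <- c(paths, p)
  counts <- make_adhesion_counts(c(6, 11, 18, 27, 34, 50), seed = config$seed + 201L)
  utils::write.csv(counts, file.path(out, "adhesion_counts.csv"), row.names = FALSE)
  det <- make_detachment_data(exp(seq(log(2), log(20), length.out = 7)),
                              seed = config$seed + 301L)
  utils::write.csv(det, file.path(out, "detachment_counts.csv"), row.names = FALSE)
  cal <- make_calibration_data(exp(seq(log(1), log(100), length.out = 20)),
                               seed = config$seed + 401L)
  utils::write.csv(cal, file.path(out, "calibration.csv"), row.names = FALSE)
  invisible(list(paths = c(paths, file.path(out, c("adhesion_counts.csv",
                                                   "detachment_counts.csv",
                                                   "calibration.csv")))))
}

pipeline_ricm <- function(config) {
  out <- config$outdir
  p <- file.path(out, "ricm_stack.pgm")
  if (!file.exists(p)) stop_param("no RICM input found at %s; run simulate first", p)
  stack <- read_pgm_stack(p)
  corr <- correct_illumination(stack)
  hm <- reconstruct_height(corr, config$optics)
  ta <- tight_adhesion_area(hm, config$h_max, config$std_max)
  write_pgm_stack(array(c(ifelse(hm$valid_mask & !is.na(hm$mean_height),
                                 hm$mean_height, 0),
                          ifelse(is.na(hm$height_std), 0, hm$height_std)),
                        c(dim(hm$mean_height), 2L)),
                  file.path(out, "height_map.pgm"))
  res <- c(provenance(config),
           list(area_um2 = ta$area_um2, empty_footprint = ta$empty,
                h_max = config$h_max, std_max = config$std_max,
                invalid_fraction = mean(!hm$valid_mask)))
  write_json_file(res, file.path(out, "ricm_result.json"))
  invisible(list(height_map = hm, tight_adhesion = ta,
                 paths = file.path(out, c("height_map.pgm", "ricm_result.json"))))
}

read_contour_csv <- function(path) {
  df <- utils::read.csv(path)
  split_polys <- split(df[, c("x", "y")], df$frame)
  list(polygons = lapply(split_polys, as.matrix),
       time = unique(df[, c("frame", "time")])$time)
}

pipeline_modes <- function(config) {
  out <- config$outdir
  files <- list.files(out, pattern = "^contours_.*\\.csv$", full.names = TRUE)
  if (!length(files)) stop_param("no contour CSVs in %s; run simulate first", out)
  results <- list()
  for (f in files) {
    cell <- sub("^contours_(.*)\\.csv$", "\\1", basename(f))
    cc <- read_contour_csv(f)
    am <- amplitude_map(cc$polygons, time = cc$time, n_theta = config$n_theta)
    ac <- autocorrelation_map(am)
    sp <- mode_power_spectrum(am, max_mode = config$mode_range[2],
                              total_range = config$mode_range)
    cl <- classify_motion(am, ac, sp)
    utils::write.csv(am$r, file.path(out, sprintf("amplitude_%s.csv", cell)),
                     row.names = FALSE)
    utils::write.csv(ac$gamma, file.path(out, sprintf("autocorr_%s.csv", cell)),
                     row.names = FALSE)
    utils::write.csv(data.frame(mode = sp$mode, power = sp$power),
                     file.path(out, sprintf("modes_%s.csv", cell)),
                     row.names = FALSE)
    rep <- c(provenance(config),
             list(cell = cell, label = cl$label,
                  features = as.list(cl$features),
                  dominant_mode = dominant_mode(sp),
                  total_power = sp$total_power,
                  total_power_with_m1 = sp$total_power_with_m1))
    write_json_file(rep, file.path(out, sprintf("modes_%s.json", cell)))
    results[[cell]] <- rep
  }
  invisible(list(results = results))
}

pipeline_hill <- function(config) {
  out <- config$outdir
  p <- file.path(out, "adhesion_counts.csv")
  if (!file.exists(p)) stop_param("no adhesion counts at %s; run simulate first", p)
  tab <- utils::read.csv(p)
  fit <- hill_fit(tab$d, 100 * tab$n_adherent / tab$n_seeded,
                  n_seeded = tab$n_seeded)
  res <- c(provenance(config),
           list(par = as.list(fit$par), se = as.list(fit$se),
                converged = fit$converged, extrapolated = fit$extrapolated))
  write_json_file(res, file.path(out, "hill_fit.json"))
  invisible(list(fit = fit, paths = file.path(out, "hill_fit.json")))
}

pipeline_detach <- function(config) {
  out <- config$outdir
  pc <- file.path(out, "calibration.csv")
  pd <- file.path(out, "detachment_counts.csv")
  if (!file.exists(pc) || !file.exists(pd))
    stop_param("missing calibration.csv / detachment_counts.csv in %s", out)
  cal_tab <- utils::read.csv(pc)
  cal <- fit_calibration(cal_tab$E, cal_tab$P)
  det_tab <- utils::read.csv(pd)
  dc <- estimate_critical_pressure(det_tab$P, det_tab$n_exposed,
                                   det_tab$n_detached, seed = config$seed)
  res <- c(provenance(config),
           list(calibration = list(prefactor = cal$prefactor,
                                   exponent = cal$exponent,
                                   exponent_se = cal$exponent_se),
                p_star = dc$p_star, p_star_ci = dc$ci, method = dc$method))
  write_json_file(res, file.path(out, "detachment_fit.json"))
  invisible(list(calibration = cal, detachment = dc,
                 paths = file.path(out, "detachment_fit.json")))
}

pipeline_report <- function(config) {
  out <- config$outdir
  files <- list.files(out, pattern = "^modes_.*\\.json$", full.names = TRUE)
  if (!length(files)) stop_param("no per-cell mode reports in %s; run modes first", out)
  rows <- lapply(files, function(f) {
    j <- jsonlite::read_json(f, simplifyVector = TRUE)
    data.frame(cell = j$cell, label = j$label,
               dominant_mode = j$dominant_mode,
               total_power = j$total_power)
  })
  cells <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(cells, cells$label), function(g) {
    data.frame(label = g$label[1], n_cells = nrow(g),
               total_power_mean = mean(g$total_power),
               total_power_sd = if (nrow(g) > 1) stats::sd(g$total_power) else NA_real_)
  }))
  p <- file.path(out, "report.csv")
  utils::write.csv(agg, p, row.names = FALSE)
  invisible(list(cells = cells, summary = agg, paths = p))
}
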