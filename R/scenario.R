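# Scenario orchestration: a declarative JSON config fully specifies grid,
# hidden screen, guide star, GA, depletion factors, phantom and seeds; one
# master seed derives independent named sub-seeds per stage so changing one
# stage's draw count cannot shift another's.

scenario_defaults <- function() list(
  grid = list(n_pixels = 128L, na = 1.4, wavelength_nm = 760,
              excitation_wavelength_nm = 635, medium_index = 1.518,
              pupil_fill = 1.0),
  screen = list(kind = "zernike_random", total_rms_rad = 1.5,
                mode_range = 4:11, defocus_um = 0.5,
                power_law_exponent = -11 / 6),
  guide_star = list(position_nm = c(0, 0), pinhole_radius_nm = NULL),
  ga = list(mode = "zernike", segments_n = 3L, zernike_modes = 4:15,
            population_size = 30L, n_generations = 300L, n_parents = 15L,
            mutation_rate_initial = 0.1, mutation_rate_final = 0.013,
            mutation_decay = 40, mutation_scale_initial = 0.5,
            mutation_scale_final = 0.05, elitism = 2L, stop_patience = 30L,
            noise_sd = 0),
  depletion = list(zeta = c(4)),
  phantom = list(kind = "bead_field", n_beads = 6L,
                 min_separation_nm = 500, field_size_nm = 3000,
                 n_close_pairs = 1L, pair_separation_nm = 150,
                 photon_scale = 200, noise = "poisson"),
  oversample = 4L,
  master_seed = 1L,
  output_dir = "stedao-out")

#' Derive a named sub-seed from the master seed
#'
#' Deterministic per-stage streams ("screen", "ga", "noise", "phantom", ...)
#' so stages cannot perturb each other's draws. Result is a valid 32-bit
#' seed.
#'
#' @param master_seed integer.
#' @param stream stage name.
#' @return integer seed.
#' @export
sub_seed <- function(master_seed, stream) {
  ids <- c(screen = 1L, ga = 2L, noise = 3L, phantom = 4L, imaging = 5L)
  id <- if (stream %in% names(ids)) ids[[stream]]
        else sum(utf8ToInt(stream)) %% 1000L
  as.integer((as.numeric(master_seed) * 7919 + id * 104729) %% 2147483647)
}

# polynomial rolling hash; cheap content hash for artifact traceability
fnv1a <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483629
  sprintf("%08x", h)
}

#' Validate a scenario config file
#'
#' Reads a JSON scenario, merges it over the documented defaults and returns
#' either a validated scenario list or the complete list of violations (not
#' just the first). Unknown keys are reported with a nearest-match
#' suggestion.
#'
#' @param path JSON file path.
#' @return list with class `scenario` on success; otherwise an error is
#'   thrown whose message enumerates all violations. Use
#'   [check_scenario()] to get the violation list without erroring.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) e)
  if (inherits(raw, "error"))
    stop("config is not valid JSON: ", conditionMessage(raw))
  v <- check_scenario(raw)
  if (length(attr(v, "violations")) > 0)
    stop("invalid scenario config:\n  - ",
         paste(attr(v, "violations"), collapse = "\n  - "))
  v
}

#' Check a scenario list against the schema
#'
#' @param cfg named list (parsed JSON).
#' @return scenario list (defaults merged) with attribute `violations`
#'   (character vector, empty when valid).
#' @export
check_scenario <- function(cfg) {
  defs <- scenario_defaults()
  viol <- character(0)
  note <- function(msg) viol <<- c(viol, msg)
  suggest <- function(key, known) {
    d <- utils::adist(key, known)
    if (min(d) <= 3) sprintf(" (did you mean '%s'?)", known[which.min(d)])
    else ""
  }
  if (!is.list(cfg)) { note("config root must be a JSON object"); cfg <- list() }
  for (k in names(cfg))
    if (!k %in% names(defs))
      note(sprintf("unknown key '%s'%s", k, suggest(k, names(defs))))
  out <- defs
  for (k in intersect(names(cfg), names(defs))) {
    if (is.list(defs[[k]])) {
      sub <- cfg[[k]]
      if (!is.list(sub)) { note(sprintf("'%s' must be an object", k)); next }
      for (k2 in names(sub))
        if (!k2 %in% names(defs[[k]]))
          note(sprintf("unknown key '%s.%s'%s", k, k2,
                       suggest(k2, names(defs[[k]]))))
      out[[k]] <- utils::modifyList(defs[[k]],
                                    sub[intersect(names(sub),
                                                  names(defs[[k]]))])
    } else out[[k]] <- cfg[[k]]
  }
  g <- out$grid
  if (!is.numeric(g$n_pixels) || g$n_pixels < 16 || g$n_pixels %% 2 != 0)
    note("grid.n_pixels must be an even integer >= 16")
  if (!is.numeric(g$na) || g$na <= 0 || g$na > g$medium_index)
    note("grid.na must satisfy 0 < na <= medium_index")
  if (!is.numeric(g$wavelength_nm) || g$wavelength_nm <= 0)
    note("grid.wavelength_nm must be positive")
  if (!out$screen$kind %in% c("zernike_random", "defocus", "spherical",
                              "turbulence"))
    note("screen.kind must be one of zernike_random/defocus/spherical/turbulence")
  if (!is.numeric(out$screen$total_rms_rad) || out$screen$total_rms_rad < 0)
    note("screen.total_rms_rad must be >= 0")
  if (!out$ga$mode %in% c("segment", "zernike", "mixed"))
    note("ga.mode must be segment/zernike/mixed")
  if (!is.numeric(out$depletion$zeta) || any(out$depletion$zeta < 0))
    note("depletion.zeta must be >= 0 (negative saturation is meaningless)")
  if (!is.numeric(out$ga$population_size) || out$ga$population_size < 2)
    note("ga.population_size must be >= 2")
  if (!out$phantom$kind %in% c("bead_field", "bead_pair", "filaments"))
    note("phantom.kind must be bead_field/bead_pair/filaments")
  if (!out$phantom$noise %in% c("none", "poisson"))
    note("phantom.noise must be none/poisson")
  if (length(viol) == 0) class(out) <- "scenario"
  attr(out, "violations") <- viol
  out
}

scenario_hash <- function(scn) {
  s <- scn; attributes(s) <- list(names = names(s))
  fnv1a(jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA))
}

#' Run a full correction-and-imaging scenario
#'
#' The end-to-end experiment shape: realize the hidden screen, run the GA on
#' the guide-star signal, then image a phantom confocally and with the
#' uncorrected/corrected STED donut. Writes PSF TIFFs, the correction mask
#' (BMP + PGM + radians TIFF), the fitness trace CSV, phantom images and a
#' metrics CSV (FWHMs, null depth, ring uniformity, mean intensity), plus a
#' manifest embedding the scenario hash and package version.
#'
#' @param scenario a validated `scenario` (from [validate_config()] /
#'   [check_scenario()]), or a named list merged over the defaults.
#' @param output_dir overrides `scenario$output_dir`.
#' @param verbose print stage progress.
#' @return invisible list: scenario, hash, metrics data.frame, ga result,
#'   file paths.
#' @export
run_scenario <- function(scenario = list(), output_dir = NULL,
                         verbose = TRUE) {
  if (!inherits(scenario, "scenario")) {
    scenario <- check_scenario(scenario)
    if (length(attr(scenario, "violations")) > 0)
      stop("invalid scenario:\n  - ",
           paste(attr(scenario, "violations"), collapse = "\n  - "))
  }
  scn <- scenario
  hash <- scenario_hash(scn)
  dir <- if (is.null(output_dir)) scn$output_dir else output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop(sprintf("scenario %s failed at stage '%s': %s", hash, name,
                 conditionMessage(e)), call. = FALSE))
  pth <- function(f) file.path(dir, f)

  g <- scn$grid
  grid_dep <- pupil_grid(g$n_pixels, g$na, g$wavelength_nm, g$medium_index,
                         g$pupil_fill)
  grid_exc <- pupil_grid(g$n_pixels, g$na, g$excitation_wavelength_nm,
                         g$medium_index, g$pupil_fill)
  ov <- scn$oversample

  say("[1/5] screen (%s, seed %d)", scn$screen$kind,
      sub_seed(scn$master_seed, "screen"))
  screen <- stage("screen", {
    rec <- screen_recipe(scn$screen$kind, scn$screen$total_rms_rad,
                         scn$screen$mode_range, scn$screen$defocus_um,
                         scn$screen$power_law_exponent,
                         sub_seed(scn$master_seed, "screen"))
    make_screen(rec, grid_dep)
  })

  star <- guide_star(scn$guide_star$position_nm,
                     scn$guide_star$pinhole_radius_nm)

  say("[2/5] GA correction (%s mode)", scn$ga$mode)
  ga_out <- stage("ga", {
    spec <- genome_spec(scn$ga$mode,
                        layout = if (scn$ga$mode != "zernike")
                          segment_layout(scn$ga$segments_n, grid_dep) else NULL,
                        zernike_modes = scn$ga$zernike_modes, grid = grid_dep)
    cfg <- ga_config(scn$ga$population_size, scn$ga$n_generations,
                     scn$ga$n_parents, scn$ga$mutation_rate_initial,
                     scn$ga$mutation_rate_final, scn$ga$mutation_decay,
                     scn$ga$mutation_scale_initial,
                     scn$ga$mutation_scale_final, scn$ga$elitism,
                     sub_seed(scn$master_seed, "ga"), scn$ga$stop_patience)
    fit <- ga_fitness(spec, screen, star, scn$ga$noise_sd)
    res <- run_ga(fit, cfg, spec)
    res$spec <- spec
    res
  })
  correction <- correction_from_genome(ga_out$best, ga_out$spec)

  say("[3/5] PSFs (uncorrected/corrected, Gaussian/donut)")
  spiral <- spiral_phase(grid_dep, 1L)
  zero <- zero_mask(grid_dep)
  psfs <- stage("psf", list(
    gauss_unc = focal_psf(grid_dep, compose_masks(zero, screen$phase),
                          oversample = ov),
    gauss_cor = focal_psf(grid_dep, compose_masks(correction, screen$phase),
                          oversample = ov),
    donut_unc = focal_psf(grid_dep, compose_masks(spiral, screen$phase),
                          oversample = ov),
    donut_cor = focal_psf(grid_dep,
                          compose_masks(spiral, correction, screen$phase),
                          oversample = ov),
    exc = focal_psf(grid_exc, oversample = ov)))

  say("[4/5] phantom imaging")
  ph <- scn$phantom
  phantom <- stage("phantom", switch(ph$kind,
    filaments = make_filaments(3L, 2000, 0, ph$field_size_nm,
                               sub_seed(scn$master_seed, "phantom")),
    make_bead_field(ph$n_beads, ph$min_separation_nm, ph$field_size_nm,
                    sub_seed(scn$master_seed, "phantom"),
                    if (ph$kind == "bead_pair") max(1L, ph$n_close_pairs)
                    else ph$n_close_pairs,
                    ph$pair_separation_nm)))
  zeta <- scn$depletion$zeta[1]
  images <- stage("imaging", {
    h_conf <- match_psf_grid(psfs$exc, psfs$donut_unc)
    h_unc <- effective_sted_psf(h_conf, psfs$donut_unc, zeta)
    h_cor <- effective_sted_psf(h_conf, psfs$donut_cor, zeta)
    iseed <- sub_seed(scn$master_seed, "imaging")
    list(confocal = scan_image(phantom, h_conf, photon_scale = ph$photon_scale,
                               noise = ph$noise, rng_seed = iseed),
         sted_uncorrected = scan_image(phantom, h_unc,
                                       photon_scale = ph$photon_scale,
                                       noise = ph$noise, rng_seed = iseed + 1L),
         sted_corrected = scan_image(phantom, h_cor,
                                     photon_scale = ph$photon_scale,
                                     noise = ph$noise, rng_seed = iseed + 2L))
  })

  say("[5/5] metrics + artifacts")
  metrics <- stage("metrics", {
    em <- phantom$emitters
    # profile the most isolated bright emitter, away from neighbours/borders
    nn <- if (nrow(em) > 1) {
      dm <- as.matrix(stats::dist(em[, c("x_nm", "y_nm")]))
      diag(dm) <- Inf
      apply(dm, 1, min)
    } else rep(Inf, nrow(em))
    border <- pmin(em$x_nm, em$y_nm, phantom$field_size_nm - em$x_nm,
                   phantom$field_size_nm - em$y_nm)
    idx <- which.max(pmin(nn / 2, border))
    bead <- em[idx, ]
    px <- attr(images$confocal, "pixel_size_nm")
    half_nm <- min(900, max(450, nn[idx] / 2), border[idx])
    line_fwhm <- function(img) {
      cx <- bead$x_nm / px + 0.5; cy <- bead$y_nm / px + 0.5
      h_px <- half_nm / px
      s <- c(max(1, cx - h_px), cy); e <- c(min(nrow(img), cx + h_px), cy)
      as.numeric(metric_fwhm(img, s, e))
    }
    data.frame(
      channel = c("confocal", "sted_uncorrected", "sted_corrected"),
      fwhm_nm = vapply(images, line_fwhm, numeric(1)),
      mean_intensity = vapply(images, metric_mean_intensity, numeric(1)),
      null_depth_donut = c(NA, metric_null_depth(psfs$donut_unc),
                           metric_null_depth(psfs$donut_cor)),
      ring_uniformity = c(NA, metric_ring_uniformity(psfs$donut_unc),
                          metric_ring_uniformity(psfs$donut_cor)))
  })

  files <- stage("write", {
    f <- c(trace = pth("fitness_trace.csv"),
           mask_bmp = pth("correction_mask.bmp"),
           mask_pgm = pth("correction_mask.pgm"),
           mask_tiff = pth("correction_mask_rad.tiff"),
           metrics = pth("metrics.csv"),
           manifest = pth("manifest.json"))
    write_trace_csv(ga_out$trace, f["trace"], hash)
    q <- quantize_mask(correction)
    write_mask_bmp(q, f["mask_bmp"])
    write_mask_pgm(q, f["mask_pgm"])
    write_tiff_float(correction, f["mask_tiff"], pixel_size_nm = 1)
    for (nm in names(psfs))
      write_tiff_float(psfs[[nm]], pth(sprintf("psf_%s.tiff", nm)))
    for (nm in names(images))
      write_tiff_float(images[[nm]], pth(sprintf("image_%s.tiff", nm)))
    write_phantom_csv(phantom, pth("phantom.csv"))
    con <- file(f["metrics"], "w")
    writeLines(sprintf("# stedao %s scenario %s",
                       as.character(utils::packageVersion("stedao")), hash),
               con)
    utils::write.csv(metrics, con, row.names = FALSE)
    close(con)
    jsonlite::write_json(
      list(package = "stedao",
           version = as.character(utils::packageVersion("stedao")),
           scenario_hash = hash,
           scenario = {
             s <- scn; attributes(s) <- list(names = names(s)); s
           },
           n_fitness_evaluations = ga_out$n_evaluations,
           files = as.list(c(f, vapply(names(psfs), function(nm)
             pth(sprintf("psf_%s.tiff", nm)), character(1))))),
      f["manifest"], auto_unbox = TRUE, pretty = TRUE, digits = NA)
    f
  })
  say("done: %s (scenario %s, %d fitness evaluations)", dir, hash,
      ga_out$n_evaluations)
  invisible(list(scenario = scn, hash = hash, metrics = metrics,
                 ga = ga_out, correction = correction, screen = screen,
                 psfs = psfs, images = images, files = files))
}
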