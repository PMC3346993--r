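#' One-call second-order calibration of a cube
#'
#' Convenience wrapper chaining decomposition ([parafac_als()] or
#' [swatld()]), factor matching ([align_factors()]), concentration
#' prediction ([predict_concentrations()]) and figures of merit
#' ([fom_report()]).
#'
#' @param cube A [data_cube()] holding calibration, prediction and
#'   (optionally) blank samples, decomposed jointly.
#' @param design The companion [calibration_design()].
#' @param reference_spectra Wavelengths x analytes matrix of reference
#'   spectra used to identify the analyte factors (e.g. measured pure
#'   standards, or the generator's ground-truth spectra).
#' @param algorithm `"parafac_als"` or `"swatld"`.
#' @param options A [fit_options()].
#' @return List with `loadings` (aligned), `prediction`
#'   (`PredictionReport`), `fom` (`FomReport`).
#' @export
second_order_calibration <- function(cube, design, reference_spectra,
                                     algorithm = c("parafac_als", "swatld"),
                                     options = fit_options(3)) {
  algorithm <- match.arg(algorithm)
  fit <- switch(algorithm,
                parafac_als = parafac_als(cube, options),
                swatld = swatld(cube, options))
  aligned <- align_factors(fit, reference_spectra)
  pred <- predict_concentrations(aligned, design)
  fom <- fom_report(aligned, pred)
  list(loadings = aligned, prediction = pred, fom = fom)
}

#' Run the full simulate / rank / decompose / calibrate / fom pipeline
#'
#' Executes the requested stages in order, writing each stage's outputs
#' before the next starts, and returns a manifest sufficient (with the
#' input directory and seeds) to reproduce every output bit for bit.
#'
#' The configuration is a list (or path to a YAML file) with fields:
#' \describe{
#'   \item{seed}{integer, drives the simulation and any random starts.}
#'   \item{outdir}{output directory.}
#'   \item{stages}{subset of `c("simulate", "rank", "decompose",
#'     "calibrate", "fom")`; always executed in that order. Stages other
#'     than `simulate` require either the `simulate` stage or `data_dir`.}
#'   \item{data_dir}{optional existing cube directory (read with
#'     [load_cube()]) used when `simulate` is not among the stages; the
#'     `calibrate` stage then also needs `reference_spectra`, a CSV whose
#'     first column is the wavelength and remaining columns the analyte
#'     spectra.}
#'   \item{n_components}{components for decomposition/calibration; defaults
#'     to the rank scan's choice when available, else 3.}
#'   \item{scan_range}{candidates for the rank stage (default 1:6).}
#'   \item{algorithms}{subset of `c("parafac_als", "swatld")`; default both.}
#'   \item{noise_sd, baseline_offset}{forwarded to [paperlike_dataset()]
#'     when simulating.}
#' }
#'
#' @param config List or path to a YAML config file.
#' @return Invisibly, a `"RunManifest"`: config snapshot, package version,
#'   per-stage output paths with MD5 checksums and timings; also written to
#'   `manifest.json` in `outdir`. If a stage fails, the partial manifest
#'   (with the failed stage marked) is written before the error propagates.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  if (is.null(config$outdir)) stop("config needs `outdir`")
  outdir <- config$outdir
  order_all <- c("simulate", "rank", "decompose", "calibrate", "fom")
  stages <- config$stages %||% order_all
  if (length(setdiff(stages, order_all)))
    stop("unknown stage(s): ",
         paste(setdiff(stages, order_all), collapse = ", "))
  stages <- order_all[order_all %in% stages]
  algorithms <- config$algorithms %||% c("parafac_als", "swatld")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(config = config, seed = seed,
                   package_version = as.character(utils::packageVersion("trical")),
                   started = format(Sys.time(), usetz = TRUE),
                   stages = list())
  st <- new.env(parent = emptyenv())   # cube, design, refs, n_comp, results
  st$n_comp <- config$n_components

  ensure_data <- function() {
    if (!is.null(st$cube)) return(invisible())
    if (is.null(config$data_dir))
      stop("no data: include the `simulate` stage or set `data_dir`")
    ld <- load_cube(config$data_dir)
    st$cube <- ld$cube; st$design <- ld$design
    if (!is.null(config$reference_spectra)) {
      rs <- utils::read.csv(config$reference_spectra, check.names = FALSE)
      st$refs <- as.matrix(rs[, -1, drop = FALSE])
    }
    invisible()
  }

  run_stage <- list(
    simulate = function() {
      sim <- paperlike_dataset(seed = seed,
                               noise_sd = config$noise_sd %||% 0.005,
                               baseline_offset = config$baseline_offset %||% 0)
      st$cube <- sim$cube; st$design <- sim$design
      st$refs <- sim$truth$B[, sim$truth$roles == "analyte", drop = FALSE]
      paths <- save_cube(sim$cube, sim$design, file.path(outdir, "cube"))
      rp <- file.path(outdir, "reference_spectra.csv")
      utils::write.csv(cbind(wavelength = sim$cube$wavelength_axis, st$refs),
                       rp, row.names = FALSE)
      c(paths, rp)
    },
    rank = function() {
      ensure_data()
      scan <- scan_components(st$cube, config$scan_range %||% 1:6,
                              fit_options(1, seed = seed))
      if (is.null(st$n_comp) && !is.na(scan$chosen_N))
        st$n_comp <- scan$chosen_N
      p <- file.path(outdir, "rank_scan.csv")
      utils::write.csv(scan$table, p, row.names = FALSE)
      p
    },
    decompose = function() {
      ensure_data()
      paths <- character()
      for (alg in algorithms) {
        opt <- fit_options(st$n_comp %||% 3L, seed = seed)
        fit <- if (alg == "parafac_als") parafac_als(st$cube, opt)
               else swatld(st$cube, opt)
        for (m in c("A", "B", "C")) {
          p <- file.path(outdir, paste0(alg, "_", m, ".csv"))
          utils::write.csv(fit[[m]], p, row.names = FALSE)
          paths <- c(paths, p)
        }
        p <- file.path(outdir, paste0(alg, "_report.json"))
        jsonlite::write_json(
          list(algorithm = alg, n_components = fit$n_components,
               iterations = fit$iterations, fit_percent = fit$fit_percent,
               converged = fit$converged, fit_trace = fit$fit_trace),
          p, auto_unbox = TRUE, digits = NA)
        paths <- c(paths, p)
      }
      paths
    },
    calibrate = function() {
      ensure_data()
      if (is.null(st$refs))
        stop("calibrate stage needs reference spectra")
      paths <- character()
      st$results <- list()
      for (alg in algorithms) {
        res <- second_order_calibration(
          st$cube, st$design, st$refs, algorithm = alg,
          options = fit_options(st$n_comp %||% 3L, seed = seed))
        st$results[[alg]] <- res
        p1 <- file.path(outdir, paste0(alg, "_prediction.csv"))
        utils::write.csv(res$prediction$table, p1, row.names = FALSE)
        p2 <- file.path(outdir, paste0(alg, "_prediction.json"))
        jsonlite::write_json(
          list(algorithm = alg, summary = res$prediction$summary,
               k = as.list(res$prediction$k)),
          p2, auto_unbox = TRUE, digits = NA, dataframe = "rows")
        paths <- c(paths, p1, p2)
      }
      paths
    },
    fom = function() {
      if (is.null(st$results))
        stop("fom stage requires the calibrate stage")
      paths <- character()
      for (alg in names(st$results)) {
        p <- file.path(outdir, paste0(alg, "_fom.csv"))
        utils::write.csv(as.data.frame(st$results[[alg]]$fom), p,
                         row.names = FALSE)
        paths <- c(paths, p)
      }
      paths
    })

  for (stage in stages) {
    t0 <- as.numeric(Sys.time())
    paths <- tryCatch(run_stage[[stage]](), error = function(e) e)
    if (inherits(paths, "error")) {
      manifest$stages[[stage]] <- list(failed = TRUE,
                                       error = conditionMessage(paths))
      jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, force = TRUE)
      stop("stage `", stage, "` failed: ", conditionMessage(paths),
           call. = FALSE)
    }
    manifest$stages[[stage]] <- list(
      paths = as.list(paths),
      md5 = as.list(unname(tools::md5sum(paths))),
      seconds = round(as.numeric(Sys.time()) - t0, 3))
  }
  manifest$finished <- format(Sys.time(), usetz = TRUE)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  class(manifest) <- "RunManifest"
  invisible(manifest)
}
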