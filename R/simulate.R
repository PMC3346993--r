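#' Describe one absorbing component for the simulator
#'
#' A component is a chemical species with a unimodal (Gaussian, optionally
#' exponentially tailed) elution profile and a smooth UV spectrum built from
#' Gaussian bands. Analytes are present in calibration samples at known
#' levels; interferents appear only in prediction samples, which is the
#' regime in which the second-order advantage matters.
#'
#' @param name Component label.
#' @param elution_center Peak apex position, minutes.
#' @param elution_width Gaussian sigma of the peak, minutes (> 0).
#' @param spectrum_bands Numeric matrix or data.frame with columns
#'   `center` (nm), `width` (nm, Gaussian sigma, > 0), `height` (>= 0);
#'   at least one band.
#' @param role `"analyte"` or `"interferent"`.
#' @param tailing Exponential tail time constant, minutes; 0 (default) gives
#'   a symmetric peak. Positive values skew the peak toward later times, as
#'   broadened peaks do in practice.
#' @return An object of class `"ComponentSpec"`.
#' @export
component_spec <- function(name, elution_center, elution_width,
                           spectrum_bands, role = c("analyte", "interferent"),
                           tailing = 0) {
  role <- match.arg(role)
  b <- as.matrix(as.data.frame(spectrum_bands))
  if (!all(c("center", "width", "height") %in% colnames(b))) {
    if (ncol(b) == 3L) colnames(b) <- c("center", "width", "height")
    else stop("spectrum_bands needs columns center, width, height")
  }
  if (nrow(b) < 1L) stop("at least one spectral band is required")
  if (any(b[, "width"] <= 0) || elution_width <= 0)
    stop("widths must be strictly positive")
  if (any(b[, "height"] < 0)) stop("band heights must be nonnegative")
  if (tailing < 0) stop("`tailing` must be >= 0")
  structure(list(name = as.character(name),
                 elution_center = as.numeric(elution_center),
                 elution_width = as.numeric(elution_width),
                 spectrum_bands = b[, c("center", "width", "height"), drop = FALSE],
                 role = role, tailing = as.numeric(tailing)),
            class = "ComponentSpec")
}

#' Evaluate a component's pure profiles on a grid
#'
#' @param spec A [component_spec()].
#' @param time_axis Retention-time grid, minutes.
#' @param wavelength_axis Wavelength grid, nm.
#' @return List with `elution` (unit maximum, nonnegative, unimodal) and
#'   `spectrum` (unit Euclidean norm, nonnegative, smooth).
#' @export
make_profile <- function(spec, time_axis, wavelength_axis) {
  stopifnot(inherits(spec, "ComponentSpec"))
  check_axis(time_axis, "time_axis")
  check_axis(wavelength_axis, "wavelength_axis")
  el <- gauss_peak(time_axis, spec$elution_center, spec$elution_width,
                   spec$tailing)
  if (max(el) <= 0) stop("elution profile vanishes on this time axis")
  el <- el / max(el)
  b <- spec$spectrum_bands
  sp <- numeric(length(wavelength_axis))
  for (r in seq_len(nrow(b)))
    sp <- sp + b[r, "height"] *
      exp(-0.5 * ((wavelength_axis - b[r, "center"]) / b[r, "width"])^2)
  nrm <- sqrt(sum(sp^2))
  if (nrm <= 0) stop("spectrum vanishes on this wavelength axis")
  list(elution = el, spectrum = sp / nrm)
}

# Gaussian peak, optionally convolved with an exponential decay (EMG shape).
# Returned unscaled; callers normalize, so constant factors are dropped.
gauss_peak <- function(t, center, sigma, tau = 0) {
  if (tau <= sigma * 1e-6)
    return(exp(-0.5 * ((t - center) / sigma)^2))
  z <- sigma / tau - (t - center) / sigma
  lg <- 0.5 * (sigma / tau)^2 - (t - center) / tau +
    stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
  out <- exp(lg)
  out[!is.finite(out)] <- 0
  out
}

#' Simulation configuration
#'
#' Defines the components, sample counts, concentration design, noise and
#' baseline of a synthetic HPLC-DAD study. Interferents are never added to
#' calibration samples; blanks contain baseline and noise only.
#'
#' @param components List of [component_spec()] objects (>= 1 analyte).
#' @param n_calibration,n_prediction,n_blank Sample counts.
#' @param time_axis,wavelength_axis Measurement grids; defaults are a
#'   0-5 min chromatogram at 1/30 min and a 200-380 nm spectrum at 2 nm.
#' @param calibration_conc Optional matrix (n_calibration x analytes) of
#'   known levels; if `NULL`, levels are drawn uniformly from
#'   `concentration_range` per analyte.
#' @param prediction_conc Optional matrix (n_prediction x analytes) of spiked
#'   levels; if `NULL`, drawn from `concentration_range`.
#' @param concentration_range Length-2 numeric, the uniform sampling range
#'   used when explicit designs are not given.
#' @param interferent_range Length-2 numeric range of interferent levels in
#'   prediction samples (relative concentration units).
#' @param noise_sd Standard deviation of the additive iid Gaussian noise as a
#'   fraction of the maximum noiseless intensity in the cube.
#' @param baseline_offset Constant offset added to every measured intensity
#'   (removable by blank subtraction).
#' @param seed Integer; fully determines the generated data.
#' @return An object of class `"SimulationConfig"`.
#' @export
simulation_config <- function(components,
                              n_calibration = 10, n_prediction = 6,
                              n_blank = 3,
                              time_axis = seq(0, 5, by = 1 / 30),
                              wavelength_axis = seq(200, 380, by = 2),
                              calibration_conc = NULL,
                              prediction_conc = NULL,
                              concentration_range = c(5, 35),
                              interferent_range = c(10, 25),
                              noise_sd = 0.005,
                              baseline_offset = 0,
                              seed = 1L) {
  if (!length(components) || !all(vapply(components, inherits, TRUE, "ComponentSpec")))
    stop("`components` must be a list of component_spec objects")
  roles <- vapply(components, `[[`, "", "role")
  if (!any(roles == "analyte")) stop("at least one analyte is required")
  if (n_calibration < 2L) stop("need at least 2 calibration samples")
  if (n_prediction < 0L || n_blank < 0L) stop("sample counts must be >= 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(components = components,
                 n_calibration = as.integer(n_calibration),
                 n_prediction = as.integer(n_prediction),
                 n_blank = as.integer(n_blank),
                 time_axis = as.numeric(time_axis),
                 wavelength_axis = as.numeric(wavelength_axis),
                 calibration_conc = calibration_conc,
                 prediction_conc = prediction_conc,
                 concentration_range = as.numeric(concentration_range),
                 interferent_range = as.numeric(interferent_range),
                 noise_sd = as.numeric(noise_sd),
                 baseline_offset = as.numeric(baseline_offset),
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a trilinear HPLC-DAD cube
#'
#' Builds each sample slab as the trilinear forward model
#' \deqn{x_{ijk} = \sum_n a_{in} b_{jn} c_{kn} + e_{ijk}}
#' with unit-maximum elution profiles `a_n`, unit-norm spectra `b_n`,
#' per-sample levels `c_kn`, iid Gaussian noise and an optional constant
#' baseline. The exact profiles and levels used are returned as ground
#' truth, so recovery by any downstream stage can be verified.
#'
#' @param config A [simulation_config()].
#' @return A list with `cube` ([data_cube()]), `design`
#'   ([calibration_design()]) and `truth`: list with `A` (I x N elution),
#'   `B` (J x N spectra), `C` (K x N levels), `component_names`, `roles`,
#'   `noise_sd_abs` (absolute noise sd actually applied).
#' @export
simulate_cube <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_seed(config$seed, simulate_cube_impl(config))
}

simulate_cube_impl <- function(config) {
  comps <- config$components
  roles <- vapply(comps, `[[`, "", "role")
  cnames <- vapply(comps, `[[`, "", "name")
  if (anyDuplicated(cnames)) stop("component names must be unique")
  analytes <- cnames[roles == "analyte"]
  I <- length(config$time_axis); J <- length(config$wavelength_axis)
  N <- length(comps)
  A <- matrix(0, I, N, dimnames = list(NULL, cnames))
  B <- matrix(0, J, N, dimnames = list(NULL, cnames))
  for (n in seq_len(N)) {
    pr <- make_profile(comps[[n]], config$time_axis, config$wavelength_axis)
    A[, n] <- pr$elution
    B[, n] <- pr$spectrum
  }

  nk <- c(config$n_calibration, config$n_prediction, config$n_blank)
  K <- sum(nk)
  ids <- c(sprintf("cal%02d", seq_len(nk[1])),
           if (nk[2]) sprintf("pred%02d", seq_len(nk[2])),
           if (nk[3]) sprintf("blank%02d", seq_len(nk[3])))
  role_vec <- rep(c("calibration", "prediction", "blank"), nk)

  Cmat <- matrix(0, K, N, dimnames = list(ids, cnames))
  cal_conc <- config$calibration_conc
  if (is.null(cal_conc))
    cal_conc <- vapply(analytes, function(a)
      runif(nk[1], config$concentration_range[1], config$concentration_range[2]),
      numeric(nk[1]))
  cal_conc <- matrix(as.numeric(cal_conc), nk[1], length(analytes),
                     dimnames = list(NULL, analytes))
  Cmat[seq_len(nk[1]), analytes] <- cal_conc
  if (nk[2]) {
    pred_conc <- config$prediction_conc
    if (is.null(pred_conc))
      pred_conc <- vapply(analytes, function(a)
        runif(nk[2], config$concentration_range[1], config$concentration_range[2]),
        numeric(nk[2]))
    pred_conc <- matrix(as.numeric(pred_conc), nk[2], length(analytes),
                        dimnames = list(NULL, analytes))
    pr_rows <- nk[1] + seq_len(nk[2])
    Cmat[pr_rows, analytes] <- pred_conc
    intf <- cnames[roles == "interferent"]
    for (nm in intf)
      Cmat[pr_rows, nm] <- runif(nk[2], config$interferent_range[1],
                                 config$interferent_range[2])
  }

  # noiseless slabs, then global noise scale
  clean <- array(0, c(I, J, K))
  AB <- vector("list", N)
  for (n in seq_len(N)) AB[[n]] <- tcrossprod(A[, n], B[, n])
  for (k in seq_len(K)) {
    slab <- matrix(0, I, J)
    for (n in seq_len(N))
      if (Cmat[k, n] != 0) slab <- slab + Cmat[k, n] * AB[[n]]
    clean[, , k] <- slab
  }
  noise_abs <- config$noise_sd * max(clean)
  values <- clean + config$baseline_offset
  if (noise_abs > 0)
    values <- values + array(rnorm(I * J * K, sd = noise_abs), c(I, J, K))

  conc <- matrix(NA_real_, K, length(analytes), dimnames = list(ids, analytes))
  conc[role_vec == "calibration", ] <- cal_conc
  if (nk[2]) conc[role_vec == "prediction", ] <- Cmat[nk[1] + seq_len(nk[2]),
                                                      analytes, drop = FALSE]
  cube <- data_cube(values, config$time_axis, config$wavelength_axis, ids)
  design <- calibration_design(ids, role_vec, conc, analytes)
  truth <- list(A = A, B = B, C = Cmat, component_names = cnames,
                roles = roles, noise_sd_abs = noise_abs,
                baseline_offset = config$baseline_offset, clean = clean)
  list(cube = cube, design = design, truth = truth)
}

#' Default two-analyte components emulating a plasma determination study
#'
#' Two analytes with heavily overlapped elution (apices about one peak width
#' apart) and one broadband interferent eluting between them, mimicking a
#' plasma background that is absent from the calibration set. The second
#' analyte's spectrum is made the most distinct in shape, so it is the more
#' selective of the two.
#'
#' @return List of three [component_spec()] objects.
#' @export
default_components <- function() {
  list(
    component_spec("vancomycin", elution_center = 2.00, elution_width = 0.25,
                   spectrum_bands = rbind(c(230, 22, 1.0), c(285, 32, 0.40)),
                   role = "analyte"),
    component_spec("cephalexin", elution_center = 2.25, elution_width = 0.25,
                   spectrum_bands = rbind(c(265, 15, 1.0), c(220, 11, 0.75)),
                   role = "analyte"),
    # plasma background: strong end absorption decaying across the UV range
    component_spec("plasma_interferent", elution_center = 2.12,
                   elution_width = 0.32,
                   spectrum_bands = rbind(c(210, 28, 1.0), c(262, 50, 0.25)),
                   role = "interferent"))
}

#' Synthetic dataset mirroring the reference study design
#'
#' Ten calibration samples spanning a fixed grid of the two analytes (no
#' interferent), six prediction samples spiked at the reference study's
#' added levels plus a plasma-like interferent, and three blanks. Noise is
#' 0.5% of the maximum signal by default.
#'
#' @param seed Integer seed; determines the noise and interferent levels.
#' @param noise_sd Noise fraction, see [simulation_config()].
#' @param baseline_offset Constant baseline, default 0.
#' @return As [simulate_cube()]: list with `cube`, `design`, `truth`.
#' @export
paperlike_dataset <- function(seed = 1L, noise_sd = 0.005,
                              baseline_offset = 0) {
  van <- seq(5, 32, by = 3)                       # 10 calibration levels
  cep <- van[c(4L, 8L, 1L, 6L, 10L, 3L, 7L, 2L, 9L, 5L)]
  added <- plasma_study_results()
  pred <- cbind(vancomycin = added$added_vancomycin,
                cephalexin = added$added_cephalexin)
  cfg <- simulation_config(
    components = default_components(),
    n_calibration = 10, n_prediction = 6, n_blank = 3,
    calibration_conc = cbind(vancomycin = van, cephalexin = cep),
    prediction_conc = pred,
    interferent_range = c(10, 25),
    noise_sd = noise_sd, baseline_offset = baseline_offset,
    seed = seed)
  simulate_cube(cfg)
}

#' Four-component synthetic cube for rank-estimation studies
#'
#' The two default analytes plus two plasma-like interferents — one the
#' default broadband end-absorber overlapping both analytes, one later
#' eluting with a distinct long-wavelength band — on a coarser grid than
#' [paperlike_dataset()]. Ten calibration and six prediction samples. This
#' is the configuration used to exercise the core consistency diagnostic:
#' the cube's chemical rank is exactly 4.
#'
#' @param seed Integer seed.
#' @param noise_sd Noise fraction of the maximum signal (default 0.5%).
#' @param n_time,n_wavelength Grid sizes (default 100 x 60).
#' @return As [simulate_cube()]: list with `cube`, `design`, `truth`.
#' @export
rank_study_dataset <- function(seed = 1L, noise_sd = 0.005,
                               n_time = 100L, n_wavelength = 60L) {
  comps <- c(default_components(), list(
    component_spec("plasma_interferent2", elution_center = 2.55,
                   elution_width = 0.28,
                   spectrum_bands = rbind(c(305, 28, 1.0), c(230, 18, 0.35)),
                   role = "interferent")))
  simulate_cube(simulation_config(
    comps, n_calibration = 10, n_prediction = 6, n_blank = 0,
    time_axis = seq(0, 5, length.out = n_time),
    wavelength_axis = seq(200, 380, length.out = n_wavelength),
    noise_sd = noise_sd, seed = seed))
}

#' Published determination results for vancomycin and cephalexin in plasma
#'
#' The added and predicted concentrations (mg/mL) for the six plasma
#' prediction samples of a published HPLC-DAD second-order calibration study
#' of vancomycin and cephalexin, for both decomposition algorithms. Used as
#' the worked example for [rmsep()] and [recovery_table()], and as the added
#' levels of [paperlike_dataset()].
#'
#' @return A data.frame with columns `sample`, `added_vancomycin`,
#'   `added_cephalexin`, and predicted concentrations
#'   `swatld_vancomycin`, `swatld_cephalexin`, `parafac_vancomycin`,
#'   `parafac_cephalexin`.
#' @export
plasma_study_results <- function() {
  data.frame(
    sample = 11:16,
    added_vancomycin   = c(15.15, 20.20, 30.30, 20.20, 25.25, 20.20),
    added_cephalexin   = c(15.27, 20.36, 10.18, 30.54, 25.45, 15.27),
    swatld_vancomycin  = c(14.25, 20.58, 30.64, 21.52, 25.24, 21.25),
    swatld_cephalexin  = c(14.71, 20.52,  9.99, 29.46, 23.68, 14.39),
    parafac_vancomycin = c(14.02, 20.06, 30.39, 21.50, 24.81, 21.45),
    parafac_cephalexin = c(14.57, 20.49, 10.02, 29.27, 23.71, 14.25))
}
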