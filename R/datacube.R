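#' Three-way HPLC-DAD data cube
#'
#' Container for a stack of elution-time x wavelength absorbance matrices,
#' one slab per sample. The first mode is chromatographic (retention time,
#' minutes), the second spectral (wavelength, nm), the third the sample mode.
#'
#' @param values Numeric array of dimension I x J x K (time x wavelength x
#'   sample), all values finite.
#' @param time_axis Numeric vector of length I, strictly increasing, minutes.
#' @param wavelength_axis Numeric vector of length J, strictly increasing, nm.
#' @param sample_ids Character vector of K unique sample labels.
#'
#' @return An object of class `"DataCube"`: a list with fields `values`,
#'   `time_axis`, `wavelength_axis`, `sample_ids`.
#' @export
#' @examples
#' x <- array(runif(5 * 4 * 2), c(5, 4, 2))
#' data_cube(x, 1:5, seq(200, 206, 2), c("s1", "s2"))
data_cube <- function(values, time_axis, wavelength_axis, sample_ids) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a three-way array (time x wavelength x sample)")
  storage.mode(values) <- "double"
  sample_ids <- as.character(sample_ids)
  d <- dim(values)
  if (d[1] != length(time_axis) || d[2] != length(wavelength_axis) ||
      d[3] != length(sample_ids))
    stop("array dimensions (", paste(d, collapse = " x "),
         ") do not match axis lengths (", length(time_axis), " x ",
         length(wavelength_axis), " x ", length(sample_ids), ")")
  if (d[3] < 1L) stop("a cube needs at least one sample")
  if (any(!is.finite(values))) stop("all cube values must be finite")
  check_axis(time_axis, "time_axis")
  check_axis(wavelength_axis, "wavelength_axis")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  dimnames(values) <- list(NULL, NULL, sample_ids)
  structure(
    list(values = values, time_axis = as.numeric(time_axis),
         wavelength_axis = as.numeric(wavelength_axis),
         sample_ids = sample_ids),
    class = "DataCube")
}

check_axis <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x)))
    stop("`", name, "` must be a finite numeric vector")
  if (length(x) > 1L && any(diff(x) <= 0))
    stop("`", name, "` must be strictly increasing")
  invisible(x)
}

#' @export
print.DataCube <- function(x, ...) {
  d <- dim(x$values)
  cat("DataCube: ", d[1], " time points x ", d[2], " wavelengths x ",
      d[3], " samples\n", sep = "")
  cat("  time: ", format(min(x$time_axis)), "-", format(max(x$time_axis)),
      " min; wavelength: ", format(min(x$wavelength_axis)), "-",
      format(max(x$wavelength_axis)), " nm\n", sep = "")
  invisible(x)
}

#' @export
dim.DataCube <- function(x) dim(x$values)

#' Calibration design for a data cube
#'
#' Records each sample's role (`calibration`, `prediction` or `blank`) and
#' the known analyte concentrations. Calibration samples must carry a
#' complete, nonnegative concentration row; for prediction samples the
#' spiked ("added") concentrations may be supplied so that recoveries can be
#' scored, and blanks carry none.
#'
#' @param sample_ids Character vector of sample labels (must match the
#'   companion cube).
#' @param roles Character vector, one of `"calibration"`, `"prediction"`,
#'   `"blank"` per sample.
#' @param conc Numeric matrix, samples x analytes, with `NA` where the
#'   concentration is unknown. Column names are the analyte names.
#' @param analyte_names Optional character vector overriding `colnames(conc)`.
#'
#' @return An object of class `"CalibrationDesign"`.
#' @export
calibration_design <- function(sample_ids, roles, conc,
                               analyte_names = colnames(conc)) {
  sample_ids <- as.character(sample_ids)
  roles <- as.character(roles)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (length(roles) != length(sample_ids))
    stop("`roles` must have one entry per sample")
  bad <- setdiff(unique(roles), c("calibration", "prediction", "blank"))
  if (length(bad))
    stop("unknown role(s): ", paste(bad, collapse = ", "))
  conc <- as.matrix(conc)
  storage.mode(conc) <- "double"
  if (nrow(conc) != length(sample_ids))
    stop("`conc` must have one row per sample")
  if (is.null(analyte_names)) analyte_names <- paste0("analyte", seq_len(ncol(conc)))
  if (length(analyte_names) != ncol(conc))
    stop("one analyte name per concentration column required")
  dimnames(conc) <- list(sample_ids, analyte_names)
  cal <- roles == "calibration"
  if (!any(cal)) stop("at least one calibration sample is required")
  if (any(is.na(conc[cal, , drop = FALSE])))
    stop("calibration samples must have a complete concentration row")
  if (any(conc[cal, , drop = FALSE] < 0))
    stop("known concentrations must be nonnegative")
  structure(
    list(sample_ids = sample_ids, roles = roles, conc = conc,
         analyte_names = as.character(analyte_names)),
    class = "CalibrationDesign")
}

#' @export
print.CalibrationDesign <- function(x, ...) {
  cat("CalibrationDesign: ", length(x$sample_ids), " samples (",
      sum(x$roles == "calibration"), " calibration, ",
      sum(x$roles == "prediction"), " prediction, ",
      sum(x$roles == "blank"), " blank); analytes: ",
      paste(x$analyte_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Subset a design to a set of samples
#'
#' @param design A [calibration_design()].
#' @param sample_ids Samples to keep, in the order given.
#' @return A `CalibrationDesign` over the requested samples.
#' @export
subset_design <- function(design, sample_ids) {
  stopifnot(inherits(design, "CalibrationDesign"))
  idx <- match(sample_ids, design$sample_ids)
  if (any(is.na(idx)))
    stop("unknown sample id(s): ",
         paste(sample_ids[is.na(idx)], collapse = ", "))
  calibration_design(design$sample_ids[idx], design$roles[idx],
                     design$conc[idx, , drop = FALSE], design$analyte_names)
}

#' Read a data cube from a directory of per-sample matrices
#'
#' Each sample is a headerless delimited file (rows = time points, columns =
#' wavelengths); the metadata file (YAML) defines the axes and, per sample,
#' the id, role, file name and any known concentrations:
#' \preformatted{
#' time_axis: [0.0, 0.0333, ...]
#' wavelength_axis: [200, 202, ...]
#' analytes: [vancomycin, cephalexin]
#' samples:
#'   - {id: c01, role: calibration, file: c01.csv,
#'      known_conc: {vancomycin: 5.0, cephalexin: 26.0}}
#' }
#'
#' The read is atomic: any missing file, shape mismatch, duplicate id or
#' non-numeric cell aborts without returning a partial cube.
#'
#' @param directory_path Directory holding the sample files.
#' @param metadata_path Path to the metadata file; defaults to
#'   `metadata.yaml` inside `directory_path`.
#' @return A list with elements `cube` ([data_cube()]) and `design`
#'   ([calibration_design()]).
#' @seealso [save_cube()] for the writer.
#' @export
load_cube <- function(directory_path,
                      metadata_path = file.path(directory_path, "metadata.yaml")) {
  if (!dir.exists(directory_path))
    stop("directory not found: ", directory_path)
  if (!file.exists(metadata_path))
    stop("metadata file not found: ", metadata_path)
  meta <- yaml::read_yaml(metadata_path)
  for (f in c("time_axis", "wavelength_axis", "samples"))
    if (is.null(meta[[f]])) stop("metadata lacks required key `", f, "`")
  time_axis <- as.numeric(meta$time_axis)
  wavelength_axis <- as.numeric(meta$wavelength_axis)
  analytes <- as.character(meta$analytes %||% character())
  ns <- length(meta$samples)
  if (ns < 1L) stop("metadata lists no samples")
  ids <- vapply(meta$samples, function(s) as.character(s$id), "")
  if (anyDuplicated(ids))
    stop("duplicate sample id in metadata: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  roles <- vapply(meta$samples, function(s) as.character(s$role), "")
  values <- array(NA_real_,
                  c(length(time_axis), length(wavelength_axis), ns))
  for (k in seq_len(ns)) {
    f <- file.path(directory_path, meta$samples[[k]]$file)
    if (!file.exists(f)) stop("missing sample file: ", f)
    m <- tryCatch(
      as.matrix(data.table::fread(f, header = FALSE, colClasses = "numeric")),
      error = function(e) stop("non-numeric or unreadable cell in ", f,
                               ": ", conditionMessage(e), call. = FALSE),
      warning = function(w) stop("malformed sample file ", f, ": ",
                                 conditionMessage(w), call. = FALSE))
    if (!is.numeric(m) || anyNA(m))
      stop("non-numeric cell in ", f)
    if (nrow(m) != length(time_axis) || ncol(m) != length(wavelength_axis))
      stop("shape mismatch in ", f, ": got ", nrow(m), " x ", ncol(m),
           ", expected ", length(time_axis), " x ", length(wavelength_axis))
    values[, , k] <- m
  }
  if (length(analytes)) {
    conc <- matrix(NA_real_, ns, length(analytes),
                   dimnames = list(ids, analytes))
    for (k in seq_len(ns)) {
      kc <- meta$samples[[k]]$known_conc
      if (!is.null(kc))
        for (a in names(kc)) {
          if (!a %in% analytes) stop("unknown analyte `", a, "` in metadata")
          conc[k, a] <- as.numeric(kc[[a]])
        }
    }
  } else {
    conc <- matrix(numeric(), ns, 0, dimnames = list(ids, NULL))
  }
  cube <- data_cube(values, time_axis, wavelength_axis, ids)
  design <- calibration_design(ids, roles, conc, analytes)
  list(cube = cube, design = design)
}

#' Write a data cube as per-sample delimited matrices plus metadata
#'
#' Inverse of [load_cube()]: one headerless CSV per sample (rows = time
#' points, columns = wavelengths) and a `metadata.yaml` with axes, roles and
#' known concentrations. Values round-trip to within 1e-8 of the originals
#' at the default precision.
#'
#' @param cube A [data_cube()].
#' @param design The companion [calibration_design()].
#' @param directory_path Destination directory (created if needed).
#' @return Invisibly, the character vector of paths written (metadata last).
#' @export
save_cube <- function(cube, design, directory_path) {
  stopifnot(inherits(cube, "DataCube"), inherits(design, "CalibrationDesign"))
  if (!identical(cube$sample_ids, design$sample_ids))
    stop("cube and design sample ids disagree")
  dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory_path))
    stop("cannot create directory: ", directory_path)
  files <- paste0(make.names(cube$sample_ids), ".csv")
  paths <- character(0)
  samples <- vector("list", length(cube$sample_ids))
  for (k in seq_along(cube$sample_ids)) {
    p <- file.path(directory_path, files[k])
    data.table::fwrite(data.table::as.data.table(cube$values[, , k]), p,
                       col.names = FALSE)
    paths <- c(paths, p)
    s <- list(id = cube$sample_ids[k], role = design$roles[k], file = files[k])
    kc <- design$conc[k, ]
    kc <- kc[!is.na(kc)]
    if (length(kc)) s$known_conc <- as.list(kc)
    samples[[k]] <- s
  }
  meta <- list(time_axis = cube$time_axis,
               wavelength_axis = cube$wavelength_axis,
               analytes = as.list(design$analyte_names),
               samples = samples)
  mp <- file.path(directory_path, "metadata.yaml")
  yaml::write_yaml(meta, mp, precision = 15)
  invisible(c(paths, mp))
}

#' Subtract the average blank slab
#'
#' Removes a constant instrumental background by subtracting the element-wise
#' mean of the blank samples' matrices from every non-blank slab, then drops
#' the blanks from the cube.
#'
#' @param cube A [data_cube()].
#' @param blank_ids Sample ids of the blanks (nonempty, all present, and not
#'   the whole cube).
#' @return A `DataCube` over the remaining samples.
#' @export
subtract_blank <- function(cube, blank_ids) {
  stopifnot(inherits(cube, "DataCube"))
  blank_ids <- as.character(blank_ids)
  if (!length(blank_ids)) stop("`blank_ids` must be nonempty")
  idx <- match(blank_ids, cube$sample_ids)
  if (any(is.na(idx)))
    stop("unknown blank id(s): ", paste(blank_ids[is.na(idx)], collapse = ", "))
  keep <- setdiff(seq_along(cube$sample_ids), idx)
  if (!length(keep)) stop("all samples are blanks; nothing left to correct")
  blank_mean <- apply(cube$values[, , idx, drop = FALSE], c(1, 2), mean)
  out <- cube$values[, , keep, drop = FALSE]
  out <- sweep(out, c(1, 2), blank_mean, "-")
  data_cube(out, cube$time_axis, cube$wavelength_axis, cube$sample_ids[keep])
}

#' Crop a cube to a time and/or wavelength window
#'
#' Region selection discards uninformative parts of the chromatogram and
#' spectrum before modelling. Windows are closed intervals on the physical
#' axes; retained points keep their original order.
#'
#' @param cube A [data_cube()].
#' @param time_window Length-2 numeric `c(lo, hi)` in minutes, or `NULL` to
#'   keep the full time axis.
#' @param wavelength_window Length-2 numeric in nm, or `NULL`.
#' @return The cropped `DataCube`; the input is not modified.
#' @export
select_region <- function(cube, time_window = NULL, wavelength_window = NULL) {
  stopifnot(inherits(cube, "DataCube"))
  ti <- axis_window(cube$time_axis, time_window, "time")
  wi <- axis_window(cube$wavelength_axis, wavelength_window, "wavelength")
  data_cube(cube$values[ti, wi, , drop = FALSE],
            cube$time_axis[ti], cube$wavelength_axis[wi], cube$sample_ids)
}

axis_window <- function(axis, window, what) {
  if (is.null(window)) return(seq_along(axis))
  if (length(window) != 2L || any(!is.finite(window)) || window[1] > window[2])
    stop("`", what, "_window` must be c(lo, hi) with lo <= hi")
  idx <- which(axis >= window[1] & axis <= window[2])
  if (!length(idx))
    stop(what, " window [", window[1], ", ", window[2],
         "] does not intersect the axis")
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a
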