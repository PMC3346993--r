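#' Regression coefficient linking scores to known concentrations
#'
#' Fits the proportionality `score = k * concentration` through the origin
#' by least squares over the calibration samples, so that a resolved
#' concentration-mode score converts to an absolute concentration as
#' `score / k`.
#'
#' @param scores Numeric vector: one concentration-mode loading column,
#'   over every sample in `design` (same order).
#' @param design A [calibration_design()].
#' @param analyte Analyte name (a column of the design's concentrations).
#' @return The scalar coefficient `k`.
#' @export
score_regression <- function(scores, design, analyte) {
  stopifnot(inherits(design, "CalibrationDesign"))
  if (length(scores) != length(design$sample_ids))
    stop("`scores` must have one entry per design sample")
  if (!analyte %in% design$analyte_names)
    stop("unknown analyte: ", analyte)
  cal <- design$roles == "calibration"
  y <- design$conc[cal, analyte]
  s <- scores[cal]
  if (length(unique(y)) < 2L)
    stop("need at least 2 distinct calibration levels for ", analyte)
  if (all(s == 0)) stop("all calibration scores are zero for ", analyte)
  sum(s * y) / sum(y^2)
}

#' Predict concentrations from a jointly decomposed cube
#'
#' Second-order calibration, scores route: the cube holding calibration,
#' prediction (and blank) samples is decomposed once, factors are matched to
#' analytes with [align_factors()], and each analyte's concentration-mode
#' column is regressed on the known calibration levels
#' ([score_regression()]). Prediction- and blank-sample scores are then
#' converted to concentrations by the same coefficient; because the
#' decomposition models the interferents as factors of their own, the
#' analyte predictions are untouched by species absent from the calibration
#' set (the second-order advantage).
#'
#' @param loadings An aligned `"LoadingSet"` (from [align_factors()]) fitted
#'   on the joint cube.
#' @param design The companion [calibration_design()]; its sample order must
#'   match the cube the loadings were fitted on.
#' @return An object of class `"PredictionReport"`: list with
#'   \describe{
#'     \item{table}{data.frame, one row per non-calibration sample x
#'       analyte: `sample`, `role`, `analyte`, `score`, `predicted`,
#'       `added` (NA when unknown), `recovery_percent` (defined only where
#'       `added > 0`).}
#'     \item{summary}{per analyte: `k`, `mean_recovery`, `recovery_sd`
#'       (m - 1 denominator), `rmsep` over the prediction samples with
#'       known added levels.}
#'     \item{k}{named coefficient vector.}
#'     \item{algorithm}{decomposition algorithm label.}
#'   }
#' @export
predict_concentrations <- function(loadings, design) {
  stopifnot(inherits(loadings, "LoadingSet"),
            inherits(design, "CalibrationDesign"))
  if (is.null(loadings$analyte_names))
    stop("loadings are not aligned; run align_factors() first")
  if (nrow(loadings$C) != length(design$sample_ids))
    stop("loadings and design cover different sample sets")
  analytes <- intersect(design$analyte_names, loadings$analyte_names)
  if (!length(analytes))
    stop("no analyte factor matched to the design's analytes")
  k <- vapply(analytes, function(a)
    score_regression(loadings$C[, a], design, a), numeric(1))
  rows <- which(design$roles != "calibration")
  tab <- do.call(rbind, lapply(analytes, function(a) {
    sc <- loadings$C[rows, a]
    pred <- sc / k[[a]]
    added <- design$conc[rows, a]
    data.frame(sample = design$sample_ids[rows], role = design$roles[rows],
               analyte = a, score = sc, predicted = pred, added = added,
               recovery_percent = ifelse(!is.na(added) & added > 0,
                                         100 * pred / added, NA_real_))
  }))
  rownames(tab) <- NULL
  summ <- do.call(rbind, lapply(analytes, function(a) {
    sub <- tab[tab$analyte == a & tab$role == "prediction" &
                 !is.na(tab$added), ]
    rec <- sub$recovery_percent[!is.na(sub$recovery_percent)]
    data.frame(analyte = a, k = k[[a]],
               mean_recovery = if (length(rec)) mean(rec) else NA_real_,
               recovery_sd = if (length(rec) > 1L) stats::sd(rec) else NA_real_,
               rmsep = if (nrow(sub)) rmsep(sub$added, sub$predicted)
                       else NA_real_)
  }))
  rownames(summ) <- NULL
  structure(list(table = tab, summary = summ, k = k,
                 algorithm = loadings$algorithm),
            class = "PredictionReport")
}

#' @export
print.PredictionReport <- function(x, ...) {
  cat("PredictionReport (", x$algorithm, ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Direct (pseudo-inverse) prediction of relative concentrations
#'
#' One-shot route: given the chromatographic and spectral profile matrices
#' of all species present, the relative concentration of each in a single
#' unknown-sample matrix is
#' \deqn{\hat c = \mathrm{diag}(A^+ X_{un} (B^T)^+).}
#' Every species present in `X_un` (interferents included) must have a
#' column in `A` and `B`, otherwise the estimate is biased.
#'
#' @param X_un Numeric matrix (time x wavelength) for one sample.
#' @param A,B Profile matrices (I x N and J x N), full column rank.
#' @return Numeric vector of N relative-concentration scores.
#' @export
direct_prediction <- function(X_un, A, B) {
  X_un <- as.matrix(X_un); A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(X_un) != nrow(A) || ncol(X_un) != nrow(B))
    stop("X_un shape does not match the profile matrices")
  for (M in list(A, B)) {
    sv <- svd(M, nu = 0, nv = 0)$d
    if (min(sv) <= 1e-10 * max(sv))
      stop("rank-deficient profile matrix")
  }
  diag(pinv_cut(A) %*% X_un %*% pinv_cut(t(B)))
}

#' Root mean square error of prediction
#'
#' \deqn{\mathrm{RMSEP} = \sqrt{\sum_i (y_i - \hat y_i)^2 / m}}
#' over the m prediction samples.
#'
#' @param added Known (spiked) concentrations.
#' @param predicted Predicted concentrations, same length.
#' @return Nonnegative scalar, zero iff the vectors are identical.
#' @export
#' @examples
#' rmsep(c(15.15, 20.20), c(14.25, 20.58))
rmsep <- function(added, predicted) {
  if (!length(added)) stop("empty input")
  if (length(added) != length(predicted)) stop("length mismatch")
  sqrt(mean((added - predicted)^2))
}

# half-up decimal rounding (R's round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Format a determination-results table
#'
#' Renders a [predict_concentrations()] report the way second-order
#' calibration studies print theirs: per-sample recoveries at 1 decimal
#' place, mean +/- sd recovery as integer percent (sd with m - 1
#' denominator, reported as NA for a single sample), RMSEP at 2 decimal
#' places; all rounding half-up.
#'
#' @param report A `"PredictionReport"`.
#' @return List with `samples` (data.frame: sample x analyte recoveries) and
#'   `summary` (data.frame: analyte, mean_recovery, recovery_sd, rmsep,
#'   label "mean +/- sd").
#' @export
recovery_table <- function(report) {
  stopifnot(inherits(report, "PredictionReport"))
  tab <- report$table[report$table$role == "prediction", ]
  samples <- data.frame(sample = unique(tab$sample))
  for (a in unique(tab$analyte)) {
    v <- tab$recovery_percent[tab$analyte == a]
    samples[[a]] <- round_half_up(v, 1)
  }
  summ <- report$summary
  out <- data.frame(
    analyte = summ$analyte,
    mean_recovery = round_half_up(summ$mean_recovery, 0),
    recovery_sd = round_half_up(summ$recovery_sd, 0),
    rmsep = round_half_up(summ$rmsep, 2))
  out$label <- ifelse(is.na(out$recovery_sd),
                      paste0(out$mean_recovery, "%"),
                      paste0(out$mean_recovery, " ± ", out$recovery_sd, "%"))
  list(samples = samples, summary = out)
}
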