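#' Multiway sensitivity from the net analyte signal
#'
#' The sensitivity of analyte n is the net analyte signal at unit
#' concentration,
#' \deqn{\mathrm{SEN}_n = k_n \{[(A^TA)^{-1}]_{nn} [(B^TB)^{-1}]_{nn}\}^{-1/2},}
#' where `A` and `B` are the unit-norm chromatographic and spectral loading
#' matrices of every modelled species (interferents included) and `k` the
#' score/concentration coefficient from [score_regression()]. Overlap with
#' the other species inflates the inverse-Gram diagonals and lowers the
#' sensitivity.
#'
#' @param A,B Loading matrices (I x N, J x N), full column rank.
#' @param k Regression coefficient for the analyte.
#' @param analyte_index Column index n of the analyte.
#' @return Sensitivity, signal units per concentration unit.
#' @export
sensitivity <- function(A, B, k, analyte_index) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- as.integer(analyte_index)
  if (n < 1L || n > ncol(A) || n > ncol(B)) stop("bad analyte index")
  ga <- gram_inv_diag(A, n)
  gb <- gram_inv_diag(B, n)
  k * (ga * gb)^(-1 / 2)
}

gram_inv_diag <- function(M, n) {
  G <- crossprod(M)
  sv <- svd(G, nu = 0, nv = 0)$d
  if (min(sv) <= 1e-10 * max(sv))
    stop("singular Gram matrix: collinear profile columns")
  solve(G)[n, n]
}

#' Multiway selectivity
#'
#' Selectivity is the sensitivity at unit regression coefficient,
#' \deqn{\mathrm{SEL}_n = \{[(A^TA)^{-1}]_{nn} [(B^TB)^{-1}]_{nn}\}^{-1/2},}
#' the fraction of the analyte's signal left after projecting out all other
#' modelled species. With unit-norm loading columns it lies in (0, 1]:
#' exactly 1 for profiles orthogonal to every other component, decreasing
#' with overlap, and `SEL = SEN / k` always.
#'
#' @inheritParams sensitivity
#' @return Selectivity, dimensionless.
#' @export
selectivity <- function(A, B, analyte_index) {
  sensitivity(A, B, 1, analyte_index)
}

#' Limit of detection from blank predictions
#'
#' \deqn{\mathrm{LOD} = 3.3\, s_0,} with `s_0` the sample standard deviation
#' (m - 1 denominator) of the concentrations estimated for at least three
#' blank samples carried through the same decomposition and regression as
#' the unknowns.
#'
#' @param blank_estimates Numeric vector of >= 3 blank concentration
#'   estimates.
#' @return LOD in concentration units.
#' @export
#' @examples
#' lod(c(1, 2, 3))  # sd = 1, LOD = 3.3
lod <- function(blank_estimates) {
  if (length(blank_estimates) < 3L)
    stop("at least 3 blank estimates are required")
  3.3 * stats::sd(blank_estimates)
}

#' Figures of merit for every analyte of a calibrated model
#'
#' Combines [sensitivity()], [selectivity()] and [lod()] for an aligned
#' loading set and its prediction report. Blank concentration estimates are
#' taken from the report's blank rows (blanks decomposed jointly with the
#' other samples and converted by the same regression coefficient).
#'
#' @param loadings An aligned `"LoadingSet"`.
#' @param report The matching `"PredictionReport"`.
#' @return An object of class `"FomReport"`: data.frame with columns
#'   `analyte`, `algorithm`, `k`, `sensitivity`, `selectivity`, `blank_sd`,
#'   `lod` (NA if fewer than 3 blanks were present).
#' @export
fom_report <- function(loadings, report) {
  stopifnot(inherits(loadings, "LoadingSet"),
            inherits(report, "PredictionReport"))
  if (is.null(loadings$analyte_names))
    stop("loadings are not aligned; run align_factors() first")
  analytes <- names(report$k)
  out <- do.call(rbind, lapply(analytes, function(a) {
    n <- match(a, colnames(loadings$B))
    blanks <- report$table[report$table$analyte == a &
                             report$table$role == "blank", "predicted"]
    s0 <- if (length(blanks) >= 3L) stats::sd(blanks) else NA_real_
    data.frame(analyte = a, algorithm = report$algorithm,
               k = report$k[[a]],
               sensitivity = sensitivity(loadings$A, loadings$B,
                                         report$k[[a]], n),
               selectivity = selectivity(loadings$A, loadings$B, n),
               blank_sd = s0,
               lod = if (is.na(s0)) NA_real_ else 3.3 * s0)
  }))
  rownames(out) <- NULL
  class(out) <- c("FomReport", "data.frame")
  out
}
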