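#' Fitting options for the trilinear decomposition engines
#'
#' @param n_components Number of components N to extract (>= 1).
#' @param tol Convergence threshold: sweeps stop once the relative change
#'   in the residual sum of squares falls below `tol` (default 1e-6), or
#'   once the residual reaches the numerical floor (1e-15 of the data's sum
#'   of squares, reachable only on exactly trilinear data).
#' @param max_iter Maximum number of alternating sweeps.
#' @param nonnegative Character vector naming the modes constrained to be
#'   nonnegative, a subset of `c("A", "B", "C")`. `NULL` (default) lets the
#'   algorithm choose: PARAFAC-ALS constrains the chromatographic and
#'   spectral modes (`c("A", "B")`), since negative elution or absorbance
#'   profiles are not physical; SWATLD runs unconstrained, as is customary.
#' @param init `"svd"` (deterministic, from the singular vectors of the
#'   three unfoldings) or `"random"`.
#' @param n_starts Number of starts; the first uses `init`, later ones are
#'   random with seeds derived from `seed`. The best fit is kept.
#' @param seed Integer seed for random initialization.
#' @return An object of class `"FitOptions"`.
#' @export
fit_options <- function(n_components, tol = 1e-6, max_iter = 2000L,
                        nonnegative = NULL, init = c("svd", "random"),
                        n_starts = 1L, seed = 1L) {
  init <- match.arg(init)
  if (n_components < 1L) stop("`n_components` must be >= 1")
  if (tol <= 0) stop("`tol` must be > 0")
  if (n_starts < 1L) stop("`n_starts` must be >= 1")
  if (!is.null(nonnegative)) {
    nonnegative <- as.character(nonnegative)
    if (length(setdiff(nonnegative, c("A", "B", "C"))))
      stop("`nonnegative` must name modes among A, B, C")
  }
  structure(list(n_components = as.integer(n_components), tol = tol,
                 max_iter = as.integer(max_iter), nonnegative = nonnegative,
                 init = init, n_starts = as.integer(n_starts),
                 seed = as.integer(seed)),
            class = "FitOptions")
}

# ---- unfoldings -----------------------------------------------------------
# X1: I x (JK), column j + (k-1)J  <-> columns of krc(C, B)
# X2: J x (IK), column i + (k-1)I  <-> columns of krc(C, A)
# X3: K x (IJ), column i + (j-1)I  <-> columns of krc(B, A)
unfold1 <- function(x) matrix(x, dim(x)[1])
unfold2 <- function(x) matrix(aperm(x, c(2, 1, 3)), dim(x)[2])
unfold3 <- function(x) matrix(aperm(x, c(3, 1, 2)), dim(x)[3])

# column-wise Khatri-Rao product: column n is kronecker(U[, n], V[, n])
krc <- function(U, V) {
  U[rep(seq_len(nrow(U)), each = nrow(V)), , drop = FALSE] *
    V[rep(seq_len(nrow(V)), nrow(U)), , drop = FALSE]
}

# symmetric-positive-semidefinite inverse with pseudo-inverse fallback
inv_sym <- function(G) {
  out <- tryCatch(chol2inv(chol(G)), error = function(e) NULL)
  if (is.null(out)) out <- pracma::pinv(G)
  out
}

pinv_cut <- function(M, rtol = 1e-10) {
  s <- svd(M)
  keep <- s$d > rtol * max(s$d, .Machine$double.xmin)
  if (!any(keep)) stop("matrix is numerically zero")
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# ---- row-wise nonnegative least squares -----------------------------------
# Solves, for every row w of W, min_{a >= 0} ||Z a - x||^2 given G = Z'Z and
# W = X Z. For small N the exact solution is found by enumerating supports
# (the optimum is the feasible support solution maximizing w'a); for larger
# N it falls back to Lawson-Hanson on the Cholesky-reduced system.
nnls_rows <- function(G, W) {
  N <- ncol(G)
  if (N <= 10L) return(nnls_rows_enum(G, W))
  R <- tryCatch(chol(G), error = function(e)
    chol(G + diag(1e-12 * max(diag(G)), N)))
  t(apply(W, 1L, function(w) {
    d <- backsolve(R, w, transpose = TRUE)
    pracma::lsqnonneg(R, d)$x
  }))
}

nnls_rows_enum <- function(G, W) {
  N <- ncol(G)
  best_val <- numeric(nrow(W))             # empty support scores 0
  best <- matrix(0, nrow(W), N)
  for (code in seq_len(2^N - 1L)) {
    S <- which(bitwAnd(code, bitwShiftL(1L, seq_len(N) - 1L)) != 0L)
    GS <- G[S, S, drop = FALSE]
    ok <- tryCatch({ch <- chol(GS); TRUE}, error = function(e) FALSE)
    if (!ok) next
    AS <- W[, S, drop = FALSE] %*% chol2inv(ch)
    feas <- rowSums(AS < -1e-9 * sqrt(diag(G))[col(AS)]) == 0
    if (!any(feas)) next
    val <- rowSums(AS * W[, S, drop = FALSE])
    upd <- feas & (val > best_val * (1 + 1e-12))
    if (any(upd)) {
      best[upd, ] <- 0
      best[upd, S] <- pmax(AS[upd, , drop = FALSE], 0)
      best_val[upd] <- val[upd]
    }
  }
  best
}

# ---- normalization --------------------------------------------------------
# unit-norm columns in A and B, all scale in C; signs canonicalized so that
# the (mostly positive) physical profiles point upward
normalize_loadings <- function(A, B, C) {
  for (n in seq_len(ncol(A))) {
    na <- sqrt(sum(A[, n]^2)); nb <- sqrt(sum(B[, n]^2))
    if (na > 0) { A[, n] <- A[, n] / na }
    if (nb > 0) { B[, n] <- B[, n] / nb }
    C[, n] <- C[, n] * na * nb
    sa <- if (sum(A[, n]) < 0) -1 else 1
    A[, n] <- sa * A[, n]; C[, n] <- sa * C[, n]
    sb <- if (sum(B[, n]) < 0) -1 else 1
    B[, n] <- sb * B[, n]; C[, n] <- sb * C[, n]
  }
  list(A = A, B = B, C = C)
}

new_loading_set <- function(A, B, C, algorithm, iterations, fit_trace,
                            converged, options) {
  nl <- normalize_loadings(A, B, C)
  structure(list(A = nl$A, B = nl$B, C = nl$C,
                 n_components = ncol(A), algorithm = algorithm,
                 iterations = iterations,
                 fit_percent = fit_trace[length(fit_trace)],
                 fit_trace = fit_trace, converged = converged,
                 options = options),
            class = "LoadingSet")
}

#' @export
print.LoadingSet <- function(x, ...) {
  cat("LoadingSet (", x$algorithm, "): ", x$n_components, " components, ",
      x$iterations, " sweeps, fit ",
      formatC(x$fit_percent, digits = 4, format = "f"), "%",
      if (isTRUE(x$converged)) ", converged" else ", NOT converged",
      "\n", sep = "")
  invisible(x)
}

#' Initialize loadings for an alternating decomposition
#'
#' `init = "svd"` takes the leading left singular vectors of the three
#' unfoldings (deterministic); `init = "random"` draws standard-normal
#' loadings from `options$seed`. Columns are normalized as in the fitted
#' model.
#'
#' @param cube A [data_cube()].
#' @param options A [fit_options()].
#' @return A `"LoadingSet"` with `iterations = 0`.
#' @export
init_loadings <- function(cube, options) {
  stopifnot(inherits(cube, "DataCube"), inherits(options, "FitOptions"))
  d <- dim(cube$values); N <- options$n_components
  if (N > min(d))
    stop("n_components (", N, ") exceeds an axis length (",
         paste(d, collapse = " x "), ")")
  if (options$init == "svd") {
    A <- svd(unfold1(cube$values), nu = N, nv = 0)$u
    B <- svd(unfold2(cube$values), nu = N, nv = 0)$u
    C <- svd(unfold3(cube$values), nu = N, nv = 0)$u
  } else {
    mats <- with_seed(options$seed, list(
      A = matrix(abs(rnorm(d[1] * N)), d[1]),
      B = matrix(abs(rnorm(d[2] * N)), d[2]),
      C = matrix(abs(rnorm(d[3] * N)), d[3])))
    A <- mats$A; B <- mats$B; C <- mats$C
  }
  new_loading_set(A, B, C, "init", 0L, NA_real_, NA, options)
}

# shared fitting harness: multi-start around a single-sweep engine
fit_trilinear <- function(cube, options, algorithm, sweep_fun, nonneg_default) {
  stopifnot(inherits(cube, "DataCube"), inherits(options, "FitOptions"))
  nonneg <- options$nonnegative %||% nonneg_default
  x <- cube$values
  d <- dim(x); N <- options$n_components
  if (N > min(d))
    stop("n_components (", N, ") exceeds an axis length")
  X1 <- unfold1(x); X2 <- unfold2(x); X3 <- unfold3(x)
  ssx <- sum(x^2)
  best <- NULL
  for (s in seq_len(options$n_starts)) {
    opt_s <- options
    if (s > 1L) { opt_s$init <- "random"; opt_s$seed <- options$seed + s - 1L }
    st <- init_loadings(cube, opt_s)
    res <- run_sweeps(st$A, st$B, st$C, X1, X2, X3, ssx, options, nonneg,
                      sweep_fun,
                      burn_in = if (length(nonneg)) 10L else 0L)
    if (is.null(best) ||
        res$fit_trace[length(res$fit_trace)] >
        best$fit_trace[length(best$fit_trace)])
      best <- res
  }
  out <- new_loading_set(best$A, best$B, best$C, algorithm,
                         best$iterations, best$fit_trace, best$converged,
                         options)
  if (any(!is.finite(out$A)) || any(!is.finite(out$B)) ||
      any(!is.finite(out$C)))
    stop("non-finite loadings encountered; the solution is degenerate ",
         "(try fewer components or another start)")
  out
}

# burn_in: constrained fits start from a short unconstrained refinement of
# the initialization (guards against swamps); the recorded trace covers the
# constrained phase only, so the ALS monotonicity of the objective holds on
# the trace.
run_sweeps <- function(A, B, C, X1, X2, X3, ssx, options, nonneg, sweep_fun,
                       burn_in = 0L) {
  fit_trace <- numeric(0)
  ssr_old <- Inf
  converged <- FALSE
  reinit_used <- FALSE
  it <- 0L
  while (it < options$max_iter) {
    it <- it + 1L
    if (it == burn_in + 1L && burn_in > 0L) {
      # orient columns positively before constraints can clip them
      nl <- normalize_loadings(A, B, C)
      A <- nl$A; B <- nl$B; C <- nl$C
      fit_trace <- numeric(0); ssr_old <- Inf
    }
    up <- sweep_fun(A, B, C, X1, X2, X3,
                    if (it <= burn_in) character() else nonneg)
    A <- up$A; B <- up$B; C <- up$C
    # degenerate-column guard: one re-randomization, then error
    norms <- pmin(sqrt(colSums(A^2)), sqrt(colSums(B^2)), sqrt(colSums(C^2)))
    if (any(norms < 1e-12)) {
      if (reinit_used)
        stop("loading column collapsed to zero twice; degenerate solution")
      reinit_used <- TRUE
      bad <- which(norms < 1e-12)
      redraw <- with_seed(options$seed + 7919L, list(
        A = matrix(abs(rnorm(nrow(A) * length(bad))), nrow(A)),
        B = matrix(abs(rnorm(nrow(B) * length(bad))), nrow(B)),
        C = matrix(abs(rnorm(nrow(C) * length(bad))), nrow(C))))
      A[, bad] <- redraw$A; B[, bad] <- redraw$B; C[, bad] <- redraw$C
    }
    ssr <- ssx - 2 * sum(C * (X3 %*% krc(B, A))) +
      sum(crossprod(C) * (crossprod(B) * crossprod(A)))
    ssr <- max(ssr, 0)
    fit <- 100 * (1 - ssr / ssx)
    fit_trace <- c(fit_trace, fit)
    # relative change in the residual sum of squares; exactly trilinear
    # data hit the absolute floor instead
    if (it > burn_in &&
        (ssr < 1e-15 * ssx ||
         (is.finite(ssr_old) &&
            abs(ssr_old - ssr) < options$tol * max(ssr_old, 1e-300)))) {
      converged <- TRUE
      break
    }
    ssr_old <- ssr
  }
  list(A = A, B = B, C = C, iterations = it, fit_trace = fit_trace,
       converged = converged)
}

#' PARAFAC by alternating least squares
#'
#' Fits the trilinear model
#' \deqn{x_{ijk} = \sum_{n=1}^N a_{in} b_{jn} c_{kn} + e_{ijk}}
#' by minimizing the residual sum of squares, cycling exact least-squares
#' (or nonnegative least-squares) updates of the chromatographic (`A`),
#' spectral (`B`) and concentration (`C`) loadings until the relative change
#' in the explained variation falls below `tol`. The objective is
#' non-increasing across sweeps. By default the physical modes `A` and `B`
#' are constrained nonnegative; `C` is left free so it can serve directly as
#' the regressor of the calibration step.
#'
#' @param cube A [data_cube()] (typically calibration and prediction samples
#'   decomposed jointly, which is what confers the second-order advantage).
#' @param options A [fit_options()].
#' @return A `"LoadingSet"`: unit-norm `A`, `B` columns, scale in `C`, plus
#'   `fit_percent` (100 x explained sum of squares fraction), the sweep-wise
#'   `fit_trace`, `iterations` and `converged`.
#' @seealso [swatld()], [align_factors()], [reconstruct()]
#' @export
parafac_als <- function(cube, options) {
  fit_trilinear(cube, options, "parafac_als", sweep_parafac, c("A", "B"))
}

sweep_parafac <- function(A, B, C, X1, X2, X3, nonneg) {
  GB <- crossprod(B); GC <- crossprod(C)
  W <- X1 %*% krc(C, B); G <- GC * GB
  A <- if ("A" %in% nonneg) nnls_rows(G, W) else W %*% inv_sym(G)
  GA <- crossprod(A)
  W <- X2 %*% krc(C, A); G <- GC * GA
  B <- if ("B" %in% nonneg) nnls_rows(G, W) else W %*% inv_sym(G)
  GB <- crossprod(B)
  W <- X3 %*% krc(B, A); G <- GB * GA
  C <- if ("C" %in% nonneg) nnls_rows(G, W) else W %*% inv_sym(G)
  list(A = A, B = B, C = C)
}

#' Self-weighted alternating trilinear decomposition (SWATLD)
#'
#' Alternating scheme in which each mode is updated as the average of two
#' pseudo-inverse projections of the corresponding unfolding, each
#' column-weighted by the inverse squared norms of the partner modes'
#' loadings. The self-weighting makes the extracted true factors largely
#' insensitive to extra (excess) components and convergence is typically
#' reached in far fewer sweeps than PARAFAC-ALS, at the cost of not
#' monotonically minimizing a single least-squares objective.
#'
#' Output contract and normalization are identical to [parafac_als()]. If
#' nonnegativity is requested the named modes are projected (negative
#' entries zeroed) after each sweep; the classical algorithm, and the
#' default here, is unconstrained.
#'
#' @inheritParams parafac_als
#' @return A `"LoadingSet"`, as for [parafac_als()].
#' @export
swatld <- function(cube, options) {
  fit_trilinear(cube, options, "swatld", sweep_swatld, character())
}

sweep_swatld <- function(A, B, C, X1, X2, X3, nonneg) {
  scl <- function(M) sweep(M, 2L, pmax(colSums(M^2), 1e-300), "/")
  Ap <- t(pinv_cut(A)); Bp <- t(pinv_cut(B)); Cp <- t(pinv_cut(C))
  A <- 0.5 * X1 %*% (krc(Cp, scl(B)) + krc(scl(C), Bp))
  if ("A" %in% nonneg) A <- pmax(A, 0)
  Ap <- t(pinv_cut(A))
  B <- 0.5 * X2 %*% (krc(Cp, scl(A)) + krc(scl(C), Ap))
  if ("B" %in% nonneg) B <- pmax(B, 0)
  Bp <- t(pinv_cut(B))
  C <- 0.5 * X3 %*% (krc(Bp, scl(A)) + krc(scl(B), Ap))
  if ("C" %in% nonneg) C <- pmax(C, 0)
  list(A = A, B = B, C = C)
}

#' Match fitted factors to analytes via reference spectra
#'
#' Resolves the permutation and sign indeterminacy of a trilinear fit:
#' components are greedily assigned to reference spectra by maximal absolute
#' correlation (ties broken by column order), matched spectral columns are
#' sign-flipped to correlate positively (the concentration column is flipped
#' with them, leaving the reconstruction unchanged), and unmatched factors
#' (interferents) are placed after the analytes in order of decreasing
#' concentration-loading norm.
#'
#' @param result A `"LoadingSet"`.
#' @param reference_spectra Numeric matrix, wavelengths x analytes, on the
#'   same wavelength grid as the fit; column names are the analyte names.
#' @return The reordered `"LoadingSet"`, with extra fields
#'   `analyte_names`, `n_analytes` and `analyte_correlations` (the
#'   correlation of each matched spectral column with its reference).
#' @export
align_factors <- function(result, reference_spectra) {
  stopifnot(inherits(result, "LoadingSet"))
  refs <- as.matrix(reference_spectra)
  if (nrow(refs) != nrow(result$B))
    stop("reference spectra are on a different wavelength grid (",
         nrow(refs), " vs ", nrow(result$B), " points)")
  M <- ncol(refs)
  if (M > result$n_components)
    stop("more reference spectra than fitted components")
  if (is.null(colnames(refs))) colnames(refs) <- paste0("analyte", seq_len(M))
  R <- suppressWarnings(stats::cor(result$B, refs))
  R[!is.finite(R)] <- 0
  assign <- integer(M)      # assign[m] = factor index matched to reference m
  free_f <- rep(TRUE, result$n_components)
  free_r <- rep(TRUE, M)
  for (step in seq_len(M)) {
    Rm <- abs(R); Rm[!free_f, ] <- -Inf; Rm[, !free_r] <- -Inf
    ij <- arrayInd(which.max(Rm), dim(Rm))
    assign[ij[2]] <- ij[1]
    free_f[ij[1]] <- FALSE; free_r[ij[2]] <- FALSE
  }
  rest <- which(free_f)
  if (length(rest) > 1L)
    rest <- rest[order(colSums(result$C[, rest, drop = FALSE]^2),
                       decreasing = TRUE)]
  ord <- c(assign, rest)
  out <- result
  out$A <- result$A[, ord, drop = FALSE]
  out$B <- result$B[, ord, drop = FALSE]
  out$C <- result$C[, ord, drop = FALSE]
  cors <- numeric(M)
  for (m in seq_len(M)) {
    r <- R[assign[m], m]
    if (r < 0) {
      out$B[, m] <- -out$B[, m]
      out$C[, m] <- -out$C[, m]
      r <- -r
    }
    cors[m] <- r
  }
  names(cors) <- colnames(refs)
  colnames(out$A) <- colnames(out$B) <- colnames(out$C) <-
    c(colnames(refs), if (length(rest)) paste0("factor", rest))
  out$analyte_names <- colnames(refs)
  out$n_analytes <- M
  out$analyte_correlations <- cors
  out
}

#' Rebuild the model intensity array from loadings
#'
#' Evaluates the trilinear forward model
#' \eqn{\hat x_{ijk} = \sum_n a_{in} b_{jn} c_{kn}}.
#'
#' @param loadings A `"LoadingSet"`.
#' @param cube_shape Optional length-3 integer vector to check against.
#' @return Numeric I x J x K array.
#' @export
reconstruct <- function(loadings, cube_shape = NULL) {
  stopifnot(inherits(loadings, "LoadingSet"))
  d <- c(nrow(loadings$A), nrow(loadings$B), nrow(loadings$C))
  if (!is.null(cube_shape) && !identical(as.integer(cube_shape), as.integer(d)))
    stop("requested shape (", paste(cube_shape, collapse = " x "),
         ") does not match the loadings (", paste(d, collapse = " x "), ")")
  array(loadings$A %*% t(krc(loadings$C, loadings$B)), d)
}

#' Explained variation of a loading set on a cube
#'
#' @param loadings A `"LoadingSet"`.
#' @param cube A [data_cube()] (or array) of matching shape.
#' @return Percentage `100 * (1 - ||X - Xhat||^2 / ||X||^2)`.
#' @export
explained_fit <- function(loadings, cube) {
  x <- if (inherits(cube, "DataCube")) cube$values else cube
  xh <- reconstruct(loadings, dim(x))
  100 * (1 - sum((x - xh)^2) / sum(x^2))
}
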