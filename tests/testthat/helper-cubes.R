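# Shared fixtures and independent oracles, all built in code.

# paper-like three-component study on a coarser grid (faster fits, same
# structure: 10 calibration / 6 prediction / 3 blank, interferent only in
# prediction samples)
coarse_paperlike <- function(seed = 11, noise_sd = 0, n_time = 76,
                             n_wavelength = 46) {
  van <- seq(5, 32, by = 3)
  cep <- van[c(4, 8, 1, 6, 10, 3, 7, 2, 9, 5)]
  added <- plasma_study_results()
  simulate_cube(simulation_config(
    default_components(), n_calibration = 10, n_prediction = 6, n_blank = 3,
    time_axis = seq(0, 5, length.out = n_time),
    wavelength_axis = seq(200, 380, length.out = n_wavelength),
    calibration_conc = cbind(vancomycin = van, cephalexin = cep),
    prediction_conc = cbind(vancomycin = added$added_vancomycin,
                            cephalexin = added$added_cephalexin),
    noise_sd = noise_sd, seed = seed))
}

# two analytes only (true rank 2), no prediction/blank samples
two_comp_cube <- function(seed = 5, noise_sd = 0, n_time = 60,
                          n_wavelength = 40, n_cal = 8) {
  simulate_cube(simulation_config(
    default_components()[1:2], n_calibration = n_cal, n_prediction = 0,
    n_blank = 0,
    time_axis = seq(0, 5, length.out = n_time),
    wavelength_axis = seq(200, 380, length.out = n_wavelength),
    noise_sd = noise_sd, seed = seed))
}

# absolute cosine between matched columns of two matrices
col_cosines <- function(X, Y) {
  vapply(seq_len(ncol(X)), function(n) {
    abs(sum(X[, n] * Y[, n])) /
      sqrt(sum(X[, n]^2) * sum(Y[, n]^2))
  }, numeric(1))
}

# cosines of fitted loadings against simulator ground truth, after matching
# the analyte factors by reference spectra (leftover factors are the
# interferents, ordered as in the truth by construction of the fixtures)
truth_cosines <- function(aligned, truth) {
  n_an <- sum(truth$roles == "analyte")
  ord <- c(which(truth$roles == "analyte"), which(truth$roles != "analyte"))
  N <- min(ncol(aligned$A), length(ord))
  list(A = col_cosines(aligned$A[, 1:N], truth$A[, ord[1:N]]),
       B = col_cosines(aligned$B[, 1:N], truth$B[, ord[1:N]]),
       C = col_cosines(aligned$C[, 1:N], truth$C[, ord[1:N]]))
}

# independent brute-force oracle: direct nonlinear least-squares
# minimization of the trilinear residual over all loadings (multi-start
# quasi-Newton), returning the best fit percentage found
bf_trilinear_fit <- function(cube, N, n_starts = 8, seed = 99) {
  x <- cube$values
  d <- dim(x)
  ssx <- sum(x^2)
  X1 <- matrix(x, d[1])
  X2 <- matrix(aperm(x, c(2, 1, 3)), d[2])
  X3 <- matrix(aperm(x, c(3, 1, 2)), d[3])
  kr <- function(U, V)
    U[rep(seq_len(nrow(U)), each = nrow(V)), , drop = FALSE] *
    V[rep(seq_len(nrow(V)), nrow(U)), , drop = FALSE]
  nA <- d[1] * N; nB <- d[2] * N; nC <- d[3] * N
  split_p <- function(p)
    list(A = matrix(p[seq_len(nA)], d[1]),
         B = matrix(p[nA + seq_len(nB)], d[2]),
         C = matrix(p[nA + nB + seq_len(nC)], d[3]))
  obj <- function(p) {
    l <- split_p(p)
    sum((X1 - l$A %*% t(kr(l$C, l$B)))^2)
  }
  grad <- function(p) {
    l <- split_p(p)
    gA <- 2 * (l$A %*% t(kr(l$C, l$B)) - X1) %*% kr(l$C, l$B)
    gB <- 2 * (l$B %*% t(kr(l$C, l$A)) - X2) %*% kr(l$C, l$A)
    gC <- 2 * (l$C %*% t(kr(l$B, l$A)) - X3) %*% kr(l$B, l$A)
    c(gA, gB, gC)
  }
  set.seed(seed)
  best <- Inf
  for (s in seq_len(n_starts)) {
    p0 <- stats::rnorm(nA + nB + nC, sd = max(abs(x))^(1 / 3))
    r <- stats::nlminb(p0, obj, grad,
                       control = list(iter.max = 3000, eval.max = 6000,
                                      rel.tol = 1e-15))
    if (r$objective < best) best <- r$objective
  }
  100 * (1 - best / ssx)
}

# tiny dense trilinear cube with O(1) entries for the oracle comparison
tiny_cube <- function(I = 8, J = 6, K = 5, N = 2, noise_sd = 0.005,
                      seed = 17) {
  set.seed(seed)
  A <- matrix(runif(I * N, 0.2, 1), I)
  B <- matrix(runif(J * N, 0.2, 1), J)
  C <- matrix(runif(K * N, 0.5, 2), K)
  x <- array(A %*% t(trical:::krc(C, B)), c(I, J, K))
  x <- x + array(rnorm(I * J * K, sd = noise_sd * max(x)), c(I, J, K))
  data_cube(x, seq_len(I), seq_len(J), paste0("s", seq_len(K)))
}
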