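# First-level two-timescale GLM: discrete-cosine high-pass (128-s cutoff)
# applied to data and design, OLS, pooled AR(1) estimation from residuals,
# prewhitening, and a second pass for the final estimates.

#' Discrete cosine high-pass drift basis
#'
#' Orthonormal DCT-II basis restricted to the `K = floor(2 * n * TR /
#' cutoff)` slowest components, i.e. all oscillations with period longer
#' than the cutoff. Residualizing a time series against this basis removes
#' frequencies below `1/cutoff` Hz while leaving the constant (the basis has
#' zero column means) and the passband essentially untouched.
#'
#' @param n_timepoints number of scans (>= 2).
#' @param tr_s repetition time (s).
#' @param cutoff_s high-pass cutoff period in seconds (default 128).
#' @return `n_timepoints x K` matrix with orthonormal columns.
#' @export
dct_highpass_basis <- function(n_timepoints, tr_s, cutoff_s = 128) {
  if (n_timepoints < 2) stop("need >= 2 time points", call. = FALSE)
  K <- floor(2 * n_timepoints * tr_s / cutoff_s)
  if (K < 1)
    stop("cutoff period longer than twice the run: no drift components",
         call. = FALSE)
  if (cutoff_s <= 2 * tr_s || K >= n_timepoints)
    stop("cutoff at or below twice the TR: the drift basis would span ",
         "the whole time series", call. = FALSE)
  t <- seq_len(n_timepoints) - 1
  B <- vapply(seq_len(K), function(k)
    sqrt(2 / n_timepoints) * cos(pi * (2 * t + 1) * k / (2 * n_timepoints)),
    numeric(n_timepoints))
  B
}

# residualize columns of M against an orthonormal basis
hp_filter <- function(M, basis) M - basis %*% crossprod(basis, M)

#' Pooled lag-1 autocorrelation of residuals
#'
#' Per-voxel lag-1 autocorrelation `sum(r_t r_{t-1}) / sum(r_t^2)`, averaged
#' over voxels. Used to estimate the AR(1) coefficient that the prewhitening
#' transform removes.
#'
#' @param residuals voxels x time matrix (or time vector).
#' @return pooled rho in (-1, 1).
#' @export
estimate_ar1 <- function(residuals) {
  if (is.vector(residuals)) residuals <- matrix(residuals, nrow = 1)
  n_t <- ncol(residuals)
  if (n_t < 3) stop("need >= 3 time points to estimate AR(1)", call. = FALSE)
  ss <- rowSums(residuals^2)
  if (all(ss < 1e-24))
    stop("constant (zero-variance) residuals: AR(1) undefined", call. = FALSE)
  keep <- ss >= 1e-24
  r <- rowSums(residuals[keep, -1, drop = FALSE] *
                 residuals[keep, -n_t, drop = FALSE]) / ss[keep]
  mean(r)
}

# AR(1) whitening transform of a time x k matrix
ar1_whiten <- function(M, rho) {
  if (abs(rho) < 1e-12) return(M)
  W <- rbind(sqrt(1 - rho^2) * M[1, , drop = FALSE],
             M[-1, , drop = FALSE] - rho * M[-nrow(M), , drop = FALSE])
  W
}

#' Fit the first-level GLM to a BOLD run
#'
#' Two-pass estimation: both data and design are high-pass filtered by
#' residualization against the DCT drift basis (the constant column, being
#' orthogonal to the basis, survives); an OLS pass yields residuals from
#' which a single pooled AR(1) coefficient is estimated; data and design are
#' then prewhitened and refit. All-zero design columns (the motion
#' placeholders of a synthetic session) are dropped from estimation and
#' reported with beta 0; any other rank deficiency is an error naming the
#' dependent columns.
#'
#' @param run a `bold_run` ([simulate_bold_run()]) or a time x voxel matrix.
#' @param X `design_matrix` (must include a constant column).
#' @param mask optional 3D logical array; default the run's mask.
#' @param cutoff_s high-pass cutoff (s), default 128; `NULL` disables
#'   filtering.
#' @return object of class `glm_fit`: list with `betas` (regressor x voxel,
#'   all 18 rows), `sigma2`, `dof`, `ar1_rho`, `xtx_inv` (whitened,
#'   estimated columns), `labels`, `mask`, `volume_shape`, `filter_cutoff_s`.
#' @export
fit_glm <- function(run, X, mask = NULL, cutoff_s = 128) {
  tr <- attr(X, "tr_s")
  if (inherits(run, "bold_run")) {
    if (is.null(mask)) mask <- run$mask
    shape <- dim(run$data)[1:3]
    n_t <- dim(run$data)[4]
    Y <- t(matrix(run$data, ncol = n_t))   # time x voxel
    vox <- which(as.vector(mask))
    Y <- Y[, vox, drop = FALSE]
  } else {
    Y <- as.matrix(run)
    n_t <- nrow(Y)
    shape <- NULL
    vox <- seq_len(ncol(Y))
  }
  if (n_t != nrow(X)) stop("time dimensions of run and design disagree",
                           call. = FALSE)

  labels <- colnames(X)
  Xm <- unclass(X)[, , drop = FALSE]
  zero_cols <- which(apply(Xm, 2, function(x) all(abs(x) < 1e-12)))
  est_cols <- setdiff(seq_along(labels), zero_cols)
  Xe <- Xm[, est_cols, drop = FALSE]

  if (!is.null(cutoff_s)) {
    B <- dct_highpass_basis(n_t, tr, cutoff_s)
    Y <- hp_filter(Y, B)
    Xe <- hp_filter(Xe, B)
  }

  qrx <- qr(Xe)
  if (qrx$rank < ncol(Xe)) {
    dep <- colnames(Xe)[qrx$pivot[(qrx$rank + 1):ncol(Xe)]]
    stop("rank-deficient design; dependent columns: ",
         paste(dep, collapse = ", "), call. = FALSE)
  }

  solve_pass <- function(Xw, Yw) {
    q <- qr(Xw)
    beta <- qr.coef(q, Yw)
    res <- Yw - Xw %*% beta
    list(beta = beta, res = res, qr = q)
  }

  p1 <- solve_pass(Xe, Y)
  resid_power <- mean(p1$res^2)
  rho <- if (resid_power < 1e-16) 0 else estimate_ar1(t(p1$res))
  if (abs(rho) > 1e-12) {
    Xw <- ar1_whiten(Xe, rho)
    Yw <- ar1_whiten(Y, rho)
    p2 <- solve_pass(Xw, Yw)
  } else {
    Xw <- Xe
    p2 <- p1
  }

  K <- if (is.null(cutoff_s)) 0 else ncol(B)
  dof <- n_t - ncol(Xe) - K
  sigma2 <- colSums(p2$res^2) / dof
  betas <- matrix(0, length(labels), ncol(Y),
                  dimnames = list(labels, NULL))
  betas[est_cols, ] <- p2$beta
  structure(list(
    betas = betas, sigma2 = sigma2, dof = dof, ar1_rho = rho,
    xtx_inv = chol2inv(qr.R(qr(Xw))), est_cols = est_cols,
    labels = labels, mask = mask, volume_shape = shape, voxels = vox,
    filter_cutoff_s = if (is.null(cutoff_s)) NA_real_ else cutoff_s,
    residuals = p2$res
  ), class = "glm_fit")
}

#' Contrast of GLM parameter estimates
#'
#' Effect size `w' beta` and its t statistic per voxel, with variance
#' `w' (X'X)^-1 w * sigma2` from the whitened design.
#'
#' @param fit `glm_fit`.
#' @param weights numeric vector over all design columns (length 18 for the
#'   standard layout) or a named vector over a subset of columns.
#' @return object of class `contrast_image`: list with `effect`, `t_stat`
#'   (vectors over in-mask voxels), `weights`, `dof`, plus `volume_shape`
#'   and `voxels` for reshaping.
#' @export
compute_contrast <- function(fit, weights) {
  if (!is.null(names(weights))) {
    w <- numeric(length(fit$labels))
    miss <- setdiff(names(weights), fit$labels)
    if (length(miss)) stop("unknown regressors: ", paste(miss, collapse = ", "),
                           call. = FALSE)
    w[match(names(weights), fit$labels)] <- weights
    weights <- w
  }
  if (length(weights) != length(fit$labels))
    stop("weights length must equal the regressor count (",
         length(fit$labels), ")", call. = FALSE)
  effect <- drop(t(weights) %*% fit$betas)
  we <- weights[fit$est_cols]
  var_scale <- drop(t(we) %*% fit$xtx_inv %*% we)
  se <- sqrt(var_scale * fit$sigma2)
  t_stat <- ifelse(se < 1e-24, 0, effect / se)
  structure(list(effect = effect, t_stat = t_stat, weights = weights,
                 dof = fit$dof, volume_shape = fit$volume_shape,
                 voxels = fit$voxels),
            class = "contrast_image")
}

#' Percent signal change of a contrast
#'
#' `100 * (w' beta) * scale_factor / beta_constant`, the convention in which
#' the contrast effect is rescaled by the peak of the convolved reference
#' trial (supplied as `scale_factor = 0.132`) and expressed as a percentage
#' of the session constant.
#'
#' @param fit `glm_fit` (its design must contain a `constant` column with
#'   nonzero beta).
#' @param weights as in [compute_contrast()].
#' @param scale_factor reference-trial scaling; default 0.132.
#' @return numeric vector of percent signal change over in-mask voxels.
#' @export
percent_signal_change <- function(fit, weights, scale_factor = 0.132) {
  if (!"constant" %in% fit$labels)
    stop("design has no constant column", call. = FALSE)
  b0 <- fit$betas["constant", ]
  if (any(abs(b0) < 1e-12))
    stop("constant-term beta is zero: percent signal change undefined",
         call. = FALSE)
  con <- compute_contrast(fit, weights)
  100 * con$effect * scale_factor / b0
}
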