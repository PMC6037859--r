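# Forward BOLD model: signal = baseline + design columns x region amplitudes
# + cosine drift + AR(1) Gaussian noise. Matches the generative assumptions
# of the first-level GLM so that the noiseless inversion is exact.

#' Ground-truth effect specification for simulated volumes
#'
#' Describes where in the synthetic brain each regressor produces signal.
#' Regions are integer labels in a 3D map (0 = background); `amplitudes`
#' maps (region, regressor) pairs to BOLD amplitudes in the units of the
#' design-matrix columns.
#'
#' @param region_map 3D integer array of region labels.
#' @param amplitudes data frame with columns `region` (integer label),
#'   `regressor` (design-matrix column name, e.g. `"SJ_sustained"`,
#'   `"TOJ_V333"`) and `amplitude` (numeric).
#' @param mask optional 3D logical/0-1 array; default: everything (must
#'   cover all non-zero regions).
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(region_map, amplitudes,
                        mask = array(TRUE, dim(region_map))) {
  if (length(dim(region_map)) != 3)
    stop("region_map must be a 3D array", call. = FALSE)
  if (!all(dim(mask) == dim(region_map)))
    stop("mask and region_map shapes differ", call. = FALSE)
  if (!all(c("region", "regressor", "amplitude") %in% names(amplitudes)))
    stop("amplitudes needs columns region, regressor, amplitude", call. = FALSE)
  labs <- setdiff(unique(as.vector(region_map)), 0)
  if (!all(labs %in% amplitudes$region))
    stop("region_map labels missing from amplitudes: ",
         paste(setdiff(labs, amplitudes$region), collapse = ", "),
         call. = FALSE)
  if (any(region_map != 0 & !mask))
    stop("mask must cover all non-zero regions", call. = FALSE)
  structure(list(region_map = region_map, amplitudes = amplitudes,
                 mask = mask != 0, volume_shape = dim(region_map)),
            class = "effect_spec")
}

#' Noise specification for simulated BOLD runs
#'
#' @param sigma marginal standard deviation of the AR(1) noise (BOLD units).
#' @param ar1_rho lag-1 autocorrelation, `|rho| < 1`.
#' @param drift_amplitude amplitude of the cosine drift (BOLD units).
#' @param drift_period_s drift period in seconds; the default 300 s lies
#'   beyond the 128-s high-pass cutoff so the filter must remove it.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 1, ar1_rho = 0.3, drift_amplitude = 0,
                       drift_period_s = 300) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (abs(ar1_rho) >= 1) stop("|ar1_rho| must be < 1", call. = FALSE)
  if (drift_amplitude < 0) stop("drift_amplitude must be >= 0", call. = FALSE)
  if (drift_period_s <= 0) stop("drift_period_s must be > 0", call. = FALSE)
  structure(list(sigma = sigma, ar1_rho = ar1_rho,
                 drift_amplitude = drift_amplitude,
                 drift_period_s = drift_period_s), class = "noise_spec")
}

#' Simulate a 4D BOLD run
#'
#' Each in-mask voxel's time series is the sum of a constant baseline, the
#' design-matrix columns weighted by the voxel's region amplitudes, a cosine
#' drift, and stationary AR(1) Gaussian noise with marginal standard
#' deviation `noise$sigma`. Out-of-mask voxels are zero. With `sigma = 0`
#' and `drift_amplitude = 0` the run is noiseless and the GLM recovers the
#' amplitudes exactly.
#'
#' @param sequence the `run_sequence` the design was built from (its
#'   duration fixes the number of scans).
#' @param design `design_matrix` for the run.
#' @param effects [effect_spec()].
#' @param noise [noise_spec()].
#' @param seed integer seed; identical seeds give bitwise-identical data.
#' @param baseline constant BOLD level (default 100), the denominator of
#'   percent signal change.
#' @return object of class `bold_run`: list with `data` (4D array
#'   x,y,z,time), `tr_s`, `mask`, `seed`, `sequence_ref`.
#' @export
simulate_bold_run <- function(sequence, design, effects, noise = noise_spec(),
                              seed = 1L, baseline = 100) {
  tr <- attr(design, "tr_s")
  dur <- attr(sequence, "duration_s")
  n_t <- nrow(design)
  if (is.null(tr))
    stop("design time axis does not match the sequence duration at this TR",
         call. = FALSE)
  if (!is.null(dur) && n_t != ceiling(dur / tr))
    stop("design time axis does not match the sequence duration at this TR",
         call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  shape <- effects$volume_shape
  n_vox <- prod(shape)
  mask <- as.vector(effects$mask)
  region <- as.vector(effects$region_map)

  # per-region signal time courses
  labs <- setdiff(unique(region[mask]), 0)
  signal <- matrix(0, n_t, n_vox)
  for (lab in labs) {
    amps <- effects$amplitudes[effects$amplitudes$region == lab, ]
    missing_cols <- setdiff(amps$regressor, colnames(design))
    if (length(missing_cols))
      stop("amplitude regressors absent from design: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    ts <- as.matrix(design[, amps$regressor, drop = FALSE]) %*% amps$amplitude
    signal[, region == lab & mask] <- ts
  }

  t_s <- (seq_len(n_t) - 1) * tr
  drift <- noise$drift_amplitude * cos(2 * pi * t_s / noise$drift_period_s)

  data <- matrix(0, n_t, n_vox)
  idx <- which(mask)
  data[, idx] <- baseline + signal[, idx] + drift
  if (noise$sigma > 0) {
    rho <- noise$ar1_rho
    innov_sd <- noise$sigma * sqrt(1 - rho^2)
    eps <- matrix(stats::rnorm(n_t * length(idx), sd = innov_sd),
                  n_t, length(idx))
    eps[1, ] <- stats::rnorm(length(idx), sd = noise$sigma)  # stationary start
    ar <- apply(eps, 2, function(e)
      stats::filter(e, rho, method = "recursive", init = 0))
    data[, idx] <- data[, idx] + ar
  }
  arr <- array(t(data), dim = c(shape, n_t))
  structure(list(data = arr, tr_s = tr, mask = effects$mask, seed = seed,
                 sequence_ref = attr(sequence, "seed")),
            class = "bold_run")
}
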