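#' Gaussian synchrony-judgment psychometric model
#'
#' Probability of a "synchronous" response in a synchrony judgment (SJ) task
#' as a function of the cue onset asynchrony (COA, ms; negative = audio
#' leading, positive = video leading). The model is a scaled Gaussian
#' `A * exp(-(coa - mu)^2 / (2 * sigma^2))`: its peak location `mu` is the
#' point of subjective simultaneity (PSS) and its standard deviation `sigma`
#' the temporal integration window (TIW).
#'
#' @param coa_ms numeric vector of signed COA values (ms).
#' @param mu_ms PSS (ms).
#' @param sigma_ms TIW (ms), strictly positive.
#' @param amplitude peak response probability `A` in (0, 1].
#' @return numeric vector of probabilities in `[0, amplitude]`.
#' @seealso [toj_model()], [fit_psychometric()]
#' @export
#' @examples
#' sj_model(c(-333, 0, 70, 333), mu_ms = 70, sigma_ms = 127, amplitude = 0.9)
sj_model <- function(coa_ms, mu_ms, sigma_ms, amplitude = 1) {
  if (!is.finite(sigma_ms) || sigma_ms <= 0)
    stop("sigma_ms must be a positive finite number", call. = FALSE)
  if (!is.finite(amplitude) || amplitude <= 0 || amplitude > 1)
    stop("amplitude must lie in (0, 1]", call. = FALSE)
  amplitude * exp(-(coa_ms - mu_ms)^2 / (2 * sigma_ms^2))
}

#' Cumulative-Gaussian temporal-order-judgment psychometric model
#'
#' Probability of a "video first" response in a temporal order judgment (TOJ)
#' task: the standard normal CDF of `(coa - mu) / sigma`. The 50% point `mu`
#' is the TOJ PSS and `sigma` the TOJ TIW.
#'
#' @inheritParams sj_model
#' @return numeric vector of probabilities, strictly increasing in `coa_ms`.
#' @export
toj_model <- function(coa_ms, mu_ms, sigma_ms) {
  if (!is.finite(sigma_ms) || sigma_ms <= 0)
    stop("sigma_ms must be a positive finite number", call. = FALSE)
  stats::pnorm((coa_ms - mu_ms) / sigma_ms)
}

#' Fit a psychometric function to one subject and task
#'
#' Least-squares fit of the SJ Gaussian ([sj_model()]; free parameters
#' `mu`, `sigma`, `A`) or the TOJ cumulative Gaussian ([toj_model()]; free
#' `mu`, `sigma`, amplitude fixed at 1) to per-level response proportions.
#' The sum of squared errors between observed proportions and the model is
#' minimized with `L-BFGS-B` from 8 deterministic starting points spanning
#' the COA range. Goodness of fit is `R^2 = 1 - SSres/SStot` computed over
#' the per-level proportions; when the proportions are constant
#' (`SStot = 0`, e.g. completely biased responding) `R^2` is defined as 0,
#' which makes such data TOJ-unable by construction.
#'
#' @param table data frame with columns `coa_ms`, `n_trials`, `n_target`
#'   (and optionally `task`), restricted to a single subject and task.
#' @param task `"SJ"` or `"TOJ"`; taken from the table's `task` column when
#'   omitted.
#' @return object of class `psychometric_fit`: a list with elements `task`,
#'   `mu_ms`, `sigma_ms`, `amplitude`, `r_squared`, `converged`, `sse`, and
#'   for TOJ fits `classification` (`"able"` or `"unable"`, see
#'   [classify_toj_ability()]).
#' @export
fit_psychometric <- function(table, task = NULL) {
  if (is.null(task)) {
    task <- unique(as.character(table$task))
    if (length(task) != 1)
      stop("table must contain a single task, or supply `task`", call. = FALSE)
  }
  task <- match.arg(task, c("SJ", "TOJ"))
  if (!all(c("coa_ms", "n_trials", "n_target") %in% names(table)))
    stop("table needs columns coa_ms, n_trials, n_target", call. = FALSE)
  tab <- stats::aggregate(cbind(n_trials, n_target) ~ coa_ms, data = table, sum)
  if (nrow(tab) < 4)
    stop("insufficient data: need >= 4 distinct COA levels, got ", nrow(tab),
         call. = FALSE)
  if (any(tab$n_trials < 1) || any(tab$n_target < 0) ||
      any(tab$n_target > tab$n_trials))
    stop("counts must satisfy 0 <= n_target <= n_trials", call. = FALSE)

  coa <- tab$coa_ms
  p_obs <- tab$n_target / tab$n_trials
  span <- diff(range(coa))

  sse_fun <- if (task == "SJ") {
    function(par) {
      p_hat <- par[3] * exp(-(coa - par[1])^2 / (2 * par[2]^2))
      sum((p_obs - p_hat)^2)
    }
  } else {
    function(par) sum((p_obs - stats::pnorm((coa - par[1]) / par[2]))^2)
  }

  # 8 deterministic multi-starts: 4 PSS locations x 2 window widths
  mu_starts <- stats::quantile(coa, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  sigma_starts <- c(span / 8, span / 3)
  amp_start <- min(1, max(0.5, max(p_obs)))
  lo <- c(min(coa) - span, 1)
  hi <- c(max(coa) + span, 5 * span + 1)
  if (task == "SJ") {
    lo <- c(lo, 1e-3)
    hi <- c(hi, 1)
  }

  best <- NULL
  for (mu0 in mu_starts) {
    for (s0 in sigma_starts) {
      par0 <- if (task == "SJ") c(mu0, s0, amp_start) else c(mu0, s0)
      res <- tryCatch(
        stats::optim(par0, sse_fun, method = "L-BFGS-B",
                     lower = lo, upper = hi,
                     control = list(maxit = 500)),
        error = function(e) NULL)
      if (is.null(res)) next
      if (is.null(best) || res$value < best$value) best <- res
    }
  }
  if (is.null(best))
    stop("optimization failed from all starting points", call. = FALSE)

  ss_res <- best$value
  ss_tot <- sum((p_obs - mean(p_obs))^2)
  r2 <- if (ss_tot < 1e-12) 0 else 1 - ss_res / ss_tot

  fit <- structure(list(
    task = task,
    mu_ms = best$par[1],
    sigma_ms = best$par[2],
    amplitude = if (task == "SJ") best$par[3] else 1,
    r_squared = r2,
    converged = best$convergence == 0,
    sse = ss_res,
    n_levels = nrow(tab)
  ), class = "psychometric_fit")
  if (task == "TOJ") fit$classification <- classify_toj_ability(fit)
  fit
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("%s psychometric fit: PSS = %.1f ms, TIW = %.1f ms", x$task,
              x$mu_ms, x$sigma_ms))
  if (x$task == "SJ") cat(sprintf(", A = %.3f", x$amplitude))
  cat(sprintf("\nR^2 = %.4f", x$r_squared))
  if (!is.null(x$classification)) cat(" ->", x$classification)
  cat("\n")
  invisible(x)
}

#' Classify TOJ ability from a psychometric fit
#'
#' Subjects whose TOJ cumulative-Gaussian fit achieves `R^2 >= 0.5` are
#' "able"; below the criterion they are "unable" (random or completely
#' biased temporal order responding). The boundary value 0.5 itself counts
#' as able.
#'
#' @param fit a `psychometric_fit` for the TOJ task.
#' @return `"able"` or `"unable"`.
#' @export
classify_toj_ability <- function(fit) {
  if (!inherits(fit, "psychometric_fit"))
    stop("fit must be a psychometric_fit", call. = FALSE)
  if (fit$task != "TOJ")
    stop("TOJ ability is only defined for TOJ fits", call. = FALSE)
  if (fit$r_squared >= 0.5) "able" else "unable"
}

#' Quantize a PSS to the video frame grid
#'
#' Stimulus asynchronies can only be realised in whole video frames
#' (60 Hz, 1000/60 ms per frame), up to 20 frames (333.33 ms) in either
#' direction. Returns the grid value nearest to `pss_ms`, clipping at
#' +/- 20 frames; exact ties go toward zero.
#'
#' @param pss_ms finite signed PSS estimate (ms).
#' @param frame_ms frame duration (ms); default `1000/60`.
#' @param max_frames clip limit in frames; default 20.
#' @return frame-quantized COA in ms (a multiple of `frame_ms`).
#' @export
#' @examples
#' select_pss_condition(70)   # 4 frames = 66.67 ms
select_pss_condition <- function(pss_ms, frame_ms = 1000 / 60,
                                 max_frames = 20L) {
  if (!is.finite(pss_ms)) stop("pss_ms must be finite", call. = FALSE)
  k <- abs(pss_ms) / frame_ms
  k_lo <- floor(k)
  # ties (fraction exactly 0.5) resolve to the smaller magnitude
  k_best <- if (k - k_lo > 0.5) k_lo + 1 else k_lo
  k_best <- min(k_best, max_frames)
  sign(pss_ms) * k_best * frame_ms
}

#' PSS condition for TOJ-unable subjects
#'
#' Subjects who cannot perform the TOJ have no usable TOJ PSS of their own;
#' the fMRI PSS condition then falls back either on a configured constant
#' (e.g. a group average from a prior study with the same stimuli) or, when
#' none is configured, on the mean PSS of the TOJ-able fits at hand.
#'
#' @param group_fits list of `psychometric_fit` objects from able subjects.
#' @param constant optional fallback PSS (ms); returned as-is when supplied.
#' @return signed PSS (ms).
#' @export
assign_fallback_pss <- function(group_fits = list(), constant = NULL) {
  if (!is.null(constant)) {
    if (!is.finite(constant)) stop("constant must be finite", call. = FALSE)
    return(constant)
  }
  if (length(group_fits) == 0)
    stop("no able fits supplied and no fallback constant configured",
         call. = FALSE)
  mean(vapply(group_fits, function(f) f$mu_ms, numeric(1)))
}

#' Classical t tests with explicit degenerate-case guards
#'
#' `paired_t()` performs the paired two-sided t test on equal-length vectors;
#' `independent_t()` the pooled-variance two-sample two-sided t test. Both
#' refuse data whose relevant variance is zero (the t statistic would be
#' infinite or undefined).
#'
#' @param x,y numeric vectors (paired: equal length >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("paired vectors must have equal length >= 2", call. = FALSE)
  d <- x - y
  if (stats::sd(d) < 1e-12) {
    if (all(abs(d) < 1e-12))   # identical vectors: no effect, t = 0 exactly
      return(list(t = 0, df = length(d) - 1, p = 1))
    stop("zero variance of nonzero paired differences: t statistic undefined",
         call. = FALSE)
  }
  res <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' @rdname paired_t
#' @export
independent_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs length >= 2", call. = FALSE)
  if (stats::sd(x) < 1e-12 && stats::sd(y) < 1e-12)
    stop("zero variance in both samples: t statistic undefined",
         call. = FALSE)
  res <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}
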