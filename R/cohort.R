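#' Default ground-truth parameter ranges for simulated subjects
#'
#' Uniform sampling bounds for the per-subject psychometric parameters.
#' Centres follow the group statistics typical of audiovisual point-light
#' drumming experiments: SJ PSS around +70 ms (video leading) with SJ TIW
#' around 127 ms, TOJ PSS around -55 ms (audio leading) with TOJ TIW around
#' 190 ms.
#'
#' @return named list of `c(lower, upper)` bounds for `sj_mu_ms`,
#'   `sj_sigma_ms`, `sj_amplitude`, `toj_mu_ms`, `toj_sigma_ms`.
#' @export
default_parameter_ranges <- function() {
  list(
    sj_mu_ms     = c(20, 120),
    sj_sigma_ms  = c(80, 180),
    sj_amplitude = c(0.7, 1),
    toj_mu_ms    = c(-200, 90),
    toj_sigma_ms = c(100, 300)
  )
}

#' Simulate a cohort of subject profiles
#'
#' Draws `n_able` subjects who can perform the temporal order judgment
#' (binary responses follow their cumulative-Gaussian TOJ model) and
#' `n_unable` subjects who cannot. Unable subjects are split evenly between
#' the two phenotypes seen empirically: "random" (coin-flip TOJ responses)
#' and "biased" (every TOJ response identical); when `n_unable` is odd the
#' extra subject is random. All subjects can perform the synchrony judgment.
#'
#' @param n_able,n_unable non-negative counts; their sum must be >= 1.
#' @param parameter_ranges named list of `c(lower, upper)` bounds, as
#'   [default_parameter_ranges()].
#' @param seed integer seed; the cohort is deterministic given the seed.
#' @return list of `subject_profile` objects, able subjects first.
#' @export
#' @examples
#' cohort <- make_cohort(9, 11, seed = 1)
#' table(vapply(cohort, `[[`, "", "responder_mode"))
make_cohort <- function(n_able, n_unable,
                        parameter_ranges = default_parameter_ranges(),
                        seed = 1L) {
  if (n_able < 0 || n_unable < 0 || n_able + n_unable < 1)
    stop("need n_able + n_unable >= 1", call. = FALSE)
  rng <- parameter_ranges
  needed <- names(default_parameter_ranges())
  if (!all(needed %in% names(rng)))
    stop("parameter_ranges must contain: ", paste(needed, collapse = ", "),
         call. = FALSE)
  for (nm in needed) {
    b <- rng[[nm]]
    if (length(b) != 2 || !all(is.finite(b)) || b[1] > b[2])
      stop("invalid range for ", nm, call. = FALSE)
  }
  if (rng$sj_sigma_ms[1] <= 0 || rng$toj_sigma_ms[1] <= 0)
    stop("sigma lower bounds must be positive", call. = FALSE)
  if (rng$sj_amplitude[1] <= 0 || rng$sj_amplitude[2] > 1)
    stop("sj_amplitude range must lie in (0, 1]", call. = FALSE)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  n <- n_able + n_unable
  modes <- c(rep("able", n_able),
             rep(c("random", "biased"), length.out = n_unable))
  draw <- function(nm) stats::runif(1, rng[[nm]][1], rng[[nm]][2])
  lapply(seq_len(n), function(i) {
    structure(list(
      subject_id = sprintf("sub-%02d", i),
      responder_mode = modes[i],
      sj_mu_ms = draw("sj_mu_ms"),
      sj_sigma_ms = draw("sj_sigma_ms"),
      sj_amplitude = draw("sj_amplitude"),
      toj_mu_ms = draw("toj_mu_ms"),
      toj_sigma_ms = draw("toj_sigma_ms"),
      bias_response = sample(0:1, 1)
    ), class = "subject_profile")
  })
}

#' Simulate a behavioral SJ/TOJ session
#'
#' Generates a per-level binomial response table for every subject and both
#' tasks. SJ responses always follow the subject's Gaussian SJ model. TOJ
#' responses follow the cumulative-Gaussian TOJ model for able subjects;
#' "random" responders answer video-first with probability 0.5 at every
#' level, and "biased" responders give `bias_response` on every trial.
#'
#' @param profiles list of `subject_profile` objects ([make_cohort()]).
#' @param coa_levels_ms numeric vector of signed COA levels (ms); default the
#'   11-level pre-scan grid from -333 to +333 ms in 66.7-ms steps.
#' @param n_trials_per_level trials per COA level per task (default 10).
#' @param seed integer seed.
#' @return data frame (ResponseTable) with columns `subject_id`, `task`,
#'   `coa_ms`, `n_trials`, `n_target`; `n_target` counts "synchronous"
#'   responses for SJ and "video first" responses for TOJ.
#' @export
simulate_behavioral_session <- function(profiles,
                                        coa_levels_ms = seq(-333, 333, length.out = 11),
                                        n_trials_per_level = 10L,
                                        seed = 1L) {
  if (length(coa_levels_ms) == 0) stop("coa_levels_ms is empty", call. = FALSE)
  if (n_trials_per_level < 1) stop("n_trials_per_level must be >= 1", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  rows <- lapply(profiles, function(pr) {
    p_sj <- sj_model(coa_levels_ms, pr$sj_mu_ms, pr$sj_sigma_ms, pr$sj_amplitude)
    p_toj <- switch(pr$responder_mode,
      able = toj_model(coa_levels_ms, pr$toj_mu_ms, pr$toj_sigma_ms),
      random = rep(0.5, length(coa_levels_ms)),
      biased = rep(as.numeric(pr$bias_response), length(coa_levels_ms)))
    data.frame(
      subject_id = pr$subject_id,
      task = rep(c("SJ", "TOJ"), each = length(coa_levels_ms)),
      coa_ms = rep(coa_levels_ms, 2),
      n_trials = n_trials_per_level,
      n_target = c(stats::rbinom(length(p_sj), n_trials_per_level, p_sj),
                   stats::rbinom(length(p_toj), n_trials_per_level, p_toj)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
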