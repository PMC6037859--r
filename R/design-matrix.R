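# Two-timescale design matrices and design optimization.
#
# Regressor layout (18 columns per session): SJ_sustained, TOJ_sustained,
# eight transient task-by-condition columns, an instruction boxcar, six
# zero-valued motion placeholders, and the constant. Sustained effects are
# 25-s boxcars, transient effects unit-mass impulses at stimulus onsets;
# both are convolved with the canonical double-gamma HRF at a fine microtime
# grid before sampling at the scanner TR.

#' Canonical double-gamma hemodynamic response function
#'
#' The conventional canonical HRF: a positive gamma density peaking near 5 s
#' minus an undershoot gamma peaking near 15 s with peak:undershoot ratio 6,
#' evaluated over 32 s and normalized to peak 1.
#'
#' @param dt_s sampling step in seconds, `0 < dt_s <= 1`.
#' @param length_s kernel support in seconds (default 32).
#' @param peak_delay,undershoot_delay gamma delays (s); defaults 6 and 16.
#' @param peak_disp,undershoot_disp gamma dispersions (s); defaults 1 and 1.
#' @param p_u_ratio peak to undershoot amplitude ratio; default 6.
#' @return numeric vector of kernel values at `seq(0, length_s, by = dt_s)`.
#' @export
canonical_hrf <- function(dt_s, length_s = 32, peak_delay = 6,
                          undershoot_delay = 16, peak_disp = 1,
                          undershoot_disp = 1, p_u_ratio = 6) {
  if (!is.finite(dt_s) || dt_s <= 0 || dt_s > 1)
    stop("dt_s must satisfy 0 < dt_s <= 1", call. = FALSE)
  t <- seq(0, length_s, by = dt_s)
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                  scale = undershoot_disp) / p_u_ratio
  h / max(h)
}

# discrete approximation to continuous convolution, truncated to length(x)
convolve_hrf <- function(x, h, dt) {
  n <- length(x)
  y <- stats::convolve(x, rev(h), type = "open")[seq_len(n)]
  y * dt
}

#' Build the 18-column two-timescale design matrix for a run
#'
#' Sustained regressors are HRF-convolved 25-s boxcars covering each task's
#' stimulation blocks; transient regressors are HRF-convolved unit-mass
#' impulses at the stimulus onsets of each task-by-condition cell (an
#' isolated event's column is the HRF shifted to its onset). Nuisance
#' columns: an instruction boxcar, six zero motion placeholders (kept so the
#' column count and indices match a realignment-corrected session), and the
#' constant.
#'
#' @param sequence a `run_sequence` ([build_run_sequence()]).
#' @param tr_s repetition time in seconds (default 2).
#' @param hrf_dt_s microtime resolution for convolution (default 0.1).
#' @param hrf optional kernel sampled at `hrf_dt_s`; default
#'   `canonical_hrf(hrf_dt_s)`.
#' @return `design_matrix`: a time x 18 numeric matrix with column names,
#'   attributes `tr_s`, `hrf_dt_s`, `labels_of_interest` (the 10 sustained +
#'   transient names) and `duration_s`.
#' @export
build_design_matrix <- function(sequence, tr_s = 2, hrf_dt_s = 0.1,
                                hrf = canonical_hrf(hrf_dt_s)) {
  if (nrow(sequence) == 0) stop("empty run sequence", call. = FALSE)
  if (tr_s <= 0) stop("tr_s must be positive", call. = FALSE)
  dur <- attr(sequence, "duration_s")
  if (is.null(dur)) dur <- max(sequence$onset_s + sequence$duration_s)
  n_micro <- ceiling(dur / hrf_dt_s)
  n_scan <- ceiling(dur / tr_s)
  micro_idx <- function(t) pmin(n_micro, floor(t / hrf_dt_s) + 1L)

  boxcar <- function(rows) {
    x <- numeric(n_micro)
    for (i in rows) {
      a <- micro_idx(sequence$onset_s[i])
      b <- micro_idx(sequence$onset_s[i] + sequence$duration_s[i] - hrf_dt_s)
      x[a:b] <- 1
    }
    x
  }
  impulses <- function(rows) {
    x <- numeric(n_micro)
    # unit-mass sticks: height 1/dt so the convolved column is the HRF itself
    x[micro_idx(sequence$onset_s[rows])] <- 1 / hrf_dt_s
    x
  }

  tasks <- c("SJ", "TOJ")
  conds <- coa_conditions()
  cols <- list()
  for (task in tasks) {
    rows <- which(sequence$kind %in% c("stimulus", "intra_block_fixation") &
                    sequence$task == task)
    # a stimulation block spans from its first stimulus for 25 s
    first <- if (length(rows)) rows[c(TRUE, diff(rows) > 1)] else integer(0)
    x <- numeric(n_micro)
    for (i in first) {
      a <- micro_idx(sequence$onset_s[i])
      b <- micro_idx(sequence$onset_s[i] + 25 - hrf_dt_s)
      x[a:b] <- 1
    }
    cols[[paste0(task, "_sustained")]] <- convolve_hrf(x, hrf, hrf_dt_s)
  }
  for (task in tasks) {
    for (cond in conds) {
      rows <- which(sequence$kind == "stimulus" & sequence$task == task &
                      sequence$coa_condition == cond)
      x <- if (length(rows)) impulses(rows) else numeric(n_micro)
      cols[[paste(task, cond, sep = "_")]] <- convolve_hrf(x, hrf, hrf_dt_s)
    }
  }
  cols[["instruction"]] <-
    convolve_hrf(boxcar(which(sequence$kind == "instruction")), hrf, hrf_dt_s)

  scan_idx <- micro_idx((seq_len(n_scan) - 1) * tr_s)
  X <- vapply(cols, function(x) x[scan_idx], numeric(n_scan))
  X <- cbind(X, matrix(0, n_scan, 6,
                       dimnames = list(NULL, paste0("motion", 1:6))),
             constant = 1)
  structure(X, class = c("design_matrix", class(X)),
            tr_s = tr_s, hrf_dt_s = hrf_dt_s, duration_s = dur,
            labels_of_interest = c(paste0(tasks, "_sustained"),
                                   as.vector(outer(tasks, conds, paste, sep = "_"))))
}

#' Estimation efficiency of a design
#'
#' Mean over contrasts of `1 / (c' (X'X)^-1 c)`: the inverse of the (unit
#' noise) estimator variance of each contrast of the GLM coefficients.
#' Zero columns are not tolerated; the matrix restricted to the columns the
#' contrasts touch (plus any non-zero nuisance columns supplied) must be of
#' full column rank.
#'
#' @param X numeric matrix (time x regressors), e.g. a `design_matrix`
#'   subset to its non-zero columns.
#' @param contrasts list of numeric weight vectors of length `ncol(X)`.
#' @return positive scalar efficiency.
#' @export
design_efficiency <- function(X, contrasts) {
  X <- unclass(X)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dep <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("design is rank deficient; dependent columns: ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  xtx_inv <- chol2inv(qr.R(qrx))
  effs <- vapply(contrasts, function(cvec) {
    if (length(cvec) != ncol(X))
      stop("contrast length must equal ncol(X)", call. = FALSE)
    1 / drop(t(cvec) %*% xtx_inv %*% cvec)
  }, numeric(1))
  mean(effs)
}

#' Mean sustained-transient regressor correlation
#'
#' For each of the 8 transient task-by-condition regressors, the absolute
#' Pearson correlation with the sustained regressor of the same task is
#' computed on the unfiltered TR-sampled columns; the mean of the 8 values
#' is returned. Low values mean the mixed design can separate block-level
#' from event-level BOLD responses.
#'
#' @param X a `design_matrix` (needs the labeled sustained and transient
#'   columns).
#' @return scalar in `[0, 1]`.
#' @export
sustained_transient_correlation <- function(X) {
  tasks <- c("SJ", "TOJ")
  pairs <- expand.grid(task = tasks, cond = coa_conditions(),
                       stringsAsFactors = FALSE)
  rs <- mapply(function(task, cond) {
    s <- X[, paste0(task, "_sustained")]
    t_ <- X[, paste(task, cond, sep = "_")]
    if (stats::sd(s) < 1e-12 || stats::sd(t_) < 1e-12)
      stop("constant regressor column: correlation undefined", call. = FALSE)
    abs(stats::cor(s, t_))
  }, pairs$task, pairs$cond)
  mean(rs)
}

#' Optimize a run sequence over random candidates
#'
#' Generates `n_candidates` independently randomized run sequences (block
#' composition, block order, within-block order, fixation jitter), builds
#' each design matrix, and scores each candidate by estimation efficiency
#' ([design_efficiency()] over the 10 contrasts of interest) and by the mean
#' sustained-transient correlation ([sustained_transient_correlation()]).
#' The two scores are standardized across candidates and combined as
#' `z(efficiency) - z(correlation)`; the argmax is selected, balancing
#' estimability of both timescales against their collinearity.
#'
#' @param n_candidates number of random candidates (1000 reproduces the
#'   published procedure).
#' @param master_seed integer; all candidate seeds derive from it.
#' @param tr_s repetition time (s).
#' @param hrf_dt_s microtime resolution (s).
#' @param contrasts optional list of weight vectors over the columns used in
#'   scoring (10 of interest + instruction + constant); default the 10 unit
#'   contrasts of interest.
#' @return list with `sequence` (the selected `run_sequence`), `design`
#'   (its design matrix), `score` (row of the score table) and `scores`
#'   (data frame: candidate, seed, efficiency, mean_st_corr, combined).
#' @export
optimize_design <- function(n_candidates = 1000L, master_seed = 1L,
                            tr_s = 2, hrf_dt_s = 0.1, contrasts = NULL) {
  if (n_candidates < 1) stop("n_candidates must be >= 1", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(master_seed)
  seeds <- matrix(sample.int(.Machine$integer.max, 3 * n_candidates),
                  ncol = 3)

  hrf <- canonical_hrf(hrf_dt_s)
  labels <- NULL
  eff <- eff_tr <- eff_su <- corr <- numeric(n_candidates)
  build_candidate <- function(i) {
    comp_sj <- assign_block_composition(seeds[i, 1])
    comp_toj <- assign_block_composition(seeds[i, 2])
    seq_i <- build_run_sequence(comp_sj, comp_toj, seed = seeds[i, 3])
    X <- build_design_matrix(seq_i, tr_s = tr_s, hrf_dt_s = hrf_dt_s, hrf = hrf)
    list(sequence = seq_i, design = X)
  }
  for (i in seq_len(n_candidates)) {
    cand <- build_candidate(i)
    X <- cand$design
    if (is.null(labels)) {
      labels <- attr(X, "labels_of_interest")
      score_cols <- c(labels, "instruction", "constant")
      unit_contrasts <- lapply(seq_along(labels), function(j) {
        w <- numeric(length(score_cols)); w[j] <- 1; w
      })
      if (is.null(contrasts)) contrasts <- unit_contrasts
    }
    Xs <- X[, score_cols, drop = FALSE]
    eff[i] <- design_efficiency(Xs, contrasts)
    # diagnostic decomposition over the 10 unit contrasts of interest
    eff_su[i] <- design_efficiency(Xs, unit_contrasts[1:2])
    eff_tr[i] <- design_efficiency(Xs, unit_contrasts[3:10])
    corr[i] <- sustained_transient_correlation(X)
  }

  z <- function(x) if (length(x) < 2 || stats::sd(x) < 1e-12)
    rep(0, length(x)) else (x - mean(x)) / stats::sd(x)
  combined <- z(eff) - z(corr)
  best <- which.max(combined)
  scores <- data.frame(candidate = seq_len(n_candidates),
                       candidate_seed = seeds[, 3],
                       efficiency = eff,
                       efficiency_sustained = eff_su,
                       efficiency_transient = eff_tr,
                       mean_st_corr = corr,
                       combined = combined)
  sel <- build_candidate(best)
  list(sequence = sel$sequence, design = sel$design,
       score = scores[best, ], scores = scores)
}
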