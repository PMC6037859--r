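# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# memoize expensive objects across test files
fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# a standard run sequence + design at TR = 2 s
std_run <- function() fixture("std_run", function() {
  sq <- build_run_sequence(assign_block_composition(101),
                           assign_block_composition(102), seed = 103)
  list(sequence = sq, design = build_design_matrix(sq))
})

# the full-scale 1000-candidate optimization (shared by the design
# trade-off property and the acceptance suite; ~3 min, computed once)
full_optimization <- function() fixture("full_opt", function()
  optimize_design(n_candidates = 1000L, master_seed = 1L))

# hand-built microtime convolution: independent oracle for design columns
hand_convolve_column <- function(onsets, durations, heights, hrf, dt,
                                 n_micro, scan_idx) {
  x <- numeric(n_micro)
  for (i in seq_along(onsets)) {
    a <- floor(onsets[i] / dt) + 1
    b <- if (durations[i] > 0) floor((onsets[i] + durations[i] - dt) / dt) + 1 else a
    x[a:b] <- x[a:b] + heights[i]
  }
  y <- numeric(n_micro)
  for (m in seq_len(n_micro)) {
    kmax <- min(m, length(hrf))
    y[m] <- sum(x[m - seq_len(kmax) + 1] * hrf[seq_len(kmax)]) * dt
  }
  y[scan_idx]
}

# brute-force grid-search oracle for the TOJ cumulative-Gaussian fit
grid_fit_toj <- function(tab, mu_grid = seq(-333, 333, by = 1),
                         sigma_grid = seq(20, 500, by = 2)) {
  p_obs <- tab$n_target / tab$n_trials
  best <- c(mu = NA, sigma = NA, sse = Inf)
  for (sg in sigma_grid) {
    z <- outer(tab$coa_ms, mu_grid, `-`) / sg
    sse <- colSums((p_obs - stats::pnorm(z))^2)
    j <- which.min(sse)
    if (sse[j] < best["sse"]) best <- c(mu = mu_grid[j], sigma = sg, sse = sse[j])
  }
  best
}

# F values per term from stats::aov with Error() strata (independent oracle)
aov_oracle <- function(df, formula, error_formula) {
  fit <- stats::aov(stats::as.formula(paste(
    "y ~", formula, "+ Error(", error_formula, ")")), data = df)
  s <- summary(fit)
  out <- list()
  for (stratum in s) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    for (i in seq_along(terms)) {
      if (terms[i] == "Residuals") next
      out[[terms[i]]] <- tab[i, "F value"]
    }
  }
  out
}
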