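# Mixed block/event-related run structure
#
# One run: 32 stimulation blocks (16 SJ + 16 TOJ, order randomized), a 4-s
# task instruction before every block, and a 16-s fixation block after every
# two stimulation blocks. A stimulation block lasts 25 s and holds 9 events:
# 5 stimuli of 3 s separated by 4 fixations whose durations are a random
# permutation of {1,2,3,4} s.

#' COA condition labels used throughout the package
#'
#' `A333` = audio leading by 333 ms, `SYNC0` = physically synchronous,
#' `PSS` = the subject's frame-quantized point of subjective simultaneity,
#' `V333` = video leading by 333 ms.
#' @export
coa_conditions <- function() c("A333", "SYNC0", "PSS", "V333")

#' Per-task block composition of COA conditions
#'
#' Assigns how often each of the 4 COA conditions appears in each of the 16
#' same-task stimulation blocks of a run. To decorrelate the transient
#' (stimulus) regressors from the sustained (block) regressor, each condition
#' appears 0 times in 4 blocks, once in 6 blocks, twice in 4 blocks and 3
#' times in 2 blocks -- 20 presentations per condition per task per run --
#' while every block still holds exactly 5 stimuli. The assignment is found
#' by randomized depth-first backtracking and is deterministic given `seed`.
#'
#' @param seed integer seed.
#' @param max_nodes search-node budget per restart (the constraint system is
#'   satisfiable; restarts are a safety valve against unlucky orderings).
#' @return 16 x 4 integer matrix (blocks x conditions), column names
#'   [coa_conditions()]; rows sum to 5, each column is a permutation of
#'   `{0,0,0,0,1,1,1,1,1,1,2,2,2,2,3,3}`.
#' @export
assign_block_composition <- function(seed = 1L, max_nodes = 200000L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  # candidate rows: counts 0..3 per condition summing to 5
  cand <- as.matrix(expand.grid(0:3, 0:3, 0:3, 0:3))
  cand <- cand[rowSums(cand) == 5, , drop = FALSE]
  target <- c(`0` = 4L, `1` = 6L, `2` = 4L, `3` = 2L)

  for (restart in 1:50) {
    # avail[v+1, j]: how many blocks may still receive count v of condition j
    avail <- matrix(rep(target, 4), nrow = 4,
                    dimnames = list(names(target), NULL))
    rows <- matrix(NA_integer_, 16, 4)
    nodes <- 0L
    ok <- local({
      dfs <- function(r) {
        nodes <<- nodes + 1L
        if (nodes > max_nodes) return(FALSE)
        if (r > 16) return(TRUE)
        feasible <- which(apply(cand, 1, function(row)
          all(avail[cbind(row + 1L, 1:4)] > 0L)))
        for (i in feasible[sample.int(length(feasible))]) {
          row <- cand[i, ]
          idx <- cbind(row + 1L, 1:4)
          avail[idx] <<- avail[idx] - 1L
          # prune: each remaining row must still be able to reach sum 5
          proceed <- r == 16L || {
            maxrow <- sum(apply(avail, 2, function(a) max(which(a > 0L)) - 1L))
            minrow <- sum(apply(avail, 2, function(a) min(which(a > 0L)) - 1L))
            maxrow >= 5 && minrow <= 5
          }
          if (proceed) {
            rows[r, ] <<- row
            if (dfs(r + 1L)) return(TRUE)
          }
          avail[idx] <<- avail[idx] + 1L
        }
        FALSE
      }
      dfs(1L)
    })
    if (ok) {
      dimnames(rows) <- list(NULL, coa_conditions())
      return(rows)
    }
  }
  stop("internal error: block composition search exhausted its restart budget",
       call. = FALSE)
}

#' Build one randomized run sequence
#'
#' Assembles the full event list of a single fMRI run from per-task block
#' compositions: randomized task order over the 32 stimulation blocks,
#' randomized stimulus order and fixation-duration permutation within each
#' block, 4-s instructions before each block, and a 16-s fixation block after
#' every two stimulation blocks.
#'
#' @param composition_sj,composition_toj 16 x 4 matrices from
#'   [assign_block_composition()].
#' @param seed integer seed.
#' @param instruction_s instruction event duration (s).
#' @return object of class `run_sequence`: a data frame of events with
#'   columns `onset_s`, `duration_s`, `kind` (`stimulus`,
#'   `intra_block_fixation`, `fixation_block`, `instruction`), `task`
#'   (`SJ`/`TOJ`/`none`) and `coa_condition` (condition label or `none`),
#'   plus attributes `n_stim_blocks`, `duration_s` and `seed`.
#' @export
build_run_sequence <- function(composition_sj, composition_toj, seed = 1L,
                               instruction_s = 4) {
  for (comp in list(composition_sj, composition_toj)) {
    if (!is.matrix(comp) || !all(dim(comp) == c(16, 4)) ||
        any(rowSums(comp) != 5) || any(colSums(comp) != 20))
      stop("invalid block composition (need 16x4 counts, rows sum 5, columns sum 20)",
           call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  task_order <- sample(rep(c("SJ", "TOJ"), 16))
  comp <- list(SJ = composition_sj, TOJ = composition_toj)
  next_row <- c(SJ = 0L, TOJ = 0L)
  conds <- coa_conditions()

  ev <- list()
  t0 <- 0
  add <- function(duration, kind, task = "none", cond = "none") {
    ev[[length(ev) + 1L]] <<- data.frame(
      onset_s = t0, duration_s = duration, kind = kind, task = task,
      coa_condition = cond, stringsAsFactors = FALSE)
    t0 <<- t0 + duration
  }

  for (b in seq_along(task_order)) {
    task <- task_order[b]
    next_row[task] <- next_row[task] + 1L
    counts <- comp[[task]][next_row[task], ]
    stimuli <- sample(rep(conds, counts))
    fix <- sample(1:4)
    add(instruction_s, "instruction", task)
    for (k in 1:5) {
      add(3, "stimulus", task, stimuli[k])
      if (k < 5) add(fix[k], "intra_block_fixation", task)
    }
    if (b %% 2 == 0) add(16, "fixation_block")
  }

  events <- do.call(rbind, ev)
  structure(events, class = c("run_sequence", "data.frame"),
            n_stim_blocks = 32L, duration_s = t0, seed = seed)
}

#' @export
print.run_sequence <- function(x, ...) {
  cat(sprintf("run_sequence: %d events, %d stimulation blocks, %.0f s\n",
              nrow(x), attr(x, "n_stim_blocks"), attr(x, "duration_s")))
  invisible(x)
}

#' Read and write event tables
#'
#' BIDS-style tab-separated events files with header
#' `onset\tduration\ttrial_type\ttask\tcoa_condition`. The round trip through
#' [write_events()] and [read_events()] is lossless for onsets, durations and
#' labels.
#'
#' @param sequence a `run_sequence` or any data frame with columns `onset_s`,
#'   `duration_s`, `kind`, `task`, `coa_condition`.
#' @param path file path of the TSV.
#' @return `read_events()` returns a `run_sequence` (duration 0 and zero rows
#'   for an empty file); `write_events()` returns `path` invisibly.
#' @export
write_events <- function(sequence, path) {
  out <- data.frame(
    onset = sequence$onset_s,
    duration = sequence$duration_s,
    trial_type = sequence$kind,
    task = sequence$task,
    coa_condition = sequence$coa_condition
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("onset", "duration", "trial_type", "task", "coa_condition")
  if (!all(needed %in% names(raw)))
    stop("malformed events file ", path, ": header must contain ",
         paste(needed, collapse = ", "), call. = FALSE)
  if (nrow(raw) > 0) {
    bad <- which(!is.finite(raw$onset) | !is.finite(raw$duration) |
                   raw$duration < 0 | raw$onset < 0)
    if (length(bad) > 0)
      stop("malformed events file ", path, ": invalid onset/duration at line ",
           bad[1] + 1L, call. = FALSE)
  }
  events <- data.frame(
    onset_s = as.numeric(raw$onset),
    duration_s = as.numeric(raw$duration),
    kind = as.character(raw$trial_type),
    task = as.character(raw$task),
    coa_condition = as.character(raw$coa_condition),
    stringsAsFactors = FALSE
  )
  dur <- if (nrow(events) == 0) 0 else max(events$onset_s + events$duration_s)
  structure(events, class = c("run_sequence", "data.frame"),
            n_stim_blocks = sum(events$kind == "instruction"),
            duration_s = dur, seed = NA_integer_)
}
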