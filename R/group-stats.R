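# Voxelwise balanced repeated-measures ANOVA (classical partitioned error
# terms) and permutation-based cluster-extent FDR inference.
#
# Error-term scheme: effects composed only of between-subject factors are
# tested against the subjects-within-group mean square; any effect whose
# within-subject part is W (non-empty) is tested against the W x
# subject-within-group interaction mean square.

#' Assemble a group design of per-subject condition images
#'
#' @param data numeric matrix, one row per (subject, within-cell)
#'   observation, one column per voxel (a single column covers ordinary
#'   behavioral tables).
#' @param subject factor/vector of subject ids, one per row.
#' @param within data frame of within-subject factors (e.g. `task`,
#'   `coa_condition`), one row per observation.
#' @param group optional between-subjects factor (constant within subject).
#' @param volume_shape optional 3D shape for reshaping voxel maps.
#' @return object of class `group_design`.
#' @export
group_design <- function(data, subject, within, group = NULL,
                         volume_shape = NULL) {
  data <- as.matrix(data)
  subject <- factor(subject)
  if (nrow(data) != length(subject))
    stop("data rows and subject labels disagree", call. = FALSE)
  within <- as.data.frame(lapply(within, factor))
  if (nrow(within) != nrow(data))
    stop("within-factor rows and data rows disagree", call. = FALSE)
  if (!is.null(group)) {
    group <- factor(group)
    if (length(group) != nrow(data))
      stop("group must be given per row", call. = FALSE)
    gt <- table(unique(data.frame(subject, group))$subject)
    if (any(gt != 1))
      stop("group labels must be constant within subject", call. = FALSE)
  }
  # balance: every subject must hold every within-cell exactly once
  cell <- interaction(within, drop = FALSE)
  tab <- table(subject, cell)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)[1, ]
    stop("unbalanced design: subject ", rownames(tab)[bad[1]],
         " has ", tab[bad[1], bad[2]], " observations in cell ",
         colnames(tab)[bad[2]], call. = FALSE)
  }
  if (!is.null(group)) {
    per_group <- table(tapply(as.character(group), subject, `[`, 1))
    if (any(per_group < 2))
      stop("need >= 2 subjects per group", call. = FALSE)
  }
  structure(list(data = data, subject = subject, within = within,
                 group = group, volume_shape = volume_shape),
            class = "group_design")
}

# crude SS ("R(S)"): sum over cells of (cell total)^2 / cell size, per voxel
crude_ss <- function(Y, cells) {
  if (is.null(cells)) {
    tot <- colSums(Y)
    return(tot^2 / nrow(Y))
  }
  cells <- droplevels(as.factor(cells))
  totals <- rowsum(Y, cells)               # cell x voxel
  n_c <- as.vector(table(cells))
  colSums(totals^2 / n_c)
}

parse_term <- function(design, term) {
  fac <- strsplit(term, ":", fixed = TRUE)[[1]]
  wnames <- names(design$within)
  has_group <- "group" %in% fac
  wfac <- setdiff(fac, "group")
  if (!all(wfac %in% wnames))
    stop("unknown factors in term '", term, "'; available: group, ",
         paste(wnames, collapse = ", "), call. = FALSE)
  if (has_group && is.null(design$group))
    stop("term involves group but the design has no group factor",
         call. = FALSE)
  list(factors = fac, within = wfac, has_group = has_group)
}

term_cells <- function(design, fac) {
  if (length(fac) == 0) return(NULL)
  cols <- lapply(fac, function(f)
    if (f == "group") design$group else design$within[[f]])
  interaction(cols, drop = FALSE)
}

# signed inclusion-exclusion of crude SS over all subsets of `fac`
effect_ss <- function(design, fac, Y) {
  ss <- 0
  n <- length(fac)
  for (k in 0:n) {
    subs <- if (k == 0) list(character(0)) else
      utils::combn(fac, k, simplify = FALSE)
    for (s in subs)
      ss <- ss + (-1)^(n - k) * crude_ss(Y, term_cells(design, s))
  }
  ss
}

# SS of the W x subject(-within-group) stratum (W possibly empty)
error_ss <- function(design, wfac, Y) {
  gfac <- if (is.null(design$group)) character(0) else "group"
  ss <- 0
  n <- length(wfac)
  for (k in 0:n) {
    subs <- if (k == 0) list(character(0)) else
      utils::combn(wfac, k, simplify = FALSE)
    for (s in subs) {
      cells_subj <- interaction(c(list(design$subject),
                                  lapply(s, function(f) design$within[[f]])),
                                drop = FALSE)
      r_subj <- crude_ss(Y, cells_subj)
      r_g <- crude_ss(Y, term_cells(design, c(gfac, s)))
      ss <- ss + (-1)^(n - k) * (r_subj - r_g)
    }
  }
  ss
}

#' Voxelwise repeated-measures ANOVA F map
#'
#' Classical balanced mixed-design ANOVA computed by sums-of-squares
#' inclusion-exclusion, vectorized over voxels. Between-only terms are
#' tested against subjects-within-group; terms with within-subject part `W`
#' against the `W x subject-within-group` stratum. Voxels whose error sum of
#' squares is (numerically) zero get `F = 0` so degenerate voxels can never
#' be suprathreshold.
#'
#' @param design `group_design`.
#' @param term character like `"task"`, `"group"`, `"task:coa_condition"`,
#'   `"group:task"`.
#' @return list with `F` (vector over voxels, or 3D array when the design
#'   has a `volume_shape`), `df1`, `df2`, `term`.
#' @export
mixed_anova <- function(design, term) {
  tm <- parse_term(design, term)
  Y <- design$data
  n_subj <- nlevels(design$subject)
  n_groups <- if (is.null(design$group)) 1 else
    nlevels(droplevels(design$group))

  lev <- function(f) {
    if (f == "group") nlevels(droplevels(design$group))
    else nlevels(droplevels(design$within[[f]]))
  }
  df1 <- prod(vapply(tm$factors, function(f) lev(f) - 1, numeric(1)))
  df_err <- (n_subj - n_groups) *
    prod(vapply(tm$within, function(f) lev(f) - 1, numeric(1)))
  if (df1 < 1 || df_err < 1)
    stop("degenerate degrees of freedom for term '", term, "'", call. = FALSE)

  ss_t <- effect_ss(design, tm$factors, Y)
  ss_e <- error_ss(design, tm$within, Y)
  ss_t <- pmax(ss_t, 0)
  ss_e <- pmax(ss_e, 0)
  Fv <- ifelse(ss_e < 1e-10, 0, (ss_t / df1) / (ss_e / df_err))
  if (!is.null(design$volume_shape)) Fv <- array(Fv, design$volume_shape)
  list(F = Fv, df1 = df1, df2 = df_err, term = term)
}

# offsets of the 18-neighborhood (6 faces + 12 edges)
connectivity_offsets <- function(connectivity = 18) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = d == 1,
                 "18" = d >= 1 & d <= 2,
                 "26" = d >= 1,
                 stop("connectivity must be 6, 18 or 26", call. = FALSE))
  as.matrix(g[keep, ])
}

#' Form suprathreshold clusters from a statistic map
#'
#' Thresholds an F (or t) map at the upper `voxel_p` quantile of its null
#' distribution and labels connected components under the chosen
#' connectivity (default 18 = faces + edges). Each cluster's peak is its
#' maximum-statistic voxel, ties broken by lowest linear index.
#'
#' @param stat_map 3D array of statistics.
#' @param df1,df2 F degrees of freedom (use `df1 = NULL, df2 = df` with
#'   `stat = "t"`).
#' @param voxel_p cluster-forming voxel-level p (default 1e-4).
#' @param connectivity 6, 18 or 26.
#' @param stat `"F"` or `"t"` (t is thresholded on its upper tail).
#' @return object of class `cluster_result`: list with `label_map` (3D
#'   integer array), `clusters` (data frame: cluster_id, peak_x/y/z,
#'   n_voxels, peak_stat, peak_equiv_z), `threshold`, `voxel_p`,
#'   `connectivity`, `df1`, `df2`, `stat`.
#' @export
form_clusters <- function(stat_map, df1, df2, voxel_p = 1e-4,
                          connectivity = 18, stat = c("F", "t")) {
  stat <- match.arg(stat)
  if (!is.array(stat_map) || length(dim(stat_map)) != 3)
    stop("stat_map must be a 3D array", call. = FALSE)
  if (length(stat_map) == 0) stop("empty statistic map", call. = FALSE)
  thr <- if (stat == "F") stats::qf(voxel_p, df1, df2, lower.tail = FALSE)
         else stats::qt(voxel_p, df2, lower.tail = FALSE)
  upper_p <- function(x) {
    if (stat == "F") stats::pf(x, df1, df2, lower.tail = FALSE)
    else stats::pt(x, df2, lower.tail = FALSE)
  }

  dims <- dim(stat_map)
  supra <- which(stat_map > thr)
  label_map <- array(0L, dims)
  clusters <- list()
  if (length(supra) > 0) {
    offs <- connectivity_offsets(connectivity)
    coord <- arrayInd(supra, dims)
    rownames(coord) <- NULL
    key <- function(m) (m[, 3] - 1) * dims[1] * dims[2] +
      (m[, 2] - 1) * dims[1] + m[, 1]
    in_set <- new.env(hash = TRUE)
    for (i in seq_along(supra)) assign(as.character(supra[i]), i, envir = in_set)
    visited <- logical(length(supra))
    cid <- 0L
    for (i in seq_along(supra)) {
      if (visited[i]) next
      cid <- cid + 1L
      queue <- i
      visited[i] <- TRUE
      members <- integer(0)
      while (length(queue)) {
        j <- queue[[1]]; queue <- queue[-1]
        members <- c(members, j)
        nb <- sweep(offs, 2, coord[j, ], `+`)
        ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
        nb <- nb[ok, , drop = FALSE]
        if (nrow(nb)) {
          lin <- key(nb)
          for (l in lin) {
            idx <- mget(as.character(l), envir = in_set, ifnotfound = list(NULL))[[1]]
            if (!is.null(idx) && !visited[idx]) {
              visited[idx] <- TRUE
              queue <- c(queue, idx)
            }
          }
        }
      }
      vox <- supra[members]
      label_map[vox] <- cid
      peak_lin <- vox[order(-stat_map[vox], vox)][1]
      pc <- arrayInd(peak_lin, dims)
      peak_stat <- stat_map[peak_lin]
      clusters[[cid]] <- data.frame(
        cluster_id = cid,
        peak_x = pc[1], peak_y = pc[2], peak_z = pc[3],
        n_voxels = length(vox),
        peak_stat = peak_stat,
        peak_equiv_z = stats::qnorm(upper_p(peak_stat), lower.tail = FALSE))
    }
  }
  clusters <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(cluster_id = integer(0), peak_x = integer(0),
               peak_y = integer(0), peak_z = integer(0),
               n_voxels = integer(0), peak_stat = numeric(0),
               peak_equiv_z = numeric(0))
  structure(list(label_map = label_map, clusters = clusters, threshold = thr,
                 voxel_p = voxel_p, connectivity = connectivity,
                 df1 = df1, df2 = df2, stat = stat),
            class = "cluster_result")
}

# permute a group design appropriately for a term (see D-scheme in vignette)
permute_design <- function(design, tm) {
  d <- design
  if (length(tm$within) == 0) {
    # between-only term: permute group labels over subjects
    subj <- levels(design$subject)
    g_of <- tapply(as.character(design$group), design$subject, `[`, 1)
    newg <- sample(g_of[subj])
    d$group <- factor(newg[match(as.character(design$subject), subj)],
                      levels = levels(design$group))
    return(d)
  }
  # within part: relabel the term's within-cells per subject, consistently
  # across the remaining within factors
  wf <- tm$within
  cell <- interaction(design$within[wf], drop = FALSE)
  levs <- levels(cell)
  new_within <- design$within
  for (s in levels(design$subject)) {
    rows <- which(design$subject == s)
    perm <- sample(levs)
    names(perm) <- levs
    relabeled <- perm[as.character(cell[rows])]
    parts <- strsplit(relabeled, ".", fixed = TRUE)
    for (k in seq_along(wf)) {
      new_within[[wf[k]]][rows] <-
        factor(vapply(parts, `[`, "", k), levels = levels(design$within[[wf[k]]]))
    }
  }
  d$within <- new_within
  d
}

#' Permutation cluster-extent FDR inference
#'
#' Computes the observed F map and clusters for a term, then builds a null
#' distribution of the maximum cluster extent by re-computing the map under
#' term-appropriate relabelings: group labels are permuted over subjects for
#' between-only terms; within-subject cell labels are permuted per subject
#' for terms with a within part. Each observed cluster receives
#' `p = (1 + #{null max extent >= observed}) / (n_perm + 1)`;
#' Benjamini-Hochberg across the observed clusters controls the FDR at `q`.
#'
#' @param design `group_design`.
#' @param term ANOVA term, as [mixed_anova()].
#' @param n_perm number of permutations (>= 100).
#' @param q FDR level over clusters (default 0.05).
#' @param voxel_p cluster-forming threshold (default 1e-4).
#' @param connectivity 6, 18 or 26 (default 18).
#' @param seed integer seed; identical seeds give identical p-values.
#' @return `cluster_result` whose `clusters` table gains `p_cluster`,
#'   `q_fdr` and `significant` columns, plus `n_perm` and `null_max_extent`.
#' @export
permutation_cluster_fdr <- function(design, term, n_perm = 1000L, q = 0.05,
                                    voxel_p = 1e-4, connectivity = 18,
                                    seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  tm <- parse_term(design, term)
  if (length(tm$within) == 0 && is.null(design$group))
    stop("no valid exchangeability scheme for term '", term, "'",
         call. = FALSE)
  if (is.null(design$volume_shape))
    stop("permutation cluster inference needs a volume_shape", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  obs <- mixed_anova(design, term)
  res <- form_clusters(obs$F, obs$df1, obs$df2, voxel_p = voxel_p,
                       connectivity = connectivity)

  null_max <- vapply(seq_len(n_perm), function(b) {
    pd <- permute_design(design, tm)
    f <- mixed_anova(pd, term)
    lab <- form_clusters(f$F, f$df1, f$df2, voxel_p = voxel_p,
                         connectivity = connectivity)
    if (nrow(lab$clusters) == 0) 0L else max(lab$clusters$n_voxels)
  }, integer(1))

  cl <- res$clusters
  if (nrow(cl) > 0) {
    cl$p_cluster <- vapply(cl$n_voxels, function(ext)
      (1 + sum(null_max >= ext)) / (n_perm + 1), numeric(1))
    cl$q_fdr <- stats::p.adjust(cl$p_cluster, method = "BH")
    cl$significant <- cl$q_fdr < q
  } else {
    cl$p_cluster <- numeric(0)
    cl$q_fdr <- numeric(0)
    cl$significant <- logical(0)
  }
  res$clusters <- cl
  res$n_perm <- n_perm
  res$null_max_extent <- null_max
  res$term <- term
  res
}

#' Cluster report table
#'
#' One row per cluster with peak coordinate, extent, peak statistic,
#' equivalent z (probit of the statistic's upper-tail p) and significance,
#' sorted by peak statistic descending.
#'
#' @param result `cluster_result`.
#' @return data frame.
#' @export
cluster_table <- function(result) {
  cl <- result$clusters
  cols <- c("cluster_id", "peak_x", "peak_y", "peak_z", "n_voxels",
            "peak_stat", "peak_equiv_z",
            intersect(c("p_cluster", "q_fdr", "significant"), names(cl)))
  cl <- cl[order(-cl$peak_stat), cols, drop = FALSE]
  rownames(cl) <- NULL
  cl
}
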