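test_that("mixed ANOVA F matches the aov sums-of-squares oracle", {
  set.seed(11)
  # (a) one between + two within factors, 8 subjects
  ns <- 8
  d <- expand.grid(task = c("SJ", "TOJ"), coa = c("c1", "c2", "c3"),
                   subj = sprintf("s%02d", 1:ns), stringsAsFactors = FALSE)
  d$grp <- ifelse(d$subj <= "s04", "able", "unable")
  d$y <- rnorm(nrow(d)) + (d$task == "TOJ") * 0.8 +
    (d$grp == "able" & d$coa == "c2") * 0.6
  gd <- group_design(matrix(d$y, ncol = 1), d$subj,
                     data.frame(task = d$task, coa = d$coa), group = d$grp)
  df <- data.frame(y = d$y, subj = factor(d$subj), grp = factor(d$grp),
                   task = factor(d$task), coa = factor(d$coa))
  oracle <- aov_oracle(df, "grp*task*coa", "subj/(task*coa)")
  map <- c(group = "grp", task = "task", coa = "coa",
           `group:task` = "grp:task", `task:coa` = "task:coa",
           `group:coa` = "grp:coa", `group:task:coa` = "grp:task:coa")
  for (term in names(map))
    expect_equal(mixed_anova(gd, term)$F, oracle[[map[[term]]]],
                 tolerance = 1e-8, label = term)

  # (b) purely within-subject 2x3 design, 6 subjects, no group factor
  d2 <- expand.grid(task = c("SJ", "TOJ"), coa = c("c1", "c2", "c3"),
                    subj = sprintf("p%d", 1:6), stringsAsFactors = FALSE)
  d2$y <- rnorm(nrow(d2)) + (d2$coa == "c3") * 0.5
  gd2 <- group_design(matrix(d2$y, ncol = 1), d2$subj,
                      data.frame(task = d2$task, coa = d2$coa))
  df2 <- data.frame(y = d2$y, subj = factor(d2$subj),
                    task = factor(d2$task), coa = factor(d2$coa))
  oracle2 <- aov_oracle(df2, "task*coa", "subj/(task*coa)")
  for (term in c("task", "coa", "task:coa"))
    expect_equal(mixed_anova(gd2, term)$F, oracle2[[term]],
                 tolerance = 1e-8, label = term)

  # (c) between-only contrast on a single within cell pair (2x2), 12 subjects
  d3 <- expand.grid(task = c("SJ", "TOJ"), subj = sprintf("q%02d", 1:12),
                    stringsAsFactors = FALSE)
  d3$grp <- ifelse(d3$subj <= "q06", "g1", "g2")
  d3$y <- rnorm(nrow(d3)) + (d3$grp == "g1") * 0.4
  gd3 <- group_design(matrix(d3$y, ncol = 1), d3$subj,
                      data.frame(task = d3$task), group = d3$grp)
  df3 <- data.frame(y = d3$y, subj = factor(d3$subj), grp = factor(d3$grp),
                    task = factor(d3$task))
  oracle3 <- aov_oracle(df3, "grp*task", "subj/task")
  for (term in c("group", "task", "group:task"))
    expect_equal(mixed_anova(gd3, term)$F,
                 oracle3[[sub("group", "grp", term)]],
                 tolerance = 1e-8, label = term)
})

test_that("ANOVA degenerate and error paths behave as designed", {
  d <- expand.grid(task = c("SJ", "TOJ"), subj = sprintf("s%d", 1:4),
                   stringsAsFactors = FALSE)
  # identical data everywhere: zero-variance voxel gets F = 0
  gd <- group_design(matrix(1, nrow(d), 1), d$subj,
                     data.frame(task = d$task))
  expect_equal(mixed_anova(gd, "task")$F, 0)
  expect_error(mixed_anova(gd, "group"), "group")
  expect_error(mixed_anova(gd, "nope"), "unknown factors")
  # missing cell is named
  expect_error(group_design(matrix(1, 7, 1), d$subj[-1],
                            data.frame(task = d$task[-1])),
               "unbalanced.*s1", ignore.case = TRUE)
})

test_that("an injected effect maximizes the F map inside its region", {
  set.seed(21)
  shape <- c(8, 8, 8)
  n_vox <- prod(shape)
  n <- 10
  d <- expand.grid(task = c("SJ", "TOJ"), subj = sprintf("s%02d", 1:n),
                   stringsAsFactors = FALSE)
  Y <- matrix(rnorm(nrow(d) * n_vox), nrow(d))
  region <- array(FALSE, shape); region[3:4, 3:4, 3:4] <- TRUE
  Y[d$task == "TOJ", as.vector(region)] <-
    Y[d$task == "TOJ", as.vector(region)] + 3
  gd <- group_design(Y, d$subj, data.frame(task = d$task),
                     volume_shape = shape)
  res <- mixed_anova(gd, "task")
  expect_true(region[which.max(res$F)])
})

test_that("voxelwise F exceeds its nominal threshold at the stated rate", {
  # global-null calibration, aggregated over > 1e6 voxel draws
  set.seed(31)
  shape <- c(12, 12, 12)
  n_vox <- prod(shape)
  n <- 12
  d <- expand.grid(task = c("SJ", "TOJ"), subj = sprintf("s%02d", 1:n),
                   stringsAsFactors = FALSE)
  n_sims <- 600
  thr <- qf(1e-4, 1, n - 1, lower.tail = FALSE)
  hits <- 0
  for (s in 1:n_sims) {
    Y <- matrix(rnorm(nrow(d) * n_vox), nrow(d))
    gd <- group_design(Y, d$subj, data.frame(task = d$task))
    hits <- hits + sum(mixed_anova(gd, "task")$F > thr)
  }
  rate <- hits / (n_sims * n_vox)
  # 1e-4 +/- 4 binomial standard errors
  se <- sqrt(1e-4 * (1 - 1e-4) / (n_sims * n_vox))
  expect_true(abs(rate - 1e-4) < 4 * se + 1e-12)
})

test_that("cluster formation respects 18-connectivity and peak rules", {
  shape <- c(6, 6, 6)
  df1 <- 1; df2 <- 10
  thr <- qf(1e-4, df1, df2, lower.tail = FALSE)
  m <- array(0, shape)
  m[2, 2, 2] <- thr + 5
  r <- form_clusters(m, df1, df2)
  expect_equal(nrow(r$clusters), 1)
  expect_equal(r$clusters$n_voxels, 1)
  expect_equal(unlist(r$clusters[1, c("peak_x", "peak_y", "peak_z")]),
               c(peak_x = 2, peak_y = 2, peak_z = 2))

  # face neighbors merge; edge neighbors merge; corner neighbors do not
  face <- array(0, shape); face[2, 2, 2] <- face[3, 2, 2] <- thr + 1
  expect_equal(nrow(form_clusters(face, df1, df2)$clusters), 1)
  edge <- array(0, shape); edge[2, 2, 2] <- edge[3, 3, 2] <- thr + 1
  expect_equal(nrow(form_clusters(edge, df1, df2)$clusters), 1)
  expect_equal(nrow(form_clusters(edge, df1, df2, connectivity = 6)$clusters), 2)
  corner <- array(0, shape); corner[2, 2, 2] <- corner[3, 3, 3] <- thr + 1
  expect_equal(nrow(form_clusters(corner, df1, df2)$clusters), 2)
  expect_equal(nrow(form_clusters(corner, df1, df2, connectivity = 26)$clusters), 1)

  # peak tie broken by lowest linear index
  tie <- array(0, shape); tie[4, 2, 2] <- tie[5, 2, 2] <- thr + 2
  rt <- form_clusters(tie, df1, df2)
  expect_equal(rt$clusters$peak_x, 4)
  expect_error(form_clusters(array(0, c(0, 0, 0)), df1, df2), "empty")
})

test_that("cluster tables report probit equivalent z and sort by statistic", {
  df1 <- 2; df2 <- 20
  thr <- qf(1e-4, df1, df2, lower.tail = FALSE)
  m <- array(0, c(5, 5, 5))
  m[1, 1, 1] <- thr + 1
  m[4:5, 4, 4] <- c(thr + 10, thr + 3)
  r <- form_clusters(m, df1, df2)
  tab <- cluster_table(r)
  expect_equal(tab$peak_stat, sort(tab$peak_stat, decreasing = TRUE))
  z_oracle <- qnorm(pf(tab$peak_stat, df1, df2, lower.tail = FALSE),
                    lower.tail = FALSE)
  expect_equal(tab$peak_equiv_z, z_oracle)
  # median upper-tail p maps to z = 0
  p_med <- qf(0.5, df1, df2)
  expect_equal(qnorm(pf(p_med, df1, df2, lower.tail = FALSE),
                     lower.tail = FALSE), 0, tolerance = 1e-12)
  empty <- form_clusters(array(0, c(3, 3, 3)), df1, df2)
  expect_equal(nrow(cluster_table(empty)), 0)
})

test_that("permutation cluster FDR is deterministic and respects q", {
  set.seed(41)
  shape <- c(8, 8, 8)
  n <- 10
  d <- expand.grid(task = c("SJ", "TOJ"), subj = sprintf("s%02d", 1:n),
                   stringsAsFactors = FALSE)
  Y <- matrix(rnorm(nrow(d) * prod(shape)), nrow(d))
  region <- array(FALSE, shape); region[3:4, 3:4, 3:4] <- TRUE
  Y[d$task == "TOJ", as.vector(region)] <-
    Y[d$task == "TOJ", as.vector(region)] + 4
  gd <- group_design(Y, d$subj, data.frame(task = d$task),
                     volume_shape = shape)
  r1 <- permutation_cluster_fdr(gd, "task", n_perm = 150, seed = 7)
  r2 <- permutation_cluster_fdr(gd, "task", n_perm = 150, seed = 7)
  expect_equal(r1$clusters$p_cluster, r2$clusters$p_cluster)
  expect_gte(nrow(r1$clusters), 1)
  expect_true(any(r1$clusters$significant))
  # the detected cluster is the injected one
  top <- r1$clusters[which.max(r1$clusters$n_voxels), ]
  expect_true(region[top$peak_x, top$peak_y, top$peak_z])
  # q = 0: nothing can ever be significant
  r0 <- permutation_cluster_fdr(gd, "task", n_perm = 150, q = 0, seed = 7)
  expect_false(any(r0$clusters$significant))
  expect_error(permutation_cluster_fdr(gd, "task", n_perm = 10, seed = 1),
               "n_perm")
})
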