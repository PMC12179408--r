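test_that("percent change reproduces its closed forms", {
  expect_equal(round(percent_change(3169.79, 3838.96), 2), 21.11)
  expect_equal(round(percent_change(5.16, 4.6), 2), -10.85)
  for (x in c(0.3, 5.16, 3169.79)) expect_equal(percent_change(x, x), 0)
  expect_error(percent_change(0, 5), "non-zero")
})

test_that("group summaries follow the qualified-only gate", {
  d <- data.frame(group = c("a", "a", "a", "b"),
                  area_um2 = c(10, 20, 100, 7),
                  qualified = c(1L, 1L, 0L, 1L))
  s <- summarize_groups(d, features = "area_um2")
  a <- s[s$group == "a", ]
  expect_equal(a$n_cells, 2)
  expect_equal(a$mean, 15)
  expect_equal(a$sem, a$sd / sqrt(a$n_cells))
  b <- s[s$group == "b", ]
  expect_equal(b$n_cells, 1)
  expect_equal(b$mean, 7)
  expect_equal(b$sd, 0)
  all_rows <- summarize_groups(d, features = "area_um2",
                               qualified_only = FALSE)
  expect_equal(all_rows[all_rows$group == "a", "n_cells"], 3)
  expect_error(summarize_groups(d, features = "nope"), "unknown feature")
})

test_that("percent-change tables are anchored at control = 0", {
  s <- data.frame(group = c("control", "ang"), feature = "width_um",
                  mean = c(28.78, 31.44))
  p <- percent_change_table(s)
  expect_equal(p$percent_change_vs_control[p$group == "control"], 0)
  expect_equal(round(p$percent_change_vs_control[p$group == "ang"], 2),
               9.24)
  expect_error(percent_change_table(s, control = "ctrl"), "not present")
})

test_that("identical groups are not called different", {
  v <- c(1.5, 2.5, 3.5, 4.5, 5.5)
  d <- data.frame(group = rep(c("control", "b"), each = 5),
                  area_um2 = c(v, v))
  cmp <- compare_groups(d, "area_um2", test = "kruskal_dunn")
  expect_gt(cmp$p_value[cmp$group == "(omnibus)"], 0.9)
  expect_equal(cmp$percent_change_vs_control[cmp$group == "b"], 0)
})

test_that("groups shifted by three SD are detected", {
  x <- cardiomorph:::with_seed(17, rnorm(200, 100, 10))
  y <- cardiomorph:::with_seed(18, rnorm(200, 130, 10))
  d <- data.frame(group = rep(c("control", "b"), each = 200),
                  area_um2 = c(x, y))
  for (t in c("kruskal_dunn", "anova_tukey", "mann_whitney")) {
    cmp <- compare_groups(d, "area_um2", test = t)
    expect_lt(cmp$p_value[cmp$group == "b"], 0.05)
  }
})

test_that("the Kruskal-Wallis statistic matches a hand-ranked oracle", {
  d <- data.frame(group = rep(c("control", "b"), each = 3),
                  area_um2 = c(1.2, 3.4, 5.6, 2.1, 7.8, 9.9))
  # ranks: control {1, 3, 4}, b {2, 5, 6}; no ties
  rbar <- c(mean(c(1, 3, 4)), mean(c(2, 5, 6)))
  H <- 12 / (6 * 7) * sum(3 * (rbar - 3.5)^2)
  kw <- kruskal.test(area_um2 ~ group, data = d)
  expect_equal(as.numeric(kw$statistic), H, tolerance = 1e-12)
  cmp <- compare_groups(d, "area_um2", test = "kruskal_dunn")
  expect_equal(nrow(cmp), 2)
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
})

test_that("four-group comparisons report every treated group vs control", {
  d <- data.frame(
    group = rep(c("control", "ang", "iso", "old"), each = 30),
    area_um2 = cardiomorph:::with_seed(19,
      c(rnorm(30, 100, 10), rnorm(30, 121, 12),
        rnorm(30, 113, 11), rnorm(30, 127, 13))))
  for (t in c("kruskal_dunn", "anova_tukey")) {
    cmp <- compare_groups(d, "area_um2", test = t)
    expect_setequal(setdiff(cmp$group, "(omnibus)"),
                    c("ang", "iso", "old"))
    expect_true(all(cmp$percent_change_vs_control[cmp$group != "(omnibus)"] > 0))
  }
})

test_that("fisher's exact path needs a 2x2 count matrix", {
  tab <- matrix(c(40, 10, 12, 38), 2)
  cmp <- compare_groups(tab, feature = "qualified",
                        test = "fisher_exact")
  expect_equal(cmp$p_value, fisher.test(tab)$p.value)
  expect_error(compare_groups(data.frame(group = "a", x = 1),
                              test = "fisher_exact"),
               "2x2")
})

test_that("rank tests refuse groups of one", {
  d <- data.frame(group = c("control", "control", "b"),
                  area_um2 = c(1, 2, 3))
  expect_error(compare_groups(d, "area_um2"), "fewer than 2")
})

test_that("the synthetic pipeline produces a complete output set", {
  out <- file.path(withr::local_tempdir(), "run")
  cfg <- pipeline_config(out_dir = out, seed = 3, n_cells = 25,
                         qc_train_n = 120, n_volume_stacks = 5,
                         n_sarcomere_cells = 3)
  res <- run_pipeline(cfg)
  for (f in c("cells.csv", "summary.csv", "summary_raw.csv",
              "percent_changes.csv", "comparisons.csv", "volumes.csv",
              "sarcomere.csv", "qc_model.json", "run_log.json"))
    expect_true(file.exists(file.path(out, f)), label = f)
  pct <- res$percent_changes
  ctrl <- pct[pct$group == "control", "percent_change_vs_control"]
  expect_true(all(ctrl == 0))
  cells <- read.csv(file.path(out, "cells.csv"))
  expect_true(all(cells$qualified %in% c(0L, 1L)))
  expect_setequal(unique(cells$group), c("control", "ang", "iso", "old"))
  # summaries were computed from qualified rows only
  s <- res$summaries
  n_sum <- sum(s$n_cells[s$feature == "surface_um2"])
  expect_equal(n_sum, sum(cells$qualified == 1))
})
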