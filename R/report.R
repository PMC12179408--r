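#' Reference group-level morphometrics
#'
#' Published-style reference table of group means and standard deviations
#' for the four study conditions: cell surface, width, length, aspect
#' ratio, 3D volume and sarcomere length. These are the worked-example
#' inputs for [percent_change()] and the generator defaults.
#'
#' @return data frame with columns `feature`, `group`, `mean`, `sd`.
#' @export
group_reference_table <- function() {
  f <- function(feature, control, ang, iso, old)
    data.frame(feature = feature,
               group = c("control", "ang", "iso", "old"),
               mean = c(control[1], ang[1], iso[1], old[1]),
               sd = c(control[2], ang[2], iso[2], old[2]))
  rbind(
    f("surface_um2", c(3169.79, 1244.09), c(3838.96, 1484.63),
      c(3592.17, 1428.37), c(4033.71, 1734.51)),
    f("width_um", c(28.78, 7.93), c(31.44, 8.29),
      c(31.15, 8.96), c(34.48, 10.44)),
    f("length_um", c(139.42, 33.06), c(154.09, 37.52),
      c(146.12, 34.29), c(147.24, 36.20)),
    f("aspect_ratio", c(5.16, 1.71), c(5.18, 1.67),
      c(5.03, 1.72), c(4.60, 1.63)),
    f("volume_um3", c(35368.88, 19283.40), c(56919.39, 28243.97),
      c(48895.67, 21910.03), c(51928.17, 29308.98)),
    f("sarcomere_um", c(1.801, 0.034), c(1.829, 0.045),
      c(1.797, 0.083), c(1.794, 0.031)))
}

#' Percent change of a group mean versus control
#'
#' `100 (group - control) / control`, the convention used for all
#' hypertrophy deltas; reported to two decimals in table outputs.
#'
#' @param control_mean control-group mean (non-zero).
#' @param group_mean treated-group mean.
#' @return percent change.
#' @examples
#' percent_change(3169.79, 3838.96)   # 21.11
#' @export
percent_change <- function(control_mean, group_mean) {
  if (any(control_mean == 0)) stop("control mean must be non-zero")
  100 * (group_mean - control_mean) / control_mean
}

#' Summarize measurements by experimental group
#'
#' Per group and feature: number of cells, mean, SD and SEM. By default
#' only rows that passed qualification (`qualified == 1`) enter the
#' summary - the single gate between measurement and statistics.
#'
#' @param measurements data frame with a `group` column, feature columns
#'   and (if `qualified_only`) a `qualified` column.
#' @param features feature columns to summarize.
#' @param qualified_only restrict to qualified rows.
#' @return data frame `group`, `feature`, `n_cells`, `mean`, `sd`, `sem`.
#' @export
summarize_groups <- function(measurements,
                             features = c("area_um2", "width_um",
                                          "length_um", "aspect_ratio"),
                             qualified_only = TRUE) {
  if (!"group" %in% names(measurements)) stop("group column required")
  missing <- setdiff(features, names(measurements))
  if (length(missing) > 0)
    stop("unknown feature(s): ", paste(missing, collapse = ", "))
  d <- measurements
  if (qualified_only) {
    if (!"qualified" %in% names(d)) stop("qualified column required")
    d <- d[!is.na(d$qualified) & d$qualified == 1, , drop = FALSE]
  }
  out <- list()
  for (g in unique(d$group)) for (feat in features) {
    v <- d[d$group == g, feat]
    v <- v[!is.na(v)]
    if (length(v) == 0) next
    out[[length(out) + 1]] <- data.frame(
      group = g, feature = feat, n_cells = length(v),
      mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
      sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0)
  }
  do.call(rbind, out)
}

#' Percent changes of every group versus control
#'
#' @param summaries output of [summarize_groups()] (or any data frame
#'   with `group`, `feature`, `mean`).
#' @param control name of the control group.
#' @return data frame `feature`, `group`, `percent_change_vs_control`.
#' @export
percent_change_table <- function(summaries, control = "control") {
  if (!control %in% summaries$group)
    stop("control group '", control, "' not present")
  out <- list()
  for (feat in unique(summaries$feature)) {
    sub <- summaries[summaries$feature == feat, ]
    cm <- sub$mean[sub$group == control]
    if (length(cm) != 1) next
    out[[length(out) + 1]] <- data.frame(
      feature = feat, group = sub$group,
      percent_change_vs_control = percent_change(cm, sub$mean))
  }
  ans <- do.call(rbind, out)
  rownames(ans) <- NULL
  ans
}

# Dunn's post hoc test versus control after Kruskal-Wallis: pairwise z
# statistics on mean ranks with tie correction, Bonferroni-adjusted over
# the treated-vs-control comparisons.
dunn_vs_control <- function(values, groups, control) {
  n <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  glev <- unique(groups)
  rbar <- tapply(r, groups, mean)
  nn <- tapply(r, groups, length)
  others <- setdiff(glev, control)
  p <- vapply(others, function(g) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / nn[[control]] + 1 / nn[[g]]))
    z <- (rbar[[g]] - rbar[[control]]) / se
    min(1, 2 * pnorm(-abs(z)) * length(others))
  }, 0)
  data.frame(group = others, p_value = as.numeric(p))
}

#' Compare groups on one feature
#'
#' Runs the requested published test and reports the omnibus p-value plus
#' pairwise p-values of every treated group versus control: Kruskal-Wallis
#' with Dunn's post hoc (default), one-way ANOVA with Tukey HSD,
#' Mann-Whitney U (two groups), or Fisher's exact test on a 2x2 count
#' matrix passed directly as `measurements`.
#'
#' @param measurements data frame with `group` and the feature column
#'   (qualified rows only are used when a `qualified` column is present),
#'   or a 2x2 matrix for `fisher_exact`.
#' @param feature feature column name.
#' @param test test to run.
#' @param control control group name.
#' @return data frame `feature`, `group`, `test_name`, `p_value` (the
#'   omnibus row has group `"(omnibus)"`), with `percent_change_vs_control`
#'   where defined.
#' @export
compare_groups <- function(measurements, feature = "area_um2",
                           test = c("kruskal_dunn", "anova_tukey",
                                    "mann_whitney", "fisher_exact"),
                           control = "control") {
  test <- match.arg(test)
  if (test == "fisher_exact") {
    if (!is.matrix(measurements) || !all(dim(measurements) == 2))
      stop("fisher_exact requires a 2x2 count matrix")
    p <- fisher.test(measurements)$p.value
    return(data.frame(feature = feature, group = "(omnibus)",
                      test_name = "fisher_exact", p_value = p))
  }
  d <- measurements
  if ("qualified" %in% names(d))
    d <- d[!is.na(d$qualified) & d$qualified == 1, , drop = FALSE]
  if (!feature %in% names(d)) stop("feature '", feature, "' missing")
  d <- d[!is.na(d[[feature]]), , drop = FALSE]
  glev <- unique(d$group)
  if (length(glev) < 2) stop("need at least two groups")
  small <- names(which(table(d$group) < 2))
  if (test != "fisher_exact" && length(small) > 0)
    stop("group(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "))
  v <- d[[feature]]; g <- factor(d$group)
  cm <- mean(v[g == control])
  gm <- tapply(v, g, mean)
  pc <- percent_change(cm, gm)
  if (test == "kruskal_dunn") {
    omni <- kruskal.test(v, g)$p.value
    pair <- dunn_vs_control(v, as.character(g), control)
    name <- "kruskal_dunn"
  } else if (test == "anova_tukey") {
    fit <- aov(v ~ g)
    omni <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$g
    want <- c(paste0(setdiff(levels(g), control), "-", control),
              paste0(control, "-", setdiff(levels(g), control)))
    tk <- tk[rownames(tk) %in% want, , drop = FALSE]
    pair <- data.frame(
      group = sub(paste0("-?", control, "-?"), "", rownames(tk)),
      p_value = tk[, "p adj"])
    name <- "anova_tukey"
  } else {
    if (length(glev) != 2) stop("mann_whitney requires exactly 2 groups")
    other <- setdiff(glev, control)
    omni <- wilcox.test(v[g == control], v[g == other])$p.value
    pair <- data.frame(group = other, p_value = omni)
    name <- "mann_whitney"
  }
  out <- rbind(
    data.frame(feature = feature, group = "(omnibus)", test_name = name,
               p_value = omni, percent_change_vs_control = NA_real_),
    data.frame(feature = feature, group = pair$group, test_name = name,
               p_value = pair$p_value,
               percent_change_vs_control =
                 as.numeric(pc[pair$group])))
  rownames(out) <- NULL
  out
}

# Pack specs into as many fields as needed; returns a list of placed
# spec lists, one per field.
place_specs_multi <- function(specs, field_size_px, pixel_size_um,
                              margin_um = 8, seed = 1L) {
  fields <- list()
  todo <- specs
  guard <- 0L
  while (length(todo) > 0) {
    guard <- guard + 1L
    if (guard > 10000L) stop("placement did not terminate")
    # binary search the largest prefix that fits
    lo <- 1L; hi <- length(todo); fit <- 0L
    while (lo <= hi) {
      mid <- (lo + hi) %/% 2L
      ok <- tryCatch({
        place_specs(todo[seq_len(mid)], field_size_px, pixel_size_um,
                    margin_um, seed + length(fields))
        TRUE
      }, error = function(e) FALSE)
      if (ok) { fit <- mid; lo <- mid + 1L } else hi <- mid - 1L
    }
    if (fit == 0L)
      stop("field too small for cell ", length(fields) + 1L)
    fields[[length(fields) + 1L]] <-
      place_specs(todo[seq_len(fit)], field_size_px, pixel_size_um,
                  margin_um, seed + length(fields))
    todo <- todo[-seq_len(fit)]
  }
  fields
}

#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed master seed; all stage seeds derive from it.
#' @param groups named list: per group, `params` (group name or parameter
#'   list) and `n_cells`.
#' @param n_cells cells per group when `groups` is left at default.
#' @param ... overrides for any other field.
#' @return config list for [run_pipeline()].
#' @export
pipeline_config <- function(out_dir, seed = 1L, groups = NULL,
                            n_cells = 150, ...) {
  if (is.null(groups))
    groups <- list(control = list(params = "control", n_cells = n_cells),
                   ang = list(params = "ang", n_cells = n_cells),
                   iso = list(params = "iso", n_cells = n_cells),
                   old = list(params = "old", n_cells = n_cells))
  cfg <- list(
    mode = "synth", out_dir = out_dir, seed = as.integer(seed),
    groups = groups,
    pixel_size_um = 0.65, field_size_px = c(1024, 1024),
    noise_sd = 0.05,
    class_proportions = list(intact_rod = 0.93, touching_pair = 0.04,
                             rounded = 0.02, fragment = 0.01),
    min_area_um2 = 500, max_area_um2 = 15000,
    qc_train_n = 600, qc_test_fraction = 0.2,
    n_volume_stacks = 30, n_sarcomere_cells = 20,
    control = "control", test = "kruskal_dunn")
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full synthetic morphometry pipeline
#'
#' End-to-end workflow on generated data: train the qualification model on
#' a labeled synthetic benchmark, then per group render fields, segment,
#' measure, classify, and finally summarize qualified cells, compute
#' percent changes versus control, run group comparisons, measure 3D
#' volumes on rendered stacks and sarcomere periods on qualified rods.
#' All outputs are CSV/JSON; a rerun with the same config is byte
#' identical.
#'
#' @param config list from [pipeline_config()], or a path to a JSON file
#'   with the same fields.
#' @return invisibly, a list with all result tables; files are written to
#'   `config$out_dir` (cells.csv, summary.csv, summary_raw.csv,
#'   comparisons.csv, volumes.csv, sarcomere.csv, qc_model.json,
#'   run_log.json).
#' @export
run_pipeline <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- config
  # named list in configs (JSON objects keep names; arrays do not)
  cfg$class_proportions <- unlist(cfg$class_proportions)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  bench <- stage("train-qc",
                 synth_benchmark(cfg$qc_train_n, seed = cfg$seed + 101,
                                 pixel_size_um = cfg$pixel_size_um,
                                 noise_sd = cfg$noise_sd))
  model <- stage("train-qc",
                 train_qc(bench, cfg$qc_test_fraction,
                          seed = cfg$seed + 102))
  save_qc_model(model, file.path(cfg$out_dir, "qc_model.json"))

  cells <- list(); sarc <- list(); vols <- list()
  gnames <- names(cfg$groups)
  for (gi in seq_along(gnames)) {
    g <- gnames[gi]
    gcfg <- cfg$groups[[g]]
    gseed <- cfg$seed + 1000 * gi
    specs <- stage(paste0("synth:", g),
                   sample_population(gcfg$n_cells, gcfg$params,
                                     cfg$class_proportions,
                                     seed = gseed,
                                     orientation_range = c(-15, 15)))
    fields <- stage(paste0("synth:", g),
                    place_specs_multi(specs, cfg$field_size_px,
                                      cfg$pixel_size_um, seed = gseed + 1))
    meas_g <- list()
    for (fi in seq_along(fields)) {
      scene <- stage(paste0("render:", g),
                     render_scene(cfg$field_size_px, cfg$pixel_size_um,
                                  fields[[fi]], cfg$noise_sd,
                                  seed = gseed + 10 + fi))
      ps <- stage(paste0("segment:", g),
                  segment(scene$image, min_area_um2 = cfg$min_area_um2,
                          max_area_um2 = cfg$max_area_um2))
      if (ps$n_particles == 0) next
      m <- stage(paste0("measure:", g), measure_all(ps))
      m <- stage(paste0("classify:", g), classify(model, m))
      m$group <- g; m$field <- fi
      meas_g[[fi]] <- m
      # sarcomere periods for the first qualified rods of the group
      have <- sum(vapply(sarc, function(s)
        sum(s$group == g), 0L))
      if (have < cfg$n_sarcomere_cells) {
        ids <- m$particle_id[m$qualified == 1 &
                               m$length_um >= 30][
          seq_len(min(cfg$n_sarcomere_cells - have,
                      sum(m$qualified == 1 & m$length_um >= 30)))]
        if (length(ids) > 0) {
          s <- stage(paste0("sarcomere:", g),
                     measure_sarcomeres(scene$image, ps, ids))
          s$group <- g; s$field <- fi
          sarc[[length(sarc) + 1]] <- s
        }
      }
    }
    cells[[g]] <- do.call(rbind, meas_g)
    # 3D volumes on stacks rendered from the group's rod specs
    rods <- Filter(function(s) s$cell_class == "intact_rod", specs)
    nvol <- min(cfg$n_volume_stacks, length(rods))
    vrows <- lapply(seq_len(nvol), function(i) {
      st <- render_stack(rods[[i]], seed = gseed + 500 + i)
      v <- measure_volumes(st$stack, st$voxel_um)
      if (nrow(v) == 0) return(NULL)
      v <- v[which.max(v$voxel_count), , drop = FALSE]
      v$group <- g
      v$truth_volume_um3 <- st$truth$volume_um3
      v
    })
    vols[[g]] <- do.call(rbind, vrows)
  }

  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  # 2D surface is the area column; expose it under both names
  cells$surface_um2 <- cells$area_um2
  summaries <- stage("summarize",
                     summarize_groups(cells,
                                      features = c("surface_um2",
                                                   "width_um", "length_um",
                                                   "aspect_ratio")))
  volumes <- do.call(rbind, vols)
  rownames(volumes) <- NULL
  volumes$qualified <- 1L
  vol_sum <- summarize_groups(volumes, features = "volume_um3")
  sarc <- do.call(rbind, sarc)
  rownames(sarc) <- NULL
  sarc$qualified <- as.integer(sarc$valid)
  sarc_sum <- summarize_groups(sarc, features = "period_um")
  all_sum <- rbind(summaries, vol_sum, sarc_sum)
  pct <- percent_change_table(all_sum, cfg$control)
  comps <- do.call(rbind, lapply(c("surface_um2", "width_um", "length_um",
                                   "aspect_ratio"), function(feat)
    stage("compare", compare_groups(cells, feat, cfg$test, cfg$control))))

  w <- function(d, f) write.csv(d, file.path(cfg$out_dir, f),
                                row.names = FALSE)
  w(cells, "cells.csv")
  rounded <- all_sum
  rounded$mean <- round(rounded$mean, 2)
  rounded$sd <- round(rounded$sd, 2)
  rounded$sem <- round(rounded$sem, 2)
  w(rounded, "summary.csv")
  w(all_sum, "summary_raw.csv")
  pct_out <- pct
  pct_out$percent_change_vs_control <-
    round(pct_out$percent_change_vs_control, 2)
  w(pct_out, "percent_changes.csv")
  w(comps, "comparisons.csv")
  w(volumes, "volumes.csv")
  w(sarc, "sarcomere.csv")
  jsonlite::write_json(
    list(seed = cfg$seed, pixel_size_um = cfg$pixel_size_um,
         field_size_px = cfg$field_size_px, noise_sd = cfg$noise_sd,
         groups = lapply(cfg$groups, function(g)
           list(params = if (is.character(g$params)) g$params else "custom",
                n_cells = g$n_cells)),
         class_proportions = as.list(cfg$class_proportions),
         min_area_um2 = cfg$min_area_um2,
         max_area_um2 = cfg$max_area_um2,
         qc_metrics = model$training_meta$metrics),
    file.path(cfg$out_dir, "run_log.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  invisible(list(cells = cells, summaries = all_sum,
                 percent_changes = pct, comparisons = comps,
                 volumes = volumes, sarcomere = sarc, qc_model = model))
}
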