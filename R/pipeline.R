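# Pipeline orchestration: simulate -> analyze -> score -> report, each
# stage also usable on its own. Every run records its seed and a config
# hash; a failed stage halts downstream stages.

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = 10,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

log_line <- function(stage, ...) {
  sprintf("[%s] %s", stage, paste0(...))
}

#' Simulate assay datasets for a configured genotype panel
#'
#' Builds one genotype profile per configured strain, simulates every
#' assay at the configured sample sizes, writes tidy per-assay CSVs and a
#' run manifest (files, seed, config hash) to `out_dir`.
#'
#' @param config A [default_config()]-style list.
#' @param out_dir Output directory.
#' @return Invisibly, a list with `datasets`, `files`, `manifest`.
#' @export
cmd_simulate <- function(config = default_config(), out_dir) {
  validate_config(config)
  profiles <- config_profiles(config)
  datasets <- simulate_experiment(profiles, n = config$sample_sizes,
                                  seed = config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (assay in names(datasets)) {
    f <- file.path(out_dir, paste0(assay, ".csv"))
    write_assay_csv(datasets[[assay]], f)
    files <- c(files, f)
  }
  manifest <- list(seed = config$seed,
                   config_hash = config_hash(config),
                   files = basename(files),
                   rows = lapply(datasets, nrow),
                   genotypes = vapply(profiles, `[[`, character(1), "name"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(datasets = datasets, files = files, manifest = manifest))
}

summarize_groups <- function(dataset, value_column) {
  groups <- group_split_values(dataset, value_column)
  res <- lapply(sort(names(groups)), function(g) {
    v <- groups[[g]]
    n <- length(v)
    m <- mean(v)
    half <- if (n > 1) stats::qt(0.975, n - 1) * stats::sd(v) / sqrt(n)
            else NA_real_
    data.frame(genotype = g, n = n, mean = m,
               ci_lo = m - half, ci_hi = m + half,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Analyze assay datasets
#'
#' Computes per-genotype summaries (mean and 95% CI, as plotted in the
#' assay figures) and the per-assay statistics: brood size and percent
#' lethality vs control (ANOVA + Dunnett), BBPS vs control (ANOVA +
#' Dunnett) plus defect fractions and chi-squared tests at the BBPS
#' threshold, mislocalized-nucleus counts (ANOVA + Tukey), bleb counts
#' (rank test + Benjamini-Hochberg), and fluorescence intensities vs
#' control (Student's t). Assays absent from the input are skipped with a
#' log entry (missing migration data degrade gracefully).
#'
#' @param config A [default_config()]-style list.
#' @param data Either a directory of tidy assay CSVs, a workbook path, or
#'   a named list of [assay_dataset()] objects.
#' @param out_dir Optional output directory for result CSVs.
#' @return A list with `summaries`, `results` (both named by assay),
#'   `defect_fractions`, `datasets` and `log`.
#' @export
cmd_analyze <- function(config = default_config(), data, out_dir = NULL) {
  validate_config(config)
  datasets <- load_any_data(data, config)
  ctrl <- resolve_control(datasets, config$control_genotype)
  logs <- character(0)
  summaries <- list()
  results <- list()
  defect_fractions <- NULL

  if (!is.null(datasets$viability)) {
    via <- datasets$viability
    summaries$brood <- summarize_groups(via, "brood")
    results$brood_dunnett <- anova_dunnett(via, "brood", ctrl,
                                           config$alpha)
    laying <- via[via$brood > 0, , drop = FALSE]
    if (nrow(laying)) {
      laying$lethality_pct <- 100 * laying$unhatched / laying$brood
      cnt <- table(laying$genotype)
      ok <- names(cnt)[cnt >= 2]
      summaries$lethality <- summarize_groups(
        laying[laying$genotype %in% ok, , drop = FALSE], "lethality_pct")
      if (ctrl %in% ok && length(ok) > 1)
        results$lethality_dunnett <- anova_dunnett(
          laying[laying$genotype %in% ok, , drop = FALSE],
          "lethality_pct", ctrl, config$alpha)
    }
    logs <- c(logs, log_line("analyze", "viability: ", nrow(via),
                             " records"))
  }
  if (!is.null(datasets$swimming)) {
    swim <- datasets$swimming
    summaries$bbps <- summarize_groups(swim, "bbps")
    results$bbps_dunnett <- anova_dunnett(swim, "bbps", ctrl, config$alpha)
    genos <- sort(unique(swim$genotype))
    wt <- swim[swim$genotype == ctrl, , drop = FALSE]
    fr <- lapply(genos, function(g) {
      d <- swim[swim$genotype == g, , drop = FALSE]
      data.frame(genotype = g,
                 defect_fraction = defect_fraction(
                   d, threshold = config$bbps_threshold),
                 n = nrow(d), stringsAsFactors = FALSE)
    })
    defect_fractions <- do.call(rbind, fr)
    results$swim_chi_squared <- rbind_stat_results(
      lapply(setdiff(genos, ctrl), function(g)
        swim_defect_test(swim[swim$genotype == g, , drop = FALSE], wt,
                         threshold = config$bbps_threshold,
                         alpha = config$alpha)))
    logs <- c(logs, log_line("analyze", "swimming: ", nrow(swim),
                             " records"))
  }
  if (!is.null(datasets$migration)) {
    mig <- datasets$migration
    summaries$migration <- summarize_groups(mig, "mislocalized")
    results$migration_tukey <- anova_tukey(mig, "mislocalized",
                                           config$alpha)
    logs <- c(logs, log_line("analyze", "migration: ", nrow(mig),
                             " records"))
  } else {
    logs <- c(logs, log_line("analyze",
                             "migration: no data, stage skipped"))
    warning("no migration data; migration results absent", call. = FALSE)
  }
  if (!is.null(datasets$morphology)) {
    mor <- datasets$morphology
    summaries$blebs <- summarize_groups(mor, "blebs")
    results$bleb_bh <- bleb_defect_tests(mor, ctrl, config$fdr)
    logs <- c(logs, log_line("analyze", "morphology: ", nrow(mor),
                             " records"))
  }
  for (nm in grep("^fluorescence", names(datasets), value = TRUE)) {
    flu <- datasets[[nm]]
    summaries[[nm]] <- summarize_groups(flu, "intensity")
    genos <- setdiff(unique(flu$genotype), ctrl)
    if (ctrl %in% flu$genotype && length(genos))
      results[[paste0(nm, "_t")]] <- rbind_stat_results(
        lapply(sort(genos), function(g)
          two_group_t(flu, "intensity", g, ctrl, config$alpha)))
    logs <- c(logs, log_line("analyze", nm, ": ", nrow(flu), " records"))
  }
  if (!is.null(out_dir)) {
    write_outputs(results, NULL, out_dir)
    for (nm in names(summaries))
      utils::write.csv(summaries[[nm]],
                       file.path(out_dir, paste0("summary_", nm, ".csv")),
                       row.names = FALSE)
    if (!is.null(defect_fractions))
      utils::write.csv(defect_fractions,
                       file.path(out_dir, "defect_fractions.csv"),
                       row.names = FALSE)
  }
  list(summaries = summaries, results = results,
       defect_fractions = defect_fractions, datasets = datasets,
       log = logs, control_genotype = ctrl)
}

#' Score variants from assay data
#'
#' Delegates to [score_variants()]; writes the score-table TSV and the
#' JSON evidence bundle when `out_dir` is given.
#'
#' @inheritParams cmd_analyze
#' @return The `variant_scorecards` object, invisibly when writing.
#' @export
cmd_score <- function(config = default_config(), data, out_dir = NULL) {
  validate_config(config)
  datasets <- load_any_data(data, config)
  ctrl <- resolve_control(datasets, config$control_genotype)
  cards <- score_variants(datasets, ctrl, config)
  if (!is.null(out_dir)) {
    write_outputs(list(), cards, out_dir)
    return(invisible(cards))
  }
  cards
}

stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p <= 0.001, "***",
                              ifelse(p <= 0.01, "**",
                                     ifelse(p <= 0.05, "*", "ns"))))
}

#' Render a human-readable pipeline report
#'
#' One markdown report with per-assay group summaries (mean, 95% CI),
#' significance stars at 0.05 / 0.01 / 0.001 (thresholds inclusive), the
#' defect-fraction table, and the score table with `N/A` for missing
#' migration components.
#'
#' @param analyzed Result of [cmd_analyze()].
#' @param scorecards A `variant_scorecards` object (optional).
#' @param path Optional file to write the report to.
#' @return The report as a character vector of lines, invisibly when
#'   writing to a file.
#' @export
cmd_report <- function(analyzed, scorecards = NULL, path = NULL) {
  if (is.null(analyzed$summaries) || !length(analyzed$summaries))
    stop("incomplete run: no summaries to report", call. = FALSE)
  out <- c("# Lamin variant phenotyping report", "")
  for (nm in names(analyzed$summaries)) {
    s <- analyzed$summaries[[nm]]
    out <- c(out, paste0("## Assay summary: ", nm), "",
             "| genotype | n | mean | 95% CI |",
             "|---|---|---|---|",
             sprintf("| %s | %d | %.3f | [%.3f, %.3f] |",
                     s$genotype, s$n, s$mean, s$ci_lo, s$ci_hi), "")
  }
  for (nm in names(analyzed$results)) {
    r <- analyzed$results[[nm]]
    out <- c(out, paste0("## Comparisons: ", nm), "",
             "| comparison | statistic | p (adj) | |",
             "|---|---|---|---|",
             sprintf("| %s | %.4g | %.4g | %s |",
                     r$comparison, r$statistic, r$p_adjusted,
                     stars(r$p_adjusted)), "")
  }
  if (!is.null(analyzed$defect_fractions)) {
    d <- analyzed$defect_fractions
    out <- c(out, "## Swimming defect fractions", "",
             "| genotype | n | fraction at/below threshold |",
             "|---|---|---|",
             sprintf("| %s | %d | %.3f |", d$genotype, d$n,
                     d$defect_fraction), "")
  }
  if (!is.null(scorecards)) {
    sc <- as.data.frame(scorecards)
    migr <- ifelse(is.na(sc$migration), "N/A", as.character(sc$migration))
    out <- c(out, "## Variant score cards", "",
             "| human | worm | viability | swimming | migration | score | class |",
             "|---|---|---|---|---|---|---|",
             sprintf("| %s | %s | %d | %d | %s | %d | %s |",
                     sc$human_label, sc$variant, sc$viability,
                     sc$swimming, migr, sc$total, sc$classification), "")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Run the full pipeline: simulate, analyze, score, report
#'
#' Stages execute in dependency order; a failed stage halts the run. The
#' returned run object records the config, its hash, the seed, per-stage
#' status, output manifest and a structured log (one line per stage with
#' row counts).
#'
#' @param config A [default_config()]-style list.
#' @param out_dir Output directory for all stage outputs.
#' @return A list of class `pipeline_run`.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run <- list(config = config, config_hash = config_hash(config),
              seed = config$seed, stages = list(), log = character(0),
              out_dir = out_dir)
  class(run) <- "pipeline_run"

  sim <- cmd_simulate(config, file.path(out_dir, "data"))
  run$stages$simulate <- "ok"
  run$log <- c(run$log, log_line("simulate", "wrote ",
                                 length(sim$files), " assay files (",
                                 sum(unlist(sim$manifest$rows)),
                                 " rows), seed ", config$seed))

  analyzed <- cmd_analyze(config, sim$datasets,
                          file.path(out_dir, "results"))
  run$stages$analyze <- "ok"
  run$log <- c(run$log, analyzed$log)

  cards <- score_variants(analyzed$datasets, analyzed$control_genotype,
                          config)
  write_outputs(list(), cards, file.path(out_dir, "results"))
  run$stages$score <- "ok"
  run$log <- c(run$log, log_line("score", nrow(cards), " variants scored"))

  report <- cmd_report(analyzed, cards, file.path(out_dir, "report.md"))
  run$stages$report <- "ok"
  run$log <- c(run$log, log_line("report", "report.md written"))

  run$scorecards <- cards
  run$analyzed <- analyzed
  writeLines(run$log, file.path(out_dir, "run.log"))
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> seed", x$seed, "config", substr(x$config_hash, 1, 8),
      "\n  stages:", paste(names(x$stages), unlist(x$stages),
                           sep = ":", collapse = " "), "\n")
  invisible(x)
}

# accept a directory of tidy CSVs, a workbook file, or a dataset list
load_any_data <- function(data, config) {
  if (is.list(data) && !is.data.frame(data)) return(data)
  if (is.character(data) && length(data) == 1L) {
    if (dir.exists(data)) return(read_tidy_assays(data))
    if (file.exists(data))
      return(read_s1_workbook(data, section_map = config$section_map))
  }
  stop("data must be a dataset list, a directory of tidy CSVs, ",
       "or a workbook file", call. = FALSE)
}

# case-insensitive control lookup against the labels present in the data
resolve_control <- function(datasets, control) {
  labels <- unique(unlist(lapply(datasets, function(d) d$genotype)))
  hit <- labels[tolower(labels) == tolower(normalize_genotype(control))]
  if (!length(hit))
    stop("control genotype '", control, "' absent from data", call. = FALSE)
  hit[1]
}
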