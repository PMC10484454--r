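# Tabular IO: tidy per-animal assay CSVs, a sectioned workbook layout
# (one column per genotype, one value per animal per cell, ragged columns
# allowed), and deterministic result/score-card writers.

#' Normalize a genotype label
#'
#' Trims leading/trailing whitespace and collapses internal runs of
#' whitespace; used on every label read from disk so that matching (e.g.
#' of the control genotype) is robust to stray spaces. Case-insensitive
#' matching is applied when locating the control.
#'
#' @param x Character vector of labels.
#' @return Normalized labels.
#' @export
normalize_genotype <- function(x) {
  gsub("\\s+", " ", trimws(as.character(x)))
}

#' Read tidy per-animal assay tables
#'
#' @param paths Either a directory containing `<assay>.csv` files
#'   (`viability.csv`, `swimming.csv`, `migration.csv`, `morphology.csv`,
#'   `fluorescence.csv`), or a named character vector/list of file paths
#'   keyed by assay name.
#' @return A named list of validated [assay_dataset()] objects. Unknown
#'   columns are preserved; genotype labels are whitespace-normalized;
#'   schema violations are reported with the offending column and row.
#' @export
read_tidy_assays <- function(paths) {
  if (length(paths) == 1L && is.null(names(paths)) && dir.exists(paths)) {
    files <- list.files(paths, pattern = "\\.csv$", full.names = TRUE)
    keys <- tools::file_path_sans_ext(basename(files))
    keep <- keys %in% c("viability", "swimming", "migration", "morphology",
                        "fluorescence")
    paths <- stats::setNames(files[keep], keys[keep])
  }
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("paths must be a directory or a named vector keyed by assay",
         call. = FALSE)
  out <- list()
  for (assay in names(paths)) {
    f <- paths[[assay]]
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
    d <- utils::read.csv(f, stringsAsFactors = FALSE)
    if (!"genotype" %in% names(d))
      stop(basename(f), ": missing column 'genotype'", call. = FALSE)
    d$genotype <- normalize_genotype(d$genotype)
    if (!"animal_id" %in% names(d))
      d$animal_id <- stats::ave(seq_len(nrow(d)), d$genotype,
                                FUN = seq_along)
    if (assay == "viability" && !"brood" %in% names(d)) {
      daycols <- grep("^eggs_day", names(d), value = TRUE)
      if (length(daycols))
        d$brood <- as.integer(rowSums(d[daycols]))
    }
    out[[assay]] <- assay_dataset(d, assay = assay)
  }
  out
}

#' Write an assay dataset to CSV
#'
#' @param dataset An [assay_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assay_csv <- function(dataset, path) {
  validate_assay_dataset(dataset)
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

workbook_sections <- c("brood_size", "hatch_pct", "bbps",
                       "mislocalized_nuclei", "nuclear_blebs")

# parse a character grid (rows x cols) of a sectioned workbook into
# named per-genotype numeric columns per section
parse_workbook_grid <- function(grid, section_map = NULL) {
  is_blank <- function(x) is.na(x) | !nzchar(trimws(x))
  sec_rows <- grep("^#\\s*section\\s*:", grid[, 1], ignore.case = TRUE)
  if (!length(sec_rows))
    stop("no section headers found (expected '# section: <name>' rows)",
         call. = FALSE)
  sections <- list()
  bounds <- c(sec_rows, nrow(grid) + 1L)
  for (i in seq_along(sec_rows)) {
    raw_name <- trimws(sub("^#\\s*section\\s*:\\s*", "",
                           grid[sec_rows[i], 1], ignore.case = TRUE))
    name <- if (!is.null(section_map) && raw_name %in% names(section_map))
      section_map[[raw_name]] else raw_name
    known <- c(workbook_sections)
    if (!(name %in% known || grepl("^fluorescence", name)))
      stop("unrecognized section header: '", raw_name, "'", call. = FALSE)
    r0 <- sec_rows[i] + 1L
    r1 <- bounds[i + 1L] - 1L
    if (r1 < r0) stop("section '", raw_name, "' is empty", call. = FALSE)
    hdr <- grid[r0, ]
    gcols <- which(!is_blank(hdr))
    genotypes <- normalize_genotype(hdr[gcols])
    body <- grid[seq(r0 + 1L, r1), gcols, drop = FALSE]
    cols <- list()
    for (j in seq_along(gcols)) {
      vals <- body[, j]
      vals <- vals[!is_blank(vals)]           # trailing blanks dropped
      if (!length(vals))
        stop("section '", raw_name, "': column '", genotypes[j],
             "' is empty", call. = FALSE)
      num <- suppressWarnings(as.numeric(vals))
      if (any(is.na(num)))
        stop("section '", raw_name, "': column '", genotypes[j],
             "' has non-numeric cell '", vals[which(is.na(num))[1]], "'",
             call. = FALSE)
      cols[[genotypes[j]]] <- num
    }
    sections[[name]] <- cols
  }
  sections
}

cols_to_long <- function(cols, value_name) {
  df <- data.frame(
    genotype = rep(names(cols), lengths(cols)),
    animal_id = unlist(lapply(cols, seq_along), use.names = FALSE),
    stringsAsFactors = FALSE)
  df[[value_name]] <- unlist(cols, use.names = FALSE)
  df
}

#' Read a sectioned assay workbook
#'
#' Reads the raw-data workbook layout used for the phenotypic assays: the
#' data are presented in sections, each labeled by a `# section: <name>`
#' row followed by one column per genotype with one value per animal per
#' cell (ragged columns allowed). Recognized sections: `brood_size` (eggs
#' per mother), `hatch_pct` (percent of laid eggs that hatched, one value
#' per laying mother, in the order of the laying mothers of the
#' brood-size section), `bbps` (per-animal swimming rate),
#' `mislocalized_nuclei`, `nuclear_blebs`, and any section starting with
#' `fluorescence` (per-nucleus intensities).
#'
#' Accepts a plain CSV or (with the readxl package installed) an XLSX
#' file with the same cell layout. A `section_map` renames nonstandard
#' section headers to the canonical names.
#'
#' @param path Workbook file (`.csv`, `.xlsx`).
#' @param section_map Optional named character vector mapping the file's
#'   section names to canonical names.
#' @return A named list of [assay_dataset()] objects: `viability`
#'   (brood + hatch sections combined), `swimming`, `migration`,
#'   `morphology`, and one `fluorescence*` dataset per fluorescence
#'   section present.
#' @export
read_s1_workbook <- function(path, section_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX workbooks requires the 'readxl' package",
           call. = FALSE)
    sheet <- readxl::read_excel(path, col_names = FALSE,
                                col_types = "text")
    grid <- as.matrix(sheet)
    grid[is.na(grid)] <- ""
  } else {
    lines <- readLines(path, warn = FALSE)
    cells <- strsplit(lines, ",", fixed = TRUE)
    ncol <- max(lengths(cells))
    grid <- t(vapply(cells, function(r) {
      c(r, rep("", ncol - length(r)))
    }, character(ncol)))
  }
  secs <- parse_workbook_grid(grid, section_map)

  out <- list()
  if (!is.null(secs$brood_size)) {
    broods <- secs$brood_size
    hatch <- secs$hatch_pct
    rows <- lapply(names(broods), function(g) {
      b <- broods[[g]]
      if (any(b != round(b)) || any(b < 0))
        stop("brood_size column '", g, "' must hold nonnegative counts",
             call. = FALSE)
      laying <- which(b > 0)
      unhatched <- integer(length(b))
      if (length(laying)) {
        h <- if (!is.null(hatch)) hatch[[g]] else NULL
        if (is.null(h)) {
          if (length(laying))
            stop("no hatch_pct column for laying genotype '", g, "'",
                 call. = FALSE)
        } else {
          if (length(h) != length(laying))
            stop("hatch_pct column '", g, "' has ", length(h),
                 " values but ", length(laying), " laying mothers",
                 call. = FALSE)
          if (any(h < 0 | h > 100))
            stop("hatch_pct column '", g, "' outside [0, 100]",
                 call. = FALSE)
          unhatched[laying] <- as.integer(round(b[laying] *
                                                  (100 - h) / 100))
        }
      }
      data.frame(genotype = g, animal_id = seq_along(b),
                 brood = as.integer(b), unhatched = unhatched,
                 stringsAsFactors = FALSE)
    })
    out$viability <- assay_dataset(do.call(rbind, rows),
                                   assay = "viability")
  }
  if (!is.null(secs$bbps))
    out$swimming <- assay_dataset(cols_to_long(secs$bbps, "bbps"),
                                  assay = "swimming")
  if (!is.null(secs$mislocalized_nuclei))
    out$migration <- assay_dataset(
      cols_to_long(secs$mislocalized_nuclei, "mislocalized"),
      assay = "migration")
  if (!is.null(secs$nuclear_blebs))
    out$morphology <- assay_dataset(
      cols_to_long(secs$nuclear_blebs, "blebs"), assay = "morphology")
  for (nm in grep("^fluorescence", names(secs), value = TRUE))
    out[[nm]] <- assay_dataset(cols_to_long(secs[[nm]], "intensity"),
                               assay = "fluorescence")
  out
}

#' Write datasets in the sectioned workbook layout (CSV)
#'
#' Inverse of [read_s1_workbook()] for the CSV front-end; used to build
#' fixture workbooks and for round-trip checks.
#'
#' @param datasets Named list of [assay_dataset()] objects (as returned
#'   by [read_s1_workbook()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_s1_workbook <- function(datasets, path) {
  lines <- character(0)
  emit <- function(section, cols) {
    genos <- names(cols)
    nmax <- max(lengths(cols))
    body <- vapply(seq_len(nmax), function(i) {
      paste(vapply(cols, function(v) {
        if (i <= length(v)) format(v[i], scientific = FALSE, trim = TRUE)
        else ""
      }, character(1)), collapse = ",")
    }, character(1))
    c(paste0("# section: ", section),
      paste(genos, collapse = ","), body)
  }
  split_col <- function(d, value) {
    g <- unique(d$genotype)
    stats::setNames(lapply(g, function(x) d[[value]][d$genotype == x]), g)
  }
  if (!is.null(datasets$viability)) {
    d <- datasets$viability
    lines <- c(lines, emit("brood_size", split_col(d, "brood")))
    laying <- d[d$brood > 0, , drop = FALSE]
    if (nrow(laying)) {
      laying$hatch_pct <- round(100 * (laying$brood - laying$unhatched) /
                                  laying$brood, 4)
      lines <- c(lines, emit("hatch_pct", split_col(laying, "hatch_pct")))
    }
  }
  if (!is.null(datasets$swimming))
    lines <- c(lines, emit("bbps", split_col(datasets$swimming, "bbps")))
  if (!is.null(datasets$migration))
    lines <- c(lines, emit("mislocalized_nuclei",
                           split_col(datasets$migration, "mislocalized")))
  if (!is.null(datasets$morphology))
    lines <- c(lines, emit("nuclear_blebs",
                           split_col(datasets$morphology, "blebs")))
  for (nm in grep("^fluorescence", names(datasets), value = TRUE))
    lines <- c(lines, emit(nm, split_col(datasets[[nm]], "intensity")))
  writeLines(lines, path)
  invisible(path)
}

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA",
         formatC(x, digits = digits, format = "f", drop0trailing = FALSE))
}

#' Write results tables and score cards to files
#'
#' Writes each `stat_result` table as `results_<name>.csv` (fixed column
#' order, fixed decimal places), the score cards as a score-table-format
#' `scorecards.tsv` (`NA` sentinel strings; missing migration printed as
#' `N/A`), and the per-variant evidence bundle as `evidence.json`.
#' Output is deterministic: identical inputs give byte-identical files.
#'
#' @param results Named list of `stat_result` data frames (may be empty).
#' @param scorecards A `variant_scorecards` object, or `NULL`.
#' @param path Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_outputs <- function(results, scorecards, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (nm in names(results)) {
    r <- as.data.frame(results[[nm]])
    out <- data.frame(comparison = r$comparison,
                      estimate = fmt_num(r$estimate),
                      statistic = fmt_num(r$statistic),
                      p_raw = fmt_num(r$p_raw),
                      p_adjusted = fmt_num(r$p_adjusted),
                      method = r$method,
                      significant = r$significant,
                      degenerate = r$degenerate,
                      stringsAsFactors = FALSE)
    f <- file.path(path, paste0("results_", nm, ".csv"))
    utils::write.csv(out, f, row.names = FALSE, quote = TRUE)
    written <- c(written, f)
  }
  if (!is.null(scorecards)) {
    sc <- as.data.frame(scorecards)
    sc$migration <- ifelse(is.na(sc$migration), "N/A",
                           as.character(sc$migration))
    names(sc) <- c("human_label", "worm_label", "viability", "swimming",
                   "migration", "score", "classification")
    f <- file.path(path, "scorecards.tsv")
    utils::write.table(sc, f, sep = "\t", row.names = FALSE,
                       quote = FALSE, na = "NA")
    written <- c(written, f)
    ev <- attr(scorecards, "evidence")
    if (!is.null(ev)) {
      f <- file.path(path, "evidence.json")
      jsonlite::write_json(ev, f, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, force = TRUE)
      written <- c(written, f)
    }
  }
  invisible(written)
}
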