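# Run configuration: statistical thresholds, genotype templates for
# simulation, sample sizes, and section-name mapping for workbook input.

#' Default run configuration
#'
#' Defaults follow the assay design: significance level 0.05, false
#' discovery rate 5%, swimming-defect threshold 1.1 BBPS (the
#' corroborated mean swimming rate of lmn-1(Y59C) worms), severe-defect
#' fraction cutoff 30% (strict), sample sizes of 10 mothers, 40 swimmers
#' and 20 animals for migration/morphology per genotype, and a simulated
#' panel of one control plus one strain per template archetype.
#'
#' @param ... Named overrides of top-level config entries.
#' @return A validated config list with entries `control_genotype`,
#'   `alpha`, `fdr`, `bbps_threshold`, `swim_fraction_cutoff`, `seed`,
#'   `sample_sizes`, `genotypes` (template + overrides per simulated
#'   strain) and `section_map`.
#' @export
default_config <- function(...) {
  cfg <- list(
    control_genotype = "wild_type",
    alpha = 0.05,
    fdr = 0.05,
    bbps_threshold = 1.1,
    swim_fraction_cutoff = 0.30,
    seed = 1,
    sample_sizes = list(mothers = 10, swimmers = 40, migration = 20,
                        morphology = 20, nuclei = 30),
    genotypes = list(
      wild_type = list(template = "wild_type"),
      severe_1 = list(template = "severe",
                      overrides = list(name = "severe_1")),
      cardiac_1 = list(template = "cardiac_only",
                       overrides = list(name = "cardiac_1")),
      vus_1 = list(template = "benign_vus",
                   overrides = list(name = "vus_1"))),
    section_map = NULL)
  dots <- list(...)
  cfg[names(dots)] <- dots
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' @param cfg A config list.
#' @return `cfg`, invisibly returned after checks: `alpha` and `fdr` in
#'   (0, 1), positive thresholds, positive sample sizes.
#' @export
validate_config <- function(cfg) {
  for (f in c("alpha", "fdr")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v >= 1)
      stop("config '", f, "' must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(cfg$bbps_threshold) || cfg$bbps_threshold <= 0)
    stop("config 'bbps_threshold' must be positive", call. = FALSE)
  if (!is.numeric(cfg$swim_fraction_cutoff) ||
      cfg$swim_fraction_cutoff <= 0 || cfg$swim_fraction_cutoff >= 1)
    stop("config 'swim_fraction_cutoff' must lie in (0, 1)", call. = FALSE)
  if (!is.null(cfg$sample_sizes) && any(unlist(cfg$sample_sizes) < 1))
    stop("config sample sizes must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Read a YAML run configuration
#'
#' Reads a YAML file and merges it over [default_config()]; unknown keys
#' are preserved.
#'
#' @param path YAML file path.
#' @return A validated config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(user)) {
    if (nm == "sample_sizes" && is.list(user$sample_sizes))
      cfg$sample_sizes[names(user$sample_sizes)] <- user$sample_sizes
    else cfg[[nm]] <- user[[nm]]
  }
  validate_config(cfg)
}

config_profiles <- function(cfg) {
  lapply(names(cfg$genotypes), function(nm) {
    spec <- cfg$genotypes[[nm]]
    ov <- spec$overrides %||% list()
    if (is.null(ov$name)) ov$name <- nm
    make_profile(spec$template, ov)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
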