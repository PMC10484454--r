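#' Generative phenotype profile for one genotype
#'
#' A `genotype_profile` holds the full generative parameter set for one
#' strain across all assays: fertility (brood size, sterility, embryonic
#' lethality), swimming motility (a two-component impaired/unimpaired
#' mixture of body bends per second, BBPS), hypodermal nuclear migration,
#' nuclear-envelope blebbing, and nuclear-envelope fluorescence intensity.
#' Profiles drive the synthetic-data generator ([simulate_viability()] and
#' friends).
#'
#' @param name Genotype label (worm residue notation, e.g. `"Y59C"`).
#' @param clinical_class One of `"wild_type"`, `"skeletal_and_cardiac"`,
#'   `"cardiac_only"`, `"vus"`.
#' @param brood_mean Expected eggs laid per *laying* mother over the 3-day
#'   window (count).
#' @param brood_dispersion Negative-binomial size parameter (> 0); smaller
#'   values give more animal-to-animal spread.
#' @param lethality_prob Per-egg probability of failing to hatch, in `[0,1]`.
#' @param sterile_fraction Probability that a mother lays no eggs at all.
#' @param swim_mean_ok Mean BBPS of unimpaired swimmers (bends/s).
#' @param swim_mean_bad Mean BBPS of impaired swimmers (bends/s).
#' @param swim_sd Within-component BBPS standard deviation (> 0).
#' @param impaired_fraction Mixture weight of the impaired component.
#' @param mig_fail_prob Per-nucleus probability that a dorsal hyp7
#'   precursor nucleus fails to migrate (ends up in the dorsal cord).
#' @param nuclei_per_animal Scorable dorsal hyp7 precursor nuclei per
#'   animal (count).
#' @param bleb_rate Expected nuclear blebs per animal lateral side (>= 0).
#' @param fluor_mean,fluor_sd Nuclear-envelope fluorescence intensity mean
#'   and SD (arbitrary units).
#' @return An object of class `genotype_profile` (a named list).
#' @seealso [make_profile()] for template-based construction.
#' @export
genotype_profile <- function(name,
                             clinical_class = c("wild_type",
                                                "skeletal_and_cardiac",
                                                "cardiac_only", "vus"),
                             brood_mean,
                             brood_dispersion = 25,
                             lethality_prob = 0.01,
                             sterile_fraction = 0,
                             swim_mean_ok = 1.86,
                             swim_mean_bad = 0.35,
                             swim_sd = 0.35,
                             impaired_fraction = 0,
                             mig_fail_prob = 0.005,
                             nuclei_per_animal = 16,
                             bleb_rate = 0.3,
                             fluor_mean = 100,
                             fluor_sd = 15) {
  clinical_class <- match.arg(clinical_class)
  p <- list(name = as.character(name),
            clinical_class = clinical_class,
            brood_mean = brood_mean,
            brood_dispersion = brood_dispersion,
            lethality_prob = lethality_prob,
            sterile_fraction = sterile_fraction,
            swim_mean_ok = swim_mean_ok,
            swim_mean_bad = swim_mean_bad,
            swim_sd = swim_sd,
            impaired_fraction = impaired_fraction,
            mig_fail_prob = mig_fail_prob,
            nuclei_per_animal = nuclei_per_animal,
            bleb_rate = bleb_rate,
            fluor_mean = fluor_mean,
            fluor_sd = fluor_sd)
  class(p) <- "genotype_profile"
  validate_profile(p)
  p
}

#' Validate a genotype profile
#'
#' Checks the profile invariants: probabilities in `[0,1]`, rates and means
#' finite and nonnegative, positive spreads, and (for non-wild-type
#' profiles) `swim_mean_bad <= swim_mean_ok`.
#'
#' @param p A `genotype_profile`.
#' @return `p`, invisibly; errors describe the offending field.
#' @export
validate_profile <- function(p) {
  if (!inherits(p, "genotype_profile"))
    stop("not a genotype_profile object", call. = FALSE)
  num <- c("brood_mean", "brood_dispersion", "lethality_prob",
           "sterile_fraction", "swim_mean_ok", "swim_mean_bad", "swim_sd",
           "impaired_fraction", "mig_fail_prob", "nuclei_per_animal",
           "bleb_rate", "fluor_mean", "fluor_sd")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("profile field '", f, "' must be a finite number", call. = FALSE)
  }
  for (f in c("lethality_prob", "sterile_fraction", "impaired_fraction",
              "mig_fail_prob")) {
    if (p[[f]] < 0 || p[[f]] > 1)
      stop("profile field '", f, "' must lie in [0, 1]", call. = FALSE)
  }
  for (f in c("brood_mean", "brood_dispersion", "swim_mean_ok",
              "swim_mean_bad", "bleb_rate", "nuclei_per_animal", "fluor_sd"))
    if (p[[f]] < 0)
      stop("profile field '", f, "' must be >= 0", call. = FALSE)
  if (p$swim_sd <= 0)
    stop("profile field 'swim_sd' must be > 0", call. = FALSE)
  if (p$brood_dispersion <= 0)
    stop("profile field 'brood_dispersion' must be > 0", call. = FALSE)
  if (p$nuclei_per_animal != round(p$nuclei_per_animal) ||
      p$nuclei_per_animal < 1)
    stop("profile field 'nuclei_per_animal' must be a positive integer",
         call. = FALSE)
  if (p$clinical_class != "wild_type" && p$swim_mean_bad > p$swim_mean_ok)
    stop("profile invariant violated: swim_mean_bad > swim_mean_ok",
         call. = FALSE)
  invisible(p)
}

# Template parameter sets. Magnitudes follow the qualitative pattern of the
# assays they emulate: a wild-type strain swims at 1.86 BBPS with essentially
# no impaired animals and is fully fertile; a severe (skeletal-and-cardiac)
# strain has a brood roughly a third of wild type, elevated embryonic
# lethality, a majority-impaired swimming mixture, a 25% per-nucleus
# migration failure rate and frequent nuclear blebs; a cardiac-only strain
# matches wild type in all rubric assays; a benign VUS is wild-type-like.
profile_templates <- function() {
  list(
    wild_type = genotype_profile(
      name = "wild_type", clinical_class = "wild_type",
      brood_mean = 250, brood_dispersion = 25,
      lethality_prob = 0.01, sterile_fraction = 0,
      swim_mean_ok = 1.86, swim_mean_bad = 0.35, swim_sd = 0.35,
      impaired_fraction = 0.02,
      mig_fail_prob = 0.005, nuclei_per_animal = 16,
      bleb_rate = 0.3, fluor_mean = 100, fluor_sd = 15),
    severe = genotype_profile(
      name = "severe", clinical_class = "skeletal_and_cardiac",
      brood_mean = 88, brood_dispersion = 10,
      lethality_prob = 0.25, sterile_fraction = 0,
      swim_mean_ok = 1.7, swim_mean_bad = 0.4, swim_sd = 0.35,
      impaired_fraction = 0.6,
      mig_fail_prob = 0.25, nuclei_per_animal = 16,
      bleb_rate = 3, fluor_mean = 100, fluor_sd = 15),
    cardiac_only = genotype_profile(
      name = "cardiac_only", clinical_class = "cardiac_only",
      brood_mean = 245, brood_dispersion = 25,
      lethality_prob = 0.012, sterile_fraction = 0,
      swim_mean_ok = 1.8, swim_mean_bad = 0.35, swim_sd = 0.35,
      impaired_fraction = 0.03,
      mig_fail_prob = 0.006, nuclei_per_animal = 16,
      bleb_rate = 0.6, fluor_mean = 100, fluor_sd = 15),
    benign_vus = genotype_profile(
      name = "benign_vus", clinical_class = "vus",
      brood_mean = 250, brood_dispersion = 25,
      lethality_prob = 0.01, sterile_fraction = 0,
      swim_mean_ok = 1.85, swim_mean_bad = 0.35, swim_sd = 0.35,
      impaired_fraction = 0.02,
      mig_fail_prob = 0.005, nuclei_per_animal = 16,
      bleb_rate = 0.35, fluor_mean = 100, fluor_sd = 15)
  )
}

#' Construct a genotype profile from a named template
#'
#' Templates encode four archetypes: `wild_type` (1.86 BBPS mean, full
#' fertility), `severe` (skeletal-and-cardiac archetype: small brood,
#' elevated lethality, > 30% impaired swimmers, nuclear-migration defect),
#' `cardiac_only` (wild-type-like in the rubric assays) and `benign_vus`.
#' Any field of [genotype_profile()] may be overridden.
#'
#' @param template Template name.
#' @param overrides Named list of profile fields to replace.
#' @return A validated `genotype_profile`. Construction is deterministic:
#'   the same template and overrides always give an identical profile.
#' @export
#' @examples
#' make_profile("wild_type")$swim_mean_ok
#' make_profile("severe", list(name = "Y59C"))
make_profile <- function(template = c("wild_type", "severe", "cardiac_only",
                                      "benign_vus"),
                         overrides = list()) {
  template <- match.arg(template)
  p <- profile_templates()[[template]]
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("overrides must be a named list", call. = FALSE)
    unknown <- setdiff(names(overrides), names(p))
    if (length(unknown))
      stop("unknown profile field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(overrides)] <- overrides
  }
  class(p) <- "genotype_profile"
  validate_profile(p)
  p
}

#' @export
print.genotype_profile <- function(x, ...) {
  cat("<genotype_profile> ", x$name, " (", x$clinical_class, ")\n", sep = "")
  cat(sprintf("  brood: mean %.1f (size %.1f), sterile %.2f, lethality %.3f\n",
              x$brood_mean, x$brood_dispersion, x$sterile_fraction,
              x$lethality_prob))
  cat(sprintf("  swim:  %.2f / %.2f BBPS (sd %.2f), impaired %.2f\n",
              x$swim_mean_ok, x$swim_mean_bad, x$swim_sd,
              x$impaired_fraction))
  cat(sprintf("  nuclei: mig_fail %.3f of %d, blebs/side %.2f, fluor %.0f±%.0f\n",
              x$mig_fail_prob, as.integer(x$nuclei_per_animal), x$bleb_rate,
              x$fluor_mean, x$fluor_sd))
  invisible(x)
}
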