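# Synthetic per-animal assay data. Every generator draws from its own
# random stream derived from (seed, assay tag), so simulating one assay
# never perturbs another's draws, and identical (profile, n, seed) always
# reproduce the same table.

# inverse-CDF draw from a normal truncated below at 0 (BBPS is nonnegative)
rtruncnorm0 <- function(n, mean, sd) {
  if (sd <= 0) return(pmax(rep(mean, n), 0))
  lo <- stats::pnorm(0, mean, sd)
  u <- stats::runif(n, lo, 1)
  stats::qnorm(u, mean, sd)
}

#' Simulate a viability (brood size and embryonic lethality) assay
#'
#' Each mother is sterile with probability `sterile_fraction` (lays zero
#' eggs); otherwise her total brood over the 3-day egg-laying window is a
#' negative-binomial draw with mean `brood_mean` and size
#' `brood_dispersion`, split uniformly-multinomially over the three daily
#' plates. Unhatched eggs are binomial with the per-egg `lethality_prob`.
#'
#' @param profile A [genotype_profile()].
#' @param n_mothers Number of mothers (>= 1).
#' @param seed Integer global seed.
#' @return An [assay_dataset()] with columns `genotype`, `animal_id`,
#'   `eggs_day1..eggs_day3`, `brood`, `unhatched`.
#' @export
simulate_viability <- function(profile, n_mothers, seed) {
  validate_profile(profile)
  stopifnot(n_mothers >= 1)
  with_seed(derive_seed(seed, paste0("viability:", profile$name)), {
    sterile <- stats::runif(n_mothers) < profile$sterile_fraction
    brood <- ifelse(sterile, 0L,
                    stats::rnbinom(n_mothers, size = profile$brood_dispersion,
                                   mu = profile$brood_mean))
    days <- t(vapply(brood, function(b) {
      if (b == 0) c(0L, 0L, 0L)
      else as.integer(stats::rmultinom(1, b, c(0.45, 0.35, 0.20)))
    }, integer(3)))
    unhatched <- stats::rbinom(n_mothers, size = brood,
                               prob = profile$lethality_prob)
    assay_dataset(data.frame(
      genotype = profile$name,
      animal_id = seq_len(n_mothers),
      eggs_day1 = days[, 1], eggs_day2 = days[, 2], eggs_day3 = days[, 3],
      brood = as.integer(brood), unhatched = as.integer(unhatched),
      stringsAsFactors = FALSE), assay = "viability", units = "eggs")
  })
}

#' Simulate a swimming (thrashing) assay
#'
#' Per-animal BBPS is drawn from a two-component mixture: with probability
#' `impaired_fraction` from the impaired component (mean `swim_mean_bad`),
#' otherwise from the unimpaired component (mean `swim_mean_ok`), both
#' normal with SD `swim_sd` truncated below at 0. The mixture reproduces
#' the wide within-strain spread of motility phenotypes, from normal
#' swimming to near-immobile animals.
#'
#' @inheritParams simulate_viability
#' @param n_animals Number of animals (>= 1).
#' @return An [assay_dataset()] with columns `genotype`, `animal_id`,
#'   `bbps`, `impaired` (true component membership).
#' @export
simulate_swimming <- function(profile, n_animals, seed) {
  validate_profile(profile)
  stopifnot(n_animals >= 1)
  with_seed(derive_seed(seed, paste0("swimming:", profile$name)), {
    impaired <- stats::runif(n_animals) < profile$impaired_fraction
    mu <- ifelse(impaired, profile$swim_mean_bad, profile$swim_mean_ok)
    bbps <- rtruncnorm0(n_animals, mu, profile$swim_sd)
    assay_dataset(data.frame(
      genotype = profile$name, animal_id = seq_len(n_animals),
      bbps = bbps, impaired = impaired, stringsAsFactors = FALSE),
      assay = "swimming", units = "bends/s")
  })
}

#' Simulate a hyp7 nuclear-migration assay
#'
#' Each animal carries `nuclei_per_animal` scorable dorsal hyp7 precursor
#' nuclei; each independently fails to migrate (is stranded in the dorsal
#' cord) with probability `mig_fail_prob`, giving a binomial mislocalized
#' count per animal.
#'
#' @inheritParams simulate_swimming
#' @return An [assay_dataset()] with columns `genotype`, `animal_id`,
#'   `mislocalized`, `nuclei_total`.
#' @export
simulate_migration <- function(profile, n_animals, seed) {
  validate_profile(profile)
  stopifnot(n_animals >= 1)
  with_seed(derive_seed(seed, paste0("migration:", profile$name)), {
    k <- as.integer(profile$nuclei_per_animal)
    mis <- stats::rbinom(n_animals, k, profile$mig_fail_prob)
    assay_dataset(data.frame(
      genotype = profile$name, animal_id = seq_len(n_animals),
      mislocalized = as.integer(mis), nuclei_total = k,
      stringsAsFactors = FALSE), assay = "migration", units = "nuclei")
  })
}

#' Simulate a nuclear-morphology (bleb count) assay
#'
#' Nuclear blebs on one lateral side of the hyp7 syncytium are Poisson
#' with rate `bleb_rate` per animal.
#'
#' @inheritParams simulate_swimming
#' @return An [assay_dataset()] with columns `genotype`, `animal_id`,
#'   `blebs`.
#' @export
simulate_blebs <- function(profile, n_animals, seed) {
  validate_profile(profile)
  stopifnot(n_animals >= 1)
  with_seed(derive_seed(seed, paste0("blebs:", profile$name)), {
    assay_dataset(data.frame(
      genotype = profile$name, animal_id = seq_len(n_animals),
      blebs = as.integer(stats::rpois(n_animals, profile$bleb_rate)),
      stringsAsFactors = FALSE), assay = "morphology", units = "blebs/side")
  })
}

#' Simulate a nuclear-envelope fluorescence assay
#'
#' Per-nucleus corrected total fluorescence intensities are normal with
#' mean `fluor_mean` and SD `fluor_sd` (arbitrary units).
#'
#' @inheritParams simulate_viability
#' @param n_nuclei Number of nuclei (>= 1).
#' @return An [assay_dataset()] with columns `genotype`, `animal_id`
#'   (nucleus index), `intensity`.
#' @export
simulate_fluorescence <- function(profile, n_nuclei, seed) {
  validate_profile(profile)
  stopifnot(n_nuclei >= 1)
  with_seed(derive_seed(seed, paste0("fluorescence:", profile$name)), {
    assay_dataset(data.frame(
      genotype = profile$name, animal_id = seq_len(n_nuclei),
      intensity = stats::rnorm(n_nuclei, profile$fluor_mean,
                               profile$fluor_sd),
      stringsAsFactors = FALSE), assay = "fluorescence", units = "a.u.")
  })
}

#' Simulate every assay for a set of genotype profiles
#'
#' Convenience wrapper producing one combined [assay_dataset()] per assay
#' for a list of profiles, at given per-assay sample sizes.
#'
#' @param profiles A list of [genotype_profile()] objects.
#' @param n Named list/vector of sample sizes with entries `mothers`,
#'   `swimmers`, `migration`, `morphology`, `nuclei`.
#' @param seed Integer global seed.
#' @param assays Character vector of assays to simulate.
#' @return Named list of `assay_dataset` objects.
#' @export
simulate_experiment <- function(profiles,
                                n = list(mothers = 10, swimmers = 40,
                                         migration = 20, morphology = 20,
                                         nuclei = 30),
                                seed = 1,
                                assays = c("viability", "swimming",
                                           "migration", "morphology",
                                           "fluorescence")) {
  assays <- match.arg(assays, several.ok = TRUE)
  bind <- function(ds) {
    out <- do.call(rbind, lapply(ds, as.data.frame))
    attr(out, "assay") <- attr(ds[[1]], "assay")
    attr(out, "units") <- attr(ds[[1]], "units")
    class(out) <- c("assay_dataset", "data.frame")
    out
  }
  res <- list()
  if ("viability" %in% assays)
    res$viability <- bind(lapply(profiles, simulate_viability,
                                 n_mothers = n$mothers, seed = seed))
  if ("swimming" %in% assays)
    res$swimming <- bind(lapply(profiles, simulate_swimming,
                                n_animals = n$swimmers, seed = seed))
  if ("migration" %in% assays)
    res$migration <- bind(lapply(profiles, simulate_migration,
                                 n_animals = n$migration, seed = seed))
  if ("morphology" %in% assays)
    res$morphology <- bind(lapply(profiles, simulate_blebs,
                                  n_animals = n$morphology, seed = seed))
  if ("fluorescence" %in% assays)
    res$fluorescence <- bind(lapply(profiles, simulate_fluorescence,
                                    n_nuclei = n$nuclei, seed = seed))
  res
}
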