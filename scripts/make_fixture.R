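#!/usr/bin/env Rscript
# Builds the packaged synthetic assay workbook
# (inst/extdata/s1_synthetic_workbook.csv): a 12-variant panel plus wild
# type whose genotype sample means are pinned to the published summary
# values (wild-type mean 1.86 BBPS, Y59C 1.1 BBPS, L535P < 1 BBPS, E358K
# brood < 40% of wild type) and whose score cards follow the published
# score table. Run from the repository root:
#   Rscript scripts/make_fixture.R

suppressMessages(library(wormlamin))

FIXTURE_SEED <- 20230825
out_path <- file.path("inst", "extdata", "s1_synthetic_workbook.csv")
dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)

# pin a continuous sample mean exactly
scale_mean <- function(v, target) v * target / mean(v)
# pin an integer-count sample mean to target within 1/(2n)
scale_mean_int <- function(v, target) {
  if (target == 0) return(rep(0L, length(v)))
  v2 <- round(v * target / mean(v))
  d <- round(target * length(v)) - sum(v2)
  i <- which.max(v2)
  v2[i] <- v2[i] + d
  as.integer(pmax(v2, 0))
}

# panel design: per-genotype targets. swim = c(mean, impaired_fraction,
# mean_bad, mean_ok); viability = c(n, brood_mean, lethality_prob)
panel <- list(
  wild_type = list(n_via = 22, brood = 250, leth = 0.010,
                   n_swim = 100, swim_mean = 1.86, imp = 0.02,
                   mu_bad = 0.40, mu_ok = 1.893, mig_p = 0.006,
                   bleb = 0.30),
  N53S  = list(n_via = 10, brood = 30,  leth = 1.000, n_swim = 40,
               swim_mean = 1.50, imp = 0.15, mu_bad = 0.40,
               mu_ok = 1.690, mig_p = 0.280, bleb = 4.0),
  Y59C  = list(n_via = 10, brood = 87,  leth = 0.250, n_swim = 40,
               swim_mean = 1.10, imp = 0.50, mu_bad = 0.40,
               mu_ok = 1.800, mig_p = 0.220, bleb = 4.5),
  R64P  = list(n_via = 10, brood = 80,  leth = 0.280, n_swim = 40,
               swim_mean = 1.20, imp = 0.45, mu_bad = 0.40,
               mu_ok = 1.850, mig_p = 0.012, bleb = 1.5),
  E358K = list(n_via = 10, brood = 87,  leth = 0.150, n_swim = 40,
               swim_mean = 1.70, imp = 0.08, mu_bad = 0.40,
               mu_ok = 1.820, mig_p = 0.012, bleb = 1.6),
  L535P = list(n_via = 10, brood = 0,   leth = NA,    n_swim = 40,
               swim_mean = 0.70, imp = 0.80, mu_bad = 0.45,
               mu_ok = 1.700, mig_p = 0.015, bleb = 5.0),
  E96K  = list(n_via = 12, brood = 248, leth = 0.015, n_swim = 40,
               swim_mean = 1.80, imp = 0.03, mu_bad = 0.40,
               mu_ok = 1.850, mig_p = 0.008, bleb = 0.9),
  E175K = list(n_via = 10, brood = 252, leth = 0.012, n_swim = 40,
               swim_mean = 1.75, imp = 0.03, mu_bad = 0.40,
               mu_ok = 1.800, mig_p = 0.008, bleb = 0.8),
  R204W = list(n_via = 10, brood = 247, leth = 0.010, n_swim = 40,
               swim_mean = 1.85, imp = 0.02, mu_bad = 0.40,
               mu_ok = 1.880, mig_p = 0.750, bleb = 1.2),
  K284Q = list(n_via = 10, brood = 251, leth = 0.010, n_swim = 40,
               swim_mean = 1.80, imp = 0.03, mu_bad = 0.40,
               mu_ok = 1.850, mig_p = 0.010, bleb = 1.1),
  K331Q = list(n_via = 10, brood = 246, leth = 0.013, n_swim = 40,
               swim_mean = 1.40, imp = 0.45, mu_bad = 0.45,
               mu_ok = 2.200, mig_p = 0.012, bleb = 1.2),
  G407D = list(n_via = 10, brood = 253, leth = 0.010, n_swim = 40,
               swim_mean = 1.85, imp = 0.02, mu_bad = 0.40,
               mu_ok = 1.880, mig_p = 0.008, bleb = 0.32),
  G528R = list(n_via = 10, brood = 249, leth = 0.011, n_swim = 40,
               swim_mean = 1.80, imp = 0.03, mu_bad = 0.40,
               mu_ok = 1.850, mig_p = NA, bleb = 0.35)  # no migration data
)

genos <- names(panel)
via_rows <- list(); swim_rows <- list(); mig_rows <- list()
bleb_rows <- list()

for (g in genos) {
  p <- panel[[g]]
  # --- viability -----------------------------------------------------
  if (p$brood == 0) {                      # sterile strain
    brood <- rep(0L, p$n_via); unhatched <- rep(0L, p$n_via)
  } else {
    prof <- make_profile("wild_type",
                         list(name = g, brood_mean = p$brood,
                              brood_dispersion = 25,
                              lethality_prob = min(p$leth, 1)))
    d <- simulate_viability(prof, p$n_via, FIXTURE_SEED)
    if (g == "E358K") {
      # half the mothers lay few or no embryos
      nlow <- p$n_via %/% 2
      low <- scale_mean_int(d$brood[seq_len(nlow)], 10)
      high <- scale_mean_int(d$brood[(nlow + 1):p$n_via],
                             (p$brood * p$n_via - 10 * nlow) /
                               (p$n_via - nlow))
      brood <- c(low, high)
    } else {
      brood <- scale_mean_int(d$brood, p$brood)
    }
    if (p$leth >= 1) {
      unhatched <- brood
    } else {
      set.seed(FIXTURE_SEED + match(g, genos))
      unhatched <- as.integer(rbinom(length(brood), brood, p$leth))
    }
  }
  via_rows[[g]] <- data.frame(genotype = g,
                              animal_id = seq_along(brood),
                              brood = brood, unhatched = unhatched,
                              stringsAsFactors = FALSE)
  # --- swimming ------------------------------------------------------
  prof_s <- make_profile(
    if (p$imp > 0.3) "severe" else "wild_type",
    list(name = g, impaired_fraction = p$imp, swim_mean_bad = p$mu_bad,
         swim_mean_ok = p$mu_ok, swim_sd = 0.35))
  ds <- simulate_swimming(prof_s, p$n_swim, FIXTURE_SEED)
  swim_rows[[g]] <- data.frame(genotype = g, animal_id = ds$animal_id,
                               bbps = round(scale_mean(ds$bbps,
                                                       p$swim_mean), 4),
                               stringsAsFactors = FALSE)
  # --- migration -----------------------------------------------------
  if (!is.na(p$mig_p)) {
    prof_m <- make_profile("wild_type",
                           list(name = g, mig_fail_prob = p$mig_p,
                                nuclei_per_animal = 16))
    dm <- simulate_migration(prof_m, 20, FIXTURE_SEED)
    mig_rows[[g]] <- data.frame(genotype = g, animal_id = dm$animal_id,
                                mislocalized = dm$mislocalized,
                                stringsAsFactors = FALSE)
  }
  # --- nuclear blebs -------------------------------------------------
  prof_b <- make_profile("wild_type", list(name = g, bleb_rate = p$bleb))
  db <- simulate_blebs(prof_b, 20, FIXTURE_SEED)
  bleb_rows[[g]] <- data.frame(genotype = g, animal_id = db$animal_id,
                               blebs = db$blebs, stringsAsFactors = FALSE)
}

# fluorescence: nuclear-envelope UNC-83 strongly reduced in R204W,
# LMN-1 itself unchanged
set.seed(FIXTURE_SEED)
flu_lmn1 <- rbind(
  data.frame(genotype = "wild_type", animal_id = 1:10,
             intensity = round(scale_mean(rnorm(10, 100, 12), 100), 3)),
  data.frame(genotype = "R204W", animal_id = 1:12,
             intensity = round(scale_mean(rnorm(12, 97, 12), 97), 3)))
flu_unc83 <- rbind(
  data.frame(genotype = "wild_type", animal_id = 1:56,
             intensity = round(scale_mean(rnorm(56, 100, 20), 100), 3)),
  data.frame(genotype = "R204W", animal_id = 1:57,
             intensity = round(scale_mean(rnorm(57, 55, 18), 55), 3)))

datasets <- list(
  viability = assay_dataset(do.call(rbind, via_rows), "viability"),
  swimming = assay_dataset(do.call(rbind, swim_rows), "swimming"),
  migration = assay_dataset(do.call(rbind, mig_rows), "migration"),
  morphology = assay_dataset(do.call(rbind, bleb_rows), "morphology"),
  fluorescence_lmn1 = assay_dataset(flu_lmn1, "fluorescence"),
  fluorescence_unc83 = assay_dataset(flu_unc83, "fluorescence"))

write_s1_workbook(datasets, out_path)
cat("wrote", out_path, "(", file.size(out_path), "bytes )\n")

# ---- verification: the workbook must reproduce the published pattern --
wb <- read_s1_workbook(out_path)
cards <- score_variants(wb, "wild_type")
expected <- data.frame(
  variant = c("N53S", "Y59C", "R64P", "E358K", "L535P", "E96K", "E175K",
              "R204W", "K284Q", "K331Q", "G407D", "G528R"),
  viability = c(2, 1, 1, 1, 2, 0, 0, 0, 0, 0, 0, 0),
  swimming = c(0, 2, 2, 0, 2, 0, 0, 0, 0, 2, 0, 0),
  migration = c(1, 1, 0, 0, 0, 0, 0, 1, 0, 0, 0, NA),
  total = c(3, 4, 3, 1, 4, 0, 0, 1, 0, 2, 0, 0))
got <- as.data.frame(cards)[match(expected$variant, cards$variant),
                            c("variant", "viability", "swimming",
                              "migration", "total")]
rownames(got) <- NULL
stopifnot(identical(got$viability, as.integer(expected$viability)),
          identical(got$swimming, as.integer(expected$swimming)),
          identical(got$migration, as.integer(expected$migration)),
          identical(got$total, as.integer(expected$total)))
mw <- function(g) mean(wb$swimming$bbps[wb$swimming$genotype == g])
stopifnot(abs(mw("wild_type") - 1.86) < 0.01,
          abs(mw("Y59C") - 1.10) < 0.01,
          mw("L535P") < 1)
bb <- function(g) mean(wb$viability$brood[wb$viability$genotype == g])
stopifnot(bb("E358K") / bb("wild_type") < 0.40)
fr <- function(g) defect_fraction(
  wb$swimming[wb$swimming$genotype == g, ])
for (g in c("Y59C", "R64P", "K331Q", "L535P"))
  stopifnot(fr(g) >= 0.35)
for (g in setdiff(genos, c("Y59C", "R64P", "K331Q", "L535P")))
  stopifnot(fr(g) <= 0.25)
cat("fixture verified: score table, printed means and brood ratio\n")
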