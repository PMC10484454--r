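sig <- function(est) stat_result("v vs wt", estimate = est,
                                 statistic = 5, p_raw = 1e-4,
                                 p_adjusted = 1e-3, method = "dunnett")
ns <- function(est) stat_result("v vs wt", estimate = est, statistic = 0.5,
                                p_raw = 0.6, p_adjusted = 0.9,
                                method = "dunnett")

test_that("viability scoring distinguishes inviable, reduced and normal", {
  # all mothers sterile (L535P-like)
  d_sterile <- viability_records("L535P", rep(0, 10), rep(0, 10))
  s <- summarize_viability(d_sterile, "L535P")
  expect_true(s$all_sterile)
  expect_equal(viability_score(s, NULL), 2L)
  # eggs laid, none viable (N53S-like)
  d_dead <- viability_records("N53S", c(30, 25, 40), c(30, 25, 40))
  s2 <- summarize_viability(d_dead, "N53S")
  expect_false(s2$all_sterile)
  expect_true(s2$no_viable_offspring)
  expect_equal(viability_score(s2, NULL), 2L)
  # significantly reduced brood with viable offspring (Y59C-like)
  d_red <- viability_records("Y59C", c(90, 85, 80), c(20, 25, 22))
  s3 <- summarize_viability(d_red, "Y59C")
  expect_equal(viability_score(s3, sig(-160)), 1L)
  # significant lethality alone also scores 1
  expect_equal(viability_score(s3, ns(-5), sig(+20)), 1L)
  # control-like: no significant defect
  expect_equal(viability_score(s3, ns(-2), ns(0.1)), 0L)
  expect_error(viability_score(s3, NULL), "missing control comparison")
})

test_that("swimming score applies the strict 30% rule", {
  expect_equal(swimming_score(0.5), 2L)
  expect_equal(swimming_score(0.0), 0L)
  expect_equal(swimming_score(0.30), 0L)       # boundary is strict
  expect_equal(swimming_score(0.300001), 2L)
  expect_error(swimming_score(1.2))
})

test_that("migration score requires significance in the defect direction", {
  expect_equal(migration_score(sig(+11)), 1L)
  expect_equal(migration_score(sig(-3)), 0L)   # fewer mislocalized than wt
  expect_equal(migration_score(ns(+0.2)), 0L)
  expect_true(is.na(migration_score(NULL, data_available = FALSE)))
})

test_that("total score sums components and classifies severity", {
  c1 <- total_score("Y59C", 1L, 2L, 1L)
  expect_equal(c1$total, 4L)
  expect_equal(c1$classification, "severe_skeletal_and_cardiac")
  expect_equal(c1$human_label, "Y45C")
  c2 <- total_score("K331Q", 0L, 2L, 0L)
  expect_equal(c2$total, 2L)
  expect_equal(c2$classification, "severe_skeletal_and_cardiac")
  c3 <- total_score("G407D", 0L, 0L, 0L)
  expect_equal(c3$total, 0L)
  expect_equal(c3$classification, "mild_or_cardiac_only")
  # missing migration contributes 0 and stays NA on the card
  c4 <- total_score("G528R", 0L, 0L, NA_integer_)
  expect_equal(c4$total, 0L)
  expect_true(is.na(c4$migration))
  expect_error(total_score("x", 3L, 0L, 0L))
})

test_that("score_variants is deterministic and validates its inputs", {
  profs <- list(make_profile("wild_type"),
                make_profile("severe", list(name = "sev")),
                make_profile("benign_vus", list(name = "vus")))
  ds <- simulate_experiment(profs, seed = 12,
                            assays = c("viability", "swimming",
                                       "migration"))
  a <- score_variants(ds, "wild_type")
  b <- score_variants(ds, "wild_type")
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_setequal(a$variant, c("sev", "vus"))
  expect_error(score_variants(ds, "nope"), "absent")
  expect_error(score_variants(ds["swimming"], "wild_type"), "viability")
  # missing migration data for one variant -> NA component
  ds2 <- ds
  ds2$migration <- ds2$migration[ds2$migration$genotype != "vus", ]
  a2 <- score_variants(ds2, "wild_type")
  expect_true(is.na(a2$migration[a2$variant == "vus"]))
})

test_that("worsening any single assay input never lowers the total", {
  profs <- list(make_profile("wild_type"),
                make_profile("cardiac_only", list(name = "v")))
  ds <- simulate_experiment(profs, seed = 30,
                            assays = c("viability", "swimming",
                                       "migration"))
  base <- score_variants(ds, "wild_type")$total
  worsen <- list(
    swimming = function(d) {      # push most animals below threshold
      d$swimming$bbps[d$swimming$genotype == "v"] <- 0.2
      d
    },
    viability = function(d) {     # collapse the brood
      sel <- d$viability$genotype == "v"
      d$viability$brood[sel] <- 3L
      d$viability$unhatched[sel] <- pmin(d$viability$unhatched[sel], 3L)
      d
    },
    lethality = function(d) {     # kill every embryo laid
      sel <- d$viability$genotype == "v"
      d$viability$unhatched[sel] <- d$viability$brood[sel]
      d
    },
    migration = function(d) {     # strand most nuclei
      sel <- d$migration$genotype == "v"
      d$migration$mislocalized[sel] <- 12L
      d
    })
  for (f in worsen) {
    worse <- score_variants(f(ds), "wild_type")$total
    expect_gte(worse, base)
  }
})
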