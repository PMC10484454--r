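test_that("simulators are seed-reproducible and stream-independent", {
  p <- make_profile("severe")
  a <- simulate_viability(p, 25, seed = 42)
  b <- simulate_viability(p, 25, seed = 42)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_false(identical(a$brood,
                         simulate_viability(p, 25, seed = 43)$brood))
  # per-assay derived streams: swimming draws do not depend on whether
  # another assay was simulated in between
  s1 <- simulate_swimming(p, 30, seed = 42)
  invisible(simulate_migration(p, 500, seed = 42))
  s2 <- simulate_swimming(p, 30, seed = 42)
  expect_identical(s1$bbps, s2$bbps)
  expect_false(derive_seed(1, "swimming") == derive_seed(1, "viability"))
  expect_identical(derive_seed(7, "x"), derive_seed(7, "x"))
})

test_that("degenerate generator settings behave as specified", {
  sterile <- make_profile("severe", list(sterile_fraction = 1))
  d <- simulate_viability(sterile, 40, seed = 1)
  expect_true(all(d$brood == 0))
  expect_true(all(d$unhatched == 0))

  still <- make_profile("severe",
                        list(impaired_fraction = 1, swim_mean_bad = 0,
                             swim_sd = 1e-8))
  s <- simulate_swimming(still, 50, seed = 1)
  expect_true(all(s$bbps < 0.01))

  frozen <- make_profile("wild_type", list(mig_fail_prob = 0))
  expect_true(all(simulate_migration(frozen, 50, 1)$mislocalized == 0))
  none <- make_profile("wild_type", list(bleb_rate = 0))
  expect_true(all(simulate_blebs(none, 50, 1)$blebs == 0))
})

test_that("empirical means track the generative model (4 SE at n = 1e4)", {
  n <- 10000
  for (tmpl in c("wild_type", "severe")) {
    p <- make_profile(tmpl)
    v <- simulate_viability(p, n, seed = 5)
    se <- stats::sd(v$brood) / sqrt(n)
    expect_lt(abs(mean(v$brood) -
                    (1 - p$sterile_fraction) * p$brood_mean), 4 * se)

    s <- simulate_swimming(p, n, seed = 5)
    se <- stats::sd(s$bbps) / sqrt(n)
    expect_lt(abs(mean(s$bbps) - swim_mixture_mean(p)), 4 * se)

    m <- simulate_migration(p, n, seed = 5)
    se <- stats::sd(m$mislocalized) / sqrt(n)
    expect_lt(abs(mean(m$mislocalized) -
                    p$nuclei_per_animal * p$mig_fail_prob), 4 * se)

    b <- simulate_blebs(p, n, seed = 5)
    se <- stats::sd(b$blebs) / sqrt(n)
    expect_lt(abs(mean(b$blebs) - p$bleb_rate), 4 * se)

    f <- simulate_fluorescence(p, n, seed = 5)
    se <- stats::sd(f$intensity) / sqrt(n)
    expect_lt(abs(mean(f$intensity) - p$fluor_mean), 4 * se)
  }
})

test_that("binomial migration counts have the expected magnitude", {
  # 75% failure of 16 scorable nuclei -> mean mislocalized count near 12
  p <- make_profile("wild_type",
                    list(mig_fail_prob = 0.75, nuclei_per_animal = 16))
  m <- simulate_migration(p, 4000, seed = 9)
  expect_true(all(m$mislocalized >= 0 & m$mislocalized <= 16))
  expect_lt(abs(mean(m$mislocalized) - 12), 0.15)
})

test_that("severe-template swimming trips the defect-fraction rule", {
  p <- make_profile("severe")
  hits <- vapply(1:200, function(seed) {
    defect_fraction(simulate_swimming(p, 40, seed)) > 0.3
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
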