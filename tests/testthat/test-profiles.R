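test_that("templates produce valid, deterministic profiles", {
  for (tmpl in c("wild_type", "severe", "cardiac_only", "benign_vus")) {
    p <- make_profile(tmpl)
    expect_s3_class(p, "genotype_profile")
    expect_silent(validate_profile(p))
    expect_identical(p, make_profile(tmpl, list()))
  }
  wt <- make_profile("wild_type")
  expect_equal(wt$swim_mean_ok, 1.86)
  expect_lte(wt$impaired_fraction, 0.05)
  expect_equal(wt$sterile_fraction, 0)
  expect_lte(wt$mig_fail_prob, 0.01)
  # the severe archetype must trip the >30%-impaired swimming rule
  expect_gt(make_profile("severe")$impaired_fraction, 0.3)
})

test_that("overrides are applied and invariants enforced", {
  p <- make_profile("wild_type", list(name = "N2", brood_mean = 300))
  expect_equal(p$name, "N2")
  expect_equal(p$brood_mean, 300)
  expect_error(make_profile("nope"), "arg")
  expect_error(make_profile("wild_type", list(not_a_field = 1)),
               "unknown profile field")
  expect_error(make_profile("wild_type", list(lethality_prob = 1.4)),
               "\\[0, 1\\]")
  expect_error(make_profile("wild_type", list(swim_sd = 0)), "swim_sd")
  expect_error(make_profile("severe", list(swim_mean_bad = 5)),
               "swim_mean_bad")
  expect_error(make_profile("wild_type", list(brood_mean = Inf)), "finite")
})
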