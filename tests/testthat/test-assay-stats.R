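test_that("brood_size and percent_lethality implement the assay arithmetic", {
  expect_equal(brood_size(c(0, 0, 0)), 0)
  expect_equal(brood_size(c(50, 40, 10)), 100)
  expect_equal(brood_size(120), 120)
  expect_error(brood_size(c(1, 2, 3, 4)), "1-3")
  expect_error(brood_size(c(10, -1)), "nonnegative")

  expect_equal(as.numeric(percent_lethality(0, 100)), 0)
  expect_equal(as.numeric(percent_lethality(100, 100)), 100)
  expect_equal(as.numeric(percent_lethality(5, 50)), 10)
  z <- percent_lethality(c(0, 3), c(0, 30))
  expect_true(is.na(z[1]))
  expect_identical(attr(z, "sterile"), c(TRUE, FALSE))
  expect_error(percent_lethality(5, 3), "exceed")
})

test_that("ctcf follows the integrated-density formula", {
  expect_equal(as.numeric(ctcf(100, 10, 2)), 80)
  expect_equal(as.numeric(ctcf(100, 10, 0)), 100)
  expect_equal(as.numeric(ctcf(50, 10, 5)), 0)
  neg <- ctcf(10, 10, 5)
  expect_equal(as.numeric(neg), -40)      # preserved, not clipped
  expect_true(attr(neg, "negative"))
  expect_error(ctcf(10, 0, 1), "positive")
  expect_error(ctcf(Inf, 1, 1), "finite")
})

test_that("bh_adjust equals the brute-force step-up definition", {
  expect_equal(bh_adjust(0.04)$adjusted, 0.04)
  expect_true(bh_adjust(0.04)$reject)
  r <- bh_adjust(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(r$adjusted, rep(0.04, 4))
  expect_true(all(r$reject))
  expect_error(bh_adjust(numeric(0)), "empty")
  expect_error(bh_adjust(c(0.5, 1.2)))
  set.seed(101)
  for (i in 1:200) {
    p <- stats::runif(sample(1:25, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)$adjusted
    expect_equal(adj, bh_bruteforce(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(diff(sort(adj)[order(order(p))][order(p)]) >= -1e-12))
  }
})

test_that("Dunnett comparisons behave at the null and under shifts", {
  # literally identical groups -> zero difference, p = 1
  d <- two_group_dataset(c(1, 2, 3, 4), c(1, 2, 3, 4),
                         labels = c("wt", "a"))
  r <- anova_dunnett(d, "intensity", "wt")
  expect_equal(r$estimate, 0)
  expect_equal(r$p_adjusted, 1, tolerance = 1e-9)
  # 3 SD shift at n = 20 -> overwhelmingly significant
  hits <- vapply(1:30, function(seed) {
    set.seed(seed)
    d <- two_group_dataset(stats::rnorm(20), stats::rnorm(20, 3),
                           labels = c("wt", "mut"))
    anova_dunnett(d, "intensity", "wt")$p_adjusted <= 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.99)
  # degenerate: zero within-group variance everywhere
  dz <- two_group_dataset(c(1, 1, 1), c(2, 2, 2), labels = c("wt", "a"))
  rz <- anova_dunnett(dz, "intensity", "wt")
  expect_true(rz$degenerate)
  expect_error(anova_dunnett(d, "intensity", "missing"), "absent")
})

test_that("Dunnett controls the familywise error over 11 variants", {
  reps <- 300
  any_sig <- vapply(seq_len(reps), function(seed) {
    set.seed(1000 + seed)
    d <- data.frame(
      genotype = rep(c("wt", paste0("v", 1:11)), each = 10),
      animal_id = rep(1:10, 12),
      intensity = stats::rnorm(120))
    r <- anova_dunnett(assay_dataset(d, "fluorescence"), "intensity",
                       "wt")
    any(r$significant)
  }, logical(1))
  rate <- mean(any_sig)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("Dunnett and Tukey reduce to two-sample forms for one comparison", {
  set.seed(7)
  a <- stats::rnorm(12); b <- stats::rnorm(10, 0.8)
  d <- two_group_dataset(a, b, labels = c("wt", "mut"))
  p_t <- stats::t.test(a, b, var.equal = TRUE)$p.value
  expect_equal(anova_dunnett(d, "intensity", "wt")$p_adjusted, p_t,
               tolerance = 1e-6)
  tk <- anova_tukey(d, "intensity")
  expect_equal(tk$p_adjusted, p_t, tolerance = 1e-6)
  # and the studentized-range route agrees with base TukeyHSD
  fit <- stats::aov(y ~ g, data.frame(y = c(a, b),
                                      g = factor(rep(c("mut", "wt"),
                                                     c(12, 10)))))
  expect_equal(tk$p_adjusted,
               unname(stats::TukeyHSD(fit)$g[, "p adj"]),
               tolerance = 1e-9)
})

test_that("Tukey all-pairs flags only the outlying group", {
  set.seed(21)
  d <- data.frame(genotype = rep(c("a", "b", "c", "d"), each = 15),
                  animal_id = rep(1:15, 4),
                  intensity = c(stats::rnorm(45), stats::rnorm(15, 4)))
  r <- anova_tukey(assay_dataset(d, "fluorescence"), "intensity")
  with_d <- grepl("\\bd\\b", r$comparison)
  expect_true(all(r$significant[with_d]))
  expect_false(any(r$significant[!with_d]))
  expect_true(all(r$p_adjusted >= r$p_raw - 1e-12))
  # cross-check every adjusted p against base TukeyHSD
  fit <- stats::aov(intensity ~ genotype,
                    transform(d, genotype = factor(genotype)))
  hsd <- stats::TukeyHSD(fit)$genotype
  expect_equal(sort(r$p_adjusted), sort(unname(hsd[, "p adj"])),
               tolerance = 1e-9)
})

test_that("the Monte-Carlo Dunnett route agrees with the quadrature", {
  set.seed(3)
  groups <- lapply(c(0, 0.5, 1, 1.5), function(m) stats::rnorm(15, m))
  d <- data.frame(genotype = rep(c("wt", "a", "b", "c"), each = 15),
                  animal_id = rep(1:15, 4),
                  intensity = unlist(groups))
  r <- anova_dunnett(assay_dataset(d, "fluorescence"), "intensity", "wt")
  pmc <- dunnett_p_mc(abs(r$statistic), n_control = 15,
                      n_groups = rep(15, 3), df = 56, B = 2e5, seed = 4)
  expect_lt(max(abs(pmc - r$p_adjusted)), 0.005)
})

test_that("two-group t test handles the null, shifts and degeneracy", {
  d <- two_group_dataset(c(1, 2, 3), c(1, 2, 3))
  # identical samples -> statistic 0, p 1 (flagged: no pooled variance
  # question arises, means are equal and variance positive)
  r <- two_group_t(d, "intensity", "A", "B")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_raw, 1)
  dz <- two_group_dataset(c(5, 5, 5), c(5, 5, 5))
  rz <- two_group_t(dz, "intensity", "A", "B")
  expect_equal(rz$statistic, 0)
  expect_equal(rz$p_raw, 1)
  expect_true(rz$degenerate)
  dz2 <- two_group_dataset(c(5, 5), c(7, 7))
  rz2 <- two_group_t(dz2, "intensity", "A", "B")
  expect_true(rz2$degenerate)
  expect_equal(rz2$p_raw, 0)
  # type-I calibration
  rej <- vapply(1:1000, function(seed) {
    set.seed(seed)
    dd <- two_group_dataset(stats::rnorm(50), stats::rnorm(50))
    two_group_t(dd, "intensity", "A", "B")$p_raw <= 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("simulated t-test power matches the noncentral-t closed form", {
  # 2 SD shift, n = 12 vs 10
  n1 <- 12; n2 <- 10; delta <- 2
  ncp <- delta / sqrt(1 / n1 + 1 / n2)
  df <- n1 + n2 - 2
  crit <- stats::qt(0.975, df)
  power_cf <- 1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
  hits <- vapply(1:3000, function(seed) {
    set.seed(seed)
    d <- two_group_dataset(stats::rnorm(n1, delta), stats::rnorm(n2))
    two_group_t(d, "intensity", "A", "B")$p_raw <= 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - power_cf), 0.02)
})

test_that("bleb comparisons feed BH and control the FDR", {
  set.seed(11)
  d <- data.frame(genotype = rep(c("wt", "wt2", "mut"), each = 20),
                  animal_id = rep(1:20, 3),
                  blebs = c(stats::rpois(20, 0.1), stats::rpois(20, 0.1),
                            stats::rpois(20, 3)))
  r <- bleb_defect_tests(assay_dataset(d, "morphology"), "wt")
  expect_true(r$significant[r$comparison == "mut vs wt"])
  # control-identical group: not significant
  expect_false(r$significant[r$comparison == "wt2 vs wt"])
  expect_true(all(r$p_adjusted >= r$p_raw - 1e-12))
  # strong separation is detected across seeds
  hits <- vapply(1:30, function(seed) {
    set.seed(seed)
    dd <- data.frame(genotype = rep(c("wt", "mut"), each = 20),
                     animal_id = rep(1:20, 2),
                     blebs = c(stats::rpois(20, 0.1),
                               stats::rpois(20, 3)))
    bleb_defect_tests(assay_dataset(dd, "morphology"), "wt")$significant
  }, logical(1))
  expect_gte(mean(hits), 0.99)
  # complete-null FDR: mean false-discovery proportion <= 5% (+ MC slack)
  fdp <- vapply(1:300, function(seed) {
    set.seed(seed)
    dd <- data.frame(genotype = rep(c("wt", paste0("v", 1:12)), each = 12),
                     animal_id = rep(1:12, 13),
                     blebs = stats::rpois(156, 1))
    r <- bleb_defect_tests(assay_dataset(dd, "morphology"), "wt")
    mean(r$significant)
  }, numeric(1))
  expect_lte(mean(fdp), 0.07)
})
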