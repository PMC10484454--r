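# Independent oracles used to pin expected values, kept deliberately
# separate from the package implementations they check.

# Benjamini-Hochberg step-up by its definition: adj_(i) = min over j >= i
# of m * p_(j) / j, capped at 1, mapped back to input order.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Pearson chi-squared on a 2x2 table by the closed-form formula
pearson_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# mean of a normal truncated below at zero
truncnorm0_mean <- function(mu, sd) {
  a <- -mu / sd
  mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

# generative mean of the swimming mixture (truncated components)
swim_mixture_mean <- function(profile) {
  profile$impaired_fraction *
    truncnorm0_mean(profile$swim_mean_bad, profile$swim_sd) +
    (1 - profile$impaired_fraction) *
    truncnorm0_mean(profile$swim_mean_ok, profile$swim_sd)
}

# tiny deterministic assay table builders
swim_records <- function(genotype, bbps) {
  assay_dataset(data.frame(genotype = genotype,
                           animal_id = seq_along(bbps), bbps = bbps,
                           stringsAsFactors = FALSE), "swimming")
}

viability_records <- function(genotype, brood, unhatched) {
  assay_dataset(data.frame(genotype = genotype,
                           animal_id = seq_along(brood),
                           brood = as.integer(brood),
                           unhatched = as.integer(unhatched),
                           stringsAsFactors = FALSE), "viability")
}

two_group_dataset <- function(a, b, labels = c("A", "B"),
                              assay = "fluorescence",
                              value = "intensity") {
  d <- data.frame(genotype = rep(labels, c(length(a), length(b))),
                  animal_id = c(seq_along(a), seq_along(b)),
                  stringsAsFactors = FALSE)
  d[[value]] <- c(a, b)
  assay_dataset(d, assay)
}

fixture_workbook_path <- function() {
  system.file("extdata", "s1_synthetic_workbook.csv",
              package = "wormlamin")
}
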