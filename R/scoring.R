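# Pathogenicity scoring rubric: viability (0/1/2), swimming (0/2),
# nuclear migration (0/1, may be missing), summed to a total score with a
# severity classification (severe = total >= 2, the pattern of variants
# affecting both skeletal and cardiac muscle).

#' Worm/human variant label aliases and clinical classes
#'
#' The bundled mapping between C. elegans LMN-1 residue labels (the
#' package's primary keys) and the homologous human LMNA residue labels,
#' with the clinical classification of the corresponding human variant.
#'
#' @return A data frame with `worm`, `human`, `clinical_class`.
#' @export
variant_aliases <- function() {
  data.frame(
    worm = c("N53S", "Y59C", "R64P", "E358K", "L535P",
             "E96K", "E175K", "R204W",
             "K284Q", "K331Q", "G407D", "G528R"),
    human = c("N39S", "Y45C", "R50P", "E358K", "L530P",
              "E82K", "E161K", "R190W",
              "K270Q", "R331Q", "S407D", "G523R"),
    clinical_class = c(rep("skeletal_and_cardiac", 5),
                       rep("cardiac_only", 3), rep("vus", 4)),
    stringsAsFactors = FALSE)
}

#' Summarize a viability dataset for one genotype
#'
#' @param dataset A viability [assay_dataset()].
#' @param genotype Genotype label.
#' @return A list with `n_mothers`, `n_sterile`, `total_brood`,
#'   `total_hatched`, `mean_brood`, `mean_lethality_pct` (sterile mothers
#'   excluded from the lethality mean), `all_sterile`, `no_viable_offspring`.
#' @export
summarize_viability <- function(dataset, genotype) {
  d <- dataset[dataset$genotype == genotype, , drop = FALSE]
  if (!nrow(d)) stop("no viability records for '", genotype, "'",
                     call. = FALSE)
  leth <- percent_lethality(d$unhatched, d$brood)
  list(n_mothers = nrow(d),
       n_sterile = sum(d$brood == 0),
       total_brood = sum(d$brood),
       total_hatched = sum(d$brood - d$unhatched),
       mean_brood = mean(d$brood),
       mean_lethality_pct = if (all(is.na(leth))) NA_real_
                            else mean(leth, na.rm = TRUE),
       all_sterile = all(d$brood == 0),
       no_viable_offspring = sum(d$brood - d$unhatched) == 0)
}

#' Viability component score (0, 1 or 2)
#'
#' Score 2 for homozygous inviable strains — all mothers sterile, or eggs
#' laid but none viable; score 1 for decreased viability — brood size or
#' embryonic lethality significantly worse than control (Dunnett-adjusted
#' p <= alpha in the worse direction); score 0 otherwise.
#'
#' @param summary A [summarize_viability()] list for the variant.
#' @param brood_stat One-row `stat_result` for the variant's brood size vs
#'   control (estimate = variant - control).
#' @param lethality_stat Optional one-row `stat_result` for the variant's
#'   percent lethality vs control; may be `NULL` (e.g. all mothers
#'   sterile).
#' @param alpha Significance level.
#' @return Integer 0, 1 or 2.
#' @export
viability_score <- function(summary, brood_stat, lethality_stat = NULL,
                            alpha = 0.05) {
  if (summary$all_sterile || summary$no_viable_offspring) return(2L)
  if (is.null(brood_stat))
    stop("missing control comparison for brood size", call. = FALSE)
  worse_brood <- isTRUE(brood_stat$significant) && brood_stat$estimate < 0
  worse_leth <- !is.null(lethality_stat) &&
    isTRUE(lethality_stat$significant) && lethality_stat$estimate > 0
  if (worse_brood || worse_leth) 1L else 0L
}

#' Swimming component score (0 or 2)
#'
#' Score 2 when strictly more than `cutoff` (default 30%) of animals show
#' a severe swimming defect (BBPS at or below the defect threshold);
#' score 0 otherwise. A fraction exactly at the cutoff scores 0 (the
#' inequality is strict).
#'
#' @param fraction Defect fraction in `[0, 1]` from [defect_fraction()].
#' @param cutoff Fraction cutoff.
#' @return Integer 0 or 2.
#' @export
swimming_score <- function(fraction, cutoff = 0.30) {
  stopifnot(is.numeric(fraction), length(fraction) == 1L,
            fraction >= 0, fraction <= 1)
  if (fraction > cutoff) 2L else 0L
}

#' Nuclear-migration component score (0, 1 or missing)
#'
#' Score 1 for a defective nuclear migration: Tukey-adjusted p <= alpha
#' with the variant's mean mislocalized-nucleus count exceeding the
#' control's; 0 otherwise. When no migration data exist for the variant
#' the component is missing (`NA`), contributes 0 to the total and is
#' reported as "N/A".
#'
#' @param tukey_stat One-row `stat_result` for variant vs control
#'   (estimate = variant - control), or `NULL`.
#' @param data_available Whether migration data exist for the variant.
#' @param alpha Significance level.
#' @return Integer 0 or 1, or `NA` when data are unavailable.
#' @export
migration_score <- function(tukey_stat, data_available = TRUE,
                            alpha = 0.05) {
  if (!data_available || is.null(tukey_stat)) return(NA_integer_)
  if (isTRUE(tukey_stat$significant) && tukey_stat$estimate > 0) 1L else 0L
}

#' Assemble a variant score card
#'
#' Sums the non-missing component scores and classifies the variant:
#' severe (skeletal-and-cardiac pattern) when the total is at least 2,
#' mild/cardiac-only otherwise.
#'
#' @param variant Worm residue label (e.g. `"Y59C"`).
#' @param viability,swimming,migration Component scores; `migration` may
#'   be `NA` (missing data).
#' @param human_label Optional human residue label; looked up from
#'   [variant_aliases()] when `NULL`.
#' @param evidence Optional list of per-component provenance (fractions,
#'   p-values) stored on the card.
#' @return A one-row data frame of class `variant_scorecard`.
#' @export
total_score <- function(variant, viability, swimming, migration,
                        human_label = NULL, evidence = NULL) {
  stopifnot(viability %in% 0:2, swimming %in% c(0L, 2L),
            is.na(migration) || migration %in% 0:1)
  if (is.null(human_label)) {
    al <- variant_aliases()
    hit <- match(variant, al$worm)
    human_label <- if (is.na(hit)) NA_character_ else al$human[hit]
  }
  total <- viability + swimming + if (is.na(migration)) 0L else migration
  card <- data.frame(
    human_label = human_label, variant = variant,
    viability = as.integer(viability), swimming = as.integer(swimming),
    migration = as.integer(migration), total = as.integer(total),
    classification = if (total >= 2) "severe_skeletal_and_cardiac"
                     else "mild_or_cardiac_only",
    stringsAsFactors = FALSE)
  attr(card, "evidence") <- evidence
  class(card) <- c("variant_scorecard", "data.frame")
  card
}

#' Score all variants of an experiment
#'
#' The headline analysis: runs the per-assay statistics (brood-size and
#' lethality ANOVA with Dunnett correction, swimming defect fractions
#' with chi-squared tests, migration ANOVA with Tukey correction) and
#' applies the scoring rubric to every non-control genotype, producing a
#' score-card table with one row per variant.
#'
#' @param datasets Named list of [assay_dataset()] objects with entries
#'   `viability` and `swimming` (required) and `migration` (optional, may
#'   cover only a subset of genotypes).
#' @param control_genotype Control genotype label.
#' @param config A [default_config()]-style list; `alpha`,
#'   `bbps_threshold` and `swim_fraction_cutoff` are used.
#' @return An object of class `variant_scorecards`: a data frame with one
#'   row per variant (`human_label`, `variant`, component scores, `total`,
#'   `classification`) and an `evidence` attribute holding the fractions
#'   and test results behind each component. Scoring is deterministic
#'   given data and config.
#' @export
score_variants <- function(datasets, control_genotype,
                           config = default_config()) {
  for (need in c("viability", "swimming"))
    if (is.null(datasets[[need]]))
      stop("datasets must include a '", need, "' assay", call. = FALSE)
  alpha <- config$alpha
  via <- datasets$viability
  swim <- datasets$swimming
  mig <- datasets$migration
  all_geno <- unique(c(via$genotype, swim$genotype,
                       if (!is.null(mig)) mig$genotype))
  if (!control_genotype %in% all_geno)
    stop("control genotype '", control_genotype, "' absent from data",
         call. = FALSE)
  variants <- setdiff(unique(c(via$genotype, swim$genotype)),
                      control_genotype)
  # keep first-appearance order of the viability table, then extras
  variants <- c(intersect(unique(via$genotype), variants),
                setdiff(variants, unique(via$genotype)))
  if (!length(variants)) stop("no variant genotypes to score", call. = FALSE)

  # viability statistics: Dunnett on brood over all genotypes; Dunnett on
  # per-mother lethality over genotypes with at least 2 laying mothers
  brood_stats <- anova_dunnett(via, "brood", control_genotype, alpha)
  leth_df <- via[via$brood > 0, , drop = FALSE]
  leth_df$lethality_pct <- 100 * leth_df$unhatched / leth_df$brood
  leth_counts <- table(leth_df$genotype)
  leth_ok <- names(leth_counts)[leth_counts >= 2]
  leth_stats <- NULL
  if (control_genotype %in% leth_ok && length(leth_ok) > 1)
    leth_stats <- anova_dunnett(
      leth_df[leth_df$genotype %in% leth_ok, , drop = FALSE],
      "lethality_pct", control_genotype, alpha)

  mig_stats <- NULL
  if (!is.null(mig) && length(unique(mig$genotype)) >= 2 &&
      control_genotype %in% mig$genotype)
    mig_stats <- anova_tukey(mig, "mislocalized", alpha)

  pick <- function(stats, variant) {
    if (is.null(stats)) return(NULL)
    hit <- stats[stats$comparison %in%
                   c(paste(variant, "vs", control_genotype),
                     paste(control_genotype, "vs", variant)), ,
                 drop = FALSE]
    if (!nrow(hit)) return(NULL)
    # orient estimate as variant - control
    if (hit$comparison[1] == paste(control_genotype, "vs", variant))
      hit$estimate <- -hit$estimate
    hit[1, , drop = FALSE]
  }

  wt_swim <- swim[swim$genotype == control_genotype, , drop = FALSE]
  cards <- list()
  evidence <- list()
  for (v in variants) {
    if (!v %in% via$genotype)
      stop("variant '", v, "' has no viability data", call. = FALSE)
    if (!v %in% swim$genotype)
      stop("variant '", v, "' has no swimming data", call. = FALSE)
    vs <- summarize_viability(via, v)
    bstat <- pick(brood_stats, v)
    lstat <- pick(leth_stats, v)
    v_score <- viability_score(vs, bstat, lstat, alpha)

    v_swim <- swim[swim$genotype == v, , drop = FALSE]
    frac <- defect_fraction(v_swim, threshold = config$bbps_threshold)
    s_score <- swimming_score(frac, cutoff = config$swim_fraction_cutoff)
    chi <- swim_defect_test(v_swim, wt_swim,
                            threshold = config$bbps_threshold,
                            alpha = alpha)

    has_mig <- !is.null(mig) && v %in% mig$genotype
    mstat <- if (has_mig) pick(mig_stats, v) else NULL
    m_score <- migration_score(mstat, data_available = has_mig,
                               alpha = alpha)

    ev <- list(viability = c(vs,
                             list(brood_stat = bstat,
                                  lethality_stat = lstat)),
               swimming = list(defect_fraction = frac,
                               threshold = config$bbps_threshold,
                               chi_squared = chi),
               migration = list(stat = mstat, data_available = has_mig))
    cards[[v]] <- total_score(v, v_score, s_score, m_score, evidence = ev)
    evidence[[v]] <- ev
  }
  out <- do.call(rbind, lapply(cards, as.data.frame))
  rownames(out) <- NULL
  attr(out, "evidence") <- evidence
  attr(out, "control_genotype") <- control_genotype
  class(out) <- c("variant_scorecards", "data.frame")
  out
}

#' @export
print.variant_scorecards <- function(x, ...) {
  cat("Phenotypic scoring of lamin variant models",
      "(control:", attr(x, "control_genotype"), ")\n\n")
  y <- as.data.frame(x)
  y$migration <- ifelse(is.na(y$migration), "N/A", y$migration)
  names(y) <- c("Human", "Worm", "Viability", "Swimming", "Migration",
                "Score", "Classification")
  print(y, row.names = FALSE)
  cat("\nClassification: severe (skeletal + cardiac pattern) when",
      "Score >= 2.\n")
  invisible(x)
}

#' @export
summary.variant_scorecards <- function(object, ...) {
  cat(nrow(object), "variants scored;",
      sum(object$classification == "severe_skeletal_and_cardiac"),
      "classified severe (total >= 2),",
      sum(is.na(object$migration)), "with missing migration data.\n")
  invisible(object)
}
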