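# Molecular-assay normalizations (2^-ddCt, ELISA per total protein) and
# the animal-level aggregation / statistics contract: statistics run on
# animal means, sex is modelled first and pooled only when it shows no
# main effect, and pairwise comparisons are Sidak-adjusted.

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = Ct(target) - Ct(reference)`; `ddCt = dCt - mean control dCt`;
#' fold change `= 2^-ddCt`.
#'
#' @param delta_ct Per-sample dCt values.
#' @param control_mean_dct Mean dCt of the control group.
#' @return Fold changes relative to control.
#' @export
ddct_fold_change <- function(delta_ct, control_mean_dct) {
  2^(-(delta_ct - control_mean_dct))
}

#' Collapse Ct triplicates to per-sample values
#'
#' Replicates more than `max_dev` cycles from the triplicate median are
#' discarded (and logged), the rest averaged.  Samples with missing Ct are
#' excluded with a log entry.
#'
#' @param ct Numeric replicate Ct values for one sample/gene.
#' @param max_dev Maximum deviation from the replicate median (cycles).
#' @param label Sample label for the log.
#' @return Mean of the retained replicates, or `NA` if none usable.
#' @export
collapse_triplicates <- function(ct, max_dev = 0.5, label = "sample") {
  ct <- ct[is.finite(ct)]
  if (length(ct) == 0L) {
    mq_log("qpcr", "%s: no usable Ct replicates — sample excluded", label)
    return(NA_real_)
  }
  keep <- abs(ct - median(ct)) <= max_dev
  if (any(!keep))
    mq_log("qpcr", "%s: discarded %d replicate(s) > %.2f cycles from the median",
           label, sum(!keep), max_dev)
  mean(ct[keep])
}

#' Per-sample 2^-ddCt fold changes from a triplicate-long Ct table
#'
#' @param df Data frame with `sample_id`, `group`, `ct_target`,
#'   `ct_reference` (replicate rows per sample).
#' @param control_group Name of the control group.
#' @param max_dev Triplicate outlier rule (cycles from the median).
#' @return One row per retained sample: `delta_ct`, `ddct`, `fold_change`.
#' @export
ddct_table <- function(df, control_group, max_dev = 0.5) {
  per <- do.call(rbind, lapply(split(df, df$sample_id), function(s) {
    data.frame(
      sample_id = s$sample_id[1],
      group = s$group[1],
      ct_target = collapse_triplicates(s$ct_target, max_dev, paste0(s$sample_id[1], "/target")),
      ct_reference = collapse_triplicates(s$ct_reference, max_dev, paste0(s$sample_id[1], "/reference"))
    )
  }))
  drop <- !is.finite(per$ct_target) | !is.finite(per$ct_reference)
  if (any(drop)) {
    mq_log("qpcr", "excluded %d sample(s) with missing Ct", sum(drop))
    per <- per[!drop, , drop = FALSE]
  }
  per$delta_ct <- per$ct_target - per$ct_reference
  ctl <- per$delta_ct[per$group == control_group]
  if (length(ctl) == 0L) stop("no samples in control group '", control_group, "'")
  control_mean_dct <- mean(ctl)
  per$ddct <- per$delta_ct - control_mean_dct
  per$fold_change <- ddct_fold_change(per$delta_ct, control_mean_dct)
  rownames(per) <- NULL
  per
}

#' ELISA concentration normalized to total protein
#'
#' `(concentration (pg/mL) * 100) / (total protein (mg/mL) * 1000)`,
#' i.e. pg of analyte per 100 mg of total protein.
#'
#' @param pg_per_ml Analyte concentration (pg/mL), >= 0.
#' @param protein_mg_per_ml Total protein (mg/mL), > 0.
#' @return pg per 100 mg protein.
#' @export
elisa_normalize <- function(pg_per_ml, protein_mg_per_ml) {
  if (any(!is.finite(protein_mg_per_ml)) || any(protein_mg_per_ml <= 0))
    stop("total protein must be strictly positive")
  if (any(pg_per_ml < 0)) stop("concentration must be non-negative")
  (pg_per_ml * 100) / (protein_mg_per_ml * 1000)
}

#' Aggregate per-cell or per-image measures to animal means
#'
#' The animal, not the cell, is the unit of analysis: group statistics run
#' on these unweighted per-animal means.
#'
#' @param cell_table Data frame with an `animal_id` column.
#' @param measure Column to average.
#' @param keep Extra columns (constant within animal, e.g. group labels)
#'   carried through.
#' @return One row per animal: `animal_id`, kept columns, `mean_value`,
#'   `n_units`.
#' @export
aggregate_to_animal <- function(cell_table, measure, keep = character(0)) {
  if (!"animal_id" %in% names(cell_table)) stop("cell_table needs an animal_id column")
  out <- do.call(rbind, lapply(split(cell_table, cell_table$animal_id), function(s) {
    row <- data.frame(animal_id = s$animal_id[1])
    for (k in keep) {
      u <- unique(s[[k]])
      if (length(u) != 1L) stop("column '", k, "' is not constant within animal ", row$animal_id)
      row[[k]] <- u
    }
    row$mean_value <- mean(s[[measure]])
    row$n_units <- nrow(s)
    row
  }))
  rownames(out) <- NULL
  out
}

#' Group comparison on animal summaries with the sex-first contract
#'
#' Fits a factorial linear model including sex (full interaction with the
#' design factors); if sex shows no main effect at `alpha` the model is
#' refit pooled across sexes.  Factor effects come from the final ANOVA
#' table and pairwise comparisons of `compare` are Sidak-adjusted
#' (via estimated marginal means).  The sex-pooling decision is logged and
#' returned.
#'
#' @param summaries Data frame of animal-level rows (e.g.
#'   [aggregate_to_animal()] output).
#' @param design List: `response` (column name), `factors` (character
#'   vector of factor columns, e.g. `c("age", "genotype")`), optional
#'   `compare` (factor for pairwise contrasts, default the first), and
#'   `sex` (column name, default `"sex"` if present).
#' @param alpha Significance level for the sex main effect (default 0.05).
#' @return A `group_comparison`: `effects` (ANOVA table), `pairwise`
#'   (Sidak-adjusted contrasts), `sex_pooled`, `sex_p`, `fit`.
#' @export
group_compare <- function(summaries, design, alpha = 0.05) {
  response <- design$response
  factors <- design$factors
  compare <- if (!is.null(design$compare)) design$compare else factors[1]
  sex_col <- if (!is.null(design$sex)) design$sex else if ("sex" %in% names(summaries)) "sex" else NULL
  if (length(factors) == 0L) stop("design$factors must name at least one factor")
  for (f in c(factors, sex_col)) {
    summaries[[f]] <- factor(summaries[[f]])
    if (nlevels(summaries[[f]]) < 2L)
      stop("singular design: factor '", f, "' has fewer than 2 levels")
  }
  base_term <- paste(factors, collapse = " * ")

  sex_pooled <- NA
  sex_p <- NA_real_
  if (!is.null(sex_col)) {
    f_full <- as.formula(paste(response, "~", base_term, "*", sex_col))
    fit_full <- lm(f_full, data = summaries)
    an_full <- anova(fit_full)
    if (!sex_col %in% rownames(an_full)) stop("singular design: sex effect not estimable")
    sex_p <- an_full[sex_col, "Pr(>F)"]
    if (!is.finite(sex_p)) stop("singular design: sex effect not testable")
    sex_pooled <- sex_p >= alpha
    mq_log("stats", "sex main effect p = %.3g -> %s", sex_p,
           if (sex_pooled) "pooling sexes" else "keeping sex in the model")
    fit <- if (sex_pooled) lm(as.formula(paste(response, "~", base_term)), data = summaries) else fit_full
  } else {
    fit <- lm(as.formula(paste(response, "~", base_term)), data = summaries)
  }
  if (any(is.na(stats::coef(fit))))
    stop("singular design: aliased coefficients in the final model")
  effects <- as.data.frame(anova(fit))

  emm <- emmeans::emmeans(fit, stats::as.formula(paste("~", compare)))
  pw <- as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = "sidak"))

  structure(list(
    effects = effects,
    pairwise = pw,
    compare = compare,
    sex_pooled = sex_pooled,
    sex_p = sex_p,
    fit = fit
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  if (!is.na(x$sex_pooled))
    cat(sprintf("  sex main effect p = %.3g (%s)\n", x$sex_p,
                if (x$sex_pooled) "pooled" else "retained"))
  print(x$effects)
  cat("  Sidak-adjusted pairwise contrasts of", x$compare, ":\n")
  print(x$pairwise)
  invisible(x)
}

#' P-value of a factor's main effect in a group comparison
#'
#' @param gc A [group_compare()] result.
#' @param factor Factor name; default the comparison factor.
#' @return The ANOVA p-value.
#' @export
effect_p_value <- function(gc, factor = NULL) {
  if (is.null(factor)) factor <- gc$compare
  if (!factor %in% rownames(gc$effects)) stop("no such factor in the effects table")
  gc$effects[factor, "Pr(>F)"]
}
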