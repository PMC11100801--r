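# Tabular generators: qPCR/ELISA assay fixtures with known fold changes,
# animal-level group studies for the statistics contract, and per-cell
# marker-intensity mixtures for the Hi/Mid/Lo classifier.

#' Generate a qPCR + ELISA assay table with known fold changes
#'
#' Ct values follow the 2^-ddCt model: the treated-group target dCt is
#' shifted by `-log2(fold_change)` relative to control.  Each sample is
#' loaded in triplicate with replicate-level jitter.  ELISA rows carry
#' pg/mL and total-protein mg/mL with the same group structure.
#'
#' @param seed Integer seed.
#' @param n_per_group Samples per group.
#' @param fold_changes Named numeric: true target fold change per group;
#'   the first entry is the control group and must be 1.
#' @param dct_control Mean control dCt (target Ct minus reference Ct).
#' @param ct_ref_mean Mean reference-gene (18S) Ct.
#' @param between_sd Between-sample dCt standard deviation.
#' @param replicate_sd Within-triplicate Ct standard deviation.
#' @param elisa_mean Control-group ELISA concentration (pg/mL).
#' @param elisa_fold ELISA fold change in non-control groups.
#' @param elisa_cv,protein_cv Coefficients of variation.
#' @param protein_mean Total protein (mg/mL).
#' @return A data frame in triplicate-long format with attribute `truth`.
#' @export
generate_assay_table <- function(seed = 1L, n_per_group = 6L,
                                 fold_changes = c(control = 1, treated = 4),
                                 dct_control = 10, ct_ref_mean = 12,
                                 between_sd = 0.15, replicate_sd = 0.1,
                                 elisa_mean = 50, elisa_fold = 2,
                                 elisa_cv = 0.2, protein_mean = 2,
                                 protein_cv = 0.1) {
  stopifnot(fold_changes[1] == 1)
  with_stage_seed(seed, "assay", {
    rows <- list()
    sid <- 0L
    for (g in names(fold_changes)) {
      for (i in seq_len(n_per_group)) {
        sid <- sid + 1L
        dct <- dct_control - log2(fold_changes[[g]]) + rnorm(1, 0, between_sd)
        ct_ref <- ct_ref_mean + rnorm(1, 0, between_sd)
        el <- max(0, (if (g == names(fold_changes)[1]) elisa_mean else elisa_mean * elisa_fold) *
                    (1 + rnorm(1, 0, elisa_cv)))
        pr <- max(1e-6, protein_mean * (1 + rnorm(1, 0, protein_cv)))
        rows[[sid]] <- data.frame(
          sample_id = sprintf("s%02d", sid),
          group = g,
          sex = if (i %% 2 == 0) "F" else "M",
          replicate = 1:3,
          ct_target = dct + ct_ref + rnorm(3, 0, replicate_sd),
          ct_reference = ct_ref + rnorm(3, 0, replicate_sd),
          elisa_pg_per_ml = el,
          total_protein_mg_per_ml = pr
        )
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "truth") <- list(fold_changes = fold_changes, elisa_fold = elisa_fold)
    out
  })
}

#' Simulate an animal-level group study
#'
#' One value per animal (e.g. the animal-mean engulfed_norm), normally
#' distributed around the group mean with a fixed between-animal
#' coefficient of variation; sexes are balanced within group.  Used for
#' the type-I and power checks of the statistics contract.
#'
#' @param seed Integer seed.
#' @param n_per_group Animals per group.
#' @param control_mean Control group mean.
#' @param fold_change Multiplicative effect in the second group (1 = null).
#' @param cv Between-animal coefficient of variation (default 0.3, a
#'   typical between-animal spread for imaging endpoints).
#' @param groups Group labels (first = control).
#' @param sex_effect Additive shift applied to males (default 0).
#' @return Data frame with `animal_id`, `group`, `sex`, `value`.
#' @export
simulate_group_study <- function(seed = 1L, n_per_group = 6L,
                                 control_mean = 0.01, fold_change = 2,
                                 cv = 0.3, groups = c("control", "treated"),
                                 sex_effect = 0) {
  with_stage_seed(seed, "group-study", {
    rows <- list()
    aid <- 0L
    for (gi in seq_along(groups)) {
      mu <- control_mean * if (gi == 1L) 1 else fold_change
      for (i in seq_len(n_per_group)) {
        aid <- aid + 1L
        sex <- if (i %% 2 == 0) "F" else "M"
        val <- rnorm(1, mu, cv * mu) + if (sex == "M") sex_effect else 0
        rows[[aid]] <- data.frame(
          animal_id = sprintf("a%02d", aid),
          group = groups[gi], sex = sex,
          value = max(val, 1e-9)
        )
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a three-component per-cell intensity mixture
#'
#' Normalized marker values drawn from a Lo/Mid/Hi Gaussian mixture with a
#' stated separation, with true class labels attached; the fixture for the
#' heterogeneity classifier's recovery tests.
#'
#' @param seed Integer seed.
#' @param n_per_class Cells per class.
#' @param means Named class means (ascending).
#' @param sd Common within-class standard deviation.
#' @return Data frame with `value` and `true_class`, in random order.
#' @export
generate_intensity_mixture <- function(seed = 1L, n_per_class = 60L,
                                       means = c(Lo = 0.5, Mid = 1.0, Hi = 1.5),
                                       sd = 0.1) {
  with_stage_seed(seed, "intensity-mixture", {
    df <- do.call(rbind, lapply(names(means), function(cl) {
      data.frame(value = rnorm(n_per_class, means[[cl]], sd), true_class = cl)
    }))
    df[sample.int(nrow(df)), , drop = FALSE]
  })
}
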