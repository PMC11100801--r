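# Masked mean-gray-value quantification and the per-cell Hi/Mid/Lo
# heterogeneity classifier with animal-level percentages.

#' Mean gray value of an image channel within a mask
#'
#' @param x A [volume_image()] (with `channel`) or a numeric 3D array.
#' @param mask A [binary_mask()] on the same lattice.
#' @param channel Channel name/index when `x` is a volume.
#' @return Arithmetic mean of the intensities at true voxels.
#' @export
masked_mean_gray <- function(x, mask, channel = NULL) {
  arr <- if (inherits(x, "volume_image")) get_channel(x, channel) else x
  if (!identical(dim(arr), dim(mask$data))) stop("mask is not on the image lattice")
  if (!any(mask$data)) stop("empty mask")
  mean(arr[mask$data])
}

#' Per-cell marker intensities normalized to Iba1
#'
#' Measures the Iba1, TMEM119 and CD68 mean gray values inside each cell
#' mask and normalizes the markers to the same cell's Iba1 signal
#' (division by default; subtraction available), controlling for
#' cell-size/process-complexity differences in stain intensity.
#'
#' @param v A [volume_image()].
#' @param cells List of `cell_object`s.
#' @param channels Named channel labels (`iba1`, `tmem`, `cd68`).
#' @param normalize `"divide"` (default) or `"subtract"`.
#' @return Data frame with raw MGVs, normalized values, and ids.
#' @export
intensity_records <- function(v, cells,
                              channels = c(iba1 = "Iba1", tmem = "TMEM119", cd68 = "CD68"),
                              normalize = c("divide", "subtract")) {
  normalize <- match.arg(normalize)
  arrs <- lapply(channels, function(ch) get_channel(v, ch))
  rows <- lapply(cells, function(cell) {
    mgv <- vapply(arrs, function(a) mean(crop_to_cell(a, cell)[cell$mask]), numeric(1))
    if (mgv[["iba1"]] <= 0) stop("Iba1 MGV must be positive for normalization")
    norm <- if (normalize == "divide") mgv / mgv[["iba1"]] else mgv - mgv[["iba1"]]
    data.frame(
      cell_id = cell$cell_id, animal_id = cell$animal_id, image_id = cell$image_id,
      iba1_mgv = mgv[["iba1"]], tmem_mgv = mgv[["tmem"]], cd68_mgv = mgv[["cd68"]],
      tmem_norm = norm[["tmem"]], cd68_norm = norm[["cd68"]]
    )
  })
  do.call(rbind, rows)
}

#' Derive Lo/Mid/Hi cutoffs from a pooled value distribution
#'
#' Rules: `"tertile"` uses the 33.3/66.7 percentiles; `"valley"` finds the
#' two deepest antimodes (local minima) of a kernel-smoothed histogram,
#' for distributions with visible subpopulations.  Cutoffs must always be
#' derived from the pooled (all-groups) population, never per group.
#'
#' @param normalized_values Numeric vector (>= 9 finite values).
#' @param rule `"tertile"` or `"valley"`.
#' @return A `cutoff_set`: `lower`, `upper`, `rule`, `n`.
#' @export
derive_cutoffs <- function(normalized_values, rule = c("tertile", "valley")) {
  rule <- match.arg(rule)
  x <- normalized_values[is.finite(normalized_values)]
  if (length(x) < 9L) stop("need at least 9 finite values to derive cutoffs")
  if (diff(range(x)) == 0) stop("all values identical: no class separation")
  if (rule == "tertile") {
    qs <- quantile(x, c(1 / 3, 2 / 3), names = FALSE)
    lower <- qs[1]; upper <- qs[2]
  } else {
    # Sheather-Jones bandwidth resolves close subpopulations that the
    # default rule-of-thumb bandwidth smears together
    de <- tryCatch(density(x, bw = "SJ", n = 512),
                   error = function(e) density(x, n = 512))
    y <- de$y
    # candidate modes: local maxima above 5% of the peak height; adjacent
    # maxima count as separate modes only when a valley deeper than the
    # merge threshold lies between them.  The threshold relaxes in steps
    # (0.75 -> 0.85 -> 0.95 of the smaller flanking peak) until three
    # modes survive: sampling noise makes the valley depth of genuinely
    # separated (>= 4 sd) components overlap the depth of unimodal
    # wiggles, so the strictest depth that still supports three modes is
    # used, and data whose density cannot support three modes at any
    # depth is rejected
    cand <- which(diff(sign(diff(y))) == -2) + 1L
    cand <- cand[y[cand] >= 0.05 * max(y)]
    peaks <- integer(0)
    for (merge_at in c(0.75, 0.85, 0.95)) {
      peaks <- cand
      k <- 1L
      while (k < length(peaks)) {
        span <- peaks[k]:peaks[k + 1L]
        if (min(y[span]) > merge_at * min(y[peaks[k]], y[peaks[k + 1L]])) {
          drop <- if (y[peaks[k]] < y[peaks[k + 1L]]) k else k + 1L
          peaks <- peaks[-drop]
          k <- max(1L, k - 1L)
        } else {
          k <- k + 1L
        }
      }
      if (length(peaks) >= 3L) break
    }
    if (length(peaks) < 3L)
      stop("valley rule: fewer than two antimodes in the smoothed histogram")
    # one antimode per gap between consecutive modes: the density minimum
    antimodes <- vapply(seq_len(length(peaks) - 1L), function(k) {
      span <- peaks[k]:peaks[k + 1L]
      span[which.min(y[span])]
    }, integer(1))
    deepest <- antimodes[order(y[antimodes])[1:2]]
    cut <- sort(de$x[deepest])
    lower <- cut[1]; upper <- cut[2]
  }
  mq_log("heterogeneity", "cutoffs (%s): lower=%.4g upper=%.4g (n=%d)",
         rule, lower, upper, length(x))
  structure(list(lower = lower, upper = upper, rule = rule, n = length(x)),
            class = "cutoff_set")
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat(sprintf("<cutoff_set> rule=%s lower=%.4g upper=%.4g (from n=%d)\n",
              x$rule, x$lower, x$upper, x$n))
  invisible(x)
}

#' Classify values into Lo / Mid / Hi
#'
#' `Lo` strictly below the lower cutoff, `Hi` strictly above the upper
#' cutoff, `Mid` otherwise — boundary values tie inward to `Mid`.
#'
#' @param values Numeric vector.
#' @param cutoffs A [derive_cutoffs()] result.
#' @return Character vector in `{"Lo", "Mid", "Hi"}`.
#' @export
classify_values <- function(values, cutoffs) {
  ifelse(values < cutoffs$lower, "Lo",
         ifelse(values > cutoffs$upper, "Hi", "Mid"))
}

#' Attach per-marker classes and the joint phenotype label
#'
#' Adds `tmem_class` and `cd68_class` from the supplied cutoff sets, plus a
#' `phenotype` label: `CD68Hi.TMEM119Lo` cells are flagged
#' `"phagocytic_non_homeostatic"`, `CD68Lo.TMEM119Hi` cells
#' `"homeostatic"`, all others `"other"`.
#'
#' @param records [intensity_records()] output.
#' @param tmem_cutoffs,cd68_cutoffs [derive_cutoffs()] results from the
#'   pooled population.
#' @return `records` with class and phenotype columns.
#' @export
classify_cells <- function(records, tmem_cutoffs, cd68_cutoffs) {
  records$tmem_class <- classify_values(records$tmem_norm, tmem_cutoffs)
  records$cd68_class <- classify_values(records$cd68_norm, cd68_cutoffs)
  records$phenotype <- ifelse(
    records$cd68_class == "Hi" & records$tmem_class == "Lo", "phagocytic_non_homeostatic",
    ifelse(records$cd68_class == "Lo" & records$tmem_class == "Hi", "homeostatic", "other")
  )
  records
}

#' Per-animal percentages of joint CD68 x TMEM119 classes
#'
#' The sampling plan is 4 cells per image, 3 images per animal: 12 cells.
#' In strict mode an animal with a different cell count is an error; in
#' relaxed mode the available n is used with a warning.  Percentages are
#' reported for all 9 joint categories and each marker's marginals sum to
#' 100.
#'
#' @param records Classified records ([classify_cells()] output) with
#'   `animal_id`.
#' @param strict Enforce the 12-cell plan (default TRUE).
#' @param expected_cells Cells expected per animal (default 12).
#' @return Data frame, one row per animal: `n_cells`, `pct_<cd68>_<tmem>`
#'   for the 9 joint categories, and marginal `pct_cd68_*`, `pct_tmem_*`.
#' @export
animal_percentages <- function(records, strict = TRUE, expected_cells = 12L) {
  lv <- c("Lo", "Mid", "Hi")
  out <- lapply(split(records, records$animal_id), function(df) {
    n <- nrow(df)
    if (n != expected_cells) {
      if (strict) {
        stop("animal ", df$animal_id[1], " has ", n, " cells; expected ",
             expected_cells, " (4 cells x 3 images). Use strict = FALSE to override.")
      }
      warning("animal ", df$animal_id[1], " has ", n, " cells; expected ",
              expected_cells, " — using available n")
    }
    row <- data.frame(animal_id = df$animal_id[1], n_cells = n)
    for (cd in lv) for (tm in lv) {
      row[[sprintf("pct_cd68%s_tmem%s", cd, tm)]] <-
        100 * sum(df$cd68_class == cd & df$tmem_class == tm) / n
    }
    for (cd in lv) row[[sprintf("pct_cd68_%s", cd)]] <- 100 * sum(df$cd68_class == cd) / n
    for (tm in lv) row[[sprintf("pct_tmem_%s", tm)]] <- 100 * sum(df$tmem_class == tm) / n
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
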