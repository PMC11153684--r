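#' Soft classifier score between truth and prediction
#'
#' `d_s(I1, I2) = 1 - mean((I1 - I2)^2)`: one minus the mean squared voxel
#' difference between a binary truth image and a real-valued prediction.
#' For inputs valued in `[0, 1]` the score lies in `[0, 1]`, with 1 for a
#' perfect match.
#'
#' @param truth binary 3D array (values 0/1).
#' @param pred real-valued 3D array, same shape.
#' @return scalar score.
#' @examples
#' soft_score(array(1, c(2, 2, 1)), array(1, c(2, 2, 1))) # 1
#' @export
soft_score <- function(truth, pred) {
  if (!identical(dim(truth), dim(pred)))
    stop("shape mismatch: truth ", paste(dim(truth), collapse = "x"),
         " vs prediction ", paste(dim(pred), collapse = "x"))
  if (!all(truth %in% c(0, 1))) stop("truth image must be binary")
  if (any(!is.finite(pred))) stop("prediction contains non-finite values")
  1 - sum((truth - pred)^2) / length(truth)
}

#' Hard classifier score
#'
#' `d_h(I1, I2, zeta) = d_s(I1, I2|zeta)` where the prediction is binarized
#' at the threshold: each value is replaced by 1 if strictly greater than
#' `zeta`, else 0.
#'
#' @inheritParams soft_score
#' @param zeta threshold applied to the prediction.
#' @return scalar score.
#' @export
hard_score <- function(truth, pred, zeta) {
  if (!identical(dim(truth), dim(pred)))
    stop("shape mismatch: truth ", paste(dim(truth), collapse = "x"),
         " vs prediction ", paste(dim(pred), collapse = "x"))
  soft_score(truth, (pred > zeta) + 0)
}

#' Score a heatmap against a ground-truth metastasis mask
#'
#' Builds the binary truth by dilating the metastasis voxels (absorbing
#' rasterization error of point-like annotations), then computes both the
#' soft and hard classifier scores. The default threshold `zeta` is the
#' uniform-probability baseline `1 / (number of grid points)`.
#'
#' @param truth_mask binary 3D metastasis mask.
#' @param hm a `heatmap` (or a bare prediction array).
#' @param zeta hard-classifier threshold; default `1 / nrow(hm$grid)`.
#' @param dilate_vox dilation radius in voxels applied to the truth (0 = none).
#' @return list with `soft`, `hard`, `zeta`.
#' @export
score_prediction <- function(truth_mask, hm, zeta = NULL, dilate_vox = 1L) {
  pred <- if (inherits(hm, "heatmap")) hm$values else hm
  if (is.null(zeta)) {
    zeta <- if (inherits(hm, "heatmap")) 1 / nrow(hm$grid) else 1 / length(pred)
  }
  truth <- if (dilate_vox > 0) dilate_mask(truth_mask, dilate_vox) else truth_mask
  list(soft = soft_score(truth, pred),
       hard = hard_score(truth, pred, zeta),
       zeta = zeta)
}

dilate_mask <- function(mask, r_vox = 1L) {
  shape <- dim(mask)
  out <- array(0L, shape)
  lin <- which(mask > 0)
  if (!length(lin)) return(out)
  ci <- arrayInd(lin, shape)
  rng <- -r_vox:r_vox
  for (dx in rng) for (dy in rng) for (dz in rng) {
    nb <- cbind(ci[, 1] + dx, ci[, 2] + dy, ci[, 3] + dz)
    nb <- nb[in_bounds(nb, shape), , drop = FALSE]
    out[nb[, 1] + (nb[, 2] - 1) * shape[1] + (nb[, 3] - 1) * shape[1] * shape[2]] <- 1L
  }
  out
}

#' Cohort summary of classifier scores
#'
#' Per-case table plus mean and sample (n-1) standard deviation of the soft
#' and hard scores, in the layout used for multi-patient validation reports.
#'
#' @param scores data.frame with columns `soft` and `hard` (one row per
#'   case), or a list of lists with those elements.
#' @param csv_path optional path to also write the report as CSV.
#' @return object of class `score_report`: list with `per_case` (data.frame
#'   `case, soft, hard`) and `summary` (data.frame `metric, mean, sd`).
#' @export
cohort_summary <- function(scores, csv_path = NULL) {
  if (!is.data.frame(scores)) {
    scores <- do.call(rbind, lapply(scores, function(s)
      data.frame(soft = s$soft, hard = s$hard)))
  }
  if (is.null(scores) || nrow(scores) == 0) stop("empty cohort")
  per_case <- data.frame(case = seq_len(nrow(scores)),
                         soft = scores$soft, hard = scores$hard)
  sd_or_zero <- function(x) if (length(x) > 1) sd(x) else 0
  summ <- data.frame(metric = c("soft", "hard"),
                     mean = c(mean(per_case$soft), mean(per_case$hard)),
                     sd = c(sd_or_zero(per_case$soft), sd_or_zero(per_case$hard)))
  rep <- structure(list(per_case = per_case, summary = summ),
                   class = "score_report")
  if (!is.null(csv_path)) {
    utils::write.csv(per_case, csv_path, row.names = FALSE)
  }
  rep
}

#' @export
print.score_report <- function(x, ...) {
  cat("<score_report> ", nrow(x$per_case), " case(s)\n", sep = "")
  for (k in seq_len(nrow(x$summary))) {
    cat(sprintf("  %s: %.4f +/- %.4f\n", x$summary$metric[k],
                x$summary$mean[k], x$summary$sd[k]))
  }
  invisible(x)
}

#' Dice overlap coefficient
#'
#' `2|A&B| / (|A| + |B|)` between two binary masks; 1 when both are empty.
#'
#' @param a,b binary arrays of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a > 0); sb <- sum(b > 0)
  if (sa + sb == 0) return(1)
  2 * sum(a > 0 & b > 0) / (sa + sb)
}
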