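#' Sample-wise (class A) imputation discrepancy scores
#'
#' Compares imputed values to the ground truth at the masked cells
#' only (observed cells are preserved by construction, so they carry no
#' information about imputation quality): root mean square error, mean
#' absolute error and the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot`, with `SS_tot` taken about the mean of
#' the true masked values.
#'
#' With `standardise = TRUE` (default), each feature's cells are first
#' divided by the standard deviation of that feature's *observed* true
#' values, so that features on large scales do not dominate the pooled
#' error. Note `R^2` can be negative (imputations worse than predicting
#' the mean) and RMSE >= MAE is not guaranteed across features.
#'
#' @param truth Complete ground-truth [mb_dataset()] (or matrix).
#' @param imputed A completed matrix, or an `mb_mimp`; for a
#'   multiple-imputation container, per-completion scores plus their
#'   mean and standard deviation are returned.
#' @param mask The `mb_mask` that was applied.
#' @param standardise Divide each feature by its observed-value
#'   standard deviation before pooling cells across features.
#' @return For a single matrix: list with `rmse`, `mae`, `r_squared`,
#'   `n_cells`. For an `mb_mimp`: list with `per_completion`
#'   (data.frame) and `summary` (mean and sd of each score).
#' @export
class_a_scores <- function(truth, imputed, mask, standardise = TRUE) {
  if (inherits(imputed, "mb_mimp")) {
    per <- lapply(imputed$completions, function(ck) {
      class_a_scores(truth, ck, mask, standardise = standardise)
    })
    df <- data.frame(completion = seq_along(per),
                     rmse = vapply(per, `[[`, numeric(1), "rmse"),
                     mae = vapply(per, `[[`, numeric(1), "mae"),
                     r_squared = vapply(per, `[[`, numeric(1), "r_squared"))
    return(list(per_completion = df,
                summary = data.frame(
                  metric = c("rmse", "mae", "r_squared"),
                  mean = c(mean(df$rmse), mean(df$mae), mean(df$r_squared)),
                  sd = c(sd(df$rmse), sd(df$mae), sd(df$r_squared)))))
  }
  tv <- as_values(truth)
  iv <- as_values(imputed)
  m <- mask_matrix(mask)
  if (!identical(dim(tv), dim(iv)) || !identical(dim(tv), dim(m))) {
    stop_invalid("truth, imputed and mask shapes must agree")
  }
  if (!any(m)) stop_invalid("no masked cells to score")
  if (standardise) {
    scale <- vapply(seq_len(ncol(tv)), function(j) {
      s <- sd(tv[!m[, j], j])
      if (!is.finite(s) || s == 0) 1 else s
    }, numeric(1))
    tv <- sweep(tv, 2, scale, "/")
    iv <- sweep(iv, 2, scale, "/")
  }
  tm <- tv[m]
  im <- iv[m]
  err <- im - tm
  ss_tot <- sum((tm - mean(tm))^2)
  r2 <- if (ss_tot == 0) {
    warning("true masked values are constant; R^2 undefined", call. = FALSE)
    NA_real_
  } else {
    1 - sum(err^2) / ss_tot
  }
  list(rmse = sqrt(mean(err^2)), mae = mean(abs(err)), r_squared = r2,
       n_cells = sum(m))
}
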