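#' PCA of independent swimming variables with axis contributions
#'
#' Principal component analysis of the per-trial kinematic variables:
#' each variable is z-score standardized, the correlation structure is
#' eigendecomposed (via [stats::prcomp()]), and the contribution of
#' variable j to axis k is `100 * loading(j,k)^2 / sum_j loading(j,k)^2`.
#' The default variable set is the eight independent variables — angle of
#' attack, body angle, tail amplitude, maximum curvature and its
#' location, Reynolds number, tail beat frequency and wave speed —
#' excluding derived quantities (Strouhal, fin effort, wavelength).
#' Rows with any missing variable are dropped and listed.
#'
#' When the table has a `speed_bl` column, the first axis is oriented to
#' correlate positively with swimming speed, fixing an otherwise
#' arbitrary sign.
#'
#' @param table trial table (e.g. from [summarize_cohort()]).
#' @param variables character vector of column names to analyse.
#' @return An object of class `kin_pca`: list with `variables`, `scores`,
#'   `loadings`, `percent_variance`, `contributions` (variables x axes,
#'   percent, each axis summing to 100), `n_used`, `dropped_rows`.
#' @export
pca_contributions <- function(table,
                              variables = c("angle_of_attack", "body_angle",
                                            "amplitude", "k_max",
                                            "k_max_loc", "reynolds", "tbf",
                                            "wave_speed")) {
  stopifnot(is.data.frame(table), length(variables) >= 2L)
  missing_cols <- setdiff(variables, names(table))
  if (length(missing_cols))
    stop("variables absent from table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  m <- as.matrix(table[, variables, drop = FALSE])
  complete <- stats::complete.cases(m)
  dropped <- which(!complete)
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 3L)
    stop("need at least 3 complete rows for PCA", call. = FALSE)
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant variable(s): ",
         paste(variables[sds == 0], collapse = ", "), call. = FALSE)

  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  pct_var <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  contrib <- sweep(pc$rotation^2, 2L, colSums(pc$rotation^2), `/`) * 100

  scores <- pc$x
  if ("speed_bl" %in% names(table)) {
    sp <- table$speed_bl[complete]
    if (stats::sd(sp) > 0 &&
        stats::cor(scores[, 1L], sp) < 0) {
      scores[, 1L] <- -scores[, 1L]
      pc$rotation[, 1L] <- -pc$rotation[, 1L]
    }
  }

  structure(
    list(variables = variables, scores = scores, loadings = pc$rotation,
         percent_variance = pct_var, contributions = contrib,
         n_used = nrow(m), dropped_rows = dropped),
    class = "kin_pca"
  )
}

#' @export
print.kin_pca <- function(x, ...) {
  cat(sprintf("PCA of %d swimming variables over %d trials\n",
              length(x$variables), x$n_used))
  cat(sprintf("  first two axes: %.1f%% of total variance\n",
              sum(x$percent_variance[1:2])))
  top <- sort(x$contributions[, 1L], decreasing = TRUE)[1:4]
  cat("  top PC1 contributions: ",
      paste(sprintf("%s %.1f%%", names(top), top), collapse = ", "), "\n",
      sep = "")
  if (length(x$dropped_rows))
    cat(sprintf("  %d row(s) dropped for missing variables\n",
                length(x$dropped_rows)))
  invisible(x)
}
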