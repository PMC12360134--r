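#' Full cross-speed statistical report
#'
#' For each kinematic variable: runs the assumption gate (Levene +
#' Shapiro-Wilk on the additive-model residuals), fits the chosen test
#' (parametric repeated-measures ANOVA or aligned-rank-transform ANOVA),
#' and computes Tukey-adjusted pairwise speed contrasts with compact
#' letter display.
#'
#' @param table trial table (columns `individual`, `speed_bl`, variables).
#' @param variables variables to test (default: the nine per-trial
#'   kinematic variables).
#' @param alpha significance level (default 0.05).
#' @return An object of class `stats_report`: list with `tests` (one row
#'   per variable: `variable`, `levene_p`, `shapiro_p`, `chosen_test`,
#'   `F`, `df_num`, `df_den`, `p`), `letters` (per variable x speed:
#'   `mean`, `sd`, `n`, `letters`), `fits` (the `speed_anova` objects)
#'   and `alpha`.
#' @export
stats_report <- function(table,
                         variables = c("tbf", "amplitude", "wave_speed",
                                       "wavelength", "k_max", "k_max_loc",
                                       "fin_effort", "body_angle",
                                       "angle_of_attack"),
                         alpha = 0.05) {
  variables <- intersect(variables, names(table))
  tests <- vector("list", length(variables))
  letters_tabs <- vector("list", length(variables))
  fits <- vector("list", length(variables))
  names(fits) <- variables
  for (i in seq_along(variables)) {
    v <- variables[i]
    gate <- assumption_gate(table, v, alpha = alpha)
    fit <- if (gate$chosen_test == "RM-ANOVA") rm_anova(table, v)
           else art_anova(table, v)
    fits[[v]] <- fit
    tests[[i]] <- data.frame(
      variable = v, levene_p = gate$levene_p, shapiro_p = gate$shapiro_p,
      chosen_test = gate$chosen_test, F = fit$F,
      df_num = fit$df_num, df_den = fit$df_den, p = fit$p,
      stringsAsFactors = FALSE)
    let <- tukey_letters(fit, alpha = alpha)
    agg_mean <- tapply(table[[v]], table$speed_bl, mean, na.rm = TRUE)
    agg_sd <- tapply(table[[v]], table$speed_bl, stats::sd, na.rm = TRUE)
    agg_n <- tapply(is.finite(table[[v]]), table$speed_bl, sum)
    sp <- as.numeric(names(agg_mean))
    letters_tabs[[i]] <- data.frame(
      variable = v, speed_bl = sp,
      mean = as.numeric(agg_mean), sd = as.numeric(agg_sd),
      n = as.integer(agg_n),
      letters = let$letters[match(as.character(sp), let$speed)],
      stringsAsFactors = FALSE)
  }
  structure(
    list(tests = do.call(rbind, tests),
         letters = do.call(rbind, letters_tabs),
         fits = fits, alpha = alpha),
    class = "stats_report"
  )
}

#' @export
print.stats_report <- function(x, ...) {
  cat("Cross-speed statistical report (alpha =", x$alpha, ")\n\n")
  df <- x$tests
  df$F <- sprintf("%.2f", df$F)
  df$p <- format.pval(df$p, digits = 3, eps = 1e-3)
  df$levene_p <- sprintf("%.3f", df$levene_p)
  df$shapiro_p <- sprintf("%.3f", df$shapiro_p)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Per-speed summary table with letter groups
#'
#' Mean, standard deviation and compact letter group for each speed, for
#' the headline variables tail beat frequency, wave speed, fin effort and
#' body angle, formatted as "mean +/- SD (letters)".
#'
#' @param table trial table.
#' @param report optional precomputed [stats_report()] covering the
#'   requested variables (computed if `NULL`).
#' @param variables variables to tabulate.
#' @return A data frame, one row per speed, one formatted column per
#'   variable; the numeric per-variable tables are attached as attribute
#'   `numeric`.
#' @export
summary_table <- function(table, report = NULL,
                          variables = c("tbf", "wave_speed", "fin_effort",
                                        "body_angle")) {
  if (is.null(report))
    report <- stats_report(table, variables = variables)
  let <- report$letters[report$letters$variable %in% variables, ,
                        drop = FALSE]
  speeds <- sort(unique(let$speed_bl))
  out <- data.frame(speed_bl = speeds)
  for (v in variables) {
    lv <- let[let$variable == v, , drop = FALSE]
    lv <- lv[match(speeds, lv$speed_bl), , drop = FALSE]
    out[[v]] <- sprintf("%.2f ± %.2f (%s)", lv$mean, lv$sd, lv$letters)
  }
  attr(out, "numeric") <- let
  out
}

#' Per-trial Strouhal-Reynolds table
#'
#' Lists each trial's Reynolds number, Strouhal number and speed with a
#' flag marking the optimal propulsive-efficiency band St in [0.2, 0.4].
#'
#' @param table trial table with `reynolds`, `strouhal`, `speed_bl`.
#' @param band optimal Strouhal band (default `c(0.2, 0.4)`).
#' @return Data frame with columns `trial_id` (if present), `speed_bl`,
#'   `reynolds`, `strouhal`, `st_in_range`.
#' @export
st_re_table <- function(table, band = c(0.2, 0.4)) {
  stopifnot(all(c("reynolds", "strouhal", "speed_bl") %in% names(table)))
  out <- data.frame(
    speed_bl = table$speed_bl,
    reynolds = table$reynolds,
    strouhal = table$strouhal,
    st_in_range = table$strouhal >= band[1L] & table$strouhal <= band[2L])
  if ("trial_id" %in% names(table))
    out <- cbind(trial_id = table$trial_id, out)
  out
}
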