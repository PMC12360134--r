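# Cross-speed comparison: individual-blocked ANOVA, parametric or on
# aligned ranks, chosen by an assumption gate.

.prep_speed_table <- function(table, variable) {
  stopifnot(is.data.frame(table), variable %in% names(table),
            all(c("individual", "speed_bl") %in% names(table)))
  dat <- data.frame(
    y = table[[variable]],
    individual = factor(table$individual),
    speed = factor(table$speed_bl,
                   levels = sort(unique(as.numeric(table$speed_bl)))))
  dat <- dat[is.finite(dat$y), , drop = FALSE]
  tab <- table(dat$individual[!duplicated(paste(dat$individual, dat$speed))])
  few <- names(tab)[tab < 2L]
  if (length(few)) {
    warning(sprintf("dropping individual(s) with < 2 speeds: %s",
                    paste(few, collapse = ", ")), call. = FALSE)
    dat <- dat[!(dat$individual %in% few), , drop = FALSE]
  }
  dat$individual <- droplevels(dat$individual)
  dat$speed <- droplevels(dat$speed)
  if (nlevels(dat$individual) < 2L || nlevels(dat$speed) < 2L)
    stop("need at least 2 individuals and 2 speeds with data", call. = FALSE)
  dat
}

.speed_anova_from_lm <- function(dat, variable, kind) {
  model <- stats::lm(y ~ individual + speed, data = dat)
  if (diff(range(dat$y)) == 0) {
    # fully tied response (e.g. constant ranks): no effect by definition
    return(structure(
      list(variable = variable, kind = kind, F = 0,
           df_num = nlevels(dat$speed) - 1L,
           df_den = nrow(dat) - nlevels(dat$speed) - nlevels(dat$individual) + 1L,
           p = 1, model = model, data = dat),
      class = "speed_anova"))
  }
  av <- stats::anova(model)                     # sequential sums of squares
  df_num <- av["speed", "Df"]
  df_den <- av["Residuals", "Df"]
  ssr <- av["speed", "Sum Sq"]; sse <- av["Residuals", "Sum Sq"]
  if (ssr <= .Machine$double.eps * sum(dat$y^2) && sse <= ssr) {
    f <- 0; p <- 1                              # all values tied
  } else {
    f <- (ssr / df_num) / (sse / df_den)
    p <- stats::pf(f, df_num, df_den, lower.tail = FALSE)
  }
  structure(
    list(variable = variable, kind = kind, F = f,
         df_num = df_num, df_den = df_den, p = p,
         model = model, data = dat),
    class = "speed_anova"
  )
}

#' Assumption gate: parametric or aligned-rank ANOVA?
#'
#' Fits the additive individual-blocked model and tests its residuals for
#' homogeneity of variances across speeds (Levene's test, median-centred)
#' and normality (Shapiro-Wilk).  When neither test rejects at
#' `alpha`, the parametric repeated-measures ANOVA is chosen; otherwise
#' the aligned-rank-transform ANOVA.
#'
#' @param table trial table with columns `individual`, `speed_bl` and the
#'   response.
#' @param variable response column name.
#' @param alpha gate significance level (default 0.05).
#' @return A list with `chosen_test` (`"RM-ANOVA"` or `"ART-ANOVA"`),
#'   `levene_p` and `shapiro_p`.
#' @export
assumption_gate <- function(table, variable, alpha = 0.05) {
  dat <- .prep_speed_table(table, variable)
  if (diff(range(dat$y)) == 0) {
    warning("constant response: normality test undefined, using ART-ANOVA",
            call. = FALSE)
    return(list(chosen_test = "ART-ANOVA", levene_p = NA_real_,
                shapiro_p = NA_real_))
  }
  res <- stats::resid(stats::lm(y ~ individual + speed, data = dat))
  lev <- car::leveneTest(res ~ dat$speed, center = stats::median)
  levene_p <- lev[["Pr(>F)"]][1L]
  shapiro_p <- tryCatch(stats::shapiro.test(res)$p.value,
                        error = function(e) NA_real_)
  if (is.na(shapiro_p)) {
    warning("Shapiro-Wilk undefined on these residuals, using ART-ANOVA",
            call. = FALSE)
    chosen <- "ART-ANOVA"
  } else {
    chosen <- if (levene_p > alpha && shapiro_p > alpha) "RM-ANOVA"
              else "ART-ANOVA"
  }
  list(chosen_test = chosen, levene_p = levene_p, shapiro_p = shapiro_p)
}

#' Repeated-measures ANOVA across speeds
#'
#' Additive two-factor fixed-effect model `y ~ individual + speed` fit by
#' least squares on the (possibly unbalanced) trial table; the speed
#' effect is tested sequentially after the individual blocks, so for a
#' design with n individuals, k speeds and N trials the degrees of
#' freedom are `(k - 1, N - 1 - (k - 1) - (n - 1))` — the study design of
#' 5 individuals, 11 speeds and 51 trials gives F(10, 36).
#'
#' @param table trial table (columns `individual`, `speed_bl`, response).
#' @param variable response column name.
#' @return An object of class `speed_anova` with `F`, `df_num`, `df_den`,
#'   `p` and the underlying `lm` fit.
#' @export
rm_anova <- function(table, variable) {
  dat <- .prep_speed_table(table, variable)
  .speed_anova_from_lm(dat, variable, "RM-ANOVA")
}

#' Aligned-rank-transform ANOVA across speeds
#'
#' Aligns the response for the speed effect — residuals of the full
#' additive fit plus the estimated speed effect — ranks the aligned
#' values (average ranks for ties), and applies the parametric
#' repeated-measures ANOVA to the ranks.  This is the single-factor
#' aligned-rank procedure appropriate to a design with one within-subject
#' factor and no interactions.
#'
#' @inheritParams rm_anova
#' @return An object of class `speed_anova` (the `lm` fit is on ranks).
#' @export
art_anova <- function(table, variable) {
  dat <- .prep_speed_table(table, variable)
  if (diff(range(dat$y)) == 0) {
    # constant response aligns to a constant; skip the fit (whose float
    # junk residuals would otherwise break the ranks)
    dat$y <- 0
    return(.speed_anova_from_lm(dat, variable, "ART-ANOVA"))
  }
  full <- stats::lm(y ~ individual + speed, data = dat)
  mm <- stats::model.matrix(full)
  beta <- stats::coef(full)
  sp_cols <- grepl("^speed", colnames(mm))
  speed_eff <- as.vector(mm[, sp_cols, drop = FALSE] %*% beta[sp_cols])
  aligned <- stats::resid(full) + speed_eff
  dat$y <- rank(aligned, ties.method = "average")
  .speed_anova_from_lm(dat, variable, "ART-ANOVA")
}

#' @export
print.speed_anova <- function(x, ...) {
  cat(sprintf("%s for '%s': F(%d, %d) = %.3f, p = %.4g\n",
              x$kind, x$variable, x$df_num, x$df_den, x$F, x$p))
  invisible(x)
}

#' @export
summary.speed_anova <- function(object, ...) {
  print(object)
  cat("\nUnderlying additive fit (sequential sums of squares):\n")
  print(stats::anova(object$model))
  invisible(object)
}
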