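# Tukey-adjusted pairwise speed contrasts and the compact letter display.

#' Tukey-adjusted pairwise contrasts with compact letter display
#'
#' Computes all pairwise speed contrasts from a fitted [rm_anova()] or
#' [art_anova()] model using Tukey-Kramer adjustment (studentized-range
#' quantiles at the model's residual degrees of freedom, valid for
#' unequal group sizes), then summarizes them as a compact letter
#' display by the insert-and-absorb algorithm: two speeds share a letter
#' exactly when their adjusted contrast p-value exceeds `alpha`.
#' Letters are assigned in increasing speed order.
#'
#' @param fit a `speed_anova` object.
#' @param alpha significance level (default 0.05).
#' @return A data frame with one row per speed: `speed`, `emmean`,
#'   `letters`.  The full contrast table is attached as attribute
#'   `contrasts`.
#' @export
tukey_letters <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "speed_anova"))
  emm <- emmeans::emmeans(fit$model, "speed", data = fit$data)
  ctr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "tukey"))
  lev <- levels(fit$data$speed)
  k <- length(lev)
  sig <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  pair_lv <- strsplit(gsub("speed", "", ctr$contrast), " - ", fixed = TRUE)
  for (i in seq_len(nrow(ctr))) {
    a <- trimws(pair_lv[[i]][1L]); b <- trimws(pair_lv[[i]][2L])
    p <- ctr$p.value[i]
    if (is.na(p)) {
      warning(sprintf("contrast %s inestimable; treated as non-significant",
                      ctr$contrast[i]), call. = FALSE)
      next
    }
    if (p <= alpha) sig[a, b] <- sig[b, a] <- TRUE
  }
  letters_vec <- .insert_absorb(sig)
  emm_df <- as.data.frame(emm)
  out <- data.frame(speed = lev,
                    emmean = emm_df$emmean[match(lev, emm_df$speed)],
                    letters = letters_vec,
                    stringsAsFactors = FALSE)
  attr(out, "contrasts") <- ctr
  out
}

# insert-and-absorb compact letter display from a logical significance
# matrix (TRUE = the pair differs); returns one letter string per group
.insert_absorb <- function(sig) {
  k <- nrow(sig)
  cols <- list(rep(TRUE, k))
  pairs <- which(upper.tri(sig) & sig, arr.ind = TRUE)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      new_cols <- list()
      for (cc in cols) {
        if (cc[i] && cc[j]) {
          c1 <- cc; c1[j] <- FALSE
          c2 <- cc; c2[i] <- FALSE
          new_cols <- c(new_cols, list(c1, c2))
        } else new_cols <- c(new_cols, list(cc))
      }
      # absorb columns that are subsets of another column
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[a] && keep[b] &&
              all(new_cols[[a]] <= new_cols[[b]]) &&
              !identical(new_cols[[a]], new_cols[[b]])) {
            keep[a] <- FALSE
          }
        }
      }
      # drop exact duplicates, keeping the first
      cols <- unique(new_cols[keep])
    }
  }
  # order letter columns by their first member so letters follow group order
  first <- vapply(cols, function(cc) which(cc)[1L], 0L)
  cols <- cols[order(first)]
  labs <- letters[seq_along(cols)]
  vapply(seq_len(k), function(g) {
    paste(labs[vapply(cols, function(cc) cc[g], TRUE)], collapse = ",")
  }, "")
}
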