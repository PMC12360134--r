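test_that("the assumption gate passes well-behaved normal data to RM-ANOVA", {
  set.seed(10)
  picks <- replicate(400, {
    tab <- make_trial_table(sd_ind = 0, sd_err = 1,
                            seed = sample.int(1e6, 1))
    assumption_gate(tab, "y")$chosen_test
  })
  frac_rm <- mean(picks == "RM-ANOVA")
  # roughly 1 - P(either Levene or Shapiro rejects at 0.05)
  expect_gt(frac_rm, 0.84)
  expect_lt(frac_rm, 0.97)
})

test_that("heteroscedastic and constant data are routed to ART-ANOVA", {
  tab <- make_trial_table(seed = 2L)
  tab$y[tab$speed_bl == 6] <- tab$y[tab$speed_bl == 6] * 100
  expect_identical(assumption_gate(tab, "y")$chosen_test, "ART-ANOVA")
  tab$y <- 1
  expect_warning(g <- assumption_gate(tab, "y"), "constant")
  expect_identical(g$chosen_test, "ART-ANOVA")
})

test_that("the study design yields F(10, 36) for the speed effect", {
  tab <- make_trial_table(seed = 3L)
  fit <- rm_anova(tab, "y")
  expect_identical(fit$df_num, 10L)
  expect_identical(fit$df_den, 36L)
  # general df invariant: (k-1, N-1-(k-1)-(n-1))
  tab2 <- make_trial_table(n_ind = 4L, speeds = c(1, 2, 3, 4),
                           missing_ind5 = c(2, 4), seed = 4L)
  fit2 <- rm_anova(tab2, "y")
  expect_identical(fit2$df_num, 3L)
  expect_identical(fit2$df_den, nrow(tab2) - 1L - 3L - 3L)
})

test_that("zero residual variance with distinct speed means gives p -> 0", {
  tab <- expand.grid(individual = c("a", "b"), speed_bl = c(1, 2, 3))
  tab$y <- c(0, 0, 5, 5, 9, 9)
  fit <- suppressWarnings(rm_anova(tab, "y"))   # lm warns on a perfect fit
  expect_true(is.infinite(fit$F) || fit$F > 1e10)
  expect_equal(fit$p, 0)
})

test_that("individuals with a single speed are dropped with a warning", {
  tab <- make_trial_table(seed = 5L)
  tab <- tab[!(tab$individual == "i1" & tab$speed_bl != 1), ]
  expect_warning(fit <- rm_anova(tab, "y"), "dropping individual")
  expect_identical(fit$df_den,
                   nrow(tab) - 1L - 1L - 10L - (4L - 1L))
})

test_that("ART-ANOVA handles ties and is invariant to affine transforms", {
  tab <- make_trial_table(seed = 6L)
  tied <- tab; tied$y <- 2
  fit <- art_anova(tied, "y")
  expect_identical(fit$F, 0)
  expect_identical(fit$p, 1)
  # positive affine transforms leave the aligned ranks unchanged
  f1 <- art_anova(tab, "y")
  tab2 <- tab; tab2$y <- 3 * tab$y + 7
  f2 <- art_anova(tab2, "y")
  expect_equal(f1$F, f2$F, tolerance = 1e-9)
  expect_equal(f1$p, f2$p, tolerance = 1e-9)
})

test_that("ART-ANOVA detects a strong speed effect in skewed data", {
  tab <- make_trial_table(trend = function(s) s,
                          sd_ind = 0.3, sd_err = 0.3, seed = 7L,
                          noise = function(n) exp(rnorm(n)) - exp(0.5))
  fit <- art_anova(tab, "y")
  expect_lt(fit$p, 0.001)
})

test_that("Tukey letters separate clearly different speeds", {
  set.seed(8)
  tab <- expand.grid(individual = paste0("i", 1:4), speed_bl = c(1, 2, 3))
  tab$y <- c(0, 0, 10)[match(tab$speed_bl, c(1, 2, 3))] + rnorm(12, 0, 0.1)
  fit <- rm_anova(tab, "y")
  let <- tukey_letters(fit)
  expect_identical(let$letters, c("a", "a", "b"))
})

test_that("identical speeds share one letter and letters ignore row order", {
  set.seed(9)
  tab <- make_trial_table(sd_ind = 0.5, sd_err = 1, seed = 9L)
  same <- tab; same$y <- rnorm(nrow(tab), 5, 0.1)  # no speed effect
  expect_true(all(tukey_letters(rm_anova(same, "y"))$letters == "a"))
  shuffled <- tab[sample(nrow(tab)), ]
  l1 <- tukey_letters(rm_anova(tab, "y"))
  l2 <- tukey_letters(rm_anova(shuffled, "y"))
  expect_identical(l1$letters, l2$letters)
})

test_that("letter groups reflect Tukey-adjusted contrast significance", {
  tab <- make_trial_table(trend = function(s) 0.6 * s, sd_ind = 0.5,
                          sd_err = 0.5, seed = 10L)
  fit <- rm_anova(tab, "y")
  let <- tukey_letters(fit)
  ctr <- attr(let, "contrasts")
  # two speeds share a letter iff their adjusted p > alpha
  shares <- function(a, b) {
    la <- strsplit(let$letters[let$speed == a], ",")[[1]]
    lb <- strsplit(let$letters[let$speed == b], ",")[[1]]
    length(intersect(la, lb)) > 0
  }
  pair_lv <- strsplit(gsub("speed", "", ctr$contrast), " - ")
  for (i in seq_len(nrow(ctr))) {
    a <- trimws(pair_lv[[i]][1]); b <- trimws(pair_lv[[i]][2])
    expect_identical(shares(a, b), ctr$p.value[i] > 0.05,
                     label = ctr$contrast[i])
  }
})

test_that("PCA normalizations and symmetries hold", {
  set.seed(11)
  n <- 40
  tab <- data.frame(a = rnorm(n))
  tab$b <- tab$a * 2 + 1                    # perfectly correlated pair
  p2 <- pca_contributions(tab, variables = c("a", "b"))
  expect_equal(p2$percent_variance[1], 100)
  tab6 <- data.frame(matrix(rnorm(n * 6), n))
  p6 <- pca_contributions(tab6, variables = names(tab6))
  expect_equal(sum(p6$percent_variance), 100)
  expect_equal(unname(colSums(p6$contributions)), rep(100, 6))
  # sign-flipping a variable changes nothing but loading signs
  tab6f <- tab6; tab6f$X3 <- -tab6f$X3
  p6f <- pca_contributions(tab6f, variables = names(tab6))
  expect_equal(p6$percent_variance, p6f$percent_variance)
  expect_equal(p6$contributions, p6f$contributions)
  tab6$X1 <- 5
  expect_error(pca_contributions(tab6, variables = names(tab6)), "X1")
})

test_that("summary table letters agree with tukey_letters", {
  tab <- make_trial_table(trend = function(s) 0.5 * s, sd_ind = 0.3,
                          sd_err = 0.4, seed = 12L)
  tab$tbf <- tab$y
  rep <- stats_report(tab, variables = "tbf")
  st <- summary_table(tab, report = rep, variables = "tbf")
  fit <- rep$fits[["tbf"]]
  let <- tukey_letters(fit)
  expect_identical(nrow(st), 11L)
  for (i in seq_len(nrow(st))) {
    expect_match(st$tbf[i],
                 paste0("\\(", gsub(",", ",", let$letters[i]), "\\)$"))
  }
})
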