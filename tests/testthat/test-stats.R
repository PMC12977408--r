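test_that("mixed-model fits recover a known interaction and flag rank deficiency", {
  est <- vapply(1:12, function(s) {
    dat <- simulate_feature_table(n_dyads = 40, effect = 1, seed = s)
    dat$Time <- factor(dat$period, levels = c("pre", "post"))
    dat$Group <- factor(dat$group, levels = c("control", "experimental"))
    f <- fit_lmm(level ~ Time * Group + (1 | dyad_id / roi), dat)
    f$fixed$estimate[f$fixed$term == "Timepost:Groupexperimental"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 1), 2 * stats::sd(est) / sqrt(length(est)) + 0.05)

  dat <- simulate_feature_table(n_dyads = 10, seed = 1)
  dat$Time <- factor(dat$period); dat$Group <- factor(dat$group)
  dat$Delta <- 1   # constant moderator: collinear with the intercept
  expect_error(fit_lmm(level ~ Time * Group * Delta + (1 | dyad_id), dat),
               "collinear")
})

test_that("likelihood-ratio machinery satisfies its identities", {
  dat <- simulate_feature_table(n_dyads = 30, effect = 0.8, seed = 3)
  dat$Time <- factor(dat$period, levels = c("pre", "post"))
  dat$Group <- factor(dat$group, levels = c("control", "experimental"))
  full <- fit_lmm(level ~ Time * Group + (1 | dyad_id / roi), dat)
  red <- fit_lmm(level ~ Time + Group + (1 | dyad_id / roi), dat)

  expect_equal(full$aic, 2 * full$npar - 2 * full$logLik)
  expect_equal(full$bic, full$npar * log(full$n) - 2 * full$logLik)
  expect_gte(full$logLik, red$logLik)     # ML on nested models

  lrt <- lrt_compare(full, red)
  expect_equal(lrt$df, 1L)
  expect_gte(lrt$chi_sq, 0)
  expect_true(lrt$p_value >= 0 && lrt$p_value <= 1)

  same <- lrt_compare(full, full)
  expect_equal(same$chi_sq, 0)
  expect_equal(same$p_value, 1)

  remlfit <- fit_lmm(level ~ Time * Group + (1 | dyad_id / roi), dat, reml = TRUE)
  expect_error(lrt_compare(remlfit, red), "estimation")
})

test_that("standardized effects scale correctly and partial R2 is nonnegative", {
  ## a 1-SD interaction effect yields a standardized beta near its
  ## construction; the reduced model never explains more than the full one
  bstd <- vapply(1:8, function(s) {
    dat <- simulate_feature_table(n_dyads = 40, effect = 1.5, sd_dyad = 0.5,
                                  sd_roi = 0.3, sd_resid = 1, seed = 20 + s)
    dat$Time <- factor(dat$period, levels = c("pre", "post"))
    dat$Group <- factor(dat$group, levels = c("control", "experimental"))
    full <- fit_lmm(level ~ Time * Group + (1 | dyad_id / roi), dat)
    red <- fit_lmm(level ~ Time + Group + (1 | dyad_id / roi), dat)
    ef <- standardized_effects(full, "Timepost:Groupexperimental", red)
    expect_gte(ef$partial_r2, 0)
    expect_lte(ef$ci_lo, ef$beta_std)
    expect_gte(ef$ci_hi, ef$beta_std)
    ef$beta_std
  }, numeric(1))
  expect_gt(mean(bstd), 0.3)

  nulls <- vapply(1:10, function(s) {
    dat <- simulate_feature_table(n_dyads = 40, effect = 0, seed = 50 + s)
    dat$Time <- factor(dat$period, levels = c("pre", "post"))
    dat$Group <- factor(dat$group, levels = c("control", "experimental"))
    full <- fit_lmm(level ~ Time * Group + (1 | dyad_id / roi), dat)
    standardized_effects(full, "Timepost:Groupexperimental")$beta_std
  }, numeric(1))
  expect_lt(abs(mean(nulls)), 0.1)
})

test_that("scripted analyses run the full model-comparison program end to end", {
  set.seed(61)
  ## DyadType control: real pairs get a level bump
  lv <- data.frame(kind = rep(c("real", "permuted"), times = c(60, 120)),
                   roi = rep(sprintf("roi%d", 1:6), 30),
                   level = c(stats::rnorm(60, 0.29, 0.03),
                             stats::rnorm(120, 0.25, 0.03)))
  beh <- do.call(rbind, lapply(1:16, function(i) {
    g <- if (i %% 2 == 0) "experimental" else "control"
    data.frame(dyad_id = sprintf("d%d", i), group = g, period = c("pre", "post"),
               total_speaking_time = stats::rnorm(2, 450, 40),
               speech_ratio = stats::rnorm(2, 5, 1),
               mean_error = c(stats::rnorm(1, 0.4, 0.1),
                              stats::rnorm(1, ifelse(g == "experimental", 1.0, 0.4), 0.1)))
  }))
  diff_tab <- do.call(rbind, lapply(1:16, function(i) {
    g <- if (i %% 2 == 0) "experimental" else "control"
    data.frame(dyad_id = sprintf("d%d", i), group = g,
               participant = sprintf("d%d_p%d", i, 1:2),
               period = rep(c("pre", "post"), each = 2),
               score = c(stats::rnorm(2, 4, 1),
                         stats::rnorm(2, ifelse(g == "experimental", 6.4, 4.2), 1)))
  }))
  res <- run_control_analyses(lv, beh, diff_tab)
  expect_lt(res$dyad_type$lrt$p_value, 0.001)
  expect_gt(res$dyad_type$means[["real"]], res$dyad_type$means[["permuted"]])
  expect_lt(res$mean_error$lrt$p_value, 0.001)
  expect_lt(res$perceived_difficulty$lrt$p_value, 0.001)
  expect_gt(res$total_speaking_time$lrt$p_value, 0.01)

  ## post-period rows must be rejected for the permuted control
  lv_bad <- lv; lv_bad$period <- "post"
  expect_error(run_control_analyses(lv_bad, beh), "pre-disruption")

  ## hypothesis tests: single-period tables are a usage error; degenerate
  ## outcomes are flagged, not crashed
  ft <- simulate_feature_table(n_dyads = 16, seed = 2)
  ft$slope <- stats::rnorm(nrow(ft), 0, 1e-4)
  ft$pct_det <- 0.5
  expect_error(run_ibs_hypothesis_tests(ft[ft$period == "pre", ]), "period")
  hyp <- run_ibs_hypothesis_tests(ft)
  expect_true(hyp$pct_det$degenerate)
  expect_false(is.null(hyp$level$lrt))
  expect_true(hyp$level$lrt$p_value > 0 && hyp$level$lrt$p_value <= 1)

  ## moderation: delta merged per dyad, 4-df factorial comparison
  dl <- data.frame(dyad_id = unique(ft$dyad_id),
                   delta = stats::rnorm(16))
  mod <- run_moderation(ft[, c("dyad_id", "group", "roi", "period", "level")], dl)
  expect_equal(mod$level$lrt$df, 4L)
  expect_error(run_moderation(ft, dl[0, ]), "dyads")
})

test_that("sensitivity simulation power is calibrated and monotone", {
  sens <- sensitivity_simulation(effect_grid = c(0, 0.6, 1.2), n_reps = 60,
                                 template = list(n_dyads = 30, sd_dyad = 0.6,
                                                 sd_roi = 0.3, sd_resid = 1),
                                 seed = 4)
  pw <- sens$grid$power
  expect_lt(pw[1], 0.15)                       # size near the nominal level
  expect_gte(pw[3] + 0.1, pw[2])               # nondecreasing within MC error
  expect_gte(pw[3], 0.9)                       # large effect detected
  expect_true(is.finite(sens$mde) || is.na(sens$mde))
  if (is.finite(sens$mde)) expect_true(sens$mde >= 0 && sens$mde <= 1.2)
})
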