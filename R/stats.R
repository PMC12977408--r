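## Linear mixed-effects inference: control analyses, manipulation checks,
## Time x Group disruption tests, moderation models, and the simulation-based
## sensitivity analysis. Model comparison is by likelihood-ratio ANOVA of a
## full model against a reduced model lacking the term of interest.

#' Fit a linear mixed-effects model
#'
#' Thin wrapper around [lme4::lmer()] that checks the fixed-effect design for
#' rank deficiency up front (naming the collinear columns), records
#' convergence, and extracts the quantities used downstream (log-likelihood,
#' parameter count, AIC/BIC, fixed-effect table).
#'
#' @param formula model formula with lme4 random-effect terms.
#' @param data data.frame.
#' @param reml fit by REML (TRUE) or ML (FALSE). Likelihood-ratio comparisons
#'   of fixed effects require ML.
#' @return object of class `lmm_fit`: list(model, formula, reml, logLik,
#'   npar, aic, bic, n, fixed (data.frame estimate/se/ci), converged).
#' @export
fit_lmm <- function(formula, data, reml = FALSE) {
  fixed_form <- lme4::nobars(formula)
  X <- stats::model.matrix(fixed_form, data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    usage_error(sprintf("fixed-effect design is rank deficient; collinear term(s): %s",
                        paste(dropped, collapse = ", ")))
  }
  fit <- suppressMessages(suppressWarnings(lme4::lmer(formula, data = data, REML = reml)))
  conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0L &&
    (fit@optinfo$conv$opt %||% 0L) == 0L
  ll <- as.numeric(stats::logLik(fit))
  npar <- attr(stats::logLik(fit), "df")
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  fixed <- data.frame(term = names(est), estimate = as.numeric(est), se = se,
                      ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
                      row.names = NULL)
  structure(list(model = fit, formula = formula, reml = reml, logLik = ll,
                 npar = npar, aic = 2 * npar - 2 * ll,
                 bic = npar * log(stats::nobs(fit)) - 2 * ll,
                 n = stats::nobs(fit), fixed = fixed, converged = conv),
            class = "lmm_fit")
}

#' Likelihood-ratio comparison of nested mixed models
#'
#' chi^2 = 2 (logLik_full - logLik_reduced) (clipped at zero), df = the
#' difference in parameter counts, p from the chi-squared distribution.
#'
#' @param full,reduced `lmm_fit` objects on the same data with the same
#'   estimation method; `reduced` must be nested in `full`.
#' @return object of class `lrt_result`: list(chi_sq, df, p_value, npar_full,
#'   npar_reduced, aic_full, aic_reduced, logLik_full, logLik_reduced).
#' @export
lrt_compare <- function(full, reduced) {
  if (!inherits(full, "lmm_fit") || !inherits(reduced, "lmm_fit"))
    usage_error("both arguments must be lmm_fit objects")
  if (full$n != reduced$n) usage_error("models were fitted to different data")
  if (full$reml != reduced$reml) usage_error("models use different estimation methods")
  if (full$npar < reduced$npar)
    usage_error("'full' must have at least as many parameters as 'reduced' (nested comparison)")
  chi <- max(0, 2 * (full$logLik - reduced$logLik))
  df <- full$npar - reduced$npar
  p <- if (df == 0L) 1 else stats::pchisq(chi, df, lower.tail = FALSE)
  structure(list(chi_sq = chi, df = df,
                 p_value = p,
                 npar_full = full$npar, npar_reduced = reduced$npar,
                 aic_full = full$aic, aic_reduced = reduced$aic,
                 logLik_full = full$logLik, logLik_reduced = reduced$logLik),
            class = "lrt_result")
}

## Marginal R^2: fixed-effect variance over total (fixed + random intercept
## variances + residual).
marginal_r2 <- function(fit) {
  m <- fit$model
  X <- stats::model.matrix(m)
  var_fix <- stats::var(as.numeric(X %*% lme4::fixef(m)))
  vc <- lme4::VarCorr(m)
  var_ran <- sum(vapply(vc, function(v) v[1, 1], numeric(1)))
  var_res <- attr(vc, "sc")^2
  var_fix / (var_fix + var_ran + var_res)
}

#' Standardized effect size and variance explained for a model term
#'
#' Standardized beta = beta * sd(x) / sd(y) with a Wald 95% CI; marginal R^2
#' is the fixed-effects variance fraction; the partial R^2 of the tested term
#' is marginal R^2(full) - marginal R^2(reduced), floored at zero.
#'
#' @param full `lmm_fit`. @param term fixed-effect name (model-matrix column).
#' @param reduced optional `lmm_fit` for the partial R^2.
#' @return object of class `effect_summary`: list(term, beta_std, ci_lo,
#'   ci_hi, raw_beta, raw_ci, marginal_r2, partial_r2).
#' @export
standardized_effects <- function(full, term, reduced = NULL) {
  m <- full$model
  y <- stats::model.frame(m)[[1L]]
  sdy <- stats::sd(y)
  if (sdy == 0) data_error("outcome has zero variance")
  X <- stats::model.matrix(m)
  if (!term %in% colnames(X))
    usage_error(sprintf("term '%s' not in the fixed-effect design (have: %s)",
                        term, paste(colnames(X), collapse = ", ")))
  sdx <- stats::sd(X[, term])
  row <- full$fixed[full$fixed$term == term, ]
  scale <- sdx / sdy
  mr2_full <- marginal_r2(full)
  pr2 <- if (!is.null(reduced)) max(0, mr2_full - marginal_r2(reduced)) else NA_real_
  structure(list(term = term,
                 beta_std = row$estimate * scale,
                 ci_lo = row$ci_lo * scale, ci_hi = row$ci_hi * scale,
                 raw_beta = row$estimate, raw_ci = c(row$ci_lo, row$ci_hi),
                 marginal_r2 = mr2_full, partial_r2 = pr2),
            class = "effect_summary")
}

## Full-vs-reduced comparison with a nested-to-crossed convergence
## fallback: try (1|Dyad/ROI); on failure refit both models with
## (1|Dyad) + (1|ROI), noting the fallback.
compare_models <- function(data, outcome, full_rhs, reduced_rhs,
                           re_primary, re_fallback = NULL, reml = FALSE) {
  mk <- function(rhs, re) stats::as.formula(paste(outcome, "~", rhs, "+", re))
  fallback <- FALSE
  full <- fit_lmm(mk(full_rhs, re_primary), data, reml)
  reduced <- fit_lmm(mk(reduced_rhs, re_primary), data, reml)
  if ((!full$converged || !reduced$converged) && !is.null(re_fallback)) {
    fallback <- TRUE
    full <- fit_lmm(mk(full_rhs, re_fallback), data, reml)
    reduced <- fit_lmm(mk(reduced_rhs, re_fallback), data, reml)
  }
  list(full = full, reduced = reduced, lrt = lrt_compare(full, reduced),
       fallback = fallback)
}

#' Control analyses: interaction-induced IBS and manipulation checks
#'
#' Reproduces the control-analysis block: (1) pre-disruption IBS level of
#' real vs permuted dyads, `IBS ~ DyadType + (1|ROI)` against the
#' intercept-only null; (2) Time x Group likelihood-ratio tests for the error
#' score, perceived difficulty (random intercept per individual), total
#' speaking time and speech ratio (random intercept per dyad).
#'
#' @param levels_pre data.frame with columns kind ("real"/"permuted"), roi,
#'   level — pre-disruption coherence levels for real and permuted pairings.
#' @param behavior data.frame from [behavior_table()] (columns dyad_id,
#'   group, period, total_speaking_time, speech_ratio, mean_error).
#' @param difficulty data.frame from [difficulty_table()].
#' @param reml use REML fits for the comparisons; default ML, as required
#'   for comparing fixed-effect structures.
#' @return named list of result entries, each containing the `lrt`, the
#'   fitted models, and an `effect` summary where applicable.
#' @export
run_control_analyses <- function(levels_pre, behavior, difficulty = NULL,
                                 reml = FALSE) {
  need <- setdiff(c("kind", "roi", "level"), names(levels_pre))
  if (length(need)) data_error(paste("levels_pre missing columns:", paste(need, collapse = ", ")))
  if ("period" %in% names(levels_pre) && any(levels_pre$period != "pre"))
    usage_error("permuted-dyad control uses pre-disruption levels only")
  lp <- levels_pre
  lp$DyadType <- factor(lp$kind, levels = c("permuted", "real"))
  res <- list()
  cmp <- compare_models(lp, "level", "DyadType", "1", "(1|roi)", reml = reml)
  cmp$effect <- standardized_effects(cmp$full, "DyadTypereal", cmp$reduced)
  cmp$means <- tapply(lp$level, lp$DyadType, mean)
  res$dyad_type <- cmp

  bh <- behavior
  bh$Time <- factor(bh$period, levels = c("pre", "post"))
  bh$Group <- factor(bh$group, levels = c("control", "experimental"))
  for (oc in c("mean_error", "total_speaking_time", "speech_ratio")) {
    if (!oc %in% names(bh)) data_error(paste("behavior missing column:", oc))
    dat <- bh[is.finite(bh[[oc]]), ]
    cmp <- compare_models(dat, oc, "Time * Group", "Time + Group",
                          "(1|dyad_id)", reml = reml)
    cmp$effect <- standardized_effects(cmp$full, "Timepost:Groupexperimental",
                                       cmp$reduced)
    res[[oc]] <- cmp
  }
  if (!is.null(difficulty)) {
    df <- difficulty
    df$Time <- factor(df$period, levels = c("pre", "post"))
    df$Group <- factor(df$group, levels = c("control", "experimental"))
    cmp <- compare_models(df, "score", "Time * Group", "Time + Group",
                          "(1|participant)", reml = reml)
    cmp$effect <- standardized_effects(cmp$full, "Timepost:Groupexperimental",
                                       cmp$reduced)
    res$perceived_difficulty <- cmp
  }
  res
}

#' Disruption tests on the three IBS features
#'
#' One likelihood-ratio ANOVA per feature (level, slope, percent
#' determinism): full model `feature ~ Time * Group + (1|Dyad/ROI)` against
#' the reduced model without the interaction, with the crossed-intercept
#' fallback `(1|Dyad) + (1|ROI)` on convergence failure. Standardized
#' interaction coefficients, 95% CIs and partial R^2 are attached.
#'
#' @param features data.frame from [feature_table()] with both periods.
#' @param reml use REML comparisons instead of ML.
#' @return named list (level, slope, pct_det) of comparison results.
#' @export
run_ibs_hypothesis_tests <- function(features, reml = FALSE) {
  if (length(unique(features$period)) < 2L)
    usage_error("feature table must contain both periods (pre and post)")
  ft <- features
  ft$Time <- factor(ft$period, levels = c("pre", "post"))
  ft$Group <- factor(ft$group, levels = c("control", "experimental"))
  out <- list()
  for (oc in intersect(c("level", "slope", "pct_det"), names(ft))) {
    if (!any(is.finite(ft[[oc]]))) next
    dat <- ft[is.finite(ft[[oc]]), ]
    if (stats::sd(dat[[oc]]) == 0) {
      out[[oc]] <- list(degenerate = TRUE)
      next
    }
    cmp <- compare_models(dat, oc, "Time * Group", "Time + Group",
                          "(1|dyad_id/roi)", "(1|dyad_id) + (1|roi)", reml)
    cmp$effect <- standardized_effects(cmp$full, "Timepost:Groupexperimental",
                                       cmp$reduced)
    out[[oc]] <- cmp
  }
  out
}

#' Moderation of the disruption effect by communication change
#'
#' Tests whether the per-dyad change (delta) in a communication feature
#' moderates the Time x Group interaction: full model
#' `feature ~ Time * Group * Delta + (1|Dyad) + (1|ROI)` against the reduced
#' `feature ~ Time * Group + ...` (a 4-df comparison under full factorial
#' expansion).
#'
#' @param features data.frame from [feature_table()].
#' @param deltas data.frame with columns dyad_id and delta (one row per
#'   dyad).
#' @param reml use REML comparisons.
#' @return named list per feature of comparison results.
#' @export
run_moderation <- function(features, deltas, reml = FALSE) {
  if (!all(c("dyad_id", "delta") %in% names(deltas)))
    data_error("deltas must have columns dyad_id and delta")
  ft <- merge(features, deltas, by = "dyad_id")
  if (nrow(ft) == 0) data_error("no dyads with both features and deltas")
  if (anyNA(ft$delta)) data_error("missing delta values")
  ft$Time <- factor(ft$period, levels = c("pre", "post"))
  ft$Group <- factor(ft$group, levels = c("control", "experimental"))
  ft$Delta <- ft$delta
  out <- list()
  for (oc in intersect(c("level", "slope", "pct_det"), names(ft))) {
    dat <- ft[is.finite(ft[[oc]]), ]
    cmp <- compare_models(dat, oc, "Time * Group * Delta", "Time * Group",
                          "(1|dyad_id) + (1|roi)", reml = reml)
    cmp$effect <- standardized_effects(cmp$full,
                                       "Timepost:Groupexperimental:Delta",
                                       cmp$reduced)
    out[[oc]] <- cmp
  }
  out
}

#' Simulate a feature table from a variance-components template
#'
#' Direct generator of long-format feature tables (dyad x ROI x period) under
#' the mixed-model data-generating process: outcome = grand mean + dyad
#' intercept + ROI-within-dyad intercept + Time and Group main effects +
#' `effect` x Time x Group interaction + residual. Used for statistical
#' calibration (type-I error) and power/sensitivity analysis.
#'
#' @param n_dyads dyads (groups balanced). @param n_roi ROIs per dyad.
#' @param effect Time x Group interaction coefficient (outcome units).
#' @param beta_time,beta_group main effects.
#' @param sd_dyad,sd_roi,sd_resid variance components (SDs).
#' @param mu grand mean.
#' @param seed integer seed.
#' @return data.frame: dyad_id, group, roi, period, level.
#' @export
simulate_feature_table <- function(n_dyads = 40L, n_roi = 6L, effect = 0,
                                   beta_time = 0, beta_group = 0,
                                   sd_dyad = 1, sd_roi = 0.5, sd_resid = 1,
                                   mu = 0, seed = 1L) {
  set.seed(seed)
  dyads <- sprintf("d%03d", seq_len(n_dyads))
  group <- rep(c("control", "experimental"), length.out = n_dyads)
  g <- expand.grid(dyad_id = dyads, roi = sprintf("roi%d", seq_len(n_roi)),
                   period = c("pre", "post"), stringsAsFactors = FALSE)
  g$group <- group[match(g$dyad_id, dyads)]
  re_d <- stats::setNames(stats::rnorm(n_dyads, 0, sd_dyad), dyads)
  re_r <- stats::rnorm(n_dyads * n_roi, 0, sd_roi)
  names(re_r) <- as.vector(outer(dyads, sprintf("roi%d", seq_len(n_roi)), paste, sep = ":"))
  tt <- as.numeric(g$period == "post")
  gg <- as.numeric(g$group == "experimental")
  g$level <- mu + re_d[g$dyad_id] + re_r[paste(g$dyad_id, g$roi, sep = ":")] +
    beta_time * tt + beta_group * gg + effect * tt * gg +
    stats::rnorm(nrow(g), 0, sd_resid)
  rownames(g) <- NULL
  g[, c("dyad_id", "group", "roi", "period", "level")]
}

#' Simulation-based sensitivity analysis of the Time x Group test
#'
#' For each candidate interaction effect size, simulates feature tables from
#' the template, runs the full-vs-reduced likelihood-ratio test, and records
#' the rejection fraction at `alpha`. The minimal detectable effect is the
#' grid point (linearly interpolated) where power crosses `power_target`.
#'
#' @param effect_grid numeric vector of interaction coefficients (outcome
#'   units).
#' @param n_reps replicates per grid point (>= 50 recommended).
#' @param alpha test level.
#' @param template named list of [simulate_feature_table()] arguments
#'   (n_dyads, n_roi, sd_dyad, sd_roi, sd_resid, ...).
#' @param power_target power level at which the minimal detectable effect is
#'   interpolated.
#' @param seed integer master seed.
#' @return object of class `sensitivity_result`: list(grid = data.frame
#'   (effect, power), mde, n_reps, alpha, seed).
#' @export
sensitivity_simulation <- function(effect_grid, n_reps = 100L, alpha = 0.05,
                                   template = list(), power_target = 0.8,
                                   seed = 1L) {
  if (length(effect_grid) == 0) usage_error("effect_grid must be nonempty")
  power <- numeric(length(effect_grid))
  for (i in seq_along(effect_grid)) {
    rej <- logical(n_reps)
    for (r in seq_len(n_reps)) {
      args <- utils::modifyList(template,
                                list(effect = effect_grid[i],
                                     seed = derive_seed(seed, i * 100000L + r)))
      dat <- do.call(simulate_feature_table, args)
      dat$Time <- factor(dat$period, levels = c("pre", "post"))
      dat$Group <- factor(dat$group, levels = c("control", "experimental"))
      cmp <- compare_models(dat, "level", "Time * Group", "Time + Group",
                            "(1|dyad_id/roi)", "(1|dyad_id) + (1|roi)")
      rej[r] <- cmp$lrt$p_value < alpha
    }
    power[i] <- mean(rej)
  }
  ord <- order(effect_grid)
  eg <- effect_grid[ord]; pw <- power[ord]
  mde <- NA_real_
  above <- which(pw >= power_target)
  if (length(above)) {
    j <- above[1]
    mde <- if (j == 1L) eg[1] else {
      eg[j - 1L] + (power_target - pw[j - 1L]) / (pw[j] - pw[j - 1L]) * (eg[j] - eg[j - 1L])
    }
  }
  structure(list(grid = data.frame(effect = eg, power = pw), mde = mde,
                 n_reps = n_reps, alpha = alpha, seed = seed),
            class = "sensitivity_result")
}
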