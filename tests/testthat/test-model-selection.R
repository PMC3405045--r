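test_that("the candidate set runs from null to saturated with the printed K", {
  set <- build_model_set("T_bill")
  labels <- vapply(set, function(s) s$label, character(1))
  expect_equal(length(set), 11)
  expect_true("Null" %in% labels)
  expect_true("SSP + Ta" %in% labels)
  expect_true("SSP * Ta + SSP * Ta^2 + SSP * Ta^3" %in% labels)
  # every spec implicitly carries sqrt_activity and the random intercept
  hb <- default_heat_table()
  k_of <- function(lbl) {
    spec <- set[[match(lbl, labels)]]
    suppressWarnings(suppressMessages(fit_model(hb, spec)))$K
  }
  expect_equal(k_of("SSP + Ta"), 6L)
  expect_equal(k_of("SSP * Ta"), 7L)
  expect_equal(k_of("SSP * Ta + SSP * Ta^2"), 9L)
  expect_equal(k_of("SSP * Ta + SSP * Ta^2 + SSP * Ta^3"), 11L)
  expect_equal(k_of("Null"), 4L)
  expect_error(model_spec("T_bill", "SSP:Ta"), "requires")
  expect_error(model_spec("T_bill", "Ta2"), "requires")
})

test_that("without a random intercept the fit reduces to least squares", {
  hb <- default_heat_table()
  spec <- model_spec("T_bill", c("SSP", "Ta"))
  fit <- fit_model(hb, spec, random_intercept = FALSE)
  ref <- lm(t_bill ~ subspecies + ta + sqrt(activity), data = hb)
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-10)
  expect_equal(fit$K, 5L)  # 4 coefficients + residual variance
})

test_that("near-noise-free data recovers the generating coefficients", {
  cohort <- generate_cohort(seed = 41)
  resp <- response_config(ranef_sd = 0, frame_sd = 1e-4)
  obs <- generate_experiment(cohort, response = resp, seed = 42)
  hb <- suppressWarnings(heat_budget_table(obs, cohort))
  fit <- suppressWarnings(fit_model(hb, model_spec("T_base",
                                                   c("SSP", "Ta", "SSP:Ta"))))
  # generating model: base elevation 9.8 -> 4.7 over ta 15 -> 37 plus the
  # coastal interaction 1.2 -> 0.2; slopes per degC. The factor reference
  # level is atlantica (alphabetical), so the ta coefficient is the coastal
  # slope and the melodia terms subtract the interaction.
  slope_east <- 1 + (4.7 - 9.8) / 22
  interaction <- (0.2 - 1.2) / 22
  ssp_at_zero <- 1.2 - interaction * 15
  est <- fit$coefficients
  expect_equal(unname(est["ta"]), slope_east + interaction, tolerance = 1e-4)
  expect_equal(unname(est["subspeciesmelodia"]), -ssp_at_zero,
               tolerance = 1e-3)
  expect_equal(unname(est["subspeciesmelodia:ta"]), -interaction,
               tolerance = 1e-3)
})

test_that("log-likelihood is monotone under nesting at the ML optimum", {
  hb <- default_heat_table()
  set <- build_model_set("T_bill")
  fits <- suppressWarnings(suppressMessages(
    lapply(set, function(s) fit_model(hb, s))))
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  labels <- vapply(set, function(s) s$label, character(1))
  saturated <- lls[match("SSP * Ta + SSP * Ta^2 + SSP * Ta^3", labels)]
  expect_true(all(saturated >= lls - 1e-6))
})

test_that("AICc follows the small-sample correction formula", {
  expect_equal(aicc(0, 0, 10), 0)
  expect_equal(aicc(-100, 6, 216), 212.4019, tolerance = 1e-4)
  # approaches AIC as n grows
  expect_equal(aicc(-100, 6, 1e8), 212, tolerance = 1e-5)
  expect_error(aicc(-100, 6, 7), "n > K")
})

test_that("comparison table ranks, normalizes weights and truncates display", {
  fits <- list(
    list(spec = model_spec("T_bill", label = "A"), loglik = -100, K = 4,
         n = 200),
    list(spec = model_spec("T_bill", label = "B"), loglik = -99, K = 5,
         n = 200),
    list(spec = model_spec("T_bill", label = "C"), loglik = -95, K = 11,
         n = 200))
  cmp <- compare_models(fits)
  tab <- cmp$table
  expect_equal(sum(tab$weight), 1)
  expect_equal(tab$delta_aicc[1], 0)
  expect_true(all(diff(tab$AICc) >= 0))
  # equal AICc -> equal weights
  twin <- compare_models(fits[c(1, 1)])
  expect_equal(twin$table$weight, c(0.5, 0.5))
  # delta = (0, 2) -> closed-form softmax weights
  f0 <- list(spec = model_spec("T_bill", label = "a"), loglik = -100, K = 4,
             n = 1e6)
  f2 <- list(spec = model_spec("T_bill", label = "b"), loglik = -101, K = 4,
             n = 1e6)
  w <- compare_models(list(f0, f2))$table$weight
  expect_equal(w, c(0.731, 0.269), tolerance = 1e-3)
})

test_that("evidence ratios are weight ratios with reciprocal symmetry", {
  fits <- list(
    list(spec = model_spec("T_bill", label = "A"), loglik = -100, K = 4,
         n = 200),
    list(spec = model_spec("T_bill", label = "B"), loglik = -102, K = 4,
         n = 200))
  cmp <- compare_models(fits)
  expect_equal(evidence_ratio(cmp, "A", "A"), 1)
  ab <- evidence_ratio(cmp, "A", "B")
  expect_equal(ab * evidence_ratio(cmp, "B", "A"), 1)
  w <- cmp$table$weight
  expect_equal(ab, w[1] / w[2])
  expect_error(evidence_ratio(cmp, "A", "missing"), "not found")
})

test_that("model averaging reproduces the closed-form two-model example", {
  hb <- default_heat_table()
  # single model, weight 1: averaged prediction equals the model's own
  one <- compare_models(list(fit_model(hb, model_spec("T_bill",
                                                      c("SSP", "Ta")))))
  grid <- data.frame(ta = c(15, 37), subspecies = "melodia",
                     sqrt_activity = mean(sqrt(hb$activity)))
  avg1 <- model_average_predictions(one, grid)
  raw <- billheat:::fit_predict(one$fits[[1]], grid)
  expect_equal(avg1$fit, raw$fit)
  expect_equal(avg1$unconditional_se, raw$se)
  # closed form: equal weights, predictions 10 and 12, zero SEs
  yhat <- c(10, 12)
  w <- c(0.5, 0.5)
  ybar <- sum(w * yhat)
  unc <- sum(w * sqrt(0 + (yhat - ybar)^2))
  expect_equal(ybar, 11)
  expect_equal(unc, 1)
  # variance inflation: unconditional SE >= smallest component SE
  two <- compare_models(list(
    fit_model(hb, model_spec("T_bill", c("SSP", "Ta"))),
    fit_model(hb, model_spec("T_bill", "Ta"))))
  avg2 <- model_average_predictions(two, grid)
  ses <- vapply(two$fits,
                function(f) billheat:::fit_predict(f, grid)$se,
                numeric(nrow(grid)))
  expect_true(all(avg2$unconditional_se >= apply(ses, 1, min) - 1e-12))
})

test_that("residual correlograms flag injected AR(1) but not white noise", {
  set.seed(77)
  ids <- rep(seq_len(20), each = 60)
  white <- data.frame(residual = rnorm(length(ids)), bird_id = ids)
  cg <- residual_correlogram(white, lag_max = 5)
  expect_equal(cg$acf[1], 1)
  expect_true(all(abs(cg$acf[-1]) < 3 * 1.96 / sqrt(nrow(white))))
  ar <- unlist(lapply(split(ids, ids), function(g)
    as.numeric(arima.sim(list(ar = 0.8), n = length(g)))))
  cg_ar <- residual_correlogram(
    data.frame(residual = ar, bird_id = ids), lag_max = 3)
  expect_equal(cg_ar$acf[2], 0.8, tolerance = 0.1)
  expect_gt(cg_ar$acf[2], cg_ar$upper[2])
  # a fitted model's residuals on default data stay inside the bounds
  hb <- default_heat_table()
  fit <- fit_model(hb, model_spec("T_bill", c("SSP", "Ta")))
  cg_fit <- residual_correlogram(fit, lag_max = 4)
  expect_true(all(abs(cg_fit$acf[-1]) <= 1))
})

test_that("pooled t-test matches the closed-form statistic and caps at 1", {
  a <- c(4.2, 5.1, 4.8, 5.5, 4.9)
  b <- c(6.1, 5.8, 6.5, 6.0, 6.3)
  res <- pooled_t_bonferroni(a, b, n_tests = 3)
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(res$statistic, t_hand)
  expect_equal(res$df, length(a) + length(b) - 2)
  expect_equal(res$p_adjusted, min(1, res$p_value * 3))
  same <- pooled_t_bonferroni(a, a, n_tests = 5)
  expect_equal(same$p_adjusted, 1)
  expect_equal(pooled_t_bonferroni(a, b, n_tests = 1)$p_adjusted,
               pooled_t_bonferroni(a, b, n_tests = 1)$p_value)
})

test_that("fixed-effect estimates are unbiased over Monte-Carlo replicates", {
  spec <- model_spec("T_base", c("SSP", "Ta", "SSP:Ta"))
  truth_interaction <- -(0.2 - 1.2) / 22  # melodia:ta, atlantica reference
  est <- vapply(1:40, function(i) {
    cohort <- generate_cohort(seed = 2000 + i)
    obs <- generate_experiment(cohort, seed = 3000 + i)
    hb <- suppressWarnings(heat_budget_table(obs, cohort))
    fit <- suppressWarnings(suppressMessages(fit_model(hb, spec)))
    unname(fit$coefficients["subspeciesmelodia:ta"])
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth_interaction), 3 * mc_se + 1e-4)
})

test_that("a single seeded replicate ranks the generating interaction on top", {
  hb <- default_heat_table()
  fits <- suppressWarnings(suppressMessages(
    lapply(build_model_set("T_base"), function(s) fit_model(hb, s))))
  cmp <- compare_models(fits)
  expect_equal(cmp$table$label[1], "SSP * Ta")
})
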