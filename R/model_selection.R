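# AICc-based multimodel inference over Gaussian random-intercept models.
#
# Candidate fixed-effect structures are built from a small vocabulary —
# subspecies (SSP), ambient temperature (Ta) with quadratic and cubic
# polynomial terms, and their interactions — plus sqrt(activity) in every
# model and a per-individual random intercept. Models are fitted by full
# maximum likelihood (not REML) because the candidates differ in fixed
# effects, the standard choice for information-theoretic comparison.

RESPONSE_COLUMNS <- c(T_bill = "t_bill", T_base = "t_base", T_body = "t_body",
                      T_legs = "t_legs", Q_bill = "q_bill",
                      percent_Q_bill = "percent_q_bill",
                      RH = "relative_humidity")

TERM_VOCAB <- c("SSP", "Ta", "Ta2", "Ta3", "SSP:Ta", "SSP:Ta2", "SSP:Ta3")

term_label <- function(terms) {
  if (!length(terms)) return("Null")
  has_int <- function(t) paste0("SSP:", t) %in% terms
  pieces <- character(0)
  polys <- intersect(c("Ta", "Ta2", "Ta3"), terms)
  if ("SSP" %in% terms && !any(grepl("^SSP:", terms)) )
    pieces <- c(pieces, "SSP")
  for (p in polys) {
    nm <- c(Ta = "Ta", Ta2 = "Ta^2", Ta3 = "Ta^3")[[p]]
    pieces <- c(pieces, if (has_int(p)) paste0("SSP * ", nm) else nm)
  }
  paste(pieces, collapse = " + ")
}

validate_terms <- function(terms) {
  bad <- setdiff(terms, TERM_VOCAB)
  if (length(bad))
    stop("unknown model terms: ", paste(bad, collapse = ", "), call. = FALSE)
  need <- list(Ta2 = "Ta", Ta3 = "Ta2",
               `SSP:Ta` = c("SSP", "Ta"),
               `SSP:Ta2` = c("SSP:Ta", "Ta2"),
               `SSP:Ta3` = c("SSP:Ta2", "Ta3"))
  for (t in intersect(names(need), terms)) {
    missing <- setdiff(need[[t]], terms)
    if (length(missing))
      stop("term ", t, " requires ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  terms
}

#' Specify one candidate model
#'
#' @param response One of \code{T_bill}, \code{T_base}, \code{T_body},
#'   \code{T_legs}, \code{Q_bill}, \code{percent_Q_bill}, \code{RH}.
#' @param terms Character vector of fixed-effect terms from the vocabulary
#'   \code{SSP, Ta, Ta2, Ta3, SSP:Ta, SSP:Ta2, SSP:Ta3}. sqrt(activity) and
#'   the individual random intercept are always included and are not listed.
#' @param label Display label; derived from the terms by default.
#' @return List of class \code{model_spec}.
#' @export
model_spec <- function(response, terms = character(0), label = NULL) {
  response <- match.arg(response, names(RESPONSE_COLUMNS))
  terms <- validate_terms(terms)
  structure(list(response = response, terms = terms,
                 label = if (is.null(label)) term_label(terms) else label),
            class = "model_spec")
}

#' Build the full candidate model set for a response
#'
#' Eleven fixed-effect structures from the null model (sqrt-activity only)
#' through the saturated model
#' \code{SSP * Ta + SSP * Ta^2 + SSP * Ta^3}, respecting marginality
#' (interactions require main effects, higher polynomial orders require
#' lower ones). Every candidate carries sqrt(activity) and the individual
#' random intercept.
#'
#' @inheritParams model_spec
#' @return List of \code{model_spec} objects.
#' @export
build_model_set <- function(response) {
  term_sets <- list(
    character(0),
    "SSP",
    "Ta",
    c("Ta", "Ta2"),
    c("Ta", "Ta2", "Ta3"),
    c("SSP", "Ta"),
    c("SSP", "Ta", "Ta2"),
    c("SSP", "Ta", "Ta2", "Ta3"),
    c("SSP", "Ta", "SSP:Ta"),
    c("SSP", "Ta", "Ta2", "SSP:Ta", "SSP:Ta2"),
    c("SSP", "Ta", "Ta2", "Ta3", "SSP:Ta", "SSP:Ta2", "SSP:Ta3"))
  lapply(term_sets, function(ts) model_spec(response, ts))
}

spec_fixed_formula <- function(spec) {
  map <- c(SSP = "subspecies", Ta = "ta", Ta2 = "I(ta^2)", Ta3 = "I(ta^3)",
           `SSP:Ta` = "subspecies:ta", `SSP:Ta2` = "subspecies:I(ta^2)",
           `SSP:Ta3` = "subspecies:I(ta^3)")
  rhs <- c(unname(map[spec$terms]), "sqrt_activity")
  stats::as.formula(paste("~", paste(rhs, collapse = " + ")))
}

prepare_model_data <- function(data, spec) {
  ycol <- RESPONSE_COLUMNS[[spec$response]]
  needed <- c(ycol, "bird_id", "ta", "activity",
              if (any(grepl("SSP", spec$terms))) "subspecies")
  missing <- setdiff(needed, names(data))
  if (length(missing))
    stop("data lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- data[stats::complete.cases(data[needed]), , drop = FALSE]
  df$.y <- df[[ycol]]
  if (any(df$activity < 0)) stop("activity must be >= 0", call. = FALSE)
  df$sqrt_activity <- sqrt(df$activity)
  if (!is.null(df$subspecies)) df$subspecies <- factor(df$subspecies)
  df$bird_id <- factor(df$bird_id)
  df
}

#' Fit one candidate random-intercept model
#'
#' Fits a Gaussian linear mixed model with a per-individual random intercept
#' by full maximum likelihood (\code{lme4::lmer}, \code{REML = FALSE}). The
#' parameter count K is the number of fixed-effect coefficients plus two
#' variance parameters (random-intercept and residual), matching the
#' conventional AICc accounting where e.g. \code{SSP + Ta} has K = 6.
#'
#' @param data Observation data.frame; must contain \code{bird_id},
#'   \code{ta}, \code{activity}, the response column, and
#'   \code{subspecies} if any SSP term is used.
#' @param spec A [model_spec()].
#' @param random_intercept Set FALSE to drop the random intercept and fit
#'   ordinary least squares (then K = fixed coefficients + 1).
#' @return List of class \code{model_fit}: the spec, fitted model,
#'   coefficient estimates, variance components, \code{loglik}, \code{K},
#'   \code{n}.
#' @export
fit_model <- function(data, spec, random_intercept = TRUE) {
  df <- prepare_model_data(data, spec)
  fixed <- spec_fixed_formula(spec)
  if (random_intercept) {
    if (nlevels(df$bird_id) < 2)
      stop("random-intercept fit needs >= 2 individuals", call. = FALSE)
    form <- stats::update(fixed, .y ~ . + (1 | bird_id))
    model <- lme4::lmer(form, data = df, REML = FALSE)
    vc <- as.data.frame(lme4::VarCorr(model))
    ranef_var <- vc$vcov[vc$grp == "bird_id"]
    resid_var <- vc$vcov[vc$grp == "Residual"]
    beta <- lme4::fixef(model)
    k <- length(beta) + 2L
  } else {
    form <- stats::update(fixed, .y ~ .)
    model <- stats::lm(form, data = df)
    ranef_var <- 0
    resid_var <- sum(stats::residuals(model)^2) / stats::nobs(model)
    beta <- stats::coef(model)
    k <- length(beta) + 1L
  }
  if (any(is.na(beta)))
    stop("singular design: collinear terms ",
         paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
  structure(list(spec = spec, model = model, fixed_formula = fixed,
                 coefficients = beta,
                 ranef_variance = ranef_var, residual_variance = resid_var,
                 loglik = as.numeric(stats::logLik(model)),
                 K = k, n = stats::nobs(model),
                 data = df),
            class = "model_fit")
}

#' Small-sample corrected Akaike information criterion
#'
#' \eqn{AICc = -2 \log L + 2K + 2K(K+1)/(n - K - 1)}.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Parameter count (fixed coefficients plus variance parameters).
#' @param n Number of observations; must exceed \code{k + 1}.
#' @return AICc value.
#' @export
#' @examples
#' aicc(-100, 6, 216) # 212.402
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1))
    stop("AICc undefined: need n > K + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Compare fitted candidate models by AICc
#'
#' Ranks fits by AICc, computes \eqn{\Delta AICc} relative to the best model
#' and Akaike weights \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)}.
#' The full set is always retained; \code{delta_max} only controls the
#' display table.
#'
#' @param fits List of [fit_model()] results on the same data.
#' @param delta_max Display cutoff for [print()]/[comparison_table()]
#'   (default 5, the conventional reporting cutoff).
#' @return List of class \code{model_comparison}: sorted \code{table}
#'   (label, K, AICc, delta_aicc, weight), the \code{fits} in table order,
#'   and \code{delta_max}.
#' @export
compare_models <- function(fits, delta_max = 5) {
  if (!length(fits)) stop("no fits to compare", call. = FALSE)
  aiccs <- vapply(fits, function(f) aicc(f$loglik, f$K, f$n), numeric(1))
  delta <- aiccs - min(aiccs)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  ord <- order(aiccs)
  tab <- data.frame(label = vapply(fits, function(f) f$spec$label,
                                   character(1)),
                    K = vapply(fits, function(f) as.numeric(f$K),
                               numeric(1)),
                    AICc = aiccs, delta_aicc = delta, weight = w,
                    stringsAsFactors = FALSE)[ord, ]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits[ord], delta_max = delta_max),
            class = "model_comparison")
}

#' Display table of a model comparison
#'
#' @param comparison A [compare_models()] result.
#' @param truncate Keep only rows with \eqn{\Delta AICc} below the
#'   comparison's \code{delta_max} (default TRUE, mirroring conventional
#'   reporting); computations elsewhere always use the full set.
#' @return Data.frame with columns label, K, AICc, delta_aicc, weight.
#' @export
comparison_table <- function(comparison, truncate = TRUE) {
  tab <- comparison$table
  if (truncate) tab <- tab[tab$delta_aicc < comparison$delta_max, ]
  tab
}

#' @export
print.model_comparison <- function(x, ...) {
  print(comparison_table(x))
  invisible(x)
}

#' Evidence ratio between two candidate models
#'
#' Ratio of the Akaike weight of the model of interest to that of the
#' comparison (null) model.
#'
#' @param comparison A [compare_models()] result.
#' @param label_a,label_b Labels of the two models in the comparison table.
#' @return The weight ratio \code{w_a / w_b}.
#' @export
evidence_ratio <- function(comparison, label_a, label_b) {
  tab <- comparison$table
  ia <- match(label_a, tab$label)
  ib <- match(label_b, tab$label)
  if (is.na(ia) || is.na(ib))
    stop("model label not found in comparison", call. = FALSE)
  if (tab$weight[ib] <= 0)
    stop("comparison model has zero weight", call. = FALSE)
  tab$weight[ia] / tab$weight[ib]
}

fit_predict <- function(fit, newdata) {
  nd <- newdata
  if (!is.null(fit$data$subspecies)) {
    if (is.null(nd$subspecies))
      stop("prediction grid lacks 'subspecies'", call. = FALSE)
    nd$subspecies <- factor(nd$subspecies,
                            levels = levels(fit$data$subspecies))
  }
  x <- stats::model.matrix(fit$fixed_formula, data = nd)
  beta <- fit$coefficients
  x <- x[, names(beta), drop = FALSE]
  vc <- as.matrix(stats::vcov(fit$model))
  yhat <- unname(drop(x %*% beta))
  se <- unname(sqrt(rowSums((x %*% vc) * x)))
  list(fit = yhat, se = se)
}

#' Model-averaged predictions with unconditional standard errors
#'
#' Averages per-model predictions over the full candidate set using Akaike
#' weights, \eqn{\bar{\hat y} = \sum_i w_i \hat y_i}, and reports the
#' unconditional standard error
#' \eqn{\sum_i w_i \sqrt{se_i^2 + (\hat y_i - \bar{\hat y})^2}}, which
#' inflates the within-model SE by between-model spread. Per-model
#' prediction SEs are fixed-effects-only (conditional on random effects at
#' zero).
#'
#' @param comparison A [compare_models()] result.
#' @param newdata Prediction grid with \code{ta}, \code{sqrt_activity} and
#'   (if any candidate includes subspecies) \code{subspecies}.
#' @return \code{newdata} with columns \code{fit} (model-averaged
#'   prediction) and \code{unconditional_se} appended.
#' @export
model_average_predictions <- function(comparison, newdata) {
  w <- comparison$table$weight
  preds <- lapply(comparison$fits, fit_predict, newdata = newdata)
  yhat <- vapply(preds, `[[`, numeric(nrow(newdata)), "fit")
  ses <- vapply(preds, `[[`, numeric(nrow(newdata)), "se")
  yhat <- matrix(yhat, nrow = nrow(newdata))
  ses <- matrix(ses, nrow = nrow(newdata))
  ybar <- drop(yhat %*% w)
  unc <- drop(sqrt(ses^2 + (yhat - ybar)^2) %*% w)
  out <- newdata
  out$fit <- ybar
  out$unconditional_se <- unc
  out
}

#' Within-individual residual correlogram
#'
#' Pooled within-individual autocorrelation of model residuals at lags 1 to
#' \code{lag_max}, with approximate 95% white-noise bounds
#' \eqn{\pm 1.96/\sqrt{n}}. Residual series are ordered by ambient
#' temperature within each individual (the protocol's time axis). Used to
#' check that step-wise repeated measures are not temporally
#' autocorrelated beyond what the random intercept absorbs.
#'
#' @param fit A [fit_model()] result, or a data.frame with columns
#'   \code{residual} and \code{bird_id} (already time-ordered).
#' @param lag_max Maximum lag.
#' @return Data.frame with columns \code{lag} (0..lag_max), \code{acf},
#'   \code{lower}, \code{upper}.
#' @export
residual_correlogram <- function(fit, lag_max = 6) {
  if (inherits(fit, "model_fit")) {
    df <- data.frame(residual = stats::residuals(fit$model),
                     bird_id = fit$data$bird_id,
                     ta = fit$data$ta)
    df <- df[order(df$bird_id, df$ta), ]
  } else {
    df <- fit
  }
  groups <- split(df$residual, df$bird_id, drop = TRUE)
  denom <- sum(vapply(groups, function(e) sum((e - mean(e))^2), numeric(1)))
  n <- nrow(df)
  acfs <- vapply(0:lag_max, function(l) {
    num <- sum(vapply(groups, function(e) {
      e <- e - mean(e)
      if (length(e) <= l) return(0)
      sum(e[seq_len(length(e) - l)] * e[-seq_len(l)])
    }, numeric(1)))
    num / denom
  }, numeric(1))
  acfs[1] <- 1
  bound <- 1.96 / sqrt(n)
  data.frame(lag = 0:lag_max, acf = acfs, lower = -bound, upper = bound)
}

#' Pooled-variance two-sample t-test with Bonferroni correction
#'
#' Equal-variance (pooled) two-sample t-test; the P-value is multiplied by
#' the number of tests in the family and capped at 1.
#'
#' @param group_a,group_b Numeric vectors of observations.
#' @param n_tests Number of tests in the family (default 1, no correction).
#' @return List with \code{statistic}, \code{df}, \code{p_value},
#'   \code{p_adjusted}.
#' @export
pooled_t_bonferroni <- function(group_a, group_b, n_tests = 1) {
  tt <- stats::t.test(group_a, group_b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       p_adjusted = min(1, tt$p.value * n_tests))
}
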