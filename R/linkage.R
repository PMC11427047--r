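# Linking pathway activation to rigidity change: a synthetic-study generator
# with known effects, a random-intercept linear mixed-effects fit (one row
# per hemisphere x setting, fixed effects = activated-axon counts per pallidal
# pathway, random intercept per hemisphere), model-prediction diagnostics and
# the paired ON-vs-OFF signed-rank test.

LINKAGE_PATHWAYS <- c("GPi_efferent", "GPe_GPi_STN", "GPe_STN",
                      "Put_GPe", "Put_GPe_GPi")

#' Synthetic study effect parameters
#'
#' Per-pathway fixed-effect coefficients (rigidity-change units per activated
#' axon), hemisphere random-intercept s.d. and residual s.d. Defaults emulate
#' a study in which GPi-efferent (and, weakly, Put-GPe) activation reduces
#' rigidity while GPe-STN activation opposes the reduction.
#'
#' @param beta named coefficients over the five pallidal pathways.
#' @param random_intercept_sd hemisphere random-intercept s.d. (>= 0).
#' @param residual_sd residual s.d. (>= 0).
#' @param n_hemispheres number of hemispheres (>= 2; default 17 leads).
#' @param settings labels of the non-off settings per hemisphere.
#' @return object of class `study_effects`.
#' @export
study_effects <- function(beta = c(GPi_efferent = -1e-5, GPe_GPi_STN = 0,
                                   GPe_STN = 4e-6, Put_GPe = -4e-6,
                                   Put_GPe_GPi = 0),
                          random_intercept_sd = 8e-4, residual_sd = 1e-3,
                          n_hemispheres = 17,
                          settings = c("clinical", "dorsal", "ventral")) {
  b <- setNames(rep(0, length(LINKAGE_PATHWAYS)), LINKAGE_PATHWAYS)
  b[names(beta)] <- beta
  stopifnot(random_intercept_sd >= 0, residual_sd >= 0, n_hemispheres >= 2)
  structure(list(beta = b, random_intercept_sd = random_intercept_sd,
                 residual_sd = residual_sd, n_hemispheres = n_hemispheres,
                 settings = settings),
            class = "study_effects")
}

# Synthetic activated-axon counts when no pipeline-derived design is given:
# counts scale with amplitude rank of the setting and vary between
# hemispheres, loosely mimicking clinical > dorsal ~ ventral activation.
synthetic_activation_design <- function(effects) {
  base <- c(GPi_efferent = 300, GPe_GPi_STN = 150, GPe_STN = 120,
            Put_GPe = 100, Put_GPe_GPi = 180)
  mult <- c(clinical = 1, dorsal = 0.45, ventral = 0.4)
  rows <- list()
  for (hid in seq_len(effects$n_hemispheres)) {
    hscale <- runif(1, 0.5, 1.5)
    for (st in effects$settings) {
      counts <- round(base * ifelse(is.na(mult[st]), 0.5, mult[st]) * hscale *
                        runif(length(base), 0.6, 1.4))
      rows[[length(rows) + 1]] <- data.frame(
        hemisphere = hid, setting = st, t(counts))
    }
  }
  do.call(rbind, rows)
}

#' Simulate a linkage study
#'
#' Responses follow response = sum_i beta_i count_i + b_hemisphere + eps with
#' b ~ N(0, random_intercept_sd^2) and eps ~ N(0, residual_sd^2);
#' deterministic per seed.
#'
#' @param effects a [study_effects()].
#' @param activations optional data frame of predictors (columns hemisphere,
#'   setting and the five pathway counts); a synthetic design is generated
#'   when omitted.
#' @param seed integer seed.
#' @return data frame (`linkage_dataset`): hemisphere, setting, pathway
#'   counts, `response`.
#' @export
simulate_study <- function(effects = study_effects(), activations = NULL,
                           seed = 1) {
  with_seed(seed, {
    if (is.null(activations)) activations <- synthetic_activation_design(effects)
    stopifnot(all(LINKAGE_PATHWAYS %in% names(activations)))
    hems <- sort(unique(activations$hemisphere))
    b <- setNames(rnorm(length(hems), 0, effects$random_intercept_sd), hems)
    X <- as.matrix(activations[, LINKAGE_PATHWAYS])
    resp <- as.numeric(X %*% effects$beta) +
      b[as.character(activations$hemisphere)] +
      rnorm(nrow(activations), 0, effects$residual_sd)
    out <- activations
    out$response <- unname(resp)
    class(out) <- c("linkage_dataset", "data.frame")
    out
  })
}

#' Fit the pathway-activation linear mixed-effects model
#'
#' REML fit of `response ~ GPi_efferent + GPe_GPi_STN + GPe_STN + Put_GPe +
#' Put_GPe_GPi + (1 | hemisphere)` (or a caller-supplied subset of
#' predictors). Fixed-effect p-values are two-sided Wald. A singular
#' random-effect fit (variance estimated at 0) is flagged, not an error.
#'
#' @param data a `linkage_dataset` (or data frame with the same columns).
#' @param response column name of the response (default `"response"`).
#' @param predictors character vector of predictor columns.
#' @return object of class `linkage_fit` with print/summary/coef/predict
#'   methods; elements include `coefficients` (table with estimates, SE, z,
#'   p), `varcor`, `singular`, `BIC` and the underlying `lme4` fit.
#' @export
fit_linkage <- function(data, response = "response",
                        predictors = LINKAGE_PATHWAYS) {
  stopifnot(all(predictors %in% names(data)), response %in% names(data),
            "hemisphere" %in% names(data))
  if (length(unique(data$hemisphere)) < 2) stop("need >= 2 hemispheres")
  X <- as.matrix(data[, predictors, drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    drop <- predictors[qrX$pivot[seq(qrX$rank + 1, ncol(X) + 1)] - 1]
    stop("rank-deficient fixed-effect matrix; collinear predictors: ",
         paste(drop, collapse = ", "))
  }
  fml <- stats::as.formula(paste(response, "~",
                                 paste(predictors, collapse = " + "),
                                 "+ (1 | hemisphere)"))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(fml, data = data, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  coefs <- data.frame(estimate = est, se = se, z = z,
                      p_value = 2 * pnorm(-abs(z)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(coefficients = coefs, varcor = vc, singular = singular,
                 BIC = BIC(fit), response = response, predictors = predictors,
                 formula = fml, model = fit, data = data),
            class = "linkage_fit")
}

#' @export
print.linkage_fit <- function(x, ...) {
  cat("Linear mixed-effects linkage model:",
      deparse(x$formula), "\n")
  if (x$singular) cat("  (singular fit: random-intercept variance at 0)\n")
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
summary.linkage_fit <- function(object, ...) {
  cat("Linkage model for", object$response, "\n\n")
  print(object$coefficients)
  cat("\nVariance components:\n")
  print(object$varcor[, c("grp", "var1", "sdcor")])
  cat("\nBIC:", object$BIC, "\n")
  invisible(object)
}

#' @export
coef.linkage_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, rownames(object$coefficients))
}

#' @export
predict.linkage_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) unname(predict(object$model))
  else unname(predict(object$model, newdata = newdata, allow.new.levels = TRUE))
}

#' Model-predicted versus measured correlation
#'
#' Fitted values (fixed effects plus predicted random intercepts) are
#' compared to the measured responses with a Kendall rank correlation
#' (tau-b).
#'
#' @param fit a [fit_linkage()] result.
#' @param data optional evaluation data (defaults to the training data).
#' @return list: `tau`, `p_value`, `n`, `predicted`, `measured`.
#' @export
predict_and_correlate <- function(fit, data = NULL) {
  if (is.null(data)) data <- fit$data
  pred <- predict(fit, newdata = data)
  meas <- data[[fit$response]]
  kc <- kendall_correlation(pred, meas)
  c(kc, list(predicted = pred, measured = meas))
}

#' Paired ON-versus-OFF rigidity test
#'
#' Exact paired Wilcoxon signed-rank test (zero differences dropped, tied
#' absolute differences midranked) of per-hemisphere rigidity under a DBS
#' setting against OFF.
#'
#' @param off,on numeric vectors of per-hemisphere rigidity measures, paired
#'   by position.
#' @return as [wilcoxon_signed_rank()] (differences are on - off).
#' @export
paired_onoff_test <- function(off, on) {
  stopifnot(length(off) == length(on))
  wilcoxon_signed_rank(on, off)
}

#' Pallidal-efferent difference analysis
#'
#' The GPe-efferent count is the sum of both GPe-origin pathways
#' (GPe-STN and GPe-GPi-STN); the difference predictor is GPe efferents
#' minus GPi efferents. A single-predictor random-intercept LME is fit per
#' response, reporting slope, Wald p and BIC.
#'
#' @param data a `linkage_dataset`.
#' @param response response column name.
#' @return list: `slope`, `se`, `p_value`, `BIC`, `fit`.
#' @export
efferent_difference_analysis <- function(data, response = "response") {
  data$efferent_difference <-
    (data$GPe_STN + data$GPe_GPi_STN) - data$GPi_efferent
  fit <- fit_linkage(data, response = response,
                     predictors = "efferent_difference")
  cf <- fit$coefficients["efferent_difference", ]
  list(slope = cf$estimate, se = cf$se, p_value = cf$p_value,
       BIC = fit$BIC, fit = fit)
}

#' Build a linkage dataset from pipeline activation summaries
#'
#' Joins per-setting activation counts (rows from [summarize_activation()],
#' augmented with `hemisphere`) into the wide one-row-per-hemisphere-setting
#' layout the LME expects.
#'
#' @param summaries data frame with columns hemisphere, setting, pathway,
#'   n_activated.
#' @return data frame: hemisphere, setting, one count column per pallidal
#'   pathway.
#' @export
linkage_dataset_from_summaries <- function(summaries) {
  keep <- summaries[summaries$pathway %in% LINKAGE_PATHWAYS, ]
  wide <- stats::reshape(keep[, c("hemisphere", "setting", "pathway", "n_activated")],
                         idvar = c("hemisphere", "setting"),
                         timevar = "pathway", direction = "wide")
  names(wide) <- sub("^n_activated\\.", "", names(wide))
  for (pw in LINKAGE_PATHWAYS) if (!pw %in% names(wide)) wide[[pw]] <- 0L
  rownames(wide) <- NULL
  wide
}
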