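#' Iterative Spearman collinearity screen
#'
#' While any covariate pair has |Spearman rho| above the threshold, the
#' member of the worst pair whose univariate smooth model of the response
#' has the higher AIC is dropped.
#'
#' @param data data.frame holding the response and covariates.
#' @param response response column name.
#' @param covariates candidate covariate names.
#' @param threshold Spearman correlation cutoff (default 0.5).
#' @return character vector of retained covariates.
#' @export
collinearity_screen <- function(data, response, covariates, threshold = 0.5) {
  if (length(covariates) < 2) return(covariates)
  uni_aic <- function(v) {
    k <- min(5, length(unique(data[[v]])) - 1)
    f <- stats::as.formula(paste(response, "~ s(", v, ", k =", k, ")"))
    stats::AIC(mgcv::gam(f, data = data, method = "GCV.Cp"))
  }
  # constant covariates carry no signal and break the rank correlation
  keep <- covariates[vapply(covariates, function(v)
    length(unique(data[[v]])) > 1, logical(1))]
  repeat {
    if (length(keep) < 2) break
    rho <- stats::cor(data[, keep], method = "spearman",
                      use = "pairwise.complete.obs")
    diag(rho) <- 0
    rho[is.na(rho)] <- 0
    worst <- which(abs(rho) == max(abs(rho)), arr.ind = TRUE)[1, ]
    if (max(abs(rho)) <= threshold) break
    pair <- keep[worst]
    drop <- pair[which.max(vapply(pair, uni_aic, numeric(1)))]
    keep <- setdiff(keep, drop)
  }
  if (!length(keep)) stop("all covariates dropped by the collinearity screen")
  keep
}

#' Fit an additive habitat model of log-FPT duration
#'
#' Gaussian additive model of the response on univariate smooths (at most 5
#' knots each, to limit over-fitting), an optional isotropic two-dimensional
#' thin-plate smooth of the projected coordinates (spatial trend), and a
#' per-bird random intercept (penalized ridge term, `s(bird, bs = "re")`).
#' Smoothing parameters are chosen by generalized cross-validation.
#'
#' @param data data.frame with the response, covariates, `x`, `y` (km) and
#'   `bird_id`.
#' @param covariates covariate names entering as univariate smooths; the
#'   empty vector gives the intercept-only (plus random-intercept) model.
#' @param response response column name (default `"log_fpt"`).
#' @param spatial include the `s(x, y)` spatial smooth.
#' @param random include the per-bird random intercept.
#' @param k knots per univariate smooth (default 5).
#' @param label optional model label used in rankings.
#' @return the fitted `gam`, with `$fs_label` and `$fs_ed` (explained
#'   deviance, percent) attached.
#' @export
fit_additive_model <- function(data, covariates, response = "log_fpt",
                               spatial = FALSE, random = TRUE, k = 5,
                               label = NULL) {
  if (anyDuplicated(covariates)) stop("duplicate terms in model structure")
  terms <- character(0)
  for (v in covariates) {
    kv <- min(k, length(unique(data[[v]])) - 1)
    terms <- c(terms, sprintf("s(%s, k = %d)", v, kv))
  }
  if (spatial) terms <- c(terms, "s(x, y)")
  if (random) {
    data$bird_id <- factor(data$bird_id)
    if (nlevels(data$bird_id) > 1)
      terms <- c(terms, 's(bird_id, bs = "re")')
  }
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fit <- mgcv::gam(stats::as.formula(paste(response, "~", rhs)),
                   data = data, method = "GCV.Cp")
  fit$fs_label <- label %||% (if (length(covariates))
    paste(covariates, collapse = " + ") else "Constant")
  fit$fs_ed <- 100 * (1 - fit$deviance / fit$null.deviance)
  fit
}

#' Corrected Akaike information criterion
#'
#' AICc = AIC + 2k(k+1)/(n-k-1), with k the effective number of parameters
#' (total effective degrees of freedom of the fit, including scale).
#'
#' @param fit a fitted model with `logLik` and `AIC` methods.
#' @return the AICc value.
#' @export
aicc <- function(fit) {
  ll <- stats::logLik(fit)
  k <- as.numeric(attr(ll, "df"))
  n <- stats::nobs(fit)
  if (n - k - 1 <= 0) return(Inf)
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank candidate models by AICc
#'
#' @param fits list of fitted models from [fit_additive_model()], all fitted
#'   to the same rows.
#' @param top_delta flag models with delta AICc below this (default 2).
#' @return data.frame ordered by AICc: label, explained deviance (%), k,
#'   AICc, delta AICc, Akaike weight, `top` flag.
#' @export
rank_models <- function(fits, top_delta = 2) {
  ns <- vapply(fits, stats::nobs, numeric(1))
  if (length(unique(ns)) != 1)
    stop("all candidate models must be fitted to the same rows")
  a <- vapply(fits, aicc, numeric(1))
  d <- a - min(a)
  w <- exp(-d / 2) / sum(exp(-d / 2))
  out <- data.frame(
    structure = vapply(fits, function(f) f$fs_label %||% "model", character(1)),
    ed_pct = vapply(fits, function(f) f$fs_ed %||% NA_real_, numeric(1)),
    k_eff = vapply(fits, function(f)
      as.numeric(attr(stats::logLik(f), "df")), numeric(1)),
    aicc = a, delta_aicc = d, weight = w, top = d < top_delta)
  out[order(out$aicc), ]
}

#' Backwards model selection by bird-stratified k-fold cross-validation
#'
#' Starting from the full covariate set, repeatedly drops the term whose
#' removal least harms the mean out-of-fold squared error, as long as the
#' increase stays within one standard error of the per-fold paired
#' differences (terms whose removal actually improves the error always
#' qualify). This is the usual parsimony rule for selecting a minimum
#' adequate model: a term is kept only when removing it demonstrably
#' worsens prediction. Folds are stratified by bird so a bird's rows never
#' straddle the train/test split.
#'
#' @param data model data (as for [fit_additive_model()]).
#' @param covariates full covariate set.
#' @param response response column name.
#' @param k_folds number of folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @param ... passed to [fit_additive_model()].
#' @return list with `covariates` (the minimum adequate set), `cv_error`,
#'   and `path` (data.frame of the drop sequence).
#' @export
backwards_select <- function(data, covariates, response = "log_fpt",
                             k_folds = 5, seed = 42, ...) {
  if (k_folds < 2) stop("k_folds must be at least 2")
  set.seed(seed)
  birds <- unique(as.character(data$bird_id))
  fold_of_bird <- stats::setNames(
    rep_len(sample(k_folds), length(birds)), birds)
  fold <- fold_of_bird[as.character(data$bird_id)]
  cv_err <- function(covs) {
    errs <- vapply(sort(unique(fold)), function(f) {
      train <- data[fold != f, , drop = FALSE]
      test <- data[fold == f, , drop = FALSE]
      fit <- fit_additive_model(train, covs, response = response, ...)
      # the random intercept is excluded when predicting held-out birds;
      # map their ids onto a training level so the design matrix builds
      if (!is.null(fit$model$bird_id)) {
        lev <- levels(fit$model$bird_id)
        test$bird_id <- factor(rep(lev[1], nrow(test)), levels = lev)
      }
      pr <- mgcv::predict.gam(fit, newdata = test, exclude = "s(bird_id)")
      mean((test[[response]] - pr)^2)
    }, numeric(1))
    errs
  }
  current <- covariates
  best <- cv_err(current)
  path <- data.frame(dropped = "(full model)", cv_error = mean(best))
  repeat {
    if (!length(current)) break
    trials <- lapply(seq_along(current), function(i) cv_err(current[-i]))
    delta <- vapply(trials, function(tr) mean(tr - best), numeric(1))
    tol <- vapply(trials, function(tr)
      stats::sd(tr - best) / sqrt(length(tr)), numeric(1))
    # parsimony tolerance: one SE of the paired fold differences, floored
    # at 2% of the current error so near-zero terms cannot survive on noise
    ok <- delta < pmax(tol, 0.02 * mean(best))
    if (!any(ok)) break
    i <- which(ok)[which.min(delta[ok])]
    path <- rbind(path, data.frame(dropped = current[i],
                                   cv_error = mean(trials[[i]])))
    best <- trials[[i]]
    current <- current[-i]
  }
  list(covariates = current, cv_error = mean(best), path = path)
}

#' Evaluate a fitted smooth term's response curve
#'
#' Predicts the response over the observed range of one covariate with all
#' other covariates held at their medians (random intercept excluded),
#' giving the habitat-selection response curve for plotting or export.
#'
#' @param fit a fit from [fit_additive_model()].
#' @param data the data used to fit.
#' @param covariate covariate name.
#' @param n number of evaluation points.
#' @return data.frame with the covariate grid and predicted response.
#' @export
response_curve <- function(fit, data, covariate, n = 100) {
  vars <- setdiff(all.vars(stats::formula(fit))[-1], covariate)
  nd <- data.frame(seq(min(data[[covariate]]), max(data[[covariate]]),
                       length.out = n))
  names(nd) <- covariate
  for (v in vars) {
    nd[[v]] <- if (is.numeric(data[[v]])) stats::median(data[[v]])
               else data[[v]][1]
  }
  pr <- mgcv::predict.gam(fit, newdata = nd, exclude = "s(bird_id)",
                          newdata.guaranteed = TRUE, se.fit = TRUE)
  data.frame(value = nd[[covariate]], fit = as.numeric(pr$fit),
             se = as.numeric(pr$se.fit))
}
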