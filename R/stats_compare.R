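check_labels <- function(labels) {
  labels <- as.logical(labels)
  if (any(is.na(labels))) stop("labels must be binary with no missing values")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present")
  labels
}

# placement values of DeLong: for each positive, the fraction of negatives
# it beats (ties count 1/2), and symmetrically for negatives
placements <- function(scores, labels) {
  xs <- scores[labels]; ys <- scores[!labels]
  cmp <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = 1 - colMeans(cmp), auc = mean(cmp))
}

#' Empirical ROC analysis of one parameter
#'
#' Builds the empirical ROC curve over all observed score thresholds,
#' computes the AUC by the trapezoidal rule (equal to the all-pairs
#' Mann-Whitney probability), a DeLong-variance normal confidence interval,
#' and the operating point closest to (0, 1) in (FPR, TPR) space (ties
#' resolved toward higher sensitivity). The score orientation is chosen so
#' the AUC is >= 0.5 and is recorded.
#'
#' @param scores Numeric scores, no missing values.
#' @param labels Logical (or 0/1) class labels; `TRUE` is the positive
#'   class. Both classes must be present.
#' @param conf_level Confidence level for the AUC interval.
#' @return A `roc_result` with `auc`, `ci`, `cutoff` (score units),
#'   `sensitivity`, `specificity`, `accuracy` (percent), `orientation`
#'   (`">="` if high scores indicate the positive class, `"<="` otherwise)
#'   and the ROC `curve`.
#' @export
roc_analysis <- function(scores, labels, conf_level = 0.95) {
  labels <- check_labels(labels)
  if (any(!is.finite(scores))) stop("scores must be finite, no missing values")
  pl <- placements(scores, labels)
  orientation <- if (pl$auc >= 0.5) ">=" else "<="
  s <- if (orientation == ">=") scores else -scores
  thr <- sort(unique(s), decreasing = TRUE)
  pos <- s[labels]; neg <- s[!labels]
  tpr <- vapply(thr, function(c) mean(pos >= c), numeric(1))
  fpr <- vapply(thr, function(c) mean(neg >= c), numeric(1))
  auc <- trapz(c(0, fpr, 1), c(0, tpr, 1))
  d2 <- fpr^2 + (1 - tpr)^2
  best <- which(d2 == min(d2))
  if (length(best) > 1L) best <- best[which.max(tpr[best])]
  cutoff <- thr[best]
  sens <- tpr[best]; spec <- 1 - fpr[best]
  n1 <- sum(labels); n0 <- sum(!labels)
  acc <- (sens * n1 + spec * n0) / (n1 + n0)
  v <- stats::var(pl$v10) / n1 + stats::var(pl$v01) / n0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * sqrt(v), 0), 1)
  structure(list(auc = auc, ci = ci, var_auc = v,
                 cutoff = if (orientation == ">=") cutoff else -cutoff,
                 sensitivity = 100 * sens, specificity = 100 * spec,
                 accuracy = 100 * acc, orientation = orientation,
                 curve = data.frame(threshold = if (orientation == ">=") thr else -thr,
                                    fpr = fpr, tpr = tpr)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (%.3f-%.3f), cutoff %.4g (positive if %s cutoff)\n",
              x$auc, x$ci[1], x$ci[2], x$cutoff, x$orientation))
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Paired one-sided DeLong superiority test
#'
#' Compares the AUCs of two markers measured on the same subjects using the
#' DeLong placement-value covariance estimate. The default alternative is
#' superiority of marker A (`auc_a > auc_b`).
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Class labels (`TRUE` positive).
#' @param alternative `"greater"` (A superior), `"less"`, or `"two.sided"`.
#' @return A list with `p.value`, `auc_a`, `auc_b`, `z`, `var_diff`.
#' @export
delong_test <- function(scores_a, scores_b, labels,
                        alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  labels <- check_labels(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels))
    stop("scores and labels must be paired vectors of equal length")
  pa <- placements(scores_a, labels)
  pb <- placements(scores_b, labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- pa$auc - pb$auc
  if (v <= 0) {
    p <- if (d == 0) switch(alternative, two.sided = 1, 0.5)
         else switch(alternative, greater = as.numeric(d < 0),
                     less = as.numeric(d > 0), two.sided = 0)
    return(list(p.value = p, auc_a = pa$auc, auc_b = pb$auc, z = NA_real_,
                var_diff = v))
  }
  z <- d / sqrt(v)
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(-abs(z)))
  list(p.value = p, auc_a = pa$auc, auc_b = pb$auc, z = z, var_diff = v)
}

# ridge-penalized logistic fit used when ordinary IRLS separates; the
# penalty keeps the stepwise search deterministic. Returns unpenalized
# log-likelihood at the penalized estimate.
ridge_logit <- function(X, y, lambda = 1e-2) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      lambda * sum(b[-1]^2)
  }
  gr <- function(b) {
    mu <- stats::plogis(drop(X %*% b))
    drop(crossprod(X, mu - y)) + 2 * lambda * c(0, b[-1])
  }
  fit <- stats::optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  eta <- drop(X %*% fit$par)
  ll <- sum(y * eta - log1p(exp(eta)))
  list(coef = fit$par, loglik = ll, scores = stats::plogis(eta))
}

fit_candidate <- function(df, vars, y, family) {
  form <- stats::as.formula(paste("y ~",
    if (length(vars)) paste(vars, collapse = " + ") else "1"))
  dat <- cbind(df[, vars, drop = FALSE], y = y)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = dat, family = family),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (family == "binomial" && (sep || any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE))) {
    X <- cbind(1, as.matrix(df[, vars, drop = FALSE]))
    rf <- ridge_logit(X, as.numeric(y))
    k <- length(rf$coef)
    return(list(aic = -2 * rf$loglik + 2 * k, scores = rf$scores,
                coef = rf$coef, penalized = TRUE))
  }
  list(aic = stats::AIC(fit), scores = stats::fitted(fit),
       coef = stats::coef(fit), penalized = FALSE)
}

#' Bidirectional stepwise selection minimizing AIC
#'
#' Starting from the intercept-only model, repeatedly applies the single
#' variable addition or removal that most reduces the Akaike information
#' criterion, stopping when no move reduces it. The default family is
#' binomial (logistic), the natural choice for a binary diagnostic outcome
#' whose fitted scores feed a ROC analysis; a Gaussian-identity family is
#' available. Candidate logistic fits with perfect separation are refitted
#' with a small fixed ridge penalty so the search stays deterministic.
#'
#' @param predictors Data frame of numeric candidate predictors.
#' @param labels Class labels (`TRUE` positive).
#' @param family `"binomial"` or `"gaussian"`.
#' @return A `stepwise_fit` with `selected` (character vector, possibly
#'   empty), `aic`, `scores` (in-sample fitted values), `coef`, `trace`.
#' @export
stepwise_glm <- function(predictors, labels, family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  stopifnot(is.data.frame(predictors))
  labels <- check_labels(labels)
  if (nrow(predictors) != length(labels))
    stop("predictors and labels must have matching rows")
  if (nrow(predictors) <= ncol(predictors))
    stop("need more subjects than candidate predictors")
  y <- if (family == "binomial") as.numeric(labels) else as.numeric(labels)
  vars <- character(0)
  all_vars <- names(predictors)
  cur <- fit_candidate(predictors, vars, y, family)
  trace <- data.frame(step = 0L, move = "<start>", aic = cur$aic)
  repeat {
    moves <- c(paste0("+", setdiff(all_vars, vars)), paste0("-", vars))
    if (!length(moves)) break
    cands <- lapply(moves, function(mv) {
      nv <- if (startsWith(mv, "+")) c(vars, substring(mv, 2))
            else setdiff(vars, substring(mv, 2))
      tryCatch(fit_candidate(predictors, nv, y, family),
               error = function(e) NULL)
    })
    aics <- vapply(cands, function(f) if (is.null(f)) Inf else f$aic, numeric(1))
    best <- which.min(aics)
    if (!is.finite(aics[best]) || aics[best] >= cur$aic - 1e-8) break
    mv <- moves[best]
    vars <- if (startsWith(mv, "+")) c(vars, substring(mv, 2))
            else setdiff(vars, substring(mv, 2))
    cur <- cands[[best]]
    trace <- rbind(trace, data.frame(step = nrow(trace), move = mv, aic = cur$aic))
  }
  structure(list(selected = vars, aic = cur$aic, scores = cur$scores,
                 coef = cur$coef, family = family, trace = trace),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("Stepwise %s model (AIC %.3f): %s\n", x$family, x$aic,
              if (length(x$selected)) paste(x$selected, collapse = " + ")
              else "(intercept only)"))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, capped at 1.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-group comparison
#'
#' Mann-Whitney (Wilcoxon rank-sum) test for continuous variables (exact
#' when the combined sample is small and untied, normal approximation with
#' continuity correction otherwise) or a chi-squared test without
#' continuity correction for categorical variables.
#'
#' @param values Observations (numeric for `mann_whitney`, anything
#'   coercible to a factor for `chi_squared`).
#' @param labels Group labels (`TRUE`/`FALSE`); both groups non-empty.
#' @param kind `"mann_whitney"` or `"chi_squared"`.
#' @return The two-sided p-value.
#' @export
group_compare <- function(values, labels, kind = c("mann_whitney", "chi_squared")) {
  kind <- match.arg(kind)
  labels <- check_labels(labels)
  if (kind == "mann_whitney") {
    a <- values[labels]; b <- values[!labels]
    exact <- (length(values) <= 20) && !anyDuplicated(values)
    suppressWarnings(stats::wilcox.test(a, b, exact = exact)$p.value)
  } else {
    tab <- table(values, labels)
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }
}

#' Spearman correlation matrix of extracted parameters
#'
#' @param params Data frame of numeric parameters, >= 3 rows, no missing
#'   values. A constant column yields `NA` correlations.
#' @return Symmetric matrix of Spearman rank correlations.
#' @export
correlation_matrix <- function(params) {
  stopifnot(is.data.frame(params), nrow(params) >= 3L)
  if (anyNA(params)) stop("missing values not allowed")
  suppressWarnings(stats::cor(as.matrix(params), method = "spearman"))
}

# fixed mapping of dynamic models to their extracted parameters
model_parameters <- list(
  sq = c("ttp", "slope"),
  sq_fit = c("a1", "a2", "p", "q", "A", "B"),
  ref_sq = c("ttp_ratio", "slope_ratio"),
  logan = c("ved", "int_logan"),
  ref_logan = c("dvr", "rrt"),
  tcm = c("K1", "k2", "k3", "k4", "Ki", "Vb"))

#' Full diagnostic comparison of the dynamic models
#'
#' Given the per-subject parameter table produced by [analyze_cohort()] and
#' the binary IDH labels, computes: a per-parameter table of ROC results
#' plus Mann-Whitney p-values with Benjamini-Hochberg adjustment; a
#' per-model multivariable analysis (stepwise-AIC logistic model on the
#' model's parameters, in-sample ROC AUC of the fitted scores); the matrix
#' of pairwise one-sided DeLong superiority p-values between the model
#' scores (with BH adjustment of the off-diagonal entries); and the
#' Spearman correlation matrix of all parameters.
#'
#' @param params Data frame with one row per subject and a column per
#'   extracted parameter (see `dynfdopa:::model_parameters` for the
#'   expected names); extra columns are ignored.
#' @param labels Logical IDH-mutant labels, one per row.
#' @return A `comparison_report`.
#' @export
run_full_comparison <- function(params, labels) {
  labels <- check_labels(labels)
  all_pars <- unlist(model_parameters, use.names = FALSE)
  missing <- setdiff(all_pars, names(params))
  if (length(missing))
    stop("parameter table missing column(s): ", paste(missing, collapse = ", "))
  if (anyNA(params[, all_pars]))
    stop("every parameter must be present for every subject")

  par_rows <- lapply(names(model_parameters), function(m) {
    do.call(rbind, lapply(model_parameters[[m]], function(pn) {
      r <- roc_analysis(params[[pn]], labels)
      data.frame(model = m, parameter = pn, p_mw = group_compare(params[[pn]], labels),
                 auc = r$auc, ci_low = r$ci[1], ci_high = r$ci[2],
                 cutoff = r$cutoff, orientation = r$orientation,
                 sensitivity = r$sensitivity, specificity = r$specificity,
                 accuracy = r$accuracy)
    }))
  })
  parameter_table <- do.call(rbind, par_rows)
  parameter_table$p_mw_bh <- bh_adjust(parameter_table$p_mw)

  fits <- lapply(names(model_parameters), function(m)
    stepwise_glm(params[, model_parameters[[m]], drop = FALSE], labels))
  names(fits) <- names(model_parameters)
  model_table <- do.call(rbind, lapply(names(fits), function(m) {
    r <- roc_analysis(fits[[m]]$scores, labels)
    data.frame(model = m, auc = r$auc, ci_low = r$ci[1], ci_high = r$ci[2],
               selected = paste(fits[[m]]$selected, collapse = "+"))
  }))

  mods <- names(fits)
  delong_p <- matrix(NA_real_, length(mods), length(mods),
                     dimnames = list(superior = mods, inferior = mods))
  for (i in mods) for (j in mods) if (i != j)
    delong_p[i, j] <- delong_test(fits[[i]]$scores, fits[[j]]$scores,
                                  labels, "greater")$p.value
  delong_p_bh <- delong_p
  off <- !is.na(delong_p)
  delong_p_bh[off] <- bh_adjust(delong_p[off])

  structure(list(parameter_table = parameter_table, model_table = model_table,
                 delong_p = delong_p, delong_p_bh = delong_p_bh,
                 correlations = correlation_matrix(params[, all_pars]),
                 stepwise_fits = fits, n = length(labels),
                 n_positive = sum(labels)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Model comparison on %d subjects (%d IDH-mutant)\n\n",
              x$n, x$n_positive))
  cat("Multivariable model AUCs:\n")
  print(x$model_table, row.names = FALSE, digits = 3)
  cat("\nTop univariate parameters by accuracy:\n")
  pt <- x$parameter_table[order(-x$parameter_table$accuracy), ]
  print(utils::head(pt[, c("model", "parameter", "auc", "cutoff", "sensitivity",
                           "specificity", "accuracy", "p_mw", "p_mw_bh")], 8),
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.comparison_report <- function(object, ...) {
  cat("Pairwise one-sided DeLong superiority p-values (row superior to column):\n")
  print(round(object$delong_p, 3))
  invisible(object)
}
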