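test_that("ROC AUC equals the all-pairs Mann-Whitney probability", {
  # perfect and reversed separation
  expect_equal(roc_analysis(c(1, 2, 3, 10, 11), c(F, F, F, T, T))$auc, 1)
  r_rev <- roc_analysis(c(10, 11, 12, 1, 2), c(F, F, F, T, T))
  expect_equal(r_rev$auc, 1)
  expect_identical(r_rev$orientation, "<=")
  # brute-force oracle, including ties
  set.seed(8)
  for (i in 1:10) {
    n <- sample(6:15, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- sample(round(rnorm(n), 1))   # rounding induces ties
    r <- roc_analysis(scores, labels)
    expect_equal(r$auc, max(auc_bruteforce(scores, labels),
                            1 - auc_bruteforce(scores, labels)))
  }
  expect_error(roc_analysis(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  expect_error(roc_analysis(c(1, NA, 3), c(TRUE, FALSE, TRUE)), "finite")
})

test_that("ROC results agree with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  for (i in 1:5) {
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), 28, replace = TRUE))
    scores <- round(rnorm(30, mean = labels), 1)
    r <- roc_analysis(scores, labels)
    pr <- pROC::roc(labels, scores, quiet = TRUE)
    expect_equal(r$auc, as.numeric(pROC::auc(pr)))
    ci <- pROC::ci.auc(pr, method = "delong")
    expect_equal(r$ci, as.numeric(ci[c(1, 3)]), tolerance = 1e-8)
  }
})

test_that("the operating point is the threshold closest to (0, 1)", {
  # constructed example: cutoff between the classes, one mislabeled point
  scores <- c(1, 2, 3, 4, 2.5, 5, 6, 7)
  labels <- c(F, F, F, F, T, T, T, T)
  r <- roc_analysis(scores, labels)
  # enumerate every candidate threshold's distance to (0, 1) explicitly
  thr <- sort(unique(scores), decreasing = TRUE)
  d <- vapply(thr, function(c) {
    sens <- mean(scores[labels] >= c); spec <- mean(scores[!labels] < c)
    (1 - spec)^2 + (1 - sens)^2
  }, numeric(1))
  expect_equal(r$cutoff, thr[which.min(d)])
  expect_equal(r$sensitivity, 100 * mean(scores[labels] >= r$cutoff))
  expect_equal(r$specificity, 100 * mean(scores[!labels] < r$cutoff))
  # accuracy is the class-weighted mean of sens and spec
  acc <- mean((scores >= r$cutoff) == labels)
  expect_equal(r$accuracy, 100 * acc)
  # tie in distance resolved toward higher sensitivity
  s2 <- c(1, 4, 2, 3)
  l2 <- c(F, F, T, T)
  r2 <- roc_analysis(s2, l2)
  expect_equal(r2$sensitivity, 100)
})

test_that("DeLong test matches enumeration and behaves at the degenerate point", {
  set.seed(3)
  labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), 16, replace = TRUE))
  a <- rnorm(18); b <- 0.5 * a + rnorm(18)
  dt <- delong_test(a, b, labels)
  expect_equal(dt$var_diff, delong_var_bruteforce(a, b, labels))
  expect_equal(dt$auc_a, auc_bruteforce(a, labels))
  # one-sided complements sum to one
  expect_equal(delong_test(a, b, labels, "greater")$p.value +
                 delong_test(b, a, labels, "greater")$p.value, 1)
  # identical scores: no evidence either way
  expect_equal(delong_test(a, a, labels, "greater")$p.value, 0.5)
  expect_equal(delong_test(a, a, labels, "two.sided")$p.value, 1)
  expect_error(delong_test(a, b[1:5], labels), "paired")
})

test_that("DeLong p-values agree with pROC's paired test", {
  skip_if_not_installed("pROC")
  set.seed(9)
  for (i in 1:5) {
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), 23, replace = TRUE))
    a <- round(rnorm(25, mean = labels), 1)
    b <- round(rnorm(25, mean = 0.5 * labels), 1)
    ra <- pROC::roc(labels, a, quiet = TRUE, direction = "<")
    rb <- pROC::roc(labels, b, quiet = TRUE, direction = "<")
    pp <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE,
                         alternative = "greater")$p.value
    expect_equal(delong_test(a, b, labels, "greater")$p.value, pp,
                 tolerance = 1e-10)
  }
})

test_that("stepwise selection minimizes AIC and finds a strong predictor", {
  set.seed(21)
  n <- 60
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  df <- data.frame(good = rnorm(n, mean = 2 * labels),
                   junk1 = rnorm(n), junk2 = rnorm(n))
  fit <- stepwise_glm(df, labels)
  expect_true("good" %in% fit$selected)
  # the reported AIC matches a direct glm refit of the selected model
  ref <- stats::glm(reformulate(fit$selected, "y"),
                    data = cbind(df, y = as.numeric(labels)),
                    family = "binomial")
  expect_equal(fit$aic, stats::AIC(ref), tolerance = 1e-8)
  # never worse than the intercept-only model
  null_aic <- stats::AIC(stats::glm(y ~ 1,
                                    data = data.frame(y = as.numeric(labels)),
                                    family = "binomial"))
  expect_lte(fit$aic, null_aic)
  idx <- c(1, 2, 31)     # both classes present, but too few rows
  expect_error(stepwise_glm(df[idx, ], labels[idx]), "more subjects")
})

test_that("stepwise search agrees with stats::step when IRLS is stable", {
  set.seed(31)
  n <- 80
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  df <- data.frame(a = rnorm(n, mean = 1.2 * labels),
                   b = rnorm(n, mean = 0.8 * labels),
                   c = rnorm(n), d = rnorm(n))
  fit <- stepwise_glm(df, labels)
  dat <- cbind(df, y = as.numeric(labels))
  full <- stats::glm(y ~ a + b + c + d, data = dat, family = "binomial")
  ref <- stats::step(stats::glm(y ~ 1, data = dat, family = "binomial"),
                     scope = stats::formula(full), direction = "both",
                     trace = 0)
  expect_setequal(fit$selected, setdiff(names(stats::coef(ref)), "(Intercept)"))
  expect_equal(fit$aic, stats::AIC(ref), tolerance = 1e-8)
})

test_that("separated logistic fits fall back to the ridge path", {
  labels <- rep(c(TRUE, FALSE), each = 10)
  df <- data.frame(sep = as.numeric(labels) + seq(0, 0.019, by = 0.001))
  fit <- stepwise_glm(df, labels)
  expect_true(all(is.finite(fit$coef)))
  expect_true(all(fit$scores >= 0 & fit$scores <= 1))
  # the ridge scores still separate the classes perfectly
  expect_equal(roc_analysis(fit$scores, labels)$auc, 1)
})

test_that("Benjamini-Hochberg adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.4), 0.4)
  set.seed(5)
  for (i in 1:10) {
    p <- runif(sample(2:10, 1))
    expect_equal(bh_adjust(p), bh_bruteforce(p))
  }
  # adjustment never decreases a p-value and preserves the ordering
  p <- runif(6)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("group comparison reduces to known small-sample answers", {
  labels <- c(T, T, T, F, F, F)
  # exact Mann-Whitney oracle: p = 2 * (#splits with U <= observed) / C(6,3)
  vals <- c(5, 6, 9, 1, 2, 7)
  p_pkg <- group_compare(vals, labels)
  combs <- utils::combn(6, 3)
  u_of <- function(idx) {
    a <- vals[idx]; b <- vals[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(which(labels))
  us <- apply(combs, 2, u_of)
  mu <- mean(us)
  p_exact <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  expect_equal(p_pkg, p_exact)
  # interleaved groups with U one step from its null mean: exact p is 1
  expect_equal(group_compare(c(1, 4, 5, 2, 3, 6), labels), 1)
  # chi-squared without continuity correction, hand-computed
  x <- rep(c("hi", "lo"), c(10, 10))
  g <- rep(c(TRUE, FALSE), 10)
  tab <- table(x, g)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  expect_equal(group_compare(x, g, "chi_squared"),
               stats::pchisq(stat, df = 1, lower.tail = FALSE))
})

test_that("Spearman correlations equal Pearson correlations of ranks", {
  set.seed(6)
  df <- data.frame(a = rnorm(12), b = rnorm(12), c = rnorm(12))
  df$d <- df$a^3          # monotone transform: rho = 1
  m <- correlation_matrix(df)
  expect_equal(m["a", "d"], 1)
  expect_equal(diag(m), setNames(rep(1, 4), names(df)))
  expect_equal(m["a", "b"], stats::cor(rank(df$a), rank(df$b)))
  expect_error(correlation_matrix(df[1:2, ]), "nrow")
  df$a[1] <- NA
  expect_error(correlation_matrix(df), "missing")
})

test_that("the full comparison report has the expected structure", {
  set.seed(77)
  n <- 30
  labels <- rep(c(TRUE, FALSE), c(12, 18))
  pars <- unlist(dynfdopa:::model_parameters, use.names = FALSE)
  params <- as.data.frame(setNames(
    lapply(pars, function(p) rnorm(n)), pars))
  # make TTP strongly separated so at least one model discriminates
  params$ttp <- ifelse(labels, rnorm(n, 22, 2), rnorm(n, 5, 2))
  rep1 <- run_full_comparison(params, labels)
  expect_s3_class(rep1, "comparison_report")
  expect_equal(nrow(rep1$model_table), 6L)
  expect_equal(sum(!is.na(rep1$delong_p)), 30L)       # 6x6 minus diagonal
  expect_true(all(rep1$model_table$auc >= 0.5 & rep1$model_table$auc <= 1))
  expect_equal(nrow(rep1$parameter_table), length(pars))
  # TTP should be flagged significant, before and after adjustment
  ttp_row <- rep1$parameter_table[rep1$parameter_table$parameter == "ttp", ]
  expect_lt(ttp_row$p_mw_bh, 0.05)
  expect_gt(ttp_row$auc, 0.9)
  # determinism
  rep2 <- run_full_comparison(params, labels)
  expect_identical(rep1$model_table, rep2$model_table)
  expect_identical(rep1$delong_p, rep2$delong_p)
  # missing columns rejected by name
  expect_error(run_full_comparison(params[, -1], labels), "ttp")
  expect_output(print(rep1), "Model comparison")
  expect_output(summary(rep1), "DeLong")
})
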