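test_that("group assignment follows the median-split and threshold rules", {
  g <- assign_groups(c(a = -1, b = -2, c = -5, d = -6))
  expect_equal(as.character(g$label), c("mild", "mild", "significant",
                                        "significant"))
  g2 <- assign_groups(c(a = -2, b = -4), rule = "threshold", threshold = -3)
  expect_equal(as.character(g2$label), c("mild", "significant"))
  # tie at the boundary goes to significant
  g3 <- assign_groups(c(a = -3, b = -1), rule = "threshold", threshold = -3)
  expect_equal(as.character(g3$label), c("significant", "mild"))
  expect_error(assign_groups(rep(-2, 5)), "identical")
  expect_error(assign_groups(c(a = -1)), "2 subjects")
})

test_that("the stump finds the midpoint split on separable data", {
  s <- fit_stump(c(1, 2, 9, 10), c("mild", "mild", "significant",
                                   "significant"))
  expect_equal(s$threshold, 5.5)
  expect_equal(s$high_class, "significant")
  expect_equal(s$low_class, "mild")
  # flipped orientation
  s2 <- fit_stump(c(1, 2, 9, 10), c("significant", "significant", "mild",
                                    "mild"))
  expect_equal(s2$high_class, "mild")
  # degenerate constant feature predicts the training majority
  s3 <- fit_stump(rep(4, 5), c("mild", "mild", "mild", "significant",
                               "significant"))
  expect_true(s3$degenerate)
  expect_equal(s3$high_class, "mild")
  expect_error(fit_stump(1:4, rep("mild", 4)), "both classes")
})

test_that("stump training error equals the brute-force minimum", {
  set.seed(55)
  for (i in 1:500) {
    n <- sample(4:8, 1)
    vals <- sample(1:6, n, replace = TRUE) + stats::runif(n, 0, 0.01)
    labs <- c("mild", "significant",
              sample(c("mild", "significant"), n - 2, replace = TRUE))
    st <- fit_stump(vals, labs)
    pred <- as.character(predict(st, vals))
    expect_equal(sum(pred != labs), stump_brute_force_error(vals, labs))
  }
})

test_that("LOOCV screening handles separable, constant and toy features", {
  x <- data.frame(sep = c(1:8, 101:108), const = rep(5, 16),
                  noise = rep(c(1, 2), 8))
  labs <- rep(c("mild", "significant"), each = 8)
  scr <- loocv_screen(x, labs)
  expect_equal(scr$f_score[scr$feature == "sep"], 1)
  expect_equal(scr$accuracy[scr$feature == "sep"], 1)
  # constant feature on a balanced cohort: every held-out subject is
  # predicted as the training majority, which is always the other class
  expect_equal(scr$accuracy[scr$feature == "const"], 0)
  expect_error(loocv_screen(x[1:3, ], labs[1:3]), "n >= 4")
  expect_error(loocv_screen(x, rep("mild", 16)), "at least 2")
})

test_that("LOOCV metrics equal fold-by-fold enumeration on a toy cohort", {
  vals <- c(1, 2, 3, 4, 5, 2.5)   # one overlapping point
  labs <- c("mild", "mild", "significant", "significant", "significant",
            "mild")
  scr <- loocv_screen(data.frame(f = vals), labs)
  # manual enumeration
  pred <- character(6)
  for (k in 1:6) {
    st <- fit_stump(vals[-k], labs[-k])
    pred[k] <- as.character(predict(st, vals[k]))
  }
  tp <- sum(pred == "significant" & labs == "significant")
  fp <- sum(pred == "significant" & labs == "mild")
  fn <- sum(pred == "mild" & labs == "significant")
  prec <- tp / (tp + fp); rec <- tp / (tp + fn)
  expect_equal(scr$accuracy, mean(pred == labs))
  expect_equal(scr$f_score, 2 * prec * rec / (prec + rec))
})

test_that("screening excludes missing subjects and stays deterministic", {
  set.seed(8)
  x <- data.frame(f = c(stats::rnorm(8, 0), stats::rnorm(8, 3)),
                  g = c(NA, NA, stats::rnorm(14, 0)))
  labs <- rep(c("mild", "significant"), each = 8)
  a <- loocv_screen(x, labs)
  b <- loocv_screen(x, labs)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(a$n_excluded[a$feature == "g"], 2)
})

test_that("feature ranking is by F-score, accuracy, then name", {
  df <- data.frame(feature = c("A", "B", "C"),
                   f_score = c(0.9, 0.9, 0.95),
                   accuracy = c(0.8, 0.9, 0.7))
  r <- rank_features(df)
  expect_equal(r$feature, c("C", "B", "A"))
  df2 <- data.frame(feature = c("B", "A"), f_score = c(0.9, 0.9),
                    accuracy = c(0.9, 0.9))
  expect_equal(rank_features(df2)$feature, c("A", "B"))
  expect_equal(rank_features(df, top_k = 1)$feature, "C")
})

test_that("the linear boundary solves canonical two-point geometry", {
  b <- train_linear_svm(c(-1, 1), c(0, 0), c("mild", "significant"),
                        cost = 1000)
  expect_equal(b$w1, 1, tolerance = 1e-3)
  expect_equal(b$w2, 0, tolerance = 1e-3)
  expect_equal(b$b, 0, tolerance = 1e-3)
  # flipping the labels flips every coefficient sign
  b2 <- train_linear_svm(c(-1, 1), c(0, 0), c("significant", "mild"),
                         cost = 1000)
  expect_equal(c(b2$w1, b2$w2, b2$b), -c(b$w1, b$w2, b$b),
               tolerance = 1e-3)
  expect_error(train_linear_svm(1:3, 1:3, rep("mild", 3)), "both classes")
})

test_that("boundary equations are formatted in the reporting layout", {
  expect_equal(format_boundary(-0.0261, -0.3366, -1.6558),
               "-0.0261x1 - 0.3366x2 - 1.6558 = 0")
  expect_equal(format_boundary(1.5, -2, 0.25),
               "1.5000x1 - 2.0000x2 + 0.2500 = 0")
})

test_that("the fitted classifier exposes the standard model interface", {
  set.seed(12)
  x <- data.frame(
    good = c(stats::rnorm(8, 0), stats::rnorm(8, 5)),
    ok = c(stats::rnorm(8, 0), stats::rnorm(8, 3)),
    junk = stats::rnorm(16))
  labs <- rep(c("mild", "significant"), each = 8)
  fit <- fatigue_classifier(x, labs)
  expect_s3_class(fit, "fatigue_classifier")
  expect_named(coef(fit), c("w1", "w2", "b"))
  pr <- predict(fit, x)
  expect_s3_class(pr, "factor")
  expect_gte(mean(pr == labs), 0.8)
  dv <- predict(fit, x, type = "decision")
  expect_equal(as.character(pr),
               ifelse(dv > 0, "significant", "mild"))
  expect_output(print(fit), "Decision boundary")
  expect_output(print(summary(fit)), "Training accuracy")
  tmp_png <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tmp_png); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tmp_png))
})

test_that("stump splits agree with an independent tree learner", {
  skip_if_not_installed("rpart")
  set.seed(77)
  for (i in 1:20) {
    vals <- stats::runif(12, 0, 10)
    labs <- ifelse(vals + stats::rnorm(12, 0, 2) > 5, "significant",
                   "mild")
    if (length(unique(labs)) < 2) next
    st <- fit_stump(vals, labs)
    rp <- rpart::rpart(y ~ x, data.frame(x = vals, y = factor(labs)),
                       method = "class",
                       control = rpart::rpart.control(maxdepth = 1,
                                                      minsplit = 2,
                                                      minbucket = 1,
                                                      cp = -1, xval = 0))
    if (is.null(rp$splits)) next
    # equal training error (split points may differ under ties)
    pred_st <- as.character(predict(st, vals))
    pred_rp <- as.character(predict(rp, type = "class"))
    expect_equal(sum(pred_st != labs), sum(pred_rp != labs))
  }
})
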