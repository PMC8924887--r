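#' Assign fatigue groups from CMJ-height change
#'
#' Subjects are split into mildly and significantly fatigued groups by their
#' relative change in countermovement-jump height between states.  The
#' default rule is a median split: subjects at or below the median change
#' (i.e. losing more jump height) are labelled `significant`; ties at the
#' boundary go to `significant`.  A fixed threshold rule is also available.
#'
#' @param cmj_changes Named numeric vector of per-subject CMJ changes in
#'   percent (negative = jump height lost).
#' @param rule `"median"` (default) or `"threshold"`.
#' @param threshold Cut point in percent for `rule = "threshold"`; changes
#'   at or below it are `significant`.
#' @return Data frame `subject_id`, `cmj_change`, `label` (factor with
#'   levels `mild`, `significant`).
#' @examples
#' assign_groups(c(a = -1, b = -2, c = -5, d = -6))
#' @export
assign_groups <- function(cmj_changes, rule = c("median", "threshold"),
                          threshold = NULL) {
  rule <- match.arg(rule)
  if (length(cmj_changes) < 2L) stop("need at least 2 subjects")
  if (rule == "median") {
    if (length(unique(cmj_changes)) == 1L) {
      stop("all CMJ changes are identical: a median split is undefined, ",
           "supply an explicit threshold (rule = \"threshold\")")
    }
    cut <- stats::median(cmj_changes)
  } else {
    if (is.null(threshold)) stop("'threshold' required for threshold rule")
    cut <- threshold
  }
  lab <- factor(ifelse(cmj_changes <= cut, "significant", "mild"),
                levels = c("mild", "significant"))
  ids <- names(cmj_changes)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_along(cmj_changes))
  data.frame(subject_id = ids, cmj_change = as.numeric(cmj_changes),
             label = lab, stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit a decision stump
#'
#' A depth-1 decision tree on a single feature: exhaustive search over the
#' midpoints between consecutive sorted distinct training values, choosing
#' the split minimizing weighted Gini impurity.  Ties between thresholds are
#' broken toward the smaller threshold; each leaf predicts its majority
#' class, with leaf ties predicting `significant`.  With fewer than two
#' distinct values the stump is degenerate: threshold `-Inf` and both sides
#' predicting the training majority (tie again to `significant`).
#'
#' @param values Numeric training values (one feature).
#' @param labels Factor (or character) with levels `mild`, `significant`;
#'   both classes must be present.
#' @return Object of class `"fatigue_stump"`: `threshold`, `low_class`,
#'   `high_class`, `gini`, `degenerate`.
#' @examples
#' s <- fit_stump(c(1, 2, 9, 10), c("mild", "mild", "significant", "significant"))
#' s$threshold
#' @export
fit_stump <- function(values, labels) {
  labels <- factor(as.character(labels), levels = c("mild", "significant"))
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  if (nlevels(droplevels(labels)) < 2L) {
    stop("both classes must be present to fit a stump")
  }
  n <- length(values)
  majority <- function(l) {
    ns <- sum(l == "significant"); nm <- sum(l == "mild")
    if (ns >= nm) "significant" else "mild"
  }
  sv <- sort(unique(values))
  if (length(sv) < 2L) {
    maj <- majority(labels)
    return(structure(list(threshold = -Inf, low_class = maj,
                          high_class = maj, gini = NA_real_,
                          degenerate = TRUE),
                     class = "fatigue_stump"))
  }
  mids <- (sv[-length(sv)] + sv[-1L]) / 2
  best <- NULL
  for (thr in mids) {
    lo <- labels[values <= thr]; hi <- labels[values > thr]
    gini_leaf <- function(l) {
      p <- mean(l == "significant")
      2 * p * (1 - p)
    }
    g <- (length(lo) * gini_leaf(lo) + length(hi) * gini_leaf(hi)) / n
    if (is.null(best) || g < best$gini - 1e-12) {
      best <- list(threshold = thr, gini = g,
                   low_class = majority(lo), high_class = majority(hi))
    }
  }
  structure(c(best[c("threshold", "low_class", "high_class", "gini")],
              list(degenerate = FALSE)),
            class = "fatigue_stump")
}

#' @export
predict.fatigue_stump <- function(object, newdata, ...) {
  out <- ifelse(newdata > object$threshold, object$high_class,
                object$low_class)
  factor(out, levels = c("mild", "significant"))
}

#' @export
print.fatigue_stump <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate decision stump: always predicts", x$high_class, "\n")
  } else {
    cat("Decision stump: value >", format(x$threshold), "->", x$high_class,
        "; else ->", x$low_class, "\n")
  }
  invisible(x)
}

pooled_metrics <- function(pred, truth) {
  tp <- sum(pred == "significant" & truth == "significant")
  fp <- sum(pred == "significant" & truth == "mild")
  fn <- sum(pred == "mild" & truth == "significant")
  acc <- mean(pred == truth)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(f_score = f, accuracy = acc)
}

#' Screen features with leave-one-out decision stumps
#'
#' For every feature and every held-out subject, a stump is fitted on the
#' remaining subjects and used to predict the held-out subject; the n pooled
#' predictions yield the feature's F-score (harmonic mean of precision and
#' recall, `significant` as positive class) and accuracy.  Subjects missing
#' a feature are excluded from that feature's folds and counted.  A training
#' fold that loses a class entirely predicts the remaining class (flagged in
#' `n_degenerate_folds`).
#'
#' @param x Data frame or matrix, subjects x features (rownames = ids).
#' @param labels Factor/character labels aligned with rows of `x`
#'   (levels `mild`, `significant`); both classes need >= 2 members.
#' @return Object of class `"fatigue_screen"`: a data frame with one row per
#'   feature (`feature`, `f_score`, `accuracy`, `n_excluded`,
#'   `n_degenerate_folds`) and attributes `predictions` (list of per-fold
#'   predictions) and `thresholds` (list of per-fold stump thresholds).
#' @export
loocv_screen <- function(x, labels) {
  x <- as.data.frame(x)
  n <- nrow(x)
  labels <- factor(as.character(labels), levels = c("mild", "significant"))
  if (n < 4L) stop("LOOCV screening needs n >= 4 subjects")
  if (min(table(labels)) < 2L) {
    stop("both classes need at least 2 subjects")
  }
  feats <- colnames(x)
  res <- data.frame(feature = feats, f_score = NA_real_,
                    accuracy = NA_real_, n_excluded = 0L,
                    n_degenerate_folds = 0L, stringsAsFactors = FALSE)
  preds <- stats::setNames(vector("list", length(feats)), feats)
  thrs <- stats::setNames(vector("list", length(feats)), feats)
  for (j in seq_along(feats)) {
    v <- x[[j]]
    ok <- which(!is.na(v))
    res$n_excluded[j] <- n - length(ok)
    if (length(ok) < 4L || min(table(droplevels(labels[ok]))) < 2L) next
    pred <- factor(rep(NA_character_, length(ok)),
                   levels = c("mild", "significant"))
    th <- numeric(length(ok))
    ndeg <- 0L
    for (k in seq_along(ok)) {
      tr <- ok[-k]
      if (length(unique(droplevels(labels[tr]))) < 2L) {
        pred[k] <- unique(as.character(droplevels(labels[tr])))
        th[k] <- NA_real_
        ndeg <- ndeg + 1L
        next
      }
      st <- fit_stump(v[tr], labels[tr])
      pred[k] <- as.character(predict(st, v[ok[k]]))
      th[k] <- st$threshold
    }
    m <- pooled_metrics(pred, labels[ok])
    res$f_score[j] <- m["f_score"]
    res$accuracy[j] <- m["accuracy"]
    res$n_degenerate_folds[j] <- ndeg
    preds[[j]] <- stats::setNames(as.character(pred), rownames(x)[ok])
    thrs[[j]] <- th
  }
  structure(res, predictions = preds, thresholds = thrs,
            class = c("fatigue_screen", "data.frame"))
}

#' Rank screened features
#'
#' Descending by F-score, ties broken by accuracy (descending) then by
#' feature name (ascending).
#'
#' @param screen A [loocv_screen()] result (or compatible data frame).
#' @param top_k Optionally return only the first `top_k` rows.
#' @return The screening data frame, reordered.
#' @export
rank_features <- function(screen, top_k = NULL) {
  df <- as.data.frame(screen)
  o <- order(-replace(df$f_score, is.na(df$f_score), -Inf),
             -replace(df$accuracy, is.na(df$accuracy), -Inf),
             df$feature)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(top_k)) df <- utils::head(df, top_k)
  df
}

#' Train a two-feature linear maximum-margin classifier
#'
#' Fits a soft-margin linear support vector machine on two features and
#' reports the boundary as coefficients `(w1, w2, b)` with the decision rule
#' `sign(w1 * x1 + w2 * x2 + b)` (positive side = `significant`), plus a
#' formatted equation string `w1 x1 + w2 x2 + b = 0`.
#'
#' @param x1,x2 Numeric feature vectors.
#' @param labels Labels (`mild` / `significant`); both classes present.
#' @param cost Soft-margin cost parameter C (default 1; large values
#'   approach the hard-margin solution).
#' @param feature_names Names reported for x1 and x2.
#' @return Object of class `"linear_boundary"`: `w1`, `w2`, `b`, `features`,
#'   `cost`, `equation`.
#' @export
train_linear_svm <- function(x1, x2, labels, cost = 1,
                             feature_names = c("x1", "x2")) {
  labels <- factor(as.character(labels), levels = c("mild", "significant"))
  ok <- is.finite(x1) & is.finite(x2) & !is.na(labels)
  x1 <- x1[ok]; x2 <- x2[ok]; labels <- droplevels(labels[ok])
  if (nlevels(labels) < 2L) stop("both classes must be present")
  # standardize internally (features can differ in scale by orders of
  # magnitude); coefficients are reported back on the original scale
  mu <- c(mean(x1), mean(x2))
  sdev <- c(stats::sd(x1), stats::sd(x2))
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  xm <- cbind(x1 = (x1 - mu[1]) / sdev[1], x2 = (x2 - mu[2]) / sdev[2])
  fit <- e1071::svm(xm, labels, kernel = "linear", cost = cost,
                    scale = FALSE)
  w_s <- drop(t(fit$coefs) %*% fit$SV)
  b_s <- -fit$rho
  w <- w_s / sdev
  b <- b_s - sum(w_s * mu / sdev)
  # orient so that w.x + b > 0 predicts 'significant'
  dv <- w[1] * x1 + w[2] * x2 + b
  pred <- predict(fit, xm)
  pos_sig <- mean(dv[pred == "significant"]) > mean(dv[pred == "mild"])
  if (!is.na(pos_sig) && !pos_sig) {
    w <- -w; b <- -b
  }
  structure(list(w1 = unname(w[1]), w2 = unname(w[2]), b = b,
                 features = feature_names, cost = cost,
                 equation = format_boundary(w[1], w[2], b)),
            class = "linear_boundary")
}

#' Format a linear decision boundary as an equation string
#'
#' @param w1,w2,b Coefficients and bias.
#' @param digits Decimal places (default 4).
#' @return A string like `"-0.0261x1 - 0.3366x2 - 1.6558 = 0"`.
#' @examples
#' format_boundary(-0.0261, -0.3366, -1.6558)
#' @export
format_boundary <- function(w1, w2, b, digits = 4) {
  fmt <- function(v) formatC(abs(v), format = "f", digits = digits)
  s1 <- if (w1 < 0) "-" else ""
  s2 <- if (w2 < 0) " - " else " + "
  s3 <- if (b < 0) " - " else " + "
  paste0(s1, fmt(w1), "x1", s2, fmt(w2), "x2", s3, fmt(b), " = 0")
}

#' @export
print.linear_boundary <- function(x, ...) {
  cat("Linear decision boundary (", x$features[1], ", ", x$features[2],
      "):\n  ", x$equation, "\n  positive side predicts 'significant'\n",
      sep = "")
  invisible(x)
}
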