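#' Fit the fatigue classifier
#'
#' The package's central fitting function.  Given a subject-by-feature
#' matrix of derived cardiovascular subparameters and the CMJ-based group
#' labels, it (1) screens every feature with leave-one-out decision stumps
#' ([loocv_screen()]), (2) ranks features by pooled F-score
#' ([rank_features()]), and (3) trains a linear maximum-margin boundary on
#' the two top-ranked features ([train_linear_svm()]).  Specific features
#' can be forced with `features`, bypassing rank selection (screening is
#' still run for reporting).
#'
#' @param x Data frame or matrix, subjects x features (rownames = subject
#'   ids), e.g. from [feature_matrix()].
#' @param labels Group labels aligned with rows (`mild` / `significant`),
#'   e.g. `assign_groups(...)$label`.
#' @param features Optional length-2 character vector of feature names to
#'   train the boundary on (default: the two top-ranked).
#' @param cost Soft-margin cost C for the linear SVM.
#' @return Object of class `"fatigue_classifier"` with components
#'   `screening` (ranked screening table), `boundary`
#'   (a `linear_boundary`), `features`, `data` (the two training columns
#'   plus labels), `labels` and `call`.
#' @seealso [predict.fatigue_classifier()], [plot.fatigue_classifier()]
#' @examples
#' coh <- simulate_cohort(cohort_config(n_subjects = 8, seed = 3))
#' meas <- cohort_measures(coh)
#' X <- feature_matrix(meas)
#' grp <- assign_groups(stats::setNames(coh$groups$cmj_change,
#'                                      coh$groups$subject_id))
#' fit <- fatigue_classifier(X, grp$label)
#' fit
#' @export
fatigue_classifier <- function(x, labels, features = NULL, cost = 1) {
  cl <- match.call()
  x <- as.data.frame(x)
  labels <- factor(as.character(labels), levels = c("mild", "significant"))
  scr <- loocv_screen(x, labels)
  ranked <- rank_features(scr)
  if (is.null(features)) {
    features <- utils::head(ranked$feature[!is.na(ranked$f_score)], 2)
  }
  if (length(features) != 2L || !all(features %in% colnames(x))) {
    stop("'features' must name two columns of 'x'")
  }
  v1 <- x[[features[1]]]; v2 <- x[[features[2]]]
  ok <- is.finite(v1) & is.finite(v2)
  boundary <- train_linear_svm(v1[ok], v2[ok], labels[ok], cost = cost,
                               feature_names = features)
  structure(list(screening = ranked, boundary = boundary,
                 features = features,
                 data = data.frame(x1 = v1[ok], x2 = v2[ok],
                                   label = labels[ok],
                                   row.names = rownames(x)[ok]),
                 labels = labels, cost = cost, call = cl),
            class = "fatigue_classifier")
}

#' @export
print.fatigue_classifier <- function(x, ...) {
  cat("Fatigue classifier (stump-screened linear maximum-margin model)\n\n")
  cat("Selected features:\n")
  top <- x$screening[x$screening$feature %in% x$features, ]
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %-18s F-score %.3f  accuracy %.3f\n", top$feature[i],
                top$f_score[i], top$accuracy[i]))
  }
  cat("\nDecision boundary:\n  ", x$boundary$equation, "\n", sep = "")
  invisible(x)
}

#' @export
summary.fatigue_classifier <- function(object, top_k = 10, ...) {
  tr <- predict(object, object$data[, c("x1", "x2")])
  acc <- mean(tr == object$data$label)
  structure(list(screening = utils::head(object$screening, top_k),
                 boundary = object$boundary,
                 n = nrow(object$data),
                 class_counts = table(object$data$label),
                 training_accuracy = acc),
            class = "summary.fatigue_classifier")
}

#' @export
print.summary.fatigue_classifier <- function(x, ...) {
  cat("Leave-one-out stump screening (top features):\n")
  print(format(x$screening, digits = 3), row.names = FALSE)
  cat("\nTraining subjects:", x$n, "(",
      paste(names(x$class_counts), x$class_counts, collapse = ", "), ")\n")
  cat("Boundary:", x$boundary$equation, "\n")
  cat(sprintf("Training accuracy: %.3f\n", x$training_accuracy))
  invisible(x)
}

#' @export
coef.fatigue_classifier <- function(object, ...) {
  b <- object$boundary
  stats::setNames(c(b$w1, b$w2, b$b), c("w1", "w2", "b"))
}

#' Predict fatigue group for new subjects
#'
#' @param object A [fatigue_classifier()] fit.
#' @param newdata Data frame containing the model's two features (either
#'   under their original names or as `x1`, `x2`).
#' @param type `"class"` (default) or `"decision"` for the signed distance
#'   `w1 x1 + w2 x2 + b`.
#' @param ... Unused.
#' @return Factor of predicted labels, or numeric decision values.
#' @export
predict.fatigue_classifier <- function(object, newdata,
                                       type = c("class", "decision"), ...) {
  type <- match.arg(type)
  nd <- as.data.frame(newdata)
  if (all(object$features %in% colnames(nd))) {
    x1 <- nd[[object$features[1]]]; x2 <- nd[[object$features[2]]]
  } else if (all(c("x1", "x2") %in% colnames(nd))) {
    x1 <- nd$x1; x2 <- nd$x2
  } else {
    stop("'newdata' must contain columns ", object$features[1], " and ",
         object$features[2], " (or x1/x2)")
  }
  b <- object$boundary
  dv <- b$w1 * x1 + b$w2 * x2 + b$b
  if (type == "decision") return(dv)
  factor(ifelse(dv > 0, "significant", "mild"),
         levels = c("mild", "significant"))
}

#' Plot the fitted decision boundary
#'
#' Scatter of the training subjects in the two-feature plane with the
#' decision line `w1 x1 + w2 x2 + b = 0` and the margins at +/- 1.
#'
#' @param x A [fatigue_classifier()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fatigue_classifier <- function(x, ...) {
  d <- x$data
  b <- x$boundary
  graphics::plot(d$x1, d$x2, pch = ifelse(d$label == "significant", 17, 1),
                 col = ifelse(d$label == "significant", "firebrick",
                              "steelblue"),
                 xlab = x$features[1], ylab = x$features[2], ...)
  if (abs(b$w2) > 1e-12) {
    graphics::abline(a = -b$b / b$w2, b = -b$w1 / b$w2)
    graphics::abline(a = (1 - b$b) / b$w2, b = -b$w1 / b$w2, lty = 3)
    graphics::abline(a = (-1 - b$b) / b$w2, b = -b$w1 / b$w2, lty = 3)
  } else if (abs(b$w1) > 1e-12) {
    graphics::abline(v = -b$b / b$w1)
  }
  graphics::legend("topright", legend = c("mild", "significant"),
                   pch = c(1, 17), col = c("steelblue", "firebrick"),
                   bty = "n")
  invisible(x)
}
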