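# The six per-nucleus measures used by the KI-67 classifier.
KI67_FEATURES <- c("area", "max_red", "sum_red", "mean_red",
                   "major_axis", "coverage_frac")

#' Partition plan for labeled nuclei
#'
#' Defines the stratified split of manually classified nuclei into a
#' balanced training set, a balanced first test set, and an all-positive
#' second test set. The defaults are a 96-cell training set (48 positive,
#' 48 negative), a 42-cell test set (21/21), and an 88-cell all-positive
#' test set.
#'
#' @param train_pos,train_neg Training counts per class.
#' @param test1_pos,test1_neg First test-set counts per class.
#' @param test2_pos Second test-set positive count.
#' @param seed Integer seed controlling the random draws.
#' @return Object of class `split_plan`.
#' @export
split_plan <- function(train_pos = 48, train_neg = 48,
                       test1_pos = 21, test1_neg = 21,
                       test2_pos = 88, seed = 1) {
  counts <- c(train_pos, train_neg, test1_pos, test1_neg, test2_pos)
  if (any(counts < 0)) stop("split counts must be >= 0")
  structure(list(train_pos = train_pos, train_neg = train_neg,
                 test1_pos = test1_pos, test1_neg = test1_neg,
                 test2_pos = test2_pos, seed = as.integer(seed)),
            class = "split_plan")
}

#' Split labeled nuclei into train / test1 / test2 sets
#'
#' Draws disjoint, seeded, stratified random subsets with exactly the
#' class counts of the plan. Errors if the labeled inventory cannot supply
#' the requested counts (the plan is never silently shrunk).
#'
#' @param records Data frame of nucleus records with a `label` column of
#'   `"positive"`/`"negative"` values.
#' @param plan A [split_plan()].
#' @return List with elements `train`, `test1`, `test2`, and `unused`
#'   (labeled records in none of the three sets).
#' @export
split_labeled <- function(records, plan) {
  if (!inherits(plan, "split_plan")) stop("plan must be a split_plan")
  labeled <- records[!is.na(records$label), , drop = FALSE]
  ipos <- which(labeled$label == "positive")
  ineg <- which(labeled$label == "negative")
  need_pos <- plan$train_pos + plan$test1_pos + plan$test2_pos
  need_neg <- plan$train_neg + plan$test1_neg
  if (length(ipos) < need_pos)
    stop("infeasible split: plan needs ", need_pos, " positive nuclei but only ",
         length(ipos), " are labeled positive")
  if (length(ineg) < need_neg)
    stop("infeasible split: plan needs ", need_neg, " negative nuclei but only ",
         length(ineg), " are labeled negative")
  set.seed(plan$seed)
  ipos <- sample(ipos)
  ineg <- sample(ineg)
  take <- function(pool, from, n) {
    if (n > 0) pool[from:(from + n - 1L)] else integer(0)
  }
  tr <- c(take(ipos, 1L, plan$train_pos), take(ineg, 1L, plan$train_neg))
  t1 <- c(take(ipos, plan$train_pos + 1L, plan$test1_pos),
          take(ineg, plan$train_neg + 1L, plan$test1_neg))
  t2 <- take(ipos, plan$train_pos + plan$test1_pos + 1L, plan$test2_pos)
  used <- c(tr, t1, t2)
  list(train = labeled[tr, , drop = FALSE],
       test1 = labeled[t1, , drop = FALSE],
       test2 = labeled[t2, , drop = FALSE],
       unused = labeled[setdiff(seq_len(nrow(labeled)), used), , drop = FALSE])
}

#' Train the ridge-stabilized logistic-regression KI-67 classifier
#'
#' Features are standardized (center 0, spread 1) using the training set,
#' then a logistic regression is fit by iteratively reweighted least
#' squares under a small fixed ridge penalty on the coefficients (the
#' intercept is unpenalized). The penalty keeps the maximum-likelihood
#' problem well posed when training classes are linearly separable, which
#' is the norm for clean fluorescence data. The fit is deterministic given
#' the training records.
#'
#' @param train Data frame of labeled nucleus records (`label` column with
#'   `"positive"`/`"negative"`).
#' @param features Character vector of feature columns; defaults to all six
#'   KI-67 measures. Zero-variance features are dropped with a warning.
#' @param penalty Ridge penalty per training observation on the
#'   standardized-scale coefficients.
#' @param decision_threshold Probability cutoff for calling a nucleus
#'   positive (called positive when probability >= threshold).
#' @return Object of class `ki67_classifier`: feature names, per-feature
#'   center/spread, coefficients (intercept first), penalty and threshold.
#' @export
train_logistic <- function(train, features = KI67_FEATURES,
                           penalty = 1e-3, decision_threshold = 0.5) {
  if (!all(features %in% names(train)))
    stop("missing feature columns: ",
         paste(setdiff(features, names(train)), collapse = ", "))
  y <- train$label
  if (any(is.na(y))) stop("training records must all be labeled")
  y <- as.integer(y == "positive")
  if (length(unique(y)) < 2)
    stop("training set must contain both classes")
  X <- as.matrix(train[, features, drop = FALSE])
  ctr <- colMeans(X)
  # population spread so the fit is invariant under duplicating the set
  spr <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  keep <- spr > 0
  if (any(!keep)) {
    warning("dropping zero-variance feature(s): ",
            paste(features[!keep], collapse = ", "))
    features <- features[keep]
    X <- X[, keep, drop = FALSE]
    ctr <- ctr[keep]; spr <- spr[keep]
  }
  if (!length(features)) stop("no usable features")
  Z <- cbind(1, sweep(sweep(X, 2, ctr), 2, spr, "/"))
  p <- ncol(Z)
  # per-observation penalty: the fit is invariant under duplicating the
  # training set; intercept unpenalized
  D <- diag(c(0, rep(penalty * nrow(Z), p - 1L)))
  beta <- numeric(p)
  for (it in seq_len(200L)) {
    eta <- drop(Z %*% beta)
    mu <- stats::plogis(eta)
    wt <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(Z, y - mu)) - D %*% beta
    hess <- crossprod(Z, Z * wt) + D
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  structure(list(feature_names = features,
                 center = ctr, spread = spr,
                 intercept = beta[1],
                 weights = stats::setNames(beta[-1], features),
                 penalty = penalty,
                 decision_threshold = decision_threshold),
            class = "ki67_classifier")
}

#' @export
print.ki67_classifier <- function(x, ...) {
  cat("<ki67_classifier> logistic regression, ridge penalty", x$penalty,
      "\n  features:", paste(x$feature_names, collapse = ", "),
      "\n  decision threshold:", x$decision_threshold, "\n")
  invisible(x)
}

#' Predict KI-67 status for nucleus records
#'
#' @param object A `ki67_classifier`.
#' @param newdata Data frame carrying all model feature columns.
#' @param type `"class"` for `"positive"`/`"negative"` calls (positive
#'   when probability >= the model's decision threshold) or `"prob"` for
#'   raw probabilities.
#' @param ... Unused.
#' @return Character vector of calls or numeric probabilities.
#' @export
predict.ki67_classifier <- function(object, newdata,
                                    type = c("class", "prob"), ...) {
  type <- match.arg(type)
  miss <- setdiff(object$feature_names, names(newdata))
  if (length(miss))
    stop("records are missing model feature(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  Z <- sweep(sweep(X, 2, object$center), 2, object$spread, "/")
  prob <- stats::plogis(drop(object$intercept + Z %*% object$weights))
  if (type == "prob") return(prob)
  ifelse(prob >= object$decision_threshold, "positive", "negative")
}

#' Classification accuracy on a labeled set
#'
#' @param model A `ki67_classifier`.
#' @param records Labeled nucleus records.
#' @return List with `accuracy` (full precision), `display` (rounded
#'   half-away-from-zero to 2 decimals), `n`, and `misclassified`.
#' @export
evaluate_accuracy <- function(model, records) {
  if (!nrow(records)) stop("labeled set is empty")
  if (any(is.na(records$label))) stop("records must all be labeled")
  pred <- predict(model, records)
  correct <- sum(pred == records$label)
  acc <- correct / nrow(records)
  list(accuracy = acc, display = round_half_up(acc, 2),
       n = nrow(records), misclassified = nrow(records) - correct)
}

#' Accuracy from misclassification counts
#'
#' `(total - misclassified) / total`; e.g. 5 misclassified of 42 gives
#' 0.88 at 2-decimal display, and 14 of 88 gives 0.84.
#'
#' @param misclassified Number of misclassified items.
#' @param total Total number of items (> 0).
#' @return List with `accuracy` and 2-decimal `display` value.
#' @export
accuracy_from_counts <- function(misclassified, total) {
  if (total <= 0) stop("total must be > 0")
  if (misclassified < 0 || misclassified > total)
    stop("misclassified must be in [0, total]")
  acc <- (total - misclassified) / total
  list(accuracy = acc, display = round_half_up(acc, 2))
}

# Half-away-from-zero rounding for display parity (R's round() is
# round-half-even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Serialize / restore a classifier as self-describing JSON
#'
#' @param model A `ki67_classifier`.
#' @param path JSON file path.
#' @return `write_classifier` invisibly returns the path;
#'   `read_classifier` the restored model.
#' @export
write_classifier <- function(model, path) {
  doc <- list(model = "logistic_regression",
              feature_names = model$feature_names,
              center = as.list(model$center),
              spread = as.list(model$spread),
              intercept = model$intercept,
              weights = as.list(model$weights),
              penalty = model$penalty,
              decision_threshold = model$decision_threshold)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(feature_names = doc$feature_names,
                 center = unlist(doc$center),
                 spread = unlist(doc$spread),
                 intercept = doc$intercept,
                 weights = unlist(doc$weights),
                 penalty = doc$penalty,
                 decision_threshold = doc$decision_threshold),
            class = "ki67_classifier")
}
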