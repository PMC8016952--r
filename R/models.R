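# Random-forest activity classifiers and their stratified cross-validation.

#' Train a random-forest activity classifier
#'
#' Fits a probability forest on the labelled compounds with 1000 trees by
#' default and mtry = floor(sqrt(number of features)), the conventional
#' node-splitting default. The feature space (5 properties + training-set
#' fingerprint bits) is frozen from the training compounds unless an
#' explicit space is supplied. The returned model scores compounds with the
#' fraction of trees voting active.
#'
#' @param labeled labelled data frame ([build_ti_dataset()] /
#'   [build_pi_dataset()]): columns compound_id, smiles, label.
#' @param strategy negative-data strategy tag, `"TI"` or `"PI"` (metadata).
#' @param n_trees number of trees (default 1000).
#' @param seed integer seed; fixed seed and data give identical forests.
#' @param space optional pre-built [build_feature_space()] result.
#' @param features optional pre-computed [featurize_set()] for `labeled`
#'   (computed when missing).
#' @return object of class `lbvs_rf`.
#' @export
train_activity_model <- function(labeled, strategy = c("TI", "PI"),
                                 n_trees = 1000, seed = 1, space = NULL,
                                 features = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(is.data.frame(labeled), nrow(labeled) >= 4)
  classes <- table(labeled$label)
  if (length(classes) < 2) stop("training data contain a single class")
  if (any(classes < 2)) stop("need at least 2 compounds per class")
  if (is.null(features)) {
    features <- featurize_set(labeled$smiles, labeled$compound_id)
  }
  if (is.null(space)) space <- build_feature_space(features)
  x <- project_features(space, features)
  y <- factor(labeled$label, levels = c("inactive", "active"))
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = n_trees,
    mtry = floor(sqrt(ncol(x))),
    probability = TRUE,
    seed = as.integer(seed),
    num.threads = 1
  )
  structure(list(forest = fit, space = space, strategy = strategy,
                 n_trees = n_trees, seed = seed,
                 training_ids = labeled$compound_id),
            class = "lbvs_rf")
}

#' Score compounds with a trained model
#'
#' @param object an `lbvs_rf` model.
#' @param newdata an `lbvs_features` object, or a character vector of SMILES.
#' @param ... unused.
#' @return numeric vector of probability-of-active scores in \[0, 1\].
#' @export
predict.lbvs_rf <- function(object, newdata, ...) {
  if (is.character(newdata)) newdata <- featurize_set(newdata)
  stopifnot(inherits(newdata, "lbvs_features"))
  x <- project_features(object$space, newdata)
  p <- stats::predict(object$forest, data = x, num.threads = 1)$predictions
  stats::setNames(p[, "active"], newdata$ids)
}

#' @export
print.lbvs_rf <- function(x, ...) {
  cat("Random-forest activity model (RF-", x$strategy, ")\n", sep = "")
  cat("  trees:", x$n_trees, " features:", feature_space_size(x$space),
      " training compounds:", length(x$training_ids), "\n")
  invisible(x)
}

#' Seed-deterministic stratified fold assignment
#'
#' Partitions compounds into `k` folds whose sizes differ by at most one and
#' whose per-fold class counts track the global class proportions within one
#' compound. Assignment is keyed by compound identifier (members are sorted
#' before the seeded shuffle), so reordering the input rows never changes
#' the folds. Classes place their "extra" members on successive folds in a
#' rotating window so total fold sizes stay even.
#'
#' @param ids compound identifiers.
#' @param labels class labels, parallel to `ids`.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return integer vector of fold numbers (1..k), named by id.
#' @export
stratified_folds <- function(ids, labels, k = 5, seed = 1) {
  stopifnot(length(ids) == length(labels), !anyDuplicated(ids))
  tab <- table(labels)
  if (any(tab < k)) {
    stop("class '", names(tab)[which.min(tab)], "' has fewer than k = ", k,
         " members")
  }
  fold <- stats::setNames(integer(length(ids)), ids)
  offset <- 0L
  for (cl in sort(names(tab))) {
    members <- sort(as.character(ids[labels == cl]))
    members <- with_seed(seed + match(cl, sort(names(tab))),
                         sample(members))
    n <- length(members); q <- n %/% k; r <- n %% k
    sizes <- rep(q, k)
    if (r > 0) {
      extra <- ((offset + seq_len(r) - 1L) %% k) + 1L
      sizes[extra] <- sizes[extra] + 1L
      offset <- (offset + r) %% k
    }
    fold[members] <- rep(seq_len(k), times = sizes)
  }
  fold[as.character(ids)]
}

#' Stratified k-fold cross-validation of a random-forest model
#'
#' For each fold, a forest is trained on the complement (with the feature
#' space rebuilt from that training portion only) and evaluated on the fold
#' at the 0.5 probability threshold, yielding accuracy, precision, recall,
#' specificity, MCC, AUCROC and AUCPR per fold plus their unweighted means.
#'
#' @inheritParams train_activity_model
#' @param k number of folds (default 5).
#' @param threshold probability threshold for the confusion counts
#'   (default 0.5).
#' @return object of class `lbvs_cv`: list with `per_fold` (data frame),
#'   `mean` (named numeric), `folds` (assignment vector).
#' @export
stratified_cv <- function(labeled, strategy = c("TI", "PI"), k = 5,
                          n_trees = 1000, seed = 1, threshold = 0.5,
                          features = NULL) {
  strategy <- match.arg(strategy)
  folds <- stratified_folds(labeled$compound_id, labeled$label, k = k, seed = seed)
  if (is.null(features)) {
    features <- featurize_set(labeled$smiles, labeled$compound_id)
  }
  metr <- c("accuracy", "precision", "recall", "specificity", "mcc",
            "aucroc", "aucpr")
  per_fold <- data.frame(fold = seq_len(k))
  for (m in metr) per_fold[[m]] <- NA_real_
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    tr_feat <- subset_features(features, train_idx)
    te_feat <- subset_features(features, test_idx)
    model <- train_activity_model(labeled[train_idx, , drop = FALSE],
                                  strategy = strategy, n_trees = n_trees,
                                  seed = seed + f, features = tr_feat)
    score <- predict(model, te_feat)
    truth <- labeled$label[test_idx] == "active"
    pred <- score >= threshold
    cm <- compute_metrics(tp = sum(pred & truth), tn = sum(!pred & !truth),
                          fp = sum(pred & !truth), fn = sum(!pred & truth))
    areas <- roc_pr_areas(score, truth)
    per_fold[f, metr] <- c(unlist(cm[metr[1:5]]), areas$aucroc, areas$aucpr)
  }
  means <- colMeans(per_fold[, metr])
  structure(list(per_fold = per_fold, mean = means, folds = folds,
                 strategy = strategy, k = k, seed = seed),
            class = "lbvs_cv")
}

#' @export
print.lbvs_cv <- function(x, ...) {
  cat("Stratified ", x$k, "-fold cross-validation (RF-", x$strategy, ")\n",
      sep = "")
  print(round(x$mean, 3))
  invisible(x)
}

# subset an lbvs_features object by position
#' @noRd
subset_features <- function(features, idx) {
  structure(list(ids = features$ids[idx], smiles = features$smiles[idx],
                 props = features$props[idx, , drop = FALSE],
                 bits = features$bits[idx]),
            class = "lbvs_features")
}
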