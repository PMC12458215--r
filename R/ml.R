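# Expression classification harness: percentile labeling, stratified
# splitting, random-forest training/evaluation, UMAP embedding and
# TreeSHAP feature attributions.

#' Binarize expression intensities at a percentile cutoff
#'
#' The cutoff is the stated percentile of the finite intensities under the
#' linear-interpolation convention (R `quantile` type 7); a receptor is
#' labeled `high` iff its intensity is >= the cutoff.
#'
#' @param intensities numeric vector (NA allowed; >= 3 finite values).
#' @param percentile cutoff percentile in [0, 100] (default 67).
#' @return list: `labels` (factor low/high, NA where intensity is NA),
#'   `cutoff`, `prevalence_high`.
#' @export
binarize_expression <- function(intensities, percentile = 67) {
  check_number(percentile, "percentile", 0, 100)
  fin <- intensities[is.finite(intensities)]
  if (length(fin) < 3L) stop("need at least 3 finite intensities")
  if (diff(range(fin)) == 0) stop("all intensities are equal; no cutoff exists")
  cutoff <- unname(quantile(fin, percentile / 100, type = 7))
  labels <- factor(ifelse(intensities >= cutoff, "high", "low"),
                   levels = c("low", "high"))
  list(labels = labels, cutoff = cutoff,
       prevalence_high = mean(labels[!is.na(labels)] == "high"))
}

#' Assemble a labeled dataset for classification
#'
#' Joins a feature matrix with intensity labels from
#' [binarize_expression()]; receptors with any missing feature or intensity
#' are excluded before modeling (their count is recorded).
#'
#' @param features data.frame/matrix of named numeric features.
#' @param intensities numeric vector aligned with `features` rows.
#' @param percentile label cutoff percentile (default 67).
#' @return list of class `labeled_dataset`: features (complete rows),
#'   labels, cutoff, prevalence_high, n_excluded.
#' @export
labeled_dataset <- function(features, intensities, percentile = 67) {
  features <- as.data.frame(features)
  stopifnot(nrow(features) == length(intensities))
  bin <- binarize_expression(intensities, percentile)
  ok <- stats::complete.cases(features) & !is.na(bin$labels)
  structure(list(features = features[ok, , drop = FALSE],
                 labels = bin$labels[ok],
                 cutoff = bin$cutoff, prevalence_high = bin$prevalence_high,
                 n_excluded = sum(!ok)),
            class = "labeled_dataset")
}

#' Stratified train/test split
#'
#' Splits ids so that class proportions are preserved within one sample per
#' class; disjoint and exhaustive; reproducible given the seed.
#'
#' @param labels factor with both classes present (>= 2 members each).
#' @param train_frac training fraction in (0, 1) (default 0.8).
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_frac = 0.8, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must be strictly inside (0, 1)")
  labels <- droplevels(as.factor(labels))
  tab <- table(labels)
  if (length(tab) < 2L || any(tab < 2L))
    stop("both classes must be present with >= 2 members")
  set.seed(seed)
  train <- integer(0)
  for (cl in names(tab)) {
    ids <- which(labels == cl)
    n_tr <- round(train_frac * length(ids))
    n_tr <- min(max(n_tr, 1L), length(ids) - 1L)
    train <- c(train, sample(ids, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

# Classify feature columns into the biologically motivated subsets by their
# schema names (transcript / topological / structural / protein-sequence).
feature_group <- function(feature_names) {
  g <- rep("other", length(feature_names))
  g[grepl("^(tmd|icl|ecl)[0-9]?|tail|^dg_|^loop_|^protein_length",
          feature_names)] <- "topological"
  g[grepl("^(sasa_|f_crg|f_plr|f_aplr|ss_|total_sasa)", feature_names)] <- "structural"
  g[grepl("^(gc|f_common|f_rare|frac_[acgt]|at_skew|cpg|minmax|length_nt|homopolymer)",
          feature_names)] <- "transcript"
  g[feature_names %in% c("mw", "pi", "aromaticity", "instability", "gravy")] <- "sequence"
  g
}

select_feature_subset <- function(features, feature_set) {
  grp <- feature_group(colnames(features))
  keep <- switch(feature_set,
    full = rep(TRUE, length(grp)),
    protein = grp %in% c("topological", "structural", "sequence"),
    topological = grp == "topological",
    structural = grp == "structural",
    stop("unknown feature_set: ", feature_set))
  if (feature_set != "full" && !any(keep))
    stop("no features belong to subset '", feature_set, "'")
  features[, keep, drop = FALSE]
}

#' Train a random-forest expression classifier
#'
#' Fits a random forest on one of the four biologically motivated feature
#' subsets (`full`, `protein`, `topological`, `structural`, selected by the
#' feature schema names; `full` keeps everything including unrecognized
#' columns). The fitted object stores the feature schema, subset, seed and
#' training data, and is reproducible given the seed.
#'
#' @param dataset a [labeled_dataset()] (>= 10 training rows).
#' @param feature_set feature subset name (default "full").
#' @param num_trees trees in the ensemble (default 500).
#' @param mtry features tried per split; default floor(sqrt(p)).
#' @param seed RNG seed.
#' @return object of class `drscan_rf`.
#' @export
train_classifier <- function(dataset, feature_set = "full", num_trees = 500L,
                             mtry = NULL, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  x <- select_feature_subset(dataset$features, feature_set)
  y <- dataset$labels
  if (nrow(x) < 10L) stop("need at least 10 training rows")
  if (nlevels(y) != 2L) stop("labels must have exactly two classes")
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(x))))
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = y, ntree = num_trees,
                                    mtry = mtry, keep.inbag = TRUE,
                                    keep.forest = TRUE)
  structure(list(fit = fit, feature_names = colnames(x),
                 feature_set = feature_set, seed = seed,
                 train_x = x, train_y = y, positive = "high"),
            class = "drscan_rf")
}

#' Predicted probability of the positive (high-expression) class
#'
#' @param model a [train_classifier()] fit.
#' @param newdata data.frame holding at least the model's feature columns.
#' @return numeric vector of probabilities.
#' @export
predict_prob <- function(model, newdata) {
  stopifnot(inherits(model, "drscan_rf"))
  missing <- setdiff(model$feature_names, colnames(newdata))
  if (length(missing)) stop("schema mismatch; missing feature(s): ",
                            paste(head(missing, 5), collapse = ", "))
  p <- predict(model$fit, newdata[, model$feature_names, drop = FALSE],
               type = "prob")
  as.numeric(p[, model$positive])
}

#' Rank-statistic AUROC
#'
#' Area under the ROC curve computed as the Mann-Whitney concordance
#' statistic (average ranks; ties count 1/2).
#'
#' @param scores numeric prediction scores.
#' @param labels factor/logical; positive = second level (or TRUE).
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == levels(as.factor(labels))[2L]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("AUROC undefined: single-class labels")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a classifier on a held-out test set
#'
#' Balanced accuracy, precision, recall and F1 from hard labels at
#' probability 0.5 (positive class = high); AUROC from the predicted
#' probabilities by rank statistic. A single-class test set leaves AUROC NA
#' and flagged.
#'
#' @param model a [train_classifier()] fit.
#' @param features test feature table.
#' @param labels test labels (factor low/high).
#' @return named numeric: balanced_accuracy, precision, recall, f1, auroc,
#'   with attribute `auroc_defined`.
#' @export
evaluate_classifier <- function(model, features, labels) {
  if (!nrow(features)) stop("empty test set")
  p <- predict_prob(model, features)
  pred <- p >= 0.5
  truth <- labels == model$positive
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (!is.na(sens) && prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  auc_ok <- length(unique(truth)) == 2L
  auc <- if (auc_ok) auroc(p, truth) else NA_real_
  structure(c(balanced_accuracy = mean(c(sens, spec), na.rm = TRUE),
              precision = prec, recall = sens, f1 = f1, auroc = auc),
            auroc_defined = auc_ok)
}

#' UMAP embedding of standardized features
#'
#' Features are z-score standardized column-wise (mean 0, sd 1; constant
#' columns are centred only), then embedded with UMAP under the stated
#' defaults. Rows with missing values are an error. Run single-threaded so
#' the embedding is reproducible given the seed.
#'
#' @param features numeric matrix/data.frame.
#' @param n_neighbors,min_dist,metric UMAP parameters (defaults 15, 0.1,
#'   "euclidean").
#' @param seed RNG seed.
#' @param ... further arguments passed to [uwot::umap()] (e.g. `n_epochs`).
#' @return n x 2 matrix of coordinates.
#' @export
embed_umap <- function(features, n_neighbors = 15, min_dist = 0.1,
                       metric = "euclidean", seed = 1L, ...) {
  x <- as.matrix(features)
  if (anyNA(x)) stop("rows with missing values cannot be embedded")
  x <- standardize_features(x)
  set.seed(seed)
  coords <- uwot::umap(x, n_neighbors = min(n_neighbors, nrow(x) - 1L),
                       min_dist = min_dist, metric = metric,
                       n_threads = 1, n_sgd_threads = 1, ...)
  dimnames(coords) <- list(rownames(features), c("umap1", "umap2"))
  coords
}

#' Z-score standardize feature columns
#' @param x numeric matrix.
#' @return matrix with each column mean 0 and sd 1 (constant columns
#'   centred only).
#' @export
standardize_features <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  s <- apply(x, 2L, sd)
  s[s == 0] <- 1
  sweep(sweep(x, 2L, mu), 2L, s, `/`)
}

# Convert a randomForest ensemble into node arrays with covers for TreeSHAP.
# Leaf value = 1 for the positive class, 0 otherwise; covers are inbag
# training-sample counts routed through each tree.
rf_tree_arrays <- function(model) {
  fit <- model$fit
  if (is.null(fit$inbag)) stop("model must be trained with keep.inbag")
  x <- as.matrix(model$train_x)
  lapply(seq_len(fit$ntree), function(t) {
    tr <- randomForest::getTree(fit, t, labelVar = FALSE)
    nn <- nrow(tr)
    left <- as.integer(tr[, "left daughter"]) - 1L
    right <- as.integer(tr[, "right daughter"]) - 1L
    leaf <- tr[, "status"] == -1L
    left[leaf] <- -1L; right[leaf] <- -1L
    feature <- as.integer(tr[, "split var"]) - 1L
    feature[leaf] <- -1L
    value <- numeric(nn)
    value[leaf] <- as.numeric(fit$classes[tr[leaf, "prediction"]] == model$positive)
    cover <- numeric(nn)
    w <- fit$inbag[, t]
    node <- rep(1L, nrow(x))
    active <- which(w > 0)
    repeat {
      cw <- tapply(w[active], node[active], sum)
      cover[as.integer(names(cw))] <- cover[as.integer(names(cw))] + cw
      inner <- active[!leaf[node[active]]]
      if (!length(inner)) break
      nd <- node[inner]
      goleft <- x[cbind(inner, feature[nd] + 1L)] <= tr[nd, "split point"]
      node[inner] <- ifelse(goleft, left[nd] + 1L, right[nd] + 1L)
      active <- inner
    }
    list(left = left, right = right, feature = feature,
         threshold = as.numeric(tr[, "split point"]), value = value,
         cover = cover)
  })
}

#' TreeSHAP feature attributions for a random-forest classifier
#'
#' Path-dependent TreeSHAP over the fitted ensemble: per receptor, the
#' base value plus the per-feature attributions reproduce the predicted
#' positive-class probability exactly (local accuracy). A global ranking by
#' mean absolute attribution and the forest's Gini impurity importances are
#' returned alongside.
#'
#' @param model a [train_classifier()] fit.
#' @param data feature table to explain (default: the training data).
#' @return list: `shap` (n x p matrix), `base_value`, `ranking` (data.frame
#'   feature / mean_abs_shap, descending), `gini` (named vector).
#' @export
feature_attributions <- function(model, data = NULL) {
  if (!inherits(model, "drscan_rf")) stop("unsupported model type")
  data <- data %||% model$train_x
  missing <- setdiff(model$feature_names, colnames(data))
  if (length(missing)) stop("schema mismatch; missing feature(s): ",
                            paste(head(missing, 5), collapse = ", "))
  X <- as.matrix(data[, model$feature_names, drop = FALSE])
  trees <- rf_tree_arrays(model)
  res <- treeshap_values(trees, X)
  shap <- res$phi
  colnames(shap) <- model$feature_names
  mean_abs <- colMeans(abs(shap))
  ranking <- data.frame(feature = names(sort(mean_abs, decreasing = TRUE)),
                        mean_abs_shap = unname(sort(mean_abs, decreasing = TRUE)))
  gini <- randomForest::importance(model$fit)[, "MeanDecreaseGini"]
  list(shap = shap, base_value = res$base_value, ranking = ranking,
       gini = gini)
}
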