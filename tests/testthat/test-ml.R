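planted_data <- function(seed = 1, n = 300) {
  sim <- simulate_feature_table(n = n, seed = seed)
  labeled_dataset(sim$features, sim$intensity)
}

test_that("percentile binarization follows the linear-interpolation convention", {
  x <- 1:100
  res <- binarize_expression(x, 67)
  # brute-force oracle: type-7 interpolation between order statistics
  h <- (100 - 1) * 0.67 + 1
  cutoff <- x[floor(h)] + (h - floor(h)) * (x[ceiling(h)] - x[floor(h)])
  expect_equal(res$cutoff, cutoff)
  expect_equal(sum(res$labels == "high"), sum(x >= cutoff))  # ~33 high
  expect_equal(sum(res$labels == "high"), 33)
  expect_true(all(binarize_expression(x, 0)$labels == "high"))
  res100 <- binarize_expression(c(1, 2, 3, 3), 100)
  expect_identical(which(res100$labels == "high"), c(3L, 4L))
  expect_error(binarize_expression(rep(2, 10), 67), "all intensities are equal")
  expect_error(binarize_expression(c(1, 2), 67), "at least 3")
})

test_that("stratified splitting preserves class proportions and is seeded", {
  labels <- factor(rep(c("low", "high"), c(67, 33)), levels = c("low", "high"))
  sp <- stratified_split(labels, 0.8, seed = 1)
  expect_identical(sort(c(sp$train, sp$test)), 1:100)
  expect_equal(sum(labels[sp$train] == "low"), 54)
  expect_equal(sum(labels[sp$train] == "high"), 26)
  sp2 <- stratified_split(labels, 0.8, seed = 2)
  expect_false(identical(sp$train, sp2$train))
  expect_equal(table(labels[sp2$train]), table(labels[sp$train]))
  expect_identical(stratified_split(labels, 0.8, seed = 3),
                   stratified_split(labels, 0.8, seed = 3))
  expect_error(stratified_split(labels, 1.0), "inside")
  expect_error(stratified_split(factor(rep("low", 10), levels = "low"), 0.8),
               "both classes")
})

test_that("rank-statistic AUROC equals the pairwise concordance oracle", {
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), factor(c("low", "low", "high", "high"),
                                                   c("low", "high"))), 1.0)
  expect_equal(auroc(rep(0.5, 10), factor(rep(c("low", "high"), 5),
                                          c("low", "high"))), 0.5)
  set.seed(30)
  scores <- rnorm(60)
  labs <- factor(sample(c("low", "high"), 60, TRUE), c("low", "high"))
  pos <- which(labs == "high"); neg <- which(labs == "low")
  conc <- 0
  for (i in pos) for (j in neg)
    conc <- conc + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  expect_equal(auroc(scores, labs), conc / (length(pos) * length(neg)))
})

test_that("classifier recovers planted effects, nulls out under shuffling, and is deterministic", {
  ds <- planted_data(seed = 41)
  sp <- stratified_split(ds$labels, 0.8, seed = 41)
  # build train/test directly to keep the original labels
  tr_ds <- structure(list(features = ds$features[sp$train, ],
                          labels = ds$labels[sp$train]),
                     class = "labeled_dataset")
  model <- train_classifier(tr_ds, "full", num_trees = 300, seed = 7)
  m <- evaluate_classifier(model, ds$features[sp$test, ], ds$labels[sp$test])
  expect_gt(m[["auroc"]], 0.9)
  expect_true(all(m[c("balanced_accuracy", "precision", "recall", "f1")] >= 0 &
                    m[c("balanced_accuracy", "precision", "recall", "f1")] <= 1))
  # determinism: same seed, same data -> identical predictions
  model2 <- train_classifier(tr_ds, "full", num_trees = 300, seed = 7)
  expect_identical(predict_prob(model, ds$features[sp$test, ]),
                   predict_prob(model2, ds$features[sp$test, ]))
  # shuffled labels -> chance performance across seeds
  aucs <- vapply(1:6, function(s) {
    set.seed(1000 + s)
    sh_labels <- sample(ds$labels)
    sh <- structure(list(features = ds$features[sp$train, ],
                         labels = sh_labels[sp$train]),
                    class = "labeled_dataset")
    msh <- train_classifier(sh, "full", num_trees = 200, seed = s)
    evaluate_classifier(msh, ds$features[sp$test, ],
                        sh_labels[sp$test])[["auroc"]]
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("feature-set selection restricts the model to the named schema group", {
  ds <- planted_data(seed = 42)
  mt <- train_classifier(ds, "topological", num_trees = 100, seed = 1)
  expect_identical(mt$feature_names, "tmd6_dg")
  ms <- train_classifier(ds, "structural", num_trees = 100, seed = 1)
  expect_identical(ms$feature_names, "sasa_total")
  expect_error(train_classifier(ds, "tango"), "unknown feature_set")
})

test_that("TreeSHAP attributions are locally accurate and rank planted features first", {
  ds <- planted_data(seed = 43, n = 200)
  model <- train_classifier(ds, "full", num_trees = 150, seed = 3)
  newx <- ds$features[1:60, ]
  attr <- feature_attributions(model, newx)
  # local accuracy: base + sum(attributions) == predicted probability
  recon <- attr$base_value + rowSums(attr$shap)
  expect_equal(recon, predict_prob(model, newx), tolerance = 1e-6)
  # planted drivers dominate the global ranking
  expect_true(all(c("tmd6_dg", "sasa_total") %in% attr$ranking$feature[1:3]))
  expect_true(all(c("tmd6_dg", "sasa_total") %in%
                    names(sort(attr$gini, decreasing = TRUE))[1:3]))
})

test_that("a single-feature model concentrates all attribution on that feature", {
  ds <- planted_data(seed = 44, n = 150)
  model <- train_classifier(ds, "topological", num_trees = 100, seed = 5)
  attr <- feature_attributions(model, ds$features[1:40, ])
  expect_identical(colnames(attr$shap), "tmd6_dg")
  expect_equal(attr$base_value + rowSums(attr$shap),
               predict_prob(model, ds$features[1:40, ]), tolerance = 1e-6)
  expect_equal(attr$ranking$feature[1], "tmd6_dg")
})

test_that("UMAP embeddings are standardized, shaped and reproducible", {
  set.seed(50)
  x <- matrix(rnorm(80 * 6), 80, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  z <- standardize_features(x)
  expect_equal(unname(colMeans(z)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 6), tolerance = 1e-12)
  emb <- embed_umap(x, seed = 9)
  expect_identical(dim(emb), c(80L, 2L))
  expect_identical(embed_umap(x, seed = 9), emb)
  # duplicated rows land next to each other: closer than 99% of all pairs
  # and within the min_dist attraction floor
  xd <- rbind(x, x[1, , drop = FALSE])
  embd <- embed_umap(xd, seed = 9)
  dup_d <- sqrt(sum((embd[81, ] - embd[1, ])^2))
  expect_lt(dup_d, quantile(dist(embd), 0.01))
  expect_lt(dup_d, 3 * 0.1)
  xna <- x; xna[3, 2] <- NA
  expect_error(embed_umap(xna), "missing values")
})

test_that("incomplete feature vectors are excluded at dataset assembly", {
  sim <- simulate_feature_table(n = 60, seed = 45)
  f <- sim$features; f$tmd6_dg[c(2, 9)] <- NA
  ds <- labeled_dataset(f, sim$intensity)
  expect_identical(ds$n_excluded, 2L)
  expect_identical(nrow(ds$features), 58L)
})
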