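# a directly constructed feature table: `n_noise` Gaussian features plus
# one feature shifted by `shift` SDs between the two groups
mk_sep_table <- function(n_per_group = 12, n_noise = 10, shift = 10,
                         seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  lab <- rep(c("baseline", "injured"), each = n_per_group)
  df <- data.frame(animal = sprintf("a%02d", seq_len(n)), label = lab,
                   stringsAsFactors = FALSE)
  for (i in seq_len(n_noise)) df[[sprintf("noise_%02d", i)]] <- rnorm(n)
  df$signal <- rnorm(n) + ifelse(lab == "injured", shift, 0)
  build_feature_table(df)
}

test_that("run rows aggregate by mean per animal and timepoint", {
  rows <- list(
    list(animal = "m1", label = "baseline", run = "r1", v = 4, w = 1),
    list(animal = "m1", label = "baseline", run = "r2", v = 6, w = 3),
    list(animal = "m2", label = "baseline", run = "r1", v = 10, w = 2))
  tab <- build_feature_table(rows)
  expect_s3_class(tab, "gait_feature_table")
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$v[tab$animal == "m1"], 5)
  expect_equal(tab$w[tab$animal == "m1"], 2)
  expect_identical(attr(tab, "features"), c("v", "w"))
})

test_that("conflicting duplicate rows are rejected; identical ones collapse", {
  rows <- list(
    list(animal = "m1", label = "b", run = "r1", v = 4),
    list(animal = "m1", label = "b", run = "r1", v = 9))
  expect_error(build_feature_table(rows), "conflicting duplicate")
  ok <- build_feature_table(list(
    list(animal = "m1", label = "b", run = "r1", v = 4),
    list(animal = "m1", label = "b", run = "r1", v = 4)))
  expect_identical(nrow(ok), 1L)
})

test_that("missing values stay missing in the aggregated table", {
  rows <- list(
    list(animal = "m1", label = "b", run = "r1", v = 4, w = NA_real_),
    list(animal = "m2", label = "b", run = "r1", v = 5, w = 2))
  tab <- build_feature_table(rows)
  expect_true(is.na(tab$w[tab$animal == "m1"]))
})

test_that("a 10-SD separated feature gives perfect held-out accuracy and top importance", {
  tab <- mk_sep_table()
  rep <- rf_profile(tab, seed = 1)
  expect_equal(rep$accuracy, 1)
  expect_identical(names(which.max(rep$importance)), "signal")
  expect_equal(sum(rep$importance), 1)
  expect_true(all(rep$importance >= 0))
  # confusion row sums equal the test-set label counts
  expect_identical(sum(rep$confusion), as.integer(rep$n_test))
})

test_that("the profile is reproducible under a fixed seed", {
  tab <- mk_sep_table()
  a <- rf_profile(tab, seed = 7)
  b <- rf_profile(tab, seed = 7)
  expect_identical(a$importance, b$importance)
  expect_identical(a$confusion, b$confusion)
  expect_identical(a$accuracy, b$accuracy)
})

test_that("the separable fixture stays >= 0.95 accurate across 20 seeds", {
  tab <- mk_sep_table()
  accs <- vapply(1:20, function(s) rf_profile(tab, seed = s)$accuracy,
                 numeric(1))
  expect_true(all(accs >= 0.95))
})

test_that("permuted labels drop accuracy to chance", {
  tab <- mk_sep_table(n_per_group = 12)
  hits <- 0; total <- 0
  for (s in 1:10) {
    set.seed(1000 + s)
    perm <- tab
    perm$label <- sample(perm$label)
    perm <- build_feature_table(as.data.frame(perm))
    rep <- rf_profile(perm, seed = s)
    hits <- hits + sum(diag(rep$confusion))
    total <- total + sum(rep$confusion)
  }
  p <- hits / total
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / total) + 0.1)
})

test_that("an added all-noise feature does not dethrone the informative one", {
  tab <- mk_sep_table(seed = 2)
  df <- as.data.frame(tab)
  set.seed(99)
  df$extra_noise <- rnorm(nrow(df))
  tab2 <- build_feature_table(df)
  rep2 <- rf_profile(tab2, seed = 3)
  expect_identical(names(which.max(rep2$importance)), "signal")
})

test_that("single-label and tiny tables are rejected", {
  tab <- mk_sep_table(n_per_group = 4)
  solo <- filter_labels(tab, "baseline")
  expect_error(rf_profile(solo), "two labels")
})

test_that("animal-level split keeps every animal on one side", {
  tab <- mk_sep_table()
  rep <- rf_profile(tab, seed = 5)
  expect_identical(rep$n_train + rep$n_test, nrow(tab))
})

test_that("top-k overlap is exact set arithmetic on constructed rankings", {
  mk_rep <- function(imp) structure(list(importance = imp),
                                    class = "classifier_report")
  feats <- sprintf("f%02d", 1:40)
  a <- mk_rep(stats::setNames(seq(40, 1), feats))
  expect_equal(top_feature_overlap(a, a, k = 20), 100)
  b <- mk_rep(stats::setNames(seq(1, 40), feats))  # reversed ranking
  expect_equal(top_feature_overlap(a, b, k = 20), 0)
  # top-20 sets sharing exactly 4 features
  imp_c <- stats::setNames(rep(0, 40), feats)
  imp_c[c("f01", "f02", "f03", "f04")] <- 100 + 1:4   # 4 shared with a's top 20
  imp_c[sprintf("f%02d", 25:40)] <- 50 + 1:16          # 16 outside a's top 20
  cr <- mk_rep(imp_c)
  expect_equal(top_feature_overlap(a, cr, k = 20), 20)
  d <- mk_rep(stats::setNames(seq(40, 1), sprintf("g%02d", 1:40)))
  expect_error(top_feature_overlap(a, d), "namespace")
  expect_error(top_feature_overlap(a, a, k = 41), "feature count")
})

test_that("PCA on the top features separates the groups along PC1", {
  # several informative parameters shift together, as an injury
  # phenotype does; the top-5 set is then mutually correlated and the
  # leading component aligns with the group axis
  set.seed(41)
  n <- 24
  lab <- rep(c("baseline", "injured"), each = n / 2)
  df <- data.frame(animal = sprintf("a%02d", seq_len(n)), label = lab,
                   stringsAsFactors = FALSE)
  for (i in 1:8) df[[sprintf("noise_%02d", i)]] <- rnorm(n)
  for (i in 1:5) df[[sprintf("signal_%d", i)]] <-
    rnorm(n) + ifelse(lab == "injured", 6 + i, 0)
  tab <- build_feature_table(df)
  rep <- rf_profile(tab, seed = 1)
  pca <- pca_top(tab, rep$importance, n_features = 5, n_components = 2)
  expect_true(any(grepl("^signal", pca$features)))
  sc <- pca$scores
  mb <- mean(sc$PC1[sc$label == "baseline"])
  mi <- mean(sc$PC1[sc$label == "injured"])
  within <- max(stats::sd(sc$PC1[sc$label == "baseline"]),
                stats::sd(sc$PC1[sc$label == "injured"]))
  expect_gt(abs(mb - mi), 3 * within)
  expect_true(all(diff(pca$explained_variance) <= 1e-12))
  expect_lte(sum(pca$explained_variance), 1 + 1e-12)
})

test_that("PCA is invariant to column order and affine feature rescaling", {
  tab <- mk_sep_table(seed = 3)
  rep <- rf_profile(tab, seed = 1)
  p1 <- pca_top(tab, rep$importance, n_features = 4)
  df <- as.data.frame(tab)
  df <- df[, c("animal", "label", rev(setdiff(names(df), c("animal", "label"))))]
  p2 <- pca_top(build_feature_table(df), rep$importance, n_features = 4)
  expect_equal(abs(p1$scores$PC1), abs(p2$scores$PC1), tolerance = 1e-9)
  # rescaling a selected column is absorbed by standardization
  df3 <- as.data.frame(tab)
  df3$signal <- df3$signal * 37 + 5
  p3 <- pca_top(build_feature_table(df3), rep$importance, n_features = 4)
  expect_equal(abs(p1$scores$PC1), abs(p3$scores$PC1), tolerance = 1e-9)
})

test_that("degenerate PCA inputs are rejected with the offending column named", {
  tab <- mk_sep_table()
  df <- as.data.frame(tab)
  df$constant <- 1
  tab2 <- build_feature_table(df)
  imp <- stats::setNames(rep(1, 3), c("constant", "signal", "noise_01"))
  imp["constant"] <- 5
  expect_error(pca_top(tab2, imp, n_features = 2), "constant")
  # explained variance sums to 1 when n_components = n_features
  rep <- rf_profile(tab, seed = 1)
  p <- pca_top(tab, rep$importance, n_features = 3, n_components = 3)
  expect_equal(sum(p$all_explained_variance), 1)
})

test_that("the end-to-end simulated cohort classifies with high accuracy", {
  groups <- list(
    baseline = gait_params(),
    injured = gait_params(deficit = list(left = 0.6, right = 0.9),
                          asynchrony_offset = 0.1,
                          noise_sd = 1, dropout_rate = 0.02))
  coh <- simulate_cohort(8, groups, seed = 11, duration = 3)
  tab <- cohort_feature_table(coh)
  expect_identical(nrow(tab), 16L)
  expect_gt(length(attr(tab, "features")), 100)
  rep <- rf_profile(tab, seed = 1)
  expect_gte(rep$accuracy, 0.95)
})
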