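#' Assemble the animal x timepoint gait feature table
#'
#' Run-level parameter rows are aggregated (mean over runs) per
#' animal x label; missing values stay NA (flagged, never imputed).
#'
#' @param rows Either a data frame or a list of named lists/one-row
#'   data frames, each carrying `animal`, `label` (group/timepoint),
#'   optionally `run`, plus numeric parameters.
#' @return Object of class `gait_feature_table`: a data frame with
#'   `animal`, `label` and one column per parameter; attribute
#'   `"features"` lists the parameter columns.
#' @export
build_feature_table <- function(rows) {
  if (is.data.frame(rows)) {
    df <- rows
  } else {
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  need <- c("animal", "label")
  if (!all(need %in% names(df)))
    stop("rows must carry 'animal' and 'label'", call. = FALSE)
  if (!"run" %in% names(df)) df$run <- "r1"
  key <- paste(df$animal, df$label, df$run, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    sub <- df[key %in% dup, , drop = FALSE]
    feat <- setdiff(names(sub), c("animal", "label", "run"))
    for (k in unique(dup)) {
      block <- sub[paste(sub$animal, sub$label, sub$run, sep = "\r") == k,
                   feat, drop = FALSE]
      if (nrow(unique(block)) > 1L)
        stop("conflicting duplicate rows for ", gsub("\r", "/", k),
             call. = FALSE)
    }
    df <- df[!duplicated(key), , drop = FALSE]
  }
  feat <- setdiff(names(df), c("animal", "label", "run"))
  agg <- stats::aggregate(df[feat],
                          by = list(animal = df$animal, label = df$label),
                          FUN = function(v) mean(v, na.rm = FALSE))
  agg <- agg[order(agg$label, agg$animal), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, features = feat,
            class = c("gait_feature_table", "data.frame"))
}

#' @export
print.gait_feature_table <- function(x, ...) {
  feat <- attr(x, "features")
  cat(sprintf("<gait_feature_table: %d rows, %d parameters, labels: %s>\n",
              nrow(x), length(feat),
              paste(unique(x$label), collapse = ", ")))
  miss <- vapply(x[feat], function(v) sum(is.na(v)), integer(1))
  if (any(miss > 0))
    cat(sprintf("  %d parameters carry missing values\n", sum(miss > 0)))
  invisible(x)
}

#' Subset a feature table to selected labels
#'
#' Parameterized label filter used for subgroup profiling (e.g.
#' baseline vs acute, baseline vs chronic).
#'
#' @param table A `gait_feature_table`.
#' @param labels Labels to keep.
#' @return A `gait_feature_table` restricted to those labels.
#' @export
filter_labels <- function(table, labels) {
  stopifnot(inherits(table, "gait_feature_table"))
  out <- table[table$label %in% labels, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, features = attr(table, "features"),
            class = class(table))
}

#' Random-forest locomotor profile
#'
#' Fits a random forest (100 trees, unrestricted depth) on a 75%/25%
#' train/test split and reports Gini-impurity-based feature
#' importances (normalized to sum to 1), the held-out confusion matrix
#' and accuracy. The split is stratified by label and performed at the
#' animal level, so no animal contributes rows to both splits.
#' Deterministic given the seed.
#'
#' @param table A `gait_feature_table` with >= 2 labels, each with >= 2
#'   rows.
#' @param split Training fraction (default 0.75).
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed for the split and the forest.
#' @return Object of class `classifier_report`: list with `importance`
#'   (named, sums to 1), `confusion` (true x predicted counts on the
#'   test split), `accuracy`, `n_train`, `n_test`, `dropped_na` (rows
#'   removed for missing features) and `seed`.
#' @export
rf_profile <- function(table, split = 0.75, n_trees = 100L, seed = 1L) {
  stopifnot(inherits(table, "gait_feature_table"),
            split > 0, split < 1, n_trees >= 1)
  feat <- attr(table, "features")
  all_na <- vapply(table[feat], function(v) all(is.na(v)), logical(1))
  if (any(all_na))
    stop("all-missing feature column(s): ",
         paste(feat[all_na], collapse = ", "), call. = FALSE)
  feat <- feat[!all_na]
  y <- factor(table$label)
  if (nlevels(y) < 2L)
    stop("classification needs at least two labels", call. = FALSE)
  if (any(table(y) < 2L))
    stop("every label needs at least two rows", call. = FALSE)
  cc <- stats::complete.cases(table[feat])
  dropped <- sum(!cc)
  tab <- table[cc, , drop = FALSE]
  y <- factor(tab$label)

  set.seed(as.integer(seed))
  # animal-level stratified split: an animal's rows stay together
  animals <- unique(tab$animal)
  an_label <- vapply(animals, function(a)
    paste(sort(unique(tab$label[tab$animal == a])), collapse = "|"),
    character(1))
  train_animals <- unlist(lapply(split(animals, an_label), function(g) {
    k <- max(1L, round(split * length(g)))
    if (k >= length(g)) k <- length(g) - 1L
    if (k < 1L) k <- 1L
    sample(g, k)
  }), use.names = FALSE)
  tr <- tab$animal %in% train_animals
  if (!any(!tr)) stop("split left no test rows", call. = FALSE)
  if (length(unique(tab$label[tr])) < nlevels(y))
    stop("split left a label without training rows; add animals",
         call. = FALSE)
  x_tr <- tab[tr, feat, drop = FALSE]
  x_te <- tab[!tr, feat, drop = FALSE]
  fit <- randomForest::randomForest(
    x = x_tr, y = factor(tab$label[tr], levels = levels(y)),
    ntree = n_trees, nodesize = 1)
  imp <- fit$importance[, "MeanDecreaseGini"]
  s <- sum(imp)
  imp <- if (s > 0) imp / s else imp
  pred <- stats::predict(fit, x_te)
  truth <- factor(tab$label[!tr], levels = levels(y))
  confusion <- table(truth = truth, predicted = pred)
  structure(
    list(importance = imp, confusion = confusion,
         accuracy = sum(diag(confusion)) / sum(confusion),
         n_train = sum(tr), n_test = sum(!tr),
         dropped_na = dropped, seed = as.integer(seed)),
    class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report: accuracy %.3f (%d train / %d test rows)>\n",
              x$accuracy, x$n_train, x$n_test))
  cat("confusion (truth x predicted):\n")
  print(x$confusion)
  top <- sort(x$importance, decreasing = TRUE)[seq_len(min(5, length(x$importance)))]
  cat("top features (Gini importance):\n")
  for (i in seq_along(top))
    cat(sprintf("  %-40s %.4f\n", names(top)[i], top[i]))
  invisible(x)
}

# deterministic top-k set: importance desc, names break ties
.top_k <- function(importance, k) {
  ord <- order(-importance, names(importance))
  names(importance)[ord][seq_len(k)]
}

#' Overlap between the top-k important features of two profiles
#'
#' @param report_a,report_b `classifier_report`s sharing one feature
#'   namespace.
#' @param k Size of each top set (default 20).
#' @return Overlap in percent: `|top_k(a) ∩ top_k(b)| / k * 100`.
#' @export
top_feature_overlap <- function(report_a, report_b, k = 20L) {
  stopifnot(inherits(report_a, "classifier_report"),
            inherits(report_b, "classifier_report"))
  if (!setequal(names(report_a$importance), names(report_b$importance)))
    stop("reports do not share a feature namespace", call. = FALSE)
  if (k > length(report_a$importance))
    stop("k exceeds the feature count", call. = FALSE)
  ta <- .top_k(report_a$importance, k)
  tb <- .top_k(report_b$importance, k)
  length(intersect(ta, tb)) / k * 100
}

#' PCA on the most important gait parameters
#'
#' Projects the rows of the feature table onto the leading principal
#' components of the standardized top-`n_features` parameters (by the
#' supplied importance scores).
#'
#' @param table A `gait_feature_table`.
#' @param importance Named importance scores (e.g. from
#'   [rf_profile()]).
#' @param n_features How many top features to use (default 5).
#' @param n_components How many components to report (default 2).
#' @return Object of class `gait_pca`: list with `scores` (data frame:
#'   `animal`, `label`, `PC1..`), `explained_variance`
#'   (non-increasing fractions), `features` (the selected columns) and
#'   `dropped_na` (rows removed for missing selected features).
#' @export
pca_top <- function(table, importance, n_features = 5L, n_components = 2L) {
  stopifnot(inherits(table, "gait_feature_table"),
            n_features >= 1, n_components >= 1,
            n_components <= n_features)
  feat <- attr(table, "features")
  importance <- importance[names(importance) %in% feat]
  if (n_features > length(importance))
    stop("n_features exceeds the scored feature count", call. = FALSE)
  sel <- .top_k(importance, n_features)
  cc <- stats::complete.cases(table[sel])
  dropped <- sum(!cc)
  tab <- table[cc, , drop = FALSE]
  if (nrow(tab) < 2L) stop("not enough complete rows for PCA", call. = FALSE)
  sds <- vapply(tab[sel], stats::sd, numeric(1))
  if (any(sds == 0))
    stop("constant selected column(s): ",
         paste(sel[sds == 0], collapse = ", "), call. = FALSE)
  pc <- stats::prcomp(as.matrix(tab[sel]), center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(pc$x))
  scores <- data.frame(animal = tab$animal, label = tab$label,
                       pc$x[, seq_len(k), drop = FALSE],
                       stringsAsFactors = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, explained_variance = ev[seq_len(k)],
                 all_explained_variance = ev, features = sel,
                 dropped_na = dropped),
            class = "gait_pca")
}

#' @export
print.gait_pca <- function(x, ...) {
  cat(sprintf("<gait_pca: %d rows on %d features; PC variance %s>\n",
              nrow(x$scores), length(x$features),
              paste(sprintf("%.1f%%", 100 * x$explained_variance),
                    collapse = ", ")))
  invisible(x)
}

#' @export
plot.gait_pca <- function(x, ...) {
  sc <- x$scores
  cols <- as.integer(factor(sc$label))
  graphics::plot(sc[[3L]], sc[[4L]], col = cols, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained_variance[1L]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained_variance[2L]),
                 ...)
  graphics::legend("topright", legend = levels(factor(sc$label)),
                   col = seq_along(unique(sc$label)), pch = 19, bty = "n")
  invisible(x)
}
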