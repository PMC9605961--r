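#' Train a lyric-vs-dramatic random forest
#'
#' Probability random forest on a single voice type's feature table, with
#' per-tree random feature subsets and a class-balanced bootstrap (each
#' tree draws the minority-class count from both classes) so the balanced
#' error rate is the natural evaluation measure. Deterministic for a fixed
#' seed (single thread).
#'
#' @param table feature table: data.frame with a `voice_structure` factor
#'   (levels lyric, dramatic) and numeric feature columns.
#' @param features character vector of feature columns; defaults to all
#'   numeric columns.
#' @param num_trees number of trees.
#' @param mtry features tried per split; default `floor(sqrt(d))`.
#' @param min_node_size minimum node size.
#' @param seed integer seed.
#' @return object of class `fach_forest`: the fitted `ranger` model plus
#'   the feature names and training metadata.
#' @export
train_fach_forest <- function(table, features = NULL, num_trees = 500L,
                              mtry = NULL, min_node_size = 5L, seed = 1L) {
  stopifnot(is.data.frame(table), "voice_structure" %in% names(table))
  y <- factor(table$voice_structure, levels = c("lyric", "dramatic"))
  if (nlevels(droplevels(y)) < 2L)
    stop("feature table contains a single class", call. = FALSE)
  if (min(table(y)) < 20L)
    warning("fewer than 20 rows in a class; estimates will be unstable")
  if (is.null(features)) {
    num <- vapply(table, is.numeric, logical(1))
    features <- setdiff(names(table)[num], "voice_structure")
  }
  x <- table[features]
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(features))))
  frac <- min(table(y)) / length(y)
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = num_trees, mtry = mtry, min.node.size = min_node_size,
    probability = TRUE, importance = "impurity",
    replace = TRUE, sample.fraction = rep(frac, 2L),
    seed = seed, num.threads = 1L
  )
  structure(list(model = fit, features = features, seed = seed,
                 classes = c("lyric", "dramatic")),
            class = "fach_forest")
}

#' Predicted probability of the dramatic class
#'
#' @param object a `fach_forest`.
#' @param newdata data.frame containing the model's feature columns.
#' @param ... unused.
#' @return numeric vector of P(dramatic).
#' @export
predict.fach_forest <- function(object, newdata, ...) {
  pr <- stats::predict(object$model, data = newdata[object$features],
                       num.threads = 1L)$predictions
  unname(pr[, "dramatic"])
}

#' Predicted class labels at a probability threshold
#'
#' @param object a `fach_forest`.
#' @param newdata feature data.frame.
#' @param threshold P(dramatic) above which a sample is called dramatic.
#' @return factor with levels lyric, dramatic.
#' @export
classify_fach <- function(object, newdata, threshold = 0.5) {
  p <- predict(object, newdata)
  factor(ifelse(p > threshold, "dramatic", "lyric"),
         levels = c("lyric", "dramatic"))
}

#' Balanced error rate
#'
#' Mean of the two class-conditional error rates, in percent: insensitive
#' to class imbalance, 50% for any single-class predictor on balanced
#' truth.
#'
#' @param truth true labels (two classes, both present).
#' @param predictions predicted labels.
#' @return BER in percent, in \[0, 100\].
#' @export
balanced_error_rate <- function(truth, predictions) {
  truth <- as.character(truth)
  predictions <- as.character(predictions)
  classes <- sort(unique(truth))
  if (length(classes) != 2L)
    stop("truth must contain exactly two classes", call. = FALSE)
  errs <- vapply(classes, function(cl) {
    mean(predictions[truth == cl] != cl)
  }, numeric(1))
  mean(errs) * 100
}

#' Impurity-decrease feature importance
#'
#' Mean decrease in node impurity per feature across the forest's trees
#' (the information-gain-style importance of tree ensembles), normalized
#' to sum to 1 and sorted in decreasing order.
#'
#' @param object a `fach_forest`.
#' @return named numeric vector, decreasing, summing to 1.
#' @export
feature_importance <- function(object) {
  stopifnot(inherits(object, "fach_forest"))
  imp <- object$model$variable.importance
  imp <- pmax(imp, 0)
  sort(imp / sum(imp), decreasing = TRUE)
}

#' Stratified cross-validated balanced error rate
#'
#' @param table feature table (see [train_fach_forest()]).
#' @param k number of folds.
#' @param seed integer seed controlling both the fold split and the
#'   per-fold forests.
#' @param ... passed to [train_fach_forest()].
#' @return list: `ber` (percent), `fold_ber` (per-fold), `predictions`
#'   (factor, one per row of `table`).
#' @export
cross_validated_ber <- function(table, k = 5L, seed = 1L, ...) {
  y <- factor(table$voice_structure, levels = c("lyric", "dramatic"))
  set.seed(seed)
  fold <- integer(nrow(table))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  pred <- factor(rep("lyric", nrow(table)), levels = levels(y))
  fold_ber <- numeric(k)
  for (j in seq_len(k)) {
    tr <- table[fold != j, , drop = FALSE]
    te <- table[fold == j, , drop = FALSE]
    fit <- train_fach_forest(tr, seed = seed + j, ...)
    pred[fold == j] <- classify_fach(fit, te)
    fold_ber[j] <- balanced_error_rate(y[fold == j], pred[fold == j])
  }
  list(ber = balanced_error_rate(y, pred), fold_ber = fold_ber,
       predictions = pred)
}

#' Exact additive per-sample feature attributions
#'
#' Interventional Shapley values of the forest's P(dramatic) output,
#' computed exactly over all 2^d feature coalitions against a background
#' sample: for each coalition the model is evaluated on hybrids that take
#' coalition features from the explained sample and the rest from the
#' background rows, and each feature's attribution is its Shapley-weighted
#' marginal contribution. Local accuracy holds by construction: per sample
#' the attributions sum to the model output minus the base value (the mean
#' background prediction). For the binary problem the attributions toward
#' the lyric class are the exact negatives (the two class probabilities
#' sum to 1), so only the dramatic-class attributions are materialized.
#'
#' Cost grows as `2^d * n_background` model evaluations per sample; it is
#' intended for the compact feature sets used here (d <= 12).
#'
#' @param object a `fach_forest`.
#' @param table data.frame of samples to explain.
#' @param background background data.frame (defaults to `table`); at most
#'   `max_background` rows are used, subsampled deterministically.
#' @param max_background cap on background rows.
#' @return list of class `fach_attribution`: `attributions` (matrix, one
#'   row per explained sample, one column per feature), `base_value`,
#'   `prediction` (P(dramatic) per sample).
#' @export
attribution_summary <- function(object, table, background = table,
                                max_background = 25L) {
  stopifnot(inherits(object, "fach_forest"))
  feats <- object$features
  d <- length(feats)
  if (d > 12L) stop("exact attributions limited to <= 12 features",
                    call. = FALSE)
  x <- as.matrix(table[feats])
  bg <- as.matrix(background[feats])
  if (nrow(bg) > max_background) {
    set.seed(object$seed)
    bg <- bg[sample(nrow(bg), max_background), , drop = FALSE]
  }
  nb <- nrow(bg)
  n <- nrow(x)

  # all coalitions as a logical matrix (2^d x d)
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), d)))
  ns <- nrow(subsets)
  sizes <- rowSums(subsets)
  # v(S) per explained sample: mean prediction over background hybrids
  vmat <- matrix(0, n, ns)
  for (s in seq_len(ns)) {
    keep <- subsets[s, ]
    # rows: each explained sample crossed with each background row
    hyb <- bg[rep(seq_len(nb), times = n), , drop = FALSE]
    xi <- x[rep(seq_len(n), each = nb), , drop = FALSE]
    hyb[, keep] <- xi[, keep]
    pr <- predict(object, as.data.frame(hyb))
    vmat[, s] <- colMeans(matrix(pr, nb, n))
  }

  w <- function(ssize) factorial(ssize) * factorial(d - ssize - 1) /
    factorial(d)
  phi <- matrix(0, n, d, dimnames = list(NULL, feats))
  key <- subsets %*% 2^(seq_len(d) - 1)            # coalition -> column id
  col_of <- integer(max(key) + 1L)
  col_of[key + 1L] <- seq_len(ns)
  for (i in seq_len(d)) {
    without <- which(!subsets[, i])
    with_i <- col_of[key[without] + 2^(i - 1) + 1L]
    wt <- w(sizes[without])
    phi[, i] <- (vmat[, with_i, drop = FALSE] -
                 vmat[, without, drop = FALSE]) %*% wt
  }
  structure(list(attributions = phi,
                 base_value = mean(vmat[, col_of[1L]]),
                 prediction = vmat[, col_of[2^d - 1 + 1L]]),
            class = "fach_attribution")
}

#' @export
print.fach_attribution <- function(x, ...) {
  cat(sprintf("<fach_attribution> %d samples x %d features, base %.3f\n",
              nrow(x$attributions), ncol(x$attributions), x$base_value))
  imp <- sort(colMeans(abs(x$attributions)), decreasing = TRUE)
  cat("mean |attribution|:\n")
  print(round(imp, 4))
  invisible(x)
}
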