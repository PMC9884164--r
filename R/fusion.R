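# Feature fusion (24 artificial + 38 abstract = 62) and the random-forest
# classifier (300 trees, mtry = floor(sqrt(62)), depth 40, soft-vote
# averaging), realized with ranger behind this module's surface.

#' Fuse artificial and abstract feature vectors
#'
#' Plain concatenation in the fixed order (artificial first); no scaling is
#' applied since tree ensembles are invariant to monotone per-feature
#' transforms.
#'
#' @param artificial numeric vector of length 24.
#' @param abstract numeric vector of length 38.
#' @return numeric vector of length 62.
#' @export
fuse <- function(artificial, abstract) {
  if (length(artificial) != 24) stop("artificial part must have length 24, got ",
                                     length(artificial))
  if (length(abstract) != 38) stop("abstract part must have length 38, got ",
                                   length(abstract))
  v <- c(artificial, abstract)
  if (!all(is.finite(v))) stop("non-finite feature value in fused vector")
  if (is.null(names(abstract))) {
    names(v) <- c(ARTIFICIAL_FEATURE_NAMES, paste0("S", 1:38))
  }
  v
}

#' Random-forest configuration
#'
#' @param n_trees number of trees.
#' @param max_depth maximum tree depth.
#' @param min_samples_split minimum samples for an internal split (mapped to
#'   a terminal-node size of `min_samples_split - 1`).
#' @param max_features features tried per split; default floor(sqrt(p)).
#' @param seed forest seed.
#' @return list of class `forest_config`.
#' @export
forest_config <- function(n_trees = 300, max_depth = 40, min_samples_split = 2,
                          max_features = NULL, seed = 1L) {
  stopifnot(n_trees >= 1)
  structure(list(n_trees = n_trees, max_depth = max_depth,
                 min_samples_split = min_samples_split,
                 max_features = max_features, seed = as.integer(seed)),
            class = "forest_config")
}

#' Train the random forest on a fused feature matrix
#'
#' Gini-split CART trees on bootstrap resamples; class membership is decided
#' by averaging the per-tree class vote fractions (soft voting).
#'
#' @param X numeric matrix or data.frame of features (rows = segments).
#' @param labels class labels over `c("N","A","O","~")`.
#' @param cfg a [forest_config()].
#' @return list of class `af_forest` with the fitted ensemble, factor level
#'   order, out-of-bag classification error (`oob_error`) and the config.
#' @export
train_forest <- function(X, labels, cfg = forest_config()) {
  X <- as.data.frame(X)
  if (nrow(X) < 2) stop("need at least 2 training rows")
  bad <- !vapply(X, function(col) all(is.finite(col)), logical(1))
  if (any(bad)) stop("non-finite values in feature column(s): ",
                     paste(names(X)[bad], collapse = ", "))
  lv <- AF_CLASSES[AF_CLASSES %in% unique(as.character(labels))]
  if (length(lv) < 2) stop("training labels must contain at least 2 classes")
  y <- factor(as.character(labels), levels = lv)
  mtry <- if (is.null(cfg$max_features)) max(1L, floor(sqrt(ncol(X)))) else cfg$max_features
  rf <- ranger::ranger(x = X, y = y,
                       num.trees = cfg$n_trees,
                       mtry = mtry,
                       min.node.size = max(1L, cfg$min_samples_split - 1L),
                       max.depth = cfg$max_depth,
                       probability = TRUE,
                       seed = cfg$seed,
                       num.threads = 1)
  oob_pred <- lv[max.col(rf$predictions, ties.method = "first")]
  structure(list(rf = rf, levels = lv, features = names(X), cfg = cfg,
                 oob_error = mean(oob_pred != as.character(y))),
            class = "af_forest")
}

#' Classify fused feature vectors
#'
#' @param model an `af_forest`.
#' @param X feature matrix/data.frame with the training columns.
#' @return list with `labels` (character; ties broken toward the earlier
#'   class in N, A, O, ~ order) and `votes` (per-class averaged vote
#'   fractions, rows summing to 1).
#' @export
predict_af <- function(model, X) {
  X <- as.data.frame(X)
  if (ncol(X) != length(model$features)) {
    stop("feature count mismatch: model has ", length(model$features),
         " columns, input has ", ncol(X))
  }
  names(X) <- model$features
  votes <- stats::predict(model$rf, data = X, num.threads = 1)$predictions
  colnames(votes) <- model$levels
  list(labels = model$levels[max.col(votes, ties.method = "first")],
       votes = votes)
}
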