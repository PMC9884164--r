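# End-to-end orchestration: ingest -> fiducials -> features -> CNN ->
# fusion -> forest -> scoring, plus the feature-scheme ablation harness.

#' Pipeline configuration
#'
#' @param counts named per-class recording counts for synthetic input
#'   (ignored when `data_dir` is given).
#' @param data_dir optional directory of on-disk records to ingest instead of
#'   generating synthetic data.
#' @param scheme feature scheme: `"fused"` (62 features), `"artificial"`
#'   (24), `"abstract"` (38) or `"fused_minus_PRE"` (61).
#' @param seeds named list of stage seeds (`synth`, `split`, `cnn`,
#'   `forest`, `crop`).
#' @param train_frac train fraction of the stratified split.
#' @param cnn_epochs,cnn_batch,cnn_lr CNN training hyperparameters.
#' @param pre_m entropy window order.
#' @param pad_mode tiling pad mode for [unify_length()].
#' @param forest_cfg a [forest_config()]; its seed is overridden by
#'   `seeds$forest`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = c(N = 40, A = 20, O = 25, "~" = 15),
                            data_dir = NULL,
                            scheme = c("fused", "artificial", "abstract",
                                       "fused_minus_PRE"),
                            seeds = list(),
                            train_frac = 0.8,
                            cnn_epochs = 10, cnn_batch = 32, cnn_lr = 1e-3,
                            pre_m = 3,
                            pad_mode = "tile",
                            forest_cfg = forest_config()) {
  scheme <- match.arg(scheme)
  seeds <- utils::modifyList(list(synth = 1L, split = 2L, cnn = 3L,
                                  forest = 4L, crop = 5L), seeds)
  structure(list(counts = counts, data_dir = data_dir, scheme = scheme,
                 seeds = seeds, train_frac = train_frac,
                 cnn_epochs = cnn_epochs, cnn_batch = cnn_batch,
                 cnn_lr = cnn_lr, pre_m = pre_m, pad_mode = pad_mode,
                 forest_cfg = forest_cfg),
            class = "pipeline_config")
}

# ingest + unify + per-segment feature extraction, shared across schemes
pipeline_features <- function(cfg) {
  records <- if (!is.null(cfg$data_dir)) {
    read_dataset(cfg$data_dir)
  } else {
    lapply(generate_dataset(cfg$counts, seed = cfg$seeds$synth),
           function(r) r$recording)
  }
  segments <- vector("list", length(records))
  for (i in seq_along(records)) {
    segments[[i]] <- unify_length(records[[i]], seed = cfg$seeds$crop + i,
                                  pad_mode = cfg$pad_mode)
  }
  art <- artificial_feature_table(segments, pre_m = cfg$pre_m)
  Xcnn <- t(vapply(segments, function(s) prepare_cnn_input(s$samples, s$fs),
                   numeric(3000)))
  list(segments = segments, artificial = art, cnn_input = Xcnn,
       labels = art$label)
}

scheme_matrix <- function(scheme, art, abstract) {
  art_m <- as.matrix(art[, ARTIFICIAL_FEATURE_NAMES])
  switch(scheme,
         artificial = art_m,
         abstract = abstract,
         fused = cbind(art_m, abstract),
         fused_minus_PRE = cbind(art_m[, setdiff(ARTIFICIAL_FEATURE_NAMES, "PRE")],
                                 abstract),
         stop("unknown scheme ", scheme))
}

#' Run the full detection pipeline
#'
#' Generates (or ingests) recordings, unifies them to 30-s segments, extracts
#' the artificial features, trains the CNN on the training split and extracts
#' abstract features (for schemes that use them), trains the random forest on
#' the scheme's feature matrix, classifies the test split and scores it.
#'
#' @param cfg a [pipeline_config()].
#' @param features optional precomputed result of the ingest/feature stage,
#'   to share it across schemes.
#' @return list of class `pipeline_result`: `metrics` (an `af_metrics`),
#'   `confusion`, `split`, `scheme`, `n_features`, `cnn_model` (NULL for the
#'   artificial scheme), `forest`, `config`.
#' @export
run_pipeline <- function(cfg, features = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(features)) features <- pipeline_features(cfg)
  labels <- features$labels
  split <- split_dataset(features$segments, train_frac = cfg$train_frac,
                         seed = cfg$seeds$split)
  cnn_model <- NULL
  abstract <- NULL
  if (cfg$scheme != "artificial") {
    cnn_model <- train_cnn(features$cnn_input[split$train, , drop = FALSE],
                           labels[split$train],
                           epochs = cfg$cnn_epochs, batch_size = cfg$cnn_batch,
                           lr = cfg$cnn_lr, seed = cfg$seeds$cnn)
    abstract <- extract_abstract(cnn_model, features$cnn_input)
  }
  M <- scheme_matrix(cfg$scheme, features$artificial, abstract)
  fcfg <- cfg$forest_cfg
  fcfg$seed <- cfg$seeds$forest
  forest <- train_forest(M[split$train, , drop = FALSE], labels[split$train],
                         cfg = fcfg)
  pred <- predict_af(forest, M[split$test, , drop = FALSE])
  cm <- af_confusion(labels[split$test], pred$labels)
  structure(list(metrics = af_score(cm), confusion = cm, split = split,
                 scheme = cfg$scheme, n_features = ncol(M),
                 cnn_model = cnn_model, forest = forest, config = cfg),
            class = "pipeline_result")
}

#' Feature-scheme ablation
#'
#' Runs the pipeline once per seed with the ingest/feature stage shared
#' across schemes within a seed, and tabulates per-scheme accuracy and the
#' F1 of the noisy class.
#'
#' @param cfg a [pipeline_config()] (its `scheme` field is ignored).
#' @param schemes character vector of schemes to compare.
#' @param n_seeds number of independent replicates; replicate `i` offsets
#'   every stage seed by `i`.
#' @return list with `runs` (data.frame: seed, scheme, acc, macro_F1, F1p)
#'   and `summary` (per-scheme mean and sd of accuracy).
#' @export
run_ablation <- function(cfg, schemes = c("artificial", "abstract", "fused"),
                         n_seeds = 10) {
  if (length(schemes) < 2) stop("need at least 2 schemes to compare")
  rows <- list()
  for (i in seq_len(n_seeds)) {
    cfg_i <- cfg
    cfg_i$seeds <- lapply(cfg$seeds, function(s) s + i * 1000L)
    features <- pipeline_features(cfg_i)
    # train the CNN once per seed; schemes reuse its abstract features
    needs_cnn <- any(schemes != "artificial")
    res_cache <- list()
    split <- split_dataset(features$segments, train_frac = cfg_i$train_frac,
                           seed = cfg_i$seeds$split)
    abstract <- NULL
    if (needs_cnn) {
      cnn_model <- train_cnn(features$cnn_input[split$train, , drop = FALSE],
                             features$labels[split$train],
                             epochs = cfg_i$cnn_epochs,
                             batch_size = cfg_i$cnn_batch,
                             lr = cfg_i$cnn_lr, seed = cfg_i$seeds$cnn)
      abstract <- extract_abstract(cnn_model, features$cnn_input)
    }
    for (sc in schemes) {
      M <- scheme_matrix(sc, features$artificial, abstract)
      fcfg <- cfg_i$forest_cfg
      fcfg$seed <- cfg_i$seeds$forest
      forest <- train_forest(M[split$train, , drop = FALSE],
                             features$labels[split$train], cfg = fcfg)
      pred <- predict_af(forest, M[split$test, , drop = FALSE])
      sc_metrics <- af_score(af_confusion(features$labels[split$test],
                                          pred$labels))
      rows[[length(rows) + 1]] <- data.frame(
        seed = i, scheme = sc, acc = sc_metrics$acc,
        macro_F1 = sc_metrics$macro_F1,
        F1p = sc_metrics$per_class["~", "F1"])
    }
  }
  runs <- do.call(rbind, rows)
  agg <- stats::aggregate(acc ~ scheme, runs, function(a) c(mean = mean(a),
                                                            sd = stats::sd(a)))
  summary <- data.frame(scheme = agg$scheme,
                        mean_acc = agg$acc[, "mean"], sd_acc = agg$acc[, "sd"])
  list(runs = runs, summary = summary)
}
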