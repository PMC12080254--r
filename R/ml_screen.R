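# Machine-learning screen: a gradient-boosted tree ensemble predicting the
# pooled positive class (PMT or vPvM or both, per the updated CLP
# criteria), gated by a Euclidean-distance applicability domain (AD) and
# interpreted with exact tree-SHAP attributions and interaction values.
#
# Feature handling: median imputation and z-scoring are fit on the
# training data only and serialized with the model. Distances are computed
# in the z-scored space (Euclidean distance on raw, mixed-unit descriptors
# would be meaningless). The AD threshold is fixed at training time as
# mean + ad_multiplier * sd of the within-training nearest-neighbour
# distances.

feature_matrix_of <- function(features) {
  stopifnot(is.data.frame(features), "compound_id" %in% names(features))
  ids <- features$compound_id
  X <- as.matrix(features[, setdiff(names(features), "compound_id"),
                          drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- ids
  X
}

impute_and_scale <- function(X, medians, center, scale) {
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- medians[j]
  }
  sweep(sweep(X, 2, center, "-"), 2, scale, "/")
}

# Euclidean cross-distances, rows of A vs rows of B. Squared distances
# below 1e-12 are clamped to zero so that identical rows report an exact
# zero distance despite floating-point cancellation.
cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  d2[d2 < 1e-12] <- 0
  sqrt(d2)
}

#' Train the PMT/vPvM candidate classifier
#'
#' Fits a gradient-boosted tree ensemble (xgboost, binary logistic) on a
#' descriptor matrix with binary labels (positive = PMT or vPvM or both —
#' one pooled class). Median imputation and per-feature z-scoring are fit
#' on the training data and stored in the returned bundle together with
#' the scaled training matrix, the applicability-domain threshold and the
#' seed, so the bundle is self-contained for prediction, AD gating and
#' explanation. Training is deterministic given the seed
#' (single-threaded).
#'
#' @param features data frame: `compound_id` + numeric descriptor columns.
#' @param labels binary vector (0/1 or logical), aligned with `features`
#'   rows.
#' @param seed integer seed for the stochastic parts of boosting.
#' @param nrounds number of boosting rounds (default 200).
#' @param params named list merged over the defaults
#'   (`max_depth = 4`, `eta = 0.1`, `subsample = 0.8`,
#'   `colsample_bytree = 0.8`).
#' @param config a [pmt_config()] (AD neighbour count and threshold
#'   multiplier).
#' @return a `pmt_model_bundle`.
#' @export
train_pmt_model <- function(features, labels, seed = 42, nrounds = 200,
                            params = list(), config = pmt_config()) {
  X <- feature_matrix_of(features)
  y <- as.integer(as.logical(labels))
  if (length(y) != nrow(X)) stop("feature/label length mismatch")
  if (length(unique(y)) < 2) {
    stop("labels contain a single class; two classes are required")
  }
  medians <- apply(X, 2, function(v) {
    m <- stats::median(v[is.finite(v)])
    if (!is.finite(m)) 0 else m
  })
  Ximp <- X
  for (j in seq_len(ncol(Ximp))) {
    bad <- !is.finite(Ximp[, j])
    if (any(bad)) Ximp[bad, j] <- medians[j]
  }
  center <- colMeans(Ximp)
  scale <- apply(Ximp, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  Xs <- sweep(sweep(Ximp, 2, center, "-"), 2, scale, "/")

  defaults <- list(objective = "binary:logistic", eval_metric = "logloss",
                   max_depth = 4, eta = 0.1, subsample = 0.8,
                   colsample_bytree = 0.8, nthread = 1,
                   seed = as.integer(seed))
  p <- utils::modifyList(defaults, params)
  set.seed(seed)
  booster <- xgboost::xgb.train(
    params = p, data = xgboost::xgb.DMatrix(Xs, label = y),
    nrounds = nrounds, verbose = 0)

  # within-training nearest-neighbour distances (k nearest, excluding self)
  D <- cross_dist(Xs, Xs)
  diag(D) <- Inf
  k <- config$ad_k
  nn <- apply(D, 1, function(r) mean(sort(r)[seq_len(k)]))
  ad_threshold <- mean(nn) + config$ad_multiplier * stats::sd(nn)

  structure(list(
    booster = booster,
    columns = colnames(X),
    medians = medians,
    center = center,
    scale = scale,
    train_matrix = Xs,
    train_labels = y,
    ad_threshold = ad_threshold,
    ad_k = k,
    ad_multiplier = config$ad_multiplier,
    nn_mean = mean(nn),
    nn_sd = stats::sd(nn),
    label_definition = "positive = PMT or vPvM or both (pooled), updated CLP criteria",
    prob_cutoff = config$prob_cutoff,
    seed = as.integer(seed),
    nrounds = nrounds,
    params = p
  ), class = "pmt_model_bundle")
}

#' @export
print.pmt_model_bundle <- function(x, ...) {
  cat("PMT/vPvM candidate classifier (gradient-boosted trees)\n")
  cat(sprintf("  training set: %d compounds x %d descriptors (%d positive)\n",
              nrow(x$train_matrix), length(x$columns), sum(x$train_labels)))
  cat(sprintf("  AD threshold: %.4f (k = %d, mean + %g sd of NN distances)\n",
              x$ad_threshold, x$ad_k, x$ad_multiplier))
  cat(sprintf("  seed: %d, rounds: %d\n", x$seed, x$nrounds))
  invisible(x)
}

align_features <- function(bundle, features) {
  X <- feature_matrix_of(features)
  if (!identical(colnames(X), bundle$columns)) {
    if (setequal(colnames(X), bundle$columns)) {
      X <- X[, bundle$columns, drop = FALSE]
    } else {
      stop("feature columns do not match the model's column manifest")
    }
  }
  X
}

#' Applicability-domain statistics
#'
#' Computes, for each query compound, the Euclidean distance in the
#' z-scored descriptor space to its nearest training compound(s) (mean of
#' the `ad_k` nearest). A lower distance means greater similarity to the
#' training set; a query identical to a training compound has distance 0.
#' The compound is in-domain iff its distance does not exceed the bundle's
#' threshold.
#'
#' @param bundle a `pmt_model_bundle`.
#' @param features data frame: `compound_id` + descriptor columns matching
#'   the bundle's manifest.
#' @return data frame with columns `compound_id`, `distance`, `in_domain`.
#' @export
applicability_domain <- function(bundle, features) {
  X <- align_features(bundle, features)
  Xs <- impute_and_scale(X, bundle$medians, bundle$center, bundle$scale)
  D <- cross_dist(Xs, bundle$train_matrix)
  k <- bundle$ad_k
  dist <- apply(D, 1, function(r) mean(sort(r)[seq_len(k)]))
  data.frame(compound_id = rownames(X), distance = unname(dist),
             in_domain = unname(dist) <= bundle$ad_threshold,
             stringsAsFactors = FALSE)
}

#' Predict PMT/vPvM candidates
#'
#' Applies the classifier to compounds, gated by the applicability domain:
#' in-domain compounds with probability above the cutoff become
#' `candidate_PMT_vPvM`, in-domain compounds below it `not_PMT_vPvM` (both
#' decided by the model); out-of-domain compounds stay `unresolved` with
#' detail "outside AD" regardless of their score.
#'
#' @param bundle a `pmt_model_bundle`.
#' @param features descriptor data frame.
#' @param domain optional precomputed [applicability_domain()] result.
#' @return data frame: `compound_id`, `probability`, `distance`,
#'   `in_domain`, `hazard_class`, `decided_by`, `detail`.
#' @export
predict_pmt <- function(bundle, features, domain = NULL) {
  X <- align_features(bundle, features)
  Xs <- impute_and_scale(X, bundle$medians, bundle$center, bundle$scale)
  if (is.null(domain)) domain <- applicability_domain(bundle, features)
  stopifnot(identical(domain$compound_id, rownames(X)))
  prob <- predict(bundle$booster, xgboost::xgb.DMatrix(Xs))
  positive <- prob >= bundle$prob_cutoff
  hazard_class <- ifelse(!domain$in_domain, "unresolved",
                         ifelse(positive, "candidate_PMT_vPvM",
                                "not_PMT_vPvM"))
  decided_by <- ifelse(domain$in_domain, "ml_model", "none")
  detail <- ifelse(!domain$in_domain,
                   sprintf("outside AD (distance %.3f > threshold %.3f)",
                           domain$distance, bundle$ad_threshold),
                   sprintf("ml_model p=%.3f, AD distance %.3f",
                           prob, domain$distance))
  data.frame(compound_id = rownames(X), probability = prob,
             distance = domain$distance, in_domain = domain$in_domain,
             hazard_class = hazard_class, decided_by = decided_by,
             detail = detail, stringsAsFactors = FALSE)
}

#' SHAP explanations
#'
#' Computes exact tree-SHAP attributions for each compound: per-feature
#' attribution values and the base value, satisfying the additivity
#' identity (base value + sum of attributions = the model's raw log-odds
#' output). Optionally computes the SHAP interaction matrix (symmetric;
#' its row sums recover the per-feature attributions). Global importance
#' is the mean absolute attribution per feature, sorted descending.
#'
#' @param bundle a `pmt_model_bundle`.
#' @param features descriptor data frame.
#' @param interactions compute SHAP interaction values (default FALSE;
#'   cubic in feature count per compound).
#' @return a `pmt_explanations` list: `shap` (n x p matrix),
#'   `base_value`, `margin` (raw model output), `feature_values`
#'   (original, unscaled), `importance` (data frame feature /
#'   mean_abs_shap), `interactions` (n x p x p array or NULL).
#' @export
explain_pmt <- function(bundle, features, interactions = FALSE) {
  X <- align_features(bundle, features)
  Xs <- impute_and_scale(X, bundle$medians, bundle$center, bundle$scale)
  dm <- xgboost::xgb.DMatrix(Xs)
  contrib <- predict(bundle$booster, dm, predcontrib = TRUE)
  margin <- predict(bundle$booster, dm, outputmargin = TRUE)
  p <- ncol(Xs)
  shap <- contrib[, seq_len(p), drop = FALSE]
  colnames(shap) <- colnames(Xs)
  rownames(shap) <- rownames(X)
  base_value <- contrib[, p + 1]
  imp <- colMeans(abs(shap))
  importance <- data.frame(feature = names(imp),
                           mean_abs_shap = unname(imp),
                           stringsAsFactors = FALSE)
  importance <- importance[order(-importance$mean_abs_shap,
                                 importance$feature), ]
  rownames(importance) <- NULL
  inter <- NULL
  if (interactions) {
    inter <- tryCatch(
      predict(bundle$booster, dm, predinteraction = TRUE),
      error = function(e) {
        warning("SHAP interaction values unavailable: ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(inter)) {
      inter <- inter[, seq_len(p), seq_len(p), drop = FALSE]
      # symmetrize: float32 evaluation leaves ~1e-7 asymmetry
      inter <- (inter + aperm(inter, c(1, 3, 2))) / 2
      dimnames(inter) <- list(rownames(X), colnames(Xs), colnames(Xs))
    }
  }
  structure(list(shap = shap, base_value = base_value, margin = margin,
                 feature_values = X, importance = importance,
                 interactions = inter),
            class = "pmt_explanations")
}

#' Dependence data for one feature
#'
#' Extracts (feature value, SHAP value) pairs for plotting a dependence
#' relation, coloured by the strongest-interacting other feature. The
#' interaction partner is taken from the SHAP interaction matrix when
#' available, otherwise from the absolute correlation between this
#' feature's SHAP values and the other features' values.
#'
#' @param explanations a `pmt_explanations`.
#' @param feature descriptor name.
#' @return data frame: `compound_id`, `value`, `shap`,
#'   `partner_feature`, `partner_value`.
#' @export
shap_dependence <- function(explanations, feature) {
  stopifnot(feature %in% colnames(explanations$shap))
  val <- explanations$feature_values[, feature]
  sh <- explanations$shap[, feature]
  others <- setdiff(colnames(explanations$shap), feature)
  if (!is.null(explanations$interactions)) {
    strength <- colMeans(abs(explanations$interactions[, feature, others,
                                                       drop = FALSE]))
    partner <- others[which.max(strength)]
  } else {
    fv <- explanations$feature_values[, others, drop = FALSE]
    ok <- apply(fv, 2, function(v) stats::sd(v[is.finite(v)]) > 0)
    cors <- rep(0, length(others))
    cors[ok] <- abs(suppressWarnings(
      stats::cor(fv[, ok, drop = FALSE], sh,
                 use = "pairwise.complete.obs")))
    cors[!is.finite(cors)] <- 0
    partner <- others[which.max(cors)]
  }
  data.frame(compound_id = rownames(explanations$shap), value = val,
             shap = sh, partner_feature = partner,
             partner_value = explanations$feature_values[, partner],
             stringsAsFactors = FALSE)
}

#' Origin-stratified importance contrast
#'
#' Ranks descriptors by mean absolute SHAP value separately within the
#' synthetic-origin stratum and the natural-or-undefined stratum (the two
#' groups used for origin contrasts), and reports the descriptors unique
#' to each stratum's top-k.
#'
#' @param explanations a `pmt_explanations` over roster compounds.
#' @param roster the `pmt_roster` (provides origin labels).
#' @param k top-k length (default 20). If k exceeds the feature count the
#'   full ranking is returned with a warning.
#' @return list with `synthetic`, `natural_or_undefined` (ranked data
#'   frames), `unique_to_synthetic`, `unique_to_natural_or_undefined`,
#'   `shared`.
#' @export
contrast_importance_by_origin <- function(explanations, roster, k = 20) {
  ids <- rownames(explanations$shap)
  origin <- roster$origin[match(ids, roster$compound_id)]
  if (anyNA(origin)) stop("explanations contain compounds missing from roster")
  strata <- list(synthetic = ids[origin == "synthetic"],
                 natural_or_undefined = ids[origin %in% c("natural",
                                                          "undefined")])
  if (any(lengths(strata) == 0)) {
    stop("empty origin stratum: ",
         paste(names(strata)[lengths(strata) == 0], collapse = ", "))
  }
  p <- ncol(explanations$shap)
  if (k > p) {
    warning("k exceeds the number of features; returning the full ranking")
    k <- p
  }
  rank_of <- function(members) {
    imp <- colMeans(abs(explanations$shap[members, , drop = FALSE]))
    df <- data.frame(feature = names(imp), mean_abs_shap = unname(imp),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$mean_abs_shap, df$feature), ]
    rownames(df) <- NULL
    utils::head(df, k)
  }
  syn <- rank_of(strata$synthetic)
  nat <- rank_of(strata$natural_or_undefined)
  list(synthetic = syn,
       natural_or_undefined = nat,
       unique_to_synthetic = setdiff(syn$feature, nat$feature),
       unique_to_natural_or_undefined = setdiff(nat$feature, syn$feature),
       shared = intersect(syn$feature, nat$feature))
}

#' Cross-validated balanced accuracy
#'
#' Stratified k-fold cross-validation of the classifier on a labelled
#' descriptor set; reports pooled balanced accuracy (mean of sensitivity
#' and specificity over the held-out predictions).
#'
#' @param features descriptor data frame.
#' @param labels binary labels.
#' @param nfolds number of folds (default 5).
#' @param seed seed controlling fold assignment and training.
#' @param nrounds boosting rounds per fold.
#' @param config a [pmt_config()].
#' @return list with `balanced_accuracy`, `accuracy`, `folds`,
#'   `predictions`.
#' @export
evaluate_model_cv <- function(features, labels, nfolds = 5, seed = 42,
                              nrounds = 200, config = pmt_config()) {
  y <- as.integer(as.logical(labels))
  n <- length(y)
  set.seed(seed)
  fold <- integer(n)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  prob <- rep(NA_real_, n)
  for (f in seq_len(nfolds)) {
    tr <- fold != f
    bundle <- train_pmt_model(features[tr, , drop = FALSE], y[tr],
                              seed = seed + f, nrounds = nrounds,
                              config = config)
    X <- align_features(bundle, features[!tr, , drop = FALSE])
    Xs <- impute_and_scale(X, bundle$medians, bundle$center, bundle$scale)
    prob[!tr] <- predict(bundle$booster, xgboost::xgb.DMatrix(Xs))
  }
  pred <- as.integer(prob >= config$prob_cutoff)
  sens <- sum(pred == 1 & y == 1) / sum(y == 1)
  spec <- sum(pred == 0 & y == 0) / sum(y == 0)
  list(balanced_accuracy = (sens + spec) / 2,
       accuracy = mean(pred == y),
       folds = fold,
       predictions = data.frame(compound_id = features$compound_id,
                                label = y, probability = prob,
                                prediction = pred,
                                stringsAsFactors = FALSE))
}

# ---- serialization ----------------------------------------------------------

#' Save / load a model bundle
#'
#' The bundle is serialized as a directory of text files: the boosted model
#' in xgboost's JSON format, a JSON sidecar with the column manifest,
#' imputation medians, scaling parameters, AD threshold, label definition
#' and seed, and the scaled training matrix as CSV. Reloading reproduces
#' predictions exactly.
#'
#' @param bundle a `pmt_model_bundle`.
#' @param dir bundle directory (created if needed).
#' @return `dir` (save) or the restored `pmt_model_bundle` (load).
#' @export
save_model_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(bundle$booster, file.path(dir, "model.json"))
  meta <- bundle[c("columns", "medians", "center", "scale", "train_labels",
                   "ad_threshold", "ad_k", "ad_multiplier", "nn_mean",
                   "nn_sd", "label_definition", "prob_cutoff", "seed",
                   "nrounds")]
  meta$params <- bundle$params[setdiff(names(bundle$params), "objective")]
  meta$objective <- bundle$params$objective
  jsonlite::write_json(meta, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tm <- bundle$train_matrix
  utils::write.csv(
    data.frame(row_id = rownames(tm) %||% seq_len(nrow(tm)),
               format(tm, digits = 17, trim = TRUE, scientific = TRUE),
               check.names = FALSE),
    file.path(dir, "training_matrix.csv"), row.names = FALSE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(dir) {
  booster <- xgboost::xgb.load(file.path(dir, "model.json"))
  meta <- jsonlite::read_json(file.path(dir, "bundle.json"),
                              simplifyVector = TRUE)
  tm_df <- utils::read.csv(file.path(dir, "training_matrix.csv"),
                           check.names = FALSE)
  tm <- as.matrix(tm_df[, -1, drop = FALSE])
  storage.mode(tm) <- "double"
  rownames(tm) <- tm_df[[1]]
  params <- as.list(meta$params)
  params$objective <- meta$objective
  structure(list(
    booster = booster,
    columns = meta$columns,
    medians = stats::setNames(as.numeric(meta$medians), meta$columns),
    center = stats::setNames(as.numeric(meta$center), meta$columns),
    scale = stats::setNames(as.numeric(meta$scale), meta$columns),
    train_matrix = tm,
    train_labels = as.integer(meta$train_labels),
    ad_threshold = meta$ad_threshold,
    ad_k = meta$ad_k,
    ad_multiplier = meta$ad_multiplier,
    nn_mean = meta$nn_mean,
    nn_sd = meta$nn_sd,
    label_definition = meta$label_definition,
    prob_cutoff = meta$prob_cutoff,
    seed = meta$seed,
    nrounds = meta$nrounds,
    params = params
  ), class = "pmt_model_bundle")
}
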