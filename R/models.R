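#' Activity models for probability maps
#'
#' Two classifiers are shipped behind one probability-of-active contract:
#' a *balanced random forest* (per tree, the majority class is
#' down-sampled to the minority size, the standard recipe for the heavy
#' class imbalance of screening data) and a *Bernoulli naive Bayes* with
#' additive Laplace smoothing and empirical class priors. Both are
#' deterministic after fitting: all randomness is fixed at fit time by the
#' seed stored on the model.
#'
#' @name ml_models
NULL

#' Balanced random forest hyperparameters
#'
#' Defaults are the grid-search optimum reported for dopamine D3
#' screening data: 100 shallow trees of depth 2.
#'
#' @param n_trees number of trees
#' @param max_depth maximum tree depth
#' @param min_samples_split minimum samples to attempt a split
#' @param min_samples_leaf minimum samples in a leaf
#' @param seed master seed for all per-tree resampling
#' @export
rf_params <- function(n_trees = 100L, max_depth = 2L,
                      min_samples_split = 2L, min_samples_leaf = 1L,
                      seed = 1L) {
  p <- list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
            min_samples_split = as.integer(min_samples_split),
            min_samples_leaf = as.integer(min_samples_leaf),
            seed = as.integer(seed))
  if (any(vapply(p, function(x) x < 1, logical(1)) &
          names(p) != "seed")) {
    abort("rf_params must all be positive integers", "simmapr_value_error")
  }
  structure(p, class = "rf_params")
}

#' @noRd
check_classes <- function(y) {
  y <- as.logical(y)
  if (anyNA(y)) {
    abort("labels must be logical (active = TRUE)", "simmapr_fit_error")
  }
  if (!any(y) || all(y)) {
    abort("both classes must be present to fit a model", "simmapr_fit_error")
  }
  y
}

#' @noRd
feature_space_of <- function(X, binary) {
  list(n_features = ncol(X), binary = binary)
}

#' Fit a balanced random forest
#'
#' For each tree, a bootstrap of the minority class (its own size, with
#' replacement) is combined with an equal-sized draw with replacement from
#' the majority class, so every per-tree training subset is exactly
#' class-balanced; the sampled row indices are recorded on the model.
#' Trees are CART stumps/shallow trees (rpart, `cp = 0`) and P(active) is
#' the mean of per-tree leaf class-probability estimates.
#'
#' @param X numeric feature matrix (rows = molecules, binary 0/1 features)
#' @param y logical labels, `TRUE` = active
#' @param params an [rf_params()] object
#' @return an `activity_model` of kind `"balanced_rf"`
#' @export
fit_balanced_rf <- function(X, y, params = rf_params()) {
  stopifnot(is.matrix(X))
  y <- check_classes(y)
  if (nrow(X) != length(y)) {
    abort("X rows must align with y", "simmapr_fit_error")
  }
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  }
  # constant columns cannot split; dropping them up front keeps rpart fast
  keep <- which(apply(X, 2, function(col) any(col != col[1])))
  df <- as.data.frame(X[, keep, drop = FALSE])
  df$.y <- factor(ifelse(y, "active", "inactive"),
                  levels = c("inactive", "active"))
  min_is_active <- sum(y) <= sum(!y)
  idx_min <- which(y == min_is_active)
  idx_maj <- which(y != min_is_active)
  n_min <- length(idx_min)
  ctrl <- rpart::rpart.control(
    maxdepth = params$max_depth, minsplit = params$min_samples_split,
    minbucket = params$min_samples_leaf, cp = 0, xval = 0,
    maxcompete = 0, maxsurrogate = 0, usesurrogate = 0
  )
  trees <- vector("list", params$n_trees)
  subsets <- vector("list", params$n_trees)
  with_seed(params$seed, {
    for (t in seq_len(params$n_trees)) {
      rows <- c(sample(idx_min, n_min, replace = TRUE),
                sample(idx_maj, n_min, replace = TRUE))
      subsets[[t]] <- rows
      trees[[t]] <- rpart::rpart(.y ~ ., data = df[rows, , drop = FALSE],
                                 method = "class", control = ctrl)
    }
  })
  structure(list(
    kind = "balanced_rf", params = params, seed = params$seed,
    feature_space = feature_space_of(X, binary = all(X %in% c(0, 1))),
    feature_names = colnames(X), kept_features = keep,
    class_counts = c(active = sum(y), inactive = sum(!y)),
    trees = trees, tree_subsets = subsets, tree_labels = y
  ), class = "activity_model")
}

#' Fit a Bernoulli naive Bayes classifier
#'
#' Closed-form fit: per class c and feature f,
#' `P(f = 1 | c) = (count_cf + alpha) / (n_c + 2 alpha)` with additive
#' Laplace smoothing `alpha`, and class priors equal to the empirical
#' class frequencies.
#'
#' @param X binary feature matrix
#' @param y logical labels, `TRUE` = active
#' @param alpha Laplace smoothing, default 1
#' @return an `activity_model` of kind `"bernoulli_nb"`
#' @export
fit_bernoulli_nb <- function(X, y, alpha = 1.0) {
  stopifnot(is.matrix(X))
  y <- check_classes(y)
  if (nrow(X) != length(y)) {
    abort("X rows must align with y", "simmapr_fit_error")
  }
  if (!all(X %in% c(0, 1))) {
    abort("Bernoulli naive Bayes needs binary features", "simmapr_fit_error")
  }
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  }
  n1 <- sum(y)
  n0 <- sum(!y)
  theta1 <- (colSums(X[y, , drop = FALSE]) + alpha) / (n1 + 2 * alpha)
  theta0 <- (colSums(X[!y, , drop = FALSE]) + alpha) / (n0 + 2 * alpha)
  structure(list(
    kind = "bernoulli_nb", alpha = alpha, seed = NA_integer_,
    feature_space = feature_space_of(X, binary = TRUE),
    feature_names = colnames(X),
    class_counts = c(active = n1, inactive = n0),
    log_prior = c(active = log(n1 / (n1 + n0)),
                  inactive = log(n0 / (n1 + n0))),
    theta1 = theta1, theta0 = theta0
  ), class = "activity_model")
}

#' @export
print.activity_model <- function(x, ...) {
  cat(sprintf(
    "<activity_model: %s, %d features (%s), trained on %d active / %d inactive>\n",
    x$kind, x$feature_space$n_features,
    if (x$feature_space$binary) "binary" else "counts",
    x$class_counts["active"], x$class_counts["inactive"]))
  invisible(x)
}

#' @noRd
densify <- function(model, fp) {
  if (is.numeric(fp)) {
    if (length(fp) != model$feature_space$n_features) {
      abort("feature vector length does not match the model feature space",
            "simmapr_model_feature_error")
    }
    return(fp)
  }
  if (!inherits(fp, "sparse_fp")) {
    abort("need a sparse_fp or a numeric feature vector",
          "simmapr_model_feature_error")
  }
  if (fp$bitspace != model$feature_space$n_features ||
      fp$binary != model$feature_space$binary) {
    abort(sprintf(
      "feature space mismatch: model expects %d features (%s), fingerprint has bitspace %g (%s)",
      model$feature_space$n_features,
      if (model$feature_space$binary) "binary" else "counts",
      fp$bitspace, if (fp$binary) "binary" else "counts"
    ), "simmapr_model_feature_error")
  }
  x <- numeric(model$feature_space$n_features)
  x[fp$bits + 1] <- fp$counts
  x
}

#' Predicted probability of activity
#'
#' @param model an `activity_model`
#' @param fp a `sparse_fp` in the model's feature space, or a dense
#'   numeric feature vector
#' @param log return `ln P(active)` instead of `P(active)`
#' @return a number in \[0, 1\] (or its log)
#' @export
predict_active_probability <- function(model, fp, log = FALSE) {
  stopifnot(inherits(model, "activity_model"))
  x <- densify(model, fp)
  if (model$kind == "bernoulli_nb") {
    ll1 <- model$log_prior["active"] +
      sum(x * base::log(model$theta1) + (1 - x) * base::log1p(-model$theta1))
    ll0 <- model$log_prior["inactive"] +
      sum(x * base::log(model$theta0) + (1 - x) * base::log1p(-model$theta0))
    m <- max(ll1, ll0)
    logp <- ll1 - (m + base::log(exp(ll1 - m) + exp(ll0 - m)))
    return(if (log) unname(logp) else unname(exp(logp)))
  }
  nd <- as.data.frame(t(x[model$kept_features]))
  names(nd) <- model$feature_names[model$kept_features]
  p <- mean(vapply(model$trees, function(tr) {
    unname(stats::predict(tr, newdata = nd, type = "prob")[, "active"])
  }, numeric(1)))
  if (log) base::log(p) else p
}

#' Batched probability prediction over a list of fingerprints.
#' @noRd
predict_prob_batch <- function(model, fps) {
  X <- do.call(rbind, lapply(fps, function(fp) densify(model, fp)))
  if (model$kind == "bernoulli_nb") {
    ll1 <- model$log_prior["active"] +
      X %*% base::log(model$theta1) + (1 - X) %*% base::log1p(-model$theta1)
    ll0 <- model$log_prior["inactive"] +
      X %*% base::log(model$theta0) + (1 - X) %*% base::log1p(-model$theta0)
    m <- pmax(ll1, ll0)
    return(as.numeric(exp(ll1 - (m + base::log(exp(ll1 - m) +
                                                 exp(ll0 - m))))))
  }
  nd <- as.data.frame(X[, model$kept_features, drop = FALSE])
  names(nd) <- model$feature_names[model$kept_features]
  preds <- vapply(model$trees, function(tr) {
    stats::predict(tr, newdata = nd, type = "prob")[, "active"]
  }, numeric(nrow(nd)))
  rowMeans(matrix(preds, nrow = nrow(nd)))
}

#' Save an activity model to disk
#'
#' Models are written as a self-describing versioned RDS payload carrying
#' the model kind, feature-space descriptor, seed and fitted state.
#'
#' @param model an `activity_model`
#' @param path output path
#' @export
save_activity_model <- function(model, path) {
  stopifnot(inherits(model, "activity_model"))
  saveRDS(list(format = "simmapr_activity_model", version = 1L,
               model = model), path)
  invisible(path)
}

#' Load an activity model from disk
#' @param path path written by [save_activity_model()]
#' @return an `activity_model`
#' @export
load_activity_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "simmapr_activity_model")) {
    abort("not a simmapr activity model file", "simmapr_model_feature_error")
  }
  if (!identical(obj$version, 1L)) {
    abort(sprintf("unsupported model format version %s", obj$version),
          "simmapr_model_feature_error")
  }
  obj$model
}

#' Train an activity model straight from a labeled molecule table
#'
#' Convenience wrapper: parses the SMILES, computes the model fingerprint
#' (folded binary circular by default, the standard choice), and fits the
#' requested classifier.
#'
#' @param screen data.frame with columns `smiles` and `active` (logical),
#'   as produced by [make_synthetic_screen()]
#' @param kind `"balanced_rf"` or `"bernoulli_nb"`
#' @param spec fingerprint flavor used as the model feature space
#' @param params [rf_params()] for the forest
#' @param alpha Laplace smoothing for naive Bayes
#' @return an `activity_model`
#' @export
train_activity_model <- function(screen,
                                 kind = c("balanced_rf", "bernoulli_nb"),
                                 spec = fingerprint_spec("morgan"),
                                 params = rf_params(), alpha = 1.0) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(screen), all(c("smiles", "active") %in% names(screen)))
  mols <- parse_molecules(screen$smiles)
  fps <- fingerprints_batch(mols, spec)
  X <- fp_matrix(lapply(fps, function(f) f$fp))
  if (kind == "balanced_rf") {
    fit_balanced_rf(X, screen$active, params)
  } else {
    fit_bernoulli_nb(X, screen$active, alpha)
  }
}
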