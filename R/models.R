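#' Model specification
#'
#' @param kind One of `logistic`, `random_forest`,
#'   `gradient_boosted_trees`, `mlp`, `attention_cnn`.
#' @param grid Data frame of hyperparameter combinations to tune over by
#'   inner cross-validation; defaults per kind via [default_grid()].
#' @param class_weight `"none"` or `"balanced"` (weights inversely
#'   proportional to class frequency).
#' @param seed Integer seed recorded in every fitted artifact.
#' @return An object of class `olf_model_spec`.
#' @export
model_spec <- function(kind = c("gradient_boosted_trees", "logistic",
                                "random_forest", "mlp", "attention_cnn"),
                       grid = NULL, class_weight = c("none", "balanced"),
                       seed = 1L) {
  kind <- match.arg(kind)
  class_weight <- match.arg(class_weight)
  grid <- grid %||% default_grid(kind)
  if (!nrow(grid)) abort("hyperparameter grid must be nonempty")
  structure(
    list(kind = kind, grid = tibble::as_tibble(grid),
         class_weight = class_weight, seed = as.integer(seed)),
    class = "olf_model_spec"
  )
}

#' Default hyperparameter grids
#'
#' @param kind Model kind, see [model_spec()].
#' @return A tibble, one row per hyperparameter combination.
#' @export
default_grid <- function(kind) {
  switch(kind,
    logistic = tibble::tibble(dummy = 1),
    random_forest = tidyr::expand_grid(num_trees = 300, mtry_frac = c(0.1, 0.3)),
    gradient_boosted_trees = tidyr::expand_grid(
      max_depth = c(2, 3, 4), eta = c(0.05, 0.1), nrounds = c(100, 300)
    ),
    mlp = tidyr::expand_grid(size = c(8, 16), decay = c(0.01, 0.1)),
    attention_cnn = tibble::tibble(lr = 1e-3),
    abort(paste0("unknown model kind: ", kind))
  )
}

#' Fit a classifier
#'
#' Fits `spec` to a standardized feature matrix and binary labels. When
#' the grid has several rows and `tune = TRUE`, hyperparameters are
#' selected by inner k-fold cross-validation restricted to the provided
#' training data (grouped by `groups` when given, so no participant spans
#' an inner split), scoring by AUC; the winning combination is refit on
#' all rows. Resampling and weighting never leave this call.
#'
#' @param spec An [model_spec()].
#' @param x Numeric matrix (rows = epochs) or feature tibble (metadata
#'   columns are dropped automatically).
#' @param y Binary labels: `"correct"`/`"incorrect"`, or 0/1 where 1 is
#'   the positive class `correct`.
#' @param groups Optional grouping vector (participant ids) for inner CV.
#' @param inner_k Inner folds (default 5).
#' @param tune Run the inner-CV grid search (default `TRUE` when the grid
#'   has more than one row).
#' @return An object of class `olf_fitted`.
#' @export
fit_model <- function(spec, x, y, groups = NULL, inner_k = 5,
                      tune = nrow(spec$grid) > 1) {
  x <- as_feature_matrix(x)
  y <- as_binary_label(y)
  if (length(unique(y)) < 2) abort("training labels contain a single class")
  if (min(table(y)) < 2) abort("need at least 2 rows per class")
  params <- spec$grid[1, , drop = FALSE]
  if (tune && nrow(spec$grid) > 1) {
    params <- tune_inner(spec, x, y, groups, inner_k)
  }
  set.seed(spec$seed)
  fit <- fit_one(spec, params, x, y)
  structure(
    list(spec = spec, params = params, fit = fit,
         schema = colnames(x), n_train = nrow(x)),
    class = "olf_fitted"
  )
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- x[setdiff(names(x), feature_meta_cols())]
    x <- as.matrix(x)
  }
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  x
}

as_binary_label <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- setdiff(unique(y), c("correct", "incorrect"))
    if (length(bad)) abort(paste0("unknown label: ", bad[1]))
    y <- as.integer(y == "correct")
  }
  if (!all(y %in% c(0, 1))) abort("labels must be binary")
  as.integer(y)
}

# inner grouped k-fold grid search, scored by AUC
tune_inner <- function(spec, x, y, groups, inner_k) {
  groups <- groups %||% seq_along(y)
  ug <- unique(groups)
  if (length(ug) < inner_k) inner_k <- max(2L, length(ug))
  set.seed(derive_seed(spec$seed, "inner"))
  fold_of <- setNames(rep_len(seq_len(inner_k), length(ug)), sample(as.character(ug)))
  scores <- vapply(seq_len(nrow(spec$grid)), function(gi) {
    aucs <- vapply(seq_len(inner_k), function(f) {
      te <- fold_of[as.character(groups)] == f
      if (length(unique(y[!te])) < 2 || !any(te) || length(unique(y[te])) < 2) {
        return(NA_real_)
      }
      set.seed(derive_seed(spec$seed, "inner", gi, f))
      m <- fit_one(spec, spec$grid[gi, , drop = FALSE], x[!te, , drop = FALSE], y[!te])
      p <- predict_one(spec$kind, m, x[te, , drop = FALSE])
      auc_rank(p, y[te])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  spec$grid[which.max(scores), , drop = FALSE]
}

fit_one <- function(spec, params, x, y) {
  w <- if (spec$class_weight == "balanced") {
    tab <- table(y)
    unname(length(y) / (2 * tab[as.character(y)]))
  } else {
    rep(1, length(y))
  }
  switch(spec$kind,
    logistic = {
      df <- data.frame(x, check.names = FALSE)
      df$.y <- y
      suppressWarnings(
        stats::glm(.y ~ ., data = df, family = stats::binomial(), weights = w)
      )
    },
    random_forest = {
      ranger::ranger(
        x = x, y = factor(y, levels = c(0, 1)),
        num.trees = params$num_trees,
        mtry = max(1, floor(params$mtry_frac * ncol(x))),
        probability = TRUE, seed = spec$seed, num.threads = 1,
        case.weights = w
      )
    },
    gradient_boosted_trees = {
      dm <- xgboost::xgb.DMatrix(x, label = y, weight = w)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = params$max_depth,
                      eta = params$eta, nthread = 1, seed = spec$seed),
        data = dm, nrounds = params$nrounds, verbose = 0
      )
    },
    mlp = {
      utils::capture.output(
        m <- nnet::nnet(x, y, size = params$size, decay = params$decay,
                        maxit = 200, entropy = TRUE, weights = w, trace = FALSE)
      )
      m
    },
    abort("attention_cnn models are fitted with train_deep()")
  )
}

predict_one <- function(kind, fit, x) {
  switch(kind,
    logistic = as.numeric(suppressWarnings(
      stats::predict(fit, newdata = data.frame(x, check.names = FALSE),
                     type = "response")
    )),
    random_forest = as.numeric(stats::predict(fit, data = x)$predictions[, "1"]),
    gradient_boosted_trees = as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(x))),
    mlp = as.numeric(stats::predict(fit, x)),
    abort(paste0("cannot score model kind ", kind))
  )
}

#' Predict class probabilities
#'
#' @param model An `olf_fitted` from [fit_model()] (or a fitted
#'   attention-CNN from [train_deep()]).
#' @param x Feature matrix/tibble with the training-time schema, or an
#'   epoch tensor for the CNN.
#' @return Numeric vector of probabilities of the positive class
#'   (`correct`); the implied label is positive iff probability >= 0.5.
#' @export
predict_proba <- function(model, x) {
  UseMethod("predict_proba")
}

#' @export
predict_proba.olf_fitted <- function(model, x) {
  x <- as_feature_matrix(x)
  if (!identical(colnames(x), model$schema)) {
    abort("feature schema does not match the training-time schema")
  }
  p <- predict_one(model$spec$kind, model$fit, x)
  pmin(pmax(p, 0), 1)
}

#' Exact tree-path feature attribution
#'
#' Per-row signed additive attributions (SHAP values) for a fitted
#' gradient-boosted-tree model, computed by the exact tree-path algorithm;
#' for every row the attributions plus the base value reproduce the model
#' margin. Deep models are rejected: no attribution method is applied to
#' the attention-CNN.
#'
#' @param model An `olf_fitted` with kind `gradient_boosted_trees`.
#' @param x Feature matrix/tibble matching the training schema.
#' @return An `olf_attribution`: list with `values` (row x feature signed
#'   matrix), `base` (base value), and `ranking` (tibble sorted by mean
#'   absolute attribution).
#' @export
attribute_features <- function(model, x) {
  if (!inherits(model, "olf_fitted") ||
      model$spec$kind != "gradient_boosted_trees") {
    abort("attribution supports tree-based (gradient-boosted) models only")
  }
  x <- as_feature_matrix(x)
  if (!identical(colnames(x), model$schema)) {
    abort("feature schema does not match the training-time schema")
  }
  contrib <- stats::predict(model$fit, xgboost::xgb.DMatrix(x), predcontrib = TRUE)
  base_col <- intersect(c("BIAS", "(Intercept)"), colnames(contrib))[1]
  base <- contrib[, base_col]
  vals <- contrib[, setdiff(colnames(contrib), base_col), drop = FALSE]
  ranking <- tibble::tibble(
    feature = colnames(vals),
    mean_abs = colMeans(abs(vals))
  )
  ranking <- dplyr::arrange(ranking, dplyr::desc(.data$mean_abs))
  ranking$rank <- seq_len(nrow(ranking))
  structure(
    list(values = vals, base = unname(base[1]), ranking = ranking),
    class = "olf_attribution"
  )
}

#' @export
print.olf_attribution <- function(x, ...) {
  cat("<olf_attribution> ", nrow(x$values), " rows x ", ncol(x$values),
      " features; top: ",
      paste(utils::head(x$ranking$feature, 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.olf_attribution <- function(x, ...) x$ranking

#' Mann-Whitney rank AUC
#'
#' Area under the ROC curve computed as the normalized rank-sum statistic
#' (ties get half credit). Returns `NA` when only one class is present.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (1/"correct" = positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  y <- as_binary_label(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
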