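# The seven semantic features used by every learner (the drug label itself
# is deliberately not a feature, so models must generalize through the
# physical descriptors).
mn_features <- c("skin_type", "mn_type", "mn_length", "mn_surface_area",
                 "drug_loading", "permeation_time", "mw")

mn_numeric_features <- c("mn_length", "mn_surface_area", "drug_loading",
                         "permeation_time", "mw")

# fixed one-hot layout (9 numeric columns)
mn_encoded_cols <- c("skin_type_R", "skin_type_H", "mn_type_hydrogel",
                     "mn_type_plastic", mn_numeric_features)

target_column <- function(target = c("amount", "percentage")) {
  target <- match.arg(target)
  switch(target, amount = "permeation_amount",
         percentage = "permeation_percentage")
}

#' One-hot encode the seven model features
#'
#' Produces the fixed 9-column numeric design: both levels of `skin_type`
#' (R, H) and `mn_type` (hydrogel, plastic) as 0/1 indicators followed by
#' the five numeric features. The layout is deterministic and identical
#' records encode identically.
#'
#' @param records Data frame with the seven feature columns.
#' @return Numeric matrix with columns `skin_type_R`, `skin_type_H`,
#'   `mn_type_hydrogel`, `mn_type_plastic`, `mn_length`,
#'   `mn_surface_area`, `drug_loading`, `permeation_time`, `mw`.
#' @export
encode_features <- function(records) {
  missing <- setdiff(mn_features, names(records))
  if (length(missing)) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  st <- as.character(records$skin_type)
  if (any(!st %in% c("R", "H"))) {
    stop("unknown skin_type level: ",
         paste(unique(st[!st %in% c("R", "H")]), collapse = ", "),
         call. = FALSE)
  }
  mt <- as.character(records$mn_type)
  if (any(!mt %in% c("hydrogel", "plastic"))) {
    stop("unknown mn_type level: ",
         paste(unique(mt[!mt %in% c("hydrogel", "plastic")]), collapse = ", "),
         call. = FALSE)
  }
  num <- as.matrix(records[, mn_numeric_features, drop = FALSE])
  storage.mode(num) <- "double"
  if (nrow(records) && any(!is.finite(num))) {
    stop("non-finite numeric feature value", call. = FALSE)
  }
  X <- cbind(skin_type_R = as.numeric(st == "R"),
             skin_type_H = as.numeric(st == "H"),
             mn_type_hydrogel = as.numeric(mt == "hydrogel"),
             mn_type_plastic = as.numeric(mt == "plastic"),
             num)
  colnames(X) <- mn_encoded_cols
  rownames(X) <- NULL
  X
}

# 7-column data frame with factor categoricals, the form the random forest
# consumes (mtry counts semantic features, matching its published values)
feature_frame <- function(records) {
  df <- as.data.frame(records)[, mn_features]
  df$skin_type <- factor(as.character(df$skin_type), levels = c("R", "H"))
  df$mn_type <- factor(as.character(df$mn_type),
                       levels = c("hydrogel", "plastic"))
  if (anyNA(df$skin_type) || anyNA(df$mn_type)) {
    stop("unknown categorical level in features", call. = FALSE)
  }
  df
}

#' Fit a first-order multiple linear regression
#'
#' Ordinary least squares of the chosen response on the one-hot encoded
#' features, `y = k1 x1 + ... + kn xn + b`. Because both levels of each
#' categorical are encoded alongside an intercept, the design is
#' rank-deficient by construction; the minimum-norm least-squares solution
#' (SVD pseudoinverse) is returned with a warning. On full-rank designs
#' this equals the usual normal-equation solution.
#'
#' @param records Training records with feature and response columns.
#' @param target `"amount"` or `"percentage"`.
#' @return An `mlr_model` with `coefficients` (per encoded feature),
#'   `intercept` and the design `rank`.
#' @export
fit_mlr <- function(records, target = c("amount", "percentage")) {
  target <- match.arg(target)
  ycol <- target_column(target)
  y <- records[[ycol]]
  keep <- !is.na(y)
  y <- y[keep]
  X <- encode_features(records[keep, , drop = FALSE])
  if (length(y) <= 1) stop("need more than one training row", call. = FALSE)
  Xd <- cbind(`(Intercept)` = 1, X)
  sv <- svd(Xd)
  tol <- max(dim(Xd)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  rank <- sum(pos)
  if (rank < ncol(Xd)) {
    warning("rank-deficient design; returning the minimum-norm ",
            "least-squares solution", call. = FALSE)
  }
  beta <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  beta <- drop(beta)
  names(beta) <- colnames(Xd)
  structure(
    list(coefficients = beta[-1], intercept = unname(beta[1]),
         rank = rank, target = target, feature_cols = colnames(X)),
    class = "mlr_model"
  )
}

#' @export
print.mlr_model <- function(x, ...) {
  cat(sprintf("MLR model for permeation %s (design rank %d)\n", x$target,
              x$rank))
  print(round(c(`(Intercept)` = x$intercept, x$coefficients), 6))
  invisible(x)
}

#' Tree-ensemble model specification
#'
#' Holds the family (`"rf"` or `"xgboost"`), the target, and the
#' hyperparameters. With `paper_defaults = TRUE` the published settings
#' are used: for the amount target XGBoost {max_depth 4, eta 0.4, nround
#' 100} and RF {500 trees, mtry 5}; for the percentage target XGBoost
#' {3, 0.2, 45} and RF {500 trees, mtry 6}. XGBoost's gamma and lambda
#' regularizers are left at the library defaults (0 and 1).
#'
#' @param family `"rf"` or `"xgboost"`.
#' @param target `"amount"` or `"percentage"`.
#' @param paper_defaults Use the published hyperparameters (default TRUE).
#' @param hyperparams Named list overriding individual hyperparameters:
#'   `n_trees`/`mtry` for RF, `max_depth`/`eta`/`nround` (and optionally
#'   `gamma`/`lambda`) for XGBoost.
#' @return A `tree_model_spec`.
#' @export
tree_model_spec <- function(family = c("rf", "xgboost"),
                            target = c("amount", "percentage"),
                            paper_defaults = TRUE, hyperparams = list()) {
  family <- match.arg(family)
  target <- match.arg(target)
  defaults <- if (family == "xgboost") {
    if (target == "amount") list(max_depth = 4, eta = 0.4, nround = 100,
                                 gamma = 0, lambda = 1)
    else list(max_depth = 3, eta = 0.2, nround = 45, gamma = 0, lambda = 1)
  } else {
    if (target == "amount") list(n_trees = 500, mtry = 5)
    else list(n_trees = 500, mtry = 6)
  }
  if (!paper_defaults && !length(hyperparams)) {
    stop("either use paper_defaults or supply hyperparams", call. = FALSE)
  }
  hp <- utils::modifyList(defaults, hyperparams)
  bad <- vapply(hp, function(v) !is.numeric(v) || length(v) != 1 || v < 0,
                logical(1))
  if (any(bad)) {
    stop("invalid hyperparameter(s): ", paste(names(hp)[bad], collapse = ", "),
         call. = FALSE)
  }
  structure(list(family = family, target = target, hyperparams = hp),
            class = "tree_model_spec")
}

#' Fit a tree-ensemble model (random forest or XGBoost)
#'
#' Random forests are fitted on the 7-column feature frame (categoricals
#' as factors, so `mtry` counts semantic features); XGBoost on the 9-column
#' one-hot matrix. Training is seeded and reproducible
#' (single-threaded boosting).
#'
#' @param records Training records; rows with a missing response are
#'   dropped.
#' @param spec A [tree_model_spec()].
#' @param seed Integer seed for the ensemble's randomness.
#' @return An `mn_tree_model` holding the fitted ensemble, its spec and the
#'   training feature schema.
#' @export
fit_tree_model <- function(records, spec, seed = 1) {
  stopifnot(inherits(spec, "tree_model_spec"))
  ycol <- target_column(spec$target)
  keep <- !is.na(records[[ycol]])
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0) stop("empty training set", call. = FALSE)
  y <- records[[ycol]]
  hp <- spec$hyperparams
  if (spec$family == "rf") {
    df <- feature_frame(records)
    fit <- local_seed(seed, randomForest::randomForest(
      x = df, y = y, ntree = hp$n_trees, mtry = min(hp$mtry, ncol(df)),
      importance = TRUE))
  } else {
    X <- encode_features(records)
    fit <- xgboost::xgb.train(
      params = xgboost::xgb.params(
        max_depth = hp$max_depth, eta = hp$eta, gamma = hp$gamma,
        lambda = hp$lambda, objective = "reg:squarederror",
        nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = hp$nround, verbose = 0)
  }
  structure(
    list(spec = spec, fit = fit, seed = seed,
         feature_cols = mn_encoded_cols, n_train = nrow(records)),
    class = "mn_tree_model"
  )
}

#' @export
print.mn_tree_model <- function(x, ...) {
  hp <- x$spec$hyperparams
  cat(sprintf("%s model for permeation %s (%d training rows, seed %d)\n",
              x$spec$family, x$spec$target, x$n_train, x$seed))
  cat("  hyperparameters:",
      paste(names(hp), unlist(hp), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.mlr_model <- function(object, newdata, ...) {
  if (nrow(newdata) == 0) return(numeric(0))
  X <- encode_features(newdata)
  if (!identical(colnames(X), object$feature_cols)) {
    stop("feature schema mismatch", call. = FALSE)
  }
  drop(X %*% object$coefficients) + object$intercept
}

#' @export
predict.mn_tree_model <- function(object, newdata, ...) {
  if (nrow(newdata) == 0) return(numeric(0))
  if (object$spec$family == "rf") {
    unname(stats::predict(object$fit, feature_frame(newdata)))
  } else {
    X <- encode_features(newdata)
    stats::predict(object$fit, X)
  }
}

#' Per-feature importance shares of a fitted tree model
#'
#' Random forests report impurity importance (total decrease in node SSE;
#' set `type = "permutation"` for the permutation alternative); XGBoost
#' reports gain, with the one-hot indicator pairs summed back to their
#' semantic feature. Shares are non-negative and normalized to sum to 100.
#'
#' @param model An `mn_tree_model`.
#' @param type `"impurity"` (RF default) or `"permutation"` (RF only).
#' @return Named numeric vector over the seven features, in percent,
#'   sorted decreasingly.
#' @export
feature_importance <- function(model, type = c("impurity", "permutation")) {
  type <- match.arg(type)
  if (!inherits(model, "mn_tree_model")) {
    stop("feature importance is only defined for tree models; ",
         "report MLR coefficients instead", call. = FALSE)
  }
  if (model$spec$family == "rf") {
    imp <- randomForest::importance(
      model$fit, type = if (type == "permutation") 1 else 2)
    v <- stats::setNames(pmax(imp[, 1], 0), rownames(imp))
  } else {
    it <- xgboost::xgb.importance(model = model$fit)
    v0 <- stats::setNames(it$Gain, it$Feature)
    v <- stats::setNames(numeric(length(mn_features)), mn_features)
    for (nm in names(v0)) {
      sem <- if (nm %in% c("skin_type_R", "skin_type_H")) "skin_type"
      else if (nm %in% c("mn_type_hydrogel", "mn_type_plastic")) "mn_type"
      else nm
      v[sem] <- v[sem] + v0[[nm]]
    }
  }
  full <- stats::setNames(numeric(length(mn_features)), mn_features)
  full[names(v)[names(v) %in% mn_features]] <-
    v[names(v) %in% mn_features]
  if (sum(full) == 0) return(sort(full, decreasing = TRUE))
  sort(100 * full / sum(full), decreasing = TRUE)
}
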