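test_that("feature encoding is a fixed deterministic one-hot layout", {
  rec <- make_records(1, skin_type = "R", mn_type = "hydrogel",
                      mn_length = 700, mn_surface_area = 26.76,
                      drug_loading = 50, permeation_time = 0.0833, mw = 194)
  X <- suppressWarnings(encode_features(rec))
  expect_equal(dim(X), c(1L, 9L))
  expect_equal(colnames(X), mnperm:::mn_encoded_cols)
  expect_equal(as.vector(X),
               c(1, 0, 1, 0, 700, 26.76, 50, 0.0833, 194))
  expect_identical(X, suppressWarnings(encode_features(rec)))

  expect_error(encode_features(transform(rec, skin_type = "X")),
               "skin_type")
  expect_error(encode_features(rec[, -1 * which(names(rec) == "mw")]),
               "mw")
})

test_that("MLR recovers a planted linear law on noiseless data", {
  rec <- make_records(20)
  rec$permeation_amount <- 2 * rec$permeation_time + 5
  expect_warning(fit_mlr(rec, "amount"), "rank-deficient")
  fit <- suppressWarnings(fit_mlr(rec, "amount"))
  expect_equal(unname(fit$coefficients["permeation_time"]), 2,
               tolerance = 1e-8)
  # the planted intercept is spread over the constant columns of this
  # rank-deficient design; it is identifiable as the prediction at time 0
  at0 <- rec[1, ]; at0$permeation_time <- 0
  expect_equal(predict(fit, at0), 5, tolerance = 1e-8)
  expect_equal(predict(fit, rec), rec$permeation_amount, tolerance = 1e-8)
})

test_that("MLR on a constant response returns zero slopes", {
  rec <- make_records(15)
  rec$permeation_amount <- rep(3.5, 15)
  fit <- suppressWarnings(fit_mlr(rec, "amount"))
  expect_equal(unname(fit$coefficients["permeation_time"]), 0,
               tolerance = 1e-8)
  expect_equal(predict(fit, rec), rep(3.5, 15), tolerance = 1e-8)
})

test_that("MLR equals the normal-equation oracle on a full-rank design", {
  # vary all five numeric features so that, with single-level categoricals
  # collapsed, the numeric block is full rank; compare against solve(X'X)X'y
  set.seed(3)
  n <- 12
  rec <- make_records(n,
                      mn_length = runif(n, 700, 1250),
                      mn_surface_area = runif(n, 26, 37),
                      drug_loading = runif(n, 50, 70940),
                      permeation_time = runif(n, 0.1, 48),
                      mw = runif(n, 64, 66430))
  rec$permeation_amount <- rnorm(n, 100, 30)
  fit <- suppressWarnings(fit_mlr(rec, "amount"))
  Xn <- cbind(1, rec$mn_length, rec$mn_surface_area, rec$drug_loading,
              rec$permeation_time, rec$mw)
  beta <- solve(crossprod(Xn), crossprod(Xn, rec$permeation_amount))
  expect_equal(unname(fit$coefficients[mnperm:::mn_numeric_features]),
               unname(beta[-1]), tolerance = 1e-6)
  expect_equal(predict(fit, rec), drop(Xn %*% beta), tolerance = 1e-6)
})

test_that("tree model specs carry the published hyperparameters", {
  sa <- tree_model_spec("xgboost", "amount")
  expect_equal(sa$hyperparams[c("max_depth", "eta", "nround")],
               list(max_depth = 4, eta = 0.4, nround = 100))
  sp <- tree_model_spec("xgboost", "percentage")
  expect_equal(sp$hyperparams[c("max_depth", "eta", "nround")],
               list(max_depth = 3, eta = 0.2, nround = 45))
  ra <- tree_model_spec("rf", "amount")
  expect_equal(ra$hyperparams, list(n_trees = 500, mtry = 5))
  rp <- tree_model_spec("rf", "percentage")
  expect_equal(rp$hyperparams, list(n_trees = 500, mtry = 6))

  ov <- tree_model_spec("rf", "amount", hyperparams = list(n_trees = 50))
  expect_equal(ov$hyperparams$n_trees, 50)
  expect_error(tree_model_spec("rf", "amount",
                               hyperparams = list(mtry = -1)), "invalid")
})

test_that("tree models fit curved noiseless surfaces well", {
  synth <- generate_dataset(
    generator_config(seed = 9, noise_sd = 0,
                     drugs = default_drug_table()[c(1, 4), ]))
  d <- synth$records
  s <- split_train_test(d, seed = 2)
  for (fam in c("rf", "xgboost")) {
    m <- fit_tree_model(s$train, tree_model_spec(fam, "amount"), seed = 2)
    expect_gt(r_squared(s$train$permeation_amount, predict(m, s$train)),
              0.9)
  }
})

test_that("predictions are finite, schema-checked and empty-safe", {
  d <- default_synth()$records
  m <- fit_tree_model(d, tree_model_spec("xgboost", "amount"), seed = 1)
  p <- predict(m, d[1:5, ])
  expect_length(p, 5)
  expect_true(all(is.finite(p)))
  expect_length(predict(m, d[0, ]), 0)
  expect_error(predict(m, transform(d[1:2, ], mn_type = "steel")),
               "mn_type")

  mlr <- suppressWarnings(fit_mlr(d, "amount"))
  expect_length(predict(mlr, d[0, ]), 0)
})

test_that("seeded fits are reproducible and row-order invariant", {
  d <- default_synth()$records
  for (fam in c("rf", "xgboost")) {
    m1 <- fit_tree_model(d, tree_model_spec(fam, "percentage"), seed = 5)
    m2 <- fit_tree_model(d, tree_model_spec(fam, "percentage"), seed = 5)
    expect_identical(predict(m1, d), predict(m2, d))
  }
  # importance ranking unchanged under row permutation of the training data
  perm <- local({set.seed(1); sample(nrow(d))})
  m1 <- fit_tree_model(d, tree_model_spec("xgboost", "amount"), seed = 5)
  m2 <- fit_tree_model(d[perm, ], tree_model_spec("xgboost", "amount"),
                       seed = 5)
  expect_identical(names(feature_importance(m1))[1:2],
                   names(feature_importance(m2))[1:2])
})

test_that("feature importances normalize to 100 and track the true driver", {
  # response driven purely by loading
  set.seed(4)
  n <- 300
  rec <- make_records(n,
                      drug_loading = exp(runif(n, log(50), log(70940))),
                      permeation_time = rep(c(1, 2, 4, 8), length.out = n))
  rec$permeation_amount <- 0.4 * rec$drug_loading
  rec$permeation_percentage <- 40
  for (fam in c("rf", "xgboost")) {
    m <- fit_tree_model(rec, tree_model_spec(fam, "amount"), seed = 1)
    imp <- feature_importance(m)
    expect_equal(sum(imp), 100, tolerance = 1e-9)
    expect_true(all(imp >= 0))
    expect_equal(names(imp)[1], "drug_loading")
  }
  mlr <- suppressWarnings(fit_mlr(rec, "amount"))
  expect_error(feature_importance(mlr), "tree")
})

test_that("a pure-noise feature ranks below the active drivers", {
  d <- default_synth()$records
  d2 <- d
  set.seed(8)
  # hijack an otherwise-constant column with noise: mn_length becomes noise
  d2$mn_length <- runif(nrow(d2), 700, 1250)
  m <- fit_tree_model(d2, tree_model_spec("rf", "amount"), seed = 3)
  imp <- feature_importance(m)
  expect_lt(imp["mn_length"], imp["drug_loading"])
  expect_lt(imp["mn_length"], imp["permeation_time"])
})
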