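# small deterministic dataset used by several blocks
toy_data <- function() {
  X <- matrix(c(
    1, 0, 1, 0,
    1, 1, 0, 0,
    0, 1, 1, 1,
    0, 0, 1, 0,
    1, 0, 0, 1,
    0, 1, 0, 0
  ), nrow = 6, byrow = TRUE)
  list(X = X, y = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
}

# closed-form smoothed Bernoulli likelihoods and priors
nb_oracle <- function(X, y, alpha = 1) {
  n1 <- sum(y)
  n0 <- sum(!y)
  list(
    theta1 = (colSums(X[y, , drop = FALSE]) + alpha) / (n1 + 2 * alpha),
    theta0 = (colSums(X[!y, , drop = FALSE]) + alpha) / (n0 + 2 * alpha),
    prior1 = n1 / (n1 + n0)
  )
}

nb_oracle_predict <- function(or, x) {
  l1 <- log(or$prior1) + sum(x * log(or$theta1) + (1 - x) * log(1 - or$theta1))
  l0 <- log(1 - or$prior1) +
    sum(x * log(or$theta0) + (1 - x) * log(1 - or$theta0))
  1 / (1 + exp(l0 - l1))
}

test_that("naive Bayes matches the hand Bayes worked example", {
  # one active with the feature, one inactive without, alpha = 1:
  # P(f=1|active) = 2/3, P(f=1|inactive) = 1/3, priors 1/2
  X <- matrix(c(1, 0), ncol = 1)
  m <- fit_bernoulli_nb(X, c(TRUE, FALSE), alpha = 1)
  expect_equal(unname(m$theta1), 2 / 3, tolerance = 1e-15)
  expect_equal(unname(m$theta0), 1 / 3, tolerance = 1e-15)
  expect_equal(predict_active_probability(m, c(1)), 2 / 3, tolerance = 1e-12)
  expect_equal(predict_active_probability(m, c(0)), 1 / 3, tolerance = 1e-12)
})

test_that("naive Bayes agrees with the closed-form oracle and e1071", {
  d <- toy_data()
  for (alpha in c(0.5, 1, 2)) {
    m <- fit_bernoulli_nb(d$X, d$y, alpha = alpha)
    or <- nb_oracle(d$X, d$y, alpha)
    expect_equal(unname(m$theta1), unname(or$theta1), tolerance = 1e-12)
    expect_equal(unname(m$theta0), unname(or$theta0), tolerance = 1e-12)
    for (r in seq_len(nrow(d$X))) {
      expect_equal(predict_active_probability(m, d$X[r, ]),
                   nb_oracle_predict(or, d$X[r, ]), tolerance = 1e-12)
    }
  }

  # independent implementation cross-check (categorical naive Bayes with
  # Laplace smoothing)
  df <- as.data.frame(lapply(as.data.frame(d$X), function(col) {
    factor(col, levels = c(0, 1))
  }))
  fit <- e1071::naiveBayes(df, factor(ifelse(d$y, "active", "inactive")),
                           laplace = 1)
  p_e1071 <- stats::predict(fit, df, type = "raw")[, "active"]
  m1 <- fit_bernoulli_nb(d$X, d$y, alpha = 1)
  p_ours <- vapply(seq_len(nrow(d$X)), function(r) {
    predict_active_probability(m1, d$X[r, ])
  }, numeric(1))
  expect_equal(p_ours, unname(p_e1071), tolerance = 1e-9)
})

test_that("huge smoothing washes likelihoods out to the class prior", {
  d <- toy_data()
  m <- fit_bernoulli_nb(d$X, d$y, alpha = 1e9)
  for (r in seq_len(nrow(d$X))) {
    expect_equal(predict_active_probability(m, d$X[r, ]), 2 / 6,
                 tolerance = 1e-6)
  }
})

test_that("log probabilities are consistent with linear ones", {
  d <- toy_data()
  m <- fit_bernoulli_nb(d$X, d$y)
  for (r in seq_len(nrow(d$X))) {
    expect_equal(predict_active_probability(m, d$X[r, ], log = TRUE),
                 log(predict_active_probability(m, d$X[r, ])),
                 tolerance = 1e-12)
    expect_lte(predict_active_probability(m, d$X[r, ], log = TRUE), 0)
  }
})

test_that("balanced forest trains on exactly class-balanced subsets", {
  d <- toy_data()
  m <- fit_balanced_rf(d$X, d$y, rf_params(n_trees = 25, seed = 5))
  for (rows in m$tree_subsets) {
    labs <- m$tree_labels[rows]
    expect_identical(sum(labs), sum(!labs))
  }
  expect_length(m$tree_subsets, 25)
})

test_that("forest predictions are deterministic given the seed", {
  d <- toy_data()
  m1 <- fit_balanced_rf(d$X, d$y, rf_params(n_trees = 15, seed = 42))
  m2 <- fit_balanced_rf(d$X, d$y, rf_params(n_trees = 15, seed = 42))
  p1 <- vapply(seq_len(nrow(d$X)), function(r) {
    predict_active_probability(m1, d$X[r, ])
  }, numeric(1))
  p2 <- vapply(seq_len(nrow(d$X)), function(r) {
    predict_active_probability(m2, d$X[r, ])
  }, numeric(1))
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
})

test_that("both fits refuse single-class data", {
  X <- matrix(c(1, 0, 1, 1), 2)
  expect_error(fit_balanced_rf(X, c(TRUE, TRUE)), class = "simmapr_fit_error")
  expect_error(fit_bernoulli_nb(X, c(FALSE, FALSE)),
               class = "simmapr_fit_error")
})

test_that("a separable synthetic screen is learned by the forest", {
  screen <- make_synthetic_screen(6, 36, seed = 13)
  model <- train_activity_model(screen, "balanced_rf",
                                params = rf_params(n_trees = 50, seed = 13))
  mols <- parse_molecules(screen$smiles)
  fps <- fingerprints_batch(mols, fingerprint_spec("morgan"))
  p <- vapply(which(screen$active), function(k) {
    predict_active_probability(model, fps[[k]]$fp)
  }, numeric(1))
  expect_true(all(p > 0.5))
})

test_that("models survive a save/load round trip exactly", {
  screen <- make_synthetic_screen(5, 20, seed = 3)
  mols <- parse_molecules(screen$smiles)
  fps <- fingerprints_batch(mols, fingerprint_spec("morgan"))
  X <- fp_matrix(lapply(fps, function(f) f$fp))
  for (kind in c("balanced_rf", "bernoulli_nb")) {
    m <- if (kind == "balanced_rf") {
      fit_balanced_rf(X, screen$active, rf_params(n_trees = 10, seed = 2))
    } else {
      fit_bernoulli_nb(X, screen$active)
    }
    path <- tempfile(fileext = ".rds")
    save_activity_model(m, path)
    m2 <- load_activity_model(path)
    p1 <- vapply(fps, function(f) predict_active_probability(m, f$fp),
                 numeric(1))
    p2 <- vapply(fps, function(f) predict_active_probability(m2, f$fp),
                 numeric(1))
    expect_identical(p1, p2)
    unlink(path)
  }
  bogus <- tempfile(fileext = ".rds")
  saveRDS(list(format = "something_else"), bogus)
  expect_error(load_activity_model(bogus),
               class = "simmapr_model_feature_error")
  unlink(bogus)
})

test_that("feature-space mismatches are rejected with both descriptors", {
  d <- toy_data()
  m <- fit_bernoulli_nb(d$X, d$y)
  wrong <- sparse_fp(c(0, 3), c(1, 1), binary = TRUE, bitspace = 1024)
  err <- tryCatch(predict_active_probability(m, wrong), error = identity)
  expect_s3_class(err, "simmapr_model_feature_error")
  expect_match(conditionMessage(err), "4")
  expect_match(conditionMessage(err), "1024")
})
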