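test_that("regression metrics match their definitions", {
  # residuals [1,-1,1,-1]: mae = rmse = 1
  y <- c(1, -1, 1, -1) + 5
  m <- regression_metrics(y, rep(5, 4))
  expect_equal(m$mae, 1)
  expect_equal(m$rmse, 1)
  # residuals [0, 2]
  m <- regression_metrics(c(0, 2), c(0, 0))
  expect_equal(m$mae, 1)
  expect_equal(m$rmse, sqrt(2))
  expect_error(regression_metrics(c(3, 3, 3), c(1, 2, 3)), "zero response")
})

test_that("rmse >= mae over random residual vectors", {
  set.seed(7)
  for (k in 1:50) {
    y <- rnorm(10)
    f <- rnorm(10)
    m <- regression_metrics(y, f)
    expect_gte(m$rmse, m$mae)
  }
})

test_that("fit_ols recovers exact lines and matches the normal-equation oracle", {
  x <- matrix(seq(0, 1, length.out = 10), dimnames = list(NULL, "x"))
  fit <- fit_ols(x, 2 * x[, 1] + 1)
  expect_equal(unname(fit$coefficients), 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r2, 1)
  expect_equal(fit$mae, 0, tolerance = 1e-12)
  expect_equal(fit$rmse, 0, tolerance = 1e-12)

  # y orthogonal to x -> slope 0, r2 = 0
  x2 <- matrix(c(-1, 0, 1, -1, 0, 1), ncol = 1, dimnames = list(NULL, "x"))
  y2 <- c(1, -2, 1, 1, -2, 1)
  fit2 <- fit_ols(x2, y2)
  expect_equal(unname(fit2$coefficients), 0, tolerance = 1e-12)
  expect_equal(fit2$r2, 0, tolerance = 1e-12)

  # random design vs direct pseudo-inverse solve
  set.seed(31)
  X <- matrix(runif(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(20)
  fit3 <- fit_ols(X, y)
  A <- cbind(1, X)
  beta <- as.numeric(solve(t(A) %*% A) %*% t(A) %*% y)
  expect_equal(fit3$intercept, beta[1], tolerance = 1e-10)
  expect_equal(unname(fit3$coefficients), beta[2:3], tolerance = 1e-10)
})

test_that("collinear designs are flagged, not silently fitted", {
  x <- runif(12)
  X <- cbind(a = x, b = 2 * x)
  fit <- fit_ols(X, rnorm(12))
  expect_true(fit$degenerate)
  expect_error(predict(fit, make_table(X)), "degenerate")
})

test_that("enumerate_models fits every singleton and unordered pair once", {
  sim <- gen_descriptor_table(12, 5, planted_law("D001", 1, noise_sd = 0.1),
                              seed = 2)
  sc <- scale_minmax(sim$table)
  rep <- enumerate_models(sc, sim$response)
  expect_equal(rep$n_models, 5 + choose(5, 2))
  expect_equal(nrow(rep$ranked), rep$n_models)
  # exhaustiveness: the multiset of term sets is singletons + pairs
  term_sets <- lapply(strsplit(rep$ranked$terms, " \\+ "), sort)
  expect_false(any(duplicated(term_sets)))
  want <- c(lapply(colnames(sc$values), identity),
            combn(colnames(sc$values), 2, simplify = FALSE))
  want <- lapply(want, sort)
  expect_setequal(sapply(term_sets, paste, collapse = "|"),
                  sapply(want, paste, collapse = "|"))
  expect_error(enumerate_models(sc, sim$response, max_terms = 3),
               "not supported")
})

test_that("a pair model never scores below its sub-singletons", {
  sim <- gen_descriptor_table(14, 6, planted_law("D002", 0.7, noise_sd = 0.2),
                              seed = 8)
  sc <- scale_minmax(sim$table)
  rep <- enumerate_models(sc, sim$response)
  r2_of <- function(t) rep$ranked$r2[match(t, rep$ranked$terms)]
  for (p in combn(colnames(sc$values), 2, simplify = FALSE)) {
    pair <- paste(p, collapse = " + ")
    expect_gte(r2_of(pair) + 1e-10, max(r2_of(p[1]), r2_of(p[2])))
  }
})

test_that("ranking agrees exactly with the brute-force oracle (d<=6, n<=12)", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(8:12, 1)
    d <- sample(3:6, 1)
    values <- matrix(runif(n * d), n,
                     dimnames = list(sprintf("C%02d", 1:n),
                                     sprintf("D%02d", 1:d)))
    y <- rnorm(n)
    rep <- enumerate_models(make_table(values), y)
    oracle <- brute_force_ranking(values, y)
    expect_equal(rep$ranked$terms, oracle$terms, info = paste("seed", seed))
    expect_equal(rep$ranked$r2, oracle$r2, tolerance = 1e-9)
    expect_equal(rep$ranked$mae, oracle$mae, tolerance = 1e-9)
    expect_equal(rep$ranked$rmse, oracle$rmse, tolerance = 1e-9)
  }
})

test_that("fit is invariant to row and column permutations", {
  set.seed(12)
  values <- matrix(runif(60), 12, 5,
                   dimnames = list(sprintf("C%02d", 1:12),
                                   sprintf("D%02d", 1:5)))
  y <- setNames(rnorm(12), rownames(values))
  rep1 <- enumerate_models(make_table(values), y)
  rows <- sample(12); cols <- sample(5)
  rep2 <- enumerate_models(make_table(values[rows, cols]), y[rows])
  expect_equal(rep1$ranked$terms, rep2$ranked$terms)
  expect_equal(rep1$ranked$r2, rep2$ranked$r2, tolerance = 1e-12)
  expect_equal(select_best(rep1)$coefficients,
               select_best(rep2)$coefficients[names(select_best(rep1)$coefficients)],
               tolerance = 1e-10)
})

test_that("select_best follows the tie cascade", {
  # exercised through enumerate_models on crafted data: a duplicated
  # descriptor gives exactly tied metrics, parsimony keeps the single
  x <- c(0, 0.25, 0.5, 0.75, 1, 0.1, 0.9, 0.3)
  values <- cbind(a = x, noise = c(0.3, 0.9, 0.1, 0.7, 0.2, 0.8, 0.4, 0.6))
  rownames(values) <- sprintf("C%d", 1:8)
  y <- 2 * x + 1
  rep <- enumerate_models(descriptor_table(values), y)
  best <- select_best(rep)
  expect_equal(best$terms, "a")   # 1-term beats tied 2-term
  expect_equal(best$r2, 1)
})

test_that("predictions apply training scaling and flag extrapolation", {
  sim <- gen_descriptor_table(16, 4, planted_law(c("D001", "D002"),
                                                 c(1.5, 0.4), 2, 0),
                              seed = 21)
  sc <- scale_minmax(sim$table)
  rep <- enumerate_models(sc, sim$response)
  best <- select_best(rep)
  # training compounds: predictions equal fitted values
  pred <- predict(best, sc)
  fitted_direct <- best$intercept +
    as.numeric(sc$values[, best$terms] %*% best$coefficients)
  expect_equal(pred$prediction, fitted_direct, tolerance = 1e-10)
  expect_false(any(pred$extrapolated))
  # all-zero scaled descriptors -> intercept
  raw_mins <- apply(sim$table$values, 2, min)
  newv <- matrix(raw_mins, 1, dimnames = list("new", names(raw_mins)))
  p0 <- predict(best, descriptor_table(newv), ids = "new")
  expect_equal(p0$prediction, best$intercept, tolerance = 1e-10)
  # out-of-range input warns and flags
  newv2 <- newv
  newv2[1, best$terms[1]] <- max(sim$table$values[, best$terms[1]]) * 2 + 1
  expect_warning(p1 <- predict(best, descriptor_table(newv2), ids = "new"),
                 "outside the training")
  expect_true(p1$extrapolated)
  expect_error(predict(best, sc, ids = "nope"), "absent")
})

test_that("planted-law holdout predictions land within 3 sigma", {
  sigma <- 0.05
  law <- planted_law(c("D001", "D002"), c(1.2, 0.3), 0.5, sigma)
  hits <- 0; total <- 0
  for (s in 1:10) {
    sim <- gen_descriptor_table(24, 6, law, seed = 300 + s)
    train_ids <- rownames(sim$table$values)[1:16]
    hold_ids <- rownames(sim$table$values)[17:24]
    train_tab <- descriptor_table(sim$table$values[train_ids, ])
    sc <- scale_minmax(train_tab)
    fit <- fit_terms(sc, sim$response[train_ids], c("D001", "D002"))
    pred <- suppressWarnings(
      predict(fit, descriptor_table(sim$table$values[hold_ids, ])))
    truth <- sim$truth$response_noiseless[hold_ids]
    hits <- hits + sum(abs(pred$prediction - truth) < 3 * sigma)
    total <- total + length(hold_ids)
  }
  expect_gte(hits / total, 0.95)
})

test_that("correlate matches the covariance-formula oracle", {
  a <- 1:10
  expect_equal(correlate(a, 2 * a + 5), list(pearson_r = 1, r_squared = 1))
  expect_equal(correlate(a, -a)$pearson_r, -1)
  set.seed(4)
  x <- rnorm(20); y <- rnorm(20)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlate(x, y)$pearson_r, r_oracle, tolerance = 1e-12)
  expect_error(correlate(rep(1, 5), 1:5), "constant")
})

test_that("model JSON serialization round-trips", {
  sim <- gen_descriptor_table(12, 4, planted_law("D001", 2, 1, 0.05),
                              seed = 6)
  sc <- scale_minmax(sim$table)
  best <- select_best(enumerate_models(sc, sim$response))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_model_json(best, tmp)
  back <- read_model_json(tmp)
  expect_equal(back$terms, best$terms)
  expect_equal(back$coefficients, best$coefficients)
  expect_equal(back$intercept, best$intercept)
  p1 <- predict(best, sim$table)
  p2 <- predict(back, sim$table)
  expect_equal(p1$prediction, p2$prediction)
})

test_that("unscaling coefficients recovers the planted raw-scale law", {
  law <- planted_law(c("D001", "D002"), c(0.8, 0.3), 1.7, 0)
  sim <- gen_descriptor_table(20, 6, law, seed = 13)
  sc <- scale_minmax(sim$table)
  best <- select_best(enumerate_models(sc, sim$response))
  expect_setequal(best$terms, c("D001", "D002"))
  raw <- unscale_coefficients(best)
  expect_equal(raw$coefficients[c("D001", "D002")],
               c(D001 = 0.8, D002 = 0.3), tolerance = 1e-8)
  expect_equal(raw$intercept, 1.7, tolerance = 1e-8)
})
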