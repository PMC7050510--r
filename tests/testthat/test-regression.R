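rand_xy <- function(n, p, seed, beta = NULL, noise = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- sprintf("d%02d", seq_len(p))
  if (is.null(beta)) beta <- rnorm(p) * rbinom(p, 1, 0.4)
  y <- drop(X %*% beta) + rnorm(n, 0, noise)
  list(X = X, y = y, beta = beta)
}

test_that("fitPCR at full rank equals the normal-equations ridge oracle", {
  for (seed in 1:5) {
    d <- rand_xy(50, 10, seed)
    lam <- c(0, 1e-6, 0.5, 10)[seed %% 4 + 1]
    fit <- fitPCR(d$X, d$y, lambda = lam)
    ## independent oracle: eigen-decomposition of the covariance and an
    ## explicit linear solve in the PC basis
    Xc <- scale(d$X, scale = FALSE)
    V <- eigen(stats::cov(Xc))$vectors
    P <- Xc %*% V
    cj <- solve(crossprod(P) + lam * diag(ncol(P)),
                crossprod(P, d$y - mean(d$y)))
    oracle <- drop(P %*% cj) + mean(d$y)
    expect_lt(max(abs(oracle - predict(fit, d$X))), 1e-8)
  }
})

test_that("lambda = 0 full-rank PCR reproduces least squares", {
  d <- rand_xy(40, 8, 3)
  fit <- fitPCR(d$X, d$y, lambda = 0)
  ols <- stats::lm.fit(cbind(1, d$X), d$y)
  expect_lt(max(abs(ols$fitted.values - predict(fit, d$X))), 1e-8)
})

test_that("ridge shrinkage is monotone and constant targets collapse", {
  d <- rand_xy(40, 8, 4)
  norms <- vapply(c(0, 0.1, 1, 10, 100), function(l)
    sum(fitPCR(d$X, d$y, lambda = l)@coef^2), 0)
  expect_true(all(diff(norms) <= 1e-12))

  fitc <- fitPCR(d$X, rep(2.5, 40))
  expect_true(all(abs(fitc@coef) < 1e-10))
  expect_equal(fitc@intercept, 2.5)
  expect_lt(sqrt(mean((predict(fitc, d$X) - 2.5)^2)), 1e-9)
})

test_that("prediction is consistent, affine and schema-checked", {
  d <- rand_xy(30, 6, 5)
  fit <- fitPCR(d$X, d$y, lambda = 0)
  expect_equal(predict(fit, d$X), drop(predict(fit, d$X))) # idempotent call
  ## all-zero centered descriptors -> intercept
  xbar <- matrix(fit@center, 1, dimnames = list(NULL, fit@schema))
  expect_equal(predict(fit, xbar), fit@intercept, tolerance = 1e-10)
  ## affine in deviations
  x1 <- d$X[1, , drop = FALSE]; x2 <- d$X[2, , drop = FALSE]
  mid <- (x1 + x2) / 2
  expect_equal(predict(fit, mid),
               (predict(fit, x1) + predict(fit, x2)) / 2, tolerance = 1e-10)
  expect_error(predict(fit, d$X[, 1:3]), "schema")
})

test_that("nAxis is clipped to the rank with a warning", {
  d <- rand_xy(10, 20, 6)
  expect_warning(fit <- fitPCR(d$X, d$y, nAxis = 15), "clipped")
  expect_lte(fit@nAxis, 9)
  expect_lte(selectNAxis(d$X, d$y, seed = 1),
             min(nrow(d$X) - 1, ncol(d$X)))
})

test_that("q2Rmse identities and error handling", {
  y <- c(0.3, 1.1, -0.4, 2)
  expect_equal(q2Rmse(y, y), c(Q2 = 1, RMSE = 0))
  expect_equal(unname(q2Rmse(rep(mean(y), 4), y)["Q2"]), 0)
  m <- q2Rmse(c(0, 1, 4), c(0, 1, 2))
  expect_equal(unname(m["Q2"]), -1)
  expect_equal(unname(m["RMSE"]), sqrt(4 / 3))
  expect_error(q2Rmse(c(1, 2), c(3, 3)), "zero variance")
})

test_that("axis selection finds a planted single-factor model", {
  set.seed(8)
  ## signal along PC1 only: one dominant direction plus tiny noise
  scores <- rnorm(60, sd = 4)
  load <- rnorm(8); load <- load / sqrt(sum(load^2))
  X <- outer(scores, load) + matrix(rnorm(480, sd = 0.2), 60, 8)
  colnames(X) <- sprintf("v%d", 1:8)
  y <- 2 * scores + rnorm(60, sd = 0.1)
  na <- selectNAxis(X, y, seed = 2)
  expect_lte(na, 3)
  cv <- kfoldCV(X, y, k = 4, seed = 2)
  expect_gte(cv$Q2, 0.9)
  expect_identical(na, selectNAxis(X, y, seed = 2)) # deterministic
})

test_that("k-fold CV partitions rows, balances folds and recovers signal", {
  d <- rand_xy(46, 9, 7, noise = 0)
  cv <- kfoldCV(d$X, d$y, k = 4, seed = 10)
  tab <- table(cv$folds)
  expect_identical(length(cv$folds), 46L)
  expect_lte(diff(range(tab)), 1)
  expect_gte(cv$Q2, 0.99) # noiseless planted linear target
  cv2 <- kfoldCV(d$X, d$y, k = 4, seed = 10)
  expect_identical(cv$predictions, cv2$predictions)
  expect_error(kfoldCV(d$X, d$y, k = 100, seed = 1), "exceeds")
})

test_that("CV Q2 decreases with label noise in expectation", {
  q_lo <- q_hi <- numeric(20)
  for (s in 1:20) {
    d1 <- rand_xy(40, 6, 100 + s, noise = 0.1)
    d2 <- rand_xy(40, 6, 100 + s, noise = 2.0)
    q_lo[s] <- kfoldCV(d1$X, d1$y, k = 4, seed = s)$Q2
    q_hi[s] <- kfoldCV(d2$X, d2$y, k = 4, seed = s)$Q2
  }
  expect_gt(mean(q_lo), mean(q_hi))
})

test_that("L1 fit matches its closed-form soft-threshold oracle", {
  d <- rand_xy(50, 10, 12)
  lam <- 3
  fit <- fitL1(d$X, d$y, lambda = lam)
  ## oracle: PC scores are orthogonal, so each coefficient is an
  ## independent soft-thresholded projection
  Xc <- scale(d$X, scale = FALSE)
  s <- svd(Xc)
  P <- s$u %*% diag(s$d)
  z <- drop(crossprod(P, d$y - mean(d$y)))
  oracle <- sign(z) * pmax(abs(z) - lam / 2, 0) / s$d^2
  expect_lt(max(abs(abs(fit@coef) - abs(oracle))), 1e-8)

  ## lambda = 0 matches the unpenalized PCR fit
  f0 <- fitL1(d$X, d$y, lambda = 0)
  p0 <- fitPCR(d$X, d$y, lambda = 0)
  expect_lt(max(abs(predict(f0, d$X) - predict(p0, d$X))), 1e-8)

  ## shrinkage direction: huge lambda kills every coefficient
  fbig <- fitL1(d$X, d$y, lambda = 1e6)
  expect_true(all(fbig@coef == 0))
  expect_lte(sum(fbig@coef != 0), sum(f0@coef != 0))
})

test_that("hold-out split honors sorting, partition and the None mode", {
  set.seed(20)
  feats <- data.frame(id = sprintf("m%03d", 1:100),
                      MW = runif(100, 100, 700),
                      N_atom = sample(10:80, 100, TRUE),
                      N_cycle = sample(0:6, 100, TRUE),
                      N_rot = sample(0:25, 100, TRUE),
                      N_ring = sample(c(0, 5, 6, 14, 16), 100, TRUE))
  for (ft in c("MW", "N_atom", "N_cycle", "N_rot", "N_ring")) {
    sp <- holdoutSplit(feats, ft)
    expect_length(sp$holdout, 25)
    expect_setequal(c(sp$train, sp$holdout), feats$id)
    expect_length(intersect(sp$train, sp$holdout), 0)
    ## hold-out molecules are never smaller than the training ones except
    ## where the boundary value itself is tied
    expect_gte(min(feats[[ft]][feats$id %in% sp$holdout]),
               sort(feats[[ft]], decreasing = TRUE)[25])
  }
  sp <- holdoutSplit(feats, "MW")
  expect_gte(min(feats$MW[feats$id %in% sp$holdout]),
             max(feats$MW[feats$id %in% sp$train])) # MW has no ties here
  rnd <- holdoutSplit(feats, "None", seed = 4)
  expect_identical(rnd, holdoutSplit(feats, "None", seed = 4))
  expect_error(holdoutSplit(feats, "logP"), "unknown")
})

test_that("hold-out evaluation extrapolates a size-independent truth", {
  set.seed(30)
  d <- rand_xy(100, 15, 31, noise = 0.1)
  feats <- data.frame(id = sprintf("m%03d", 1:100),
                      MW = runif(100, 100, 700))
  rownames(d$X) <- feats$id
  ho <- holdoutEvaluate(d$X, d$y, feats, "MW", seed = 3)
  expect_gte(ho$R, 0.95)
  expect_setequal(c(ho$split$train, ho$split$holdout), feats$id)
  ## hold-out rows never entered the fit: refitting on train rows only
  ## reproduces the model exactly
  refit <- fitPCR(d$X[ho$split$train, ], d$y[match(ho$split$train, feats$id)],
                  nAxis = ho$nAxis)
  expect_equal(refit@coef, ho$model@coef, tolerance = 1e-10)
  ho2 <- holdoutEvaluate(d$X, d$y, feats, "MW", seed = 3)
  expect_identical(ho$R, ho2$R)
})

test_that("coefficient correlation: identity, antisymmetry, stability", {
  d <- rand_xy(120, 10, 40, noise = 0.1)
  fit <- fitPCR(d$X, d$y)
  expect_equal(coefficientCorrelation(fit, fit), 1)
  neg <- fit; neg@coef <- -neg@coef
  expect_equal(coefficientCorrelation(fit, neg), -1)
  ## two disjoint halves of one planted-model dataset agree
  f1 <- fitPCR(d$X[1:60, ], d$y[1:60])
  f2 <- fitPCR(d$X[61:120, ], d$y[61:120])
  expect_gte(coefficientCorrelation(f1, f2), 0.9)
  d2 <- rand_xy(30, 4, 41)
  expect_error(coefficientCorrelation(fit, fitPCR(d2$X, d2$y)), "schema")
})

test_that("PCR models serialize to JSON and round-trip", {
  d <- rand_xy(30, 6, 50)
  fit <- fitPCR(d$X, d$y, meta = list(charge_scheme = "gasteiger"))
  f <- tempfile(fileext = ".json")
  writePCRModel(fit, f)
  back <- readPCRModel(f)
  expect_identical(back@schema, fit@schema)
  expect_equal(back@coef, fit@coef, tolerance = 1e-12)
  expect_equal(predict(back, d$X), predict(fit, d$X), tolerance = 1e-12)
  expect_identical(back@meta$charge_scheme, "gasteiger")
})
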