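## Principal-component regression with L2 (ridge) or L1 (lasso) penalty on
## the PC coefficients, Q2/RMSE metrics, axis selection by cross-validated
## Q2, k-fold CV with optional nested axis selection, and the
## size-stratified hold-out protocol.

.drop_constant <- function(X) {
  sdv <- apply(X, 2, stats::sd)
  keep <- which(sdv > 1e-12)
  list(X = X[, keep, drop = FALSE],
       dropped = colnames(X)[setdiff(seq_len(ncol(X)), keep)])
}

.pcr_decompose <- function(X) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  s <- svd(Xc)
  tol <- max(dim(Xc)) * max(s$d) * .Machine$double.eps
  r <- sum(s$d > tol)
  list(center = ctr, d = s$d[seq_len(r)],
       loadings = s$v[, seq_len(r), drop = FALSE],
       scores = s$u[, seq_len(r), drop = FALSE] %*%
         diag(s$d[seq_len(r)], r, r))
}

#' Fit a principal-component regression with an L2 penalty
#'
#' Descriptor columns are centered by their means and decomposed into
#' principal components; the coefficients of the first \code{nAxis} PC
#' axes minimize the squared prediction error plus lambda times the sum of
#' squared coefficients (the intercept is unpenalized and equals the mean
#' response, since PC scores are centered). Because PC scores are
#' orthogonal the ridge solution is elementwise. Zero-variance columns
#' (e.g. constant MACCS keys) are dropped before the PCA and recorded.
#'
#' @param X numeric descriptor matrix (rows = molecules, named columns).
#' @param y response vector.
#' @param lambda L2 weight (>= 0), default 1e-6.
#' @param nAxis number of retained axes; default = full rank. Clipped to
#'   the rank with a warning if larger.
#' @param meta provenance list stored on the model.
#' @return a \code{\linkS4class{PCRModel}}.
#' @export
fitPCR <- function(X, y, lambda = 1e-6, nAxis = NULL, meta = list()) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 3, lambda >= 0)
  if (anyNA(X) || anyNA(y)) .stopf("missing values are not supported")
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%03d", seq_len(ncol(X)))
  dc <- .drop_constant(X)
  dec <- .pcr_decompose(dc$X)
  r <- length(dec$d)
  if (is.null(nAxis)) nAxis <- r
  if (nAxis > r) {
    .warnf("nAxis = %d exceeds rank %d; clipped", nAxis, r)
    nAxis <- r
  }
  jj <- seq_len(nAxis)
  yc <- y - mean(y)
  cj <- drop(crossprod(dec$scores[, jj, drop = FALSE], yc)) /
    (dec$d[jj]^2 + lambda)
  new("PCRModel", schema = colnames(dc$X), center = dec$center,
      loadings = dec$loadings, coef = as.numeric(cj),
      intercept = mean(y), lambda = lambda, nAxis = as.integer(nAxis),
      penalty = "L2", dropped = dc$dropped, meta = meta)
}

#' Fit the L1-regularized variant in the PC basis
#'
#' Same decomposition as \code{\link{fitPCR}}, but the PC coefficients
#' minimize the squared error plus lambda times the sum of absolute
#' coefficients, solved by coordinate descent (the orthogonality of PC
#' scores makes the solution a soft-thresholding, but the solver does not
#' assume it). Large lambda shrinks every coefficient to exactly zero; the
#' surviving axes, back-projected to descriptor space with
#' \code{\link{backProjectCoefficients}}, expose the dominant descriptors.
#'
#' @inheritParams fitPCR
#' @param maxIter,tol coordinate-descent controls.
#' @return a \code{\linkS4class{PCRModel}} with penalty \code{"L1"}.
#' @export
fitL1 <- function(X, y, lambda = 1e-6, nAxis = NULL, meta = list(),
                  maxIter = 1000, tol = 1e-10) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 3, lambda >= 0)
  if (anyNA(X) || anyNA(y)) .stopf("missing values are not supported")
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%03d", seq_len(ncol(X)))
  dc <- .drop_constant(X)
  dec <- .pcr_decompose(dc$X)
  r <- length(dec$d)
  if (is.null(nAxis)) nAxis <- r
  nAxis <- min(nAxis, r)
  P <- dec$scores[, seq_len(nAxis), drop = FALSE]
  yc <- y - mean(y)
  ss <- colSums(P^2)
  cj <- numeric(nAxis)
  resid <- yc
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    delta <- 0
    for (j in seq_len(nAxis)) {
      zj <- sum(P[, j] * resid) + ss[j] * cj[j]
      newc <- soft(zj, lambda / 2) / ss[j]
      if (newc != cj[j]) {
        resid <- resid - P[, j] * (newc - cj[j])
        delta <- max(delta, abs(newc - cj[j]))
        cj[j] <- newc
      }
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    .stopf("L1 coordinate descent did not converge in %d iterations (last max step %.3g)",
           maxIter, delta)
  new("PCRModel", schema = colnames(dc$X), center = dec$center,
      loadings = dec$loadings, coef = as.numeric(cj),
      intercept = mean(y), lambda = lambda, nAxis = as.integer(nAxis),
      penalty = "L1", dropped = dc$dropped, meta = meta)
}

#' Predict with a PCRModel
#'
#' Centers the descriptors with the stored means, projects them on the
#' retained loading vectors and applies the PC coefficients and intercept.
#'
#' @param object a \code{\linkS4class{PCRModel}}.
#' @param newdata descriptor matrix containing (at least) the model schema
#'   columns by name.
#' @return numeric predictions.
#' @export
setMethod("predict", "PCRModel", function(object, newdata) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)) && ncol(newdata) == length(object@schema))
    colnames(newdata) <- object@schema
  miss <- setdiff(object@schema, colnames(newdata))
  if (length(miss))
    .stopf("descriptor schema mismatch; missing: %s",
           paste(utils::head(miss, 5), collapse = ", "))
  Xc <- sweep(newdata[, object@schema, drop = FALSE], 2, object@center)
  P <- Xc %*% object@loadings[, seq_len(object@nAxis), drop = FALSE]
  drop(P %*% object@coef) + object@intercept
})

#' Back-project PC coefficients to descriptor space
#'
#' @param model a \code{\linkS4class{PCRModel}}.
#' @return named numeric vector of per-descriptor weights over the model
#'   schema (dropped constant columns get weight 0).
#' @export
backProjectCoefficients <- function(model) {
  beta <- drop(model@loadings[, seq_len(model@nAxis), drop = FALSE] %*%
                 model@coef)
  out <- stats::setNames(beta, model@schema)
  if (length(model@dropped))
    out <- c(out, stats::setNames(numeric(length(model@dropped)),
                                  model@dropped))
  out
}

#' Cross-validation metrics Q2 and RMSE
#'
#' RMSE = sqrt(mean((pred - exp)^2)); Q2 = 1 - sum((pred - exp)^2) /
#' sum((exp - mean(exp))^2). Q2 is undefined (error) when the experimental
#' values have zero variance.
#'
#' @param yPred predicted values.
#' @param yExp experimental values.
#' @return named vector \code{c(Q2, RMSE)}.
#' @export
q2Rmse <- function(yPred, yExp) {
  stopifnot(length(yPred) == length(yExp), length(yExp) >= 2)
  sst <- sum((yExp - mean(yExp))^2)
  if (sst <= 0) .stopf("Q2 undefined: zero variance in experimental values")
  sse <- sum((yPred - yExp)^2)
  c(Q2 = 1 - sse / sst, RMSE = sqrt(sse / length(yExp)))
}

.make_folds <- function(n, k, seed) {
  stopifnot(k >= 2, k <= n)
  .with_seed(seed, sample(rep_len(seq_len(k), n)[sample.int(n)]))
}

## cumulative-axis prediction path: column m = prediction using m axes
.pcr_path <- function(Xtr, ytr, Xte, lambda) {
  dc <- .drop_constant(Xtr)
  dec <- .pcr_decompose(dc$X)
  r <- length(dec$d)
  yc <- ytr - mean(ytr)
  cj <- drop(crossprod(dec$scores, yc)) / (dec$d^2 + lambda)
  Pte <- sweep(Xte[, colnames(dc$X), drop = FALSE], 2, dec$center) %*%
    dec$loadings
  contrib <- sweep(Pte, 2, cj, `*`)
  path <- matrix(0, nrow(Xte), r)
  acc <- numeric(nrow(Xte))
  for (m in seq_len(r)) {
    acc <- acc + contrib[, m]
    path[, m] <- acc + mean(ytr)
  }
  path
}

#' Select the number of PC axes by cross-validated Q2
#'
#' Evaluates every candidate axis count from 1 to the rank by k-fold CV
#' and returns the count maximizing the pooled Q2. Because the Q2 curve
#' plateaus once the informative axes are in, the smallest count within
#' \code{tol} of the maximum is returned (exact ties therefore also go to
#' the smaller count). Deterministic given the seed.
#'
#' @param X descriptor matrix.
#' @param y response.
#' @param lambda L2 weight.
#' @param kFolds folds (default 3).
#' @param seed fold-assignment seed.
#' @param tol parsimony tolerance on the Q2 scale (default 1e-3).
#' @return integer axis count.
#' @export
selectNAxis <- function(X, y, lambda = 1e-6, kFolds = 3, seed = 1,
                        tol = 1e-3) {
  X <- as.matrix(X)
  n <- nrow(X)
  folds <- .make_folds(n, kFolds, seed)
  rmax <- 0L
  pooled <- NULL
  for (f in seq_len(kFolds)) {
    tr <- folds != f
    path <- .pcr_path(X[tr, , drop = FALSE], y[tr],
                      X[!tr, , drop = FALSE], lambda)
    if (is.null(pooled))
      pooled <- matrix(NA_real_, n, ncol(path))
    r <- min(ncol(pooled), ncol(path))
    pooled <- pooled[, seq_len(r), drop = FALSE]
    pooled[!tr, ] <- path[, seq_len(r)]
    rmax <- r
  }
  q2 <- vapply(seq_len(rmax), function(m)
    unname(q2Rmse(pooled[, m], y)["Q2"]), 0)
  which(q2 >= max(q2) - tol)[1]
}

#' k-fold cross-validation of the PCR model
#'
#' Seeded random fold assignment (fold sizes differ by at most one); every
#' row is predicted exactly once from a model that never saw it. By
#' default the axis count is re-selected inside each fold on the training
#' part only (nested inner CV, no selection leakage); with \code{nested =
#' FALSE} a single axis count is selected on the full data first.
#'
#' @param X descriptor matrix.
#' @param y response.
#' @param k outer folds (default 4).
#' @param lambda L2 weight (default 1e-6).
#' @param seed seed for fold assignment and nested selection.
#' @param nested logical; nested axis selection (default TRUE).
#' @param innerK inner folds for axis selection (default 3).
#' @return list with \code{predictions}, \code{folds}, \code{Q2},
#'   \code{RMSE}, \code{R} (Pearson), \code{nAxis} (per fold), \code{seed}.
#' @export
kfoldCV <- function(X, y, k = 4, lambda = 1e-6, seed = 1, nested = TRUE,
                    innerK = 3) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) .stopf("k = %d exceeds the number of rows (%d)", k, n)
  folds <- .make_folds(n, k, seed)
  preds <- numeric(n)
  nAxisUsed <- integer(k)
  globalAxis <- if (!nested)
    selectNAxis(X, y, lambda, kFolds = innerK, seed = .child_seed(seed, 0))
  else NA_integer_
  for (f in seq_len(k)) {
    tr <- folds != f
    na <- if (nested)
      selectNAxis(X[tr, , drop = FALSE], y[tr], lambda, kFolds = innerK,
                  seed = .child_seed(seed, f))
    else globalAxis
    fit <- fitPCR(X[tr, , drop = FALSE], y[tr], lambda = lambda,
                  nAxis = na)
    preds[!tr] <- predict(fit, X[!tr, , drop = FALSE])
    nAxisUsed[f] <- fit@nAxis
  }
  m <- q2Rmse(preds, y)
  list(predictions = preds, folds = folds,
       Q2 = unname(m["Q2"]), RMSE = unname(m["RMSE"]),
       R = stats::cor(preds, y), nAxis = nAxisUsed, seed = seed)
}

#' Size-stratified hold-out split
#'
#' Sorts molecules by a size feature in decreasing order and assigns the
#' top fraction (largest molecules) to the hold-out set, the rest to the
#' training set: the model must extrapolate from small to large. Feature
#' \code{"None"} draws a seeded random hold-out instead (the unbiased
#' reference). Ties are broken by molecule id for determinism.
#'
#' @param features data.frame with an \code{id} column and the candidate
#'   feature columns (\code{MW}, \code{N_atom}, \code{N_cycle},
#'   \code{N_rot}, \code{N_ring}).
#' @param feature feature name, or \code{"None"} for random selection.
#' @param fraction hold-out fraction (default 0.25).
#' @param seed used only for \code{feature = "None"}.
#' @return list with \code{train} and \code{holdout} id vectors (disjoint,
#'   exhaustive).
#' @export
holdoutSplit <- function(features, feature, fraction = 0.25, seed = 1) {
  stopifnot(is.data.frame(features), "id" %in% names(features))
  n <- nrow(features)
  nHold <- ceiling(fraction * n)
  ids <- as.character(features$id)
  if (identical(feature, "None")) {
    hold <- .with_seed(seed, sample(ids, nHold))
    return(list(train = setdiff(ids, hold), holdout = hold))
  }
  if (!feature %in% names(features))
    .stopf("unknown hold-out feature '%s'; available: %s, None", feature,
           paste(setdiff(names(features), "id"), collapse = ", "))
  ord <- order(-features[[feature]], ids)
  hold <- ids[ord[seq_len(nHold)]]
  list(train = ids[ord[-seq_len(nHold)]], holdout = hold)
}

#' Hold-out evaluation with axis selection on the training side
#'
#' Splits by the given size feature, selects the axis count by 3-fold CV
#' on the training (smaller-molecule) side only, fits, predicts the
#' held-out larger molecules and reports the Pearson correlation and RMSE
#' between predicted and experimental values.
#'
#' @param X descriptor matrix with rownames matching \code{features$id}.
#' @param y response aligned to \code{X} rows.
#' @param features see \code{\link{holdoutSplit}}.
#' @param feature stratification feature or \code{"None"}.
#' @param lambda L2 weight.
#' @param seed seed (fold assignment; random split for \code{"None"}).
#' @param fraction hold-out fraction.
#' @param penalty \code{"L2"} or \code{"L1"}.
#' @return list with \code{R}, \code{RMSE}, \code{model}, \code{split}.
#' @export
holdoutEvaluate <- function(X, y, features, feature, lambda = 1e-6,
                            seed = 1, fraction = 0.25, penalty = "L2") {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 12, !is.null(rownames(X)))
  names(y) <- rownames(X)
  sp <- holdoutSplit(features, feature, fraction, seed)
  Xtr <- X[sp$train, , drop = FALSE]
  Xho <- X[sp$holdout, , drop = FALSE]
  na <- selectNAxis(Xtr, y[sp$train], lambda, kFolds = 3,
                    seed = .child_seed(seed, 1))
  fit <- if (penalty == "L2")
    fitPCR(Xtr, y[sp$train], lambda = lambda, nAxis = na)
  else fitL1(Xtr, y[sp$train], lambda = lambda, nAxis = na)
  yp <- predict(fit, Xho)
  yh <- y[sp$holdout]
  if (stats::sd(yh) <= 0)
    .stopf("hold-out responses have zero variance; R undefined")
  list(R = stats::cor(yp, yh),
       RMSE = sqrt(mean((yp - yh)^2)),
       model = fit, split = sp, nAxis = na)
}

#' Correlation between the coefficient sets of two models
#'
#' Back-projects both models' PC coefficients to descriptor space and
#' returns the Pearson correlation of the two weight vectors: a
#' robustness measure of how much the fitted model depends on the choice
#' of training set.
#'
#' @param m1,m2 \code{\linkS4class{PCRModel}}s fit on the same descriptor
#'   schema.
#' @return Pearson correlation.
#' @export
coefficientCorrelation <- function(m1, m2) {
  b1 <- backProjectCoefficients(m1)
  b2 <- backProjectCoefficients(m2)
  if (!setequal(names(b1), names(b2)))
    .stopf("models use different descriptor schemas")
  nm <- sort(names(b1))
  stats::cor(b1[nm], b2[nm])
}

#' Serialize / restore a PCRModel as JSON
#'
#' The JSON file carries the schema, centering means, loading vectors, PC
#' coefficients, intercept, penalty settings and provenance metadata, so a
#' trained model can be applied in a later session (schema names are
#' checked at prediction time).
#'
#' @param model a \code{\linkS4class{PCRModel}}.
#' @param path JSON file path.
#' @return \code{writePCRModel}: the path, invisibly. \code{readPCRModel}:
#'   the restored model.
#' @export
writePCRModel <- function(model, path) {
  obj <- list(schema = model@schema, center = model@center,
              loadings = model@loadings, coef = model@coef,
              intercept = model@intercept, lambda = model@lambda,
              nAxis = model@nAxis, penalty = model@penalty,
              dropped = model@dropped, meta = model@meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writePCRModel
#' @export
readPCRModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("PCRModel", schema = as.character(obj$schema),
      center = as.numeric(obj$center),
      loadings = matrix(as.numeric(obj$loadings),
                        nrow = length(obj$schema)),
      coef = as.numeric(obj$coef), intercept = as.numeric(obj$intercept),
      lambda = as.numeric(obj$lambda), nAxis = as.integer(obj$nAxis),
      penalty = as.character(obj$penalty),
      dropped = as.character(obj$dropped %||% character()),
      meta = as.list(obj$meta %||% list()))
}
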