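## End-to-end orchestration: preparation -> conformer ensembles ->
## solvation -> descriptors -> features -> regression artifacts, plus the
## conformer-number sweep experiment. Every stage is a pure function of
## its declared inputs and the resolved configuration; per-run artifacts
## embed the configuration for provenance.

#' Pipeline run configuration
#'
#' All tunables with their defaults: 100 Monte-Carlo samples per molecule
#' (the accuracy/cost operating point; up to 300 supported), solvation
#' parameters (+10 / -5 cal/mol/A^2, dielectrics 78.5 / 2.0, 298.15 K),
#' the 1.5 Angstrom clustering threshold, hydrogen-bond cutoffs, the
#' regression penalty and weight (L2, lambda = 1e-6), the feature model
#' tag and the ablation flags (diffusion-term subsets; \code{forceN1}
#' replaces all conformer degeneracies by 1).
#'
#' @param ... overrides of the named defaults.
#' @return a named list of class \code{"RunConfig"}.
#' @export
runConfig <- function(...) {
  cfg <- list(
    n_samples = 100, seed = 7, temperature_K = 298.15,
    sigma_water = 10, sigma_membrane = -5,
    dielectric_water = 78.5, dielectric_membrane = 2.0,
    cluster_rmsd = 1.5, hbond_dist = 2.5, hbond_angle = 120,
    lambda = 1e-6, penalty = "L2", model = "AB",
    ablate = character(), forceN1 = FALSE,
    charge_scheme = "gasteiger", probe = 1.4, asa_points = 240,
    cv_folds = 4)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$n_samples >= 1, cfg$n_samples <= 300)
  class(cfg) <- "RunConfig"
  cfg
}

.solv_params <- function(cfg) {
  solvationParams(temperature = cfg$temperature_K,
                  sigmaWater = cfg$sigma_water,
                  sigmaMembrane = cfg$sigma_membrane,
                  dielectricWater = cfg$dielectric_water,
                  dielectricMembrane = cfg$dielectric_membrane,
                  probe = cfg$probe, asaPoints = cfg$asa_points)
}

#' Compute ensemble descriptors for a set of molecules
#'
#' Runs conformer generation, solvation and descriptor computation per
#' molecule under a shared configuration. Per-molecule failures (e.g. ring
#' closure failing for every sample) drop the molecule with a warning
#' rather than aborting the set.
#'
#' @param mols list of prepared \code{Molecule}s.
#' @param config a \code{\link{runConfig}}.
#' @param nSamples optional override of \code{config$n_samples}.
#' @return named list of \code{EnsembleDescriptors}.
#' @export
computeDescriptors <- function(mols, config = runConfig(),
                               nSamples = NULL) {
  params <- .solv_params(config)
  nS <- nSamples %||% config$n_samples
  out <- list()
  for (k in seq_along(mols)) {
    mol <- mols[[k]]
    ed <- tryCatch({
      ens <- generateEnsemble(mol, nSamples = nS,
                              seed = .child_seed(config$seed, k),
                              threshold = config$cluster_rmsd)
      ens <- addSolvationEnergies(ens, params)
      ensembleDescriptors(ens, params, hbondDist = config$hbond_dist,
                          hbondAngle = config$hbond_angle,
                          forceN1 = config$forceN1)
    }, error = function(e) {
      .warnf("stage descriptors, molecule '%s': %s; dropped from run",
             mol@id, conditionMessage(e))
      NULL
    })
    if (!is.null(ed)) out[[mol@id]] <- ed
  }
  if (length(out) == 0) .stopf("all molecules failed descriptor computation")
  out
}

#' Run the full pipeline
#'
#' Preparation (skipped for already-prepared molecules), conformer
#' ensembles, solvation, descriptors and feature assembly; with labels the
#' model is cross-validated and fit on all data, without labels a
#' supplied model predicts. Artifacts (descriptor CSV, model JSON, eval
#' report) are written when \code{outDir} is given; the resolved
#' configuration is embedded in the model metadata.
#'
#' @param mols list of \code{Molecule}s (prepared or raw).
#' @param labels optional named response vector (LogPapp) by molecule id.
#' @param config a \code{\link{runConfig}}.
#' @param model optional \code{\linkS4class{PCRModel}} for prediction-only
#'   runs.
#' @param outDir optional output directory for artifacts.
#' @return list with \code{features} (matrix), \code{descriptors},
#'   \code{cv} (eval list, if labels), \code{model} (fitted or supplied),
#'   \code{predictions}, \code{config}.
#' @export
runPipeline <- function(mols, labels = NULL, config = runConfig(),
                        model = NULL, outDir = NULL) {
  prepared <- lapply(mols, function(m)
    if (isTRUE(m@meta$prepared)) m else
      prepareMolecule(m, chargeScheme = config$charge_scheme))
  eds <- computeDescriptors(prepared, config)
  X <- featureMatrix(eds, model = config$model, ablate = config$ablate)
  res <- list(features = X, descriptors = eds, config = config)
  if (!is.null(labels)) {
    y <- labels[rownames(X)]
    if (anyNA(y)) .stopf("labels missing for: %s",
                         paste(rownames(X)[is.na(y)], collapse = ", "))
    res$cv <- kfoldCV(X, y, k = config$cv_folds, lambda = config$lambda,
                      seed = config$seed)
    meta <- list(config = unclass(config),
                 charge_scheme = config$charge_scheme)
    na <- selectNAxis(X, y, config$lambda, kFolds = 3,
                      seed = .child_seed(config$seed, 99))
    res$model <- if (config$penalty == "L2")
      fitPCR(X, y, lambda = config$lambda, nAxis = na, meta = meta)
    else fitL1(X, y, lambda = config$lambda, nAxis = na, meta = meta)
    res$predictions <- predict(res$model, X)
  } else if (!is.null(model)) {
    res$model <- model
    res$predictions <- predict(model, X)
  }
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(data.frame(id = rownames(X), X, check.names = FALSE),
                     file.path(outDir, "descriptors.csv"),
                     row.names = FALSE)
    if (!is.null(res$model))
      writePCRModel(res$model, file.path(outDir, "model.json"))
    if (!is.null(res$cv))
      jsonlite::write_json(
        list(Q2 = res$cv$Q2, RMSE = res$cv$RMSE, R = res$cv$R,
             nAxis = res$cv$nAxis, seed = res$cv$seed,
             config = unclass(config)),
        file.path(outDir, "eval.json"), digits = NA, auto_unbox = TRUE)
  }
  res
}

#' Conformer-number sweep
#'
#' Re-runs descriptor computation and 4-fold cross-validation at each
#' requested Monte-Carlo sample count and tabulates Q2 and RMSE against
#' the conformer number — the experiment design that shows how much of
#' the prediction signal comes from the conformational ensemble.
#'
#' @param mols prepared molecules.
#' @param labels named response vector by molecule id.
#' @param nValues sample counts to sweep (default c(1, 3, 10, 30, 100,
#'   300)).
#' @param config a \code{\link{runConfig}}.
#' @return data.frame with columns \code{n_samples}, \code{Q2},
#'   \code{RMSE}, \code{R}, \code{n_molecules}.
#' @export
sweepConformerNumber <- function(mols, labels,
                                 nValues = c(1, 3, 10, 30, 100, 300),
                                 config = runConfig()) {
  rows <- lapply(nValues, function(nS) {
    eds <- computeDescriptors(mols, config, nSamples = nS)
    X <- featureMatrix(eds, model = config$model, ablate = config$ablate)
    y <- labels[rownames(X)]
    cv <- kfoldCV(X, y, k = config$cv_folds, lambda = config$lambda,
                  seed = config$seed)
    data.frame(n_samples = nS, Q2 = cv$Q2, RMSE = cv$RMSE, R = cv$R,
               n_molecules = nrow(X))
  })
  do.call(rbind, rows)
}
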