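## QSPR feature layouts. Model A treats the conformer as fixed while it
## crosses the membrane (water-ensemble statistics and a per-conformer
## LogD averaged under water weights); Model B re-equilibrates the
## conformers inside the membrane (ensemble LogD plus membrane-ensemble
## statistics); Model AB is the union of the two descriptor sets with the
## shared conformer-independent block appearing once.

.static_block <- function(st) {
  c(stats::setNames(c(st$q_OH, st$q_NH, st$N_atom, st$N_rot, st$N_HA,
                      st$N_HD),
                    c("q_OH", "q_NH", "N_atom", "N_rot", "N_HA", "N_HD")),
    stats::setNames(as.numeric(st$maccs), sprintf("MACCS_%03d", 1:166)))
}

.asa_block <- function(ed) {
  c(stats::setNames(ed$asa$wat, paste0("ASAwat_", names(ed$asa$wat))),
    stats::setNames(ed$asa$mem, paste0("ASAmem_", names(ed$asa$mem))))
}

.r_block <- function(stat, tag, ablate) {
  f <- diffusionFeatures(unname(stat[["mean"]]), unname(stat[["sd"]]),
                         ablate = ablate)
  stats::setNames(as.numeric(f), paste0(names(f), "_", tag))
}

#' Model A feature vector (conformer fixed during crossing)
#'
#' Terms: mean and deviation of the per-conformer LogD under water
#' weights, water- and membrane-weighted atom-typed ASA means, the
#' water-ensemble hydrogen-bond mean, the water-ensemble diffusion block
#' (<R>, <R>^2, <R>^3, sigma(R), Log10<R>), the hydrogen charges q(OH) and
#' q(NH), atom/rotor/donor/acceptor counts and the 166 MACCS keys.
#'
#' @param ed an \code{EnsembleDescriptors} object.
#' @param ablate diffusion-term ablation flags (see
#'   \code{\link{diffusionFeatures}}).
#' @return named numeric feature vector with attribute \code{model = "A"}.
#' @export
featuresModelA <- function(ed, ablate = character()) {
  stopifnot(inherits(ed, "EnsembleDescriptors"))
  v <- c(
    LogDconf_mean = unname(ed$logd_conf["mean"]),
    LogDconf_sd = unname(ed$logd_conf["sd"]),
    .asa_block(ed),
    B_wat = unname(ed$B$wat["mean"]),
    .r_block(ed$R$wat, "wat", ablate),
    .static_block(ed$static))
  attr(v, "model") <- "A"
  v
}

#' Model B feature vector (conformers re-equilibrated in the membrane)
#'
#' Terms: the ensemble partition-function LogD, water- and
#' membrane-weighted atom-typed ASA means, the membrane-ensemble
#' hydrogen-bond mean, the membrane-ensemble diffusion block and the
#' shared conformer-independent block.
#'
#' @inheritParams featuresModelA
#' @return named numeric feature vector with attribute \code{model = "B"}.
#' @export
featuresModelB <- function(ed, ablate = character()) {
  stopifnot(inherits(ed, "EnsembleDescriptors"))
  v <- c(
    LogD = ed$logD,
    .asa_block(ed),
    B_mem = unname(ed$B$mem["mean"]),
    .r_block(ed$R$mem, "mem", ablate),
    .static_block(ed$static))
  attr(v, "model") <- "B"
  v
}

#' Merged Model AB feature vector
#'
#' Union of the Model A and Model B schemas; descriptors appearing in both
#' (ASA blocks, charges, counts, MACCS keys) are included once. An error
#' is raised if a shared term disagrees between the two inputs.
#'
#' @param a,b feature vectors from \code{\link{featuresModelA}} and
#'   \code{\link{featuresModelB}} for the same molecule.
#' @return named numeric feature vector with attribute \code{model = "AB"}.
#' @export
featuresModelAB <- function(a, b) {
  stopifnot(identical(attr(a, "model"), "A"),
            identical(attr(b, "model"), "B"))
  shared <- intersect(names(a), names(b))
  if (length(shared) &&
      max(abs(a[shared] - b[shared])) > 1e-9)
    .stopf("shared terms disagree between Model A and Model B vectors")
  v <- c(a, b[setdiff(names(b), names(a))])
  attr(v, "model") <- "AB"
  v
}

#' Assemble feature vectors per molecule and model
#'
#' @param eds list of \code{EnsembleDescriptors}.
#' @param model \code{"A"}, \code{"B"} or \code{"AB"}.
#' @param ablate diffusion ablation flags passed through.
#' @return numeric matrix, rows = molecules (named by id), columns = the
#'   model schema.
#' @export
featureMatrix <- function(eds, model = c("AB", "A", "B"),
                          ablate = character()) {
  model <- match.arg(model)
  rows <- lapply(eds, function(ed) {
    switch(model,
           A = featuresModelA(ed, ablate),
           B = featuresModelB(ed, ablate),
           AB = featuresModelAB(featuresModelA(ed, ablate),
                                featuresModelB(ed, ablate)))
  })
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(eds, function(ed) ed$id, "")
  X
}

#' Cumulant approximation of a Boltzmann-weighted Log10 average
#'
#' For values L(a) in the Log10 domain with weights d(a), the exact
#' ensemble value is Log10(sum_a d(a) 10^L(a)). Its cumulant expansion
#' truncated at first order is the weighted mean <L>; at second order the
#' weighted variance is added on the natural-log scale:
#' <L> + ln(10)/2 * Var(L). Both the truncations and the exact log-sum are
#' returned; in the regression every expansion term carries a fitted
#' coefficient, so the sign and scale of the second-order term are
#' absorbed by the fit.
#'
#' @param values Log10-domain values L(a).
#' @param weights normalized weights d(a).
#' @param order 1 or 2.
#' @return list with \code{approx} (the truncated expansion),
#'   \code{exact} (the log-sum), \code{mean} and \code{sd}.
#' @export
cumulantLogAverage <- function(values, weights, order = 2) {
  if (length(values) == 0) .stopf("empty input")
  if (length(values) != length(weights))
    .stopf("values and weights differ in length")
  stopifnot(order %in% c(1, 2))
  st <- ensembleStats(values, weights)
  exact <- .logsumexp10(log(weights) + values * log(10))
  approx <- if (order == 1) unname(st["mean"]) else
    unname(st["mean"] + log(10) / 2 * st["sd"]^2)
  list(approx = approx, exact = exact,
       mean = unname(st["mean"]), sd = unname(st["sd"]))
}
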