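## Internal constants and small helpers shared across modules.

# Boltzmann constant in kcal/mol/K; k_B * 298.15 K = 0.5925 kcal/mol.
.KB <- 0.0019872041

#' @noRd
.kbt <- function(temperature) .KB * temperature

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code under a local, seeded RNG without disturbing the caller's stream.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## Derive a child seed deterministically (kept below 2^31).
.child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483629)
}

## Standard atomic weights (g/mol), elements covered by the Sybyl typing used.
.ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904
)

## Bondi van der Waals radii (Angstrom), used for ASA and GB intrinsic radii.
.VDW_RADIUS <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98
)

## Single-bond covalent radii (Angstrom), fallback for bond r0 assignment.
.COV_RADIUS <- c(
  H = 0.32, C = 0.75, N = 0.71, O = 0.63, F = 0.64,
  P = 1.11, S = 1.03, Cl = 0.99, Br = 1.14, I = 1.33
)

## Canonical Sybyl atom-type inventory for schema-stable ASA blocks.
.SYBYL_TYPES <- c(
  "C.3", "C.2", "C.1", "C.ar", "C.cat",
  "N.3", "N.2", "N.1", "N.ar", "N.am", "N.pl3", "N.4",
  "O.3", "O.2", "O.co2",
  "S.3", "S.2", "S.o", "S.o2",
  "P.3", "H", "F", "Cl", "Br", "I", "Other"
)

.element_of <- function(sybyl) sub("\\..*$", "", sybyl)

.canon_type <- function(sybyl) {
  ifelse(sybyl %in% .SYBYL_TYPES, sybyl,
         ifelse(.element_of(sybyl) %in% c("H", "F", "Cl", "Br", "I"),
                .element_of(sybyl), "Other"))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
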