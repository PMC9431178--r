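# Closed registries shared across the package: amino-acid codes, configuration
# labels, solvents, monoisotopic atomic masses, and the random-coil style
# (C-H)alpha base shift table used by the synthetic fingerprint generator.

#' Amino-acid registry
#'
#' Three-letter codes accepted throughout the package. `Glx` is a pseudo-code
#' used only by Marfey constraint classes (acid hydrolysis prior to Marfey's
#' derivatization converts Gln to Glu, so the two are indistinguishable there).
#'
#' @keywords internal
.AA_CODES <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
               "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
               "Thr", "Trp", "Tyr", "Val", "Dab", "Hse")

## residues whose side chain carries a hydroxyl able to donate the macrolactone
## ester bond of a depsipeptide
.ESTER_DONOR_CODES <- c("Ser", "Thr", "Hse", "Tyr")

## residues with a second stereocenter at the beta carbon, for which "allo"
## diastereomer labels are meaningful
.ALLO_CODES <- c("Thr", "Ile")

.CONFIG_LEVELS <- c("L", "D", "D-allo", "L-allo", "unknown")

.SOLVENTS <- c("acetonitrile-d3", "DMSO-d6", "DMF-d7", "CDCl3",
               "methanol-d4", "D2O", "H2O/D2O", "pyridine-d5")

## IUPAC monoisotopic atomic masses (most abundant isotope), Da
.MONO_MASS <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.99491461956,
  P  = 30.97376163,
  S  = 31.97207100,
  F  = 18.99840322,
  Cl = 34.96885268,
  Br = 78.9183371,
  I  = 126.904473,
  Na = 22.9897692809,
  K  = 38.96370668,
  Se = 73.9224764
)

## Random-coil style Calpha/Halpha centres (ppm) used as base positions by the
## synthetic fingerprint generator. Only *differences* between simulated
## fingerprints carry information, so the absolute values merely need to be
## plausible for the (C-H)alpha region.
.BASE_SHIFTS <- data.frame(
  code   = c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
             "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
             "Thr", "Trp", "Tyr", "Val", "Dab", "Hse"),
  deltaC = c(52.5, 56.0, 53.1, 54.2, 58.2, 55.7, 56.6, 45.1,
             55.0, 61.1, 55.1, 56.2, 55.4, 57.7, 63.3, 58.3,
             61.8, 57.5, 57.9, 62.2, 53.5, 55.8),
  deltaH = c(4.32, 4.34, 4.74, 4.64, 4.55, 4.34, 4.35, 3.96,
             4.60, 4.17, 4.34, 4.32, 4.48, 4.62, 4.42, 4.47,
             4.35, 4.66, 4.55, 4.12, 4.40, 4.45),
  stringsAsFactors = FALSE
)

## base position of the fatty-acyl CHbeta cross-peak (the 3-OH methine)
.FA_BASE <- c(deltaC = 68.4, deltaH = 3.98)

.isConfigD <- function(config) config %in% c("D", "D-allo")
.isConfigL <- function(config) config %in% c("L", "L-allo")

.checkConfig <- function(code, config) {
  if (!config %in% .CONFIG_LEVELS)
    stop("unknown configuration label '", config, "'", call. = FALSE)
  if (config %in% c("D-allo", "L-allo") && !code %in% .ALLO_CODES)
    stop("'", config, "' is only defined for ", paste(.ALLO_CODES, collapse = "/"),
         ", not ", code, call. = FALSE)
  invisible(TRUE)
}
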