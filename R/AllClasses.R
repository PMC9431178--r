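#' @import methods
NULL

## ---------------------------------------------------------------------------
## FattyAcyl
## ---------------------------------------------------------------------------

#' Fatty-acyl moiety of a lipopeptide
#'
#' Describes the N-terminal acyl chain of a CLiP: carbon count, position of
#' the hydroxyl substituent (if any) and the configuration of the C3
#' stereocenter. The common "3R-OH C10:0" tail is
#' \code{FattyAcyl(10, 3, "R")}.
#'
#' @slot chainLength integer, number of carbons in the chain.
#' @slot hydroxylPosition integer, carbon bearing the hydroxyl, or \code{NA}
#'   for an unsubstituted chain.
#' @slot c3Config \code{"R"}, \code{"S"} or \code{"unknown"}; only meaningful
#'   when the hydroxyl sits at C3.
#' @export
setClass("FattyAcyl",
  representation(chainLength = "integer",
                 hydroxylPosition = "integer",
                 c3Config = "character"))

setValidity("FattyAcyl", function(object) {
  msg <- character()
  if (length(object@chainLength) != 1L || is.na(object@chainLength) ||
      object@chainLength < 1L)
    msg <- c(msg, "chainLength must be a single positive integer")
  if (length(object@hydroxylPosition) != 1L)
    msg <- c(msg, "hydroxylPosition must be length 1 (NA for none)")
  else if (!is.na(object@hydroxylPosition) &&
           object@hydroxylPosition > object@chainLength)
    msg <- c(msg, "hydroxylPosition exceeds chainLength")
  if (!object@c3Config %in% c("R", "S", "unknown"))
    msg <- c(msg, "c3Config must be 'R', 'S' or 'unknown'")
  if (object@c3Config != "unknown" &&
      (is.na(object@hydroxylPosition) || object@hydroxylPosition != 3L))
    msg <- c(msg, "c3Config is only meaningful for a 3-hydroxy acyl chain")
  if (length(msg)) msg else TRUE
})

#' @param chainLength,hydroxylPosition,c3Config see slot descriptions.
#' @return \code{FattyAcyl()} returns a \code{FattyAcyl} object.
#' @rdname FattyAcyl-class
#' @export
FattyAcyl <- function(chainLength, hydroxylPosition = NA_integer_,
                      c3Config = "unknown") {
  new("FattyAcyl", chainLength = as.integer(chainLength),
      hydroxylPosition = as.integer(hydroxylPosition),
      c3Config = as.character(c3Config))
}

## ---------------------------------------------------------------------------
## Lipopeptide
## ---------------------------------------------------------------------------

#' Cyclic lipodepsipeptide sequence
#'
#' A lipopeptide: ordered residues (1-based from the N-terminus) each with a
#' three-letter code and a d/l configuration label, the fatty-acyl tail, and
#' the ester-donor position whose side-chain hydroxyl closes the macrolactone
#' with the C-terminal carboxyl. A missing ester-donor position denotes a
#' linear peptide.
#'
#' @slot name free-text compound name.
#' @slot producer free-text producing strain.
#' @slot residues \code{data.frame} with columns \code{position},
#'   \code{code}, \code{config} (\code{"L"}, \code{"D"}, \code{"D-allo"},
#'   \code{"L-allo"} or \code{"unknown"}).
#' @slot fattyAcyl a \linkS4class{FattyAcyl}.
#' @slot esterDonorPosition integer or \code{NA} (linear peptide).
#' @export
setClass("Lipopeptide",
  representation(name = "character", producer = "character",
                 residues = "data.frame", fattyAcyl = "FattyAcyl",
                 esterDonorPosition = "integer"))

setValidity("Lipopeptide", function(object) {
  msg <- character()
  res <- object@residues
  need <- c("position", "code", "config")
  if (!all(need %in% names(res)))
    return("residues must have columns position, code, config")
  l <- nrow(res)
  if (l < 1L) msg <- c(msg, "at least one residue required")
  if (!identical(as.integer(res$position), seq_len(l)))
    msg <- c(msg, "residue positions must be contiguous 1..l")
  bad <- setdiff(res$code, .AA_CODES)
  if (length(bad))
    msg <- c(msg, paste0("unknown residue code(s): ", paste(bad, collapse = ", ")))
  for (i in seq_len(l)) {
    ok <- tryCatch({.checkConfig(res$code[i], res$config[i]); TRUE},
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) msg <- c(msg, ok)
  }
  edp <- object@esterDonorPosition
  if (!is.na(edp)) {
    if (edp < 1L || edp >= l)
      msg <- c(msg, "esterDonorPosition must lie before the final residue")
    else if (!res$code[edp] %in% .ESTER_DONOR_CODES)
      msg <- c(msg, paste0("residue ", edp, " (", res$code[edp],
                           ") has no hydroxyl side chain to donate the ester bond"))
  }
  if (length(msg)) msg else TRUE
})

#' @param name,producer,residues,fattyAcyl,esterDonorPosition see slots.
#'   \code{residues} may also be given as a character vector of codes
#'   (configs then default to \code{"unknown"}).
#' @return \code{Lipopeptide()} returns a \code{Lipopeptide} object.
#' @rdname Lipopeptide-class
#' @export
Lipopeptide <- function(name, residues, esterDonorPosition = NA_integer_,
                        fattyAcyl = FattyAcyl(10L, 3L, "R"),
                        producer = NA_character_) {
  if (is.character(residues))
    residues <- data.frame(position = seq_along(residues), code = residues,
                           config = "unknown", stringsAsFactors = FALSE)
  residues$position <- as.integer(residues$position)
  residues <- residues[order(residues$position), , drop = FALSE]
  rownames(residues) <- NULL
  new("Lipopeptide", name = as.character(name),
      producer = as.character(producer),
      residues = residues[c("position", "code", "config")],
      fattyAcyl = fattyAcyl,
      esterDonorPosition = as.integer(esterDonorPosition))
}

## ---------------------------------------------------------------------------
## DomainArchitecture
## ---------------------------------------------------------------------------

#' NRPS condensation-domain architecture
#'
#' Ordered condensation-domain types of the NRPS assembly line, one per
#' module. Module 1 carries the \code{Cstart} domain that acylates the first
#' residue with the fatty acid; downstream modules carry either a dual
#' condensation/epimerization \code{C/E} domain (appends an l-amino acid and
#' epimerizes the preceding residue to d, when active) or an \code{LCL}
#' domain that lacks epimerization activity.
#'
#' @slot modules character vector over \code{{"Cstart", "C/E", "LCL"}}.
#' @export
setClass("DomainArchitecture", representation(modules = "character"))

setValidity("DomainArchitecture", function(object) {
  msg <- character()
  mods <- object@modules
  if (length(mods) < 1L) msg <- c(msg, "at least one module required")
  bad <- setdiff(mods, c("Cstart", "C/E", "LCL"))
  if (length(bad))
    msg <- c(msg, paste0("unknown domain type(s): ", paste(bad, collapse = ", ")))
  if (length(mods) && mods[1L] != "Cstart")
    msg <- c(msg, "module 1 must be Cstart")
  if (any(mods[-1L] == "Cstart"))
    msg <- c(msg, "Cstart only allowed in module 1")
  if (length(msg)) msg else TRUE
})

#' @param modules character vector of domain types.
#' @return \code{DomainArchitecture()} returns a \code{DomainArchitecture}.
#' @rdname DomainArchitecture-class
#' @export
DomainArchitecture <- function(modules) {
  new("DomainArchitecture", modules = as.character(modules))
}

## ---------------------------------------------------------------------------
## MarfeyConstraint
## ---------------------------------------------------------------------------

#' Marfey's analysis d/l composition constraint
#'
#' Per-residue-class d/l counts obtained from Marfey's analysis of the total
#' hydrolysate. Total hydrolysis destroys positional information, so counts
#' apply to the whole class of sequence positions sharing a code. The
#' pseudo-class \code{"Glx"} covers Glu and Gln jointly (hydrolysis converts
#' Gln to Glu before derivatization).
#'
#' @slot counts \code{data.frame} with columns \code{class} (three-letter
#'   code or \code{"Glx"}), \code{nD}, \code{nL}, and logical \code{allo}
#'   (d counts refer to the allo diastereomer, e.g. d-allo-Thr).
#' @export
setClass("MarfeyConstraint", representation(counts = "data.frame"))

setValidity("MarfeyConstraint", function(object) {
  cts <- object@counts
  need <- c("class", "nD", "nL", "allo")
  if (!all(need %in% names(cts)))
    return("counts must have columns class, nD, nL, allo")
  msg <- character()
  bad <- setdiff(cts$class, c(.AA_CODES, "Glx"))
  if (length(bad))
    msg <- c(msg, paste0("unknown residue class(es): ", paste(bad, collapse = ", ")))
  if (anyDuplicated(cts$class))
    msg <- c(msg, "duplicate residue class")
  if (any(cts$nD < 0L) || any(cts$nL < 0L))
    msg <- c(msg, "counts must be non-negative")
  if (any(cts$allo & !cts$class %in% .ALLO_CODES))
    msg <- c(msg, "allo flag only allowed for Thr/Ile classes")
  if (length(msg)) msg else TRUE
})

#' @param ... named per-class counts, each a vector like \code{c(D = 2, L = 2)}.
#' @param allo character vector of classes whose d count is the allo
#'   diastereomer.
#' @return \code{MarfeyConstraint()} returns a \code{MarfeyConstraint}.
#' @examples
#' MarfeyConstraint(Leu = c(D = 2, L = 2), Glu = c(D = 1, L = 0))
#' @rdname MarfeyConstraint-class
#' @export
MarfeyConstraint <- function(..., allo = character()) {
  classes <- list(...)
  if (length(classes) == 1L && is.list(classes[[1L]]) &&
      is.null(names(classes)[1L]))
    classes <- classes[[1L]]
  nm <- names(classes)
  if (is.null(nm)) nm <- character(0)
  cts <- data.frame(
    class = as.character(nm),
    nD = vapply(classes, function(x) as.integer(x[["D"]]), integer(1)),
    nL = vapply(classes, function(x) as.integer(x[["L"]]), integer(1)),
    stringsAsFactors = FALSE)
  cts$allo <- cts$class %in% allo
  rownames(cts) <- NULL
  new("MarfeyConstraint", counts = cts)
}

## ---------------------------------------------------------------------------
## AcquisitionMeta
## ---------------------------------------------------------------------------

#' NMR acquisition metadata
#'
#' Conditions under which a fingerprint was recorded. Chemical shifts are
#' strongly solvent- and temperature-dependent, so fingerprints are only
#' compared when recorded under compatible conditions; these fields are
#' stored, never inferred.
#'
#' @slot solvent deuterated solvent, from a controlled vocabulary.
#' @slot temperatureK sample temperature in kelvin.
#' @slot fieldMHz spectrometer 1H frequency in MHz.
#' @slot referencingNote free-text chemical-shift referencing note.
#' @export
setClass("AcquisitionMeta",
  representation(solvent = "character", temperatureK = "numeric",
                 fieldMHz = "numeric", referencingNote = "character"))

setValidity("AcquisitionMeta", function(object) {
  msg <- character()
  if (!object@solvent %in% .SOLVENTS)
    msg <- c(msg, paste0("unknown solvent '", object@solvent, "' (known: ",
                         paste(.SOLVENTS, collapse = ", "), ")"))
  if (is.na(object@temperatureK) || object@temperatureK < 260 ||
      object@temperatureK > 340)
    msg <- c(msg, "temperatureK outside the plausible range [260, 340]")
  if (!is.na(object@fieldMHz) && object@fieldMHz <= 0)
    msg <- c(msg, "fieldMHz must be positive")
  if (length(msg)) msg else TRUE
})

#' @param solvent,temperatureK,fieldMHz,referencingNote see slots.
#' @return \code{AcquisitionMeta()} returns an \code{AcquisitionMeta}.
#' @rdname AcquisitionMeta-class
#' @export
AcquisitionMeta <- function(solvent, temperatureK, fieldMHz = NA_real_,
                            referencingNote = NA_character_) {
  new("AcquisitionMeta", solvent = as.character(solvent),
      temperatureK = as.numeric(temperatureK),
      fieldMHz = as.numeric(fieldMHz),
      referencingNote = as.character(referencingNote))
}

## ---------------------------------------------------------------------------
## Fingerprint
## ---------------------------------------------------------------------------

#' HSQC chemical-shift fingerprint
#'
#' A set of 1H-13C HSQC cross-peaks with acquisition metadata. In the
#' \code{"CHalpha"} region the peaks are the backbone Calpha-Halpha
#' correlations (one per residue) plus the fatty-acyl CHbeta methine -- the
#' cross-peaks most sensitive to backbone stereochemistry.
#'
#' @slot peaks \code{data.frame} with columns \code{tag} (\code{"AA"},
#'   \code{"FA"} or \code{NA} for unassigned), \code{position} (residue
#'   number, \code{NA} for FA/unassigned), \code{atomPair} (e.g.
#'   \code{"CA-HA"}), \code{deltaH}, \code{deltaC} (ppm), \code{intensity}.
#' @slot meta an \linkS4class{AcquisitionMeta}.
#' @slot region \code{"CHalpha"} or \code{"full"}.
#' @slot compoundName free text.
#' @export
setClass("Fingerprint",
  representation(peaks = "data.frame", meta = "AcquisitionMeta",
                 region = "character", compoundName = "character"))

setValidity("Fingerprint", function(object) {
  pk <- object@peaks
  need <- c("tag", "position", "atomPair", "deltaH", "deltaC", "intensity")
  if (!all(need %in% names(pk)))
    return("peaks must have columns tag, position, atomPair, deltaH, deltaC, intensity")
  msg <- character()
  if (nrow(pk) < 1L) msg <- c(msg, "a fingerprint needs at least one peak")
  if (any(pk$deltaH < -2 | pk$deltaH > 12, na.rm = TRUE))
    msg <- c(msg, "delta_H out of range [-2, 12] ppm")
  if (any(pk$deltaC < 0 | pk$deltaC > 220, na.rm = TRUE))
    msg <- c(msg, "delta_C out of range [0, 220] ppm")
  if (any(is.na(pk$deltaH)) || any(is.na(pk$deltaC)))
    msg <- c(msg, "peaks must have both delta_H and delta_C")
  if (!object@region %in% c("CHalpha", "full"))
    msg <- c(msg, "region must be 'CHalpha' or 'full'")
  if (object@region == "CHalpha") {
    lab <- !is.na(pk$tag)
    ok <- (pk$tag %in% "AA" & pk$atomPair %in% "CA-HA") |
          (pk$tag %in% "FA" & pk$atomPair %in% c("CB-HB", "CA-HA"))
    if (any(lab & !ok))
      msg <- c(msg, "CHalpha region allows only residue CA-HA peaks and the fatty-acyl CB-HB/CA-HA")
  }
  if (length(msg)) msg else TRUE
})

#' @param peaks,meta,region,compoundName see slots.
#' @return \code{Fingerprint()} returns a \code{Fingerprint}.
#' @rdname Fingerprint-class
#' @export
Fingerprint <- function(peaks, meta, region = "CHalpha",
                        compoundName = NA_character_) {
  if (is.null(peaks$intensity)) peaks$intensity <- NA_real_
  if (is.null(peaks$tag)) peaks$tag <- NA_character_
  if (is.null(peaks$position)) peaks$position <- NA_integer_
  if (is.null(peaks$atomPair)) peaks$atomPair <- NA_character_
  peaks$position <- as.integer(peaks$position)
  rownames(peaks) <- NULL
  new("Fingerprint",
      peaks = peaks[c("tag", "position", "atomPair", "deltaH", "deltaC",
                      "intensity")],
      meta = meta, region = region, compoundName = as.character(compoundName))
}

## ---------------------------------------------------------------------------
## ReferenceRecord
## ---------------------------------------------------------------------------

#' Reference-library record
#'
#' One entry of a fingerprint reference library: a fingerprint, the
#' associated lipopeptide sequence (whose stereochemistry may be unknown),
#' and provenance. Dereplication against such records works irrespective of
#' the stereochemical characterization of the reference, but a query matching
#' an \code{"elucidated"} record inherits its stereo assignment.
#'
#' @slot id unique record identifier.
#' @slot fingerprint a \linkS4class{Fingerprint}.
#' @slot sequence a \linkS4class{Lipopeptide}.
#' @slot provenance non-empty citation / DOI / producer strain.
#' @slot stereoStatus \code{"elucidated"}, \code{"partial"} or
#'   \code{"unknown"}.
#' @export
setClass("ReferenceRecord",
  representation(id = "character", fingerprint = "Fingerprint",
                 sequence = "Lipopeptide", provenance = "character",
                 stereoStatus = "character"))

setValidity("ReferenceRecord", function(object) {
  msg <- character()
  if (!nzchar(object@id)) msg <- c(msg, "id must be non-empty")
  if (is.na(object@provenance) || !nzchar(object@provenance))
    msg <- c(msg, "provenance must be non-empty")
  if (!object@stereoStatus %in% c("elucidated", "partial", "unknown"))
    msg <- c(msg, "stereoStatus must be elucidated/partial/unknown")
  cfg <- object@sequence@residues$config
  if (object@stereoStatus == "elucidated" && any(cfg == "unknown"))
    msg <- c(msg, "stereoStatus 'elucidated' requires all residue configs known")
  if (object@stereoStatus == "unknown" && all(cfg != "unknown") &&
      nrow(object@sequence@residues) > 1L)
    msg <- c(msg, "stereoStatus 'unknown' but every residue config is assigned")
  if (length(msg)) msg else TRUE
})

#' @param id,fingerprint,sequence,provenance,stereoStatus see slots.
#' @return \code{ReferenceRecord()} returns a \code{ReferenceRecord}.
#' @rdname ReferenceRecord-class
#' @export
ReferenceRecord <- function(id, fingerprint, sequence, provenance,
                            stereoStatus = "unknown") {
  new("ReferenceRecord", id = as.character(id), fingerprint = fingerprint,
      sequence = sequence, provenance = as.character(provenance),
      stereoStatus = as.character(stereoStatus))
}

## ---------------------------------------------------------------------------
## MatchReport / ScreenReport
## ---------------------------------------------------------------------------

#' Fingerprint match report
#'
#' Result of the quantitative comparison of two fingerprints: the peak
#' pairing, per-pair composite shift distances, summary statistics and a
#' verdict.
#'
#' @slot pairs \code{data.frame} of paired peaks with per-pair composite
#'   distance (column \code{delta}).
#' @slot unmatchedQuery,unmatchedRef peaks left unpaired on either side.
#' @slot rmsd root-mean-square composite distance over pairs (ppm).
#' @slot maxDev largest per-pair composite distance (ppm).
#' @slot nOver number of pairs above the overlap threshold.
#' @slot coverage matched fraction of peaks.
#' @slot conditionsCompatible whether acquisition conditions allow comparison.
#' @slot verdict \code{"match"}, \code{"mismatch"}, \code{"ambiguous"} or
#'   \code{"incomparable"}.
#' @slot offsets global (H, C) offsets subtracted before scoring (0 when
#'   offset correction is off).
#' @slot params the \code{\link{matchParams}} used.
#' @export
setClass("MatchReport",
  representation(pairs = "data.frame", unmatchedQuery = "data.frame",
                 unmatchedRef = "data.frame", rmsd = "numeric",
                 maxDev = "numeric", nOver = "integer", coverage = "numeric",
                 conditionsCompatible = "logical", verdict = "character",
                 offsets = "numeric", params = "list"))

setValidity("MatchReport", function(object) {
  msg <- character()
  if (!object@verdict %in% c("match", "mismatch", "ambiguous", "incomparable"))
    msg <- c(msg, "invalid verdict")
  if ((object@verdict == "incomparable") != !object@conditionsCompatible)
    msg <- c(msg, "verdict 'incomparable' iff conditions incompatible")
  if (!is.na(object@rmsd) && !is.na(object@maxDev) &&
      object@rmsd > object@maxDev + 1e-12)
    msg <- c(msg, "rmsd cannot exceed maxDev")
  if (object@nOver > nrow(object@pairs))
    msg <- c(msg, "nOver cannot exceed the number of pairs")
  if (length(msg)) msg else TRUE
})

#' Library screening report
#'
#' Result of screening a query fingerprint against a reference library:
#' per-record match reports ranked best-first, the dereplication decision,
#' and any records skipped for incompatible acquisition conditions.
#'
#' @slot results ranked \code{data.frame} (id, verdict, rmsd, maxDev, nOver,
#'   coverage).
#' @slot reports named list of \linkS4class{MatchReport}s.
#' @slot bestId id of the top-ranked record, or \code{NA}.
#' @slot decision \code{"known"}, \code{"novel"} or \code{"inconclusive"}.
#' @slot skipped \code{data.frame} (id, reason) of condition-incompatible
#'   records.
#' @slot transferredStereo config string inherited from a matching
#'   elucidated record, else \code{NA}.
#' @slot notes character vector of warnings (e.g. empty library).
#' @export
setClass("ScreenReport",
  representation(results = "data.frame", reports = "list",
                 bestId = "character", decision = "character",
                 skipped = "data.frame", transferredStereo = "character",
                 notes = "character"))

setValidity("ScreenReport", function(object) {
  msg <- character()
  if (!object@decision %in% c("known", "novel", "inconclusive"))
    msg <- c(msg, "invalid decision")
  if ((object@decision == "known") !=
      any(object@results$verdict == "match"))
    msg <- c(msg, "decision 'known' iff some verdict is 'match'")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ShiftModel
## ---------------------------------------------------------------------------

#' Synthetic (C-H)alpha shift model
#'
#' Generative model for assigned HSQC fingerprints used as the validation
#' substrate: each residue's Calpha-Halpha cross-peak sits at a random-coil
#' style base position, displaced by a deterministic stereochemistry term and
#' Gaussian measurement noise. The stereochemistry term is a seeded hash of
#' the local d/l environment (residue codes and configs within
#' \code{window} positions, plus the fatty-acyl C3 configuration near the
#' N-terminus), scaled by \code{stereoEffect} -- so inverting one center
#' displaces exactly the peaks within \code{window} of it.
#'
#' @slot baseTable per-code (deltaC, deltaH) base positions (ppm).
#' @slot stereoEffect named numeric \code{c(C=, H=)}: perturbation magnitude
#'   (ppm).
#' @slot window integer residue radius of the stereo perturbation.
#' @slot noise named numeric \code{c(C=, H=)}: measurement-noise sd (ppm).
#' @slot seed integer seed of the deterministic perturbation field.
#' @export
setClass("ShiftModel",
  representation(baseTable = "data.frame", stereoEffect = "numeric",
                 window = "integer", noise = "numeric", seed = "integer"))

setValidity("ShiftModel", function(object) {
  msg <- character()
  if (!all(c("code", "deltaC", "deltaH") %in% names(object@baseTable)))
    msg <- c(msg, "baseTable needs columns code, deltaC, deltaH")
  if (!all(c("C", "H") %in% names(object@stereoEffect)) ||
      any(object@stereoEffect <= 0))
    msg <- c(msg, "stereoEffect must be positive, named c(C=, H=)")
  if (!all(c("C", "H") %in% names(object@noise)) || any(object@noise < 0))
    msg <- c(msg, "noise must be non-negative, named c(C=, H=)")
  if (object@window < 0L) msg <- c(msg, "window must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param stereoEffect,window,noise,seed,baseTable see slots. Defaults:
#'   stereo effect 0.4 ppm (13C) / 0.08 ppm (1H); noise 0.01 / 0.002 ppm,
#'   typical same-instrument HSQC peak-position reproducibility; window 1.
#' @return \code{ShiftModel()} returns a \code{ShiftModel}.
#' @rdname ShiftModel-class
#' @export
ShiftModel <- function(stereoEffect = c(C = 0.4, H = 0.08), window = 1L,
                       noise = c(C = 0.01, H = 0.002), seed = 1L,
                       baseTable = .BASE_SHIFTS) {
  new("ShiftModel", baseTable = baseTable,
      stereoEffect = stereoEffect, window = as.integer(window),
      noise = noise, seed = as.integer(seed))
}
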