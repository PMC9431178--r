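#' Accessors for clipmatch classes
#'
#' Small accessor methods: \code{residues()}, \code{fattyAcyl()},
#' \code{esterDonor()} and \code{configString()} for
#' \linkS4class{Lipopeptide}; \code{modules()} for
#' \linkS4class{DomainArchitecture}; \code{peaks()} and \code{acquisition()}
#' for \linkS4class{Fingerprint}; \code{verdict()} and \code{rmsd()} for
#' \linkS4class{MatchReport}; \code{decision()}, \code{bestId()} and
#' \code{screenResults()} for \linkS4class{ScreenReport}.
#'
#' @param x an object of the documented class.
#' @return the corresponding slot value; \code{configString(x)} collapses
#'   residue configurations to compact \code{"D"}/\code{"L"} letters
#'   (allo diastereomers count with their d/l parent).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("residues", "Lipopeptide", function(x) x@residues)

#' @rdname accessors
#' @export
setMethod("fattyAcyl", "Lipopeptide", function(x) x@fattyAcyl)

#' @rdname accessors
#' @export
setMethod("esterDonor", "Lipopeptide", function(x) x@esterDonorPosition)

#' @rdname accessors
#' @export
setMethod("configString", "Lipopeptide",
          function(x) .collapseConfig(x@residues$config))

#' @rdname accessors
#' @export
setMethod("modules", "DomainArchitecture", function(x) x@modules)

#' @rdname accessors
#' @export
setMethod("peaks", "Fingerprint", function(x) x@peaks)

#' @rdname accessors
#' @export
setMethod("acquisition", "Fingerprint", function(x) x@meta)

#' @rdname accessors
#' @export
setMethod("verdict", "MatchReport", function(x) x@verdict)

#' @rdname accessors
#' @export
setMethod("rmsd", "MatchReport", function(x) x@rmsd)

#' @rdname accessors
#' @export
setMethod("decision", "ScreenReport", function(x) x@decision)

#' @rdname accessors
#' @export
setMethod("bestId", "ScreenReport", function(x) x@bestId)

#' @rdname accessors
#' @export
screenResults <- function(x) {
  stopifnot(is(x, "ScreenReport"))
  x@results
}

## collapse config labels to single letters; allo folds onto its d/l parent
.collapseConfig <- function(config) {
  paste(ifelse(.isConfigD(config), "D",
        ifelse(.isConfigL(config), "L", "?")), collapse = "")
}

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "FattyAcyl", function(object) {
  oh <- if (is.na(object@hydroxylPosition)) ""
        else sprintf("%d%s-OH ",
                     object@hydroxylPosition,
                     if (object@c3Config == "unknown") "" else object@c3Config)
  cat(sprintf("FattyAcyl: %sC%d:0\n", oh, object@chainLength))
})

setMethod("show", "Lipopeptide", function(object) {
  res <- object@residues
  lab <- ifelse(res$config == "unknown", res$code,
                paste0(sub("^(.)-?a.*", "\\1-a", sub("-allo", "-a", res$config)),
                       "-", res$code))
  lm <- tryCatch(classifyLM(object), error = function(e) NULL)
  head <- if (is.null(lm)) "linear"
          else sprintf("(%d:%d)", lm[["l"]], lm[["m"]])
  cat(sprintf("Lipopeptide '%s' %s, %d residues\n", object@name, head,
              nrow(res)))
  cat(" ", paste(lab, collapse = " - "), "\n")
  show(object@fattyAcyl)
  if (!is.na(object@esterDonorPosition))
    cat(sprintf("  ester bond: %s%d side chain -> C-terminus\n",
                res$code[object@esterDonorPosition], object@esterDonorPosition))
})

setMethod("show", "DomainArchitecture", function(object) {
  cat(sprintf("DomainArchitecture, %d modules: %s\n", length(object@modules),
              paste(object@modules, collapse = " ")))
})

setMethod("show", "MarfeyConstraint", function(object) {
  cat("MarfeyConstraint:\n")
  cts <- object@counts
  for (i in seq_len(nrow(cts)))
    cat(sprintf("  %s: %d D%s : %d L\n", cts$class[i], cts$nD[i],
                if (cts$allo[i]) "-allo" else "", cts$nL[i]))
})

setMethod("show", "Fingerprint", function(object) {
  cat(sprintf("Fingerprint '%s' [%s], %d peaks; %s, %.0f K%s\n",
              object@compoundName, object@region, nrow(object@peaks),
              object@meta@solvent, object@meta@temperatureK,
              if (is.na(object@meta@fieldMHz)) ""
              else sprintf(", %.0f MHz", object@meta@fieldMHz)))
})

setMethod("show", "MatchReport", function(object) {
  cat(sprintf("MatchReport: verdict %s\n", object@verdict))
  cat(sprintf("  pairs %d (coverage %.2f), rmsd %.4f ppm, max dev %.4f ppm, %d over threshold\n",
              nrow(object@pairs), object@coverage, object@rmsd, object@maxDev,
              object@nOver))
  if (any(object@offsets != 0))
    cat(sprintf("  offset correction applied: dH %.4f, dC %.4f ppm\n",
                object@offsets[["H"]], object@offsets[["C"]]))
})

setMethod("show", "ScreenReport", function(object) {
  cat(sprintf("ScreenReport: decision %s%s\n", object@decision,
              if (is.na(object@bestId)) ""
              else sprintf(" (best: %s)", object@bestId)))
  if (nrow(object@results)) print(object@results, row.names = FALSE)
  if (nrow(object@skipped))
    cat(sprintf("  skipped %d record(s) for incompatible conditions\n",
                nrow(object@skipped)))
  for (n in object@notes) cat("  note:", n, "\n")
})
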