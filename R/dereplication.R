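# Library screening: has this lipopeptide been isolated before?

#' Screen a query fingerprint against a reference library
#'
#' Scores the query against every condition-compatible record and ranks by
#' verdict class (match < ambiguous < mismatch), then ascending rmsd, ties
#' broken by record id. The decision is \code{"known"} iff at least one
#' verdict is a match; \code{"inconclusive"} when the best verdict is
#' ambiguous; otherwise \code{"novel"}. Records recorded under incompatible
#' conditions are reported as skipped, never silently dropped -- a "novel"
#' decision reached while references had to be skipped is downgraded to
#' \code{"inconclusive"}. An empty library yields \code{"novel"} with an
#' explicit warning note.
#'
#' When the decision is \code{"known"} and the matched record has
#' \code{stereoStatus = "elucidated"}, the query inherits that record's
#' configuration string (\code{transferredStereo}): matching an elucidated
#' reference settles the query's stereochemistry without any new chemistry.
#'
#' @param query a \linkS4class{Fingerprint}.
#' @param library list of \linkS4class{ReferenceRecord}s.
#' @param params see \code{\link{matchParams}}.
#' @return a \linkS4class{ScreenReport}.
#' @export
screenLibrary <- function(query, library, params = matchParams()) {
  notes <- character(0)
  if (!length(library)) {
    notes <- c(notes, "empty library: novelty cannot be cross-checked")
    warning("screening against an empty library", call. = FALSE)
  }
  ids <- vapply(library, function(r) r@id, character(1))
  if (anyDuplicated(ids))
    .stopf("duplicate record id(s): %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))

  reports <- list()
  skipped <- data.frame(id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (r in library) {
    rep <- scoreMatch(query, r@fingerprint, params)
    if (!rep@conditionsCompatible) {
      skipped <- rbind(skipped, data.frame(
        id = r@id, reason = paste(rep@params$conditionNotes, collapse = "; "),
        stringsAsFactors = FALSE))
    } else {
      reports[[r@id]] <- rep
    }
  }

  if (length(reports)) {
    results <- do.call(rbind, lapply(names(reports), function(id) {
      rep <- reports[[id]]
      data.frame(id = id, verdict = rep@verdict, rmsd = rep@rmsd,
                 maxDev = rep@maxDev, nOver = rep@nOver,
                 coverage = rep@coverage, stringsAsFactors = FALSE)
    }))
    vclass <- match(results$verdict, c("match", "ambiguous", "mismatch"))
    results <- results[order(vclass, results$rmsd, results$id,
                             method = "radix"), , drop = FALSE]
    rownames(results) <- NULL
  } else {
    results <- data.frame(id = character(0), verdict = character(0),
                          rmsd = numeric(0), maxDev = numeric(0),
                          nOver = integer(0), coverage = numeric(0),
                          stringsAsFactors = FALSE)
  }

  decision <- if (any(results$verdict == "match")) "known"
    else if (nrow(results) && results$verdict[1L] == "ambiguous") "inconclusive"
    else "novel"
  if (decision == "novel" && nrow(skipped)) {
    decision <- "inconclusive"
    notes <- c(notes, sprintf(
      "%d reference(s) skipped for incompatible conditions; novelty downgraded to inconclusive",
      nrow(skipped)))
  }

  bestId <- if (nrow(results)) results$id[1L] else NA_character_
  transferred <- NA_character_
  if (decision == "known") {
    best <- library[[match(bestId, ids)]]
    if (best@stereoStatus == "elucidated")
      transferred <- configString(best@sequence)
  }
  new("ScreenReport", results = results, reports = reports,
      bestId = bestId, decision = decision, skipped = skipped,
      transferredStereo = transferred, notes = notes)
}

#' Export a screening report as JSON
#'
#' @param report a \linkS4class{ScreenReport}.
#' @param path output path.
#' @export
writeScreenReport <- function(report, path) {
  doc <- list(
    schema = "clipmatch-report/1",
    decision = report@decision,
    best_id = if (is.na(report@bestId)) NULL else report@bestId,
    transferred_stereo = if (is.na(report@transferredStereo)) NULL
                         else report@transferredStereo,
    results = report@results,
    skipped = report@skipped,
    notes = report@notes)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
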