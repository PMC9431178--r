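# Peak-list readers/writers (TSV and Sparky-list dialects) and the JSON
# reference-library format ("clipmatch-lib/1").
#
# TSV dialect: comment lines "#key=value" (solvent, temp_K, field_MHz,
# optional compound, region, referencing), then a mandatory header
# "label<TAB>delta_H<TAB>delta_C[<TAB>intensity]". Labels are "AA<pos>",
# "AA<pos>:<atomPair>", "FA", "FA:<atomPair>", or empty for unassigned
# peaks.
#
# Sparky dialect: the assignment column uses single-letter residue codes,
# e.g. "L4CA-HA"; "FA" is reserved for the fatty-acyl peak. Column order is
# delta_C then delta_H (the w1/w2 convention of a 13C HSQC list). The same
# "#key=value" comment lines carry acquisition metadata.

.parseMetaComments <- function(lines) {
  kv <- list()
  for (ln in grep("^#", lines, value = TRUE)) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) kv[[m[2L]]] <- trimws(m[3L])
  }
  kv
}

.metaFromComments <- function(kv, meta) {
  if (!is.null(meta)) return(meta)
  if (is.null(kv$solvent) || is.null(kv$temp_K))
    stop("missing acquisition metadata: provide meta= or #solvent=/#temp_K= header comments",
         call. = FALSE)
  AcquisitionMeta(kv$solvent, as.numeric(kv$temp_K),
                  if (is.null(kv$field_MHz)) NA_real_ else as.numeric(kv$field_MHz),
                  if (is.null(kv$referencing)) NA_character_ else kv$referencing)
}

.parseTsvLabel <- function(label) {
  if (!nzchar(label))
    return(list(tag = NA_character_, position = NA_integer_,
                atomPair = NA_character_))
  parts <- strsplit(label, ":", fixed = TRUE)[[1L]]
  head <- parts[1L]
  if (grepl("^FA$", head))
    return(list(tag = "FA", position = NA_integer_,
                atomPair = if (length(parts) > 1L) parts[2L] else "CB-HB"))
  m <- regmatches(head, regexec("^AA(\\d+)$", head))[[1L]]
  if (length(m) != 2L)
    .stopf("cannot parse peak label '%s'", label)
  list(tag = "AA", position = as.integer(m[2L]),
       atomPair = if (length(parts) > 1L) parts[2L] else "CA-HA")
}

.parseSparkyLabel <- function(label) {
  if (label %in% c("?", "?-?", ""))
    return(list(tag = NA_character_, position = NA_integer_,
                atomPair = NA_character_))
  fa <- regmatches(label,
                   regexec("^FA\\d*([A-Z]+\\d*-[A-Z]+\\d*)$", label))[[1L]]
  if (length(fa) == 2L)
    return(list(tag = "FA", position = NA_integer_, atomPair = fa[2L]))
  m <- regmatches(label,
                  regexec("^([A-Za-z])(\\d+)([A-Z]+\\d*-[A-Z]+\\d*)$",
                          label))[[1L]]
  if (length(m) != 4L)
    .stopf("cannot parse Sparky assignment '%s'", label)
  list(tag = "AA", position = as.integer(m[3L]), atomPair = m[4L])
}

.checkShiftRow <- function(dH, dC, lineno) {
  if (is.na(dH) || is.na(dC))
    .stopf("line %d: missing chemical shift value", lineno)
  if (dH < -2 || dH > 12)
    .stopf("line %d: delta_H out of range (%.3f ppm, plausible [-2, 12])",
           lineno, dH)
  if (dC < 0 || dC > 220)
    .stopf("line %d: delta_C out of range (%.3f ppm, plausible [0, 220])",
           lineno, dC)
  invisible(TRUE)
}

#' Read an HSQC peak list
#'
#' Parses a peak list in either the tab-separated dialect or the
#' Sparky-list dialect (see the format notes in this file's help index;
#' Sparky columns are delta_C then delta_H per the w1/w2 convention of a
#' 13C HSQC). Every data row becomes one peak; rows are never silently
#' dropped -- malformed rows or implausible shifts raise an error carrying
#' the line number.
#'
#' @param path file path (or a character vector of lines).
#' @param dialect \code{"tsv"} or \code{"sparky"}.
#' @param meta an \linkS4class{AcquisitionMeta}; if \code{NULL}, read from
#'   \code{#key=value} comment lines.
#' @param region,compoundName overrides for the fingerprint fields;
#'   defaults come from \code{#region=}/\code{#compound=} comments, else
#'   \code{"CHalpha"} / \code{NA}.
#' @return a \linkS4class{Fingerprint}.
#' @export
readPeaklist <- function(path, dialect = c("tsv", "sparky"), meta = NULL,
                         region = NULL, compoundName = NULL) {
  dialect <- match.arg(dialect)
  lines <- if (length(path) == 1L && file.exists(path))
    readLines(path, warn = FALSE) else path
  kv <- .parseMetaComments(lines)
  meta <- .metaFromComments(kv, meta)
  if (is.null(region))
    region <- if (!is.null(kv$region)) kv$region else "CHalpha"
  if (is.null(compoundName))
    compoundName <- if (!is.null(kv$compound)) kv$compound else NA_character_
  body <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(body)) stop("peak list contains no data", call. = FALSE)

  if (dialect == "tsv") {
    hdr <- strsplit(lines[body[1L]], "\t", fixed = TRUE)[[1L]]
    need <- c("label", "delta_H", "delta_C")
    if (!all(need %in% hdr))
      .stopf("missing mandatory column(s): %s",
             paste(setdiff(need, hdr), collapse = ", "))
    rows <- body[-1L]
    pk <- do.call(rbind, lapply(rows, function(i) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
      length(f) <- length(hdr)
      f <- setNames(f, hdr)
      lab <- .parseTsvLabel(if (is.na(f[["label"]])) "" else f[["label"]])
      dH <- suppressWarnings(as.numeric(f[["delta_H"]]))
      dC <- suppressWarnings(as.numeric(f[["delta_C"]]))
      .checkShiftRow(dH, dC, i)
      data.frame(tag = lab$tag, position = lab$position,
                 atomPair = lab$atomPair, deltaH = dH, deltaC = dC,
                 intensity = if ("intensity" %in% hdr)
                   suppressWarnings(as.numeric(f[["intensity"]]))
                 else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  } else {
    rows <- body
    first <- strsplit(trimws(lines[rows[1L]]), "\\s+")[[1L]]
    if (identical(tolower(first[1L]), "assignment")) rows <- rows[-1L]
    pk <- do.call(rbind, lapply(rows, function(i) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
      if (length(f) < 3L)
        .stopf("line %d: expected 'assignment w1 w2' fields", i)
      lab <- .parseSparkyLabel(f[1L])
      dC <- suppressWarnings(as.numeric(f[2L]))  # w1 = 13C
      dH <- suppressWarnings(as.numeric(f[3L]))  # w2 = 1H
      .checkShiftRow(dH, dC, i)
      data.frame(tag = lab$tag, position = lab$position,
                 atomPair = lab$atomPair, deltaH = dH, deltaC = dC,
                 intensity = if (length(f) >= 4L)
                   suppressWarnings(as.numeric(f[4L])) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  Fingerprint(pk, meta, region = region, compoundName = compoundName)
}

.formatTsvLabel <- function(pk) {
  vapply(seq_len(nrow(pk)), function(i) {
    if (is.na(pk$tag[i])) ""
    else if (pk$tag[i] == "FA") paste0("FA:", pk$atomPair[i])
    else paste0("AA", pk$position[i], ":", pk$atomPair[i])
  }, character(1))
}

#' @param fp a \linkS4class{Fingerprint}.
#' @param digits decimal places for shifts on write.
#' @rdname readPeaklist
#' @export
writePeaklist <- function(fp, path, dialect = c("tsv", "sparky"),
                          digits = 4L) {
  dialect <- match.arg(dialect)
  m <- fp@meta
  hdr <- c(sprintf("#solvent=%s", m@solvent),
           sprintf("#temp_K=%g", m@temperatureK),
           if (!is.na(m@fieldMHz)) sprintf("#field_MHz=%g", m@fieldMHz),
           if (!is.na(m@referencingNote))
             sprintf("#referencing=%s", m@referencingNote),
           sprintf("#region=%s", fp@region),
           if (!is.na(fp@compoundName))
             sprintf("#compound=%s", fp@compoundName))
  pk <- fp@peaks
  fmt <- function(x) formatC(x, digits = digits, format = "f")
  if (dialect == "tsv") {
    lines <- c(hdr, paste("label", "delta_H", "delta_C", "intensity",
                          sep = "\t"),
               paste(.formatTsvLabel(pk), fmt(pk$deltaH), fmt(pk$deltaC),
                     ifelse(is.na(pk$intensity), "", pk$intensity),
                     sep = "\t"))
  } else {
    lab <- vapply(seq_len(nrow(pk)), function(i) {
      if (is.na(pk$tag[i])) "?-?"
      else if (pk$tag[i] == "FA") paste0("FA", pk$atomPair[i])
      else paste0(substr(pk$tag[i], 1L, 1L), pk$position[i], pk$atomPair[i])
    }, character(1))
    lines <- c(hdr, "Assignment w1 w2",
               sprintf("%-14s %9s %9s", lab, fmt(pk$deltaC), fmt(pk$deltaH)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Build a fingerprint from tabulated chemical shifts
#'
#' Literature reports often tabulate assigned Calpha/Halpha shifts rather
#' than depositing spectra; this turns such a table into a fingerprint that
#' can be matched like any other (the route used to dereplicate compounds
#' reported only as shift tables).
#'
#' @param rows \code{data.frame} with columns \code{position},
#'   \code{deltaH}, \code{deltaC}; optional \code{atomPair} (default
#'   \code{"CA-HA"}) and \code{tag} (default \code{"AA"}; use \code{"FA"}
#'   with \code{position = NA} for the fatty-acyl methine).
#' @param meta an \linkS4class{AcquisitionMeta}.
#' @param compoundName free text.
#' @return a \linkS4class{Fingerprint} with one peak per row.
#' @export
fingerprintFromShiftTable <- function(rows, meta,
                                      compoundName = NA_character_) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L)
  if (is.null(rows$atomPair)) rows$atomPair <- "CA-HA"
  if (is.null(rows$tag)) rows$tag <- "AA"
  miss <- rows$position[is.na(rows$deltaH) | is.na(rows$deltaC)]
  if (length(miss))
    .stopf("missing Calpha/Halpha shift for position(s): %s",
           paste(miss, collapse = ", "))
  key <- paste(rows$tag, rows$position, rows$atomPair)
  if (anyDuplicated(key))
    .stopf("duplicate (position, atom) entries: %s",
           paste(unique(key[duplicated(key)]), collapse = "; "))
  rows$intensity <- NA_real_
  Fingerprint(rows, meta, region = "CHalpha", compoundName = compoundName)
}

## ---------------------------------------------------------------------------
## Reference library JSON ("clipmatch-lib/1")
## ---------------------------------------------------------------------------

.LIB_SCHEMA <- "clipmatch-lib/1"

.fingerprintToList <- function(fp) {
  m <- fp@meta
  list(
    compound_name = if (is.na(fp@compoundName)) NULL else fp@compoundName,
    region = fp@region,
    meta = list(solvent = m@solvent, temp_K = m@temperatureK,
                field_MHz = if (is.na(m@fieldMHz)) NULL else m@fieldMHz,
                referencing = if (is.na(m@referencingNote)) NULL
                              else m@referencingNote),
    peaks = lapply(seq_len(nrow(fp@peaks)), function(i) {
      p <- fp@peaks[i, ]
      c(if (!is.na(p$tag)) list(tag = p$tag),
        if (!is.na(p$position)) list(position = p$position),
        if (!is.na(p$atomPair)) list(atom_pair = p$atomPair),
        list(delta_H = round(p$deltaH, 5), delta_C = round(p$deltaC, 5)),
        if (!is.na(p$intensity)) list(intensity = p$intensity))
    }))
}

.fingerprintFromList <- function(doc, where) {
  for (f in c("region", "meta", "peaks"))
    if (is.null(doc[[f]])) .stopf("%s: missing field '%s'", where, f)
  m <- doc$meta
  for (f in c("solvent", "temp_K"))
    if (is.null(m[[f]])) .stopf("%s: meta missing field '%s'", where, f)
  pk <- do.call(rbind, lapply(seq_along(doc$peaks), function(i) {
    p <- doc$peaks[[i]]
    for (f in c("delta_H", "delta_C"))
      if (is.null(p[[f]]))
        .stopf("%s: peak %d missing field '%s'", where, i, f)
    data.frame(
      tag = if (is.null(p$tag)) NA_character_ else p$tag,
      position = if (is.null(p$position)) NA_integer_ else as.integer(p$position),
      atomPair = if (is.null(p$atom_pair)) NA_character_ else p$atom_pair,
      deltaH = p$delta_H, deltaC = p$delta_C,
      intensity = if (is.null(p$intensity)) NA_real_ else p$intensity,
      stringsAsFactors = FALSE)
  }))
  Fingerprint(pk,
              AcquisitionMeta(m$solvent, m$temp_K,
                              if (is.null(m$field_MHz)) NA_real_ else m$field_MHz,
                              if (is.null(m$referencing)) NA_character_
                              else m$referencing),
              region = doc$region,
              compoundName = if (is.null(doc$compound_name)) NA_character_
                             else doc$compound_name)
}

#' Read / write a fingerprint reference library
#'
#' The library is a versioned JSON document (schema tag
#' \code{"clipmatch-lib/1"}) holding \linkS4class{ReferenceRecord}s. All
#' fields are validated on read and errors name the offending record and
#' field; \code{writeLibrary} then \code{readLibrary} is the identity to
#' 1e-4 ppm.
#'
#' @param path JSON file path.
#' @return \code{readLibrary()} returns a list of
#'   \linkS4class{ReferenceRecord}s.
#' @export
readLibrary <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$schema, .LIB_SCHEMA))
    .stopf("library schema must be '%s' (found '%s')", .LIB_SCHEMA,
           if (is.null(doc$schema)) "<missing>" else doc$schema)
  if (is.null(doc$records)) stop("library missing field 'records'", call. = FALSE)
  lapply(seq_along(doc$records), function(i) {
    r <- doc$records[[i]]
    where <- sprintf("record %d", i)
    for (f in c("id", "provenance", "stereo_status", "sequence", "fingerprint"))
      if (is.null(r[[f]])) .stopf("%s: missing field '%s'", where, f)
    ReferenceRecord(
      id = r$id,
      fingerprint = .fingerprintFromList(r$fingerprint, where),
      sequence = .lipopeptideFromList(r$sequence),
      provenance = r$provenance,
      stereoStatus = r$stereo_status)
  })
}

#' @param records list of \linkS4class{ReferenceRecord}s.
#' @rdname readLibrary
#' @export
writeLibrary <- function(records, path) {
  stopifnot(all(vapply(records, is, logical(1), "ReferenceRecord")))
  for (r in records) validObject(r)
  doc <- list(
    schema = .LIB_SCHEMA,
    records = lapply(records, function(r)
      list(id = r@id, provenance = r@provenance,
           stereo_status = r@stereoStatus,
           sequence = .lipopeptideToList(r@sequence),
           fingerprint = .fingerprintToList(r@fingerprint))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
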