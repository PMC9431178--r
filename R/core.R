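#' Classify a CLiP with the (l:m) notation
#'
#' The (l:m) notation classifies cyclic lipodepsipeptides by their total
#' residue count \eqn{l} and macrocycle size \eqn{m}: the macrocycle runs
#' from the ester-donor residue (whose side-chain hydroxyl closes the
#' lactone) through the C-terminus, so \eqn{m = l - p + 1} for donor position
#' \eqn{p}. Bananamides are (8:6), orfamides (10:8), xantholysins (14:8).
#'
#' @param x a \linkS4class{Lipopeptide} with an ester-donor position.
#' @return named integer vector \code{c(l = , m = )}.
#' @examples
#' classifyLM(bananamideSWRI103()$sequence)  # c(l = 8, m = 6)
#' @rdname classifyLM
#' @export
setMethod("classifyLM", "Lipopeptide", function(x) {
  l <- nrow(x@residues)
  p <- x@esterDonorPosition
  if (is.na(p))
    stop("linear peptide, no (l:m) class", call. = FALSE)
  c(l = l, m = l - p + 1L)
})

## ---------------------------------------------------------------------------
## Elemental formulas and monoisotopic mass
## ---------------------------------------------------------------------------

#' Parse a molecular formula string
#'
#' @param formula a string like \code{"C52H92N8O14"}, or a named numeric
#'   vector of element counts (returned unchanged after validation).
#' @return named integer vector of element counts.
#' @export
parseFormula <- function(formula) {
  if (is.numeric(formula)) {
    counts <- formula
  } else {
    stopifnot(is.character(formula), length(formula) == 1L)
    if (!nzchar(formula)) return(setNames(integer(0), character(0)))
    m <- gregexpr("([A-Z][a-z]?)(\\d*)", formula)
    toks <- regmatches(formula, m)[[1L]]
    if (sum(nchar(toks)) != nchar(formula))
      .stopf("cannot parse formula '%s'", formula)
    el <- sub("\\d+$", "", toks)
    n <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", toks)))
    n[is.na(n)] <- 1L
    counts <- tapply(n, el, sum)
    counts <- setNames(as.numeric(counts), names(counts))
  }
  bad <- setdiff(names(counts), names(.MONO_MASS))
  if (length(bad))
    .stopf("unknown element symbol(s): %s", paste(bad, collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("element counts must be non-negative integers", call. = FALSE)
  setNames(as.integer(counts), names(counts))
}

#' Neutral monoisotopic mass of a molecular formula
#'
#' Sums IUPAC monoisotopic atomic masses (most abundant isotope) over the
#' formula. Reports the neutral mass; no protonation, average mass or
#' isotope-pattern handling. Deterministic to 1e-4 Da.
#'
#' @param formula formula string or named count vector, see
#'   \code{\link{parseFormula}}.
#' @return mass in Da.
#' @examples
#' monoisotopicMass("H2O")        # 18.0106
#' monoisotopicMass("C52H92N8O14")
#' @export
monoisotopicMass <- function(formula) {
  counts <- parseFormula(formula)
  if (!length(counts)) return(0)
  sum(counts * .MONO_MASS[names(counts)])
}

## ---------------------------------------------------------------------------
## Lipopeptide serialization (YAML / JSON)
## ---------------------------------------------------------------------------

.lipopeptideToList <- function(x) {
  fa <- x@fattyAcyl
  list(
    name = x@name,
    producer = if (is.na(x@producer)) NULL else x@producer,
    residues = lapply(seq_len(nrow(x@residues)), function(i)
      list(pos = x@residues$position[i], code = x@residues$code[i],
           config = x@residues$config[i])),
    fatty_acyl = c(list(chain_length = fa@chainLength),
                   if (!is.na(fa@hydroxylPosition))
                     list(hydroxyl_position = fa@hydroxylPosition),
                   list(c3_config = fa@c3Config)),
    ester_donor_position = if (is.na(x@esterDonorPosition)) NULL
                           else x@esterDonorPosition)
}

.lipopeptideFromList <- function(doc) {
  for (f in c("name", "residues", "fatty_acyl"))
    if (is.null(doc[[f]])) .stopf("lipopeptide document missing field '%s'", f)
  res <- do.call(rbind, lapply(doc$residues, function(r) {
    for (f in c("pos", "code"))
      if (is.null(r[[f]])) .stopf("residue entry missing field '%s'", f)
    data.frame(position = as.integer(r$pos), code = r$code,
               config = if (is.null(r$config)) "unknown" else r$config,
               stringsAsFactors = FALSE)
  }))
  fa <- doc$fatty_acyl
  if (is.null(fa$chain_length))
    stop("fatty_acyl missing field 'chain_length'", call. = FALSE)
  Lipopeptide(
    name = doc$name,
    producer = if (is.null(doc$producer)) NA_character_ else doc$producer,
    residues = res,
    fattyAcyl = FattyAcyl(
      fa$chain_length,
      if (is.null(fa$hydroxyl_position)) NA_integer_ else fa$hydroxyl_position,
      if (is.null(fa$c3_config)) "unknown" else fa$c3_config),
    esterDonorPosition = if (is.null(doc$ester_donor_position)) NA_integer_
                         else as.integer(doc$ester_donor_position))
}

#' Read / write lipopeptide descriptions
#'
#' Lipopeptides serialize to a small YAML (or JSON) document with keys
#' \code{name}, \code{producer}, \code{residues} (list of
#' \code{{pos, code, config}}), \code{fatty_acyl}
#' (\code{{chain_length, hydroxyl_position, c3_config}}) and
#' \code{ester_donor_position}. Field presence and values are validated on
#' read; errors name the missing field.
#'
#' @param path file path; format chosen by extension (\code{.json} vs
#'   \code{.yaml}/\code{.yml}).
#' @return \code{readLipopeptide()} returns a \linkS4class{Lipopeptide}.
#' @export
readLipopeptide <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  .lipopeptideFromList(doc)
}

#' @param x a \linkS4class{Lipopeptide}.
#' @rdname readLipopeptide
#' @export
writeLipopeptide <- function(x, path) {
  validObject(x)
  doc <- .lipopeptideToList(x)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else yaml::write_yaml(doc, path)
  invisible(path)
}
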