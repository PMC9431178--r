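# Configuration prediction from NRPS condensation-domain architecture,
# genomic hard constraints, and Marfey-constrained diastereomer enumeration.
#
# The modeling asymmetry exploited throughout: a C/E domain *predicts* d for
# the preceding residue but its epimerization activity can be cryptically
# inactive, so C/E-derived d's are soft evidence. LCL domains lack the
# epimerization machinery altogether, so the residue preceding an LCL module
# -- and the final residue, which no downstream module can epimerize -- are
# *hard* l constraints.

#' Predict residue configurations from the domain architecture
#'
#' During nonribosomal assembly each module's condensation domain appends an
#' l-amino acid; a dual C/E domain additionally epimerizes the preceding
#' residue from l to d. Assuming every C/E domain is active, residue
#' \eqn{i} is predicted d exactly when module \eqn{i+1} carries a C/E
#' domain; the final residue, with no downstream module, stays l.
#'
#' @param arch a \linkS4class{DomainArchitecture}.
#' @param ... unused.
#' @return character vector of \code{"D"}/\code{"L"}, one per residue.
#' @examples
#' arch <- DomainArchitecture(c("Cstart", rep("C/E", 6), "LCL"))
#' predictConfigs(arch)  # D D D D D D L L
#' @rdname predictConfigs
#' @export
setMethod("predictConfigs", "DomainArchitecture", function(arch, ...) {
  mods <- arch@modules
  n <- length(mods)
  cfg <- character(n)
  for (i in seq_len(n)) {
    cfg[i] <- if (i < n) {
      switch(mods[i + 1L], "C/E" = "D", "LCL" = "L",
             .stopf("module %d has unexpected type %s", i + 1L, mods[i + 1L]))
    } else "L"
  }
  cfg
})

#' Hard configuration constraints implied by the architecture
#'
#' Only the *absence* of epimerization machinery yields certainty: the
#' residue immediately preceding an LCL module necessarily retains its
#' l-configuration, as does the final residue. C/E-derived d predictions are
#' deliberately NOT constraints, since epimerization can be inactive.
#'
#' @param arch a \linkS4class{DomainArchitecture}.
#' @param ... unused.
#' @return named character vector, names = 1-based positions, values
#'   \code{"L"}.
#' @examples
#' hardConstraints(DomainArchitecture(c("Cstart", rep("C/E", 6), "LCL")))
#' # 7 = "L" (precedes the LCL module), 8 = "L" (terminal residue)
#' @rdname hardConstraints
#' @export
setMethod("hardConstraints", "DomainArchitecture", function(arch, ...) {
  mods <- arch@modules
  n <- length(mods)
  pos <- sort(unique(c(which(mods == "LCL") - 1L, n)))
  pos <- pos[pos >= 1L]
  setNames(rep("L", length(pos)), pos)
})

## ---------------------------------------------------------------------------
## Enumeration
## ---------------------------------------------------------------------------

## map positions to Marfey classes; Glu/Gln fold into "Glx" when the
## constraint carries that class
.classOfPositions <- function(seq, marfey) {
  codes <- seq@residues$code
  cls <- codes
  if (!is.null(marfey) && "Glx" %in% marfey@counts$class)
    cls[codes %in% c("Glu", "Gln")] <- "Glx"
  cls
}

## forced configs from sequence (known configs) + hard constraints;
## errors on conflict. Returns list(letter = named chr of "D"/"L",
## label = named chr of display labels).
.forcedConfigs <- function(seq, hc) {
  res <- seq@residues
  letter <- character(0); label <- character(0)
  known <- which(res$config != "unknown")
  if (length(known)) {
    letter[as.character(known)] <-
      ifelse(.isConfigD(res$config[known]), "D", "L")
    label[as.character(known)] <- res$config[known]
  }
  for (p in names(hc)) {
    v <- hc[[p]]
    if (!v %in% c("D", "L"))
      .stopf("hard constraint at position %s must be 'D' or 'L'", p)
    if (p %in% names(letter) && letter[[p]] != v)
      .stopf("conflicting constraint at position %s: sequence says %s, constraint says %s",
             p, letter[[p]], v)
    if (!p %in% names(letter)) {
      letter[[p]] <- v
      label[[p]] <- v
    }
  }
  list(letter = letter, label = label)
}

#' Enumerate stereo-sequences consistent with Marfey's counts and constraints
#'
#' Marfey's analysis of the total hydrolysate yields d/l counts per
#' amino-acid class but no positional information; this enumerates every
#' assignment of those counts to sequence positions that also honors the
#' hard constraints. Positions whose configuration is already set in
#' \code{seq} (uniquely occurring residues, or prior knowledge) consume
#' their class's budget; the remainder is distributed over the free
#' positions, giving \eqn{\prod_c \binom{n_{free,c}}{d_{free,c}}} candidates.
#'
#' @param seq a \linkS4class{Lipopeptide}; residues of classes covered by
#'   \code{marfey} may be \code{"unknown"}, all others must be set.
#' @param marfey a \linkS4class{MarfeyConstraint}.
#' @param hc hard constraints as returned by \code{\link{hardConstraints}}
#'   (named character vector position -> \code{"L"}/\code{"D"}), or
#'   \code{NULL} for none.
#' @return \code{data.frame} with one row per candidate, sorted
#'   lexicographically by collapsed config string: \code{name} (the
#'   \code{"(l:m)-Lx"} style name when exactly one class is heterogeneous
#'   over its free positions, else the config string), \code{config}
#'   (collapsed \code{"D"}/\code{"L"} string), \code{labels}
#'   (comma-separated full labels incl. allo), \code{satisfiesMarfey},
#'   \code{satisfiesConstraints}.
#' @examples
#' ban <- bananamideSWRI103()
#' nrow(enumerateCandidates(ban$enumSequence, ban$marfey))           # 6
#' nrow(enumerateCandidates(ban$enumSequence, ban$marfey,
#'                          hardConstraints(ban$architecture)))      # 3
#' @export
enumerateCandidates <- function(seq, marfey, hc = NULL) {
  validObject(seq); validObject(marfey)
  res <- seq@residues
  l <- nrow(res)
  if (!is.null(hc)) {
    badp <- setdiff(as.integer(names(hc)), res$position)
    if (length(badp))
      .stopf("hard constraint position(s) outside sequence: %s",
             paste(badp, collapse = ", "))
  }
  cls <- .classOfPositions(seq, marfey)
  forced <- .forcedConfigs(seq, hc)
  cts <- marfey@counts

  ## classes without Marfey counts must be fully determined
  uncovered <- setdiff(unique(cls), cts$class)
  for (cl in uncovered) {
    p <- res$position[cls == cl]
    open <- setdiff(as.character(p), names(forced$letter))
    if (length(open))
      .stopf("class %s has unknown configuration at position(s) %s and no Marfey counts",
             cl, paste(open, collapse = ", "))
  }

  ## per covered class: check budget, collect free positions and remaining D
  perClass <- list()
  for (i in seq_len(nrow(cts))) {
    cl <- cts$class[i]
    p <- res$position[cls == cl]
    if (!length(p))
      .stopf("Marfey class %s does not occur in the sequence", cl)
    if (cts$nD[i] + cts$nL[i] != length(p))
      .stopf("Marfey counts for class %s (%d D + %d L) do not sum to its %d position(s)",
             cl, cts$nD[i], cts$nL[i], length(p))
    pf <- intersect(as.character(p), names(forced$letter))
    forcedD <- sum(forced$letter[pf] == "D")
    forcedL <- sum(forced$letter[pf] == "L")
    remD <- cts$nD[i] - forcedD
    remL <- cts$nL[i] - forcedL
    if (remD < 0L || remL < 0L)
      .stopf("infeasible constraints for class %s: forced %d D / %d L exceed Marfey's %d D / %d L",
             cl, forcedD, forcedL, cts$nD[i], cts$nL[i])
    free <- setdiff(p, as.integer(pf))
    perClass[[cl]] <- list(free = free, remD = remD, allo = cts$allo[i])
  }

  ## cartesian product of per-class D-placements
  choiceSets <- lapply(perClass, function(x) {
    if (x$remD == 0L) list(integer(0))
    else if (x$remD == length(x$free)) list(x$free)
    else {
      cc <- utils::combn(x$free, x$remD)
      lapply(seq_len(ncol(cc)), function(j) cc[, j])
    }
  })
  grid <- expand.grid(lapply(choiceSets, seq_along))
  nCand <- if (nrow(grid)) nrow(grid) else 1L

  alloSeq <- res$config %in% c("D-allo", "L-allo")
  buildOne <- function(k) {
    label <- setNames(rep(NA_character_, l), as.character(res$position))
    label[names(forced$label)] <- forced$label
    for (cl in names(perClass)) {
      x <- perClass[[cl]]
      dpos <- if (nrow(grid)) choiceSets[[cl]][[grid[k, cl]]] else integer(0)
      lab <- rep("L", length(x$free))
      lab[x$free %in% dpos] <- if (x$allo) "D-allo" else "D"
      label[as.character(x$free)] <- lab
    }
    label
  }
  cands <- lapply(seq_len(nCand), buildOne)

  ## heterogeneous-over-free classes drive the "(l:m)-Lx" naming
  het <- names(perClass)[vapply(perClass, function(x)
    x$remD > 0L && x$remD < length(x$free), logical(1))]
  lmName <- tryCatch({
    lm <- classifyLM(seq); sprintf("(%d:%d)", lm[["l"]], lm[["m"]])
  }, error = function(e) NA_character_)

  cfg <- vapply(cands, .collapseConfig, character(1))
  name <- vapply(seq_along(cands), function(k) {
    if (length(het) == 1L && !is.na(lmName)) {
      x <- perClass[[het]]
      lpos <- sort(x$free[.isConfigL(cands[[k]][as.character(x$free)])])
      paste0(lmName, "-", paste0("L", lpos, collapse = ""))
    } else cfg[k]
  }, character(1))

  out <- data.frame(
    name = name, config = cfg,
    labels = vapply(cands, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  out <- out[order(out$config, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL

  ## by-construction guarantees, asserted per candidate
  out$satisfiesMarfey <- vapply(seq_len(nrow(out)), function(k) {
    lab <- strsplit(out$labels[k], ",", fixed = TRUE)[[1L]]
    all(vapply(seq_len(nrow(cts)), function(i) {
      p <- which(cls == cts$class[i])
      sum(.isConfigD(lab[p])) == cts$nD[i] && sum(.isConfigL(lab[p])) == cts$nL[i]
    }, logical(1)))
  }, logical(1))
  out$satisfiesConstraints <- vapply(seq_len(nrow(out)), function(k) {
    lab <- strsplit(out$labels[k], ",", fixed = TRUE)[[1L]]
    all(vapply(seq_along(hc), function(j) {
      p <- as.integer(names(hc)[j])
      (hc[[j]] == "D") == .isConfigD(lab[p])
    }, logical(1)))
  }, logical(1))
  stopifnot(all(out$satisfiesMarfey), all(out$satisfiesConstraints))
  out
}

#' Convert a printed d:l ratio to integer counts
#'
#' Literature reports Marfey's results as ratios like "2:2" or "1:3". For a
#' class with \code{n} sequence positions this returns the integer split
#' \code{(k, n - k)} whose d fraction is closest to
#' \code{ratioD / (ratioD + ratioL)}; ties take the smaller d count. When no
#' split reproduces the ratio exactly the result is flagged ambiguous (and a
#' warning is raised): explicit integer counts should then take precedence
#' over the printed ratio.
#'
#' @param ratioD,ratioL non-negative, not both zero.
#' @param n number of sequence positions in the class.
#' @return list with \code{nD}, \code{nL}, \code{exact}.
#' @examples
#' ratioToCounts(2, 2, 4)  # 2 D, 2 L, exact
#' ratioToCounts(2, 1, 5)  # 3 D, 2 L, flagged ambiguous
#' @export
ratioToCounts <- function(ratioD, ratioL, n) {
  stopifnot(ratioD >= 0, ratioL >= 0, ratioD + ratioL > 0, n >= 1)
  target <- ratioD / (ratioD + ratioL)
  k <- 0:n
  dev <- abs(k / n - target)
  nD <- k[which.min(dev)]
  exact <- isTRUE(all.equal(nD * ratioL, (n - nD) * ratioD))
  if (!exact)
    warning(sprintf("d:l ratio %g:%g has no exact split over %d positions; using %d:%d (ambiguous)",
                    ratioD, ratioL, n, nD, n - nD), call. = FALSE)
  list(nD = as.integer(nD), nL = as.integer(n - nD), exact = exact)
}

#' Infer epimerization-inactive modules
#'
#' Given a finally elucidated stereo-sequence, any module whose C/E domain
#' is annotated as epimerizing but whose preceding residue is l must carry a
#' cryptically inactive epimerization function.
#'
#' @param final the elucidated configuration: a character vector of labels
#'   (\code{"D"}, \code{"L"}, \code{"D-allo"}, ...), a collapsed config
#'   string, or a \linkS4class{Lipopeptide}.
#' @param arch the \linkS4class{DomainArchitecture}; module count must equal
#'   residue count.
#' @return integer vector of inactive module indices.
#' @examples
#' ban <- bananamideSWRI103()
#' inferInactiveEpimerization(ban$sequence, ban$architecture)  # 5
#' @export
inferInactiveEpimerization <- function(final, arch) {
  cfg <- .asConfigVector(final)
  mods <- arch@modules
  if (length(cfg) != length(mods))
    .stopf("config length (%d) does not match module count (%d)",
           length(cfg), length(mods))
  if (any(cfg == "?"))
    stop("final configuration contains unknown residues", call. = FALSE)
  which(mods == "C/E" & c("", cfg[-length(cfg)]) == "L")
}

.asConfigVector <- function(x) {
  if (is(x, "Lipopeptide")) x <- x@residues$config
  if (length(x) == 1L && !x %in% .CONFIG_LEVELS)
    x <- strsplit(x, "")[[1L]]
  ifelse(.isConfigD(x), "D", ifelse(.isConfigL(x), "L", "?"))
}

#' Compare a bioinformatic prediction against Marfey's counts
#'
#' Per residue class, tallies the predicted d/l counts and flags whether
#' they agree with the experimental Marfey's counts -- the check that
#' exposes inactive epimerization domains (e.g. a predicted 3:1 d:l for four
#' leucines against an experimental 2:2).
#'
#' @param pred predicted configuration (vector, collapsed string, or
#'   \linkS4class{Lipopeptide}).
#' @param marfey a \linkS4class{MarfeyConstraint}.
#' @param seq the \linkS4class{Lipopeptide} giving class membership of
#'   positions.
#' @return \code{data.frame} with columns \code{class}, \code{predD},
#'   \code{predL}, \code{marfeyD}, \code{marfeyL}, \code{consistent}.
#' @export
validatePredictionVsMarfey <- function(pred, marfey, seq) {
  cfg <- .asConfigVector(pred)
  if (length(cfg) != nrow(seq@residues))
    stop("prediction length does not match sequence length", call. = FALSE)
  cls <- .classOfPositions(seq, marfey)
  cts <- marfey@counts
  out <- do.call(rbind, lapply(seq_len(nrow(cts)), function(i) {
    p <- which(cls == cts$class[i])
    pd <- sum(cfg[p] == "D"); pl <- sum(cfg[p] == "L")
    data.frame(class = cts$class[i], predD = pd, predL = pl,
               marfeyD = cts$nD[i], marfeyL = cts$nL[i],
               consistent = pd == cts$nD[i] && pl == cts$nL[i],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## Text formats
## ---------------------------------------------------------------------------

#' Read / write domain architectures and candidate tables
#'
#' Architectures use a one-line text format of comma-separated tokens
#' \code{Cstart|C/E|LCL} (whitespace ignored); Marfey constraints a
#' YAML/JSON mapping \code{class: \{D: n, L: n[, allo: true]\}};
#' candidate sets a TSV with columns name, config, labels and the two
#' satisfaction flags.
#'
#' @param path file path; for \code{readArchitecture} a literal one-line
#'   specification is also accepted.
#' @return \code{readArchitecture()} a \linkS4class{DomainArchitecture};
#'   \code{readMarfey()} a \linkS4class{MarfeyConstraint}.
#' @export
readArchitecture <- function(path) {
  line <- if (file.exists(path)) readLines(path, warn = FALSE)[1L] else path
  DomainArchitecture(trimws(strsplit(line, ",", fixed = TRUE)[[1L]]))
}

#' @param arch a \linkS4class{DomainArchitecture}.
#' @rdname readArchitecture
#' @export
writeArchitecture <- function(arch, path) {
  writeLines(paste(arch@modules, collapse = ","), path)
  invisible(path)
}

#' @rdname readArchitecture
#' @export
readMarfey <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  allo <- names(doc)[vapply(doc, function(x) isTRUE(x$allo), logical(1))]
  counts <- lapply(doc, function(x) {
    for (f in c("D", "L"))
      if (is.null(x[[f]])) .stopf("Marfey class entry missing count '%s'", f)
    c(D = as.integer(x$D), L = as.integer(x$L))
  })
  do.call(MarfeyConstraint, c(counts, list(allo = allo)))
}

#' @param candidates a candidate \code{data.frame} from
#'   \code{\link{enumerateCandidates}}.
#' @rdname readArchitecture
#' @export
writeCandidates <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
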