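# Synthetic assigned (C-H)alpha fingerprints: the validation substrate.
#
# Peak position = per-code base position (random-coil style table)
#                 + deterministic stereo term + Gaussian measurement noise.
# The stereo term for residue p hashes p together with the codes and
# configurations of residues within `window` of p (plus the fatty-acyl C3
# configuration when p is near the N-terminus) into a uniform deviate in
# [-1, 1] per axis, scaled by the stereo effect magnitude. The hash is a
# seeded counter-based construction with no global RNG state, so the
# perturbation field is reproducible across platforms, and inverting one
# stereocenter displaces exactly the peaks whose window covers it.

.stereoKey <- function(seq, model, p) {
  res <- seq@residues
  l <- nrow(res)
  w <- model@window
  nb <- max(1L, p - w):min(l, p + w)
  env <- paste(nb - p, res$code[nb], res$config[nb], sep = ":",
               collapse = "|")
  fa <- if ((p - 1L) <= w)
    paste0("|FA:", seq@fattyAcyl@c3Config) else ""
  paste0("s", model@seed, ";p", p, ";", env, fa)
}

.faKey <- function(seq, model) {
  res <- seq@residues
  w <- model@window
  nb <- seq_len(min(nrow(res), max(1L, w)))
  env <- paste(nb, res$code[nb], res$config[nb], sep = ":", collapse = "|")
  fa <- seq@fattyAcyl
  paste0("s", model@seed, ";FA;", fa@chainLength, ":", fa@hydroxylPosition,
         ":", fa@c3Config, ";", env)
}

#' Simulate an assigned (C-H)alpha fingerprint
#'
#' Generates one Calpha-Halpha peak per residue plus the fatty-acyl CHbeta
#' peak. Two calls with the same sequence, model and noise seed are
#' identical; the same sequence re-simulated under a different noise seed
#' differs only by measurement noise. Inverting a d/l center displaces only
#' the peaks within \code{window} residues of it (the fatty-acyl C3 center
#' acts on the FA peak and the first \code{window + 1} residues).
#'
#' @param seq a \linkS4class{Lipopeptide} with every residue configuration
#'   and the fatty-acyl C3 configuration known.
#' @param model a \linkS4class{ShiftModel}.
#' @param noiseSeed integer seed for the measurement noise.
#' @param meta acquisition metadata to stamp on the fingerprint.
#' @return a \linkS4class{Fingerprint} (region \code{"CHalpha"}).
#' @export
simulateFingerprint <- function(seq, model = ShiftModel(), noiseSeed = 1L,
                                meta = AcquisitionMeta("DMF-d7", 298, 500)) {
  validObject(seq); validObject(model)
  res <- seq@residues
  if (any(res$config == "unknown"))
    .stopf("cannot simulate: unknown configuration at position(s) %s",
           paste(res$position[res$config == "unknown"], collapse = ", "))
  if (seq@fattyAcyl@c3Config == "unknown" &&
      identical(seq@fattyAcyl@hydroxylPosition, 3L))
    stop("cannot simulate: fatty-acyl C3 configuration unknown", call. = FALSE)
  l <- nrow(res)
  base <- model@baseTable
  bi <- match(res$code, base$code)
  if (anyNA(bi))
    .stopf("no base shifts for residue code(s): %s",
           paste(unique(res$code[is.na(bi)]), collapse = ", "))

  dC <- numeric(l + 1L); dH <- numeric(l + 1L)
  for (p in seq_len(l)) {
    key <- .stereoKey(seq, model, p)
    dC[p] <- model@stereoEffect[["C"]] * .hashUnit(paste0(key, ";C"))
    dH[p] <- model@stereoEffect[["H"]] * .hashUnit(paste0(key, ";H"))
  }
  fk <- .faKey(seq, model)
  dC[l + 1L] <- model@stereoEffect[["C"]] * .hashUnit(paste0(fk, ";C"))
  dH[l + 1L] <- model@stereoEffect[["H"]] * .hashUnit(paste0(fk, ";H"))

  noise <- .withSeed(noiseSeed, {
    cbind(C = stats::rnorm(l + 1L, 0, model@noise[["C"]]),
          H = stats::rnorm(l + 1L, 0, model@noise[["H"]]))
  })

  pk <- data.frame(
    tag = c(rep("AA", l), "FA"),
    position = c(res$position, NA_integer_),
    atomPair = c(rep("CA-HA", l), "CB-HB"),
    deltaH = c(base$deltaH[bi], .FA_BASE[["deltaH"]]) + dH + noise[, "H"],
    deltaC = c(base$deltaC[bi], .FA_BASE[["deltaC"]]) + dC + noise[, "C"],
    intensity = NA_real_,
    stringsAsFactors = FALSE)
  Fingerprint(pk, meta, region = "CHalpha", compoundName = seq@name)
}

## ---------------------------------------------------------------------------
## The three benchmark CLiP systems
## ---------------------------------------------------------------------------

.withConfigs <- function(seq, labels, name = seq@name) {
  res <- seq@residues
  res$config <- labels
  Lipopeptide(name, res, esterDonorPosition = seq@esterDonorPosition,
              fattyAcyl = seq@fattyAcyl, producer = seq@producer)
}

## blank the configs of the positions enumeration is meant to decide
.blankPositions <- function(seq, positions) {
  res <- seq@residues
  res$config[res$position %in% positions] <- "unknown"
  Lipopeptide(seq@name, res, esterDonorPosition = seq@esterDonorPosition,
              fattyAcyl = seq@fattyAcyl, producer = seq@producer)
}

#' Benchmark CLiP systems
#'
#' Fully specified descriptions of three well-characterized Pseudomonas
#' CLiP systems used throughout the package's validation: the (8:6)
#' bananamide from P. azadiae SWRI103, (10:8) orfamide B from P. aestus
#' CMR5c and (14:8) xantholysin A from P. mosselii BW11M1. Each returns a
#' list with:
#' \describe{
#'   \item{sequence}{the elucidated \linkS4class{Lipopeptide} (full
#'     stereochemistry).}
#'   \item{enumSequence}{the same sequence with the configurationally
#'     heterogeneous class positions blanked to \code{"unknown"} -- the
#'     state of knowledge after Marfey's analysis, input to
#'     \code{\link{enumerateCandidates}}.}
#'   \item{architecture}{the NRPS \linkS4class{DomainArchitecture}.}
#'   \item{marfey}{the \linkS4class{MarfeyConstraint} from hydrolysate
#'     analysis.}
#'   \item{truthName}{candidate name of the elucidated structure.}
#'   \item{meta}{the \linkS4class{AcquisitionMeta} used for simulated
#'     spectra of this system.}
#' }
#'
#' For xantholysin the condensation-domain architecture is reconstructed
#' from the elucidated structure (modules 12 and 13 as LCL, all other
#' elongation modules C/E): the genome annotation itself is in the primary
#' genome reports, not re-derived here. The xantholysin Marfey leucine
#' counts are the explicit 2 d : 3 l of the elucidated structure; the
#' literature-printed d:l ratio 2:1 over five positions has no exact
#' integer split (see \code{\link{ratioToCounts}}) and explicit counts take
#' precedence.
#'
#' @return list as described above.
#' @examples
#' ban <- bananamideSWRI103()
#' classifyLM(ban$sequence)
#' predictConfigs(ban$architecture)
#' @name benchmarkSystems
NULL

#' @rdname benchmarkSystems
#' @export
bananamideSWRI103 <- function() {
  codes <- c("Leu", "Glu", "Thr", "Leu", "Leu", "Ser", "Leu", "Ile")
  elucidated <- c("D", "D", "D-allo", "L", "D", "D", "L", "L")  # (8:6)-L4
  seq <- Lipopeptide("bananamide SWRI103",
                     data.frame(position = 1:8, code = codes,
                                config = elucidated),
                     esterDonorPosition = 3L,
                     fattyAcyl = FattyAcyl(10L, 3L, "R"),
                     producer = "P. azadiae SWRI103")
  list(sequence = seq,
       enumSequence = .blankPositions(seq, c(1L, 4L, 5L, 7L)),
       architecture = DomainArchitecture(c("Cstart", rep("C/E", 6), "LCL")),
       marfey = MarfeyConstraint(Leu = c(D = 2, L = 2)),
       truthName = "(8:6)-L4",
       meta = AcquisitionMeta("acetonitrile-d3", 303, 700))
}

#' @rdname benchmarkSystems
#' @export
orfamideCMR5c <- function() {
  codes <- c("Leu", "Glu", "Thr", "Val", "Leu", "Ser", "Leu", "Leu", "Ser",
             "Val")
  elucidated <- c("L", "D", "D-allo", "D", "D", "D", "L", "L", "D", "L")  # (10:8)-L1
  seq <- Lipopeptide("orfamide B CMR5c",
                     data.frame(position = 1:10, code = codes,
                                config = elucidated),
                     esterDonorPosition = 3L,
                     fattyAcyl = FattyAcyl(14L, 3L, "R"),
                     producer = "P. aestus CMR5c")
  list(sequence = seq,
       enumSequence = .blankPositions(seq, c(1L, 4L, 5L, 7L, 8L, 10L)),
       architecture = DomainArchitecture(c("Cstart", rep("C/E", 6),
                                           "LCL", "LCL", "C/E")),
       marfey = MarfeyConstraint(Leu = c(D = 1, L = 3), Val = c(D = 1, L = 1)),
       truthName = "(10:8)-L1",
       meta = AcquisitionMeta("DMF-d7", 298, 500))
}

#' @rdname benchmarkSystems
#' @export
xantholysinBW11M1 <- function() {
  codes <- c("Leu", "Glu", "Gln", "Val", "Leu", "Gln", "Ser", "Val", "Leu",
             "Gln", "Leu", "Leu", "Gln", "Ile")
  elucidated <- c("L", "D", "D", "D", "D", "L", "D", "D", "D", "D", "L", "L",
                  "D", "L")
  seq <- Lipopeptide("xantholysin A",
                     data.frame(position = 1:14, code = codes,
                                config = elucidated),
                     esterDonorPosition = 7L,
                     fattyAcyl = FattyAcyl(10L, 3L, "R"),
                     producer = "P. mosselii BW11M1")
  list(sequence = seq,
       enumSequence = .blankPositions(seq, c(1L, 2L, 3L, 5L, 6L, 9L, 10L,
                                             11L, 12L, 13L)),
       architecture = DomainArchitecture(c("Cstart", rep("C/E", 10),
                                           "LCL", "LCL", "C/E")),
       marfey = MarfeyConstraint(Leu = c(D = 2, L = 3), Glx = c(D = 4, L = 1)),
       ## two classes stay heterogeneous after the genomic trim, so candidate
       ## names fall back to plain config strings
       truthName = "LDDDDLDDDDLLDL",
       meta = AcquisitionMeta("DMF-d7", 328, 700))
}

#' Build the simulated fixture bundle
#'
#' For each benchmark system, enumerates the genomically constrained
#' candidate set, simulates a reference fingerprint for every candidate
#' (each under its own noise seed), and simulates a "natural" query from
#' the elucidated structure. The designated truth candidate is the
#' elucidated structure's name, so screening the query against the
#' candidate library should recover it.
#'
#' @param model a \linkS4class{ShiftModel}.
#' @param seed integer; offsets the per-fingerprint noise seeds.
#' @param systems which systems to build.
#' @return named list per system: \code{candidates} (data.frame),
#'   \code{library} (list of \linkS4class{ReferenceRecord}s),
#'   \code{query} (\linkS4class{Fingerprint}), \code{truthName}, and the
#'   system description fields.
#' @export
makeFixtureBundle <- function(model = ShiftModel(), seed = 1L,
                              systems = c("bananamide", "orfamide",
                                          "xantholysin")) {
  builders <- list(bananamide = bananamideSWRI103,
                   orfamide = orfamideCMR5c,
                   xantholysin = xantholysinBW11M1)
  systems <- match.arg(systems, several.ok = TRUE)
  out <- list()
  for (sname in systems) {
    sys <- builders[[sname]]()
    hc <- hardConstraints(sys$architecture)
    cand <- enumerateCandidates(sys$enumSequence, sys$marfey, hc)
    lib <- lapply(seq_len(nrow(cand)), function(k) {
      cseq <- .withConfigs(sys$enumSequence,
                           strsplit(cand$labels[k], ",", fixed = TRUE)[[1L]],
                           name = cand$name[k])
      ReferenceRecord(
        id = cand$name[k],
        fingerprint = simulateFingerprint(cseq, model,
                                          noiseSeed = seed + 1000L + k,
                                          meta = sys$meta),
        sequence = cseq,
        provenance = sprintf("synthetic reference, %s candidate set",
                             sys$sequence@name),
        stereoStatus = "elucidated")
    })
    query <- simulateFingerprint(sys$sequence, model, noiseSeed = seed,
                                 meta = sys$meta)
    stopifnot(sys$truthName %in% cand$name)
    out[[sname]] <- c(sys, list(candidates = cand, library = lib,
                                query = query))
  }
  out
}

#' Write the fixture bundle to a directory tree
#'
#' Writes, per system, the candidate TSV, the reference library JSON, the
#' query peak list TSV, and a manifest JSON tying them together.
#'
#' @param dir output directory (created if needed).
#' @inheritParams makeFixtureBundle
#' @return the directory, invisibly.
#' @export
writeFixtureBundle <- function(dir, model = ShiftModel(), seed = 1L) {
  bundle <- makeFixtureBundle(model, seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (sname in names(bundle)) {
    sys <- bundle[[sname]]
    sdir <- file.path(dir, sname)
    dir.create(sdir, showWarnings = FALSE)
    writeCandidates(sys$candidates, file.path(sdir, "candidates.tsv"))
    writeLibrary(sys$library, file.path(sdir, "library.json"))
    writePeaklist(sys$query, file.path(sdir, "query.tsv"))
    writeLipopeptide(sys$sequence, file.path(sdir, "sequence.yaml"))
    writeArchitecture(sys$architecture, file.path(sdir, "architecture.txt"))
    manifest[[sname]] <- list(
      candidates = file.path(sname, "candidates.tsv"),
      library = file.path(sname, "library.json"),
      query = file.path(sname, "query.tsv"),
      sequence = file.path(sname, "sequence.yaml"),
      architecture = file.path(sname, "architecture.txt"),
      truth = sys$truthName)
  }
  jsonlite::write_json(list(schema = "clipmatch-fixtures/1",
                            seed = seed, systems = manifest),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
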