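meta <- AcquisitionMeta("acetonitrile-d3", 303, 700)

tsvLines <- function(rows, header = c("#solvent=acetonitrile-d3", "#temp_K=303",
                                      "#field_MHz=700")) {
  c(header, paste("label", "delta_H", "delta_C", sep = "\t"), rows)
}

test_that("TSV peak lists parse row-per-peak with metadata from comments", {
  rows <- sprintf("AA%d\t%.3f\t%.2f", 1:8, 4 + (1:8) / 100, 50 + 1:8)
  fp <- readPeaklist(tsvLines(rows), dialect = "tsv")
  expect_s4_class(fp, "Fingerprint")
  expect_equal(nrow(peaks(fp)), 8L)
  expect_equal(peaks(fp)$position, 1:8)
  expect_equal(peaks(fp)$atomPair, rep("CA-HA", 8))
  expect_equal(acquisition(fp)@solvent, "acetonitrile-d3")
  expect_equal(acquisition(fp)@temperatureK, 303)
})

test_that("Sparky lists parse with the w1=13C, w2=1H column convention", {
  lines <- c("#solvent=DMSO-d6", "#temp_K=298",
             "Assignment w1 w2",
             "L4CA-HA 55.12 4.21",
             "FACB-HB 68.40 3.98",
             "?-? 54.00 4.50")
  fp <- readPeaklist(lines, dialect = "sparky")
  pk <- peaks(fp)
  expect_equal(pk$deltaC[1], 55.12)
  expect_equal(pk$deltaH[1], 4.21)
  expect_equal(pk$position[1], 4L)
  expect_equal(pk$tag[2], "FA")
  expect_true(is.na(pk$tag[3]))
})

test_that("implausible shifts and missing columns error with the line number", {
  rows <- c("AA1\t4.10\t55.0", "AA2\t4.20\t300")
  expect_error(readPeaklist(tsvLines(rows), dialect = "tsv"),
               "line 6.*delta_C out of range")
  bad <- c("#solvent=DMSO-d6", "#temp_K=298",
           paste("label", "delta_H", sep = "\t"), "AA1\t4.1")
  expect_error(readPeaklist(bad, dialect = "tsv"),
               "missing mandatory column.*delta_C")
  ## metadata is required, never guessed
  expect_error(readPeaklist(c("label\tdelta_H\tdelta_C", "AA1\t4.1\t55"),
                            dialect = "tsv"),
               "missing acquisition metadata")
})

test_that("peak lists round-trip through both dialects to 1e-4 ppm", {
  fp <- simulateFingerprint(bananamideSWRI103()$sequence, meta = meta)
  for (d in c("tsv", "sparky")) {
    path <- withr::local_tempfile(fileext = ".list")
    writePeaklist(fp, path, dialect = d)
    back <- readPeaklist(path, dialect = d)
    expect_equal(nrow(peaks(back)), nrow(peaks(fp)))
    expect_equal(peaks(back)$deltaH, peaks(fp)$deltaH, tolerance = 1e-4)
    expect_equal(peaks(back)$deltaC, peaks(fp)$deltaC, tolerance = 1e-4)
    expect_equal(peaks(back)$position, peaks(fp)$position)
    expect_equal(acquisition(back)@solvent, acquisition(fp)@solvent)
  }
})

test_that("shift tables become fingerprints, rejecting gaps and duplicates", {
  rows <- data.frame(position = 1:8, deltaH = 4 + (1:8) / 50,
                     deltaC = 50 + 1:8)
  fp <- fingerprintFromShiftTable(rows, meta, compoundName = "MDN-0066")
  expect_equal(nrow(peaks(fp)), 8L)
  expect_equal(fp@region, "CHalpha")
  rows2 <- rows; rows2$deltaH[3] <- NA
  expect_error(fingerprintFromShiftTable(rows2, meta), "position.*3")
  expect_error(fingerprintFromShiftTable(rbind(rows, rows[2, ]), meta),
               "duplicate")
})

test_that("reference libraries round-trip through versioned JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  ## empty library
  writeLibrary(list(), path)
  expect_length(readLibrary(path), 0L)
  ## three-record fixture
  bundle <- makeFixtureBundle(seed = 7, systems = "bananamide")
  lib <- bundle$bananamide$library
  writeLibrary(lib, path)
  back <- readLibrary(path)
  expect_length(back, length(lib))
  for (i in seq_along(lib)) {
    expect_equal(back[[i]]@id, lib[[i]]@id)
    expect_equal(peaks(back[[i]]@fingerprint)$deltaH,
                 peaks(lib[[i]]@fingerprint)$deltaH, tolerance = 1e-4)
    expect_equal(back[[i]]@stereoStatus, lib[[i]]@stereoStatus)
    expect_equal(configString(back[[i]]@sequence),
                 configString(lib[[i]]@sequence))
  }
})

test_that("library schema violations are rejected naming the field", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(schema = "other/1", records = list()), path,
                       auto_unbox = TRUE)
  expect_error(readLibrary(path), "clipmatch-lib/1")
  seqdoc <- list(name = "x", residues = list(list(pos = 1, code = "Leu")),
                 fatty_acyl = list(chain_length = 10))
  rec <- list(id = "r1", stereo_status = "unknown", sequence = seqdoc,
              fingerprint = list(region = "CHalpha",
                                 meta = list(solvent = "DMSO-d6", temp_K = 298),
                                 peaks = list(list(delta_H = 4.2, delta_C = 55))))
  jsonlite::write_json(list(schema = "clipmatch-lib/1", records = list(rec)),
                       path, auto_unbox = TRUE)
  expect_error(readLibrary(path), "provenance")
  ## a record missing provenance cannot be constructed directly either
  expect_s4_class(
    ReferenceRecord("r1", fingerprintFromShiftTable(
      data.frame(position = 1, deltaH = 4.2, deltaC = 55),
      AcquisitionMeta("DMSO-d6", 298)),
      Lipopeptide("x", c("Leu", "Ser", "Ile"), esterDonorPosition = 2L),
      provenance = "doi:10/xyz"),
    "ReferenceRecord")
})
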