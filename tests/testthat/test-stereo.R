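ban <- bananamideSWRI103()
orf <- orfamideCMR5c()
xan <- xantholysinBW11M1()

test_that("configuration prediction follows the condensation-domain logic", {
  expect_equal(predictConfigs(ban$architecture),
               c("D", "D", "D", "D", "D", "D", "L", "L"))
  expect_equal(predictConfigs(orf$architecture),
               c("D", "D", "D", "D", "D", "D", "L", "L", "D", "L"))
  ## no epimerizing domains at all: everything stays l
  expect_equal(predictConfigs(DomainArchitecture(c("Cstart", "LCL", "LCL"))),
               c("L", "L", "L"))
})

test_that("hard constraints arise only from LCL modules and the terminus", {
  expect_equal(hardConstraints(ban$architecture),
               c(`7` = "L", `8` = "L"))
  expect_equal(hardConstraints(orf$architecture),
               c(`7` = "L", `8` = "L", `10` = "L"))
  ## all-C/E architecture: only the terminal rule fires
  arch <- DomainArchitecture(c("Cstart", rep("C/E", 5)))
  expect_equal(hardConstraints(arch), c(`6` = "L"))
})

test_that("Marfey-constrained enumeration reproduces the benchmark counts", {
  expect_equal(nrow(enumerateCandidates(ban$enumSequence, ban$marfey)), 6L)
  expect_equal(nrow(enumerateCandidates(ban$enumSequence, ban$marfey,
                                        hardConstraints(ban$architecture))), 3L)
  expect_equal(nrow(enumerateCandidates(orf$enumSequence, orf$marfey)), 8L)
  expect_equal(nrow(enumerateCandidates(orf$enumSequence, orf$marfey,
                                        hardConstraints(orf$architecture))), 2L)
  expect_equal(nrow(enumerateCandidates(xan$enumSequence, xan$marfey)), 50L)
  expect_equal(nrow(enumerateCandidates(xan$enumSequence, xan$marfey,
                                        hardConstraints(xan$architecture))), 15L)
})

test_that("the constrained bananamide candidates are the L1/L4/L5 variants", {
  cand <- enumerateCandidates(ban$enumSequence, ban$marfey,
                              hardConstraints(ban$architecture))
  expect_setequal(cand$name, c("(8:6)-L1", "(8:6)-L4", "(8:6)-L5"))
  labels <- setNames(cand$labels, cand$name)
  expect_equal(labels[["(8:6)-L1"]], "L,D,D-allo,D,D,D,L,L")
  expect_equal(labels[["(8:6)-L4"]], "D,D,D-allo,L,D,D,L,L")
  expect_equal(labels[["(8:6)-L5"]], "D,D,D-allo,D,L,D,L,L")
  ## output is sorted lexicographically by config string
  expect_equal(cand$config, sort(cand$config))
})

test_that("enumeration count equals the brute-force filter on all three systems", {
  cases <- list(
    list(sys = ban, glx = FALSE), list(sys = orf, glx = FALSE),
    list(sys = xan, glx = TRUE))
  for (cs in cases) {
    sys <- cs$sys
    res <- residues(sys$enumSequence)
    fixedIdx <- which(res$config != "unknown")
    fixed <- setNames(ifelse(res$config[fixedIdx] %in% c("D", "D-allo"),
                             "D", "L"), fixedIdx)
    cts <- sys$marfey@counts
    marfey <- setNames(lapply(seq_len(nrow(cts)), function(i)
      c(D = cts$nD[i], L = cts$nL[i])), cts$class)
    for (hc in list(character(0), hardConstraints(sys$architecture))) {
      oracle <- bruteForceConfigs(res$code, fixed, marfey, hc, glx = cs$glx)
      got <- enumerateCandidates(sys$enumSequence, sys$marfey,
                                 if (length(hc)) hc else NULL)
      expect_identical(got$config, oracle)
    }
  }
})

test_that("enumeration agrees with brute force on random instances", {
  set.seed(2024)
  for (i in 1:50) {
    l <- sample(4:12, 1L)
    inst <- randomEnumInstance(l)
    seq <- instanceLipopeptide(inst)
    marfey <- do.call(MarfeyConstraint, inst$marfey)
    got <- enumerateCandidates(seq, marfey,
                               if (length(inst$hc)) inst$hc else NULL)
    oracle <- bruteForceConfigs(inst$codes, inst$fixed, inst$marfey,
                                inst$hc)
    expect_identical(got$config, oracle)
    ## every instance is feasible by construction: truth must be present
    expect_true(paste(inst$truth, collapse = "") %in% got$config)
    ## count law: product of per-class binomials
    expect_true(all(got$satisfiesMarfey) && all(got$satisfiesConstraints))
  }
})

test_that("adding hard constraints never enlarges the candidate set", {
  set.seed(99)
  for (i in 1:10) {
    inst <- randomEnumInstance(sample(5:10, 1L))
    seq <- instanceLipopeptide(inst)
    marfey <- do.call(MarfeyConstraint, inst$marfey)
    free <- enumerateCandidates(seq, marfey)
    if (length(inst$hc)) {
      constrained <- enumerateCandidates(seq, marfey, inst$hc)
      expect_lte(nrow(constrained), nrow(free))
      expect_true(all(constrained$config %in% free$config))
    }
  }
})

test_that("the architecture prediction is itself an admissible candidate", {
  for (sys in list(ban, orf, xan)) {
    pred <- predictConfigs(sys$architecture)
    res <- residues(sys$enumSequence)
    cls <- res$code
    if ("Glx" %in% sys$marfey@counts$class)
      cls[cls %in% c("Glu", "Gln")] <- "Glx"
    ## Marfey counts taken from the prediction itself
    counts <- lapply(split(pred, cls), function(x)
      c(D = sum(x == "D"), L = sum(x == "L")))
    seqAllFree <- Lipopeptide(sys$sequence@name,
                              data.frame(position = res$position,
                                         code = res$code, config = "unknown"),
                              esterDonorPosition = esterDonor(sys$sequence),
                              fattyAcyl = fattyAcyl(sys$sequence))
    cand <- enumerateCandidates(seqAllFree, do.call(MarfeyConstraint, counts))
    expect_true(paste(pred, collapse = "") %in% cand$config)
    ## and the prediction implies no inactive module, by definition
    expect_length(inferInactiveEpimerization(pred, sys$architecture), 0L)
  }
})

test_that("infeasible or incomplete constraints fail loudly", {
  ## more forced D than the Marfey budget allows
  expect_error(
    enumerateCandidates(ban$enumSequence, MarfeyConstraint(Leu = c(D = 0, L = 4)),
                        c(`1` = "D")),
    "infeasible.*Leu")
  ## counts that do not sum to the class size
  expect_error(
    enumerateCandidates(ban$enumSequence, MarfeyConstraint(Leu = c(D = 1, L = 2))),
    "do not sum")
  ## a class with unknown positions but no counts
  expect_error(
    enumerateCandidates(ban$enumSequence, MarfeyConstraint(Val = c(D = 0, L = 0))),
    "Leu|Val")
  ## all-L Marfey forces a single candidate
  one <- enumerateCandidates(ban$enumSequence,
                             MarfeyConstraint(Leu = c(D = 0, L = 4)))
  expect_equal(nrow(one), 1L)
  expect_equal(substr(one$config, 1, 1), "L")
})

test_that("printed d:l ratios convert to integer counts, flagging inexact ones", {
  expect_equal(ratioToCounts(2, 2, 4)[c("nD", "nL", "exact")],
               list(nD = 2L, nL = 2L, exact = TRUE))
  expect_equal(ratioToCounts(1, 3, 4)[c("nD", "nL", "exact")],
               list(nD = 1L, nL = 3L, exact = TRUE))
  ## the xantholysin leucine case: 2:1 over five positions has no exact split
  expect_warning(r <- ratioToCounts(2, 1, 5), "ambiguous")
  expect_equal(r[c("nD", "nL", "exact")], list(nD = 3L, nL = 2L, exact = FALSE))
})

test_that("epimerization-inactive modules are read off the final structure", {
  expect_equal(inferInactiveEpimerization(ban$sequence, ban$architecture), 5L)
  expect_equal(inferInactiveEpimerization(orf$sequence, orf$architecture), 2L)
  expect_equal(inferInactiveEpimerization(xan$sequence, xan$architecture),
               c(2L, 7L))
  ## config-string input form and the length check
  expect_equal(inferInactiveEpimerization("DDDLDDLL", ban$architecture), 5L)
  expect_error(inferInactiveEpimerization("DDL", ban$architecture),
               "does not match")
})

test_that("prediction vs Marfey comparison flags the leucine discrepancies", {
  repB <- validatePredictionVsMarfey(predictConfigs(ban$architecture),
                                     ban$marfey, ban$enumSequence)
  leuB <- repB[repB$class == "Leu", ]
  expect_false(leuB$consistent)
  expect_equal(c(leuB$predD, leuB$predL), c(3, 1))  # 3:1 predicted vs 2:2 found
  repO <- validatePredictionVsMarfey(predictConfigs(orf$architecture),
                                     orf$marfey, orf$enumSequence)
  leuO <- repO[repO$class == "Leu", ]
  expect_false(leuO$consistent)
  expect_equal(c(leuO$predD, leuO$predL), c(2, 2))  # 2:2 predicted vs 1:3 found
  ## valines agree in the orfamide system
  expect_true(repO[repO$class == "Val", "consistent"])
})

test_that("architecture text format round-trips and validates", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeArchitecture(orf$architecture, path)
  expect_equal(modules(readArchitecture(path)), modules(orf$architecture))
  expect_equal(modules(readArchitecture("Cstart, C/E, LCL")),
               c("Cstart", "C/E", "LCL"))
  expect_error(DomainArchitecture(c("C/E", "C/E")), "Cstart")
  expect_error(DomainArchitecture(c("Cstart", "XX")), "unknown domain type")
})

test_that("Marfey YAML format round-trips counts and the allo flag", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(Leu = list(D = 2, L = 2),
                        Thr = list(D = 1, L = 0, allo = TRUE)), path)
  mc <- readMarfey(path)
  cts <- mc@counts
  expect_equal(cts$nD[cts$class == "Leu"], 2L)
  expect_true(cts$allo[cts$class == "Thr"])
  yaml::write_yaml(list(Leu = list(D = 2)), path)
  expect_error(readMarfey(path), "'L'")
})
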