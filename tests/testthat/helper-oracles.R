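# Independent oracles and small fixture builders shared across tests.

## Brute-force enumeration oracle: walk all 2^l D/L strings and keep those
## consistent with fixed configs, per-class Marfey counts and hard
## constraints. Deliberately independent of the package's enumeration path.
bruteForceConfigs <- function(codes, fixed = character(), marfey = list(),
                              hc = character(), glx = FALSE) {
  l <- length(codes)
  cls <- codes
  if (glx) cls[cls %in% c("Glu", "Gln")] <- "Glx"
  keep <- character(0)
  for (mask in 0:(2^l - 1)) {
    cfg <- ifelse(bitwAnd(mask, 2^(seq_len(l) - 1L)) > 0, "D", "L")
    ok <- TRUE
    for (p in names(fixed))
      if (cfg[as.integer(p)] != fixed[[p]]) { ok <- FALSE; break }
    if (ok) for (p in names(hc))
      if (cfg[as.integer(p)] != hc[[p]]) { ok <- FALSE; break }
    if (ok) for (cl in names(marfey)) {
      idx <- which(cls == cl)
      if (sum(cfg[idx] == "D") != marfey[[cl]][["D"]]) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, paste(cfg, collapse = ""))
  }
  sort(keep)
}

## All permutations of 1..n (n <= 7), for the exhaustive assignment oracle.
allPerms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in allPerms(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(sub, n, after = k - 1L)
  out
}

## Exhaustive minimum-total-cost assignment over square cost matrices.
bruteForceAssignmentCost <- function(cost) {
  n <- nrow(cost)
  best <- Inf
  for (perm in allPerms(n)) {
    tot <- sum(cost[cbind(seq_len(n), perm)])
    if (tot < best) best <- tot
  }
  best
}

## Random enumeration instance with a guaranteed-feasible truth config.
## Returns everything both the package path and the oracle need.
randomEnumInstance <- function(l) {
  pool <- c("Leu", "Val", "Ser", "Gln", "Glu", "Ile", "Thr", "Ala")
  codes <- sample(pool, l, replace = TRUE)
  codes[1L] <- "Leu"  # guarantee at least one multi-capable class
  truth <- sample(c("D", "L"), l, replace = TRUE)
  truth[l] <- "L"
  tab <- table(codes)
  multi <- names(tab)[tab > 1L]
  single <- names(tab)[tab == 1L]
  marfey <- lapply(multi, function(cl) {
    idx <- which(codes == cl)
    c(D = sum(truth[idx] == "D"), L = sum(truth[idx] == "L"))
  })
  names(marfey) <- multi
  fixed <- setNames(truth[match(single, codes)],
                    as.character(match(single, codes)))
  ## hard constraints: a random subset of the truth's L positions
  lpos <- which(truth == "L")
  k <- sample(0:min(2L, length(lpos)), 1L)
  hcn <- lpos[sample.int(length(lpos), k)]
  hc <- setNames(rep("L", length(hcn)), hcn)
  list(codes = codes, truth = truth, marfey = marfey, fixed = fixed, hc = hc)
}

## Lipopeptide for a random instance: single-occurrence classes fixed to the
## truth, multi-occurrence class positions left unknown.
instanceLipopeptide <- function(inst) {
  cfg <- rep("unknown", length(inst$codes))
  cfg[as.integer(names(inst$fixed))] <- inst$fixed
  Lipopeptide("random instance",
              data.frame(position = seq_along(inst$codes),
                         code = inst$codes, config = cfg))
}

## Apply a full config labelling to a sequence (candidate realization).
withConfigs <- function(seq, labels) {
  res <- residues(seq)
  res$config <- labels
  Lipopeptide(seq@name, res, esterDonorPosition = esterDonor(seq),
              fattyAcyl = fattyAcyl(seq))
}

## Quick unlabeled fingerprint around given shift coordinates.
unlabeledFingerprint <- function(deltaH, deltaC,
                                 meta = AcquisitionMeta("DMSO-d6", 298)) {
  Fingerprint(data.frame(tag = NA_character_, position = NA_integer_,
                         atomPair = NA_character_, deltaH = deltaH,
                         deltaC = deltaC, intensity = NA_real_),
              meta, region = "CHalpha")
}
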