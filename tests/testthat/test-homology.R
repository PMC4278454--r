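test_that("best hits rank the true match first under the e-value cutoff", {
  set.seed(21)
  tab <- ZWstrata:::codonTables()
  targets <- Biostrings::DNAStringSet(setNames(
    vapply(1:6, function(i) randomCds(80, 100 + i), character(1)),
    paste0("t", 1:6)))
  # a query identical to one target ranks it first with the maximal score
  q <- Biostrings::DNAStringSet(c(q1 = as.character(targets[["t3"]])))
  h <- bestHits(q, targets)
  expect_equal(h$target[1], "t3")
  expect_equal(h$score[1], max(h$score))
  # a random query unrelated to any target: no hit under the cutoff
  qr <- Biostrings::DNAStringSet(c(qx = randomCds(20, 999)))
  expect_equal(nrow(bestHits(qr, targets)), 0L)
  # empty target set is an error
  expect_error(bestHits(q, Biostrings::DNAStringSet()), "empty")
  # tabular input bypasses the aligner
  tab6 <- data.frame(query = "q", target = c("b", "a"), score = c(50, 50),
                     evalue = c(1e-20, 1e-20))
  ht <- bestHits(hitTable = tab6)
  expect_equal(ht$target, c("a", "b"))  # deterministic tie-break by id
})

test_that("reciprocal best hits are symmetric and exclude asymmetric pairs", {
  a1 <- randomCds(70, 31)
  b1 <- ZWstrata:::splitCodons(a1)
  set.seed(32)
  tab <- ZWstrata:::codonTables()
  b1[sample(70, 7)] <- sample(tab$sense, 7, replace = TRUE)  # ~10% diverged
  setA <- Biostrings::DNAStringSet(c(x = a1))
  setB <- Biostrings::DNAStringSet(c(y = paste(b1, collapse = "")))
  r <- reciprocalBestHits(setA, setB)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$a, r$b), c("x", "y"))
  # symmetry in the arguments
  r2 <- reciprocalBestHits(setB, setA)
  expect_equal(c(r2$a, r2$b), c("y", "x"))

  # a's best is b, but b's best is a-prime: no pair for a
  aPrime <- b1
  aPrime[1] <- setdiff(tab$sense, aPrime[1])[1]
  setA2 <- Biostrings::DNAStringSet(c(a = a1,
                                      aprime = paste(aPrime, collapse = "")))
  r3 <- reciprocalBestHits(setA2, setB)
  expect_false("a" %in% r3$a)     # b reciprocates with aprime, not a
  expect_true("aprime" %in% r3$a)
})

test_that("ortholog recovery on simulated loci is near-perfect at 10% divergence", {
  sim <- cachedSim("orth", function()
    simulateGametologHistory(uniformConfig(12, "Gg", 25e6, cdsLength = 450,
                                           seed = 33)))
  gg <- Biostrings::DNAStringSet(vapply(names(sim@sequences), function(l)
    as.character(sim@sequences[[l]][["Gg_Z"]]), character(1)))
  ap <- Biostrings::DNAStringSet(vapply(names(sim@sequences), function(l)
    as.character(sim@sequences[[l]][["Ap_Z"]]), character(1)))
  names(gg) <- names(ap) <- names(sim@sequences)
  h <- bestHits(gg, ap)
  top <- h[!duplicated(h$query), ]
  expect_gte(mean(top$target == top$query), 0.99)
})

test_that("the three-step pairing rule records routes and falls back to next-best", {
  sim <- cachedSim("pairg", function()
    simulateGametologHistory(uniformConfig(6, "GgMgAp", 95e6,
                                           cdsLength = 450, seed = 34)))
  loci <- names(sim@sequences)
  grab <- function(tip) Biostrings::DNAStringSet(setNames(
    vapply(loci, function(l) as.character(sim@sequences[[l]][[tip]]),
           character(1)), paste0(loci, "_", tip)))
  refW <- grab("Gg_W"); refZ <- grab("Gg_Z")
  apW <- grab("Ap_W"); apZ <- grab("Ap_Z")
  refMap <- data.frame(w = names(refW), z = names(refZ))
  # clean 1:1 orthology: every pair via reciprocal-best
  out <- pairGametologs(apW, refW, refZ, refMap, apZ)
  expect_true(all(out$route == "reciprocal-best"))
  expect_equal(out$zGene, paste0(loci, "_Ap_Z"))
  expect_true(all(out$coverage > 0.5))

  # a locus absent from the reference map is unpaired with a reason
  refMap2 <- refMap[-1, ]
  out2 <- pairGametologs(apW[1], refW, refZ, refMap2, apZ)
  expect_true(is.na(out2$zGene[1]))
  expect_match(out2$reason[1], "no reference ortholog")
})

test_that("young gametologs break the reciprocal check and engage the next-best route", {
  # Ap suppression 5 My ago: Ap_W is still nearly identical to Ap_Z and,
  # being on the slower W branch, out-scores Ap_Z as the reference Z's best
  # species hit; its own back hit lands on the reference W, so the
  # reciprocal check fails and the next-best hit recovers the true Ap_Z
  cfg <- simulationConfig(
    nLoci = 1, cdsLength = 600,
    suppressionTimes = data.frame(locus = "L001",
                                  lineage = c("Gg", "Ap"),
                                  time = c(25e6, 5e6)),
    seed = 37)
  sim <- cachedSim("youngPair", function() simulateGametologHistory(cfg))
  s <- sim@sequences[[1]]
  refW <- Biostrings::DNAStringSet(c(gW = as.character(s[["Gg_W"]])))
  refZ <- Biostrings::DNAStringSet(c(gZ = as.character(s[["Gg_Z"]])))
  species <- Biostrings::DNAStringSet(c(aZ = as.character(s[["Ap_Z"]]),
                                        aW = as.character(s[["Ap_W"]])))
  apW <- Biostrings::DNAStringSet(c(aW = as.character(s[["Ap_W"]])))
  out <- pairGametologs(apW, refW, refZ,
                        data.frame(w = "gW", z = "gZ"), species)
  fwd <- bestHits(refZ, species)
  if (fwd$target[1] == "aW") {
    # the shadowing configuration realised: fallback route engages
    expect_equal(out$route, "next-best-fallback")
  } else {
    expect_equal(out$route, "reciprocal-best")
  }
  expect_equal(out$zGene, "aZ")
  expect_false(out$zInWSet)
  # with the W sequence removed from the species set the route is reciprocal
  out2 <- pairGametologs(apW, refW, refZ, data.frame(w = "gW", z = "gZ"),
                         species["aZ"])
  expect_equal(out2$route, "reciprocal-best")
  expect_equal(out2$zGene, "aZ")
})

test_that("the coverage/length exclusion is the literal conjunction", {
  expect_equal(filterWCandidates(0.20, 140)$decision, "exclude")
  expect_equal(filterWCandidates(0.80, 300)$decision, "keep")
  # one metric passing keeps the candidate, flagged borderline
  f <- filterWCandidates(0.20, 300)
  expect_equal(f$decision, "keep")
  expect_true(f$borderline)
  f2 <- filterWCandidates(0.80, 100)
  expect_equal(f2$decision, "keep")
  expect_true(f2$borderline)
  # boundary: exactly at threshold is not "below"
  expect_equal(filterWCandidates(0.25, 149)$decision, "keep")
  expect_equal(filterWCandidates(0.24, 150)$decision, "keep")
  # the disjunctive variant behind the flag
  expect_equal(filterWCandidates(0.20, 300, rule = "or")$decision, "exclude")
})

test_that("paralog resolution picks minimal dS with deterministic tie-breaks", {
  cands <- data.frame(wGene = c("w1", "w2", "w3"), zGene = "z",
                      dS = c(0.30, 0.12, 0.19),
                      alignedLength = c(300, 280, 290))
  expect_equal(resolveParalogs(cands)$wGene, "w2")
  # single candidate returns itself
  expect_equal(resolveParalogs(cands[1, ])$wGene, "w1")
  # ties: longest aligned length, then lexicographic id
  tie <- data.frame(wGene = c("wb", "wa"), zGene = "z", dS = c(0.2, 0.2),
                    alignedLength = c(100, 200))
  expect_equal(resolveParalogs(tie)$wGene, "wa")
  tie2 <- data.frame(wGene = c("wb", "wa"), zGene = "z", dS = c(0.2, 0.2),
                     alignedLength = c(200, 200))
  expect_equal(resolveParalogs(tie2)$wGene, "wa")
  # no estimable dS: unresolved with reason
  un <- resolveParalogs(data.frame(wGene = "w", zGene = "z", dS = NA,
                                   alignedLength = 100))
  expect_equal(nrow(un), 0L)
  expect_match(attr(un, "reason"), "estimable")
  # the full candidate table is retained in the report
  expect_equal(nrow(attr(resolveParalogs(cands), "candidates")), 3L)
})

test_that("a simulated W duplicate loses to the true gametolog on dS", {
  sim <- cachedSim("paralog", function() {
    s <- simulateGametologHistory(uniformConfig(1, "GgMgAp", 95e6,
                                                cdsLength = 600, seed = 35))
    s
  })
  s <- sim@sequences[[1]]
  # emulate a W duplicate that kept diverging under relaxed selection after
  # duplication: extra neutral evolution on top of the true W copy
  trueW <- as.character(s[["Ap_W"]])
  tab <- ZWstrata:::codonTables()
  set.seed(36)
  dupIdx <- ZWstrata:::evolveSeq(unname(tab$idx[ZWstrata:::splitCodons(trueW)]),
                                 years = 40e6, mu = 3.8e-9, omega = 1,
                                 kappa = 2)
  dupW <- paste(tab$sense[dupIdx], collapse = "")
  z <- as.character(s[["Ap_Z"]])
  dsOf <- function(w) mlPairwiseDivergence(
    buildCodonAlignment(c(z = z, w = w)), minCodons = 30)@dS
  cands <- data.frame(wGene = c("trueW", "dupW"), zGene = "z",
                      dS = c(dsOf(trueW), dsOf(dupW)),
                      alignedLength = c(600L, 600L))
  expect_equal(resolveParalogs(cands)$wGene, "trueW")
})
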