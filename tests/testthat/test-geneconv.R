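mkProfile <- function(states, cols = NULL) {
  # states: character matrix sequences x sites
  if (is.null(cols)) cols <- seq_len(ncol(states)) * 3L - 1L
  new("SilentSiteProfile", cols = as.integer(cols), states = states,
      labels = rownames(states))
}

test_that("silent polymorphic sites are exactly the synonymous variable columns", {
  # invariant alignment: empty profile
  cds <- randomCds(40, 61)
  p0 <- silentPolymorphicSites(CodonAlignment(c(a_Z = cds, b_W = cds)))
  expect_length(p0@cols, 0L)
  # TTT vs TTC (both Phe): included; TTT vs TTA (Phe/Leu): excluded
  aln <- CodonAlignment(c(a_Z = "TTTGGGAAA", b_W = "TTCGGGTTA"))
  p <- silentPolymorphicSites(aln)
  expect_equal(p@cols, 2L)                     # third position of codon 1
  expect_equal(unname(p@states[, 1]), c("T", "C"))
  # positions are strictly increasing 0-based alignment columns
  sim <- cachedSim("treeShared", function()
    simulateGametologHistory(uniformConfig(1, "GgMg", 70e6, cdsLength = 900,
                                           seed = 53)))
  aln2 <- tipsAln(sim, "L001", c("Gg_Z", "Gg_W", "Mg_Z", "Mg_W", "Tg_Z"))
  p2 <- silentPolymorphicSites(aln2)
  expect_gt(length(p2@cols), 10)
  expect_false(is.unsorted(p2@cols, strictly = TRUE))
  # every listed column truly varies and is amino-acid invariant
  m <- alnMatrix(aln2)
  gc_map <- Biostrings::GENETIC_CODE
  for (col in p2@cols[1:5]) {
    cc <- col %/% 3L
    cods <- apply(m[, (cc * 3 + 1):(cc * 3 + 3), drop = FALSE], 1, paste,
                  collapse = "")
    expect_length(unique(gc_map[cods]), 1L)
    expect_gt(length(unique(m[, col + 1L])), 1L)
  }
})

test_that("fragment finding matches the spec'd run semantics", {
  # 12 sites: disagreements at 2 and 11 bound a run of 8 agreeing sites
  agree <- c(TRUE, FALSE, rep(TRUE, 8), FALSE, TRUE)
  st <- rbind(A_Z = rep("A", 12), B_W = ifelse(agree, "A", "G"),
              C_Z = rep("C", 12))
  prof <- mkProfile(st)
  fr <- findFragments(prof, c("A_Z", "B_W"), gscale = 0)
  top <- fr[1, ]
  expect_equal(top$nSites, 8L)
  expect_equal(top$startCol, prof@cols[3])
  expect_equal(top$endCol, prof@cols[10] + 1L)
  expect_equal(top$spanBp, prof@cols[10] - prof@cols[3] + 1L)
  expect_equal(top$nMismatch, 0L)

  # a pair agreeing at every site yields one fragment spanning all sites
  allAgree <- mkProfile(rbind(A_Z = rep("A", 6), B_W = rep("A", 6),
                              C_Z = rep("C", 6)))
  fa <- findFragments(allAgree, c("A_Z", "B_W"))
  expect_equal(nrow(fa), 1L)
  expect_equal(fa$nSites, 6L)

  # gscale = 2 merges across a single internal mismatch iff the merged
  # penalized score beats both sub-runs
  ag2 <- c(rep(TRUE, 5), FALSE, rep(TRUE, 5))
  st2 <- rbind(A_Z = rep("A", 11), B_W = ifelse(ag2, "A", "G"),
               C_Z = rep("C", 11))
  # widely spaced sites: spans are large relative to the penalty -> merge
  profWide <- mkProfile(st2, cols = seq(0, 300, length.out = 11))
  f2 <- findFragments(profWide, c("A_Z", "B_W"), gscale = 2)
  expect_equal(f2$nMismatch[1], 1L)
  expect_equal(f2$nSites[1], 10L)
  # under gscale = 0 the same data give two clean sub-runs
  f0 <- findFragments(profWide, c("A_Z", "B_W"), gscale = 0)
  expect_equal(nrow(f0), 2L)
  expect_true(all(f0$nMismatch == 0L))
})

test_that("the linear-time fragment scorer equals brute-force enumeration", {
  set.seed(71)
  for (rep in 1:60) {
    n <- sample(5:30, 1)
    cols <- sort(sample.int(400, n))
    agree <- runif(n) < runif(1, 0.3, 0.9)
    for (pen in c(1e9, 2.5 * (max(cols) - min(cols) + 1) / n)) {
      expect_equal(ZWstrata:::.maxFragScore(agree, cols, pen),
                   bruteMaxFragScore(agree, cols, pen))
    }
  }
})

test_that("permutation test calibrates degenerate input and reproduces with a seed", {
  # a single polymorphic site cannot be significant
  st1 <- rbind(A_Z = "A", B_W = "A", C_Z = "G")
  prof1 <- mkProfile(st1, cols = 10L)
  aln <- CodonAlignment(c(A_Z = "AAA", B_W = "AAA", C_Z = "AAG"))
  res1 <- permutationTest(aln, c(A_Z = "Z", B_W = "W", C_Z = NA),
                          nPerm = 200, profile = prof1)
  expect_equal(res1$sim_p, 1)
  # missing between-group pairs are an error; tiny nPerm warns
  expect_error(permutationTest(aln, c(A_Z = "Z", B_W = NA, C_Z = NA),
                               nPerm = 200, profile = prof1), "between-group")
  expect_warning(permutationTest(aln, c(A_Z = "Z", B_W = "W", C_Z = NA),
                                 nPerm = 50, profile = prof1), "coarse")
  # identical fragment tables under the same seed
  sim <- cachedSim("convLocus", function() {
    s <- simulateGametologHistory(uniformConfig(1, "GgMgAp", 100e6,
                                                cdsLength = 900, seed = 41))
    injectGeneConversion(s, "L001", donor = "Ap_W", recipient = "Ap_Z",
                         start = 300, end = 474)
  })
  nm <- c("Gg_Z", "Gg_W", "Ap_Z", "Ap_W", "Tg_Z")
  alnC <- tipsAln(sim, "L001", nm)
  gs <- setNames(c("Z", "W", "Z", "W", NA), nm)
  r1 <- permutationTest(alnC, gs, nPerm = 500, seed = 11)
  r2 <- permutationTest(alnC, gs, nPerm = 500, seed = 11)
  expect_identical(r1, r2)
})

test_that("an injected tract is recovered as a significant inner fragment with direction", {
  sim <- cachedSim("convLocus", function() {
    s <- simulateGametologHistory(uniformConfig(1, "GgMgAp", 100e6,
                                                cdsLength = 900, seed = 41))
    injectGeneConversion(s, "L001", donor = "Ap_W", recipient = "Ap_Z",
                         start = 300, end = 474)
  })
  nm <- c("Gg_Z", "Gg_W", "Ap_Z", "Ap_W", "Tg_Z")
  alnC <- tipsAln(sim, "L001", nm)
  gs <- setNames(c("Z", "W", "Z", "W", NA), nm)
  res <- permutationTest(alnC, gs, nPerm = 2000, seed = 9)
  hit <- res[res$seq1 == "Ap_Z" & res$seq2 == "Ap_W", ][1, ]
  expect_lt(hit$sim_p, 0.05)
  expect_equal(hit$class, "global-inner")
  ov <- max(0, min(hit$endCol, 474) - max(hit$startCol, 300))
  expect_gte(ov / 174, 0.8)
  # direction: material moved from the W to the Z copy
  d <- inferDirection(alnC, hit)
  expect_equal(d$direction, "Ap_W->Ap_Z")
  expect_gte(d$nInformative, 3)
})

test_that("direction is unknown without informative sites", {
  # two sequences only: no relatives to vote with
  st <- rbind(A_Z = rep("A", 6), B_W = rep("A", 6), C_Z = rep("G", 6))
  prof <- mkProfile(st)
  frag <- data.frame(seq1 = "A_Z", seq2 = "B_W", startCol = prof@cols[1],
                     endCol = prof@cols[6] + 1L)
  aln <- CodonAlignment(c(A_Z = strrep("AAA", 6), B_W = strrep("AAA", 6),
                          C_Z = strrep("AAG", 6)))
  d <- inferDirection(aln, frag, profile = prof)
  expect_equal(d$direction, "unknown")
  expect_equal(d$nInformative, 0L)
})

test_that("the exon-span filter drops short within-exon spans with a strict threshold", {
  frags <- data.frame(seq1 = "Z", seq2 = "W",
                      startCol = c(0L, 0L, 100L),
                      endCol = c(40L, 50L, 250L),
                      spanBp = c(40L, 50L, 150L), nSites = c(4L, 5L, 12L),
                      nMismatch = 0L, score = c(40, 50, 150))
  em <- data.frame(exon = 1:3, start = c(0L, 70L, 130L),
                   end = c(60L, 130L, 400L))
  out <- filterFragmentsByExon(frags, em, minSpanBp = 50)
  # 40 bp within its only exon: dropped
  expect_false(any(out$startCol == 0 & out$endCol == 40))
  # exactly 50 bp: kept (the exclusion is a strict less-than)
  expect_true(any(out$endCol == 50))
  # fragment [100, 250): 30 bp of exon 2 and 120 bp of exon 3 ->
  # exon 2 removed from the spanning list, exon 3 kept
  third <- out[out$startCol == 100, ]
  expect_equal(third$spanningExons, "3")
  expect_equal(third$exonSpans, "120")
  # a missing exon map passes fragments through with a warning flag
  expect_warning(pass <- filterFragmentsByExon(frags, NULL), "exon map")
  expect_equal(pass$exonFilter, rep("no-exon-map", 3))
})

test_that("removing a converted exon restores the divergence estimate", {
  sim <- cachedSim("convLocus", function() {
    s <- simulateGametologHistory(uniformConfig(1, "GgMgAp", 100e6,
                                                cdsLength = 900, seed = 41))
    injectGeneConversion(s, "L001", donor = "Ap_W", recipient = "Ap_Z",
                         start = 300, end = 474)
  })
  s <- sim@sequences[[1]]
  em <- data.frame(exon = 1:3, start = c(0L, 300L, 474L),
                   end = c(300L, 474L, 900L))
  aln <- CodonAlignment(setNames(as.character(s[c("Ap_Z", "Ap_W")]),
                                 c("Ap_Z", "Ap_W")), exonMap = em)
  out <- recomputeDivergenceExcluding(aln, convertedExons = 2)
  # the zero-divergence tract drags dS down; removing it raises dS strictly
  expect_gt(out$after@dS, out$before@dS)
  expect_gte(out$dateAfter, out$dateBefore)
  # the recovered dS is within 2 SE of the suppression-time expectation
  expect_lt(abs(out$after@dS - 0.38), 2 * out$after@seDS + 0.02)
  # excluding an unconverted exon of matching divergence leaves dS within SE
  out2 <- recomputeDivergenceExcluding(aln, convertedExons = 1)
  expect_lt(abs(out2$after@dS - out2$before@dS),
            2 * max(out2$after@seDS, out2$before@seDS))
  # errors: empty exon list and emptying exclusions
  expect_error(recomputeDivergenceExcluding(aln, integer(0)), "empty")
  expect_error(recomputeDivergenceExcluding(aln, 1:3), "empties")
})
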