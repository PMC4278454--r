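# Shared fixtures and small constructors for the test suite. Everything is
# generated in code under fixed seeds; heavier simulated datasets are cached
# per session.

.fixtures <- new.env(parent = emptyenv())

# pair alignment (taxon Z vs W) from a simulated locus
pairAln <- function(sim, locus, taxon = "Gg") {
  s <- sim@sequences[[locus]]
  nm <- paste0(taxon, c("_Z", "_W"))
  CodonAlignment(setNames(as.character(s[nm]), nm))
}

# n-tip alignment with chosen tips from a simulated locus
tipsAln <- function(sim, locus, tips) {
  s <- sim@sequences[[locus]]
  CodonAlignment(setNames(as.character(s[tips]), tips))
}

# one suppression event per locus, same lineage/time for all loci
uniformConfig <- function(nLoci, lineage, time, cdsLength = 900, seed = 1,
                          ...) {
  simulationConfig(
    nLoci = nLoci, cdsLength = cdsLength,
    suppressionTimes = data.frame(locus = sprintf("L%03d", seq_len(nLoci)),
                                  lineage = lineage, time = time),
    seed = seed, ...)
}

cachedSim <- function(key, maker) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- maker()
  .fixtures[[key]]
}

# a random in-frame CDS without stop codons
randomCds <- function(nCodons, seed = 1) {
  set.seed(seed)
  tab <- ZWstrata:::codonTables()
  paste(sample(tab$sense, nCodons, replace = TRUE), collapse = "")
}

# brute-force oracle for span-scored fragments: max over all site pairs
# (i, j) with agreeing endpoints of span - pen * internal mismatches
bruteMaxFragScore <- function(agree, cols, pen) {
  idx <- which(agree)
  if (!length(idx)) return(0)
  best <- 1
  for (i in idx) for (j in idx[idx >= i]) {
    mis <- sum(!agree[i:j])
    sc <- (cols[j] - cols[i] + 1) - pen * mis
    if (sc > best) best <- sc
  }
  best
}
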