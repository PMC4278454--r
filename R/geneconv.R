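# Gene-conversion detection between gametologs: silent-site profiles,
# maximal identical fragments bounded by variable sites, a permutation
# test of fragment scores, exon-span filtering, direction inference and
# divergence recomputation after removing converted exons.

#' SilentSiteProfile: silent polymorphic alignment columns
#'
#' @slot cols integer, 0-based alignment columns (strictly increasing)
#' @slot states character matrix (sequences x sites) of nucleotide states,
#'   NA where a sequence is gapped
#' @slot labels sequence labels
#' @exportClass SilentSiteProfile
setClass("SilentSiteProfile",
  representation(cols = "integer", states = "matrix", labels = "character"))

setValidity("SilentSiteProfile", function(object) {
  if (is.unsorted(object@cols, strictly = TRUE))
    return("columns must be strictly increasing")
  TRUE
})

setMethod("show", "SilentSiteProfile", function(object) {
  cat(sprintf("SilentSiteProfile: %d silent polymorphic sites over %d sequences\n",
              length(object@cols), length(object@labels)))
})

#' Silent polymorphic sites of a codon alignment
#'
#' Exactly the nucleotide columns where every present (ungapped) codon
#' encodes the same amino acid but the nucleotides differ across sequences.
#' Conversion fragments are detected on these sites only, because selection
#' heterogeneity at amino-acid-changing sites mimics conversion.
#'
#' @param aln a \linkS4class{CodonAlignment}
#' @return a \linkS4class{SilentSiteProfile}
#' @export
silentPolymorphicSites <- function(aln) {
  stopifnot(is(aln, "CodonAlignment"))
  mr <- maskRanges(aln)
  if (nrow(mr) && any(mr$start %% 3L != 0L | mr$end %% 3L != 0L))
    stop("mask breaks the reading frame: ranges must cover whole codons")
  m <- alnMatrix(aln)
  gc_map <- Biostrings::GENETIC_CODE
  keep <- unmaskedCodonIndex(aln)
  cols <- integer(0)
  states <- list()
  for (cc in keep) {
    colIdx <- (cc - 1L) * 3L + 1:3
    sub <- m[, colIdx, drop = FALSE]
    gap <- apply(sub == "-", 1, any)
    if (sum(!gap) < 2) next
    cods <- apply(sub[!gap, , drop = FALSE], 1, paste, collapse = "")
    if (any(grepl("[^ACGT]", cods))) next
    aas <- gc_map[cods]
    if (length(unique(aas)) != 1) next
    for (p in 1:3) {
      nt <- sub[, p]
      nt[gap] <- NA
      if (length(unique(nt[!is.na(nt)])) > 1) {
        cols <- c(cols, colIdx[p])
        states[[length(states) + 1L]] <- nt
      }
    }
  }
  st <- if (length(states)) do.call(cbind, states) else
    matrix(character(0), nrow = nrow(m), ncol = 0)
  rownames(st) <- alnLabels(aln)
  new("SilentSiteProfile", cols = as.integer(cols - 1L), states = st,
      labels = alnLabels(aln))
}

#' Maximum span-scored fragment of an agreement sequence
#'
#' Fragments run between agreeing sites; the score of a fragment from site
#' i to site j is its alignment span in bp (cols[j] - cols[i] + 1) minus
#' \code{pen} per internal disagreeing site. Linear-time recurrence over
#' sites: the best fragment ending at an agreeing site either extends the
#' previous best or restarts.
#'
#' @param agree logical vector over sites (in positional order)
#' @param cols alignment columns of the sites (same order, increasing for
#'   the observed data; for permuted data the positions stay fixed and the
#'   contents move, so \code{cols} stays sorted)
#' @param pen penalty per internal mismatch in bp
#' @return max score (0 when no site agrees)
#' @keywords internal
.maxFragScore <- function(agree, cols, pen) {
  best <- 0
  cur <- -Inf       # best fragment score ending at the previous agreeing site
  lastC <- NA_real_ # column of that site
  n <- length(agree)
  mis <- 0L         # mismatches since that site
  for (k in seq_len(n)) {
    if (agree[k]) {
      ext <- if (is.finite(cur)) cur + (cols[k] - lastC) - pen * mis else 1
      cur <- max(1, ext)
      lastC <- cols[k]
      mis <- 0L
      if (cur > best) best <- cur
    } else mis <- mis + 1L
  }
  best
}

#' Maximum run span for the strict (gscale = 0) case, vectorised
#' @keywords internal
.maxRunSpan <- function(agree, cols) {
  d <- which(!agree)
  n <- length(agree)
  b <- c(0L, d, n + 1L)
  starts <- b[-length(b)] + 1L
  ends <- b[-1] - 1L
  ok <- starts <= ends
  if (!any(ok)) return(0)
  max(cols[ends[ok]] - cols[starts[ok]] + 1)
}

#' All disjoint span-scored fragments, best first (greedy)
#' @return list of c(startSite, endSite, score, nSites, nMismatch)
#' @keywords internal
.allFragments <- function(agree, cols, pen) {
  n <- length(agree)
  segs <- list()
  findIn <- function(idx) {
    if (!length(idx)) return(NULL)
    a <- agree[idx]; cc <- cols[idx]
    best <- 0; bi <- NA; bj <- NA
    cur <- -Inf; curStart <- NA; lastK <- NA; mis <- 0L
    for (k in seq_along(a)) {
      if (a[k]) {
        ext <- if (is.finite(cur)) cur + (cc[k] - cc[lastK]) - pen * mis else
          -Inf
        if (ext >= 1) cur <- ext else { cur <- 1; curStart <- k }
        lastK <- k
        mis <- 0L
        if (cur > best) { best <- cur; bi <- curStart; bj <- k }
      } else mis <- mis + 1L
    }
    if (best <= 0) return(NULL)
    seg <- idx[bi:bj]
    segs[[length(segs) + 1L]] <<- c(start = seg[1], end = seg[length(seg)],
                                    score = best,
                                    nSites = sum(agree[seg]),
                                    nMismatch = sum(!agree[seg]))
    findIn(idx[idx < seg[1]])
    findIn(idx[idx > seg[length(seg)]])
  }
  findIn(seq_len(n))
  if (!length(segs)) return(segs)
  segs[order(-vapply(segs, `[[`, numeric(1), "score"))]
}

#' @keywords internal
.fragPenalty <- function(cols, gscale, mismatchPenalty) {
  if (gscale == 0) return(1e9)
  spacing <- (max(cols) - min(cols) + 1) / length(cols)
  mismatchPenalty * spacing
}

#' Candidate conversion fragments for a sequence pair
#'
#' Fragments are maximal stretches of identity between the pair over its
#' silent polymorphic sites, bounded by disagreeing sites, and scored by
#' their alignment span in bp (monomorphic columns between the first and
#' last site included). Under \code{gscale = 0} no internal mismatch is
#' permitted; under \code{gscale = 2} each internal mismatch costs
#' \code{mismatchPenalty} mean inter-site spacings of span (default 2.5,
#' so two mismatches cancel roughly five matches' worth of identical
#' span), and only positive-score maximal fragments are kept.
#'
#' @param profile a \linkS4class{SilentSiteProfile}
#' @param pair character of two sequence labels
#' @param gscale 0 (strict) or 2 (relaxed mismatch penalty)
#' @param mismatchPenalty penalty per mismatch under gscale = 2, in units
#'   of the pair's mean inter-site spacing
#' @return data.frame: seq1, seq2, startCol, endCol (0-based half-open
#'   alignment columns), spanBp, nSites, nMismatch, score (sorted by
#'   descending score)
#' @export
findFragments <- function(profile, pair, gscale = 0, mismatchPenalty = 2.5) {
  stopifnot(is(profile, "SilentSiteProfile"), length(pair) == 2)
  if (!gscale %in% c(0, 2)) stop("gscale must be 0 or 2")
  a <- .pairAgreement(profile, pair)
  if (!length(a$agree) || !any(a$agree))
    return(.emptyFragments(pair))
  pen <- .fragPenalty(a$cols, gscale, mismatchPenalty)
  segs <- .allFragments(a$agree, a$cols, pen)
  if (!length(segs)) return(.emptyFragments(pair))
  rows <- lapply(segs, function(s) {
    colFirst <- a$cols[s[["start"]]]
    colLast <- a$cols[s[["end"]]]
    data.frame(seq1 = pair[1], seq2 = pair[2], startCol = colFirst,
               endCol = colLast + 1L, spanBp = colLast - colFirst + 1L,
               nSites = as.integer(s[["nSites"]]),
               nMismatch = as.integer(s[["nMismatch"]]),
               score = s[["score"]])
  })
  out <- do.call(rbind, rows)
  out[order(-out$score, out$startCol), , drop = FALSE]
}

#' @keywords internal
.emptyFragments <- function(pair) {
  data.frame(seq1 = character(), seq2 = character(), startCol = integer(),
             endCol = integer(), spanBp = integer(), nSites = integer(),
             nMismatch = integer(), score = numeric())
}

#' @keywords internal
.pairAgreement <- function(profile, pair) {
  i <- match(pair[1], profile@labels)
  j <- match(pair[2], profile@labels)
  if (is.na(i) || is.na(j)) stop("pair labels not in profile")
  s1 <- profile@states[i, ]
  s2 <- profile@states[j, ]
  ok <- !is.na(s1) & !is.na(s2)
  list(agree = s1[ok] == s2[ok], cols = profile@cols[ok],
       siteIdx = which(ok))
}

#' Permutation test for gene conversion between Z and W groups
#'
#' For every between-group (Z vs W) sequence pair, the observed maximal
#' fragment scores are referred to a null distribution built by randomly
#' permuting the polymorphic-site columns of the alignment
#' (\code{nPerm} shared permutations). Per fragment,
#' \code{sim_p = (1 + #\{permutation max >= score\}) / (nPerm + 1)};
#' \code{corrected_p} applies a Bonferroni factor over the tested pairs,
#' and \code{ka_p} is a Karlin-Altschul-style run-length tail bound
#' reported alongside. Fragments are classed \emph{inner} when the pair's
#' shared states are private to the pair over most of the fragment
#' (conversion between the two aligned sequences' ancestors) and
#' \emph{outer} otherwise; ambiguous cases default to outer.
#'
#' @param aln a \linkS4class{CodonAlignment}
#' @param groupSpec named character: "Z" or "W" per sequence label; NA
#'   excludes a sequence (e.g. the outgroup) from testing (it still
#'   contributes polymorphic sites and the inner/outer classification)
#' @param nPerm permutations (default 10000; below 100 draws a warning)
#' @param seed integer seed
#' @param gscale 0 or 2 (see \code{\link{findFragments}})
#' @param mismatchPenalty penalty per mismatch under gscale = 2
#' @param profile optional precomputed \linkS4class{SilentSiteProfile}
#' @return data.frame of fragments with columns of
#'   \code{\link{findFragments}} plus class, sim_p, corrected_p, ka_p
#' @export
permutationTest <- function(aln, groupSpec, nPerm = 10000L, seed = 1L,
                            gscale = 0, mismatchPenalty = 2.5,
                            profile = NULL) {
  if (nPerm < 100) warning("nPerm < 100 gives a very coarse p-value")
  if (is.null(profile)) profile <- silentPolymorphicSites(aln)
  if (!length(profile@cols)) stop("profile is empty: no silent polymorphic sites")
  gs <- groupSpec[profile@labels]
  zs <- names(gs)[!is.na(gs) & gs == "Z"]
  ws <- names(gs)[!is.na(gs) & gs == "W"]
  if (!length(zs) || !length(ws))
    stop("no between-group (Z vs W) pair under groupSpec")
  pairs <- expand.grid(z = zs, w = ws, stringsAsFactors = FALSE)
  nPairs <- nrow(pairs)
  set.seed(seed)
  nSites <- length(profile@cols)
  perms <- replicate(nPerm, sample.int(nSites), simplify = FALSE)
  out <- list()
  for (k in seq_len(nPairs)) {
    pair <- c(pairs$z[k], pairs$w[k])
    frags <- findFragments(profile, pair, gscale, mismatchPenalty)
    a <- .pairAgreement(profile, pair)
    np <- length(a$agree)
    if (np == 0 || !nrow(frags)) next
    pen <- .fragPenalty(a$cols, gscale, mismatchPenalty)
    full <- np == nSites
    # permute the site contents over the fixed site positions
    nullMax <- vapply(perms, function(p) {
      ap <- if (full) a$agree[p] else {
        sel <- p[p %in% a$siteIdx]
        a$agree[match(sel, a$siteIdx)]
      }
      if (gscale == 0) .maxRunSpan(ap, a$cols) else
        .maxFragScore(ap, a$cols, pen)
    }, numeric(1))
    phat <- mean(a$agree)
    spacing <- (max(a$cols) - min(a$cols) + 1) / np
    frags$class <- vapply(seq_len(nrow(frags)), function(r)
      .innerOuter(profile, pair, frags$startCol[r], frags$endCol[r]),
      character(1))
    frags$sim_p <- vapply(frags$score, function(s)
      (1 + sum(nullMax >= s - 1e-9)) / (nPerm + 1), numeric(1))
    frags$corrected_p <- pmin(1, frags$sim_p * nPairs)
    kap <- 1 - exp(-(np * (1 - phat) + 1) * phat^(frags$score / spacing))
    frags$ka_p <- pmin(1, kap * nPairs)
    out[[length(out) + 1L]] <- frags
  }
  if (!length(out)) return(cbind(.emptyFragments(c("", "")),
                                 data.frame(class = character(),
                                            sim_p = numeric(),
                                            corrected_p = numeric(),
                                            ka_p = numeric())))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Inner/outer classification of a fragment
#'
#' Inner: the identical run is specific to the pair (no outside sequence
#' shares the pair's states over the fragment), pointing at conversion
#' between the two aligned sequences' ancestors. Outer: some sequence
#' outside the pair carries (nearly) the same run, so the identity is
#' ancestral or originated outside the pair. Ambiguity defaults to outer.
#' @keywords internal
.innerOuter <- function(profile, pair, startCol, endCol,
                        outerShareFrac = 0.9) {
  idx <- which(profile@cols >= startCol & profile@cols < endCol)
  i <- match(pair[1], profile@labels)
  j <- match(pair[2], profile@labels)
  others <- setdiff(seq_along(profile@labels), c(i, j))
  if (!length(others) || !length(idx)) return("global-outer")
  s1 <- profile@states[i, idx]
  s2 <- profile@states[j, idx]
  agree <- !is.na(s1) & !is.na(s2) & s1 == s2
  if (!sum(agree)) return("global-outer")
  shareFrac <- vapply(others, function(o) {
    so <- profile@states[o, idx][agree]
    mean(!is.na(so) & so == s1[agree])
  }, numeric(1))
  if (max(shareFrac) >= outerShareFrac) "global-outer" else "global-inner"
}

#' Filter conversion fragments by within-exon span
#'
#' Fragments bounded by distant variable sites can spuriously bridge exons
#' separated by dissimilar introns. For each exon a fragment spans, the
#' within-exon span in bp is computed; exons where the fragment spans less
#' than \code{minSpanBp} are removed from the fragment's spanning-exon
#' list, and fragments left spanning no exon are dropped.
#'
#' @param fragments output of \code{\link{permutationTest}} or
#'   \code{\link{findFragments}}
#' @param exonMap data.frame(exon, start, end), 0-based half-open columns;
#'   NULL passes fragments through with a warning flag
#' @param minSpanBp minimum within-exon span (default 50; exactly 50 is
#'   kept, the rule is a strict less-than)
#' @return the filtered fragments with columns spanningExons and exonSpans
#'   added (comma-separated)
#' @export
filterFragmentsByExon <- function(fragments, exonMap, minSpanBp = 50L) {
  if (is.null(exonMap) || !nrow(exonMap)) {
    warning("no exon map: fragments passed through unfiltered")
    fragments$spanningExons <- NA_character_
    fragments$exonSpans <- NA_character_
    fragments$exonFilter <- "no-exon-map"
    return(fragments)
  }
  keepRows <- logical(nrow(fragments))
  spanning <- character(nrow(fragments))
  spans <- character(nrow(fragments))
  for (r in seq_len(nrow(fragments))) {
    s <- fragments$startCol[r]; e <- fragments$endCol[r]
    ov <- pmin(exonMap$end, e) - pmax(exonMap$start, s)
    hit <- which(ov >= minSpanBp)
    keepRows[r] <- length(hit) > 0
    spanning[r] <- paste(exonMap$exon[hit], collapse = ",")
    spans[r] <- paste(ov[hit], collapse = ",")
  }
  out <- fragments[keepRows, , drop = FALSE]
  out$spanningExons <- spanning[keepRows]
  out$exonSpans <- spans[keepRows]
  out$exonFilter <- "applied"
  rownames(out) <- NULL
  out
}

#' Infer the direction of a conversion tract
#'
#' At each silent site inside the fragment where the pair shares a state,
#' the state is compared with the consensus of each member's chromosome
#' group among the remaining sequences (other species' Z or W genes; the
#' outgroup counts toward the Z side). A site votes for donor = the member
#' whose group consensus the shared state matches exclusively. The
#' direction is called when at least \code{minVotes} informative sites
#' exist and at least \code{voteFrac} of them agree; otherwise a
#' maximum-likelihood tree of the fragment-spanning exon columns is built
#' and its topology class (cluster by sex chromosome vs by species)
#' reported, with the direction left unknown.
#'
#' @param aln the \linkS4class{CodonAlignment} (including outgroup /
#'   third-species sequences)
#' @param fragment one row of \code{\link{permutationTest}} output
#' @param minVotes minimum informative sites for a vote call (default 3)
#' @param voteFrac minimum agreeing fraction (default 0.8)
#' @param outgroup outgroup label for the fallback exon tree
#' @param profile optional precomputed profile
#' @return list: direction ("<donor>-><recipient>" or "unknown"),
#'   votes (named), nInformative, exonTreeTopology
#'   ("by-sex"/"by-species"/"other"/NA)
#' @export
inferDirection <- function(aln, fragment, minVotes = 3L, voteFrac = 0.8,
                           outgroup = "Tg_Z", profile = NULL) {
  if (is.null(profile)) profile <- silentPolymorphicSites(aln)
  pair <- c(fragment$seq1, fragment$seq2)
  idx <- which(profile@cols >= fragment$startCol &
                 profile@cols < fragment$endCol)
  i <- match(pair[1], profile@labels)
  j <- match(pair[2], profile@labels)
  chromOf <- function(lbl) sub(".*_", "", lbl)
  grp <- chromOf(profile@labels)
  votes <- c(0L, 0L)
  names(votes) <- pair
  for (s in idx) {
    s1 <- profile@states[i, s]; s2 <- profile@states[j, s]
    if (is.na(s1) || is.na(s2) || s1 != s2) next
    cons <- function(member) {
      rel <- setdiff(which(grp == chromOf(profile@labels[member])),
                     c(i, j))
      st <- profile@states[rel, s]
      st <- st[!is.na(st)]
      if (!length(st)) return(NA_character_)
      tb <- sort(table(st), decreasing = TRUE)
      if (length(tb) > 1 && tb[1] == tb[2]) return(NA_character_)
      names(tb)[1]
    }
    c1 <- cons(i); c2 <- cons(j)
    m1 <- !is.na(c1) && c1 == s1
    m2 <- !is.na(c2) && c2 == s1
    if (m1 && !m2) votes[1] <- votes[1] + 1L
    if (m2 && !m1) votes[2] <- votes[2] + 1L
  }
  nInf <- sum(votes)
  if (nInf >= minVotes && max(votes) / nInf >= voteFrac) {
    donor <- names(votes)[which.max(votes)]
    recipient <- setdiff(pair, donor)
    return(list(direction = paste0(donor, "->", recipient), votes = votes,
                nInformative = nInf, exonTreeTopology = NA_character_))
  }
  # fallback: exon tree over the fragment-spanning columns
  topo <- NA_character_
  n <- length(alnLabels(aln))
  if (n >= 4 && n <= 8 && outgroup %in% alnLabels(aln)) {
    s0 <- (fragment$startCol %/% 3L) * 3L
    e0 <- min(alnLength(aln), as.integer(ceiling(fragment$endCol / 3) * 3))
    m <- alnMatrix(aln)[, (s0 + 1L):e0, drop = FALSE]
    sub <- try(CodonAlignment(setNames(apply(m, 1, paste, collapse = ""),
                                       alnLabels(aln))), silent = TRUE)
    if (!inherits(sub, "try-error") && alnLength(sub) >= 30) {
      tr <- try(suppressWarnings(mlTree(sub, outgroup = outgroup)),
                silent = TRUE)
      if (!inherits(tr, "try-error")) {
        splits <- tr@fits$splits[[tr@fits$bestIdx]]
        tips <- alnLabels(aln)
        wTips <- tips[chromOf(tips) == "W"]
        bySex <- length(wTips) >= 2 &&
          .splitKey(wTips, tips) %in% splits
        taxa <- unique(sub("_[ZW]$", "", tips))
        byTaxon <- vapply(taxa, function(tx) {
          tt <- tips[sub("_[ZW]$", "", tips) == tx]
          length(tt) == 2 && .splitKey(tt, tips) %in% splits
        }, logical(1))
        topo <- if (bySex) "by-sex" else if (any(byTaxon)) "by-species"
        else "other"
      }
    }
  }
  list(direction = "unknown", votes = votes, nInformative = nInf,
       exonTreeTopology = topo)
}

#' Recompute pairwise divergence after removing converted exons
#'
#' Drops the converted exons' columns from the pair alignment and
#' re-estimates dS/dN by maximum likelihood; reports before/after
#' estimates and molecular-clock dates. Conversion homogenises tracts, so
#' removing them is expected to increase the estimated divergence time.
#'
#' @param aln a two-sequence \linkS4class{CodonAlignment} with an exon map
#' @param convertedExons exon ids (matching \code{exonMap(aln)$exon})
#' @param minCodons passed to \code{\link{mlPairwiseDivergence}}
#' @return list: before, after (\linkS4class{DivergenceEstimate}s),
#'   dateBefore, dateAfter (My)
#' @export
recomputeDivergenceExcluding <- function(aln, convertedExons,
                                         minCodons = 50L) {
  em <- exonMap(aln)
  if (!nrow(em)) stop("alignment has no exon map")
  if (!length(convertedExons)) stop("converted exon list is empty")
  sel <- em[em$exon %in% convertedExons, , drop = FALSE]
  if (!nrow(sel)) stop("no exon map entry matches the converted exons")
  before <- mlPairwiseDivergence(aln, minCodons)
  reduced <- dropColumns(aln, sel[, c("start", "end")])
  after <- mlPairwiseDivergence(reduced, minCodons)
  list(before = before, after = after,
       dateBefore = if (before@dS <= 1) clockDate(before@dS) else NA_real_,
       dateAfter = if (after@dS <= 1) clockDate(after@dS) else NA_real_)
}
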