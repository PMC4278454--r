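# Similarity search with an internal Smith-Waterman scorer and a
# Karlin-Altschul e-value calibration, reciprocal-best-hit orthology, the
# three-step W->Z gametolog pairing rule, candidate filtering, and paralog
# resolution by minimal dS.

#' Karlin-Altschul parameters for the internal nucleotide scorer
#'
#' Solves sum p_i p_j exp(lambda s_ij) = 1 for lambda under i.i.d. uniform
#' base composition and the match/mismatch scores in use. K is a documented
#' calibration constant (0.1): e-values are used as a ranked cutoff, not as
#' exact tail probabilities.
#'
#' @param match,mismatch alignment scores (defaults +5/-4)
#' @param K Karlin-Altschul K (default 0.1)
#' @return list(lambda, K)
#' @keywords internal
karlinAltschulParams <- function(match = 5, mismatch = -4, K = 0.1) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  lambda <- stats::uniroot(f, c(1e-6, 2))$root
  list(lambda = lambda, K = K)
}

#' @keywords internal
.swScore <- function(queries, targets) {
  # local alignment scores of each query against each target
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                  baseOnly = TRUE)
  out <- matrix(0, length(queries), length(targets),
                dimnames = list(names(queries), names(targets)))
  for (q in seq_along(queries)) {
    out[q, ] <- Biostrings::pairwiseAlignment(
      targets, queries[[q]], type = "local", substitutionMatrix = mat,
      gapOpening = 10, gapExtension = 2, scoreOnly = TRUE)
  }
  out
}

#' Ranked similarity hits under an e-value cutoff
#'
#' Scores every query against every target with the internal local aligner
#' (match +5, mismatch -4, affine gaps) and converts scores to e-values via
#' the Karlin-Altschul formula E = K m n exp(-lambda S) over the whole
#' target set. Hits at or below the cutoff are returned per query, sorted
#' by descending score with deterministic ties broken by target id. A
#' pre-computed tabular hit table (BLAST outfmt-6-like columns
#' query, target, score, evalue) can be supplied instead of sequences via
#' \code{hitTable}.
#'
#' @param queries,targets named \code{DNAStringSet}s (or named character)
#' @param evalueCutoff e-value threshold (default 1e-10)
#' @param hitTable optional data.frame(query, target, score, evalue)
#'   bypassing the internal aligner
#' @return data.frame: query, target, score, evalue (possibly 0 rows)
#' @export
bestHits <- function(queries, targets, evalueCutoff = 1e-10,
                     hitTable = NULL) {
  if (!is.null(hitTable)) {
    h <- hitTable[hitTable$evalue <= evalueCutoff, , drop = FALSE]
    h <- h[order(h$query, -h$score, h$target), , drop = FALSE]
    rownames(h) <- NULL
    return(h)
  }
  if (is.character(queries)) queries <- Biostrings::DNAStringSet(queries)
  if (is.character(targets)) targets <- Biostrings::DNAStringSet(targets)
  if (length(targets) == 0) stop("empty target set")
  if (length(queries) == 0) stop("empty query set")
  ka <- karlinAltschulParams()
  n <- sum(Biostrings::width(targets))
  sc <- .swScore(queries, targets)
  rows <- list()
  for (q in seq_along(queries)) {
    m <- Biostrings::width(queries)[q]
    ev <- ka$K * m * n * exp(-ka$lambda * sc[q, ])
    keep <- which(ev <= evalueCutoff)
    if (!length(keep)) next
    d <- data.frame(query = names(queries)[q],
                    target = names(targets)[keep],
                    score = sc[q, keep], evalue = ev[keep])
    d <- d[order(-d$score, d$target), , drop = FALSE]
    rows[[length(rows) + 1L]] <- d
  }
  if (!length(rows))
    return(data.frame(query = character(), target = character(),
                      score = numeric(), evalue = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reciprocal best hits between two sequence sets
#'
#' (a, b) is reported iff b is a's highest-scoring hit in B and a is b's
#' highest-scoring hit in A, both under the e-value cutoff. Symmetric in
#' its arguments.
#'
#' @param setA,setB named \code{DNAStringSet}s
#' @param evalueCutoff e-value threshold (default 1e-10)
#' @return data.frame: a, b, scoreAB, scoreBA
#' @export
reciprocalBestHits <- function(setA, setB, evalueCutoff = 1e-10) {
  ab <- bestHits(setA, setB, evalueCutoff)
  ba <- bestHits(setB, setA, evalueCutoff)
  topOf <- function(h) {
    if (!nrow(h)) return(h)
    h[!duplicated(h$query), , drop = FALSE]
  }
  tab <- topOf(ab)
  tba <- topOf(ba)
  rows <- list()
  for (k in seq_len(nrow(tab))) {
    a <- tab$query[k]; b <- tab$target[k]
    hit <- tba[tba$query == b, , drop = FALSE]
    if (nrow(hit) && hit$target[1] == a)
      rows[[length(rows) + 1L]] <- data.frame(a = a, b = b,
                                              scoreAB = tab$score[k],
                                              scoreBA = hit$score[1])
  }
  if (!length(rows))
    return(data.frame(a = character(), b = character(), scoreAB = numeric(),
                      scoreBA = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pair W-linked genes with their Z-linked gametologs (three-step rule)
#'
#' For each W-linked query: (1) find the orthologous reference W gene by
#' best hit; (2) map it to the reference Z ortholog through the supplied
#' W-Z table; (3) take the reciprocal best hit of that reference Z gene in
#' the species' Z/candidate CDS set; when no reciprocal best hit exists
#' (typically because of high Z-W similarity), fall back to the reference Z
#' gene's next-best hit and record the route. A chosen Z gene that is
#' itself in the W candidate set is flagged rather than accepted.
#'
#' @param wGenes named \code{DNAStringSet}: the species' W-linked queries
#' @param referenceW named \code{DNAStringSet}: reference W genes
#' @param referenceZ named \code{DNAStringSet}: reference Z genes
#' @param refMap data.frame(w, z): reference W -> Z gametolog table
#' @param speciesCds named \code{DNAStringSet}: the species' CDS set in
#'   which the Z ortholog is sought (it may contain the W candidates
#'   themselves; a young W gene can out-score the true Z ortholog, in
#'   which case the reciprocal choice is rejected and the next-best hit
#'   engaged)
#' @param evalueCutoff e-value threshold (default 1e-10)
#' @return data.frame per W query: wGene, refW, refZ, zGene, route
#'   ("reciprocal-best" / "next-best-fallback" / NA), coverage (aligned
#'   fraction of the reference W gene), alignedLength (bp aligned with the
#'   chosen Z gene), zInWSet flag, reason (for unpaired records)
#' @export
pairGametologs <- function(wGenes, referenceW, referenceZ, refMap,
                           speciesCds, evalueCutoff = 1e-10) {
  hitsWrefW <- bestHits(wGenes, referenceW, evalueCutoff)
  hitsRefZsp <- bestHits(referenceZ, speciesCds, evalueCutoff)
  hitsSpRefZ <- bestHits(speciesCds, referenceZ, evalueCutoff)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                  baseOnly = TRUE)
  rows <- list()
  for (w in names(wGenes)) {
    row <- data.frame(wGene = w, refW = NA_character_, refZ = NA_character_,
                      zGene = NA_character_, route = NA_character_,
                      coverage = NA_real_, alignedLength = NA_integer_,
                      zInWSet = FALSE, reason = NA_character_)
    h1 <- hitsWrefW[hitsWrefW$query == w, , drop = FALSE]
    if (!nrow(h1)) {
      row$reason <- "no reference W hit"
      rows[[length(rows) + 1L]] <- row; next
    }
    row$refW <- h1$target[1]
    pa <- Biostrings::pairwiseAlignment(
      wGenes[[w]], referenceW[[row$refW]], type = "local",
      substitutionMatrix = mat, gapOpening = 10, gapExtension = 2)
    row$coverage <- Biostrings::nchar(pa) /
      Biostrings::width(referenceW)[names(referenceW) == row$refW][1]
    mz <- refMap$z[refMap$w == row$refW]
    if (!length(mz)) {
      row$reason <- "no reference ortholog"
      rows[[length(rows) + 1L]] <- row; next
    }
    row$refZ <- mz[1]
    fwd <- hitsRefZsp[hitsRefZsp$query == row$refZ, , drop = FALSE]
    if (!nrow(fwd)) {
      row$reason <- "no species hit for reference Z"
      rows[[length(rows) + 1L]] <- row; next
    }
    candidate <- fwd$target[1]
    back <- hitsSpRefZ[hitsSpRefZ$query == candidate, , drop = FALSE]
    reciprocal <- nrow(back) && back$target[1] == row$refZ
    # a reciprocal partner that is itself a W candidate is a gametolog
    # shadowing the Z ortholog, not the Z ortholog
    if (reciprocal && !candidate %in% names(wGenes)) {
      row$zGene <- candidate
      row$route <- "reciprocal-best"
    } else {
      nxt <- setdiff(fwd$target, names(wGenes))
      nxt <- nxt[nxt != candidate]
      if (length(nxt)) {
        row$zGene <- nxt[1]
        row$route <- "next-best-fallback"
      } else {
        row$reason <- "no reciprocal best hit and no next-best hit"
        rows[[length(rows) + 1L]] <- row; next
      }
    }
    row$zInWSet <- row$zGene %in% names(wGenes)
    paz <- Biostrings::pairwiseAlignment(
      wGenes[[w]], speciesCds[[row$zGene]], type = "local",
      substitutionMatrix = mat, gapOpening = 10, gapExtension = 2)
    row$alignedLength <- Biostrings::nchar(paz)
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Coverage/length exclusion filter for W candidates
#'
#' A candidate is excluded iff the coverage of the reference W ortholog is
#' below \code{minCoverage} AND the aligned length with the Z ortholog is
#' below \code{minAligned} (the literal conjunction); \code{rule = "or"}
#' selects the stricter disjunctive variant. Candidates failing exactly one
#' metric under the default rule are kept but flagged borderline.
#'
#' @param coverage aligned fraction of the reference W ortholog (vector ok)
#' @param alignedLength aligned length with the Z ortholog in bp
#' @param minCoverage default 0.25
#' @param minAligned default 150
#' @param rule "and" (default, literal) or "or"
#' @return data.frame: coverage, alignedLength, decision
#'   ("keep"/"exclude"), borderline, reason
#' @examples
#' filterWCandidates(0.20, 140)$decision  # "exclude"
#' filterWCandidates(0.20, 300)$decision  # "keep" (conjunction)
#' @export
filterWCandidates <- function(coverage, alignedLength, minCoverage = 0.25,
                              minAligned = 150, rule = c("and", "or")) {
  rule <- match.arg(rule)
  lowCov <- coverage < minCoverage
  lowLen <- alignedLength < minAligned
  excl <- if (rule == "and") lowCov & lowLen else lowCov | lowLen
  reason <- character(length(excl))
  reason[lowCov & lowLen] <- sprintf(
    "coverage %.2f < %.2f and aligned length %d < %d",
    coverage[lowCov & lowLen], minCoverage,
    as.integer(alignedLength[lowCov & lowLen]), as.integer(minAligned))
  reason[xor(lowCov, lowLen)] <- "one metric below threshold"
  data.frame(coverage = coverage, alignedLength = alignedLength,
             decision = ifelse(excl, "exclude", "keep"),
             borderline = xor(lowCov, lowLen) & !excl,
             reason = ifelse(nzchar(reason), reason, NA_character_))
}

#' Resolve multiple W paralogs to the true gametolog pair
#'
#' Among candidate pairs for one locus, the pair with the lowest dS is
#' retained (gene duplicates accumulate divergence under relaxed or
#' diversifying selection); ties are broken by the longest aligned length,
#' then lexicographically by W gene id. All candidates are retained in the
#' attached report.
#'
#' @param candidates data.frame with columns \code{wGene}, \code{zGene},
#'   \code{dS}, \code{alignedLength}
#' @return the chosen row, with the full candidate table (ordered by dS) in
#'   attribute \code{"candidates"}; a 0-row data.frame with attribute
#'   \code{"reason"} when no candidate has an estimable dS (unresolved)
#' @export
resolveParalogs <- function(candidates) {
  stopifnot(all(c("wGene", "zGene", "dS", "alignedLength") %in%
                  names(candidates)))
  ok <- candidates[!is.na(candidates$dS), , drop = FALSE]
  if (!nrow(ok)) {
    out <- candidates[0, , drop = FALSE]
    attr(out, "reason") <- "no candidate with estimable dS"
    return(out)
  }
  ord <- order(ok$dS, -ok$alignedLength, ok$wGene)
  chosen <- ok[ord[1], , drop = FALSE]
  rownames(chosen) <- NULL
  attr(chosen, "candidates") <- ok[ord, , drop = FALSE]
  chosen
}
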