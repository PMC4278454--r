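# Codon-aware alignment construction, masking and FASTA round-tripping.

#' Construct a CodonAlignment from pre-aligned sequences
#'
#' Low-level constructor; most users call \code{\link{buildCodonAlignment}}.
#'
#' @param seqs named character vector or \code{DNAStringSet} of equal-width
#'   aligned CDS (gaps as \code{-}, whole codons only)
#' @param exonMap optional data.frame(exon, start, end), 0-based half-open
#'   alignment columns
#' @param mask optional data.frame(start, end) of masked column ranges,
#'   0-based half-open
#' @return a \linkS4class{CodonAlignment}
#' @export
CodonAlignment <- function(seqs, exonMap = NULL, mask = NULL) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(exonMap))
    exonMap <- data.frame(exon = integer(), start = integer(),
                          end = integer())
  ir <- if (is.null(mask) || nrow(as.data.frame(mask)) == 0) {
    IRanges::IRanges()
  } else {
    m <- as.data.frame(mask)
    IRanges::reduce(IRanges::IRanges(start = m$start + 1L, end = m$end))
  }
  new("CodonAlignment", seqs = seqs, exonMap = exonMap, mask = ir)
}

#' @describeIn CodonAlignment number of alignment columns
#' @param x,object a CodonAlignment
#' @export
alnLength <- function(x) unname(Biostrings::width(x@seqs)[1])

#' @describeIn CodonAlignment sequence labels
#' @export
alnLabels <- function(x) names(x@seqs)

#' @describeIn CodonAlignment alignment as a character matrix
#'   (sequences x columns)
#' @export
alnMatrix <- function(x) as.matrix(x@seqs)

#' @describeIn CodonAlignment masked column ranges as a 0-based half-open
#'   data.frame
#' @export
maskRanges <- function(x) {
  ir <- x@mask
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' @describeIn CodonAlignment the exon map (0-based half-open columns)
#' @export
exonMap <- function(x) x@exonMap

#' Indices of codon columns not covered by the mask
#' @param x a CodonAlignment
#' @return integer vector of codon-column indices (1-based)
#' @keywords internal
unmaskedCodonIndex <- function(x) {
  ncod <- alnLength(x) %/% 3L
  if (length(x@mask) == 0) return(seq_len(ncod))
  maskedCols <- unlist(lapply(seq_along(x@mask), function(i)
    seq(IRanges::start(x@mask)[i], IRanges::end(x@mask)[i])))
  maskedCodons <- unique((maskedCols - 1L) %/% 3L + 1L)
  setdiff(seq_len(ncod), maskedCodons)
}

#' Per-sequence codon matrix of the unmasked alignment
#'
#' @param x a CodonAlignment
#' @param drop logical; drop codon columns that are gapped or ambiguous in
#'   any sequence (pairwise-complete extraction is the caller's job)
#' @return character matrix (codon columns x sequences); gapped/ambiguous
#'   codons are NA
#' @keywords internal
codonMatrix <- function(x, drop = FALSE) {
  m <- alnMatrix(x)
  keep <- unmaskedCodonIndex(x)
  tab <- codonTables()
  cods <- vapply(seq_len(nrow(m)), function(i) {
    cc <- apply(matrix(m[i, ], nrow = 3), 2, paste, collapse = "")
    cc
  }, character(alnLength(x) %/% 3L))
  if (is.null(dim(cods))) cods <- matrix(cods, nrow = 1)
  cods <- cods[keep, , drop = FALSE]
  colnames(cods) <- alnLabels(x)
  cods[!cods %in% tab$sense] <- NA
  if (drop) cods <- cods[stats::complete.cases(cods), , drop = FALSE]
  cods
}

setMethod("show", "CodonAlignment", function(object) {
  cat(sprintf("CodonAlignment: %d sequences x %d columns (%d codons)\n",
              length(object@seqs), alnLength(object),
              alnLength(object) %/% 3L))
  cat(sprintf("  masked ranges: %d; exons annotated: %d\n",
              length(object@mask), nrow(object@exonMap)))
  cat("  tips:", paste(alnLabels(object), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------

.stops <- c("TAA", "TAG", "TGA")

#' Validate and translate a set of CDS, stripping terminal stop codons
#' @keywords internal
.checkCds <- function(cds) {
  if (is.character(cds)) cds <- Biostrings::DNAStringSet(cds)
  if (is.null(names(cds)))
    names(cds) <- paste0("seq", seq_along(cds))
  for (i in seq_along(cds)) {
    s <- as.character(cds[[i]])
    if (nchar(s) %% 3L != 0L)
      stop("CDS '", names(cds)[i], "' length is not a multiple of 3")
    cod <- splitCodons(s)
    if (cod[length(cod)] %in% .stops) {
      cod <- cod[-length(cod)]
      s <- paste(cod, collapse = "")
      cds[[i]] <- Biostrings::DNAString(s)
    }
    hit <- which(cod %in% .stops)
    if (length(hit))
      stop("CDS '", names(cds)[i], "' contains an internal stop codon at codon ",
           hit[1])
    if (grepl("[^ACGT]", s))
      stop("CDS '", names(cds)[i], "' contains non-ACGT characters")
  }
  cds
}

#' Build a codon-aware alignment by protein alignment and back-translation
#'
#' Sequences are translated, the proteins aligned (Needleman-Wunsch with
#' BLOSUM62 for a pair; centre-star progressive alignment of pairwise
#' profiles for more than two sequences), and the codons threaded back
#' through the protein alignment, so gaps always occupy whole codons.
#'
#' @param cds named character vector or \code{DNAStringSet} of in-frame CDS
#'   (terminal stop codons are stripped; internal stops are an error naming
#'   the codon)
#' @param exonMap optional data.frame(exon, start, end) of exon boundaries in
#'   0-based half-open CDS coordinates of the first sequence; converted to
#'   alignment columns
#' @param aligner optional function(aa1, aa2) returning a list with aligned
#'   character scalars \code{a} and \code{b}; defaults to the built-in
#'   Needleman-Wunsch via \code{Biostrings::pairwiseAlignment}
#' @return a \linkS4class{CodonAlignment}
#' @examples
#' aln <- buildCodonAlignment(c(a = "ATGAAACCC", b = "ATGAAACCC"))
#' alnLength(aln)
#' @export
buildCodonAlignment <- function(cds, exonMap = NULL, aligner = NULL) {
  cds <- .checkCds(cds)
  aa <- vapply(seq_along(cds), function(i)
    as.character(Biostrings::translate(cds[[i]])), character(1))
  names(aa) <- names(cds)
  if (is.null(aligner)) aligner <- .proteinPairAligner
  alignedAA <- if (length(cds) == 1) {
    aa
  } else if (length(cds) == 2) {
    al <- aligner(aa[1], aa[2])
    setNames(c(al$a, al$b), names(aa))
  } else {
    .centerStarAlign(aa, aligner)
  }
  alignedCodons <- vapply(seq_along(cds), function(i) {
    prot <- strsplit(alignedAA[[names(cds)[i]]], "")[[1]]
    cods <- splitCodons(as.character(cds[[i]]))
    out <- character(length(prot))
    k <- 0L
    for (p in seq_along(prot)) {
      if (prot[p] == "-") out[p] <- "---"
      else { k <- k + 1L; out[p] <- cods[k] }
    }
    paste(out, collapse = "")
  }, character(1))
  names(alignedCodons) <- names(cds)
  em <- NULL
  if (!is.null(exonMap)) {
    # map CDS coordinates of the first sequence to alignment columns
    prot1 <- strsplit(alignedAA[[names(cds)[1]]], "")[[1]]
    colOfCds <- integer(0)      # alignment column (1-based) per CDS position
    k <- 0L
    for (p in seq_along(prot1)) {
      if (prot1[p] != "-") {
        colOfCds <- c(colOfCds, (p - 1L) * 3L + 1:3)
        k <- k + 1L
      }
    }
    em <- data.frame(exon = exonMap$exon,
                     start = colOfCds[exonMap$start + 1L] - 1L,
                     end = colOfCds[exonMap$end])
  }
  CodonAlignment(alignedCodons, exonMap = em)
}

#' @keywords internal
.proteinPairAligner <- function(aa1, aa2) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(aa1), Biostrings::AAString(aa2),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

#' Centre-star progressive protein alignment
#'
#' The centre is the sequence with the highest summed pairwise score; every
#' other sequence is aligned to it and the pairwise gap patterns merged.
#' Adequate for the small sets of closely related gametolog CDS this package
#' handles; not a general MSA engine.
#' @keywords internal
.centerStarAlign <- function(aa, aligner) {
  n <- length(aa)
  sc <- matrix(0, n, n)
  als <- vector("list", n * n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    al <- aligner(aa[i], aa[j])
    sc[i, j] <- sc[j, i] <- if (!is.null(al$score)) al$score else 0
  }
  center <- which.max(rowSums(sc))
  Lc <- nchar(aa[center])
  # per pairwise alignment: insertions relative to centre at slots 0..Lc
  ins <- matrix(0L, n, Lc + 1L)
  pairAl <- vector("list", n)
  for (j in seq_len(n)) {
    if (j == center) next
    al <- aligner(aa[center], aa[j])
    pairAl[[j]] <- al
    cc <- strsplit(al$a, "")[[1]]
    pos <- 0L
    run <- 0L
    for (ch in cc) {
      if (ch == "-") run <- run + 1L
      else {
        ins[j, pos + 1L] <- max(ins[j, pos + 1L], run)
        run <- 0L; pos <- pos + 1L
      }
    }
    ins[j, Lc + 1L] <- max(ins[j, Lc + 1L], run)
  }
  gIns <- apply(ins, 2, max)    # merged insertion width per slot
  pad <- function(k) strrep("-", k)
  out <- setNames(character(n), names(aa))
  # centre in merged coordinates
  ccods <- strsplit(aa[center], "")[[1]]
  buf <- pad(gIns[1])
  for (p in seq_len(Lc)) buf <- paste0(buf, ccods[p], pad(gIns[p + 1L]))
  out[center] <- buf
  for (j in seq_len(n)) {
    if (j == center) next
    al <- pairAl[[j]]
    cc <- strsplit(al$a, "")[[1]]
    ss <- strsplit(al$b, "")[[1]]
    buf <- character(0)
    pos <- 0L                    # centre residues consumed
    slotUsed <- 0L               # insertion width used in current slot
    for (k in seq_along(cc)) {
      if (cc[k] == "-") {
        buf <- c(buf, ss[k]); slotUsed <- slotUsed + 1L
      } else {
        buf <- c(buf, pad(gIns[pos + 1L] - slotUsed), ss[k])
        slotUsed <- 0L; pos <- pos + 1L
      }
    }
    buf <- c(buf, pad(gIns[Lc + 1L] - slotUsed))
    out[j] <- paste(buf, collapse = "")
  }
  out
}

# ---------------------------------------------------------------------------

#' Mask poorly aligned regions
#'
#' A deterministic surrogate for manual alignment inspection: codon columns
#' with more than \code{maxGapFrac} gapped sequences, and windows of
#' \code{window} codons whose mean pairwise codon identity falls below
#' \code{minIdentity}, are added to the alignment mask. Masking operates on
#' whole codon columns and never splits a codon; it is idempotent because
#' the rule is a pure function of the unaligned content.
#'
#' @param aln a \linkS4class{CodonAlignment}
#' @param maxGapFrac mask codon columns with a gap fraction above this
#'   (default 0.5)
#' @param window window width in codons for the identity rule (default 5)
#' @param minIdentity minimum mean pairwise identity per window (default 0.4)
#' @return the alignment with an updated mask
#' @export
maskPoorRegions <- function(aln, maxGapFrac = 0.5, window = 5L,
                            minIdentity = 0.4) {
  stopifnot(is(aln, "CodonAlignment"))
  m <- alnMatrix(aln)
  ncod <- alnLength(aln) %/% 3L
  nseq <- nrow(m)
  codList <- lapply(seq_len(nseq), function(i)
    apply(matrix(m[i, ], nrow = 3), 2, paste, collapse = ""))
  cods <- do.call(rbind, codList)          # nseq x ncod
  gapFrac <- colMeans(cods == "---")
  maskCodon <- gapFrac > maxGapFrac
  if (nseq >= 2 && ncod >= window) {
    prs <- combn(nseq, 2)
    ident <- matrix(NA, ncol(prs), ncod)
    for (k in seq_len(ncol(prs))) {
      a <- cods[prs[1, k], ]; b <- cods[prs[2, k], ]
      ok <- a != "---" & b != "---"
      ident[k, ok] <- as.numeric(a[ok] == b[ok])
    }
    meanIdent <- colMeans(ident, na.rm = TRUE)
    for (s in seq_len(ncod - window + 1L)) {
      w <- s:(s + window - 1L)
      mi <- mean(meanIdent[w], na.rm = TRUE)
      if (!is.nan(mi) && mi < minIdentity) maskCodon[w] <- TRUE
    }
  }
  if (all(maskCodon)) stop("empty alignment after masking")
  idx <- which(maskCodon)
  newMask <- if (length(idx)) {
    cols <- sort(unique(c(unlist(lapply(idx, function(i)
      ((i - 1L) * 3L + 1L):(i * 3L))))))
    IRanges::reduce(c(aln@mask, IRanges::IRanges(cols, cols)))
  } else aln@mask
  initialize(aln, mask = newMask)
}

# ---------------------------------------------------------------------------

#' Read coding sequences from a FASTA file
#' @param path file path
#' @return a \code{DNAStringSet}
#' @export
readCodonFasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write sequences or an alignment to FASTA
#' @param x a \code{DNAStringSet} or \linkS4class{CodonAlignment}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writeCodonFasta <- function(x, path) {
  if (is(x, "CodonAlignment")) x <- x@seqs
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Drop alignment columns (e.g. converted exons) from a CodonAlignment
#' @param aln a CodonAlignment
#' @param ranges data.frame(start, end), 0-based half-open columns to remove
#'   (rounded out to whole codons)
#' @return a new CodonAlignment without those columns
#' @keywords internal
dropColumns <- function(aln, ranges) {
  L <- alnLength(aln)
  drop <- rep(FALSE, L)
  for (k in seq_len(nrow(ranges))) {
    s <- (ranges$start[k] %/% 3L) * 3L
    e <- ceiling(ranges$end[k] / 3) * 3
    drop[(s + 1L):min(e, L)] <- TRUE
  }
  if (all(drop)) stop("removing these ranges empties the alignment")
  m <- alnMatrix(aln)[, !drop, drop = FALSE]
  seqs <- apply(m, 1, paste, collapse = "")
  CodonAlignment(setNames(seqs, alnLabels(aln)))
}
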