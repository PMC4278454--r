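# Genetic-code machinery shared by the divergence, simulation and selection
# code. Everything here is precomputed once per session and cached.

.zw_cache <- new.env(parent = emptyenv())

#' Sense-codon tables for the universal genetic code
#'
#' Returns (and caches) the codon bookkeeping used by the codon substitution
#' model and the counting estimator: the 61 sense codons, their amino acids,
#' and the single-nucleotide neighbour structure (which codon pairs differ at
#' one position, whether that change is a transition, and whether it is
#' synonymous).
#'
#' @return A list with elements \code{sense} (character, 61 codons),
#'   \code{aa} (amino acid per sense codon), \code{idx} (named lookup from
#'   codon string to 1..61), \code{pairs} (data.frame of single-difference
#'   sense-codon pairs with columns \code{i}, \code{j}, \code{pos},
#'   \code{transition}, \code{synonymous}), and \code{ngsites}
#'   (61 x 1 numeric: Nei-Gojobori synonymous site count per codon).
#' @keywords internal
codonTables <- function() {
  if (!is.null(.zw_cache$codons)) return(.zw_cache$codons)
  gc_map <- Biostrings::GENETIC_CODE
  all64 <- names(gc_map)
  sense <- all64[gc_map != "*"]
  aa <- unname(gc_map[sense])
  idx <- seq_along(sense)
  names(idx) <- sense
  nts <- c("A", "C", "G", "T")
  is_transition <- function(a, b) {
    (a == "A" & b == "G") | (a == "G" & b == "A") |
      (a == "C" & b == "T") | (a == "T" & b == "C")
  }
  # enumerate single-nucleotide neighbours among sense codons
  cmat <- do.call(rbind, strsplit(sense, ""))
  pr <- list()
  for (i in seq_along(sense)) {
    for (pos in 1:3) {
      for (nt in nts) {
        if (nt == cmat[i, pos]) next
        cod <- cmat[i, ]
        cod[pos] <- nt
        cods <- paste(cod, collapse = "")
        j <- idx[cods]
        if (is.na(j) || j <= i) next  # skip stops; record each pair once
        pr[[length(pr) + 1L]] <- c(i, j, pos)
      }
    }
  }
  pairs <- as.data.frame(do.call(rbind, pr))
  names(pairs) <- c("i", "j", "pos")
  pairs$transition <- is_transition(cmat[cbind(pairs$i, pairs$pos)],
                                    cmat[cbind(pairs$j, pairs$pos)])
  pairs$synonymous <- aa[pairs$i] == aa[pairs$j]

  # Nei-Gojobori synonymous site count per codon: at each position, the
  # fraction of possible changes that are synonymous; nonsense (stop)
  # mutations are eliminated from the opportunity count, as in the original
  # counting method, so each position still contributes one full site.
  ngs <- numeric(length(sense))
  for (i in seq_along(sense)) {
    s <- 0
    for (pos in 1:3) {
      nSyn <- 0L; nOk <- 0L
      for (nt in nts) {
        if (nt == cmat[i, pos]) next
        cod <- cmat[i, ]
        cod[pos] <- nt
        cods <- paste(cod, collapse = "")
        tgt <- gc_map[cods]
        if (tgt == "*") next
        nOk <- nOk + 1L
        if (tgt == aa[i]) nSyn <- nSyn + 1L
      }
      if (nOk > 0) s <- s + nSyn / nOk
    }
    ngs[i] <- s
  }
  out <- list(sense = sense, aa = aa, idx = idx, pairs = pairs,
              ngsites = ngs, cmat = cmat)
  .zw_cache$codons <- out
  out
}

#' Split a gapless in-frame CDS string into codons
#' @param x character scalar (DNA, length divisible by 3)
#' @return character vector of codons
#' @keywords internal
splitCodons <- function(x) {
  n <- nchar(x)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not a multiple of 3")
  substring(x, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' F3x4 codon frequencies
#'
#' Position-specific nucleotide frequencies from a set of codon vectors,
#' multiplied across the three codon positions and renormalised over the 61
#' sense codons (the F3x4 convention). A pseudocount keeps all frequencies
#' strictly positive so the substitution model stays irreducible.
#'
#' @param codons character vector of codons (may contain entries with gaps or
#'   ambiguity; those are ignored)
#' @return numeric vector of length 61, summing to one
#' @keywords internal
f3x4Frequencies <- function(codons) {
  tab <- codonTables()
  codons <- codons[codons %in% tab$sense]
  mat <- do.call(rbind, strsplit(codons, ""))
  nts <- c("A", "C", "G", "T")
  f <- sapply(1:3, function(p) {
    counts <- table(factor(mat[, p], levels = nts)) + 0.5
    as.numeric(counts / sum(counts))
  })  # 4 x 3
  rownames(f) <- nts
  cm <- tab$cmat
  pi61 <- f[cbind(match(cm[, 1], nts), 1)] *
    f[cbind(match(cm[, 2], nts), 2)] *
    f[cbind(match(cm[, 3], nts), 3)]
  pi61 / sum(pi61)
}

#' Goldman-Yang codon rate structure
#'
#' Builds the reversible codon substitution rate matrix with
#' transition/transversion ratio \code{kappa} and nonsynonymous/synonymous
#' ratio \code{omega} over the supplied codon frequencies, scaled to one
#' expected substitution per codon per unit branch length, together with its
#' symmetric eigendecomposition and the proportions of synonymous and
#' nonsynonymous flux.
#'
#' @param kappa transition/transversion rate ratio (> 0)
#' @param omega dN/dS ratio (>= 0)
#' @param pi61 sense-codon equilibrium frequencies
#' @return list with \code{U}, \code{Ui}, \code{lam} (so that
#'   \code{P(t) = U diag(exp(lam t)) Ui}), \code{rhoS}, \code{rhoN}
#'   (proportions of synonymous / nonsynonymous substitutions) and
#'   \code{rate0} (pre-scaling total rate).
#' @keywords internal
gy94Eigen <- function(kappa, omega, pi61) {
  tab <- codonTables()
  p <- tab$pairs
  n <- length(tab$sense)
  Q <- matrix(0, n, n)
  w <- kappa^p$transition * ifelse(p$synonymous, 1, omega)
  Q[cbind(p$i, p$j)] <- pi61[p$j] * w
  Q[cbind(p$j, p$i)] <- pi61[p$i] * w
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi61 * diag(Q))
  Q <- Q / rate
  flux <- pi61[p$i] * Q[cbind(p$i, p$j)] + pi61[p$j] * Q[cbind(p$j, p$i)]
  rhoS <- sum(flux[p$synonymous])
  rhoN <- sum(flux[!p$synonymous])
  sp <- sqrt(pi61)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = e$vectors / sp, Ui = t(e$vectors * sp), lam = e$values,
       rhoS = rhoS, rhoN = rhoN, rate0 = rate)
}

#' Transition probability matrix from an eigendecomposition
#' @param eig output of \code{gy94Eigen} or \code{hkyEigen}
#' @param t branch length (expected substitutions per state)
#' @return probability matrix (rows: from, columns: to); tiny negative
#'   entries from roundoff are clamped at zero
#' @keywords internal
probMatrix <- function(eig, t) {
  P <- eig$U %*% (exp(eig$lam * t) * eig$Ui)
  P[P < 0] <- 0
  P
}

#' HKY85 nucleotide rate structure
#'
#' Same contract as \code{gy94Eigen} but over the four nucleotides, scaled to
#' one expected substitution per site per unit branch length.
#' @keywords internal
hkyEigen <- function(kappa, pi4) {
  nts <- c("A", "C", "G", "T")
  Q <- matrix(0, 4, 4, dimnames = list(nts, nts))
  for (a in 1:4) for (b in 1:4) {
    if (a == b) next
    ts <- (nts[a] == "A" && nts[b] == "G") || (nts[a] == "G" && nts[b] == "A") ||
      (nts[a] == "C" && nts[b] == "T") || (nts[a] == "T" && nts[b] == "C")
    Q[a, b] <- pi4[b] * if (ts) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi4 * diag(Q))
  Q <- Q / rate
  sp <- sqrt(pi4)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = e$vectors / sp, Ui = t(e$vectors * sp), lam = e$values)
}
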