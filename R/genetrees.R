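# Maximum-likelihood gene trees by exhaustive topology enumeration under an
# HKY85 nucleotide model, bootstrap support, and shared-vs-independent
# classification of recombination suppression from tree shape.

#' Felsenstein pruning over a fixed tree
#'
#' Generic over the state space (4 nucleotides or 61 codons). Missing tip
#' states (gaps/ambiguity) contribute a vector of ones.
#'
#' @param edgeMat postorder edge matrix (parent, child)
#' @param nTip number of tips
#' @param states integer matrix (tips x patterns), NA = missing
#' @param Plist list of transition matrices, one per edge row
#' @param pi root frequencies
#' @return numeric vector of per-pattern likelihoods
#' @keywords internal
.pruneSiteLik <- function(edgeMat, nTip, states, Plist, pi) {
  npat <- ncol(states)
  ns <- length(pi)
  maxNode <- max(edgeMat)
  partial <- vector("list", maxNode)
  for (k in seq_len(nrow(edgeMat))) {
    par <- edgeMat[k, 1]
    ch <- edgeMat[k, 2]
    P <- Plist[[k]]
    if (ch <= nTip) {
      idx <- states[ch, ]
      M <- matrix(1, ns, npat)
      ok <- !is.na(idx)
      M[, ok] <- P[, idx[ok]]
    } else {
      M <- P %*% partial[[ch]]
    }
    partial[[par]] <- if (is.null(partial[[par]])) M else partial[[par]] * M
  }
  root <- edgeMat[nrow(edgeMat), 1]
  as.numeric(pi %*% partial[[root]])
}

#' Nucleotide site patterns of a CodonAlignment
#' @return list: states (tips x npat), weights, patIndex (column ->
#'   pattern), labels, pi (empirical base frequencies), ncodons
#' @keywords internal
.nucPatterns <- function(aln) {
  m <- alnMatrix(aln)
  keepCod <- unmaskedCodonIndex(aln)
  cols <- sort(unlist(lapply(keepCod, function(i) (i * 3L - 2L):(i * 3L))))
  m <- m[, cols, drop = FALSE]
  nts <- c("A", "C", "G", "T")
  sm <- matrix(match(m, nts), nrow = nrow(m))
  key <- apply(sm, 2, paste, collapse = ",")
  patIndex <- match(key, unique(key))
  first <- !duplicated(key)
  states <- sm[, first, drop = FALSE]
  weights <- as.numeric(table(factor(patIndex, levels = seq_len(sum(first)))))
  counts <- table(factor(m[!is.na(match(m, nts))], levels = nts))
  pi <- as.numeric(counts + 1) / sum(counts + 4)
  list(states = states, weights = weights, patIndex = patIndex,
       labels = alnLabels(aln), pi = pi, ncodons = length(cols) %/% 3L)
}

#' @keywords internal
.hkyTreeFit <- function(tree, pat, kappaInit = 2, maxit = 200) {
  tree <- ape::reorder.phylo(tree, "postorder")
  edgeMat <- tree$edge
  nTip <- length(tree$tip.label)
  ord <- match(tree$tip.label, pat$labels)
  states <- pat$states[ord, , drop = FALSE]
  nE <- nrow(edgeMat)
  cache <- new.env(parent = emptyenv())
  nll <- function(par) {
    bl <- exp(par[seq_len(nE)])
    kappa <- exp(par[nE + 1L])
    key <- sprintf("%.12g", kappa)
    if (is.null(cache[[key]])) cache[[key]] <- hkyEigen(kappa, pat$pi)
    eig <- cache[[key]]
    Plist <- lapply(bl, function(t) probMatrix(eig, t))
    lik <- .pruneSiteLik(edgeMat, nTip, states, Plist, pat$pi)
    -sum(pat$weights * log(pmax(lik, 1e-300)))
  }
  p0 <- c(rep(log(0.05), nE), log(kappaInit))
  fit <- optim(p0, nll, method = "L-BFGS-B",
               lower = c(rep(log(1e-7), nE), log(0.1)),
               upper = c(rep(log(3), nE), log(50)),
               control = list(maxit = maxit,
                              factr = 1e-7 / .Machine$double.eps))
  bl <- exp(fit$par[seq_len(nE)])
  kappa <- exp(fit$par[nE + 1L])
  eig <- hkyEigen(kappa, pat$pi)
  Plist <- lapply(bl, function(t) probMatrix(eig, t))
  siteLik <- .pruneSiteLik(edgeMat, nTip, states, Plist, pat$pi)
  tree$edge.length <- bl
  list(tree = tree, logLik = -fit$value, kappa = kappa,
       siteLL = log(pmax(siteLik, 1e-300)))
}

#' Canonical key for an unrooted bipartition
#' @keywords internal
.splitKey <- function(tips, allTips) {
  ref <- sort(allTips)[1]
  side <- sort(tips)
  if (ref %in% side) side <- sort(setdiff(allTips, tips))
  paste(side, collapse = "|")
}

#' All internal bipartition keys of an unrooted tree
#' @keywords internal
.treeSplits <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  nTip <- length(tree$tip.label)
  below <- vector("list", max(tree$edge))
  for (i in seq_len(nTip)) below[[i]] <- tree$tip.label[i]
  keys <- character(0)
  for (k in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[k, 2]
    if (ch > nTip) keys <- c(keys, .splitKey(below[[ch]], tree$tip.label))
    par <- tree$edge[k, 1]
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  sz <- vapply(strsplit(keys, "\\|"), length, integer(1))
  unique(keys[sz >= 2 & sz <= nTip - 2])
}

#' Maximum-likelihood gene tree by exhaustive topology search
#'
#' Enumerates every unrooted topology over the alignment's sequences (3 for
#' 4 tips, 15 for 5, 105 for 6), optimises branch lengths and the HKY85
#' transition/transversion ratio for each by bounded quasi-Newton, and
#' returns the maximum-likelihood topology rooted on the designated
#' outgroup. When all topologies tie (identical sequences) the result is
#' flagged star-like and the resolution is arbitrary.
#'
#' @param aln a \linkS4class{CodonAlignment} with 4-8 sequences
#' @param outgroup tip label used to root (e.g. "Tg_Z")
#' @return a \linkS4class{SupportedTree} (no supports until
#'   \code{\link{bootstrapSupport}} is run)
#' @export
mlTree <- function(aln, outgroup) {
  labels <- alnLabels(aln)
  n <- length(labels)
  if (n < 4 || n > 8)
    stop("exhaustive search supports 4-8 sequences, got ", n)
  if (!outgroup %in% labels) stop("outgroup '", outgroup, "' not among tips")
  pat <- .nucPatterns(aln)
  topos <- phangorn::allTrees(n, rooted = FALSE, tip.label = labels)
  fits <- lapply(topos, .hkyTreeFit, pat = pat)
  lls <- vapply(fits, function(f) f$logLik, numeric(1))
  bestIdx <- which.max(lls)
  starLike <- (max(lls) - min(lls)) < 1e-6
  if (starLike)
    warning("all topologies have equal likelihood (star-like signal); ",
            "resolution is arbitrary")
  best <- fits[[bestIdx]]
  rooted <- ape::root(best$tree, outgroup = outgroup, resolve.root = TRUE)
  siteLL <- vapply(fits, function(f) f$siteLL, numeric(ncol(pat$states)))
  if (is.null(dim(siteLL))) siteLL <- matrix(siteLL, nrow = 1)
  new("SupportedTree", tree = rooted, support = numeric(0),
      outgroup = outgroup, kappa = best$kappa, logLik = best$logLik,
      starLike = starLike,
      fits = list(trees = lapply(fits, `[[`, "tree"), logLik = lls,
                  siteLL = siteLL, patIndex = pat$patIndex,
                  ncodons = pat$ncodons, bestIdx = bestIdx, pat = pat,
                  splits = lapply(topos, .treeSplits),
                  allTips = labels))
}

#' Bootstrap support for the ML tree's bipartitions
#'
#' Resamples codon triplets with replacement (keeping the reading frame
#' intact) and scores each enumerated topology on every replicate; the
#' support of a bipartition of the ML tree is the percentage of replicates
#' whose winning topology contains it. The default method re-weights the
#' per-topology site log-likelihoods fitted to the original data (the RELL
#' approximation, avoiding per-replicate re-optimisation);
#' \code{method = "full"} re-runs the exhaustive search on each replicate.
#'
#' @param stree result of \code{\link{mlTree}}
#' @param nReps bootstrap replicates (default 1000)
#' @param seed integer seed
#' @param method "rell" (default) or "full"
#' @param resampleUnit "codon" (default, triplet resampling) or "column"
#' @return the \linkS4class{SupportedTree} with supports filled in
#' @export
bootstrapSupport <- function(stree, nReps = 1000L, seed = 1L,
                             method = c("rell", "full"),
                             resampleUnit = c("codon", "column")) {
  stopifnot(is(stree, "SupportedTree"))
  method <- match.arg(method)
  resampleUnit <- match.arg(resampleUnit)
  if (nReps < 1) stop("nReps must be >= 1")
  f <- stree@fits
  set.seed(seed)
  mlSplits <- f$splits[[f$bestIdx]]
  nTopo <- length(f$splits)
  contains <- vapply(f$splits, function(sp) mlSplits %in% sp,
                     logical(length(mlSplits)))
  if (is.null(dim(contains))) contains <- matrix(contains, nrow = 1)
  if (method == "rell") {
    colLL <- f$siteLL[f$patIndex, , drop = FALSE]   # columns x topologies
    if (resampleUnit == "codon") {
      unit <- rowsum(colLL, rep(seq_len(f$ncodons), each = 3L))
    } else unit <- colLL
    nU <- nrow(unit)
    counts <- rmultinom(nReps, nU, rep(1 / nU, nU))  # nU x nReps
    scores <- crossprod(counts, unit)                # nReps x nTopo
    win <- max.col(scores, ties.method = "first")
  } else {
    win <- integer(nReps)
    nU <- if (resampleUnit == "codon") f$ncodons else length(f$patIndex)
    for (r in seq_len(nReps)) {
      u <- sample.int(nU, nU, replace = TRUE)
      cols <- if (resampleUnit == "codon")
        as.vector(t(outer(u, 0:2, function(a, b) (a - 1L) * 3L + b + 1L)))
      else u
      patIdx <- f$patIndex[cols]
      w <- as.numeric(table(factor(patIdx, levels = seq_len(nrow(f$siteLL)))))
      pat2 <- f$pat
      keep <- w > 0
      pat2$states <- f$pat$states[, keep, drop = FALSE]
      pat2$weights <- w[keep]
      lls <- vapply(f$trees, function(tr) .hkyTreeFit(tr, pat2,
                                                      maxit = 60)$logLik,
                    numeric(1))
      win[r] <- which.max(lls)
    }
  }
  supp <- 100 * rowMeans(contains[, win, drop = FALSE])
  names(supp) <- mlSplits
  initialize(stree, support = supp)
}

#' Classify recombination suppression as shared or independent
#'
#' \emph{Shared} when the W-linked tips form a clade (to the exclusion of
#' the Z tips and outgroup) with bootstrap support at or above the
#' threshold: gametologs cluster by sex chromosome, so divergence predates
#' the species split. \emph{Independent} when each species' Z and W tips
#' form their own supported clade. Anything else (including low support)
#' is \emph{unresolved}.
#'
#' @param stree a \linkS4class{SupportedTree} with bootstrap supports
#' @param supportThreshold percent support required (default 95)
#' @return list: class ("shared"/"independent"/"unresolved"),
#'   wCladeSupport, speciesCladeSupport (named by taxon)
#' @export
classifyTopology <- function(stree, supportThreshold = 95) {
  stopifnot(is(stree, "SupportedTree"))
  if (!length(stree@support))
    stop("run bootstrapSupport() before classifying")
  tips <- stree@tree$tip.label
  if (!all(grepl("_[ZW]$", tips)))
    stop("tips must be labelled <taxon>_<Z|W>")
  taxa <- sub("_[ZW]$", "", tips)
  chrom <- sub(".*_", "", tips)
  allTips <- stree@fits$allTips
  mlSplits <- names(stree@support)
  lookup <- function(tipSet) {
    key <- .splitKey(tipSet, allTips)
    if (key %in% mlSplits) unname(stree@support[key]) else NA_real_
  }
  wTips <- tips[chrom == "W"]
  wSupport <- if (length(wTips) >= 2) lookup(wTips) else NA_real_
  both <- intersect(taxa[chrom == "W"], taxa[chrom == "Z"])
  spSupport <- vapply(both, function(tx)
    lookup(paste0(tx, c("_Z", "_W"))), numeric(1))
  if (!length(both)) stop("no taxon carries both Z and W tips")
  cls <- "unresolved"
  if (!is.na(wSupport) && wSupport >= supportThreshold) {
    cls <- "shared"
  } else if (all(!is.na(spSupport)) && all(spSupport >= supportThreshold)) {
    cls <- "independent"
  }
  list(class = cls, wCladeSupport = wSupport,
       speciesCladeSupport = spSupport)
}

setMethod("show", "SupportedTree", function(object) {
  cat(sprintf("SupportedTree: %d tips, lnL = %.2f, kappa = %.2f%s\n",
              length(object@tree$tip.label), object@logLik, object@kappa,
              if (object@starLike) " [star-like]" else ""))
  cat("  outgroup:", object@outgroup, "\n")
  if (length(object@support)) {
    cat("  bipartition support:\n")
    for (k in seq_along(object@support))
      cat(sprintf("    {%s}: %.0f%%\n", names(object@support)[k],
                  object@support[k]))
  } else cat("  (no bootstrap supports yet)\n")
})
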