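# Branch-model and branch-site likelihood-ratio tests of the selective
# regime on designated W or Z branches, on the fixed gene-tree templates
# for shared and independent recombination-suppression histories.

.sharedTemplate <-
  "(Tg_Z,(((Gg_W,Mg_W),Ap_W),((Gg_Z,Mg_Z),Ap_Z)));"
.independentTemplate <-
  "(Tg_Z,(((Gg_W,Mg_W),(Gg_Z,Mg_Z)),(Ap_Z,Ap_W)));"

#' Build a labelled gene-tree template for selection tests
#'
#' Returns the fixed topology appropriate to the recombination-suppression
#' history: under \emph{shared} suppression the W-linked genes of all
#' species form a clade sister to the Z clade; under \emph{independent}
#' suppression the A. platyrhynchos Z and W pair off on their own. The
#' template is pruned to the taxa present, and every branch whose
#' descendants are all on the foreground chromosome (including the clade
#' stem) is labelled foreground.
#'
#' @param case "shared" or "independent"
#' @param taxa subset of c("Gg", "Mg", "Ap", "Tg"); Tg (the outgroup) is
#'   always required
#' @param foreground "W" (default) or "Z"
#' @return a \linkS4class{LabeledTreeTemplate}
#' @export
buildBranchTree <- function(case = c("shared", "independent"),
                            taxa = c("Gg", "Mg", "Ap", "Tg"),
                            foreground = c("W", "Z")) {
  case <- match.arg(case)
  foreground <- match.arg(foreground)
  if (!"Tg" %in% taxa) stop("Tg must be present as the outgroup")
  bad <- setdiff(taxa, c("Gg", "Mg", "Ap", "Tg"))
  if (length(bad)) stop("unknown taxa: ", paste(bad, collapse = ", "))
  tree <- ape::read.tree(text = if (case == "shared") .sharedTemplate else
    .independentTemplate)
  dropTips <- tree$tip.label[!sub("_[ZW]$", "", tree$tip.label) %in% taxa]
  if (length(dropTips)) tree <- ape::drop.tip(tree, dropTips)
  tree <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  fg <- .chromEdges(tree, foreground, excludeTips = "Tg_Z")
  new("LabeledTreeTemplate", tree = tree, case = case,
      foreground = foreground, foregroundEdges = fg)
}

#' Edges whose descendant tips all lie on one chromosome
#'
#' Tips in \code{excludeTips} (the outgroup) never count as foreground:
#' the foreground Z set is the ingroup Z clade, not the outgroup's Z.
#' @keywords internal
.chromEdges <- function(tree, chrom, excludeTips = character(0)) {
  nTip <- length(tree$tip.label)
  below <- vector("list", max(tree$edge))
  for (i in seq_len(nTip)) below[[i]] <- tree$tip.label[i]
  edges <- integer(0)
  for (k in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[k, 2]
    tips <- below[[ch]]
    if (all(sub(".*_", "", tips) == chrom) &&
        !any(tips %in% excludeTips)) edges <- c(edges, k)
    par <- tree$edge[k, 1]
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  edges
}

#' Codon patterns of an alignment ordered to match a template's tips
#' @keywords internal
.codonPatterns <- function(aln, tree) {
  cods <- codonMatrix(aln)                 # codon columns x sequences
  tab <- codonTables()
  if (!all(tree$tip.label %in% colnames(cods)))
    stop("alignment tips do not match the template: missing ",
         paste(setdiff(tree$tip.label, colnames(cods)), collapse = ", "))
  cods <- cods[, tree$tip.label, drop = FALSE]
  idx <- matrix(tab$idx[cods], nrow = nrow(cods))    # NA for gaps
  key <- apply(idx, 1, paste, collapse = ",")
  patIndex <- match(key, unique(key))
  first <- !duplicated(key)
  states <- t(idx[first, , drop = FALSE])            # tips x patterns
  weights <- as.numeric(table(factor(patIndex,
                                     levels = seq_len(sum(first)))))
  pi61 <- f3x4Frequencies(as.vector(cods[!is.na(cods)]))
  list(states = states, weights = weights, pi61 = pi61,
       ncodons = nrow(cods))
}

#' @keywords internal
.branchNll <- function(template, cp, cache) {
  edgeMat <- template@tree$edge
  nE <- nrow(edgeMat)
  nTip <- length(template@tree$tip.label)
  fg <- template@foregroundEdges
  function(par, wFg = NULL) {
    bl <- exp(par[seq_len(nE)])
    kappa <- exp(par[nE + 1L])
    wBg <- exp(par[nE + 2L])
    if (is.null(wFg)) wFg <- exp(par[nE + 3L])
    eBg <- .gyEigCache(cache, kappa, wBg, cp$pi61)
    eFg <- .gyEigCache(cache, kappa, wFg, cp$pi61)
    Plist <- vector("list", nE)
    for (k in seq_len(nE))
      Plist[[k]] <- probMatrix(if (k %in% fg) eFg else eBg, bl[k])
    lik <- .pruneSiteLik(edgeMat, nTip, cp$states, Plist, cp$pi61)
    -sum(cp$weights * log(pmax(lik, 1e-300)))
  }
}

#' Branch-model likelihood-ratio tests on foreground branches
#'
#' Fits a two-ratio codon model (background omega, foreground omega) on the
#' fixed template topology with all branch lengths, kappa and the omegas
#' re-optimised under every model, then compares the free model against
#' models with the foreground omega fixed to 1 (neutral evolution) and/or 0
#' (strict purifying selection), each on one degree of freedom against
#' chi-squared.
#'
#' @param aln a \linkS4class{CodonAlignment} whose tips match the template
#' @param template a \linkS4class{LabeledTreeTemplate}
#' @param nulls which null models to fit: subset of c("fix1", "fix0")
#' @param minCodons minimum codon columns (default 50)
#' @return a \linkS4class{SelectionTestResult}
#' @export
branchModelLrt <- function(aln, template, nulls = c("fix1", "fix0"),
                           minCodons = 50L) {
  stopifnot(is(template, "LabeledTreeTemplate"))
  nulls <- match.arg(nulls, several.ok = TRUE)
  cp <- .codonPatterns(aln, template@tree)
  if (cp$ncodons < minCodons)
    stop("only ", cp$ncodons, " codon columns; need >= ", minCodons)
  nE <- nrow(template@tree$edge)
  cache <- new.env(parent = emptyenv())
  nll <- .branchNll(template, cp, cache)
  lower <- c(rep(log(1e-7), nE), log(0.1), log(1e-4), log(1e-4))
  upper <- c(rep(log(5), nE), log(50), log(20), log(20))
  p0 <- c(rep(log(0.1), nE), log(2), log(0.3), log(0.3))
  ctl <- list(maxit = 400, factr = 1e-7 / .Machine$double.eps)
  fitFree <- optim(p0, nll, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = ctl)
  if (fitFree$convergence != 0)
    stop("branch model (free) did not converge: optimizer code ",
         fitFree$convergence, " / ", fitFree$message)
  fits <- list(free = fitFree)
  for (nl in nulls) {
    wFix <- if (nl == "fix1") 1 else 0
    nllF <- function(par) nll(par, wFg = wFix)
    f <- optim(p0[seq_len(nE + 2L)], nllF, method = "L-BFGS-B",
               lower = lower[seq_len(nE + 2L)],
               upper = upper[seq_len(nE + 2L)], control = ctl)
    if (f$convergence != 0)
      stop("branch model (", nl, ") did not converge: code ", f$convergence)
    fits[[nl]] <- f
    # nesting guard: the free model must not fall below a null
    if (fitFree$value > f$value + 1e-6) {
      p1 <- c(f$par, log(max(wFix, 1e-4)))
      refit <- optim(p1, nll, method = "L-BFGS-B", lower = lower,
                     upper = upper, control = ctl)
      if (refit$value < fitFree$value) { fitFree <- refit
        fits$free <- refit }
    }
  }
  par <- fits$free$par
  lnL <- vapply(fits, function(f) -f$value, numeric(1))
  lrt <- do.call(rbind, lapply(nulls, function(nl) {
    stat <- max(0, 2 * (lnL["free"] - lnL[nl]))
    data.frame(comparison = paste0("free-vs-", nl), statistic = stat,
               df = 1L, p = pchisq(stat, 1, lower.tail = FALSE))
  }))
  omega <- c(background = exp(par[nE + 2L]), foreground = exp(par[nE + 3L]))
  new("SelectionTestResult", model = "branch", lnL = lnL, omega = omega,
      lrt = lrt,
      siteClasses = data.frame(class = character(), proportion = numeric()),
      converged = TRUE)
}

#' Branch-site test of positive selection (model A)
#'
#' Four site classes: 0 (omega0 < 1 on all branches), 1 (neutral
#' everywhere), 2a and 2b (omega2 >= 1 on the foreground branches layered
#' over classes 0 and 1). The alternative estimates omega2; the null fixes
#' omega2 = 1. The LRT is reported against chi-squared with 1 df and
#' against the 50:50 mixture of a point mass at 0 and chi-squared(1);
#' significance flags use the former.
#'
#' @inheritParams branchModelLrt
#' @return a \linkS4class{SelectionTestResult} with site-class proportions
#' @export
branchSiteTest <- function(aln, template, minCodons = 50L) {
  stopifnot(is(template, "LabeledTreeTemplate"))
  cp <- .codonPatterns(aln, template@tree)
  if (cp$ncodons < minCodons)
    stop("only ", cp$ncodons, " codon columns; need >= ", minCodons)
  tree <- template@tree
  edgeMat <- tree$edge
  nE <- nrow(edgeMat)
  nTip <- length(tree$tip.label)
  fg <- template@foregroundEdges
  cache <- new.env(parent = emptyenv())
  classLik <- function(bl, kappa, wBgClass, wFgClass) {
    eBg <- .gyEigCache(cache, kappa, wBgClass, cp$pi61)
    eFg <- .gyEigCache(cache, kappa, wFgClass, cp$pi61)
    Plist <- vector("list", nE)
    for (k in seq_len(nE))
      Plist[[k]] <- probMatrix(if (k %in% fg) eFg else eBg, bl[k])
    .pruneSiteLik(edgeMat, nTip, cp$states, Plist, cp$pi61)
  }
  nll <- function(par, fixW2 = FALSE) {
    bl <- exp(par[seq_len(nE)])
    kappa <- exp(par[nE + 1L])
    q0 <- plogis(par[nE + 2L])            # p0 + p1
    q1 <- plogis(par[nE + 3L])            # p0 / (p0 + p1)
    w0 <- plogis(par[nE + 4L])
    w2 <- if (fixW2) 1 else exp(par[nE + 5L])
    p0 <- q0 * q1; p1 <- q0 * (1 - q1); p2 <- 1 - q0
    p2a <- p2 * q1; p2b <- p2 * (1 - q1)
    L <- p0 * classLik(bl, kappa, w0, w0) +
      p1 * classLik(bl, kappa, 1, 1) +
      p2a * classLik(bl, kappa, w0, w2) +
      p2b * classLik(bl, kappa, 1, w2)
    -sum(cp$weights * log(pmax(L, 1e-300)))
  }
  lower <- c(rep(log(1e-7), nE), log(0.1), -8, -8, -8, 0)
  upper <- c(rep(log(5), nE), log(50), 8, 8, 8, log(50))
  p0v <- c(rep(log(0.1), nE), log(2), qlogis(0.85), qlogis(0.6),
           qlogis(0.2), log(1.5))
  ctl <- list(maxit = 500, factr = 1e-7 / .Machine$double.eps)
  nllNull <- function(par) nll(par, fixW2 = TRUE)
  fitNull <- optim(p0v[seq_len(nE + 4L)], nllNull, method = "L-BFGS-B",
                   lower = lower[seq_len(nE + 4L)],
                   upper = upper[seq_len(nE + 4L)], control = ctl)
  fitAlt <- optim(p0v, nll, method = "L-BFGS-B", lower = lower,
                  upper = upper, control = ctl)
  if (fitAlt$value > fitNull$value + 1e-6) {
    refit <- optim(c(fitNull$par, 0), nll, method = "L-BFGS-B",
                   lower = lower, upper = upper, control = ctl)
    if (refit$value < fitAlt$value) fitAlt <- refit
  }
  if (fitAlt$convergence != 0 || fitNull$convergence != 0)
    stop("branch-site optimisation did not converge (codes ",
         fitAlt$convergence, "/", fitNull$convergence, ")")
  par <- fitAlt$par
  q0 <- plogis(par[nE + 2L]); q1 <- plogis(par[nE + 3L])
  p0 <- q0 * q1; p1 <- q0 * (1 - q1); p2 <- 1 - q0
  props <- data.frame(
    class = c("0", "1", "2a", "2b"),
    proportion = c(p0, p1, p2 * q1, p2 * (1 - q1)),
    omegaBackground = c(plogis(par[nE + 4L]), 1, plogis(par[nE + 4L]), 1),
    omegaForeground = c(plogis(par[nE + 4L]), 1, exp(par[nE + 5L]),
                        exp(par[nE + 5L])))
  stat <- max(0, 2 * (fitNull$value - fitAlt$value))
  pChi <- pchisq(stat, 1, lower.tail = FALSE)
  pMix <- if (stat <= 0) 1 else 0.5 * pChi
  lrt <- data.frame(comparison = "modelA-vs-modelAnull", statistic = stat,
                    df = 1L, p = pChi, p_mixture = pMix)
  new("SelectionTestResult", model = "branch-site",
      lnL = c(alternative = -fitAlt$value, null = -fitNull$value),
      omega = c(omega0 = plogis(par[nE + 4L]),
                omega2 = exp(par[nE + 5L])),
      lrt = lrt, siteClasses = props, converged = TRUE)
}

setMethod("show", "SelectionTestResult", function(object) {
  cat(sprintf("SelectionTestResult (%s model)\n", object@model))
  cat("  lnL:", paste(names(object@lnL),
                      sprintf("%.3f", object@lnL), collapse = "; "), "\n")
  cat("  omega:", paste(names(object@omega),
                        sprintf("%.4g", object@omega), collapse = "; "), "\n")
  for (k in seq_len(nrow(object@lrt)))
    cat(sprintf("  %s: 2dL = %.3f, df = %d, p = %.4g\n",
                object@lrt$comparison[k], object@lrt$statistic[k],
                object@lrt$df[k], object@lrt$p[k]))
})
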