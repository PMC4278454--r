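# Pairwise synonymous/nonsynonymous divergence: a Nei-Gojobori (1986)
# counting estimator (the independent oracle) and a maximum-likelihood
# estimator under a Goldman-Yang codon model with F3x4 frequencies.

#' Per-codon-pair pathway-averaged difference counts (NG86)
#'
#' For every ordered pair of sense codons, the synonymous and nonsynonymous
#' difference counts averaged over all substitution pathways that avoid stop
#' codons (all pathways are used if every one passes through a stop).
#' Precomputed once and cached.
#' @return list of two 61 x 61 matrices \code{sd} and \code{nd}
#' @keywords internal
ngDiffTables <- function() {
  if (!is.null(.zw_cache$ngdiff)) return(.zw_cache$ngdiff)
  tab <- codonTables()
  gc_map <- Biostrings::GENETIC_CODE
  n <- length(tab$sense)
  sdm <- matrix(0, n, n)
  ndm <- matrix(0, n, n)
  cm <- tab$cmat
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      pos <- which(cm[i, ] != cm[j, ])
      perms <- if (length(pos) == 1) list(pos) else
        lapply(asplit(.permutations(pos), 1), as.vector)
      paths <- lapply(perms, function(ord) {
        cur <- cm[i, ]
        sdc <- 0; ndc <- 0; okPath <- TRUE
        for (p in ord) {
          nxt <- cur
          nxt[p] <- cm[j, p]
          a1 <- gc_map[paste(cur, collapse = "")]
          a2 <- gc_map[paste(nxt, collapse = "")]
          if (a2 == "*") okPath <- FALSE
          if (a1 == a2) sdc <- sdc + 1 else ndc <- ndc + 1
          cur <- nxt
        }
        c(sdc, ndc, okPath)
      })
      pm <- do.call(rbind, paths)
      use <- pm[, 3] == 1
      if (!any(use)) use <- rep(TRUE, nrow(pm))
      sdm[i, j] <- mean(pm[use, 1])
      ndm[i, j] <- mean(pm[use, 2])
    }
  }
  .zw_cache$ngdiff <- list(sd = sdm, nd = ndm)
  .zw_cache$ngdiff
}

#' @keywords internal
.permutations <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (k in seq_along(v)) {
    rest <- .permutations(v[-k])
    out <- rbind(out, cbind(v[k], rest))
  }
  out
}

#' Extract complete-case codon index pairs from a two-sequence alignment
#' @keywords internal
.pairCodons <- function(aln) {
  stopifnot(is(aln, "CodonAlignment"), length(aln@seqs) == 2)
  cods <- codonMatrix(aln, drop = TRUE)
  tab <- codonTables()
  list(i = unname(tab$idx[cods[, 1]]), j = unname(tab$idx[cods[, 2]]),
       codons = cods)
}

#' Nei-Gojobori (1986) counting estimate of dS and dN
#'
#' Fractional synonymous/nonsynonymous site counts per codon (averaged over
#' the two sequences), pathway-averaged difference counts, and Jukes-Cantor
#' correction of the proportions. Serves as the model-free oracle for the
#' maximum-likelihood estimator.
#'
#' @param aln a two-sequence \linkS4class{CodonAlignment}
#' @return a \linkS4class{DivergenceEstimate} with \code{method = "NG86"}
#'   (no standard errors)
#' @examples
#' aln <- buildCodonAlignment(c(a = "TTTGGGAAA", b = "TTCGGGAAA"))
#' est <- ng86Divergence(aln)
#' round(est@dS, 3)  # 1.207
#' @export
ng86Divergence <- function(aln) {
  pc <- .pairCodons(aln)
  if (length(pc$i) < 1) stop("no ungapped, unmasked codon columns")
  tab <- codonTables()
  dt <- ngDiffTables()
  S <- (sum(tab$ngsites[pc$i]) + sum(tab$ngsites[pc$j])) / 2
  N <- 3 * length(pc$i) - S
  Sd <- sum(dt$sd[cbind(pc$i, pc$j)])
  Nd <- sum(dt$nd[cbind(pc$i, pc$j)])
  pS <- Sd / S
  pN <- Nd / N
  if (pS >= 3 / 4)
    stop("synonymous proportion ", round(pS, 3),
         " >= 3/4: Jukes-Cantor correction undefined (saturation)")
  if (pN >= 3 / 4)
    stop("nonsynonymous proportion >= 3/4: correction undefined (saturation)")
  dS <- -3 / 4 * log(1 - 4 * pS / 3)
  dN <- -3 / 4 * log(1 - 4 * pN / 3)
  new("DivergenceEstimate", dS = dS, dN = dN,
      omega = if (dS > 0) dN / dS else NA_real_,
      seDS = NA_real_, seDN = NA_real_, ci95DS = c(NA_real_, NA_real_),
      method = "NG86", nCodons = length(pc$i),
      kappa = NA_real_, t = NA_real_, lnL = NA_real_, converged = TRUE)
}

# ---------------------------------------------------------------------------

#' @keywords internal
.gyEigCache <- function(cache, kappa, omega, pi61) {
  key <- sprintf("%.10g_%.10g", kappa, omega)
  if (is.null(cache[[key]])) cache[[key]] <- gy94Eigen(kappa, omega, pi61)
  cache[[key]]
}

#' Maximum-likelihood pairwise dS and dN under a codon model
#'
#' Fits divergence \code{t}, transition/transversion ratio \code{kappa} and
#' \code{omega} by bounded quasi-Newton optimisation on the log scale
#' (three fixed starting points, the best-scoring one polished;
#' log-likelihood tolerance 1e-8) under a Goldman-Yang codon model with
#' F3x4 frequencies estimated from the pair. dS and dN are derived from the
#' fitted substitution flux; standard errors come from the curvature of the
#' log-likelihood via the delta method.
#'
#' @param aln a two-sequence \linkS4class{CodonAlignment}
#' @param minCodons minimum ungapped codon columns required (default 50)
#' @return a \linkS4class{DivergenceEstimate} with \code{method = "ML"}
#' @export
mlPairwiseDivergence <- function(aln, minCodons = 50L) {
  pc <- .pairCodons(aln)
  ncod <- length(pc$i)
  if (ncod < minCodons)
    stop("only ", ncod, " ungapped codon columns; need >= ", minCodons)
  if (all(pc$i == pc$j)) {
    return(new("DivergenceEstimate", dS = 0, dN = 0, omega = NA_real_,
               seDS = 0, seDN = 0, ci95DS = c(0, 0), method = "ML",
               nCodons = ncod, kappa = NA_real_, t = 0, lnL = 0,
               converged = TRUE))
  }
  pi61 <- f3x4Frequencies(c(pc$codons[, 1], pc$codons[, 2]))
  pat <- paste(pc$i, pc$j)
  ut <- !duplicated(pat)
  wts <- as.numeric(table(factor(pat, levels = pat[ut])))
  ii <- pc$i[ut]; jj <- pc$j[ut]
  cache <- new.env(parent = emptyenv())
  nll <- function(par) {
    t <- exp(par[1]); k <- exp(par[2]); w <- exp(par[3])
    eig <- .gyEigCache(cache, k, w, pi61)
    P <- probMatrix(eig, t)
    -sum(wts * log(pmax(pi61[ii] * P[cbind(ii, jj)], 1e-300)))
  }
  lower <- log(c(1e-6, 0.05, 1e-4))
  upper <- log(c(10, 50, 50))
  starts <- list(log(c(0.2, 2, 0.5)), log(c(0.5, 2, 1)),
                 log(c(0.05, 1, 0.2)))
  v0 <- vapply(starts, nll, numeric(1))
  ord <- order(v0)
  fit <- NULL
  tried <- character(0)
  for (s in ord) {
    f <- try(optim(starts[[s]], nll, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(factr = 1e-8 / .Machine$double.eps,
                                  maxit = 300)), silent = TRUE)
    if (!inherits(f, "try-error") && f$convergence == 0) { fit <- f; break }
    tried <- c(tried, if (inherits(f, "try-error")) "error" else
      paste0("code", f$convergence))
  }
  if (is.null(fit))
    stop("pairwise ML did not converge from any start (trace: ",
         paste(tried, collapse = ", "), ")")
  par <- fit$par
  t <- exp(par[1]); k <- exp(par[2]); w <- exp(par[3])
  dsdn <- function(p) {
    tt <- exp(p[1]); kk <- exp(p[2]); ww <- exp(p[3])
    e1 <- gy94Eigen(kk, ww, pi61)
    e0 <- gy94Eigen(kk, 1, pi61)
    c(dS = tt * e1$rhoS / (3 * e0$rhoS),
      dN = tt * e1$rhoN / (3 * e0$rhoN))
  }
  est <- dsdn(par)
  # delta-method SEs from the observed information in log-parameter space
  H <- .numHessian(nll, par)
  seDS <- seDN <- NA_real_
  Sigma <- try(solve(H), silent = TRUE)
  if (!inherits(Sigma, "try-error")) {
    G <- .numJacobian(dsdn, par)        # 2 x 3
    V <- G %*% Sigma %*% t(G)
    if (V[1, 1] >= 0) seDS <- sqrt(V[1, 1])
    if (V[2, 2] >= 0) seDN <- sqrt(V[2, 2])
  }
  ci <- c(max(0, est["dS"] - 1.96 * seDS), est["dS"] + 1.96 * seDS)
  new("DivergenceEstimate", dS = unname(est["dS"]), dN = unname(est["dN"]),
      omega = if (est["dS"] > 0) unname(est["dN"] / est["dS"]) else NA_real_,
      seDS = seDS, seDN = seDN, ci95DS = unname(ci), method = "ML",
      nCodons = ncod, kappa = k, t = t, lnL = -fit$value, converged = TRUE)
}

#' @keywords internal
.numHessian <- function(f, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(0, n, n)
  f0 <- f(x)
  for (a in seq_len(n)) {
    for (b in a:n) {
      if (a == b) {
        xp <- x; xp[a] <- x[a] + h
        xm <- x; xm[a] <- x[a] - h
        H[a, a] <- (f(xp) - 2 * f0 + f(xm)) / h^2
      } else {
        xpp <- x; xpp[c(a, b)] <- x[c(a, b)] + h
        xpm <- x; xpm[a] <- x[a] + h; xpm[b] <- x[b] - h
        xmp <- x; xmp[a] <- x[a] - h; xmp[b] <- x[b] + h
        xmm <- x; xmm[c(a, b)] <- x[c(a, b)] - h
        H[a, b] <- H[b, a] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h^2)
      }
    }
  }
  H
}

#' @keywords internal
.numJacobian <- function(f, x, h = 1e-5) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (a in seq_along(x)) {
    xp <- x; xp[a] <- x[a] + h
    xm <- x; xm[a] <- x[a] - h
    J[, a] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Saturation gate on a divergence estimate
#'
#' Pairs with dS above 1 are excluded from strata assignment and clock
#' dating to avoid inaccurate estimates due to mutational saturation; the
#' boundary dS = 1 passes.
#'
#' @param est a \linkS4class{DivergenceEstimate}
#' @return "pass" or "fail"
#' @export
checkSaturation <- function(est) {
  stopifnot(is(est, "DivergenceEstimate"))
  if (est@dS > 1) "fail" else "pass"
}

#' @describeIn ng86Divergence coerce an estimate to a one-row data.frame
#' @param x a DivergenceEstimate
#' @param ... unused
#' @export
setMethod("as.data.frame", "DivergenceEstimate", function(x, ...) {
  data.frame(dS = x@dS, dN = x@dN, omega = x@omega, seDS = x@seDS,
             seDN = x@seDN, ciDSlo = x@ci95DS[1], ciDShi = x@ci95DS[2],
             method = x@method, nCodons = x@nCodons, kappa = x@kappa,
             t = x@t, lnL = x@lnL)
})

setMethod("show", "DivergenceEstimate", function(object) {
  cat(sprintf("DivergenceEstimate (%s, %d codons)\n", object@method,
              object@nCodons))
  cat(sprintf("  dS = %.4f (SE %.4f), dN = %.4f, omega = %s\n", object@dS,
              object@seDS, object@dN, format(object@omega, digits = 3)))
})
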