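# W-linkage from sexed expression: female-limited and strongly
# female-biased classification, and Z/W distinctness verification for very
# young gametolog pairs.

#' Classify putative W-linked genes from sexed expression
#'
#' A gene is \emph{female-limited} when every male sample, rounded to two
#' decimals, is at or below \code{maxMaleExpr} (default 0) and the mean
#' female expression reaches \code{minFemaleExpr}; it is
#' \emph{strongly-female-biased} when the female/male mean ratio reaches
#' \code{minBiasRatio} with non-zero male expression. Both classes are
#' putative W-linked genes. The thresholds are explicit, configurable
#' stand-ins for a fold-change rule.
#'
#' @param expr a \code{SummarizedExperiment} with a \code{sex} column
#'   ("M"/"F") in colData, or a numeric matrix (genes x samples)
#' @param sex required when \code{expr} is a matrix: character vector of
#'   "M"/"F" per sample
#' @param minFemaleExpr minimum mean female expression (default 1.0)
#' @param maxMaleExpr maximum per-sample male expression after rounding to
#'   two decimals (default 0)
#' @param minBiasRatio minimum female/male mean ratio (default 10)
#' @return data.frame: gene, class ("female-limited",
#'   "strongly-female-biased" or "not-candidate"), meanFemale, meanMale,
#'   maxMaleRounded
#' @export
classifyWCandidates <- function(expr, sex = NULL, minFemaleExpr = 1.0,
                                maxMaleExpr = 0, minBiasRatio = 10) {
  if (is(expr, "SummarizedExperiment")) {
    sex <- as.character(SummarizedExperiment::colData(expr)$sex)
    mat <- SummarizedExperiment::assay(expr)
  } else {
    mat <- as.matrix(expr)
  }
  if (is.null(sex) || length(sex) != ncol(mat))
    stop("every sample needs a sex label")
  if (!any(sex == "M") || !any(sex == "F"))
    stop("both sexes must be represented among the samples")
  if (any(mat < 0)) stop("expression values must be >= 0")
  male <- mat[, sex == "M", drop = FALSE]
  fem <- mat[, sex == "F", drop = FALSE]
  meanM <- rowMeans(male)
  meanF <- rowMeans(fem)
  maxMaleR <- apply(round(male, 2), 1, max)
  cls <- rep("not-candidate", nrow(mat))
  biased <- meanM > 0 & (meanF / meanM) >= minBiasRatio
  cls[biased] <- "strongly-female-biased"
  limited <- maxMaleR <= maxMaleExpr & meanF >= minFemaleExpr
  cls[limited] <- "female-limited"
  data.frame(gene = rownames(mat), class = cls, meanFemale = meanF,
             meanMale = meanM, maxMaleRounded = maxMaleR,
             row.names = NULL)
}

#' Verify that a young Z/W pair is genuinely distinct
#'
#' Applied to gametolog pairs with dS below \code{dsThreshold} (default
#' 0.02), where annotation artefacts could masquerade as gametologs. The
#' pair is \emph{verified} when the alignment contains at least one fixed
#' Z-W difference, or the SNP table contains at least one female-limited
#' variant whose W allele differs from the Z allele (a W-specific allele
#' carried only by females).
#'
#' @param aln a two-sequence \linkS4class{CodonAlignment} of the Z and W
#'   sequences
#' @param snps optional data.frame with columns \code{cds_pos},
#'   \code{z_allele}, \code{w_allele}, \code{n_female_carriers},
#'   \code{n_male_carriers}
#' @param dsThreshold pairs with dS below this need verification; recorded
#'   in the result
#' @return list: status ("verified"/"unverified"), nFixedDifferences,
#'   nFemaleLimitedSNPs, dsThreshold
#' @export
verifyDistinctGametologs <- function(aln, snps = NULL, dsThreshold = 0.02) {
  stopifnot(is(aln, "CodonAlignment"))
  m <- alnMatrix(aln)
  if (nrow(m) != 2) stop("pair alignment must contain exactly two sequences")
  if (ncol(m) == 0) stop("empty alignment")
  ok <- m[1, ] != "-" & m[2, ] != "-"
  nFixed <- sum(m[1, ok] != m[2, ok])
  nSnp <- 0L
  if (!is.null(snps) && nrow(snps)) {
    hit <- snps$w_allele != snps$z_allele & snps$n_female_carriers >= 1 &
      snps$n_male_carriers == 0
    nSnp <- sum(hit)
  }
  list(status = if (nFixed >= 1 || nSnp >= 1) "verified" else "unverified",
       nFixedDifferences = nFixed, nFemaleLimitedSNPs = nSnp,
       dsThreshold = dsThreshold)
}
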