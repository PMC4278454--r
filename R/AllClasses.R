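#' @import methods
#' @importFrom stats optim optimize pchisq qlogis plogis rnorm rpois runif
#'   rlnorm rmultinom setNames quantile sd ks.test
#' @importFrom utils head combn
NULL

setOldClass("phylo")

#' CodonAlignment: an in-frame, codon-aware multiple alignment
#'
#' The container every downstream stage consumes: a set of aligned coding
#' sequences in which gaps occur only as whole codons on codon boundaries,
#' with an optional exon map and a mask of excluded column ranges. All
#' coordinates exposed by the API are 0-based half-open alignment columns.
#'
#' @slot seqs a \link[Biostrings]{DNAStringSet} of equal-width aligned CDS
#' @slot exonMap data.frame with columns \code{exon}, \code{start},
#'   \code{end} (0-based half-open alignment columns), or 0 rows
#' @slot mask an \link[IRanges]{IRanges} of masked alignment columns
#'   (stored 1-based internally; accessors convert)
#' @exportClass CodonAlignment
setClass("CodonAlignment",
  representation(seqs = "DNAStringSet", exonMap = "data.frame",
                 mask = "ANY"))

setValidity("CodonAlignment", function(object) {
  s <- object@seqs
  if (length(s) < 1) return("alignment must contain at least one sequence")
  w <- Biostrings::width(s)
  if (length(unique(w)) != 1) return("sequences have unequal aligned widths")
  if (w[1] %% 3L != 0L) return("alignment width is not a multiple of 3")
  if (is.null(names(s)) || anyDuplicated(names(s)))
    return("sequences must carry unique names")
  m <- as.matrix(s)
  ncod <- w[1] %/% 3L
  for (i in seq_len(nrow(m))) {
    g <- matrix(m[i, ] == "-", nrow = 3)
    bad <- colSums(g) %in% c(1L, 2L)
    if (any(bad))
      return(sprintf("sequence '%s': gaps not in whole codons at codon %d",
                     names(s)[i], which(bad)[1]))
  }
  # no internal stop codons in unmasked columns
  stops <- c("TAA", "TAG", "TGA")
  keep <- unmaskedCodonIndex(object)
  for (i in seq_len(nrow(m))) {
    cods <- apply(matrix(m[i, ], nrow = 3), 2, paste, collapse = "")
    hit <- which(cods[keep] %in% stops)
    if (length(hit))
      return(sprintf("sequence '%s': stop codon in unmasked codon column %d",
                     names(s)[i], keep[hit[1]]))
  }
  if (nrow(object@exonMap)) {
    em <- object@exonMap
    if (!all(c("exon", "start", "end") %in% names(em)))
      return("exonMap needs columns exon, start, end")
    if (any(em$start < 0 | em$end > w[1] | em$start >= em$end))
      return("exonMap coordinates out of range")
  }
  TRUE
})

#' DivergenceEstimate: pairwise dS/dN with uncertainty
#'
#' @slot dS,dN synonymous / nonsynonymous substitutions per site
#' @slot omega dN/dS (NA when dS is zero)
#' @slot seDS,seDN standard errors (NA for the counting method)
#' @slot ci95DS numeric length 2, estimate +/- 1.96 SE floored at 0
#' @slot method "ML" or "NG86"
#' @slot nCodons codons used after pairwise deletion
#' @slot kappa,t,lnL ML nuisance estimates (NA for NG86)
#' @slot converged logical
#' @exportClass DivergenceEstimate
setClass("DivergenceEstimate",
  representation(dS = "numeric", dN = "numeric", omega = "numeric",
                 seDS = "numeric", seDN = "numeric", ci95DS = "numeric",
                 method = "character", nCodons = "integer",
                 kappa = "numeric", t = "numeric", lnL = "numeric",
                 converged = "logical"))

setValidity("DivergenceEstimate", function(object) {
  if (object@dS < 0 || object@dN < 0) return("dS and dN must be >= 0")
  if (length(object@ci95DS) != 2) return("ci95DS must have length 2")
  if (!object@method %in% c("ML", "NG86")) return("method must be ML or NG86")
  TRUE
})

#' SupportedTree: a gene tree with bootstrap support
#'
#' @slot tree rooted \code{phylo} (rooted on the designated outgroup)
#' @slot support named numeric, percent support per internal bipartition of
#'   the ML tree (names are semicolon-joined sorted tip subsets)
#' @slot outgroup tip label used to root
#' @slot kappa HKY transition/transversion estimate
#' @slot logLik log-likelihood of the ML topology
#' @slot starLike TRUE when all enumerated topologies tie (flagged arbitrary
#'   resolution)
#' @slot fits internal per-topology fit cache used for bootstrapping
#' @exportClass SupportedTree
setClass("SupportedTree",
  representation(tree = "phylo", support = "numeric", outgroup = "character",
                 kappa = "numeric", logLik = "numeric", starLike = "logical",
                 fits = "list"))

setValidity("SupportedTree", function(object) {
  if (length(object@support) &&
      (any(object@support < 0) || any(object@support > 100)))
    return("supports must lie in [0, 100]")
  if (!object@outgroup %in% object@tree$tip.label)
    return("outgroup is not among the tips")
  TRUE
})

#' SimulationConfig: parameters of the gametolog history simulator
#'
#' The defaults describe a four-taxon bird phylogeny
#' (((Gg, Mg), Ap), Tg) with splits at 30, 90 and 130 My, a combined Z+W
#' synonymous substitution rate of 3.8e-9 per site per year partitioned
#' 1:2.4 (W:Z) for male mutation bias, HKY kappa = 2 and purifying selection
#' omega = 0.2 on both chromosomes.
#'
#' @slot splitTimes named numeric: years before present of the GgMg, GgMgAp
#'   and root splits
#' @slot nLoci number of loci
#' @slot cdsLength CDS length in nucleotides (multiple of 3)
#' @slot suppressionTimes data.frame(locus, lineage, time): the lineage
#'   (one of Gg, Mg, Ap, GgMg, GgMgAp) and years-before-present at which Z-W
#'   recombination ceased for that locus
#' @slot muW,muZ substitution rates per site per year on W and Z lineages
#' @slot omegaW,omegaZ dN/dS applied during simulation
#' @slot kappa HKY transition/transversion ratio of the proposal process
#' @slot conversionTracts data.frame(locus, donor, recipient, start, end,
#'   time): tracts copied between tips (0-based half-open CDS coordinates)
#' @slot seed integer RNG seed
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(splitTimes = "numeric", nLoci = "integer",
                 cdsLength = "integer", suppressionTimes = "data.frame",
                 muW = "numeric", muZ = "numeric",
                 omegaW = "numeric", omegaZ = "numeric", kappa = "numeric",
                 conversionTracts = "data.frame", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  st <- object@splitTimes
  if (!all(c("GgMg", "GgMgAp", "root") %in% names(st)))
    return("splitTimes needs GgMg, GgMgAp, root")
  if (!(st["GgMg"] < st["GgMgAp"] && st["GgMgAp"] < st["root"]))
    return("splitTimes must be ordered GgMg < GgMgAp < root")
  if (object@cdsLength %% 3L != 0L) return("cdsLength must be a multiple of 3")
  if (object@cdsLength <= 0L) return("cdsLength must be positive")
  if (object@muW <= 0 || object@muZ <= 0 || object@kappa <= 0)
    return("rates must be > 0")
  if (any(object@omegaW < 0) || any(object@omegaZ < 0))
    return("omega must be >= 0")
  sup <- object@suppressionTimes
  if (nrow(sup)) {
    if (!all(c("locus", "lineage", "time") %in% names(sup)))
      return("suppressionTimes needs locus, lineage, time")
    if (any(sup$time < 0)) return("suppression times must be >= 0")
    if (any(sup$time > st["root"]))
      return("suppression times must not exceed the root age")
    iv <- lineageInterval(st)
    for (k in seq_len(nrow(sup))) {
      ln <- as.character(sup$lineage[k])
      if (!ln %in% rownames(iv)) return(sprintf("unknown lineage '%s'", ln))
      if (sup$time[k] < iv[ln, 1] || sup$time[k] > iv[ln, 2])
        return(sprintf(
          "suppression at %g years predates/postdates the %s branch [%g, %g]",
          sup$time[k], ln, iv[ln, 1], iv[ln, 2]))
    }
  }
  tr <- object@conversionTracts
  if (nrow(tr)) {
    if (any(tr$start < 0 | tr$end > object@cdsLength | tr$start >= tr$end))
      return("tract coordinates must satisfy 0 <= start < end <= cdsLength")
  }
  TRUE
})

#' SimulatedDataset: sequences plus ground truth
#'
#' @slot sequences list (one per locus) of named \code{DNAStringSet}s with
#'   tips named \code{<taxon>_<Z|W>}
#' @slot truth data.frame: per-locus lineage, suppression time, topology
#'   class ("shared" / "independent"), and per-taxon W presence
#' @slot tracts data.frame of injected conversion tracts (0 rows if none)
#' @slot expression a \code{SummarizedExperiment} of sexed expression or NULL
#' @slot snps data.frame of female-limited variants or NULL
#' @slot config the generating \code{SimulationConfig}
#' @exportClass SimulatedDataset
setClass("SimulatedDataset",
  representation(sequences = "list", truth = "data.frame",
                 tracts = "data.frame", expression = "ANY", snps = "ANY",
                 config = "SimulationConfig"))

setValidity("SimulatedDataset", function(object) {
  if (!all(names(object@sequences) %in% object@truth$locus))
    return("truth records must exist for every locus")
  ok <- vapply(object@sequences, function(s) "Tg_Z" %in% names(s), logical(1))
  if (!all(ok)) return("every locus must carry a Tg_Z outgroup sequence")
  TRUE
})

#' SelectionTestResult: branch / branch-site likelihood-ratio test
#'
#' @slot model model family ("branch" or "branch-site")
#' @slot lnL named numeric of log-likelihoods (alternative and null(s))
#' @slot omega named numeric of estimated/fixed omega per branch class (and
#'   site class for the branch-site model)
#' @slot lrt data.frame: comparison, statistic (2*delta lnL), df, p (chi2)
#'   and p_mixture for the branch-site test
#' @slot siteClasses data.frame of site-class proportions (branch-site) or
#'   0 rows
#' @slot converged logical
#' @exportClass SelectionTestResult
setClass("SelectionTestResult",
  representation(model = "character", lnL = "numeric", omega = "numeric",
                 lrt = "data.frame", siteClasses = "data.frame",
                 converged = "logical"))

setValidity("SelectionTestResult", function(object) {
  if (nrow(object@lrt) && any(object@lrt$statistic < -1e-6))
    return("LRT statistics must be >= 0 (nested models)")
  if (nrow(object@siteClasses)) {
    s <- sum(object@siteClasses$proportion)
    if (abs(s - 1) > 1e-6) return("site-class proportions must sum to 1")
  }
  TRUE
})

#' LabeledTreeTemplate: a selection-test topology with foreground labels
#'
#' @slot tree \code{phylo} fixed topology over \code{<taxon>_<Z|W>} tips
#' @slot case "shared" or "independent" recombination-suppression history
#' @slot foreground "W" or "Z": which chromosome's branches are foreground
#' @slot foregroundEdges integer indices into \code{tree$edge} rows
#' @exportClass LabeledTreeTemplate
setClass("LabeledTreeTemplate",
  representation(tree = "phylo", case = "character", foreground = "character",
                 foregroundEdges = "integer"))

setValidity("LabeledTreeTemplate", function(object) {
  if (!object@case %in% c("shared", "independent"))
    return("case must be 'shared' or 'independent'")
  if (!object@foreground %in% c("W", "Z"))
    return("foreground must be 'W' or 'Z'")
  TRUE
})
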