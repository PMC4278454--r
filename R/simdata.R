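# Forward simulation of gametolog histories on the bird phylogeny
# (((Gg, Mg), Ap), Tg): proto-sex-chromosome loci evolve as a single
# sequence until recombination suppression, then on separate Z and W
# lineages with sex-specific rates. The proposal process is HKY on
# nucleotides layered over codons, with rejection sampling to enforce the
# target dN/dS; the proposal intensity is corrected for discarded
# stop-codon moves so that the realised synonymous rate per site per year
# equals the configured rate exactly.

#' Branch interval (years before present) for each lineage label
#' @keywords internal
lineageInterval <- function(st) {
  m <- rbind(Gg = c(0, st[["GgMg"]]),
             Mg = c(0, st[["GgMg"]]),
             Ap = c(0, st[["GgMgAp"]]),
             GgMg = c(st[["GgMg"]], st[["GgMgAp"]]),
             GgMgAp = c(st[["GgMgAp"]], st[["root"]]))
  colnames(m) <- c("lo", "hi")
  m
}

#' Create a simulation configuration
#'
#' Defaults describe the study system: four taxa splitting at 30, 90 and
#' 130 My; a combined Z+W synonymous substitution rate of 3.8e-9 per site
#' per year split 1:2.4 (W:Z) for male mutation bias; HKY kappa = 2;
#' purifying selection omega = 0.2 on both chromosomes; 30 loci of 900 bp
#' distributed over five recombination-suppression events mirroring the
#' avian strata (two Galloanserae-ancestral, two Galliform, one
#' Anseriform-specific).
#'
#' @param nLoci number of loci
#' @param cdsLength CDS length in nucleotides (multiple of 3)
#' @param suppressionTimes data.frame(locus, lineage, time) and optionally
#'   \code{z_position_mb}; NULL for the default five-stratum layout
#' @param muW,muZ substitution rates per site per year (defaults sum to
#'   3.8e-9 in ratio 1:2.4)
#' @param omegaW,omegaZ dN/dS during simulation
#' @param kappa transition/transversion ratio
#' @param splitTimes named numeric (GgMg, GgMgAp, root) in years
#' @param conversionTracts data.frame(locus, donor, recipient, start, end,
#'   time) or NULL
#' @param seed integer seed
#' @return a \linkS4class{SimulationConfig}
#' @export
simulationConfig <- function(nLoci = 30L, cdsLength = 900L,
                             suppressionTimes = NULL,
                             muW = 3.8e-9 / 3.4, muZ = 3.8e-9 * 2.4 / 3.4,
                             omegaW = 0.2, omegaZ = 0.2, kappa = 2,
                             splitTimes = c(GgMg = 30e6, GgMgAp = 90e6,
                                            root = 130e6),
                             conversionTracts = NULL, seed = 1L) {
  if (is.null(suppressionTimes)) {
    strata <- data.frame(
      lineage = c("GgMgAp", "GgMgAp", "GgMg", "GgMg", "Ap"),
      time = c(100e6, 92e6, 55e6, 45e6, 20e6),
      lo = c(45, 54, 17, 0, 0), hi = c(51, 61, 43, 11, 75))
    k <- rep(seq_len(5), length.out = nLoci)
    posFrac <- stats::ave(seq_len(nLoci), k, FUN = function(v)
      seq_along(v) / (length(v) + 1))
    suppressionTimes <- data.frame(
      locus = sprintf("L%03d", seq_len(nLoci)),
      lineage = strata$lineage[k], time = strata$time[k],
      z_position_mb = strata$lo[k] + (strata$hi[k] - strata$lo[k]) * posFrac)
  }
  if (is.null(conversionTracts))
    conversionTracts <- data.frame(locus = character(), donor = character(),
                                   recipient = character(), start = integer(),
                                   end = integer(), time = numeric())
  new("SimulationConfig", splitTimes = splitTimes, nLoci = as.integer(nLoci),
      cdsLength = as.integer(cdsLength), suppressionTimes = suppressionTimes,
      muW = muW, muZ = muZ, omegaW = omegaW, omegaZ = omegaZ, kappa = kappa,
      conversionTracts = conversionTracts, seed = as.integer(seed))
}

# --- codon-level proposal machinery ----------------------------------------

#' Neighbour lookup tables for the event-driven simulator
#' @return list: \code{tgt[c, pos, nt]} sense-codon index reached from codon
#'   c by putting nucleotide nt at position pos (0 if stop / identical),
#'   \code{ntIdx[c, pos]} current nucleotide index per codon position,
#'   \code{syn[c, pos, nt]} synonymy indicator, and \code{stopFrac(kappa)}.
#' @keywords internal
.simTables <- function() {
  if (!is.null(.zw_cache$sim)) return(.zw_cache$sim)
  tab <- codonTables()
  gc_map <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  n <- length(tab$sense)
  tgt <- array(0L, c(n, 3, 4))
  syn <- array(FALSE, c(n, 3, 4))
  isStop <- array(FALSE, c(n, 3, 4))
  ntIdx <- matrix(0L, n, 3)
  for (c in seq_len(n)) {
    for (p in 1:3) {
      ntIdx[c, p] <- match(tab$cmat[c, p], nts)
      for (a in 1:4) {
        if (a == ntIdx[c, p]) next
        cod <- tab$cmat[c, ]
        cod[p] <- nts[a]
        cods <- paste(cod, collapse = "")
        if (gc_map[cods] == "*") { isStop[c, p, a] <- TRUE; next }
        j <- tab$idx[cods]
        tgt[c, p, a] <- j
        syn[c, p, a] <- tab$aa[c] == tab$aa[j]
      }
    }
  }
  TS <- matrix(FALSE, 4, 4)
  TS[1, 3] <- TS[3, 1] <- TS[2, 4] <- TS[4, 2] <- TRUE  # A<->G, C<->T
  stopFrac <- function(kappa) {
    num <- 0; den <- 0
    for (c in seq_len(n)) for (p in 1:3) for (a in 1:4) {
      if (a == ntIdx[c, p]) next
      w <- if (TS[ntIdx[c, p], a]) kappa else 1
      den <- den + w
      if (isStop[c, p, a]) num <- num + w
    }
    num / den
  }
  .zw_cache$sim <- list(tgt = tgt, syn = syn, isStop = isStop, ntIdx = ntIdx,
                        TS = TS, stopFrac = stopFrac)
  .zw_cache$sim
}

#' Evolve a codon sequence for a span of years
#'
#' @param seq integer vector of sense-codon indices
#' @param years branch duration
#' @param mu substitution rate per site per year
#' @param omega dN/dS; scalar or per-codon vector; values > 1 add a
#'   nonsynonymous-only event stream at the excess rate
#' @param kappa transition/transversion ratio
#' @return the evolved sequence
#' @keywords internal
evolveSeq <- function(seq, years, mu, omega, kappa) {
  if (years <= 0) return(seq)
  st <- .simTables()
  ncod <- length(seq)
  key <- sprintf("sf_%.8g", kappa)
  if (is.null(.zw_cache[[key]])) .zw_cache[[key]] <- st$stopFrac(kappa)
  sf <- .zw_cache[[key]]
  if (length(omega) == 1) omega <- rep(omega, ncod)
  nEv <- rpois(1, 3 * mu * years * ncod / (1 - sf))
  if (nEv > 0) {
    sites <- sample.int(3L * ncod, nEv, replace = TRUE)
    for (s in sites) {
      cpos <- (s - 1L) %/% 3L + 1L
      p <- (s - 1L) %% 3L + 1L
      c0 <- seq[cpos]
      cur <- st$ntIdx[c0, p]
      w <- ifelse(st$TS[cur, ], kappa, 1)
      w[cur] <- 0
      a <- sample.int(4L, 1L, prob = w)
      j <- st$tgt[c0, p, a]
      if (j == 0L) next                       # stop codon: discard proposal
      if (!st$syn[c0, p, a]) {
        om <- omega[cpos]
        if (om < 1 && runif(1) > om) next     # rejected nonsynonymous change
      }
      seq[cpos] <- j
    }
  }
  # excess nonsynonymous stream for omega > 1 (positive selection)
  exc <- pmax(omega - 1, 0)
  if (any(exc > 0)) {
    n2 <- rpois(1, 3 * mu * years * sum(exc) / (1 - sf))
    if (n2 > 0) {
      cps <- sample.int(ncod, n2, replace = TRUE, prob = exc)
      for (cpos in cps) {
        p <- sample.int(3L, 1L)
        c0 <- seq[cpos]
        cur <- st$ntIdx[c0, p]
        w <- ifelse(st$TS[cur, ], kappa, 1)
        w[cur] <- 0
        a <- sample.int(4L, 1L, prob = w)
        j <- st$tgt[c0, p, a]
        if (j == 0L || st$syn[c0, p, a]) next # nonsynonymous changes only
        seq[cpos] <- j
      }
    }
  }
  seq
}

# --- the history simulator -------------------------------------------------

#' Simulate gametolog histories on the four-taxon bird phylogeny
#'
#' Each locus starts as one proto-sex-chromosome sequence at the root. On
#' the branch carrying that locus's recombination-suppression event the
#' sequence duplicates into Z and W lineages, which then evolve
#' independently at \code{muZ} and \code{muW}; unsuppressed loci travel at
#' \code{muZ}. The within-species Z-W expected synonymous divergence is
#' therefore (muZ + muW) * T_supp. Conversion tracts listed in the
#' configuration are applied to the tip sequences (copy donor over
#' recipient, then re-diverge both copies for the tract's age). A truth
#' table records per-event lineage, time, topology class and Z position,
#' and a female-limited SNP table is emitted for every W-bearing taxon.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @return a \linkS4class{SimulatedDataset}
#' @examples
#' cfg <- simulationConfig(nLoci = 2, cdsLength = 300, seed = 7)
#' sim <- simulateGametologHistory(cfg)
#' names(sim@sequences[[1]])
#' @export
simulateGametologHistory <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  tab <- codonTables()
  st <- config@splitTimes
  ncod <- config@cdsLength %/% 3L
  sup <- config@suppressionTimes
  loci <- if (nrow(sup)) unique(as.character(sup$locus)) else
    sprintf("L%03d", seq_len(config@nLoci))

  sequences <- vector("list", length(loci))
  names(sequences) <- loci
  truthRows <- list()
  snpRows <- list()

  for (li in seq_along(loci)) {
    locus <- loci[li]
    ev <- sup[as.character(sup$locus) == locus, , drop = FALSE]
    evOn <- setNames(rep(NA_real_, 5),
                     c("Gg", "Mg", "Ap", "GgMg", "GgMgAp"))
    if (nrow(ev)) evOn[as.character(ev$lineage)] <- ev$time
    rootSeq <- sample.int(61L, ncod, replace = TRUE)
    tips <- list()
    addTip <- function(name, s) tips[[name]] <<- s
    evolveBranch <- function(seqZ, seqW, branch, tTop, tBot) {
      # handles one species-tree branch; returns list(Z, W)
      tSup <- evOn[[branch]]
      if (!is.na(tSup) && is.null(seqW)) {
        seqZ <- evolveSeq(seqZ, tTop - tSup, config@muZ, config@omegaZ,
                          config@kappa)
        seqW <- seqZ
        tTop <- tSup
      } else if (!is.na(tSup) && !is.null(seqW)) {
        stop("locus ", locus, ": suppression on lineage ", branch,
             " but the locus is already suppressed upstream")
      }
      seqZ <- evolveSeq(seqZ, tTop - tBot, config@muZ, config@omegaZ,
                        config@kappa)
      if (!is.null(seqW))
        seqW <- evolveSeq(seqW, tTop - tBot, config@muW, config@omegaW,
                          config@kappa)
      list(Z = seqZ, W = seqW)
    }
    # root -> Tg tip (Z only; no suppression modelled on the outgroup)
    tg <- evolveSeq(rootSeq, st[["root"]], config@muZ, config@omegaZ,
                    config@kappa)
    addTip("Tg_Z", tg)
    # root -> Galloanserae ancestor
    anc <- evolveBranch(rootSeq, NULL, "GgMgAp", st[["root"]], st[["GgMgAp"]])
    # -> Ap tip
    ap <- evolveBranch(anc$Z, anc$W, "Ap", st[["GgMgAp"]], 0)
    addTip("Ap_Z", ap$Z)
    if (!is.null(ap$W)) addTip("Ap_W", ap$W)
    # -> Galliform ancestor -> Gg, Mg tips
    gal <- evolveBranch(anc$Z, anc$W, "GgMg", st[["GgMgAp"]], st[["GgMg"]])
    gg <- evolveBranch(gal$Z, gal$W, "Gg", st[["GgMg"]], 0)
    addTip("Gg_Z", gg$Z)
    if (!is.null(gg$W)) addTip("Gg_W", gg$W)
    mg <- evolveBranch(gal$Z, gal$W, "Mg", st[["GgMg"]], 0)
    addTip("Mg_Z", mg$Z)
    if (!is.null(mg$W)) addTip("Mg_W", mg$W)

    seqChar <- vapply(tips, function(s)
      paste(tab$sense[s], collapse = ""), character(1))
    dss <- Biostrings::DNAStringSet(seqChar)
    names(dss) <- names(tips)
    sequences[[locus]] <- dss

    if (nrow(ev)) {
      for (k in seq_len(nrow(ev))) {
        ln <- as.character(ev$lineage[k])
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          locus = locus, lineage = ln, time = ev$time[k],
          class = if (ln %in% c("GgMg", "GgMgAp")) "shared" else
            "independent",
          expected_dS = (config@muZ + config@muW) * ev$time[k],
          z_position_mb = if ("z_position_mb" %in% names(ev))
            ev$z_position_mb[k] else NA_real_)
      }
    } else {
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        locus = locus, lineage = NA_character_, time = NA_real_,
        class = NA_character_, expected_dS = NA_real_,
        z_position_mb = NA_real_)
    }
  }
  truth <- do.call(rbind, truthRows)

  ds <- new("SimulatedDataset", sequences = sequences, truth = truth,
            tracts = data.frame(locus = character(), donor = character(),
                                recipient = character(), start = integer(),
                                end = integer(), time = numeric()),
            expression = NULL, snps = NULL, config = config)

  # conversion tracts from the config
  tr <- config@conversionTracts
  if (nrow(tr)) {
    for (k in seq_len(nrow(tr))) {
      ds <- injectGeneConversion(ds, tr$locus[k], tr$donor[k],
                                 tr$recipient[k], tr$start[k], tr$end[k],
                                 time = tr$time[k])
    }
  }

  # female-limited SNP channel: fixed Z-W differences plus one segregating
  # W variant per W gene lacking fixed differences
  for (locus in names(ds@sequences)) {
    s <- ds@sequences[[locus]]
    for (tax in c("Gg", "Mg", "Ap")) {
      wn <- paste0(tax, "_W"); zn <- paste0(tax, "_Z")
      if (!wn %in% names(s)) next
      z <- strsplit(as.character(s[[zn]]), "")[[1]]
      w <- strsplit(as.character(s[[wn]]), "")[[1]]
      d <- which(z != w)
      if (length(d)) {
        snpRows[[length(snpRows) + 1L]] <- data.frame(
          locus = locus, taxon = tax, cds_pos = d - 1L, z_allele = z[d],
          w_allele = w[d], n_female_carriers = 5L, n_male_carriers = 0L,
          fixed = TRUE)
      } else {
        p <- sample.int(length(w), 1L)
        alt <- sample(setdiff(c("A", "C", "G", "T"), w[p]), 1L)
        snpRows[[length(snpRows) + 1L]] <- data.frame(
          locus = locus, taxon = tax, cds_pos = p - 1L, z_allele = z[p],
          w_allele = alt, n_female_carriers = 2L, n_male_carriers = 0L,
          fixed = FALSE)
      }
    }
  }
  ds@snps <- if (length(snpRows)) do.call(rbind, snpRows) else NULL
  validObject(ds)
  ds
}

#' Copy a conversion tract from a donor tip onto a recipient tip
#'
#' The recipient sequence becomes identical to the donor over
#' \code{[start, end)} (0-based half-open CDS coordinates). With
#' \code{time > 0} both copies then re-diverge independently for that many
#' years at their chromosome-specific rates, emulating a conversion event
#' \code{time} years before the present. A chimeric boundary codon that
#' would become a stop codon is reverted to the recipient's original codon.
#'
#' @param dataset a \linkS4class{SimulatedDataset}
#' @param locus locus name
#' @param donor,recipient tip names such as \code{"Ap_W"}
#' @param start,end tract coordinates, 0-based half-open, within the CDS
#' @param time age of the event in years (0 = copy at the present)
#' @return the modified dataset with its truth/tract tables updated
#' @export
injectGeneConversion <- function(dataset, locus, donor, recipient,
                                 start, end, time = 0) {
  stopifnot(is(dataset, "SimulatedDataset"))
  s <- dataset@sequences[[locus]]
  if (is.null(s)) stop("unknown locus '", locus, "'")
  if (!donor %in% names(s) || !recipient %in% names(s))
    stop("donor or recipient tip not present at locus ", locus)
  L <- Biostrings::width(s)[1]
  if (start < 0 || end > L || start >= end)
    stop("tract coordinates must satisfy 0 <= start < end <= ", L)
  prev <- dataset@tracts
  ov <- prev$locus == locus & prev$recipient == recipient &
    prev$start < end & prev$end > start & prev$donor != donor
  if (any(ov)) stop("overlapping contradictory tracts for ", recipient,
                    " at locus ", locus)
  tab <- codonTables()
  dn <- strsplit(as.character(s[[donor]]), "")[[1]]
  rc <- strsplit(as.character(s[[recipient]]), "")[[1]]
  orig <- rc
  idx <- (start + 1L):end
  rc[idx] <- dn[idx]
  # revert chimeric boundary codons that became stops
  for (cp in unique((idx - 1L) %/% 3L)) {
    cod <- paste(rc[(cp * 3L + 1L):(cp * 3L + 3L)], collapse = "")
    if (cod %in% c("TAA", "TAG", "TGA"))
      rc[(cp * 3L + 1L):(cp * 3L + 3L)] <- orig[(cp * 3L + 1L):(cp * 3L + 3L)]
  }
  if (time > 0) {
    cfg <- dataset@config
    rates <- function(tip) {
      chrom <- sub(".*_", "", tip)
      if (chrom == "W") c(cfg@muW, cfg@omegaW) else c(cfg@muZ, cfg@omegaZ)
    }
    cs <- (start %/% 3L) + 1L
    ce <- ((end - 1L) %/% 3L) + 1L
    rediv <- function(chars, tip) {
      cods <- splitCodons(paste(chars, collapse = ""))
      seg <- unname(tab$idx[cods[cs:ce]])
      r <- rates(tip)
      seg <- evolveSeq(seg, time, r[1], r[2], cfg@kappa)
      cods[cs:ce] <- tab$sense[seg]
      strsplit(paste(cods, collapse = ""), "")[[1]]
    }
    rc <- rediv(rc, recipient)
    dn <- rediv(dn, donor)
    s[[donor]] <- Biostrings::DNAString(paste(dn, collapse = ""))
  }
  s[[recipient]] <- Biostrings::DNAString(paste(rc, collapse = ""))
  dataset@sequences[[locus]] <- s
  dataset@tracts <- rbind(prev, data.frame(
    locus = locus, donor = donor, recipient = recipient,
    start = start, end = end, time = time))
  dataset
}

#' Simulate a sexed expression matrix
#'
#' W-linked genes have zero expectation in males (with a sub-threshold
#' technical leakage exercising the rounding rule of the classifier); Z and
#' autosomal genes are expressed equally in both sexes. Multiplicative
#' lognormal noise with dispersion \code{sdlog}.
#'
#' @param dataset a \linkS4class{SimulatedDataset}
#' @param nMales,nFemales samples per sex (>= 1)
#' @param sdlog lognormal noise dispersion (default 0.5)
#' @param nAutosomal number of autosomal decoy genes (default 50)
#' @param seed integer seed
#' @return a \code{SummarizedExperiment} with assay \code{fpkm}, colData
#'   \code{sex}, and rowData \code{class} ("W", "Z" or "autosome")
#' @export
simulateExpression <- function(dataset, nMales = 5L, nFemales = 5L,
                               sdlog = 0.5, nAutosomal = 50L, seed = 1L) {
  stopifnot(is(dataset, "SimulatedDataset"), nMales >= 1, nFemales >= 1)
  set.seed(seed)
  rows <- list()
  for (locus in names(dataset@sequences)) {
    for (tip in names(dataset@sequences[[locus]])) {
      chrom <- sub(".*_", "", tip)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = paste0(locus, "_", tip), class = chrom, locus = locus)
    }
  }
  if (nAutosomal > 0)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = sprintf("auto%03d", seq_len(nAutosomal)), class = "autosome",
      locus = NA_character_)
  rd <- do.call(rbind, rows)
  ng <- nrow(rd)
  nS <- nMales + nFemales
  sex <- c(rep("M", nMales), rep("F", nFemales))
  baseMean <- rlnorm(ng, meanlog = log(20), sdlog = 1)
  mat <- matrix(0, ng, nS, dimnames = list(rd$gene, sprintf("s%02d",
                                                            seq_len(nS))))
  for (g in seq_len(ng)) {
    fem <- baseMean[g] * rlnorm(nFemales, 0, sdlog)
    male <- if (rd$class[g] == "W") runif(nMales, 0, 0.004) else
      baseMean[g] * rlnorm(nMales, 0, sdlog)
    mat[g, ] <- c(male, fem)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = mat),
    colData = S4Vectors::DataFrame(sex = sex, row.names = colnames(mat)),
    rowData = S4Vectors::DataFrame(class = rd$class, locus = rd$locus,
                                   row.names = rd$gene))
}

setMethod("show", "SimulatedDataset", function(object) {
  cat(sprintf("SimulatedDataset: %d loci, %d bp CDS, seed %d\n",
              length(object@sequences), object@config@cdsLength,
              object@config@seed))
  cls <- table(object@truth$class)
  if (length(cls)) cat("  suppression classes:",
                       paste(names(cls), cls, sep = "=", collapse = ", "),
                       "\n")
  cat(sprintf("  conversion tracts: %d; SNP records: %d\n",
              nrow(object@tracts),
              if (is.null(object@snps)) 0L else nrow(object@snps)))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d loci x %d bp; muZ=%.3g muW=%.3g kappa=%.2g\n",
    object@nLoci, object@cdsLength, object@muZ, object@muW, object@kappa))
  cat(sprintf("  omegaZ=%.2g omegaW=%.2g; seed %d\n", object@omegaZ,
              object@omegaW, object@seed))
})
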