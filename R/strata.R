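# Evolutionary strata: molecular-clock dating of recombination suppression
# and assignment of gametologs to strata by confidence-interval overlap
# along the Z chromosome, with gene-tree evidence taking precedence.

#' Molecular-clock date from synonymous divergence
#'
#' Converts Z-W synonymous divergence to years since recombination
#' suppression as T = dS / rate, with the default rate of 3.8e-9
#' substitutions per site per year absorbing the sex-specific (male-biased)
#' mutation rates of the Z and W. Estimates with dS above 1 are refused:
#' they fail the saturation gate and cannot be dated reliably.
#'
#' @param dS synonymous divergence (vector allowed), 0 <= dS <= 1
#' @param rate substitutions per site per year (default 3.8e-9)
#' @param roundMy round the result to the nearest million years
#'   (default TRUE, matching reported integer dates)
#' @return divergence time(s) in millions of years
#' @examples
#' clockDate(0.285)  # 75
#' clockDate(0.137)  # 36
#' @export
clockDate <- function(dS, rate = 3.8e-9, roundMy = TRUE) {
  if (any(is.na(dS))) stop("dS contains NA")
  if (any(dS < 0)) stop("dS must be >= 0")
  if (any(dS > 1))
    stop("dS = ", max(dS), " exceeds 1: saturated estimates are not dated")
  if (rate <= 0) stop("rate must be > 0")
  t <- dS / rate / 1e6
  if (roundMy) round(t) else t
}

#' @describeIn clockDate map a dS confidence interval through the clock
#' @param ci numeric length 2 (lower, upper dS)
#' @export
clockDateCI <- function(ci, rate = 3.8e-9, roundMy = TRUE) {
  c(lo = clockDate(max(0, ci[1]), rate, roundMy),
    hi = clockDate(ci[2], rate, roundMy))
}

#' @keywords internal
.ciOverlap <- function(lo1, hi1, lo2, hi2) lo1 <= hi2 && lo2 <= hi1

#' Assign gametologs to evolutionary strata
#'
#' A locus joins the reference stratum at its Z position when its dS 95\%
#' confidence interval overlaps the reference (orthologous) locus's
#' interval; when the intervals are disjoint and the locus diverged less, it
#' is called lineage-specific. An "independent" gene-tree call overrides CI
#' evidence (the conflict is flagged); saturated loci (dS > 1) are excluded
#' upstream by \code{\link{checkSaturation}}.
#'
#' @param pairs data.frame with columns \code{locus}, \code{dS},
#'   \code{ciLo}, \code{ciHi}, \code{z_position_mb}
#' @param reference data.frame with columns \code{locus}, \code{stratum},
#'   \code{dS}, \code{ciLo}, \code{ciHi} (per-gene reference estimates)
#' @param treeCalls optional named character vector of topology classes per
#'   locus ("shared", "independent", "unresolved")
#' @param lineageLabel stratum label used for lineage-specific loci
#'   (default "lineage-specific")
#' @param poolReference compare against the pooled dS range of each
#'   reference stratum instead of the orthologous gene (default FALSE)
#' @return data.frame: locus, stratum, basis, conflict, z_position_mb, dS,
#'   ciLo, ciHi, date_my, reason
#' @export
assignStrata <- function(pairs, reference, treeCalls = NULL,
                         lineageLabel = "lineage-specific",
                         poolReference = FALSE) {
  need <- c("locus", "dS", "ciLo", "ciHi", "z_position_mb")
  stopifnot(all(need %in% names(pairs)))
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    p <- pairs[k, ]
    row <- data.frame(locus = p$locus, stratum = NA_character_,
                      basis = NA_character_, conflict = FALSE,
                      z_position_mb = p$z_position_mb, dS = p$dS,
                      ciLo = p$ciLo, ciHi = p$ciHi,
                      date_my = if (p$dS <= 1) clockDate(p$dS) else NA_real_,
                      reason = NA_character_)
    if (is.na(p$z_position_mb)) {
      row$basis <- "unassignable"
      row$reason <- "no Z position"
      out[[k]] <- row
      next
    }
    if (poolReference) {
      refRow <- NULL
      for (strat in unique(reference$stratum)) {
        rs <- reference[reference$stratum == strat, ]
        if (.ciOverlap(p$ciLo, p$ciHi, min(rs$ciLo), max(rs$ciHi)))
          refRow <- data.frame(stratum = strat, ciLo = min(rs$ciLo),
                               ciHi = max(rs$ciHi), dS = mean(rs$dS))
      }
    } else {
      m <- reference[reference$locus == p$locus, ]
      refRow <- if (nrow(m)) m[1, ] else NULL
    }
    if (is.null(refRow)) {
      row$basis <- "unassignable"
      row$reason <- "no reference ortholog"
      out[[k]] <- row
      next
    }
    ciCall <- if (.ciOverlap(p$ciLo, p$ciHi, refRow$ciLo, refRow$ciHi)) {
      "overlap"
    } else if (p$dS < refRow$dS) "lower" else "higher"
    row$stratum <- switch(ciCall,
                          overlap = as.character(refRow$stratum),
                          lower = lineageLabel,
                          higher = NA_character_)
    row$basis <- switch(ciCall,
                        overlap = "ci-overlap-with-reference",
                        lower = "ci-nonoverlap-lower",
                        higher = "ci-nonoverlap-higher")
    tc <- if (!is.null(treeCalls))
      unname(treeCalls[as.character(p$locus)]) else NA_character_
    if (!is.na(tc) && tc == "independent") {
      if (identical(ciCall, "overlap")) row$conflict <- TRUE
      row$stratum <- lineageLabel
      row$basis <- "tree-independent"
    }
    out[[k]] <- row
  }
  do.call(rbind, out)
}

#' Summarise strata: Z interval, dS range and clock-dated range
#'
#' @param assignments output of \code{\link{assignStrata}}
#' @param rate clock rate passed to \code{\link{clockDate}}
#' @return data.frame ordered by Z start: stratum, n, z_start_mb, z_end_mb,
#'   dS_min, dS_max, date_min_my, date_max_my
#' @examples
#' a <- data.frame(locus = c("x", "y"), stratum = "CS-I",
#'                 basis = "ci-overlap-with-reference", conflict = FALSE,
#'                 z_position_mb = c(45, 51), dS = c(0.285, 0.404),
#'                 ciLo = c(0.25, 0.35), ciHi = c(0.32, 0.45),
#'                 date_my = c(75, 106), reason = NA)
#' summarizeStrata(a)  # dates 75 and 106 My
#' @export
summarizeStrata <- function(assignments, rate = 3.8e-9) {
  a <- assignments[!is.na(assignments$stratum), , drop = FALSE]
  if (!nrow(a)) stop("no assigned loci to summarise")
  out <- lapply(split(a, a$stratum), function(g) {
    data.frame(stratum = g$stratum[1], n = nrow(g),
               z_start_mb = min(g$z_position_mb),
               z_end_mb = max(g$z_position_mb),
               dS_min = min(g$dS), dS_max = max(g$dS),
               date_min_my = clockDate(min(g$dS), rate),
               date_max_my = clockDate(max(g$dS), rate))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$z_start_mb), , drop = FALSE]
}
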