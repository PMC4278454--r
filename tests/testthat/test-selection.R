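test_that("branch-tree templates reproduce the two suppression histories", {
  shared <- buildBranchTree("shared")
  expected <- ape::read.tree(
    text = "(Tg_Z,(((Gg_W,Mg_W),Ap_W),((Gg_Z,Mg_Z),Ap_Z)));")
  expect_true(ape::all.equal.phylo(ape::unroot(expected), shared@tree,
                                   use.edge.length = FALSE))
  indep <- buildBranchTree("independent")
  expectedI <- ape::read.tree(
    text = "(Tg_Z,(((Gg_W,Mg_W),(Gg_Z,Mg_Z)),(Ap_Z,Ap_W)));")
  expect_true(ape::all.equal.phylo(ape::unroot(expectedI), indep@tree,
                                   use.edge.length = FALSE))
  # pruning Mg from the shared case keeps the (Gg_W, Ap_W) clade
  p5 <- buildBranchTree("shared", taxa = c("Gg", "Ap", "Tg"))
  expect_equal(ape::Ntip(p5@tree), 5L)
  expect_true(ZWstrata:::.splitKey(c("Gg_W", "Ap_W"), p5@tree$tip.label) %in%
                ZWstrata:::.treeSplits(p5@tree))
  # foreground labelling covers exactly the W branches (tips + clade stem)
  nTip <- ape::Ntip(p5@tree)
  fgTips <- p5@tree$edge[p5@foregroundEdges, 2]
  fgTipLabels <- p5@tree$tip.label[fgTips[fgTips <= nTip]]
  expect_setequal(fgTipLabels, c("Gg_W", "Ap_W"))
  expect_equal(length(p5@foregroundEdges), 3L)  # two tips + the stem
  # Z foreground flips the labelling
  z5 <- buildBranchTree("shared", taxa = c("Gg", "Ap", "Tg"),
                        foreground = "Z")
  zTips <- z5@tree$edge[z5@foregroundEdges, 2]
  expect_setequal(z5@tree$tip.label[zTips[zTips <= nTip]],
                  c("Gg_Z", "Ap_Z"))
  # errors
  expect_error(buildBranchTree("shared", taxa = c("Gg", "Ap")), "outgroup")
  expect_error(buildBranchTree("shared", taxa = c("Gg", "Xx", "Tg")),
               "unknown taxa")
})

test_that("the tree likelihood agrees with the pairwise engine on two taxa", {
  sim <- cachedSim("ml8", function() simulateGametologHistory(
    simulationConfig(
      nLoci = 8, cdsLength = 900,
      suppressionTimes = data.frame(locus = sprintf("L%03d", 1:8),
                                    lineage = "GgMg", time = 55e6),
      omegaW = 1, omegaZ = 1, kappa = 1, seed = 17)))
  aln <- pairAln(sim, "L002", "Gg")
  ml <- mlPairwiseDivergence(aln)
  # evaluate the tree likelihood at the pairwise MLE (t split across the
  # two edges, same kappa, same omega in both branch classes)
  tree <- ape::reorder.phylo(ape::read.tree(text = "(Gg_Z,Gg_W);"),
                             "postorder")
  tpl <- new("LabeledTreeTemplate", tree = tree, case = "shared",
             foreground = "W",
             foregroundEdges = ZWstrata:::.chromEdges(tree, "W"))
  cp <- ZWstrata:::.codonPatterns(aln, tree)
  # align the frequency model: reuse the pairwise F3x4 vector
  pc <- ZWstrata:::.pairCodons(aln)
  cp$pi61 <- ZWstrata:::f3x4Frequencies(c(pc$codons[, 1], pc$codons[, 2]))
  nll <- ZWstrata:::.branchNll(tpl, cp, new.env(parent = emptyenv()))
  par <- c(log(ml@t / 2), log(ml@t / 2), log(ml@kappa), log(ml@omega),
           log(ml@omega))
  expect_lt(abs(-nll(par) - ml@lnL), 1e-4)
})

test_that("branch-model LRT separates purifying from neutral foregrounds", {
  nm <- c("Gg_Z", "Gg_W", "Ap_Z", "Ap_W", "Tg_Z")
  tpl <- buildBranchTree("shared", taxa = c("Gg", "Ap", "Tg"),
                         foreground = "W")
  mk <- function(omegaW, seed) {
    cfg <- simulationConfig(
      nLoci = 1, cdsLength = 900,
      suppressionTimes = data.frame(locus = "L001", lineage = "GgMgAp",
                                    time = 100e6),
      omegaW = omegaW, omegaZ = 0.3, seed = seed)
    tipsAln(simulateGametologHistory(cfg), "L001", nm)
  }
  purifying <- branchModelLrt(mk(0.1, 81), tpl, nulls = c("fix1", "fix0"))
  expect_lt(purifying@lrt$p[purifying@lrt$comparison == "free-vs-fix1"],
            0.01)
  expect_lt(abs(purifying@omega[["foreground"]] - 0.1), 0.15)
  # nesting: the free model dominates both nulls
  expect_gte(purifying@lnL[["free"]], purifying@lnL[["fix1"]] - 1e-6)
  expect_gte(purifying@lnL[["free"]], purifying@lnL[["fix0"]] - 1e-6)
  expect_true(all(purifying@lrt$statistic >= 0))

  neutral <- branchModelLrt(mk(1, 82), tpl, nulls = "fix1")
  expect_gt(neutral@lrt$p[1], 0.05)
  expect_lt(abs(neutral@omega[["foreground"]] - 1), 0.6)
})

test_that("the branch-site test detects strong episodic positive selection and not its absence", {
  nm <- c("Gg_Z", "Gg_W", "Ap_Z", "Ap_W", "Tg_Z")
  tpl <- buildBranchTree("shared", taxa = c("Gg", "Ap", "Tg"),
                         foreground = "W")
  mk <- function(omegaW, seed) {
    cfg <- simulationConfig(
      nLoci = 1, cdsLength = 900,
      suppressionTimes = data.frame(locus = "L001", lineage = "GgMgAp",
                                    time = 100e6),
      omegaW = omegaW, omegaZ = 0.3, seed = seed)
    tipsAln(simulateGametologHistory(cfg), "L001", nm)
  }
  posVec <- c(rep(0.2, 210), rep(8, 90))     # 30% of sites at omega2 = 8
  hits <- vapply(1:4, function(k)
    branchSiteTest(mk(posVec, 200 + k), tpl)@lrt$p < 0.05, logical(1))
  expect_gte(mean(hits), 0.7)
  nullRes <- branchSiteTest(mk(0.2, 210), tpl)
  expect_gt(nullRes@lrt$p[1], 0.05)
  expect_gte(nullRes@lnL[["alternative"]], nullRes@lnL[["null"]] - 1e-6)
  # mixture p is half the chi-squared p (or 1 at the boundary)
  expect_true(nullRes@lrt$p_mixture == 1 ||
                abs(nullRes@lrt$p_mixture - nullRes@lrt$p / 2) < 1e-12)
  # site-class proportions form a distribution
  expect_equal(sum(nullRes@siteClasses$proportion), 1, tolerance = 1e-6)
})
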