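test_that("configuration validity rejects impossible histories", {
  # suppression older than the lineage's origin
  expect_error(uniformConfig(1, "Gg", 50e6), "predates")
  # zero-length CDS
  expect_error(simulationConfig(nLoci = 1, cdsLength = 0L), "positive")
  # frame violation
  expect_error(simulationConfig(nLoci = 1, cdsLength = 100L), "multiple of 3")
  # suppression beyond the root
  expect_error(uniformConfig(1, "GgMgAp", 140e6), "root|branch")
  # negative rates
  expect_error(simulationConfig(nLoci = 1, muZ = -1e-9), "rates")
})

test_that("identical seed and config reproduce the dataset byte-for-byte", {
  cfg <- uniformConfig(3, "GgMg", 60e6, cdsLength = 300, seed = 42)
  s1 <- simulateGametologHistory(cfg)
  s2 <- simulateGametologHistory(cfg)
  for (l in names(s1@sequences))
    expect_identical(as.character(s1@sequences[[l]]),
                     as.character(s2@sequences[[l]]))
  expect_identical(s1@truth, s2@truth)
  expect_identical(s1@snps, s2@snps)
  # a different seed gives different sequences
  s3 <- simulateGametologHistory(uniformConfig(3, "GgMg", 60e6,
                                               cdsLength = 300, seed = 43))
  expect_false(identical(as.character(s1@sequences[[1]]),
                         as.character(s3@sequences[[1]])))
})

test_that("zero suppression time leaves Z and W identical; tips and truth are complete", {
  sim <- simulateGametologHistory(uniformConfig(2, "Gg", 0, cdsLength = 300,
                                                seed = 3))
  for (l in names(sim@sequences)) {
    s <- sim@sequences[[l]]
    expect_identical(as.character(s[["Gg_Z"]]), as.character(s[["Gg_W"]]))
    expect_true("Tg_Z" %in% names(s))
  }
  expect_true(all(names(sim@sequences) %in% sim@truth$locus))
  expect_equal(unique(sim@truth$class), "independent")
  sh <- simulateGametologHistory(uniformConfig(1, "GgMgAp", 100e6,
                                               cdsLength = 300, seed = 3))
  expect_equal(unique(sh@truth$class), "shared")
  # shared suppression gives W tips to all three ingroup taxa
  expect_true(all(c("Gg_W", "Mg_W", "Ap_W") %in%
                    names(sh@sequences[[1]])))
})

test_that("realized Z-W synonymous divergence follows the clock expectation", {
  # regression of NG86 dS on suppression time across three time points;
  # kappa = 1, omega = 1 keeps the counting estimator unbiased
  times <- rep(c(20e6, 50e6, 80e6), each = 8)
  lins <- rep(c("Gg", "GgMg", "GgMg"), each = 8)
  cfg <- simulationConfig(
    nLoci = 24, cdsLength = 900,
    suppressionTimes = data.frame(locus = sprintf("L%03d", 1:24),
                                  lineage = lins, time = times),
    omegaW = 1, omegaZ = 1, kappa = 1, seed = 13)
  sim <- cachedSim("clock24", function() simulateGametologHistory(cfg))
  ds <- vapply(names(sim@sequences), function(l)
    ng86Divergence(pairAln(sim, l, "Gg"))@dS, numeric(1))
  fit <- stats::lm(ds ~ times)
  slope <- unname(stats::coef(fit)[2])
  expected <- cfg@muZ + cfg@muW            # 3.8e-9 per site per year
  expect_lt(abs(slope - expected) / expected, 0.10)
  # dS is monotone non-decreasing in time, in expectation
  m <- tapply(ds, times, mean)
  expect_true(all(diff(m) > 0))
})

test_that("conversion-tract injection has exact copy semantics", {
  sim <- cachedSim("inject", function()
    simulateGametologHistory(uniformConfig(1, "GgMgAp", 100e6,
                                           cdsLength = 600, seed = 8)))
  s0 <- sim@sequences[[1]]
  # whole-CDS tract: recipient == donor everywhere
  whole <- injectGeneConversion(sim, "L001", "Gg_W", "Gg_Z", 0, 600)
  expect_identical(as.character(whole@sequences[[1]][["Gg_Z"]]),
                   as.character(whole@sequences[[1]][["Gg_W"]]))
  # 150 bp tract: identity 100% inside, outside untouched
  tr <- injectGeneConversion(sim, "L001", "Ap_W", "Ap_Z", 150, 300)
  z0 <- strsplit(as.character(s0[["Ap_Z"]]), "")[[1]]
  z1 <- strsplit(as.character(tr@sequences[[1]][["Ap_Z"]]), "")[[1]]
  w <- strsplit(as.character(s0[["Ap_W"]]), "")[[1]]
  expect_identical(z1[151:300], w[151:300])
  expect_identical(z1[-(151:300)], z0[-(151:300)])
  expect_equal(nrow(tr@tracts), 1L)
  # overlapping contradictory tract (different donor) is rejected
  expect_error(injectGeneConversion(tr, "L001", "Gg_W", "Ap_Z", 200, 350),
               "contradictory")
  # coordinates outside the CDS are rejected
  expect_error(injectGeneConversion(sim, "L001", "Ap_W", "Ap_Z", 500, 700),
               "coordinates")
})

test_that("sexed expression has female-limited W genes and balanced autosomes", {
  sim <- cachedSim("expr", function()
    simulateGametologHistory(uniformConfig(6, "GgMgAp", 95e6,
                                           cdsLength = 300, seed = 5)))
  se <- simulateExpression(sim, nMales = 5, nFemales = 5, nAutosomal = 60,
                           seed = 2)
  mat <- SummarizedExperiment::assay(se)
  sex <- SummarizedExperiment::colData(se)$sex
  cls <- SummarizedExperiment::rowData(se)$class
  male <- mat[, sex == "M", drop = FALSE]
  fem <- mat[, sex == "F", drop = FALSE]
  # W genes: zero expectation in males (leakage below the rounding threshold)
  expect_true(all(round(male[cls == "W", ], 2) == 0))
  expect_true(all(rowMeans(fem[cls == "W", ]) > 0))
  # autosomal genes: male/female ratio about 1 over many genes
  ratio <- rowMeans(male[cls == "autosome", ]) /
    rowMeans(fem[cls == "autosome", ])
  expect_lt(abs(mean(log(ratio))), 0.15)
  # configuration errors
  expect_error(simulateExpression(sim, nMales = 0), "nMales")
})
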