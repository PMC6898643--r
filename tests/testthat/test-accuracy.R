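# Accuracy metrics, threshold sweeps, pooling, summary ROC, chi-square.

test_that("accuracy metrics follow their defining formulas", {
  m <- accuracyMetrics(ConfusionCounts(90, 30, 10))
  expect_equal(unname(m), c(0.9, 0.25, 2.25))
  p <- accuracyMetrics(ConfusionCounts(50, 0, 0))
  expect_equal(unname(p[1:2]), c(1, 0))
  expect_identical(unname(p[3]), Inf)
  z <- accuracyMetrics(ConfusionCounts(0, 5, 5))
  expect_equal(unname(z), c(0, 1, 0))
  expect_error(accuracyMetrics(ConfusionCounts(0, 5, 0)), "empty reference")
})

test_that("the ADR is determined by the two rates alone", {
  # cells printed in the published per-ablation table
  expect_equal(round(adrFromRates(0.97, 0.57), 2), 0.74)
  expect_equal(round(adrFromRates(1.00, 0.80), 2), 0.25)
  expect_equal(adrFromRates(1.00, 0.50), 1.00)
  expect_equal(adrFromRates(0, 0.3), 0)
  expect_equal(adrFromRates(0.9, 1), 0)
  # identity against raw counts
  set.seed(5)
  for (k in 1:50) {
    tp <- sample(1:500, 1); fp <- sample(1:500, 1); fn <- sample(1:500, 1)
    m <- accuracyMetrics(ConfusionCounts(tp, fp, fn))
    expect_equal(adrFromRates(m[["tpr"]], m[["fdr"]]), tp / (fp + fn),
                 tolerance = 1e-12)
  }
})

test_that("threshold sweeps match an exhaustive per-threshold oracle", {
  # 3-level 8x8 toy image with a seeded core
  v <- matrix(9, 8, 8)
  v[3:6, 3:6] <- 3
  v[4:5, 4:5] <- 1
  img <- ImageGrid(v, 1, "HBV")
  ref <- matrix(0L, 8, 8); ref[3:6, 3:6] <- 1L
  sw <- thresholdSweep(img, ref, seedXY = c(4, 4), connectivity = 8,
                       ablationId = "toy")
  tb <- sweepTable(sw)
  expect_equal(tb$threshold, 1:9)
  for (i in seq_len(nrow(tb))) {
    w <- (v >= 0 & v <= tb$threshold[i]) * 1L
    grown <- bfs_flood_oracle(w, c(4, 4), 8)
    o <- overlay_oracle(grown, ref)
    expect_equal(c(tb$tp[i], tb$fp[i], tb$fn[i]), unname(o))
  }
  expect_true(all(diff(tb$tp) >= 0))            # nesting
  expect_true(all(diff(tb$tpr) >= 0))
})

test_that("optimal thresholds maximize ADR with smallest-threshold ties", {
  case <- generatePhantom(tiny_spec(31))         # noiseless two-level
  img <- case@images$CECT
  seed <- defaultSeed(img, case@truth$imageMarkerXY)
  al <- maskValues(case@reference)
  sw <- thresholdSweep(img, al, seed, 8, "a")
  o <- optimalThreshold(sw)
  expect_equal(o$threshold, 120)                 # first fully separable cutoff
  expect_equal(o$tpr, sum(sweepTable(sw)$tp[120]) /
                 (sweepTable(sw)$tp[120] + sweepTable(sw)$fn[120]))
  # exhaustive argmax oracle on a noisy sweep
  case2 <- generatePhantom(tiny_spec(32, noiseSd = c(CECT = 30)))
  img2 <- case2@images$CECT
  sw2 <- thresholdSweep(img2, align_case(case2),
                        defaultSeed(img2, case2@truth$imageMarkerXY), 8, "b")
  tb2 <- sweepTable(sw2)
  o2 <- optimalThreshold(sw2)
  best <- max(tb2$adr)
  expect_equal(o2$threshold, min(tb2$threshold[tb2$adr == best]))
  # all-empty sweep -> flagged no-optimum (the integer grid stops at
  # floor(max), so a flat 500.5 image is never inside any window)
  flat <- ImageGrid(matrix(500.5, 8, 8), 1, "CECT")
  swf <- thresholdSweep(flat, ref <- {r <- matrix(0L, 8, 8); r[4, 4] <- 1L; r},
                        c(4, 4), 8, "c")
  expect_false(optimalThreshold(swf)$found)
})

test_that("pooled cutoffs reduce correctly and pool both ways", {
  cases <- lapply(41:43, function(s) generatePhantom(tiny_spec(s)))
  sweeps <- lapply(seq_along(cases), function(i) {
    img <- cases[[i]]@images$CECT
    thresholdSweep(img, maskValues(cases[[i]]@reference),
                   defaultSeed(img, cases[[i]]@truth$imageMarkerXY), 8,
                   paste0("a", i))
  })
  pc <- pooledCutoff(sweeps)
  expect_gt(pc$threshold, 119)                   # inside the separable band
  expect_lt(pc$threshold, 281)
  # noiseless recovery is perfect except the sentinel-excluded marker disk
  # (~1 mm^2 / pi*16 mm^2, i.e. up to ~9% on these small-core phantoms)
  expect_gte(unname(pc$macro["tpr"]), 0.90)
  expect_equal(unname(pc$macro["fdr"]), 0)
  expect_equal(unname(pc$macro["tpr"]),
               mean(pc$perAblation$tpr))         # macro = unweighted mean
  expect_equal(unname(pc$macro["fdr"]), mean(pc$perAblation$fdr))
  # single sweep reduces to the per-ablation optimum
  single <- pooledCutoff(sweeps[1])
  expect_equal(single$threshold, optimalThreshold(sweeps[[1]])$threshold)
  # identical per-ablation metrics: macro equals micro
  same <- data.frame(tpr = rep(0.8, 3), fdr = rep(0.2, 3),
                     adr = rep(2, 3))
  cnts <- replicate(3, ConfusionCounts(80, 20, 20), simplify = FALSE)
  expect_equal(poolMetrics(same, "macro")[c("tpr", "fdr")],
               poolMetrics(same, "micro", counts = cnts)[c("tpr", "fdr")])
})

test_that("macro pooling the printed per-ablation rates reproduces the pooled row", {
  tab <- studyAccuracyTable()
  cect <- tab[tab$modality == "CECT", ]
  pooled <- poolMetrics(data.frame(tpr = cect$tpr_pct / 100,
                                   fdr = cect$fdr_pct / 100,
                                   adr = cect$adr), "macro")
  expect_equal(round(100 * pooled[["tpr"]]), 81)
  expect_equal(round(100 * pooled[["fdr"]]), 52)
  expect_equal(round(pooled[["adr"]], 2), 0.66)
})

test_that("summary ROC is near-perfect for separable cohorts and collapses for shuffled references", {
  cases <- lapply(51:53, function(s)
    generatePhantom(tiny_spec(s, noiseSd = c(CECT = 25))))
  sweeps <- lapply(seq_along(cases), function(i) {
    img <- cases[[i]]@images$CECT
    thresholdSweep(img, align_case(cases[[i]]),
                   defaultSeed(img, cases[[i]]@truth$imageMarkerXY), 8,
                   paste0("a", i))
  })
  sr <- summaryROC(sweeps)
  expect_gt(sr@auc, 0.90)       # marker disk caps TPR on small-core phantoms
  expect_true(all(diff(sr@meanTpr) >= 0))
  # permutation invariance
  sr2 <- summaryROC(rev(sweeps))
  expect_equal(sr2@auc, sr@auc)

  # reference-independent predictor: necrosis mask pixels shuffled in place
  aucs <- vapply(1:4, function(s) {
    css <- lapply(1:3, function(i)
      generatePhantom(tiny_spec(60 + 10 * s + i, noiseSd = c(CECT = 25))))
    sws <- lapply(css, function(cs) {
      img <- cs@images$CECT
      ref <- maskValues(cs@reference)
      shuf <- matrix(0L, nrow(ref), ncol(ref))
      shuf[withr::with_seed(s, sample(length(ref), sum(ref)))] <- 1L
      thresholdSweep(img, shuf, defaultSeed(img, cs@truth$imageMarkerXY),
                     8, "x")
    })
    summaryROC(sws)@auc
  }, 0)
  # in (FDR, TPR) space a reference-independent predictor cannot reach low
  # FDR except by tiny lucky regions, so its AUC sits far below both the
  # separable value and the classical 0.5 diagonal of specificity-based ROC
  expect_gt(mean(aucs), 0.02)
  expect_lt(mean(aucs), 0.40)
  expect_lt(mean(aucs), sr@auc - 0.3)
})

test_that("chi-squared accuracy comparison is Pearson without correction", {
  same <- ConfusionCounts(90, 5, 5)
  r <- compareAccuracy(same, same)
  expect_equal(unname(r["statistic"]), 0)
  expect_equal(unname(r["p.value"]), 1)
  r2 <- compareAccuracy(ConfusionCounts(90, 4, 6), ConfusionCounts(50, 20, 30))
  expect_equal(unname(r2["statistic"]), 38.095, tolerance = 0.001)
  expect_error(compareAccuracy(ConfusionCounts(0, 0, 0),
                               ConfusionCounts(1, 1, 0)), "zero margin")
})

test_that("the chi-squared comparison holds its type-I error on equal-contrast phantoms", {
  reject <- 0
  nsim <- 200
  for (s in seq_len(nsim)) {
    spec <- tiny_spec(7000 + s,
                      zones = list(CECT = c(120, 280, 320),
                                   AF = c(30, 118, 140)),
                      noiseSd = c(CECT = 40, AF = 22))  # equal in gap units
    cs <- generatePhantom(spec)
    # exclude the deterministic marker-disk false negatives: shared between
    # the modalities, they damp the multinomial variation the test assumes
    marker <- gridValues(cs@images$CECT) == necromap:::.MARKER_SENTINEL
    ref <- maskValues(cs@reference)
    ref[marker] <- 0L
    counts <- lapply(c(CECT = 200, AF = 74), function(thr) {
      m <- if (thr == 200) "CECT" else "AF"
      img <- cs@images[[m]]
      iso <- isolateAblation(img, thr, defaultSeed(img, cs@truth$imageMarkerXY), 8)
      overlayCount(iso$mask, ref)
    })
    p <- compareAccuracy(counts[[1]], counts[[2]])["p.value"]
    if (p < 0.05) reject <- reject + 1
  }
  # binomial(200, 0.05): 3-sigma band around the nominal rate
  expect_gte(reject / nsim, 0.003)
  expect_lte(reject / nsim, 0.12)
})
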