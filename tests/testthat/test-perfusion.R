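# Dual-input box-IRF perfusion model: forward simulation and estimation.

test_that("the box residue function has unit plateau and area MTT", {
  g <- defaultTimeGrid()
  expect_equal(boxIRF(6, g)[1:4], c(1, 1, 0, 0))
  expect_equal(sum(boxIRF(38, g)), 13)          # samples 0..36 inside
  fine <- seq(0, 120, by = 0.01)
  expect_equal(pracma::trapz(fine, boxIRF(17.3, fine)), 17.3,
               tolerance = 0.01)
  expect_error(boxIRF(0, g), "mttS")
})

test_that("tissue simulation is causal, linear, and boxes an impulse input", {
  g <- defaultTimeGrid()
  dt <- g[2] - g[1]
  zero <- TACurve(g, numeric(40), "arterial_input")
  expect_equal(simulateTissueTAC(PerfusionParams(0, 0, 20), zero, zero)@values,
               numeric(40))

  # impulse arterial input (one sample of height V at t = 3): flow-scaled
  # box of height (AF/6000) * V * dt lasting MTT; oracle = direct Riemann sum
  V <- 100; af <- 60; mtt <- 12
  ca <- TACurve(g, c(0, V, rep(0, 38)), "arterial_input")
  sim <- simulateTissueTAC(PerfusionParams(af, 0, mtt), ca, zero)
  oracle <- vapply(seq_along(g), function(i) {
    acc <- 0
    for (j in seq_along(g)) {
      lag <- g[i] - g[j]
      if (lag >= 0 && lag < mtt) acc <- acc + ca@values[j]
    }
    (af / 6000) * dt * acc
  }, 0)
  expect_equal(sim@values, oracle, tolerance = 1e-12)
  expect_equal(max(sim@values), (af / 6000) * V * dt)
  expect_equal(sim@values[1], 0)                 # causal

  inp <- inputFunctions()
  one <- simulateTissueTAC(PerfusionParams(40, 50, 25), inp$ca, inp$cp)
  two <- simulateTissueTAC(PerfusionParams(80, 100, 25), inp$ca, inp$cp)
  expect_equal(two@values, 2 * one@values, tolerance = 1e-12)
  expect_error(simulateTissueTAC(PerfusionParams(1, 1, 5), inp$ca,
                                 TACurve(seq(0, 78, 2), numeric(40),
                                         "portal_input")),
               "grid")
})

test_that("the published cutoff parameters are recovered from their own curve", {
  inp <- inputFunctions()
  truth <- PerfusionParams(AF = 74, PF = 75, MTT = 38)
  fit <- estimatePerfusion(simulateTissueTAC(truth, inp$ca, inp$cp),
                           inp$ca, inp$cp)
  expect_lt(abs(fit@AF - 74) / 74, 0.05)
  expect_lt(abs(fit@PF - 75) / 75, 0.05)
  expect_lt(abs(fit@MTT - 38) / 38, 0.05)
  expect_equal(totalFlow(fit), fit@AF + fit@PF)
  expect_lt(abs(bloodVolume(fit) - totalFlow(fit) * fit@MTT / 60),
            1e-6 * max(1, bloodVolume(fit)))
})

test_that("degenerate inputs are handled: zero curve and the central volume identity", {
  inp <- inputFunctions()
  g <- defaultTimeGrid()
  z <- estimatePerfusion(TACurve(g, numeric(40), "tissue"), inp$ca, inp$cp)
  expect_equal(c(z@AF, z@PF, totalFlow(z)), c(0, 0, 0))
  expect_equal(bloodVolume(z), 0)
  expect_equal(bloodVolume(PerfusionParams(50, 50, 18)), 30)  # 100*18/60
  expect_error(estimatePerfusion(TACurve(g, c(0, NA, rep(0, 38)), "tissue"),
                                 inp$ca, inp$cp), "non-finite")
})

test_that("random draws round-trip noiselessly and degrade monotonically with noise", {
  inp <- inputFunctions()
  draw_errors <- function(n, noise_frac, seed) {
    withr::with_seed(seed, {
      errs <- matrix(NA_real_, n, 3)
      for (k in seq_len(n)) {
        p <- PerfusionParams(runif(1, 20, 120), runif(1, 20, 150),
                             runif(1, 8, 45), runif(1, 0, 6), runif(1, 0, 6))
        y <- simulateTissueTAC(p, inp$ca, inp$cp)
        if (noise_frac > 0)
          y <- TACurve(y@times,
                       c(0, y@values[-1] +
                           rnorm(39, 0, noise_frac * max(y@values))),
                       "tissue")
        f <- estimatePerfusion(y, inp$ca, inp$cp)
        errs[k, ] <- abs(c(f@AF - p@AF, f@PF - p@PF, f@MTT - p@MTT)) /
          c(p@AF, p@PF, p@MTT)
      }
      errs
    })
  }
  e0 <- draw_errors(100, 0, 900)
  med0 <- apply(e0, 2, stats::median)
  expect_true(all(med0 <= 0.05))
  e5 <- draw_errors(40, 0.05, 901)
  med5 <- apply(e5, 2, stats::median)
  expect_true(all(med5 <= 0.15))
  e15 <- draw_errors(40, 0.15, 902)
  med15 <- apply(e15, 2, stats::median)
  expect_true(all(med0 <= med5 + 1e-9))
  expect_true(all(med5 <= med15 + 1e-9))
})

test_that("parameter maps recover two-zone fields and flag no-data pixels", {
  inp <- inputFunctions()
  core <- PerfusionParams(25, 30, 30)
  bg <- PerfusionParams(70, 80, 14)
  field <- array(0, dim = c(6, 6, 40))
  isCore <- matrix(FALSE, 6, 6); isCore[3:4, 3:4] <- TRUE
  isNoData <- matrix(FALSE, 6, 6); isNoData[1, 1] <- TRUE
  yc <- simulateTissueTAC(core, inp$ca, inp$cp)@values
  yb <- simulateTissueTAC(bg, inp$ca, inp$cp)@values
  for (i in 1:6) for (j in 1:6) {
    field[i, j, ] <- if (isNoData[i, j]) 0 else if (isCore[i, j]) yc else yb
  }
  maps <- makeParameterMaps(field, inp$ca, inp$cp, spacingMm = 0.5)
  expect_named(maps, c("AF", "PF", "TF", "HBV", "MTT"))
  expect_equal(sum(is.na(gridValues(maps$AF))), sum(isNoData))
  for (m in names(maps)) expect_equal(sum(is.na(gridValues(maps[[m]]))), 1)
  truthVals <- list(AF = c(25, 70), PF = c(30, 80), TF = c(55, 150),
                    HBV = c(55 * 30 / 60, 150 * 14 / 60), MTT = c(30, 14))
  for (m in names(maps)) {
    v <- gridValues(maps[[m]])
    expect_equal(mean(v[isCore]), truthVals[[m]][1],
                 tolerance = 0.05 * truthVals[[m]][1])
    expect_equal(mean(v[!isCore & !isNoData]), truthVals[[m]][2],
                 tolerance = 0.05 * truthVals[[m]][2])
  }
  # a uniform field produces spatially constant maps
  uf <- array(rep(yb, each = 4), dim = c(2, 2, 40))
  um <- makeParameterMaps(uf, inp$ca, inp$cp)
  expect_equal(max(gridValues(um$AF)) - min(gridValues(um$AF)), 0,
               tolerance = 1e-6)
})
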