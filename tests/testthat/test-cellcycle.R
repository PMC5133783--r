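test_that("phase gating recovers composition and rejects bad input", {
  # pure G1 sample: essentially everything in the G0/1 gate
  s <- gen_dna_histogram(1, 0, 0, cv = 0.04, n_events = 3000, seed = 1)
  pf <- phase_fractions(s)
  expect_gte(pf$fractions[["g01"]], 0.95)

  # generator -> gater round trip at 10^4 events
  s2 <- gen_dna_histogram(0.5, 0.2, 0.3, cv = 0.04, n_events = 10000,
                          seed = 2)
  f <- phase_fractions(s2)$fractions
  expect_lt(abs(f[["g01"]] - 0.5), 0.02)
  expect_lt(abs(f[["s"]] - 0.2), 0.02)
  expect_lt(abs(f[["g2m"]] - 0.3), 0.02)
  expect_lte(sum(f), 1 + 1e-9)

  # gates must not intersect
  pf2 <- phase_fractions(s2)
  expect_lt(pf2$gates["g01", 2], pf2$gates["g2m", 1])
  expect_error(phase_fractions(s2, cv = 0.2), "intersect")
  expect_error(phase_fractions(s2$values[1:100]), "500")
})

test_that("colcemid depletion fit recovers the arrested plateau", {
  ser <- gen_colcemid_series(f0 = 0.5, residual = 0.16, tau = 24,
                             n_events = 4000, seed = 4)
  fit <- colcemid_depletion(ser$samples, ser$times)
  expect_lt(abs(fit$residual_fraction - 0.16), 0.03)

  # fully cycling population: plateau estimate near zero
  ser0 <- gen_colcemid_series(f0 = 0.5, residual = 0, tau = 20,
                              n_events = 4000, seed = 5)
  fit0 <- colcemid_depletion(ser0$samples, ser0$times)
  expect_lte(fit0$residual_fraction, 0.03)

  # constant series: degenerate tau -> Inf branch, plateau = f0
  serc <- lapply(1:4, function(i)
    gen_dna_histogram(0.5, 0.2, 0.3, n_events = 3000, seed = 6))
  fitc <- colcemid_depletion(serc, c(0, 24, 48, 72))
  expect_identical(fitc$tau, Inf)
  expect_equal(fitc$residual_fraction, fitc$f0)
})

test_that("division statistics report fold change and t-test", {
  tr <- gen_division_tracks(24, 1.37, cv = 0.15, n_cells = 50,
                            n_generations = 1, seed = 7)
  st <- division_stats(tr[[1]], tr[[2]])
  expect_lt(abs(st$fold_change - 1.37) / 1.37, 0.05)
  expect_lt(st$test$p, 0.01)

  # identical tracks: fold 1, p 1
  st0 <- division_stats(tr[[1]], tr[[1]])
  expect_equal(st0$fold_change, 1)
  expect_equal(st0$test$p, 1)

  # B = A scaled x2: fold exactly 2, and fold is unit invariant
  b <- tr[[1]]; b$interval_h <- b$interval_h * 2
  expect_equal(division_stats(tr[[1]], b)$fold_change, 2)
  a_min <- tr[[1]]; a_min$interval_h <- a_min$interval_h * 60
  b_min <- tr[[2]]; b_min$interval_h <- b_min$interval_h * 60
  expect_equal(division_stats(a_min, b_min)$fold_change, st$fold_change)
})

test_that("generation alignment anchors lineages on a common event", {
  tr <- data.frame(
    lineage = rep(1:2, each = 3),
    generation = c(1:3, 1:3),
    interval_h = rep(10, 6))
  tr$division_time_h <- stats::ave(tr$interval_h, tr$lineage, FUN = cumsum)
  # lineage 2 started one generation later
  tr$division_time_h[tr$lineage == 2] <-
    tr$division_time_h[tr$lineage == 2] + 10

  # no anchor time: identity re-indexing
  id <- align_generations(tr)
  expect_identical(id$aligned_generation, id$generation)

  # anchor at t = 25 h: lineage 1 is in generation 3, lineage 2 in 2
  al <- align_generations(tr, anchor_generation = 3L, anchor_time = 25)
  g1 <- al[al$lineage == 1, ]; g2 <- al[al$lineage == 2, ]
  expect_identical(g1$aligned_generation[g1$generation == 3], 3L)
  expect_identical(g2$aligned_generation[g2$generation == 2], 3L)
  # the anchored generations span the anchor time in both lineages
  for (d in list(g1, g2)) {
    row <- d[d$aligned_generation == 3, ]
    expect_true(row$division_time_h - row$interval_h <= 25 &&
                  25 < row$division_time_h)
  }

  # gaps are preserved, not imputed
  gap <- tr[tr$generation != 2, ]
  expect_identical(nrow(align_generations(gap)), nrow(gap))
})
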