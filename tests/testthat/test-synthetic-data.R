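test_that("foci phantom is deterministic and respects geometry invariants", {
  p <- coarse_phantom(seed = 1, n_nuclei = 2L, n_gh2ax = 6L,
                      stack_shape = c(20L, 100L, 200L))
  a <- gen_foci_stack(p)
  b <- gen_foci_stack(p)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth, b$truth)

  # every focus centre lies strictly inside its nucleus ellipsoid
  tr <- a$truth
  for (i in seq_len(nrow(tr$foci))) {
    f <- tr$foci[i, ]
    nuc <- tr$nuclei[tr$nuclei$label == f$nucleus, ]
    e <- ((f$cz_um - nuc$cz_um) / nuc$rz_um)^2 +
      ((f$cy_um - nuc$cy_um) / nuc$ry_um)^2 +
      ((f$cx_um - nuc$cx_um) / nuc$rx_um)^2
    expect_lt(e, 1)
  }
  # counts match list lengths and overlap bound
  expect_equal(tr$counts$n_gh2ax,
               as.integer(table(factor(tr$foci$nucleus[tr$foci$channel == "gh2ax"],
                                       levels = tr$counts$nucleus))))
  expect_true(all(tr$counts$n_overlap <=
                    pmin(tr$counts$n_gh2ax, tr$counts$n_smc6)))
})

test_that("colocalization flags are Bernoulli(coloc_prob)", {
  # coloc_prob = 0 with no extra SMC6: zero overlap everywhere
  p0 <- coarse_phantom(seed = 2, coloc_prob = 0, extra_smc6 = 0L)
  t0 <- gen_foci_stack(p0, render = FALSE)$truth
  expect_true(all(t0$counts$n_overlap == 0))
  expect_true(all(t0$counts$n_smc6 == 0))

  # over many foci the overlap fraction converges to coloc_prob; the
  # binomial test is the exact oracle for the flag-generating process
  p <- foci_phantom_params(
    stack_shape = c(20L, 430L, 430L), voxel_size_nm = c(300, 150, 150),
    n_nuclei = 36L, nucleus_radii_um = c(1.8, 3, 3), n_gh2ax = 30L,
    coloc_prob = 0.5, extra_smc6 = 0L, focus_sigma_um = 0.2,
    min_separation_um = 0.4, seed = 3)
  tr <- gen_foci_stack(p, render = FALSE)$truth
  n_total <- sum(tr$counts$n_gh2ax)
  n_coloc <- sum(tr$counts$n_overlap)
  expect_gte(n_total, 1000)
  expect_gt(stats::binom.test(n_coloc, n_total, 0.5)$p.value, 0.01)
})

test_that("phantom generation fails cleanly when nuclei cannot fit", {
  expect_error(gen_foci_stack(coarse_phantom(1, n_nuclei = 50L)),
               "too small")
  expect_error(gen_foci_stack(
    foci_phantom_params(stack_shape = c(4L, 100L, 100L),
                        voxel_size_nm = c(300, 150, 150),
                        nucleus_radii_um = c(1.8, 3, 3))),
    "axial")
})

test_that("colony counts follow the binomial dose-response law", {
  # alpha = beta = 0: survival term is 1, counts are Binomial(n, pe)
  tab <- gen_colony_counts(pe = 1, alpha = 0, beta = 0, doses = 0,
                           n_plated = 100, replicates = 5,
                           densities = 1, seed = 1)
  expect_true(all(tab$colonies == 100))

  # mean over many replicates matches n * pe at dose 0 within 3 SE
  tab <- gen_colony_counts(pe = 0.75, alpha = 0.3, beta = 0.02,
                           doses = c(0, 2), n_plated = 200,
                           replicates = 1000, densities = 1, seed = 2)
  d0 <- tab$colonies[tab$dose == 0]
  se <- sqrt(200 * 0.75 * 0.25 / 1000)
  expect_lt(abs(mean(d0) - 150), 3 * se)
  # and the dose-2 mean matches n * pe * exp(-2 alpha - 4 beta)
  d2 <- tab$colonies[tab$dose == 2]
  mu2 <- 200 * 0.75 * exp(-0.6 - 0.08)
  se2 <- sqrt(mu2 * (1 - mu2 / 200) / 1000)
  expect_lt(abs(mean(d2) - mu2), 3 * se2)
})

test_that("DNA histogram generator hits requested composition", {
  s <- gen_dna_histogram(1, 0, 0, cv = 0.04, n_events = 2000, seed = 1)
  # pure G1: a single peak at mu
  expect_lt(abs(mean(s$values) - s$mu) / s$mu, 0.01)
  expect_lt(sd(s$values) / mean(s$values), 0.06)

  s2 <- gen_dna_histogram(0.5, 0.2, 0.3, n_events = 1000, seed = 9)
  s3 <- gen_dna_histogram(0.5, 0.2, 0.3, n_events = 1000, seed = 9)
  expect_identical(s2$values, s3$values)
  expect_equal(sum(s2$true_fractions), 1, tolerance = 1e-12)
})

test_that("division tracks have the requested mean structure", {
  # cv = 0: every interval equals its line mean exactly
  tr <- gen_division_tracks(20, 1.5, cv = 0, n_cells = 5,
                            n_generations = 3, seed = 1)
  expect_true(all(tr[[1]]$interval_h == 20))
  expect_true(all(tr[[2]]$interval_h == 30))
  # division times strictly increase within a lineage
  expect_true(all(tapply(tr[[1]]$division_time_h, tr[[1]]$lineage,
                         function(v) all(diff(v) > 0))))

  # LLN: sample-mean ratio approaches the fold
  tr <- gen_division_tracks(24, 1.37, cv = 0.15, n_cells = 50,
                            n_generations = 2, seed = 2)
  fold_hat <- mean(tr[[2]]$interval_h) / mean(tr[[1]]$interval_h)
  expect_lt(abs(fold_hat - 1.37) / 1.37, 0.05)
})
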