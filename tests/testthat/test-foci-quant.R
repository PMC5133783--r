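test_that("3D labelling agrees with the min-propagation oracle", {
  set.seed(11)
  for (i in 1:60) {
    d <- c(sample(2:8, 1), sample(4:16, 1), sample(4:16, 1))
    m <- array(runif(prod(d)) < runif(1, 0.2, 0.6), d)
    conn <- sample(c(6L, 18L, 26L), 1)
    got <- canonical_labels(label_components(m, conn))
    ref <- canonical_labels(label_oracle(m, conn))
    expect_identical(got, array(as.integer(ref), d))
  }
})

test_that("nucleus segmentation recovers ellipsoid geometry", {
  p <- coarse_phantom(seed = 21, n_nuclei = 3L, n_gh2ax = 1L,
                      stack_shape = c(20L, 100L, 300L))
  ph <- gen_foci_stack(p)
  m <- segment_nuclei(ph$stack)
  expect_s3_class(m, "nucleus_mask")
  expect_identical(m$n, 3L)
  v_analytic <- 4 / 3 * pi * prod(p$nucleus_radii_um) /
    voxel_volume(p$voxel_size_nm)
  expect_true(all(abs(m$table$voxels - v_analytic) / v_analytic < 0.05))

  # blank image: zero labels, warning not crash
  expect_warning(m0 <- segment_nuclei(array(0, c(4, 10, 10)),
                                      voxel_size_nm = c(300, 150, 150)),
                 "no nuclei")
  expect_identical(m0$n, 0L)

  # a nucleus clipped by the XY border is excluded
  dna <- array(0, c(10L, 40L, 40L))
  dna[3:8, 10:20, 10:20] <- 1   # interior box
  dna[3:8, 30:40, 30:40] <- 1   # touches the y/x = 40 border
  m1 <- segment_nuclei(dna, min_nucleus_voxels = 50, close_radius = 0,
                       voxel_size_nm = c(300, 150, 150))
  expect_identical(m1$n, 1L)
  expect_identical(unname(unlist(m1$table[1, c("y0", "x0")])), c(10L, 10L))
})

test_that("foci detection applies the inclusive minimal-size filter", {
  mask <- box_mask()
  ch <- array(0, mask$dim)
  ch[5, 10:16, 10:16] <- 1          # 49 voxels
  ch[5, 25:31, 25:31] <- 1; ch[6, 25, 25] <- 1   # 50 voxels
  f50 <- detect_foci(ch, mask, min_voxels = 50)
  expect_identical(nrow(f50$foci), 1L)
  expect_identical(f50$foci$volume_voxels, 50L)
  f49 <- detect_foci(ch, mask, min_voxels = 49)
  expect_identical(sort(f49$foci$volume_voxels), c(49L, 50L))
  # volume unit bookkeeping
  expect_equal(f49$foci$volume_um3,
               f49$foci$volume_voxels * voxel_volume(c(300, 150, 150)))
  # empty channel: zero foci, no error
  expect_identical(nrow(detect_foci(array(0, mask$dim), mask,
                                    min_voxels = 1)$foci), 0L)
})

test_that("raising thresholds is monotone in foci count and volume", {
  p <- coarse_phantom(seed = 31, n_nuclei = 2L, n_gh2ax = 8L,
                      snr = c(dna = 20, gh2ax = 10, smc6 = 12),
                      stack_shape = c(20L, 100L, 200L))
  ph <- gen_foci_stack(p)
  m <- segment_nuclei(ph$stack)
  counts <- vapply(c(1, 5, 20, 60, 200), function(mv)
    nrow(detect_foci(ph$stack, m, min_voxels = mv)$foci), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("overlap counting uses shared voxels within the same nucleus", {
  mask <- box_mask()
  gh <- array(0, mask$dim)
  gh[5:6, 8:10, 8:10] <- 1       # focus A
  gh[5:6, 20:22, 8:10] <- 1      # focus B
  sm <- array(0, mask$dim)
  sm[5, 8:22, 9] <- 1            # one elongated SMC6 focus spanning A and B
  fg <- detect_foci(gh, mask, min_voxels = 1)
  fs <- detect_foci(sm, mask, min_voxels = 1)
  ov <- count_overlaps(fg, fs)
  expect_identical(ov$per_nucleus$n_overlap, 2L)

  # spatially disjoint channels: all overlap counts zero
  sm2 <- array(0, mask$dim); sm2[9, 30:32, 30:32] <- 1
  ov0 <- count_overlaps(fg, detect_foci(sm2, mask, min_voxels = 1))
  expect_identical(ov0$per_nucleus$n_overlap, 0L)
})

test_that("per-cell records implement the selection and fraction rules", {
  mask <- box_mask()
  gh <- array(0, mask$dim); gh[5, 8:10, 8:10] <- 1
  sm <- array(0, mask$dim); sm[5, 8:10, 8:10] <- 1   # 1 SMC6 focus only
  rec <- per_cell_records(mask, detect_foci(gh, mask, 1),
                          detect_foci(sm, mask, 1))
  expect_false(rec$selected)     # needs >= 2 SMC6 foci
  expect_equal(rec$frac_smc6_positive, 1)

  # no gamma-H2AX foci: fraction undefined
  rec0 <- per_cell_records(mask, detect_foci(array(0, mask$dim), mask, 1),
                           detect_foci(sm, mask, 1))
  expect_identical(rec0$n_gh2ax, 0L)
  expect_true(is.na(rec0$frac_smc6_positive))
})

test_that("noiseless phantom quantification matches ground truth exactly", {
  mv <- coarse_min_voxels()
  p <- coarse_phantom(seed = 41, n_nuclei = 4L, n_gh2ax = 10L,
                      coloc_prob = 1, extra_smc6 = 2L)
  ph <- gen_foci_stack(p)
  q <- quantify_stack(ph$stack, min_voxels = mv)
  expect_equal(q$records$n_gh2ax, ph$truth$counts$n_gh2ax)
  expect_equal(q$records$n_smc6, ph$truth$counts$n_smc6)
  expect_equal(q$records$n_overlap, ph$truth$counts$n_overlap)
  # coloc_prob = 1, co-centred: every gamma-H2AX focus is SMC6-positive
  expect_true(all(q$records$n_overlap == q$records$n_gh2ax))
  # units invariant: volume ratio is the voxel volume for every focus
  expect_equal(q$gh2ax$foci$volume_um3,
               q$gh2ax$foci$volume_voxels * voxel_volume(p$voxel_size_nm))
})

test_that("condition summaries compute mean and SEM over cells", {
  rec <- data.frame(nucleus = 1:2, n_gh2ax = c(4L, 6L), n_smc6 = c(3L, 3L),
                    n_overlap = c(2L, 3L),
                    frac_smc6_positive = c(0.5, 0.5),
                    selected = c(TRUE, TRUE))
  s <- summarize_condition(rec)
  expect_equal(s$mean_gh2ax, 5)
  expect_equal(s$sem_gh2ax, 1)   # sd(c(4,6))/sqrt(2) = 1
  expect_equal(s$mean_frac_smc6_positive, 0.5)

  # single cell: SEM reported as missing
  s1 <- summarize_condition(rec[1, ])
  expect_true(is.na(s1$sem_gh2ax))

  # pooled mode divides total overlaps by total foci
  rec$n_overlap <- c(4L, 0L)
  rec$frac_smc6_positive <- c(1, 0)
  expect_equal(summarize_condition(rec, frac_mode = "pooled")$
                 mean_frac_smc6_positive, 0.4)
  expect_equal(summarize_condition(rec)$mean_frac_smc6_positive, 0.5)
})
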