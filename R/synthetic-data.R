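#' Parameters for the foci phantom generator
#'
#' Bundles and validates the geometry, biology and noise settings used by
#' [gen_foci_stack()].  Defaults emulate a confocal acquisition of U2OS-like
#' nuclei: 47 x 47 nm lateral pixels, 200 nm z-steps over 42 planes, nuclei
#' of roughly 11 um lateral diameter, ~20 DSB foci per nucleus of which
#' about half carry a co-centred focus in the second channel, and
#' Poisson-Gaussian counting noise at channel SNRs of 10 (gamma-H2AX) and
#' 12 (SMC6).
#'
#' @param stack_shape integer triple `c(nz, ny, nx)`.
#' @param voxel_size_nm nm triple `c(dz, dy, dx)`.
#' @param n_nuclei number of nuclei to place (axis-aligned ellipsoids).
#' @param nucleus_radii_um um triple `c(rz, ry, rx)` of the ellipsoid radii.
#' @param n_gh2ax gamma-H2AX foci per nucleus: a scalar, a vector recycled
#'   over nuclei, or a function `f(n_nuclei)` returning counts.
#' @param coloc_prob probability in `[0, 1]` that a gamma-H2AX focus carries
#'   a co-centred SMC6 focus.
#' @param extra_smc6 count of SMC6-only foci per nucleus.
#' @param focus_sigma_um isotropic Gaussian blob sd in um (single value or
#'   named per-channel `c(gh2ax = , smc6 = )`).
#' @param snr per-channel signal-to-background ratios, named
#'   `c(dna = , gh2ax = , smc6 = )`; a non-finite entry disables noise for
#'   that channel (clean signal, no background).
#' @param background background level as a fraction of focus amplitude.
#' @param min_separation_um minimum distance between focus centres within a
#'   nucleus, preventing blob merging.
#' @param seed integer RNG seed.
#' @return A validated list of class `foci_phantom_params`.
#' @export
foci_phantom_params <- function(stack_shape = c(42L, 792L, 792L),
                                voxel_size_nm = c(200, 47, 47),
                                n_nuclei = 4L,
                                nucleus_radii_um = c(3, 5.5, 5.5),
                                n_gh2ax = 20L,
                                coloc_prob = 0.5,
                                extra_smc6 = 2L,
                                focus_sigma_um = c(gh2ax = 0.15, smc6 = 0.15),
                                snr = c(dna = 20, gh2ax = 10, smc6 = 12),
                                background = 0.05,
                                min_separation_um = 0.8,
                                seed = 1L) {
  stopifnot(length(stack_shape) == 3, all(stack_shape >= 1),
            length(voxel_size_nm) == 3, all(voxel_size_nm > 0),
            n_nuclei >= 1,
            length(nucleus_radii_um) == 3, all(nucleus_radii_um > 0),
            coloc_prob >= 0, coloc_prob <= 1,
            extra_smc6 >= 0, background >= 0,
            min_separation_um >= 0)
  if (length(focus_sigma_um) == 1)
    focus_sigma_um <- c(gh2ax = unname(focus_sigma_um),
                        smc6 = unname(focus_sigma_um))
  stopifnot(all(focus_sigma_um > 0))
  if (is.null(names(snr))) names(snr) <- c("dna", "gh2ax", "smc6")
  structure(list(stack_shape = as.integer(stack_shape),
                 voxel_size_nm = as.numeric(voxel_size_nm),
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radii_um = as.numeric(nucleus_radii_um),
                 n_gh2ax = n_gh2ax,
                 coloc_prob = coloc_prob,
                 extra_smc6 = as.integer(extra_smc6),
                 focus_sigma_um = focus_sigma_um,
                 snr = snr, background = background,
                 min_separation_um = min_separation_um,
                 seed = as.integer(seed)),
            class = "foci_phantom_params")
}

# render an isotropic (in um) Gaussian blob of unit amplitude into `arr`
# at centre `ctr_um` (z,y,x in um); modifies and returns the array
render_blob <- function(arr, ctr_um, sigma_um, vs_um) {
  d <- dim(arr)
  rad <- ceiling(4 * sigma_um / vs_um)
  cvx <- ctr_um / vs_um + 0.5          # voxel-space centre (1-based continuous)
  lo <- pmax(1L, floor(cvx - rad)); hi <- pmin(d, ceiling(cvx + rad))
  if (any(lo > hi)) return(arr)
  ax <- lapply(1:3, function(i) {
    u <- ((lo[i]:hi[i]) - 0.5) * vs_um[i] - ctr_um[i]
    exp(-0.5 * (u / sigma_um)^2)
  })
  blob <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + blob
  arr
}

# sample a point uniformly inside an ellipsoid scaled by `shrink`
sample_in_ellipsoid <- function(centre, radii, shrink = 0.75) {
  u <- rnorm(3)
  u <- u / sqrt(sum(u^2)) * runif(1)^(1 / 3)
  centre + u * radii * shrink
}

#' Generate a 3-channel foci phantom with ground truth
#'
#' Produces a synthetic confocal stack with three channels -- `dna`
#' (nucleus counterstain filling axis-aligned ellipsoids), `gh2ax` (DSB
#' marker foci) and `smc6` (second-channel foci) -- plus the exact ground
#' truth used to generate it.  Each gamma-H2AX focus carries a co-centred
#' SMC6 focus with probability `coloc_prob`; `extra_smc6` SMC6-only foci per
#' nucleus are placed away from all existing foci.  Foci are isotropic
#' Gaussian blobs in micrometre space rendered onto the (generally
#' anisotropic) voxel grid; channels with a finite SNR receive Poisson shot
#' noise plus unit-variance Gaussian read noise on a photon scale of
#' `snr^2` photons per unit intensity.
#'
#' The same seed and parameters always reproduce the identical stack.
#'
#' @param params a [foci_phantom_params()] object.
#' @param render render intensities into the channels (default).  With
#'   `render = FALSE` the channels are left at zero but the ground truth
#'   (placements, colocalization flags, counts) is identical to a rendered
#'   run with the same seed -- useful for studying the generator's
#'   statistical properties without paying the rendering cost.
#' @return A list with `stack` (an [image_stack()] with channels `dna`,
#'   `gh2ax`, `smc6`) and `truth`: a list with data frames `nuclei`
#'   (label, centre and radii in um), `foci` (nucleus, channel, centre,
#'   coloc flag) and `counts` (per-nucleus `n_gh2ax`, `n_smc6`,
#'   `n_overlap`).
#' @examples
#' p <- foci_phantom_params(stack_shape = c(16, 96, 96),
#'                          voxel_size_nm = c(400, 200, 200),
#'                          n_nuclei = 1, nucleus_radii_um = c(2, 3.5, 3.5),
#'                          n_gh2ax = 5, snr = c(dna = Inf, gh2ax = Inf,
#'                          smc6 = Inf), seed = 7)
#' ph <- gen_foci_stack(p)
#' ph$truth$counts
#' @export
gen_foci_stack <- function(params, render = TRUE) {
  if (!inherits(params, "foci_phantom_params"))
    params <- do.call(foci_phantom_params, params)
  p <- params
  set.seed(p$seed)
  d <- p$stack_shape
  vs_um <- p$voxel_size_nm / 1000
  size_um <- d * vs_um
  r <- p$nucleus_radii_um

  if (2 * r[1] > size_um[1])
    stop("stack too small: nucleus axial extent exceeds stack depth")
  gap <- 1.0  # um clearance between nuclei and from the XY border
  cell <- 2 * r[2:3] + gap
  n_y <- floor((size_um[2] - gap) / cell[1])
  n_x <- floor((size_um[3] - gap) / cell[2])
  if (n_y * n_x < p$n_nuclei)
    stop("stack too small to contain ", p$n_nuclei, " nuclei of this size")

  # nucleus centres on a jittered grid, strictly inside the field
  centres <- matrix(0, p$n_nuclei, 3)
  zslack <- max(0, (size_um[1] - 2 * r[1]) / 2)
  for (k in seq_len(p$n_nuclei)) {
    iy <- (k - 1) %/% n_x; ix <- (k - 1) %% n_x
    cy <- gap / 2 + cell[1] * (iy + 0.5) + runif(1, -0.15, 0.15)
    cx <- gap / 2 + cell[2] * (ix + 0.5) + runif(1, -0.15, 0.15)
    cz <- size_um[1] / 2 + runif(1, -1, 1) * min(0.2, zslack)
    centres[k, ] <- c(cz, cy, cx)
  }

  n_g <- if (is.function(p$n_gh2ax)) p$n_gh2ax(p$n_nuclei)
         else rep_len(as.integer(p$n_gh2ax), p$n_nuclei)

  dna <- array(0, d); gh2ax <- array(0, d); smc6 <- array(0, d)
  foci <- list()
  for (k in seq_len(p$n_nuclei)) {
    ctr <- centres[k, ]
    # fill the nucleus ellipsoid in the DNA channel (bounding-box scan)
    lo <- pmax(1L, floor((ctr - r) / vs_um)); hi <- pmin(d, ceiling((ctr + r) / vs_um))
    zz <- ((lo[1]:hi[1]) - 0.5) * vs_um[1]; yy <- ((lo[2]:hi[2]) - 0.5) * vs_um[2]
    xx <- ((lo[3]:hi[3]) - 0.5) * vs_um[3]
    e <- outer(outer(((zz - ctr[1]) / r[1])^2, ((yy - ctr[2]) / r[2])^2, `+`),
               ((xx - ctr[3]) / r[3])^2, `+`)
    sub <- dna[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    sub[e <= 1] <- 1
    dna[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub

    # place foci with a minimum pairwise separation (no blob merging)
    placed <- matrix(numeric(0), 0, 3)
    place_one <- function() {
      for (try in 1:500) {
        cand <- sample_in_ellipsoid(ctr, r)
        if (nrow(placed) == 0 ||
            min(sqrt(colSums((t(placed) - cand)^2))) >= p$min_separation_um)
          return(cand)
      }
      stop("could not place foci with the requested separation; ",
           "reduce counts or min_separation_um")
    }
    for (j in seq_len(n_g[k])) {
      ctr_f <- place_one()
      placed <- rbind(placed, ctr_f)
      coloc <- runif(1) < p$coloc_prob
      if (render) {
        gh2ax <- render_blob(gh2ax, ctr_f, p$focus_sigma_um[["gh2ax"]], vs_um)
        if (coloc)
          smc6 <- render_blob(smc6, ctr_f, p$focus_sigma_um[["smc6"]], vs_um)
      }
      foci[[length(foci) + 1L]] <-
        data.frame(nucleus = k, channel = "gh2ax", cz_um = ctr_f[1],
                   cy_um = ctr_f[2], cx_um = ctr_f[3], coloc = coloc)
    }
    for (j in seq_len(p$extra_smc6)) {
      ctr_f <- place_one()
      placed <- rbind(placed, ctr_f)
      if (render)
        smc6 <- render_blob(smc6, ctr_f, p$focus_sigma_um[["smc6"]], vs_um)
      foci[[length(foci) + 1L]] <-
        data.frame(nucleus = k, channel = "smc6", cz_um = ctr_f[1],
                   cy_um = ctr_f[2], cx_um = ctr_f[3], coloc = FALSE)
    }
  }
  foci <- do.call(rbind, foci)
  rownames(foci) <- NULL

  add_noise <- function(img, snr_ch) {
    if (is.null(snr_ch) || !is.finite(snr_ch)) return(img)
    photons <- snr_ch^2
    lam <- (img + p$background) * photons
    noisy <- (rpois(length(lam), lam) + rnorm(length(lam))) / photons
    array(pmax(noisy, 0), dim(img))
  }
  if (render) {
    dna <- add_noise(dna, p$snr[["dna"]])
    gh2ax <- add_noise(gh2ax, p$snr[["gh2ax"]])
    smc6 <- add_noise(smc6, p$snr[["smc6"]])
  }

  gh <- foci[foci$channel == "gh2ax", ]
  counts <- data.frame(
    nucleus = seq_len(p$n_nuclei),
    n_gh2ax = vapply(seq_len(p$n_nuclei),
                     function(k) sum(gh$nucleus == k), 0L),
    n_smc6 = vapply(seq_len(p$n_nuclei), function(k)
      sum(gh$nucleus == k & gh$coloc) +
        sum(foci$nucleus == k & foci$channel == "smc6"), 0L),
    n_overlap = vapply(seq_len(p$n_nuclei),
                       function(k) sum(gh$nucleus == k & gh$coloc), 0L))

  nuclei <- data.frame(label = seq_len(p$n_nuclei),
                       cz_um = centres[, 1], cy_um = centres[, 2],
                       cx_um = centres[, 3],
                       rz_um = r[1], ry_um = r[2], rx_um = r[3])
  list(stack = image_stack(list(dna = dna, gh2ax = gh2ax, smc6 = smc6),
                           p$voxel_size_nm),
       truth = list(nuclei = nuclei, foci = foci, counts = counts,
                    params = p))
}

#' Simulate a clonogenic-assay colony table
#'
#' Colony counts follow a binomial law: each plated cell forms a colony with
#' probability \eqn{PE \cdot S(D)} where the dose-response survival follows
#' the linear-quadratic model \eqn{S(D) = \exp(-\alpha D - \beta D^2)}.
#' Each dose is administered at two plating densities within every
#' experiment, mirroring standard clonogenic practice.
#'
#' @param pe plating efficiency in `(0, 1]`.
#' @param alpha linear-quadratic \eqn{\alpha} (per Gy or per uM).
#' @param beta linear-quadratic \eqn{\beta} (per Gy^2 or per uM^2).
#' @param doses numeric vector of doses (>= 0); 0 must be included for a
#'   usable control.
#' @param n_plated cells plated per dose at density level 1 (scalar or
#'   per-dose vector); density level 2 plates twice as many.
#' @param replicates number of independent experiments.
#' @param densities multipliers for the plating densities.
#' @param genotype,agent labels copied into the table.
#' @param seed integer RNG seed.
#' @return A `data.frame` of class `colony_table` with columns
#'   `experiment`, `genotype`, `agent`, `dose`, `density`, `cells_plated`,
#'   `colonies`.
#' @examples
#' tab <- gen_colony_counts(0.75, 0.3, 0.03, c(0, 2, 4), 200, seed = 1)
#' head(tab)
#' @export
gen_colony_counts <- function(pe, alpha, beta, doses, n_plated,
                              replicates = 3L, densities = c(1, 2),
                              genotype = "WT", agent = "IR", seed = 1L) {
  stopifnot(pe > 0, pe <= 1, all(doses >= 0), all(n_plated > 0),
            replicates >= 1)
  set.seed(as.integer(seed))
  n_plated <- rep_len(as.integer(n_plated), length(doses))
  rows <- expand.grid(density = seq_along(densities),
                      dose_i = seq_along(doses),
                      experiment = seq_len(replicates))
  surv <- exp(-alpha * doses - beta * doses^2)
  out <- data.frame(
    experiment = rows$experiment,
    genotype = genotype, agent = agent,
    dose = doses[rows$dose_i],
    density = rows$density,
    cells_plated = n_plated[rows$dose_i] * densities[rows$density])
  prob <- pmin(1, pe * surv[rows$dose_i])
  out$colonies <- rbinom(nrow(out), out$cells_plated, prob)
  class(out) <- c("colony_table", "data.frame")
  out
}

#' Simulate a DNA-content sample
#'
#' Draws per-event DNA fluorescence values from the standard univariate
#' cell-cycle model: a Gaussian 2N peak at `mu` (G0/G1), a Gaussian 4N peak
#' at `2 * mu` (G2/M), both with coefficient of variation `cv`, and an
#' S-phase plateau uniform on `(mu, 2 mu)` convolved with the same Gaussian
#' measurement noise.  An `arrested_frac` of events is forced into the 2N
#' peak regardless of the phase fractions, modelling a non-cycling
#' subpopulation.
#'
#' @param frac_g01,frac_s,frac_g2m phase fractions of the cycling
#'   population (non-negative, summing to 1).
#' @param cv coefficient of variation of the 2N peak (> 0).
#' @param arrested_frac fraction of events pinned at 2N.
#' @param n_events number of events to draw.
#' @param mu mean fluorescence of the 2N peak (arbitrary units).
#' @param seed integer RNG seed.
#' @return A list of class `dna_content_sample`: `values` (numeric vector),
#'   `mu`, `cv` and `true_fractions` (`g01`, `s`, `g2m` of all events,
#'   arrested cells counted as G0/G1).
#' @examples
#' s <- gen_dna_histogram(0.5, 0.2, 0.3, n_events = 2000, seed = 3)
#' s$true_fractions
#' @export
gen_dna_histogram <- function(frac_g01, frac_s, frac_g2m, cv = 0.04,
                              arrested_frac = 0, n_events = 10000L,
                              mu = 100, seed = 1L) {
  fr <- c(frac_g01, frac_s, frac_g2m)
  stopifnot(all(fr >= 0), abs(sum(fr) - 1) < 1e-8, cv > 0,
            arrested_frac >= 0, arrested_frac <= 1, n_events >= 1, mu > 0)
  set.seed(as.integer(seed))
  n_arr <- round(arrested_frac * n_events)
  n_cyc <- n_events - n_arr
  n1 <- round(n_cyc * frac_g01); n2 <- round(n_cyc * frac_s)
  n3 <- n_cyc - n1 - n2
  v <- c(rnorm(n_arr + n1, mu, cv * mu),
         runif(n2, mu, 2 * mu) + rnorm(n2, 0, cv * mu),
         rnorm(n3, 2 * mu, cv * 2 * mu))
  v <- pmax(v, mu * 1e-3)
  structure(list(values = v, mu = mu, cv = cv,
                 true_fractions = c(g01 = (n_arr + n1) / n_events,
                                    s = n2 / n_events,
                                    g2m = n3 / n_events)),
            class = "dna_content_sample")
}

#' Simulate a colcemid time series of DNA-content samples
#'
#' Under a mitotic block, cycling cells leave G0/G1 and accumulate with 4N
#' DNA content, so the G0/G1 fraction decays towards the non-cycling
#' residual: \eqn{f(t) = r + (f_0 - r) e^{-t/\tau}}.  S-phase drains with
#' the same time constant; the remainder sits at 4N.
#'
#' @param f0 G0/G1 fraction at time zero.
#' @param residual plateau fraction `r` of permanently arrested cells.
#' @param tau decay time constant in hours.
#' @param times sampling times in hours (must include 0).
#' @param f_s0 initial S-phase fraction.
#' @param cv,n_events,mu,seed passed to [gen_dna_histogram()].
#' @return A list with `samples` (list of `dna_content_sample`), `times`,
#'   and `truth` (`f0`, `residual`, `tau`, the per-time `f_g01`).
#' @export
gen_colcemid_series <- function(f0 = 0.5, residual = 0.16, tau = 24,
                                times = c(0, 24, 48, 72, 96), f_s0 = 0.2,
                                cv = 0.04, n_events = 5000L, mu = 100,
                                seed = 1L) {
  stopifnot(f0 >= 0, f0 <= 1, residual >= 0, residual <= f0 || residual <= 1,
            tau > 0, 0 %in% times, f0 + f_s0 <= 1)
  f_g01 <- residual + (f0 - residual) * exp(-times / tau)
  f_s <- f_s0 * exp(-times / tau)
  f_g2m <- 1 - f_g01 - f_s
  samples <- lapply(seq_along(times), function(i) {
    gen_dna_histogram(f_g01[i], f_s[i], f_g2m[i], cv = cv,
                      arrested_frac = 0, n_events = n_events, mu = mu,
                      seed = child_seed(seed, i))
  })
  list(samples = samples, times = times,
       truth = list(f0 = f0, residual = residual, tau = tau, f_g01 = f_g01))
}

#' Simulate division-interval tracks for two cell lines
#'
#' Division intervals are lognormal with the requested mean and coefficient
#' of variation; the second line's mean interval is `fold` times the
#' first's, emulating a slower-cycling mutant.  Each lineage carries
#' `n_generations` consecutive intervals with cumulative division times.
#'
#' @param mean_wt mean division interval of line A in hours (> 0).
#' @param fold ratio of line B's mean interval to line A's (> 0).
#' @param cv coefficient of variation of intervals (>= 0; 0 gives exactly
#'   constant intervals).
#' @param n_cells lineages per line.
#' @param n_generations intervals per lineage.
#' @param line_names character length-2 labels.
#' @param seed integer RNG seed.
#' @return Named list of two `data.frame`s (one per line) with columns
#'   `lineage`, `generation`, `interval_h`, `division_time_h`.
#' @examples
#' tr <- gen_division_tracks(24, 1.37, cv = 0.15, n_cells = 10,
#'                           n_generations = 3, seed = 2)
#' sapply(tr, function(d) mean(d$interval_h))
#' @export
gen_division_tracks <- function(mean_wt = 24, fold = 1.37, cv = 0.15,
                                n_cells = 50L, n_generations = 5L,
                                line_names = c("A", "B"), seed = 1L) {
  stopifnot(mean_wt > 0, fold > 0, cv >= 0, n_cells >= 1, n_generations >= 1,
            length(line_names) == 2)
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + cv^2))
  one_line <- function(m) {
    meanlog <- log(m) - sdlog^2 / 2
    iv <- if (cv == 0) rep(m, n_cells * n_generations)
          else rlnorm(n_cells * n_generations, meanlog, sdlog)
    d <- data.frame(lineage = rep(seq_len(n_cells), each = n_generations),
                    generation = rep(seq_len(n_generations), n_cells),
                    interval_h = iv)
    d$division_time_h <- stats::ave(d$interval_h, d$lineage, FUN = cumsum)
    d
  }
  out <- list(one_line(mean_wt), one_line(mean_wt * fold))
  names(out) <- line_names
  out
}
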