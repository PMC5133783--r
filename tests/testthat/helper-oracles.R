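# Independent oracles used across the test files.

# --- connected-component labelling oracle -----------------------------------
# Fixed-point minimum-label propagation: start with each foreground voxel
# labelled by its own linear index, then repeatedly take the minimum over
# all neighbours until nothing changes.  Algorithmically unrelated to the
# package's stack-based flood fill.

shift3 <- function(a, dz, dy, dx, fill = Inf) {
  d <- dim(a)
  out <- array(fill, d)
  src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  dst <- src
  sh <- c(dz, dy, dx)
  for (i in 1:3) {
    if (sh[i] > 0) {
      dst[[i]] <- (1 + sh[i]):d[i]; src[[i]] <- 1:(d[i] - sh[i])
    } else if (sh[i] < 0) {
      dst[[i]] <- 1:(d[i] + sh[i]); src[[i]] <- (1 - sh[i]):d[i]
    }
    if (length(dst[[i]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

label_oracle <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  manh <- rowSums(abs(offs))
  offs <- offs[switch(as.character(connectivity),
                      "6" = manh == 1, "18" = manh <= 2, "26" = rep(TRUE, 26)), ]
  lab <- array(seq_along(mask), d)
  lab[!mask] <- Inf
  repeat {
    new <- lab
    for (i in seq_len(nrow(offs))) {
      sh <- shift3(lab, offs$dz[i], offs$dy[i], offs$dx[i])
      new <- pmin(new, sh)
    }
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  lab[!mask] <- 0
  lab
}

# relabel components to consecutive integers in raster order of first voxel
canonical_labels <- function(lab) {
  v <- as.vector(lab)
  u <- unique(v[v > 0])
  map <- integer(0)
  map[as.character(u)] <- seq_along(u)
  out <- v
  out[v > 0] <- map[as.character(v[v > 0])]
  array(out, dim(lab))
}

# --- brute-force circular convolution / RL update ---------------------------
# Direct-sum circular convolution matching the semantics richardson_lucy
# applies to its reflect-padded working array.

conv_circ_brute <- function(x, k, mirror = FALSE) {
  d <- dim(x); dk <- dim(k); ctr <- (dk - 1) / 2
  out <- array(0, d)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x3 in 1:d[3]) {
    acc <- 0
    for (kz in 1:dk[1]) for (ky in 1:dk[2]) for (kx in 1:dk[3]) {
      o <- c(kz, ky, kx) - 1 - ctr
      if (mirror) o <- -o
      src <- (c(z, y, x3) - 1 - o) %% d + 1
      acc <- acc + k[kz, ky, kx] * x[src[1], src[2], src[3]]
    }
    out[z, y, x3] <- acc
  }
  out
}

rl_update_brute <- function(obs, est, k) {
  denom <- conv_circ_brute(est, k)
  ratio <- obs / pmax(denom, .Machine$double.eps)
  pmax(est * conv_circ_brute(ratio, k, mirror = TRUE), 0)
}

# reflect-pad (same rule as the package) for driving the brute-force RL
pad_reflect_oracle <- function(x, pad) {
  d <- dim(x)
  ix <- lapply(1:3, function(i) {
    p <- pad[i]
    if (p == 0) seq_len(d[i])
    else c(rev(seq_len(p) + 1L), seq_len(d[i]), d[i] - seq_len(p))
  })
  x[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

# --- small phantom helper ----------------------------------------------------
# Coarse-grid phantom parameters used throughout the imaging tests: 150 nm
# lateral / 300 nm axial voxels keep stacks small while preserving the
# anisotropy the pipeline must handle.

coarse_phantom <- function(seed, n_nuclei = 4L, n_gh2ax = 10L,
                           coloc_prob = 1, extra_smc6 = 0L,
                           snr = c(dna = Inf, gh2ax = Inf, smc6 = Inf),
                           stack_shape = c(20L, 200L, 200L)) {
  foci_phantom_params(
    stack_shape = stack_shape, voxel_size_nm = c(300, 150, 150),
    n_nuclei = n_nuclei, nucleus_radii_um = c(1.8, 3, 3),
    n_gh2ax = n_gh2ax, coloc_prob = coloc_prob, extra_smc6 = extra_smc6,
    focus_sigma_um = 0.2, min_separation_um = 1.2, snr = snr, seed = seed)
}

coarse_min_voxels <- function() {
  vv <- voxel_volume(c(300, 150, 150))
  c(gh2ax = max(1, round(0.022 / vv)), smc6 = max(1, round(0.0044 / vv)))
}

# hand-built nucleus mask: a filled box inside an otherwise empty grid
box_mask <- function(dim_zyx = c(12L, 40L, 40L), z = 2:11, y = 5:36, x = 5:36,
                     voxel_size_nm = c(300, 150, 150)) {
  dna <- array(0, dim_zyx)
  dna[z, y, x] <- 1
  segment_nuclei(dna, min_nucleus_voxels = 50, close_radius = 0,
                 voxel_size_nm = voxel_size_nm)
}
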