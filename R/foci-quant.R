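# ---- internal helpers -------------------------------------------------------

# Otsu threshold of a numeric vector, returned in original intensity units.
# Uses EBImage's histogram-based implementation on the rescaled values.
otsu_threshold <- function(v, levels = 256L) {
  rng <- range(v)
  if (diff(rng) <= .Machine$double.eps) return(Inf)  # constant: nothing above
  vn <- (v - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(matrix(vn, ncol = 1L)),
                       range = c(0, 1), levels = levels)
  rng[1] + thr * diff(rng)
}

#' Label 3D connected components
#'
#' Labels the connected foreground components of a 3D logical array using
#' 6-, 18- or 26-connectivity (default 26: faces, edges and corners, the
#' standard choice for blob-like structures).  Labels are assigned in
#' raster-scan order starting from 1.
#'
#' @param mask logical (or 0/1 numeric) 3D array, `dim = c(nz, ny, nx)`.
#' @param connectivity one of 6, 18, 26.
#' @return Integer array of the same shape; 0 is background.
#' @examples
#' m <- array(FALSE, c(3, 3, 3)); m[1, 1, 1] <- TRUE; m[3, 3, 3] <- TRUE
#' max(label_components(m))
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  storage.mode(mask) <- "logical"
  .label3d_cpp(mask, as.integer(dim(mask)), as.integer(connectivity))
}

# ---- nucleus segmentation ---------------------------------------------------

#' Segment nuclei from a DNA counterstain channel
#'
#' Global Otsu thresholding of the DNA channel, slice-wise morphological
#' closing and hole filling, then 3D connected-component labelling.
#' Components smaller than `min_nucleus_voxels` are removed, as are nuclei
#' touching the lateral (XY) image border, whose truncated volumes would
#' bias per-cell counts.  Finding no nuclei is reported as a warning, not
#' an error, so that batch runs survive empty fields.
#'
#' @param x an [image_stack()] (the channel named by `channel` is used) or
#'   a numeric 3D array.
#' @param min_nucleus_voxels minimum component size kept, in voxels.
#' @param channel channel name when `x` is an `image_stack`.
#' @param exclude_border drop nuclei touching the XY border (default TRUE).
#' @param close_radius radius (pixels) of the slice-wise closing brush;
#'   0 disables morphology.
#' @param connectivity passed to [label_components()].
#' @param voxel_size_nm voxel geometry when `x` is a bare array.
#' @return An object of class `nucleus_mask`: list with `labels` (integer
#'   array), `n` (number of nuclei), `table` (`label`, `voxels`, bounding
#'   box columns `z0,z1,y0,y1,x0,x1`), `dim`, `voxel_size_nm`.
#' @export
segment_nuclei <- function(x, min_nucleus_voxels = 500L, channel = "dna",
                           exclude_border = TRUE, close_radius = 2L,
                           connectivity = 26L, voxel_size_nm = NULL) {
  if (inherits(x, "image_stack")) {
    voxel_size_nm <- x$voxel_size_nm
    x <- if (channel %in% names(x$channels)) x$channels[[channel]]
         else x$channels[[1]]
  }
  stopifnot(is.array(x), length(dim(x)) == 3)
  d <- dim(x)
  empty <- function() {
    warning("no nuclei found")
    structure(list(labels = array(0L, d), n = 0L,
                   table = data.frame(label = integer(), voxels = integer(),
                                      z0 = integer(), z1 = integer(),
                                      y0 = integer(), y1 = integer(),
                                      x0 = integer(), x1 = integer()),
                   dim = d, voxel_size_nm = voxel_size_nm),
              class = "nucleus_mask")
  }
  thr <- otsu_threshold(as.vector(x))
  if (!is.finite(thr)) return(empty())
  bw <- x > thr
  if (!any(bw)) return(empty())

  if (close_radius > 0) {
    a <- aperm(bw, c(2, 3, 1)) * 1  # (y, x, z): morphology acts per z-slice
    brush <- EBImage::makeBrush(2L * as.integer(close_radius) + 1L, "disc")
    a <- EBImage::closing(EBImage::Image(a), brush)
    a <- EBImage::fillHull(a)
    bw <- aperm(as.array(a) > 0.5, c(3, 1, 2))
  }

  lab <- label_components(bw, connectivity)
  k <- max(lab)
  if (k == 0) return(empty())
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  keep <- sizes >= min_nucleus_voxels
  if (exclude_border) {
    border <- unique(c(lab[, 1, ], lab[, d[2], ], lab[, , 1], lab[, , d[3]]))
    keep[border[border > 0L]] <- FALSE
  }
  if (!any(keep)) return(empty())
  remap <- integer(k)
  remap[which(keep)] <- seq_len(sum(keep))
  nz <- lab > 0L
  lab[nz] <- remap[lab[nz]]

  idx <- which(lab > 0L)
  co <- arrayInd(idx, d)
  lv <- lab[idx]
  tab <- data.frame(label = sort(unique(lv)))
  tab$voxels <- as.integer(tabulate(lv, nbins = max(lv))[tab$label])
  agg <- function(f, col) as.integer(tapply(co[, col], lv, f))
  tab$z0 <- agg(min, 1); tab$z1 <- agg(max, 1)
  tab$y0 <- agg(min, 2); tab$y1 <- agg(max, 2)
  tab$x0 <- agg(min, 3); tab$x1 <- agg(max, 3)
  structure(list(labels = lab, n = nrow(tab), table = tab, dim = d,
                 voxel_size_nm = voxel_size_nm),
            class = "nucleus_mask")
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat(sprintf("nucleus_mask: %d nuclei in a %s grid\n", x$n,
              paste(x$dim, collapse = " x ")))
  invisible(x)
}

# ---- foci detection ---------------------------------------------------------

#' Detect size-filtered 3D foci within segmented nuclei
#'
#' Within each nucleus, voxels above a nucleus-local intensity threshold
#' are grouped into 26-connected 3D components; components of at least
#' `min_voxels` voxels (inclusive, per the "minimal size" convention) are
#' kept as foci and assigned to their nucleus.  Signal outside all nuclei
#' is ignored.  Thresholding is computed per nucleus -- either Otsu on the
#' in-nucleus intensities (default) or mean + `k_sd` standard deviations --
#' which makes detection robust to cell-to-cell staining variation.
#'
#' @param x an [image_stack()] or numeric 3D array (one channel).
#' @param mask a `nucleus_mask` from [segment_nuclei()].
#' @param min_voxels minimum focus volume in voxels (inclusive).  The
#'   reference settings are 50 voxels (0.022 um^3 at 47 x 47 x 200 nm) for
#'   gamma-H2AX and 10 voxels for SMC6.
#' @param channel channel name when `x` is an `image_stack`.
#' @param threshold_method `"otsu"` or `"mean_sd"`.
#' @param k_sd multiplier for the `"mean_sd"` method.
#' @param connectivity passed to [label_components()].
#' @return An object of class `focus_set`: list with `channel`,
#'   `min_voxels`, `foci` (data.frame: `id`, `nucleus`, `volume_voxels`,
#'   `volume_um3`, centroid `cz_um, cy_um, cx_um`, `peak`), `voxels`
#'   (list of linear voxel-index vectors, parallel to `foci`), `dim`,
#'   `voxel_size_nm`.
#' @export
detect_foci <- function(x, mask, min_voxels, channel = "gh2ax",
                        threshold_method = c("otsu", "mean_sd"), k_sd = 3,
                        connectivity = 26L) {
  threshold_method <- match.arg(threshold_method)
  if (inherits(x, "image_stack"))
    x <- if (channel %in% names(x$channels)) x$channels[[channel]]
         else stop("channel '", channel, "' not found in stack")
  stopifnot(inherits(mask, "nucleus_mask"), is.array(x),
            identical(dim(x), as.integer(mask$dim)) || identical(dim(x), mask$dim),
            min_voxels >= 1)
  d <- dim(x)
  vs_nm <- mask$voxel_size_nm
  vv <- if (!is.null(vs_nm)) voxel_volume(vs_nm) else NA_real_
  vs_um <- if (!is.null(vs_nm)) vs_nm / 1000 else c(NA, NA, NA)

  foci <- list(); voxsets <- list(); id <- 0L
  for (i in seq_len(mask$n)) {
    row <- mask$table[i, ]
    bz <- row$z0:row$z1; by <- row$y0:row$y1; bx <- row$x0:row$x1
    sub <- x[bz, by, bx, drop = FALSE]
    dim(sub) <- c(length(bz), length(by), length(bx))
    msub <- mask$labels[bz, by, bx, drop = FALSE] == row$label
    dim(msub) <- dim(sub)
    vals <- sub[msub]
    thr <- switch(threshold_method,
                  otsu = otsu_threshold(vals),
                  mean_sd = mean(vals) + k_sd * sd(vals))
    if (!is.finite(thr)) next
    bw <- (sub > thr) & msub
    lab <- label_components(bw, connectivity)
    kk <- max(lab)
    if (kk == 0) next
    sizes <- tabulate(lab[lab > 0L], nbins = kk)
    for (cmp in which(sizes >= min_voxels)) {
      li <- which(lab == cmp)
      co <- arrayInd(li, dim(sub))
      gz <- bz[co[, 1]]; gy <- by[co[, 2]]; gx <- bx[co[, 3]]
      gidx <- gz + d[1] * ((gy - 1) + d[2] * (gx - 1))
      id <- id + 1L
      foci[[id]] <- data.frame(
        id = id, nucleus = row$label,
        volume_voxels = length(li),
        volume_um3 = length(li) * vv,
        cz_um = (mean(gz) - 0.5) * vs_um[1],
        cy_um = (mean(gy) - 0.5) * vs_um[2],
        cx_um = (mean(gx) - 0.5) * vs_um[3],
        peak = max(sub[li]))
      voxsets[[id]] <- as.integer(gidx)
    }
  }
  foci <- if (id > 0) do.call(rbind, foci) else
    data.frame(id = integer(), nucleus = integer(),
               volume_voxels = integer(), volume_um3 = numeric(),
               cz_um = numeric(), cy_um = numeric(), cx_um = numeric(),
               peak = numeric())
  structure(list(channel = channel, min_voxels = min_voxels, foci = foci,
                 voxels = voxsets, dim = d, voxel_size_nm = vs_nm),
            class = "focus_set")
}

#' @export
print.focus_set <- function(x, ...) {
  cat(sprintf("focus_set '%s': %d foci (min %d voxels)\n", x$channel,
              nrow(x$foci), x$min_voxels))
  invisible(x)
}

# ---- overlap counting -------------------------------------------------------

#' Count channel-overlap of foci per nucleus
#'
#' A focus in the first channel counts as overlapping when its voxel set
#' shares at least one voxel with any focus of the second channel in the
#' same nucleus (the `"voxel"` rule; each first-channel focus is counted at
#' most once).  Alternatively, the `"centroid"` rule requires the
#' first-channel focus centroid voxel to lie inside a second-channel
#' focus.
#'
#' @param a,b two `focus_set` objects derived from the same nucleus mask
#'   (`a` is the reference channel whose foci are classified, e.g.
#'   gamma-H2AX; `b` the test channel, e.g. SMC6).
#' @param rule `"voxel"` (default) or `"centroid"`.
#' @return List with `per_focus` (`id`, `nucleus`, `overlaps` logical) and
#'   `per_nucleus` (`nucleus`, `n_overlap`).
#' @export
count_overlaps <- function(a, b, rule = c("voxel", "centroid")) {
  rule <- match.arg(rule)
  stopifnot(inherits(a, "focus_set"), inherits(b, "focus_set"))
  if (!identical(a$dim, b$dim))
    stop("focus sets come from different grids")
  nuclei <- sort(unique(c(a$foci$nucleus, b$foci$nucleus)))
  per_focus <- a$foci[, c("id", "nucleus")]
  per_focus$overlaps <- logical(nrow(per_focus))
  for (nuc in nuclei) {
    ai <- which(a$foci$nucleus == nuc)
    bi <- which(b$foci$nucleus == nuc)
    if (!length(ai) || !length(bi)) next
    bset <- unlist(b$voxels[b$foci$id[bi]], use.names = FALSE)
    for (j in ai) {
      av <- a$voxels[[a$foci$id[j]]]
      hit <- if (rule == "voxel") any(av %in% bset) else {
        # centroid rule: the voxel nearest the centroid must be in b
        co <- arrayInd(av, a$dim)
        ctr <- round(colMeans(co))
        cidx <- ctr[1] + a$dim[1] * ((ctr[2] - 1) + a$dim[2] * (ctr[3] - 1))
        cidx %in% bset
      }
      per_focus$overlaps[per_focus$id == a$foci$id[j]] <- hit
    }
  }
  per_nucleus <- data.frame(nucleus = nuclei)
  per_nucleus$n_overlap <- vapply(nuclei, function(nuc)
    sum(per_focus$overlaps[per_focus$nucleus == nuc]), 0L)
  list(per_focus = per_focus, per_nucleus = per_nucleus)
}

# ---- per-cell records and condition summaries -------------------------------

#' Per-nucleus foci records
#'
#' Combines two channel `focus_set`s into one record per nucleus: focus
#' counts, overlap count, the fraction of reference-channel foci positive
#' for the test channel (undefined when the nucleus has no reference
#' foci), and a `selected` flag marking cells with at least
#' `selection_min_smc6` test-channel foci -- the automated counterpart of
#' restricting analysis to cells with clearly detectable second-channel
#' signal.
#'
#' @param mask a `nucleus_mask`.
#' @param gh2ax,smc6 `focus_set`s for the reference and test channels.
#' @param selection_min_smc6 minimum test-channel foci for selection.
#' @param rule overlap rule passed to [count_overlaps()].
#' @return `data.frame` with columns `nucleus`, `n_gh2ax`, `n_smc6`,
#'   `n_overlap`, `frac_smc6_positive`, `selected`.
#' @export
per_cell_records <- function(mask, gh2ax, smc6, selection_min_smc6 = 2L,
                             rule = "voxel") {
  stopifnot(inherits(mask, "nucleus_mask"))
  ov <- count_overlaps(gh2ax, smc6, rule = rule)
  labs <- mask$table$label
  cnt <- function(fs) vapply(labs, function(l) sum(fs$foci$nucleus == l), 0L)
  rec <- data.frame(nucleus = labs,
                    n_gh2ax = cnt(gh2ax), n_smc6 = cnt(smc6))
  rec$n_overlap <- vapply(labs, function(l) {
    i <- match(l, ov$per_nucleus$nucleus)
    if (is.na(i)) 0L else ov$per_nucleus$n_overlap[i]
  }, 0L)
  rec$frac_smc6_positive <- ifelse(rec$n_gh2ax > 0,
                                   rec$n_overlap / rec$n_gh2ax, NA_real_)
  rec$selected <- rec$n_smc6 >= selection_min_smc6
  rec
}

#' Summarise per-cell records for one experimental condition
#'
#' Computes mean and SEM (sd / sqrt(n)) over cells of the reference-channel
#' focus count and of the test-channel-positive fraction.  By default only
#' `selected` cells enter, and the fraction is averaged per cell (cells
#' with no reference foci are excluded from the fraction average); the
#' `"pooled"` mode instead divides total overlaps by total reference foci
#' across cells.  A single-cell condition reports `NA` SEM.
#'
#' @param records output of [per_cell_records()] (possibly row-bound over
#'   several stacks).
#' @param genotype,treatment,timepoint labels copied into the summary.
#' @param use_selected restrict to `selected` cells (default TRUE).
#' @param frac_mode `"per_cell"` (default) or `"pooled"`.
#' @return One-row `data.frame` of class `condition_summary`.
#' @export
summarize_condition <- function(records, genotype = NA, treatment = NA,
                                timepoint = NA, use_selected = TRUE,
                                frac_mode = c("per_cell", "pooled")) {
  frac_mode <- match.arg(frac_mode)
  r <- if (use_selected) records[records$selected, , drop = FALSE] else records
  if (nrow(r) < 1) stop("no cells to summarise (after selection)")
  sem <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  fr <- r$frac_smc6_positive[!is.na(r$frac_smc6_positive)]
  frac_mean <- if (frac_mode == "per_cell") {
    if (length(fr)) mean(fr) else NA_real_
  } else if (sum(r$n_gh2ax) > 0) sum(r$n_overlap) / sum(r$n_gh2ax) else NA_real_
  out <- data.frame(genotype = genotype, treatment = treatment,
                    timepoint = timepoint, n_cells = nrow(r),
                    mean_gh2ax = mean(r$n_gh2ax), sem_gh2ax = sem(r$n_gh2ax),
                    mean_frac_smc6_positive = frac_mean,
                    sem_frac_smc6_positive =
                      if (frac_mode == "per_cell") sem(fr) else NA_real_)
  class(out) <- c("condition_summary", "data.frame")
  out
}

#' One-call quantification of a multi-channel stack
#'
#' Convenience wrapper running the full per-stack pipeline: optional
#' Richardson-Lucy deconvolution of the two foci channels, nucleus
#' segmentation on the DNA channel, size-filtered foci detection in both
#' channels and per-cell record assembly.
#'
#' @param stack an [image_stack()] with DNA, reference and test channels.
#' @param channels named character vector mapping roles to channel names,
#'   `c(dna = , gh2ax = , smc6 = )`.
#' @param min_voxels named numeric, minimal focus sizes per role
#'   (`gh2ax`, `smc6`).
#' @param deconvolve logical; apply [richardson_lucy()] to both foci
#'   channels first.
#' @param psf optional `psf_model`; defaults to a Gaussian PSF with
#'   `sigma_xy = 0.1` um and `sigma_z = 0.3` um on the stack's grid.
#' @param max_iter,snr deconvolution settings (see [richardson_lucy()]).
#' @param min_nucleus_voxels,threshold_method,selection_min_smc6,rule
#'   passed to the respective stages.
#' @return List with `mask`, `gh2ax`, `smc6` (focus sets) and `records`.
#' @export
quantify_stack <- function(stack,
                           channels = c(dna = "dna", gh2ax = "gh2ax",
                                        smc6 = "smc6"),
                           min_voxels = c(gh2ax = 50, smc6 = 10),
                           deconvolve = FALSE, psf = NULL, max_iter = 40L,
                           snr = NULL, min_nucleus_voxels = 500L,
                           threshold_method = "otsu",
                           selection_min_smc6 = 2L, rule = "voxel") {
  stopifnot(inherits(stack, "image_stack"))
  if (deconvolve) {
    if (is.null(psf))
      psf <- make_gaussian_psf(0.1, 0.3, stack$voxel_size_nm)
    for (role in c("gh2ax", "smc6")) {
      ch <- channels[[role]]
      dec <- richardson_lucy(stack$channels[[ch]], psf, max_iter = max_iter,
                             snr = if (is.null(snr)) NULL else snr[[role]])
      attr(dec, "iterations") <- NULL
      stack$channels[[ch]] <- dec
    }
  }
  mask <- segment_nuclei(stack, min_nucleus_voxels = min_nucleus_voxels,
                         channel = channels[["dna"]])
  gh <- detect_foci(stack, mask, min_voxels = min_voxels[["gh2ax"]],
                    channel = channels[["gh2ax"]],
                    threshold_method = threshold_method)
  sm <- detect_foci(stack, mask, min_voxels = min_voxels[["smc6"]],
                    channel = channels[["smc6"]],
                    threshold_method = threshold_method)
  rec <- per_cell_records(mask, gh, sm,
                          selection_min_smc6 = selection_min_smc6,
                          rule = rule)
  list(mask = mask, gh2ax = gh, smc6 = sm, records = rec)
}
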