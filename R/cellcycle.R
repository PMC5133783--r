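# locate the 2N peak of a DNA-content sample by kernel density.
# Candidate modes are scored by the density at the mode plus the density at
# twice its position, which distinguishes the 2N peak from the 4N peak.
find_2n_peak <- function(values) {
  dens <- density(values, n = 1024)
  i <- which(diff(sign(diff(dens$y))) == -2) + 1L
  i <- i[dens$y[i] >= 0.05 * max(dens$y)]  # ignore low-prominence wiggles
  if (!length(i)) i <- which.max(dens$y)
  dens_at <- stats::approxfun(dens$x, dens$y, yleft = 0, yright = 0)
  cand <- dens$x[i]
  # also consider each mode being the 4N peak of an unseen 2N population
  cand <- c(cand, cand / 2)
  score <- dens_at(cand) + dens_at(2 * cand)
  mu <- cand[which.max(score)]
  if (!is.finite(mu) || dens_at(mu) + dens_at(2 * mu) <= 0)
    stop("no detectable DNA-content peak")
  mu
}

#' Cell-cycle phase fractions from DNA content
#'
#' Gated phase analysis of a univariate DNA-content sample.  The 2N peak
#' position `mu` is located as the kernel-density mode (scored jointly with
#' the density at `2 mu` so the 2N peak is not confused with the 4N peak),
#' the G0/G1 gate is `mu (1 +/- k cv)`, the G2/M gate is `2 mu (1 +/- k
#' cv)` and S is the interval between them.  Raw gate counts are then
#' corrected for the predictable spill of the uniform S-phase plateau into
#' the G0/G1 and G2/M gates and for Gaussian peak tails escaping their
#' gates, by solving the 3 x 3 linear mixing system those assumptions
#' imply.  Supplying `mu` (and `cv`) fixes the gates externally -- the
#' natural choice when analysing a time series against its t = 0 sample.
#'
#' @param sample a `dna_content_sample`, or a numeric vector of per-event
#'   DNA fluorescence values (>= 500 events).
#' @param mu optional 2N peak position; estimated from the data if `NULL`.
#' @param cv optional coefficient of variation of the 2N peak; estimated
#'   from events within 10% of `mu` if `NULL`.
#' @param k gate half-width in cv units (default 2.5).  Gates must not
#'   intersect, which requires `cv < 1 / (3 k)`.
#' @return An object of class `phase_fractions`: list with `fractions`
#'   (`g01`, `s`, `g2m`), `raw_fractions` (uncorrected gate counts /
#'   total), `gates` (matrix), `mu`, `cv`, `n_events`.
#' @examples
#' s <- gen_dna_histogram(0.6, 0.15, 0.25, n_events = 5000, seed = 1)
#' phase_fractions(s)$fractions
#' @export
phase_fractions <- function(sample, mu = NULL, cv = NULL, k = 2.5) {
  v <- if (inherits(sample, "dna_content_sample")) sample$values
       else as.numeric(sample)
  if (length(v) < 500) stop("need >= 500 events")
  if (any(v <= 0)) stop("DNA content values must be positive")
  if (is.null(mu)) mu <- find_2n_peak(v)
  if (is.null(cv)) {
    win <- v[abs(v - mu) < 0.1 * mu]
    cv <- if (length(win) > 50) min(0.12, max(0.01, sd(win) / mu)) else 0.05
  }
  if (cv >= 1 / (3 * k))
    stop("gates intersect: cv must be below 1/(3k) = ",
         signif(1 / (3 * k), 3))
  g01 <- mu * c(1 - k * cv, 1 + k * cv)
  g2m <- 2 * mu * c(1 - k * cv, 1 + k * cv)
  stopifnot(g01[2] < g2m[1])  # non-intersecting gates by construction
  n <- length(v)
  raw <- c(g01 = sum(v >= g01[1] & v <= g01[2]),
           s = sum(v > g01[2] & v < g2m[1]),
           g2m = sum(v >= g2m[1] & v <= g2m[2])) / n

  # mixing model: expected gate content given true fractions
  # peaks: mass 2*pnorm(k)-1 inside own gate, tails split to the S gate side
  inside <- 2 * stats::pnorm(k) - 1
  tail1 <- (1 - inside) / 2
  # uniform S on (mu, 2mu): widths k*cv and 2*k*cv fall into the peak gates
  A <- rbind(
    c(inside, k * cv,              0),
    c(tail1,  1 - 3 * k * cv,      tail1),
    c(0,      2 * k * cv,          inside))
  f <- tryCatch(solve(A, raw), error = function(e) raw)
  f <- pmin(pmax(f, 0), 1)
  names(f) <- c("g01", "s", "g2m")
  structure(list(fractions = f, raw_fractions = raw,
                 gates = rbind(g01 = g01, s = c(g01[2], g2m[1]), g2m = g2m),
                 mu = mu, cv = cv, n_events = n),
            class = "phase_fractions")
}

#' @export
print.phase_fractions <- function(x, ...) {
  cat(sprintf("phase_fractions: G0/1 %.3f, S %.3f, G2/M %.3f (mu = %.1f, cv = %.3f)\n",
              x$fractions["g01"], x$fractions["s"], x$fractions["g2m"],
              x$mu, x$cv))
  invisible(x)
}

#' G0/G1 depletion kinetics under a mitotic block
#'
#' Computes the G0/G1 fraction at each time point of a colcemid series
#' (gates anchored on the t = 0 sample, so the gate does not drift as the
#' 2N peak empties) and fits the decay-to-plateau model
#' \eqn{f(t) = r + (f_0 - r) e^{-t/\tau}}.  The plateau `r` estimates the
#' fraction of cells not participating in the cell cycle.  A constant
#' series is handled as the degenerate `tau -> Inf` limit with plateau
#' `f0`.
#'
#' @param samples list of `dna_content_sample`s (or numeric vectors), one
#'   per time point.
#' @param times numeric vector of treatment durations in hours; must
#'   include 0 and have >= 3 time points.
#' @param k gate half-width, passed to [phase_fractions()].
#' @return List with `table` (`time_h`, `f_g01`), `residual_fraction`,
#'   `f0`, `tau`, and the `nls` fit (`NULL` in the degenerate case).
#' @examples
#' ser <- gen_colcemid_series(n_events = 2000, seed = 5)
#' colcemid_depletion(ser$samples, ser$times)$residual_fraction
#' @export
colcemid_depletion <- function(samples, times, k = 2.5) {
  stopifnot(length(samples) == length(times), length(times) >= 3,
            0 %in% times)
  o <- order(times); times <- times[o]; samples <- samples[o]
  p0 <- phase_fractions(samples[[which(times == 0)[1]]], k = k)
  f <- vapply(samples, function(s)
    phase_fractions(s, mu = p0$mu, cv = p0$cv, k = k)$fractions[["g01"]], 0)
  tab <- data.frame(time_h = times, f_g01 = f)
  if (sd(f) < 1e-9) {
    return(list(table = tab, residual_fraction = f[1], f0 = f[1],
                tau = Inf, fit = NULL))
  }
  fit <- minpack.lm::nlsLM(
    f_g01 ~ r + (f0 - r) * exp(-time_h / tau), data = tab,
    start = list(r = max(0.01, min(f)), f0 = f[1],
                 tau = max(diff(range(times)) / 4, 1)),
    lower = c(r = 0, f0 = 0, tau = 1e-3),
    upper = c(r = 1, f0 = 1, tau = 1e6),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  list(table = tab, residual_fraction = unname(cf["r"]),
       f0 = unname(cf["f0"]), tau = unname(cf["tau"]), fit = fit)
}

# intervals of a division-track data frame (one row per division interval)
division_intervals <- function(tracks) {
  stopifnot(all(c("lineage", "interval_h") %in% names(tracks)))
  if (any(tracks$interval_h <= 0)) stop("division intervals must be positive")
  tracks$interval_h
}

#' Division-interval statistics and fold change between two lines
#'
#' Mean +/- SEM of the division interval per line, the fold change
#' `mean(B) / mean(A)`, and a two-tailed unpaired Student's t-test on the
#' pooled intervals.  The fold change is invariant under a common rescaling
#' of the time unit.
#'
#' @param tracks_a,tracks_b division-track `data.frame`s (columns
#'   `lineage`, `interval_h`), e.g. the two elements of
#'   [gen_division_tracks()]; >= 2 intervals per line.
#' @return List with `summary` (per-line mean, sem, n), `fold_change` and
#'   `test` (a [two_sample_t()] result).
#' @examples
#' tr <- gen_division_tracks(24, 1.4, n_cells = 20, seed = 9)
#' division_stats(tr[[1]], tr[[2]])$fold_change
#' @export
division_stats <- function(tracks_a, tracks_b) {
  a <- division_intervals(tracks_a); b <- division_intervals(tracks_b)
  stopifnot(length(a) >= 2, length(b) >= 2)
  sem <- function(v) sd(v) / sqrt(length(v))
  summary <- data.frame(line = c("A", "B"),
                        mean_h = c(mean(a), mean(b)),
                        sem_h = c(sem(a), sem(b)),
                        n = c(length(a), length(b)))
  tt <- two_sample_t(b, a, tails = 2L, paired = FALSE)
  list(summary = summary, fold_change = mean(b) / mean(a), test = tt)
}

#' Align lineage generations to a common anchor
#'
#' Re-indexes the generation numbers of each lineage so that the
#' generation spanning `anchor_time` becomes generation
#' `anchor_generation` in every lineage (the convention of anchoring on
#' the generation during which a shared event, such as a medium refresh,
#' occurred).  Without an `anchor_time` the indexing is left unchanged.
#' Missing generations stay missing; nothing is imputed.
#'
#' @param tracks division-track `data.frame` (columns `lineage`,
#'   `generation`, `interval_h`, `division_time_h`).
#' @param anchor_generation target index for the anchored generation.
#' @param anchor_time time (same units as `division_time_h`) falling
#'   within the generation to be anchored; `NULL` leaves indices as-is.
#' @return The tracks with an added `aligned_generation` column.
#' @export
align_generations <- function(tracks, anchor_generation = 3L,
                              anchor_time = NULL) {
  stopifnot(all(c("lineage", "generation", "interval_h",
                  "division_time_h") %in% names(tracks)))
  if (is.null(anchor_time)) {
    tracks$aligned_generation <- tracks$generation
    return(tracks)
  }
  out <- lapply(split(tracks, tracks$lineage), function(d) {
    d <- d[order(d$generation), , drop = FALSE]
    start <- d$division_time_h - d$interval_h
    hit <- which(start <= anchor_time & anchor_time < d$division_time_h)
    if (!length(hit))
      stop("lineage ", d$lineage[1], " does not span anchor_time")
    d$aligned_generation <- d$generation - d$generation[hit[1]] +
      anchor_generation
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
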