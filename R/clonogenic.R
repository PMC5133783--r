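#' Plating efficiency
#'
#' The fraction of plated single cells that grow into a colony of at least
#' 50 cells under control (untreated) conditions.
#'
#' @param colonies number of colonies counted (>= 0).
#' @param cells_plated number of cells plated (> 0).
#' @return `colonies / cells_plated`.
#' @examples
#' plating_efficiency(150, 200)  # 0.75
#' @export
plating_efficiency <- function(colonies, cells_plated) {
  stopifnot(all(cells_plated > 0), all(colonies >= 0))
  colonies / cells_plated
}

#' Relative survival curve from a colony table
#'
#' For every experiment, survival at dose D is the colony-forming fraction
#' divided by the plating efficiency of the dose-0 control, so S(0) = 1 by
#' construction.  When each dose was plated at two densities, the survival
#' estimates of the two density levels are computed against their own
#' density-matched controls and averaged with equal weight within the
#' experiment.  The curve aggregates experiments as mean +/- SEM.
#'
#' @param table a `colony_table` (columns `experiment`, `dose`,
#'   `cells_plated`, `colonies`, optionally `density`, `genotype`,
#'   `agent`), e.g. from [gen_colony_counts()] or read from CSV.
#' @return An object of class `survival_curve`: list with `points`
#'   (`dose`, `relative_survival`, `sem`, `n_experiments`),
#'   `by_experiment` (matrix experiments x doses), `plating_efficiency`
#'   (per experiment), `genotype`, `agent`.
#' @examples
#' tab <- gen_colony_counts(0.75, 0.3, 0.03, c(0, 2, 4), 400, seed = 1)
#' relative_survival(tab)$points
#' @export
relative_survival <- function(table) {
  stopifnot(all(c("experiment", "dose", "cells_plated", "colonies") %in%
                  names(table)))
  if (any(table$colonies > table$cells_plated))
    stop("colonies exceed cells plated")
  if (any(table$dose < 0)) stop("negative dose")
  if (!("density" %in% names(table))) table$density <- 1L
  exps <- sort(unique(table$experiment))
  doses <- sort(unique(table$dose))
  S <- matrix(NA_real_, length(exps), length(doses),
              dimnames = list(exps, doses))
  pe <- numeric(length(exps))
  for (ei in seq_along(exps)) {
    te <- table[table$experiment == exps[ei], , drop = FALSE]
    ctrl <- te[te$dose == 0, , drop = FALSE]
    if (nrow(ctrl) == 0)
      stop("experiment ", exps[ei], " has no dose-0 control")
    pe_by_density <- vapply(split(ctrl, ctrl$density), function(cc)
      plating_efficiency(sum(cc$colonies), sum(cc$cells_plated)), 0)
    pe[ei] <- mean(pe_by_density)
    for (di in seq_along(doses)) {
      td <- te[te$dose == doses[di], , drop = FALSE]
      if (nrow(td) == 0) next
      s_by_density <- vapply(seq_len(nrow(td)), function(i) {
        dens <- as.character(td$density[i])
        pe_d <- if (dens %in% names(pe_by_density)) pe_by_density[[dens]]
                else pe[ei]
        (td$colonies[i] / td$cells_plated[i]) / pe_d
      }, 0)
      S[ei, di] <- mean(s_by_density)
    }
  }
  pts <- data.frame(
    dose = doses,
    relative_survival = colMeans(S, na.rm = TRUE),
    sem = apply(S, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
    }),
    n_experiments = colSums(!is.na(S)))
  rownames(pts) <- NULL
  structure(list(points = pts, by_experiment = S, plating_efficiency = pe,
                 genotype = if ("genotype" %in% names(table))
                   table$genotype[1] else NA,
                 agent = if ("agent" %in% names(table)) table$agent[1] else NA),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("survival_curve (%s, %s): mean PE %.3f over %d experiment(s)\n",
              x$genotype, x$agent, mean(x$plating_efficiency),
              nrow(x$by_experiment)))
  print(x$points)
  invisible(x)
}

#' Compare two survival curves dose by dose
#'
#' Paired Student's t-test per dose across experiments (pairing by
#' experiment), one-tailed by default with the alternative that curve A
#' survives better than curve B (`direction = "greater"`).  Dose 0 is
#' skipped (both curves are 1 there by construction).  When the paired
#' differences are all zero the test statistic is 0 and the one-tailed
#' p-value is 0.5 (two-tailed: 1).
#'
#' @param a,b `survival_curve` objects with matched doses and >= 2 paired
#'   experiments.
#' @param direction `"greater"` (A more resistant), `"less"`, or
#'   `"two.sided"`.
#' @return `data.frame` with `dose`, `mean_diff`, `statistic`, `df`, `p`.
#' @export
compare_survival <- function(a, b,
                             direction = c("greater", "less", "two.sided")) {
  direction <- match.arg(direction)
  stopifnot(inherits(a, "survival_curve"), inherits(b, "survival_curve"))
  doses <- intersect(colnames(a$by_experiment), colnames(b$by_experiment))
  doses <- doses[as.numeric(doses) > 0]
  if (!length(doses)) stop("no positive doses shared between curves")
  exps <- intersect(rownames(a$by_experiment), rownames(b$by_experiment))
  if (length(exps) < 2) stop("need >= 2 paired experiments")
  out <- lapply(doses, function(dn) {
    x <- a$by_experiment[exps, dn]; y <- b$by_experiment[exps, dn]
    ok <- !is.na(x) & !is.na(y)
    tt <- two_sample_t(x[ok], y[ok],
                       tails = if (direction == "two.sided") 2L else 1L,
                       paired = TRUE,
                       alternative = if (direction == "two.sided")
                         "two.sided" else direction)
    data.frame(dose = as.numeric(dn), mean_diff = mean(x[ok] - y[ok]),
               statistic = tt$statistic, df = tt$df, p = tt$p)
  })
  do.call(rbind, out)
}

#' Linear-quadratic fit of a survival curve
#'
#' Least-squares fit of \eqn{\log S(D) = -\alpha D - \beta D^2} to the
#' per-experiment mean survival values.  This goes beyond plotting raw
#' relative survival and is provided as an optional extension (doses where
#' the mean survival is zero are dropped).
#'
#' @param curve a `survival_curve`.
#' @return List with `alpha`, `beta` and the underlying `lm` fit.
#' @export
fit_lq <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  pts <- curve$points[curve$points$relative_survival > 0, ]
  if (nrow(pts) < 3) stop("need >= 3 doses with positive survival")
  D <- pts$dose; y <- log(pts$relative_survival)
  fit <- stats::lm(y ~ 0 + D + I(D^2))
  cf <- coef(fit)
  list(alpha = -unname(cf[1]), beta = -unname(cf[2]), fit = fit)
}
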