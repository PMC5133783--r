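#' Student's two-sample t-test (one- or two-tailed, paired or unpaired)
#'
#' Classic Student t statistic -- pooled variance for the unpaired case
#' (Welch available via `var_equal = FALSE`) -- with explicit control of
#' tails and pairing, matching the conventions used throughout the
#' package: two-tailed unpaired for per-cell foci counts, one-tailed
#' paired for dose-matched survival.  For a one-tailed test the p-value is
#' half the two-tailed p when the observed effect lies in the hypothesised
#' direction.  Degenerate inputs with zero variance are handled: a zero
#' mean difference gives `t = 0` (p = 1 two-tailed, 0.5 one-tailed).
#'
#' @param x,y numeric samples (equal lengths >= 2 when `paired`).
#' @param tails 1 or 2.
#' @param paired logical.
#' @param alternative for `tails = 1`: `"greater"` tests mean(x) > mean(y).
#' @param var_equal pooled-variance Student t (default) or Welch.
#' @return One-row `data.frame` with `test`, `tails`, `paired`,
#'   `statistic`, `df`, `p`.
#' @examples
#' two_sample_t(c(1, 2, 3), c(1, 2, 3), paired = TRUE)$p  # 1
#' @export
two_sample_t <- function(x, y, tails = 2L, paired = FALSE,
                         alternative = c("greater", "less"),
                         var_equal = TRUE) {
  stopifnot(tails %in% c(1L, 2L), length(x) >= 2, length(y) >= 2,
            !paired || length(x) == length(y))
  alternative <- if (tails == 2L) "two.sided" else match.arg(alternative)
  res <- tryCatch(
    t.test(x, y, alternative = alternative, paired = paired,
           var.equal = var_equal),
    error = function(e) NULL)
  if (!is.null(res) && is.nan(res$statistic)) res <- NULL
  if (is.null(res)) {  # zero-variance degenerate case
    md <- mean(x) - mean(y)
    stat <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) {
      if (tails == 2L) 1 else 0.5
    } else if (tails == 2L) 0 else if (
      (alternative == "greater") == (md > 0)) 0 else 1
    df <- if (paired) length(x) - 1 else length(x) + length(y) - 2
    return(data.frame(test = "Student t (degenerate)", tails = tails,
                      paired = paired, statistic = stat, df = df, p = p))
  }
  data.frame(test = if (paired) "paired Student t"
             else if (var_equal) "Student t (pooled)" else "Welch t",
             tails = tails, paired = paired,
             statistic = unname(res$statistic), df = unname(res$parameter),
             p = res$p.value)
}

# minimal focus volume in voxels equivalent to `um3` on a given grid
min_voxels_for_volume <- function(um3, voxel_size_nm) {
  max(1L, as.integer(round(um3 / voxel_volume(voxel_size_nm))))
}

#' Default configuration for a synthetic foci experiment
#'
#' Study layout mirroring a damage-response imaging series: two genotypes
#' imaged at 0 min, 30 min, 3 h and 6 h after damage induction, three
#' independent experiments, ~6 analysable nuclei per stack.  Expected
#' gamma-H2AX counts per nucleus follow fast induction and gradual decay;
#' `effect` multiplies the second genotype's counts (1 = null scenario).
#' Stacks are generated at a reduced 150 x 150 x 300 nm grid so a full
#' experiment stays light; the minimal focus sizes are rescaled to the
#' reference physical volumes (0.022 um^3 and 10/50 of that ratio).
#'
#' @param n_experiments,timepoints,genotypes design.
#' @param mean_foci expected gamma-H2AX foci per nucleus per time point.
#' @param effect fold applied to genotype 2's expected counts.
#' @param coloc_prob probability a DSB focus carries the second marker.
#' @param n_nuclei,stack_shape,voxel_size_nm,nucleus_radii_um,focus_sigma_um
#'   phantom geometry.
#' @param deconvolve run Richardson-Lucy before detection.
#' @param seed master seed.
#' @return Named list of class `foci_experiment_config`.
#' @export
foci_experiment_config <- function(n_experiments = 3L,
                                   timepoints = c("0min", "30min", "3h", "6h"),
                                   genotypes = c("WT", "null"),
                                   mean_foci = c(4, 18, 10, 5),
                                   effect = 1,
                                   coloc_prob = 0.5,
                                   n_nuclei = 6L,
                                   stack_shape = c(24L, 220L, 220L),
                                   voxel_size_nm = c(300, 150, 150),
                                   nucleus_radii_um = c(1.8, 3, 3),
                                   focus_sigma_um = 0.25,
                                   deconvolve = FALSE,
                                   seed = 1L) {
  stopifnot(length(mean_foci) == length(timepoints), length(genotypes) == 2)
  structure(list(n_experiments = n_experiments, timepoints = timepoints,
                 genotypes = genotypes, mean_foci = mean_foci,
                 effect = effect, coloc_prob = coloc_prob,
                 n_nuclei = n_nuclei, stack_shape = stack_shape,
                 voxel_size_nm = voxel_size_nm,
                 nucleus_radii_um = nucleus_radii_um,
                 focus_sigma_um = focus_sigma_um,
                 deconvolve = deconvolve, seed = seed),
            class = "foci_experiment_config")
}

#' Run a synthetic two-genotype foci time-course experiment
#'
#' Generates phantoms for every experiment x genotype x time point cell of
#' the design, quantifies each stack ([quantify_stack()]), summarises
#' per-cell records per condition and tests genotype differences per time
#' point at both levels of replication: cell-level (cells pooled across
#' experiments, two-tailed unpaired Student t) and experiment-level
#' (per-experiment means, n = `n_experiments`).  Because which level the
#' "n" of a figure refers to is often ambiguous, both are reported, plus a
#' Holm-corrected column across time points for the cell-level tests.
#' Identical config and seed reproduce the report bit-identically.
#'
#' @param config a [foci_experiment_config()].
#' @return List of class `foci_experiment_report`: `summaries` (one row
#'   per genotype x time point), `cell_tests`, `experiment_tests`,
#'   `records`, `config`.
#' @export
run_foci_experiment <- function(config = foci_experiment_config()) {
  stopifnot(inherits(config, "foci_experiment_config"))
  cfg <- config
  mv_gh <- min_voxels_for_volume(0.022, cfg$voxel_size_nm)
  mv_sm <- min_voxels_for_volume(0.022 * 10 / 50, cfg$voxel_size_nm)
  records <- list()
  run <- 0L
  for (e in seq_len(cfg$n_experiments))
    for (gi in 1:2)
      for (ti in seq_along(cfg$timepoints)) {
        run <- run + 1L
        m <- cfg$mean_foci[ti] * if (gi == 2) cfg$effect else 1
        p <- foci_phantom_params(
          stack_shape = cfg$stack_shape,
          voxel_size_nm = cfg$voxel_size_nm,
          n_nuclei = cfg$n_nuclei,
          nucleus_radii_um = cfg$nucleus_radii_um,
          n_gh2ax = function(n) rpois(n, m),
          coloc_prob = cfg$coloc_prob,
          extra_smc6 = 2L,
          focus_sigma_um = cfg$focus_sigma_um,
          seed = child_seed(cfg$seed, run))
        q <- quantify_stack(gen_foci_stack(p)$stack,
                            min_voxels = c(gh2ax = mv_gh, smc6 = mv_sm),
                            deconvolve = cfg$deconvolve)
        r <- q$records
        if (nrow(r)) {
          r$experiment <- e
          r$genotype <- cfg$genotypes[gi]
          r$timepoint <- cfg$timepoints[ti]
          records[[run]] <- r
        }
      }
  records <- do.call(rbind, records)

  summaries <- list(); cell_tests <- list(); exp_tests <- list()
  for (ti in seq_along(cfg$timepoints)) {
    tp <- cfg$timepoints[ti]
    sel <- records[records$timepoint == tp & records$selected, ]
    for (g in cfg$genotypes)
      summaries[[length(summaries) + 1L]] <-
        summarize_condition(records[records$timepoint == tp &
                                      records$genotype == g, ],
                            genotype = g, timepoint = tp)
    x <- sel$n_gh2ax[sel$genotype == cfg$genotypes[1]]
    y <- sel$n_gh2ax[sel$genotype == cfg$genotypes[2]]
    if (length(x) >= 2 && length(y) >= 2) {
      ct <- two_sample_t(x, y, tails = 2L)
      ct$timepoint <- tp; ct$level <- "cell"
      cell_tests[[length(cell_tests) + 1L]] <- ct
    }
    ex <- vapply(seq_len(cfg$n_experiments), function(e) c(
      mean(sel$n_gh2ax[sel$experiment == e &
                         sel$genotype == cfg$genotypes[1]]),
      mean(sel$n_gh2ax[sel$experiment == e &
                         sel$genotype == cfg$genotypes[2]])),
      numeric(2))
    if (cfg$n_experiments >= 2 && all(is.finite(ex))) {
      et <- two_sample_t(ex[1, ], ex[2, ], tails = 2L)
      et$timepoint <- tp; et$level <- "experiment"
      exp_tests[[length(exp_tests) + 1L]] <- et
    }
  }
  cell_tests <- do.call(rbind, cell_tests)
  if (!is.null(cell_tests))
    cell_tests$p_holm <- stats::p.adjust(cell_tests$p, method = "holm")
  structure(list(summaries = do.call(rbind, summaries),
                 cell_tests = cell_tests,
                 experiment_tests = do.call(rbind, exp_tests),
                 records = records, config = cfg),
            class = "foci_experiment_report")
}

#' @export
print.foci_experiment_report <- function(x, ...) {
  cat("foci_experiment_report\n\nCondition summaries:\n")
  print(x$summaries, digits = 3)
  if (!is.null(x$cell_tests)) {
    cat("\nCell-level tests (two-tailed unpaired Student t):\n")
    print(x$cell_tests[, c("timepoint", "statistic", "df", "p", "p_holm")],
          digits = 3)
  }
  if (!is.null(x$experiment_tests)) {
    cat("\nExperiment-level tests:\n")
    print(x$experiment_tests[, c("timepoint", "statistic", "df", "p")],
          digits = 3)
  }
  invisible(x)
}

#' End-to-end demonstration on freshly generated synthetic data
#'
#' Runs every stage of the package on synthetic data derived from one
#' master seed: a two-genotype foci imaging experiment (with and without
#' an induced effect), a deconvolution sanity check, clonogenic survival
#' curves for a sensitive and a resistant line, a colcemid depletion
#' series, division-interval statistics, and CRISPR verification on a
#' synthetic amplicon.  Embedded assertions check the structural
#' invariants of each stage (S(0) = 1, fragment conservation, count
#' consistency); problem sizes are kept small enough for the full demo to
#' run in minutes on one CPU.
#'
#' @param master_seed integer seed driving every stage.
#' @param n_experiments experiments per arm of the imaging stage.
#' @return List of stage reports (invisibly printable), with the seed and
#'   stage parameters echoed.
#' @export
run_full_demo <- function(master_seed = 1L, n_experiments = 2L) {
  seeds <- function(k) child_seed(master_seed, k)

  # --- imaging + foci quantification -----------------------------------
  foci_null <- run_foci_experiment(foci_experiment_config(
    n_experiments = n_experiments, timepoints = c("30min", "3h"),
    mean_foci = c(15, 8), effect = 1, n_nuclei = 4L,
    stack_shape = c(20L, 180L, 180L), seed = seeds(1)))
  foci_eff <- run_foci_experiment(foci_experiment_config(
    n_experiments = n_experiments, timepoints = c("30min", "3h"),
    mean_foci = c(15, 8), effect = 1.5, n_nuclei = 4L,
    stack_shape = c(20L, 180L, 180L), seed = seeds(2)))
  stopifnot(all(foci_null$records$n_overlap <= foci_null$records$n_gh2ax))

  # --- deconvolution sanity check --------------------------------------
  vox <- c(300, 150, 150)
  psf <- make_gaussian_psf(0.15, 0.35, vox)
  blob <- array(0, c(16, 48, 48))
  blob[8, 24, 24] <- 100
  blurred <- fft_convolve3(pad_reflect3(blob, c(2, 4, 4)), psf$kernel)
  blurred <- blurred[2 + 1:16, 4 + 1:48, 4 + 1:48]
  dim(blurred) <- dim(blob)
  restored <- richardson_lucy(pmax(blurred, 0), psf, max_iter = 40)
  deconv <- list(peak_blurred = max(blurred), peak_restored = max(restored),
                 iterations = attr(restored, "iterations"))
  stopifnot(deconv$peak_restored > deconv$peak_blurred)

  # --- clonogenic survival ---------------------------------------------
  doses <- c(0, 1, 2, 4, 8)
  wt_tab <- gen_colony_counts(0.75, 0.25, 0.03, doses, 400,
                              replicates = 3, genotype = "WT",
                              seed = seeds(3))
  nl_tab <- gen_colony_counts(0.25, 0.6, 0.05, doses, 400,
                              replicates = 3, genotype = "null",
                              seed = seeds(4))
  wt_curve <- relative_survival(wt_tab)
  nl_curve <- relative_survival(nl_tab)
  stopifnot(abs(wt_curve$points$relative_survival[1] - 1) < 1e-12,
            abs(nl_curve$points$relative_survival[1] - 1) < 1e-12)
  surv_tests <- compare_survival(wt_curve, nl_curve, direction = "greater")

  # --- cell cycle -------------------------------------------------------
  ser <- gen_colcemid_series(f0 = 0.5, residual = 0.16, tau = 24,
                             n_events = 4000, seed = seeds(5))
  colc <- colcemid_depletion(ser$samples, ser$times)
  tracks <- gen_division_tracks(24, 1.37, cv = 0.15, n_cells = 50,
                                n_generations = 3, seed = seeds(6))
  divs <- division_stats(tracks[[1]], tracks[[2]])

  # --- CRISPR verification ---------------------------------------------
  crispr <- demo_crispr_report(seed = seeds(7))

  out <- list(master_seed = master_seed,
              foci_null_scenario = foci_null,
              foci_effect_scenario = foci_eff,
              deconvolution = deconv,
              survival = list(WT = wt_curve, null = nl_curve,
                              tests = surv_tests),
              colcemid = colc,
              divisions = divs,
              crispr = crispr)
  class(out) <- "full_demo_report"
  out
}

# synthetic-amplicon CRISPR verification: builds a 417-bp template
# (labelled synthetic; the real genomic sequence is not bundled) carrying
# the two guide target sites and the primer pair such that the first
# guide's cut splits the amplicon into 304 + 113 bp, then runs the full
# verification chain.
demo_crispr_report <- function(seed = 1L,
                               guides = c("TTCCAAGCCTGTATCAACTC",
                                          "AGCCTGTATCAACTCTGGTA"),
                               fwd_primer = "AATTTCAAGATGCCAGGACGT",
                               rev_primer = "GGATCTTCAAATCTTTGCCCAT",
                               amplicon_length = 417L,
                               cut_site = 304L) {
  set.seed(as.integer(seed))
  # guide 2 overlaps guide 1 shifted by 5 nt in the real locus; embed the
  # merged 25-nt region + NGG PAM so both guides hit
  region <- paste0(guides[1], substr(guides[2], 16, 20), "TGG")
  g1_start <- cut_site - 16L  # plus-strand hit => cut at start + 16
  pre_len <- g1_start - 1L - nchar(fwd_primer)
  post_len <- amplicon_length - (g1_start + nchar(region) - 1L) -
    nchar(rev_primer)
  stopifnot(pre_len >= 0, post_len >= 0)
  rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  template <- paste0(fwd_primer, rand_dna(pre_len), region,
                     rand_dna(post_len), rc(rev_primer))
  # regenerate until accidental extra guide/primer matches are absent
  for (try in 1:50) {
    ok <- nrow(find_protospacer(template, guides[1])) == 1 &&
      nrow(find_protospacer(template, guides[2])) == 1
    amp <- tryCatch(in_silico_pcr(template, fwd_primer, rev_primer),
                    error = function(e) NULL)
    if (ok && !is.null(amp)) break
    template <- paste0(fwd_primer, rand_dna(pre_len), region,
                       rand_dna(post_len), rc(rev_primer))
  }
  hits1 <- find_protospacer(amp$seq, guides[1])
  hits2 <- find_protospacer(amp$seq, guides[2])
  frags <- predict_fragments(amp$length, hits1$cut_site[1])
  stopifnot(sum(frags) == amp$length)
  # band intensities for a cut fraction of 0.3144 (fragment molarities)
  surv <- indel_fraction(a = 6856, b = 1572, c = 1572)
  list(template = template, amplicon = amp,
       guide_hits = list(hits1, hits2),
       fragments = frags, surveyor = surv)
}
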