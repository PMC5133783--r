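# coerce a sequence argument (character, DNAString, or single-sequence
# FASTA path is NOT accepted here -- see read_template) to an uppercase
# ACGT character string
as_dna_chr <- function(x, what = "sequence") {
  if (inherits(x, "DNAString") || inherits(x, "DNAStringSet"))
    x <- as.character(x)
  if (length(x) != 1 || !is.character(x)) stop(what, " must be one sequence")
  x <- toupper(x)
  if (grepl("[^ACGT]", x)) stop(what, " contains non-ACGT characters")
  x
}

rc <- function(x) as.character(Biostrings::reverseComplement(
  Biostrings::DNAString(x)))

#' Read a template sequence from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning the first
#' (or named) record as an uppercase character string for use with
#' [find_protospacer()] and [in_silico_pcr()].
#'
#' @param path FASTA file path.
#' @param which record index or name (default: first).
#' @return Character scalar sequence.
#' @export
read_template <- function(path, which = 1L) {
  ss <- Biostrings::readDNAStringSet(path)
  if (!length(ss)) stop("no sequences in ", path)
  toupper(as.character(ss[[which]]))
}

#' Locate protospacers matched by a 20-nt guide
#'
#' Finds exact matches of the guide on both strands of a template that are
#' immediately followed (3' on the protospacer strand) by a valid PAM:
#' 5'-NGG, or additionally 5'-NAG when `allow_nag = TRUE`.  SpCas9 cleaves
#' bluntly 3 bp 5' of the PAM, i.e. between protospacer positions 17 and
#' 18; the reported `cut_site` is the number of template bases 5' (in
#' forward-strand coordinates) of the cut, so it equals the length of the
#' 5' fragment when the template is an amplicon.
#'
#' @param template template DNA (character or `DNAString`), uppercase ACGT.
#' @param guide 20-nt guide sequence (the protospacer, without PAM).
#' @param allow_nag also accept the weaker NAG alternative PAM.
#' @return `data.frame` with one row per hit: `strand` (`"+"`/`"-"`),
#'   `start` (1-based forward-strand position of the protospacer's first
#'   base), `pam`, `cut_site`.  Zero rows when the guide does not match.
#' @examples
#' g <- "TTCCAAGCCTGTATCAACTC"
#' find_protospacer(paste0(g, "AGG"), g)  # one + hit, cut_site 17
#' @export
find_protospacer <- function(template, guide, allow_nag = FALSE) {
  template <- as_dna_chr(template, "template")
  guide <- as_dna_chr(guide, "guide")
  if (nchar(guide) != 20) stop("guide must be 20 nt")
  pam_ok <- function(p) nchar(p) == 3 &&
    (substr(p, 2, 3) == "GG" || (allow_nag && substr(p, 2, 3) == "AG"))
  tpl <- Biostrings::DNAString(template)
  L <- nchar(template)
  hits <- list()

  m <- Biostrings::matchPattern(guide, tpl)
  for (s in Biostrings::start(m)) {
    pam <- substr(template, s + 20, s + 22)
    if (pam_ok(pam))
      hits[[length(hits) + 1L]] <- data.frame(
        strand = "+", start = s, pam = pam, cut_site = s + 16L)
  }
  m <- Biostrings::matchPattern(rc(guide), tpl)
  for (s in Biostrings::start(m)) {
    if (s < 4) next
    pam <- rc(substr(template, s - 3, s - 1))
    if (pam_ok(pam))
      hits[[length(hits) + 1L]] <- data.frame(
        strand = "-", start = s, pam = pam, cut_site = s + 2L)
  }
  if (!length(hits))
    return(data.frame(strand = character(), start = integer(),
                      pam = character(), cut_site = integer()))
  out <- do.call(rbind, hits)
  out[order(out$start), , drop = FALSE]
}

#' Predicted Surveyor cleavage fragment lengths
#'
#' An amplicon cut at `cut_site` (bases 5' of the cut) yields fragments of
#' `cut_site` and `amplicon_length - cut_site` base pairs; they always sum
#' to the amplicon length.
#'
#' @param amplicon_length total amplicon length in bp.
#' @param cut_site cut position, strictly inside the amplicon.
#' @return Named numeric `c(len5 = , len3 = )`.
#' @examples
#' predict_fragments(417, 304)  # 304 and 113 bp
#' @export
predict_fragments <- function(amplicon_length, cut_site) {
  stopifnot(cut_site > 0, cut_site < amplicon_length)
  c(len5 = as.numeric(cut_site),
    len3 = as.numeric(amplicon_length - cut_site))
}

#' Surveyor indel estimate from band intensities
#'
#' Given the integrated intensities of the uncleaved band `a` and the two
#' cleavage bands `b` and `c`, the cut fraction is
#' \eqn{f_{cut} = (b + c) / (a + b + c)} and the indel frequency follows
#' the standard reannealing correction
#' \eqn{indel = 100 (1 - \sqrt{1 - f_{cut}})}: only heteroduplexes between
#' a mutant and a different strand are cleaved, so the observed cut
#' fraction understates the allele-level indel frequency.
#'
#' @param a uncleaved band intensity (>= 0).
#' @param b,c cleavage band intensities (>= 0); `a + b + c > 0`.
#' @return List of class `surveyor_result` with `a`, `b`, `c`,
#'   `cut_fraction` and `indel_percent` (clamped to `[0, 100]`).
#' @examples
#' indel_fraction(6856, 1572, 1572)$indel_percent  # 17.2
#' @export
indel_fraction <- function(a, b, c) {
  stopifnot(a >= 0, b >= 0, c >= 0, a + b + c > 0)
  fcut <- (b + c) / (a + b + c)
  indel <- 100 * (1 - sqrt(max(0, 1 - fcut)))
  structure(list(a = a, b = b, c = c, cut_fraction = fcut,
                 indel_percent = min(100, max(0, indel))),
            class = "surveyor_result")
}

#' @export
print.surveyor_result <- function(x, ...) {
  cat(sprintf("surveyor_result: cut fraction %.4f -> indel %.1f%%\n",
              x$cut_fraction, x$indel_percent))
  invisible(x)
}

#' In-silico PCR with exact primer matching
#'
#' Predicts the amplicon from a primer pair on a template: the forward
#' primer binds the forward strand and the reverse primer binds the
#' reverse strand (i.e. its reverse complement appears downstream on the
#' forward strand).  A reverse primer accidentally supplied already
#' reverse-complemented is also recognised.  Matching is exact -- this is a
#' verification tool, not a primer-design tool -- and exactly one product
#' must exist.
#'
#' @param template template DNA (character or `DNAString`).
#' @param fwd_primer,rev_primer primer sequences, >= 15 nt.
#' @return List with `seq` (amplicon, forward strand), `start`, `end`
#'   (1-based template coordinates) and `length`.
#' @export
in_silico_pcr <- function(template, fwd_primer, rev_primer) {
  template <- as_dna_chr(template, "template")
  fwd <- as_dna_chr(fwd_primer, "fwd_primer")
  rev <- as_dna_chr(rev_primer, "rev_primer")
  if (nchar(fwd) < 15 || nchar(rev) < 15) stop("primers must be >= 15 nt")
  tpl <- Biostrings::DNAString(template)
  fs <- Biostrings::start(Biostrings::matchPattern(fwd, tpl))
  if (!length(fs)) stop("no product: forward primer not found")
  # reverse primer: normal orientation (rc appears on forward strand) or
  # already reverse-complemented by the caller
  re <- Biostrings::end(Biostrings::matchPattern(rc(rev), tpl))
  if (!length(re))
    re <- Biostrings::end(Biostrings::matchPattern(rev, tpl))
  if (!length(re)) stop("no product: reverse primer not found")
  prods <- expand.grid(s = fs, e = re)
  prods <- prods[prods$s < prods$e, , drop = FALSE]
  if (nrow(prods) == 0) stop("no product: primers do not face each other")
  if (nrow(prods) > 1) stop(nrow(prods), " alternative products; ",
                            "primers are not specific on this template")
  s <- prods$s[1]; e <- prods$e[1]
  list(seq = substr(template, s, e), start = s, end = e,
       length = e - s + 1L)
}
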