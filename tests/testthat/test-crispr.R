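test_that("protospacer search applies the PAM rule on both strands", {
  g <- "TTCCAAGCCTGTATCAACTC"

  hit <- find_protospacer(paste0(g, "AGG"), g)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$strand, "+")
  expect_identical(hit$cut_site, 17L)

  # guide present but PAM invalid: no hit; NAG accepted only when allowed
  expect_identical(nrow(find_protospacer(paste0(g, "ATT"), g)), 0L)
  expect_identical(nrow(find_protospacer(paste0(g, "TAG"), g)), 0L)
  expect_identical(nrow(find_protospacer(paste0(g, "TAG"), g,
                                         allow_nag = TRUE)), 1L)

  # reverse-complemented construct: one minus-strand hit
  tpl <- paste0("AAAA", g, "AGG", "TTTT")
  rtpl <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tpl)))
  hit_m <- find_protospacer(rtpl, g)
  expect_identical(hit_m$strand, "-")
  # coordinates transform consistently under reverse complement
  expect_identical(hit_m$cut_site, nchar(tpl) - find_protospacer(tpl, g)$cut_site)
})

test_that("cleavage fragments partition the amplicon", {
  expect_equal(predict_fragments(417, 304), c(len5 = 304, len3 = 113))
  expect_equal(predict_fragments(100, 50), c(len5 = 50, len3 = 50))
  for (cs in c(1, 57, 211, 416))
    expect_equal(sum(predict_fragments(417, cs)), 417)
  expect_error(predict_fragments(417, 0))
  expect_error(predict_fragments(417, 417))
})

test_that("surveyor indel formula has the right shape and endpoints", {
  expect_equal(indel_fraction(100, 0, 0)$indel_percent, 0)
  expect_equal(indel_fraction(0, 50, 50)$indel_percent, 100)
  # cut fraction 0.3144 -> 17.2% indels
  r <- indel_fraction(6856, 1572, 1572)
  expect_equal(r$cut_fraction, 0.3144)
  expect_equal(round(r$indel_percent, 1), 17.2)

  # monotone in cut fraction, and round-trip identity to 1e-12
  fcut <- seq(0.01, 0.99, by = 0.01)
  ind <- vapply(fcut, function(f)
    indel_fraction(1 - f, f / 2, f / 2)$indel_percent, 0)
  expect_true(all(diff(ind) > 0))
  back <- 1 - (1 - ind / 100)^2
  expect_equal(back, fcut, tolerance = 1e-12)
})

test_that("in-silico PCR finds the unique facing-primer product", {
  set.seed(77)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
  fwd <- "AATTTCAAGATGCCAGGACGT"
  rev <- "GGATCTTCAAATCTTTGCCCAT"
  rev_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev)))
  insert <- rand(150)
  tpl <- paste0(rand(60), fwd, insert, rev_rc, rand(40))

  amp <- in_silico_pcr(tpl, fwd, rev)
  expect_identical(amp$length, nchar(fwd) + 150L + nchar(rev))
  expect_identical(substr(amp$seq, 1, nchar(fwd)), fwd)

  # reverse primer given already reverse-complemented still works
  amp2 <- in_silico_pcr(tpl, fwd, rev_rc)
  expect_identical(amp2$seq, amp$seq)

  # absent primer: "no product" error
  expect_error(in_silico_pcr(tpl, fwd, paste0(rand(22))), "no product")
  # non-unique product: descriptive error
  tpl2 <- paste0(tpl, rand(20), rev_rc)
  expect_error(in_silico_pcr(tpl2, fwd, rev), "products")
})

test_that("FASTA template round trip feeds the verification chain", {
  g <- "AGCCTGTATCAACTCTGGTA"
  tpl <- paste0("GATTACAGATTACAGATTACA", g, "CGGTTTTACGCTGACGT")
  path <- tempfile(fileext = ".fa")
  on.exit(unlink(path))
  writeLines(c(">synthetic_template", tpl), path)
  seq <- read_template(path)
  expect_identical(seq, tpl)
  hit <- find_protospacer(seq, g)
  expect_identical(hit$cut_site, 21L + 17L)
})
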