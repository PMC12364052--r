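test_that("log-KD affinity scale reproduces the published conversions", {
  expect_equal(affinity_from_kd(4e-8, 4e-8), 0)
  # ceiling Ka 1e10 /M (KD 1e-10 M) and threshold Ka 1e6 /M against the
  # naive KD of 40 nM
  expect_equal(affinity_from_kd(1e-10, 4e-8), 2.6, tolerance = 0.01)
  expect_equal(affinity_from_kd(1e-6, 4e-8), -1.4, tolerance = 0.01)
  expect_error(affinity_from_kd(-1e-9, 4e-8), "positive")
  expect_error(affinity_from_kd(1e-9, 0), "positive")
})

test_that("affinity_from_kd is strictly decreasing and inverts exactly", {
  kds <- 10^seq(-12, -4, length.out = 40)
  x <- affinity_from_kd(kds, 4e-8)
  expect_true(all(diff(x) < 0))
  expect_equal(kd_from_affinity(x, 4e-8), kds, tolerance = 1e-12)
})

test_that("translation matches Biostrings on random coding sequences", {
  withr::with_seed(11, {
    for (i in 1:20) {
      s <- paste0(sample(c("A", "C", "G", "T"), 3 * sample(5:40, 1),
                         replace = TRUE), collapse = "")
      expect_identical(
        translate_nt(s),
        as.character(Biostrings::translate(Biostrings::DNAString(s),
                                           no.init.codon = TRUE)))
    }
  })
  expect_error(translate_nt("ATGCC"), "divisible by 3")
  expect_error(translate_nt("ATGNNN"), "invalid nucleotide")
})

test_that("stop-codon detection flags all three stop codons", {
  expect_true(is_nonfunctional("ATGTAAGGG"))
  expect_true(is_nonfunctional("ATGTAGGGG"))
  expect_true(is_nonfunctional("ATGTGAGGG"))
  expect_false(is_nonfunctional("ATGGGGCCC"))
  fx <- fixture_inputs()
  expect_false(is_nonfunctional(fx$naive))
})

test_that("DMS affinity is additive over amino-acid differences", {
  fx <- fixture_inputs()
  naive <- fx$naive; dms <- fx$dms
  expect_equal(affinity_of_sequence(naive, naive, dms), 0)
  # single- and double-mutant hand sums
  codons <- strsplit(naive, "(?<=...)", perl = TRUE)[[1]]
  mk <- function(site, codon) {
    cs <- codons; cs[site] <- codon
    paste0(cs, collapse = "")
  }
  s1 <- mk(5, "TGG")  # -> W at site 5
  s2 <- mk(40, "CAT") # -> H at site 40
  e1 <- unname(dms$effects[5, "W"]); e2 <- unname(dms$effects[40, "H"])
  expect_equal(affinity_of_sequence(s1, naive, dms), e1)
  expect_equal(affinity_of_sequence(s2, naive, dms), e2)
  cs <- codons; cs[5] <- "TGG"; cs[40] <- "CAT"
  expect_equal(affinity_of_sequence(paste0(cs, collapse = ""), naive, dms),
               e1 + e2)
  # k-mutants equal the sum of their single-mutant effects
  withr::with_seed(12, {
    for (r in 1:10) {
      sites <- sample(seq_along(codons), 4)
      cs <- codons
      tot <- 0
      for (st in sites) {
        cod <- sample(c("TGG", "CAT", "AAA", "GAT"), 1)
        cs[st] <- cod
        aa <- translate_nt(cod)
        naive_aa <- substr(dms$naive_protein, st, st)
        if (aa != naive_aa) tot <- tot + unname(dms$effects[st, aa])
      }
      expect_equal(affinity_of_sequence(paste0(cs, collapse = ""), naive, dms),
                   tot)
    }
  })
  expect_error(affinity_of_sequence(substr(naive, 1, 297), naive, dms),
               "length")
})

test_that("synthetic DMS tables are complete, reproducible, and shaped", {
  fx <- fixture_inputs()
  d1 <- withr::with_seed(77, synth_dms(fx$naive))
  d2 <- withr::with_seed(77, synth_dms(fx$naive))
  expect_identical(d1, d2)
  L <- nchar(d1$naive_protein)
  naive_aa <- strsplit(d1$naive_protein, "")[[1]]
  aa20 <- colnames(d1$effects)
  expect_true(all(d1$effects[cbind(seq_len(L), match(naive_aa, aa20))] == 0))
  expect_true(all(is.finite(d1$effects)))
  d0 <- withr::with_seed(78, synth_dms(fx$naive, frac_beneficial = 0))
  expect_true(all(d0$effects <= 0))
  expect_error(synth_dms(fx$naive, frac_beneficial = 2), "frac_beneficial")
})

test_that("DMS CSV round-trips through the documented schema", {
  fx <- fixture_inputs()
  path <- withr::local_tempfile(fileext = ".csv")
  write_dms_csv(fx$dms, path)
  d2 <- read_dms_csv(path)
  expect_identical(d2$naive_protein, fx$dms$naive_protein)
  expect_equal(unname(d2$effects), unname(fx$dms$effects), tolerance = 1e-6)
  # incomplete tables are rejected
  lines <- readLines(path)
  writeLines(lines[-5], path)
  expect_error(read_dms_csv(path), "incomplete")
})
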