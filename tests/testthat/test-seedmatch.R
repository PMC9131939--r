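# Seed patterns, KMP search and UTR site scanning with context features.

let7 <- mature_mirna("let-7", "UGAGGUAGUAGGUUGUAUAGUU")

test_that("mature miRNA validation and normalization", {
  expect_equal(mature_mirna("x", "tgaggtag")$sequence, "UGAGGUAG")
  expect_error(mature_mirna("x", "UGAGGUA"), ">= 8")
  expect_error(mature_mirna("x", "UGAGGUAX"), "A/C/G/U")
})

test_that("seed patterns are the reverse complements of the seed", {
  pats <- seed_patterns(let7)
  expect_equal(pats[["7mer-m8"]], "CUACCUC")
  expect_equal(pats[["8mer"]], "CUACCUCA")
  expect_equal(pats[["7mer-A1"]], "UACCUCA")
  expect_equal(pats[["6mer"]], "UACCUC")
  # DNA-alphabet input normalizes to the same patterns
  expect_equal(seed_patterns(mature_mirna("d", "TGAGGTAGTAGGTTGTATAGTT")),
               pats)
  expect_error(mature_mirna("x", "UGAGGUA"), ">= 8")
})

test_that("prefix function matches brute-force borders", {
  expect_equal(kmp_prefix_function("AABAACAABAA"),
               c(0, 1, 0, 1, 2, 0, 1, 2, 3, 4, 5))
  expect_error(kmp_prefix_function(""), "nonempty")
  withr::with_seed(11, {
    for (k in 1:50) {
      pat <- paste(sample(c("A", "B"), sample(1:12, 1), replace = TRUE),
                   collapse = "")
      expect_equal(kmp_prefix_function(pat), naive_borders(pat), info = pat)
    }
  })
})

test_that("KMP finds all overlapping occurrences", {
  expect_equal(kmp_search("ACA", "ACACACA"), c(1L, 3L, 5L))
  expect_equal(kmp_search("ACGUACGU", "ACG"), integer(0))
  expect_error(kmp_search("", "ACGU"), "nonempty")
  expect_equal(kmp_search("acgu", "TACGTT"), 2L)  # case and U/T equivalence
})

test_that("KMP equals naive search on random pairs including periodic", {
  withr::with_seed(99, {
    for (k in 1:1000) {
      if (k %% 5 == 0) {
        unit <- paste(sample(c("A", "C", "G", "U"), sample(1:3, 1),
                             replace = TRUE), collapse = "")
        pat <- strrep(unit, sample(1:4, 1))  # periodic patterns
      } else {
        pat <- paste(sample(c("A", "C", "G", "U"), sample(1:8, 1),
                            replace = TRUE), collapse = "")
      }
      txt <- paste(sample(c("A", "C", "G", "U"), sample(0:60, 1),
                          replace = TRUE), collapse = "")
      expect_identical(kmp_search(pat, txt), naive_search(pat, txt))
    }
  })
})

test_that("site scanning classifies types with precedence", {
  pats <- seed_patterns(let7)
  base <- strrep("G", 100)
  with8 <- paste0(substr(base, 1, 49), pats[["8mer"]],
                  substr(base, 1, 100 - 49 - 8))
  hits <- scan_utr(let7, stats::setNames(with8, "u1"), include_6mer = TRUE)
  expect_equal(nrow(hits), 1)  # the 8mer consumes its 7mer/6mer sub-hits
  expect_equal(hits$start, 50)
  expect_equal(hits$end, 57)
  expect_equal(hits$site_type, "8mer")

  clean <- scan_utr(let7, stats::setNames(strrep("G", 80), "u2"),
                    include_6mer = TRUE)
  expect_equal(nrow(clean), 0)

  # 6mer only reported when asked
  with6 <- paste0("GGGG", pats[["6mer"]], "GGGGC")
  expect_equal(nrow(scan_utr(let7, c(u3 = with6))), 0)
  expect_equal(scan_utr(let7, c(u3 = with6), include_6mer = TRUE)$site_type,
               "6mer")
})

test_that("context features measure AU content, distance and 3' pairing", {
  pats <- seed_patterns(let7)
  # site at 10-16 (7mer-m8); G background cannot pair miRNA 13-16 (UUGU)
  utr <- paste0(strrep("G", 9), pats[["7mer-m8"]], strrep("G", 84))
  site <- data.frame(start = 10, end = 16, site_type = "7mer-m8")
  f <- context_features(site, let7, utr)
  expect_equal(f$distance_to_end, 9)
  expect_equal(f$supp_pairing, 0)

  au_utr <- paste0(strrep("A", 9), pats[["7mer-m8"]], strrep("U", 84))
  fa <- context_features(site, let7, au_utr)
  expect_equal(fa$local_au, 1)

  # place complements of miRNA positions 13-16 opposite them: for a
  # 7mer-m8 ending at e, position 1 sits opposite e+1, so miRNA k pairs
  # the UTR base at e + 2 - k; with the site at 43-49 that is 35-38
  ms <- strsplit(let7$sequence, "")[[1]]
  comp <- chartr("ACGU", "UGCA", paste(rev(ms[13:16]), collapse = ""))
  utr3 <- paste0(strrep("G", 34), comp, strrep("G", 4), pats[["7mer-m8"]],
                 strrep("G", 40))
  site3 <- data.frame(start = 43, end = 49, site_type = "7mer-m8")
  f3 <- context_features(site3, let7, utr3)
  expect_equal(f3$supp_pairing, 4)

  expect_error(context_features(data.frame(start = 90, end = 120,
                                           site_type = "8mer"),
                                let7, utr), "outside")
})

test_that("score hierarchy orders site types for identical context", {
  pats <- seed_patterns(let7)
  score_of <- function(type) {
    pat <- pats[[type]]
    utr <- paste0(strrep("C", 40), pat, strrep("C", 40))
    site <- data.frame(start = 41, end = 40 + nchar(pat), site_type = type)
    context_features(site, let7, utr)$simple_context_score
  }
  s8 <- score_of("8mer"); s7m8 <- score_of("7mer-m8")
  s7a1 <- score_of("7mer-A1")
  expect_lt(s8, s7m8)
  expect_lt(s7m8, s7a1)
})

test_that("FASTA I/O round-trips UTR sets", {
  seqs <- c(u1 = "ACGUACGUACGU", u2 = "GGGCCCAAAUUU")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_utr_fasta(seqs, f)
  expect_equal(read_utr_fasta(f), seqs)
})
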