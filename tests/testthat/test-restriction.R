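test_that("cut coordinates follow the prefix-length convention", {
  enz <- clai()
  # motif at p = 3, cut offset 2 -> c = 3 + 2 - 1 = 4 (hand enumeration)
  expect_identical(find_cut_sites("AAATCGATAA", enz)$cut_coords, 4L)
  # no occurrence
  expect_identical(find_cut_sites("AAAAAAAAAA", enz)$cut_coords, integer(0))
  # sequence shorter than the motif: empty result, not an error
  expect_identical(find_cut_sites("ATC", enz)$cut_coords, integer(0))
  # a cut at c = 0 or c = L would create a zero-length fragment: discarded
  gaatt <- enzyme_spec("EcoRI", "GAATTC", 1)
  expect_identical(find_cut_sites("GAATTC", gaatt)$cut_coords, 1L)
  zero <- enzyme_spec("Blunt0", "GAATTC", 0)
  expect_identical(find_cut_sites("GAATTC", zero)$cut_coords, integer(0))
  endc <- enzyme_spec("Blunt6", "GAATTC", 6)
  expect_identical(find_cut_sites("GAATTC", endc)$cut_coords, integer(0))
})

test_that("IUPAC motif semantics: ambiguity in motif matches, in sequence never", {
  hinf <- enzyme_spec("HinfI", "GANTC", 1)       # N in motif
  expect_identical(find_cut_sites("AAGACTCAA", hinf)$cut_coords, 3L)
  expect_identical(find_cut_sites("AAGAGTCAA", hinf)$cut_coords, 3L)
  # N in the sequence must not satisfy the motif's N (or anything else)
  expect_identical(find_cut_sites("AAGANTCAA", hinf)$cut_coords, integer(0))
  expect_error(enzyme_spec("BadI", "ATXGAT", 2), "non-IUPAC")
})

test_that("non-palindromic motifs are also found on the bottom strand", {
  # BsrDI-like: GCAATG, not a palindrome; its revcomp CATTGC on the top
  # strand marks a bottom-strand site
  enz <- enzyme_spec("AsymI", "GCAATG", 2)
  expect_identical(find_cut_sites("TTGCAATGTT", enz)$cut_coords, 4L)
  # revcomp occurrence at p = 3: c = p + (6 - 2) - 1 = 6
  expect_identical(find_cut_sites("TTCATTGCTT", enz)$cut_coords, 6L)
})

test_that("digest fragments are successive cut differences and conserve length", {
  enz <- clai()
  pat <- digest("AAATCGATAA", enz)
  expect_identical(pat$fragments, c(4L, 6L))
  expect_equal(sum(pat$fragments), pat$length)
  # uncut variant: single full-length fragment
  expect_identical(digest("ACGTACGTAC", enz)$fragments, 10L)
})

test_that("scanner agrees with a regex oracle and conserves length on random sequences", {
  set.seed(301)
  enzymes <- load_enzymes()
  for (i in 1:60) {
    L <- sample(50:5000, 1)
    s <- rand_dna(L)
    enz <- enzymes[[sample(length(enzymes), 1)]]
    pat <- digest(s, enz)
    expect_identical(pat$cut_coords, regex_cut_sites(s, enz))
    expect_equal(sum(pat$fragments), L)
    expect_true(all(pat$fragments >= 1))
    expect_equal(length(pat$fragments), length(pat$cut_coords) + 1)
  }
})

test_that("band classification partitions fragments and flags diagnostics", {
  fx <- trio_fixture()
  bt <- fx$bands
  members <- attr(bt, "members")
  # partition: every fragment in exactly one class
  expect_equal(nrow(members), sum(lengths(lapply(fx$pats, `[[`, "fragments"))))
  expect_true(all(members$band %in% bt$band))
  # the published fingerprint: a:1968, b:1752, c:{1098, 654}, shared 207
  diag <- bt[bt$diagnostic, ]
  expect_setequal(diag$length, c(1968, 1752, 1098, 654))
  expect_equal(diag$variants[diag$length == 1968], "variant_a")
  expect_equal(diag$variants[diag$length == 1752], "variant_b")
  expect_setequal(diag$variants[diag$length %in% c(1098, 654)], "variant_c")
  shared <- bt[!bt$diagnostic, ]
  expect_equal(shared$length, 207)
  expect_equal(shared$variants, "variant_b,variant_c")
})

test_that("identical patterns give zero diagnostic bands", {
  enz <- clai()
  s <- "AAATCGATAAGG"
  pats <- digest(c(x = s, y = s), enz)
  bt <- classify_bands(pats, 0)
  expect_false(any(bt$diagnostic))
})

test_that("co-migration tolerance merges nearby lengths by single linkage", {
  enz <- enzyme_spec("FakeI", "ATCGAT", 2)
  pats <- list(
    structure(list(variant_id = "x", length = 1000L, cut_coords = integer(0),
                   fragments = 1000L), class = "digest_pattern"),
    structure(list(variant_id = "y", length = 1015L, cut_coords = integer(0),
                   fragments = 1015L), class = "digest_pattern")
  )
  # |1000 - 1015| / 1007.5 = 0.0149 <= 0.02 -> one shared class
  bt <- classify_bands(pats, 0.02)
  expect_equal(nrow(bt), 1)
  expect_false(bt$diagnostic)
  # at tolerance 0 they separate and become diagnostic by length alone
  bt0 <- classify_bands(pats, 0)
  expect_equal(nrow(bt0), 2)
  expect_true(all(bt0$diagnostic))
  expect_error(classify_bands(pats, 0.5), "tolerance")
  expect_error(classify_bands(list()), "no digest patterns")
})

test_that("enzyme screening ranks ClaI as fully discriminating the trio", {
  fx <- trio_fixture()
  res <- screen_enzymes(fx$trio, load_enzymes())
  expect_equal(res$score[res$enzyme == "ClaI"], 3)
  expect_true(res$full_discrimination[res$enzyme == "ClaI"])
  expect_equal(res$enzyme[1], "ClaI")  # nothing else cuts by construction
})

test_that("screening degenerate cases: uncut variants and single-site pairs", {
  enz <- enzyme_spec("NoCut", "GCGCGC", 3)
  # identical-length uncut variants: indistinguishable, score 0
  set.seed(77)
  a <- gsub("GCGCGC", "ATATAT", rand_dna(600))
  b <- gsub("GCGCGC", "ATATAT", rand_dna(600))
  expect_equal(screen_enzymes(c(v1 = a, v2 = b), list(enz))$score, 0)
  # distinct uncut lengths beyond tolerance ARE diagnostic
  expect_equal(
    screen_enzymes(c(v1 = a, v2 = substr(b, 1, 400)), list(enz))$score, 2)
  # one site present/absent -> both variants get a diagnostic band
  s1 <- paste0(strrep("A", 300), "ATCGAT", strrep("G", 300))
  s2 <- paste0(strrep("A", 300), "ATAGAT", strrep("G", 300))
  expect_equal(screen_enzymes(c(v1 = s1, v2 = s2), list(clai()))$score, 2)
  expect_error(screen_enzymes(c(v1 = s1, v2 = s2), list()), "empty enzyme")
  expect_error(screen_enzymes(c(v1 = s1), list(clai())), ">= 2 variants")
})
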