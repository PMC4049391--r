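# Independent oracles and fixture builders shared across test files.

IUPAC_REGEX <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

# Oracle for the motif scanner: overlapping matches via a perl lookahead
# regex, an entirely different engine from the package's vectorised scan.
# Ambiguity codes in the sequence must not match, which plain-base character
# classes guarantee.
regex_motif_starts <- function(seq, motif) {
  pat <- paste0("(?=", paste(IUPAC_REGEX[strsplit(motif, "")[[1]]],
                             collapse = ""), ")")
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

regex_cut_sites <- function(seq, enzyme) {
  m <- nchar(enzyme$recognition)
  cuts <- regex_motif_starts(seq, enzyme$recognition) + enzyme$cut_offset - 1L
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(enzyme$recognition)))
  if (!identical(rc, enzyme$recognition)) {
    cuts <- c(cuts,
              regex_motif_starts(seq, rc) + (m - enzyme$cut_offset) - 1L)
  }
  cuts <- sort(unique(cuts))
  cuts[cuts >= 1 & cuts <= nchar(seq) - 1]
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

clai <- function() enzyme_spec("ClaI", "ATCGAT", 2)

# The standard synthetic trio and its digest machinery, built once.
trio_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      trio <- make_paralog_set(seed = 11)
      pats <- digest(trio, clai())
      bands <- classify_bands(pats, tolerance = 0)
      M <- build_incidence(bands, pats)
      cache <<- list(trio = trio, pats = pats, bands = bands, M = M)
    }
    cache
  }
})
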