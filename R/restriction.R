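#' @title In-silico restriction digestion of sequence variants
#' @description
#' CAPS-style discrimination of near-identical coding-sequence variants:
#' locate restriction sites, predict the fragment pattern each variant gives
#' on a gel, and find the diagnostic bands that fingerprint each variant.
#'
#' Conventions: coordinates are 1-based; a cut at coordinate `c` splits the
#' sequence into `[1..c]` and `[c+1..L]`, so `c` equals the length of the
#' prefix fragment. For a motif match starting at position `p`,
#' `c = p + cut_offset - 1`. Digestion is of linear molecules (PCR
#' amplicons); partial digestion and circular templates are not modelled.
#' Palindromic motifs are scanned on the top strand only; non-palindromic
#' motifs are additionally scanned as their reverse complement with cut
#' coordinates mapped back to the top strand. IUPAC ambiguity codes in the
#' motif match the base set they denote; ambiguity codes in the *sequence*
#' never match (conservative for assay design).
#' @name restriction
NULL

# Normalise a variant to list(id=, seq=): accepts a character scalar
# (optionally named), a Biostrings::DNAString, or one element of a set.
as_variant <- function(x, id = NULL) {
  if (is.list(x) && !is.null(x$seq)) {
    if (is.null(id)) id <- x$id
    x <- x$seq
  }
  if (inherits(x, "DNAString") || inherits(x, "BString")) {
    x <- as.character(x)
  }
  if (!is.character(x) || length(x) != 1) {
    stop_usage("a sequence variant must be a single DNA string")
  }
  if (is.null(id)) {
    id <- if (!is.null(names(x))) names(x) else "variant"
  }
  seq <- toupper(gsub("[[:space:]]", "", unname(x)))
  if (!nzchar(seq)) stop_usage("sequence '%s' is empty", id)
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad)) {
    stop_usage("sequence '%s' has non-IUPAC character '%s' at position %d",
               id, chars[bad[1]], bad[1])
  }
  list(id = id, seq = seq)
}

# Coerce a collection of variants (DNAStringSet or named character vector)
# to a named list of list(id, seq).
as_variant_list <- function(x) {
  if (inherits(x, "XStringSet")) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("variant_", seq_along(x))
    x <- setNames(as.character(x), ids)
  }
  if (is.list(x) && all(vapply(x, function(v) is.list(v) && !is.null(v$seq),
                               logical(1)))) {
    return(x)
  }
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("variant_", seq_along(x))
  out <- lapply(seq_along(x), function(i) as_variant(x[[i]], ids[i]))
  names(out) <- ids
  out
}

# Positions (1-based starts) where `motif` (IUPAC) matches `seq` exactly on
# the given strand of characters. Vectorised over start positions.
scan_motif <- function(chars, motif) {
  m <- nchar(motif)
  n <- length(chars) - m + 1L
  if (n < 1L) return(integer(0))
  mot <- strsplit(motif, "")[[1]]
  ok <- rep(TRUE, n)
  for (j in seq_len(m)) {
    allowed <- IUPAC_SETS[[mot[j]]]   # plain bases only: ambiguity in the
    ok <- ok & chars[j:(j + n - 1L)] %in% allowed  # sequence never matches
  }
  which(ok)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

is_palindromic_motif <- function(motif) {
  identical(motif, revcomp_chr(motif))
}

#' Locate restriction cut sites in one variant
#'
#' @param variant A DNA sequence: character scalar, `DNAString`, or one
#'   element of a `DNAStringSet`.
#' @param enzyme An [enzyme_spec()].
#' @param id Optional variant id (defaults to the sequence's name).
#' @return A `digest_pattern` with `variant_id`, `length` and sorted,
#'   deduplicated 1-based `cut_coords`; `fragments` is `NULL` until
#'   [digest()] is applied. Cuts that would fall at coordinate 0 or L (which
#'   would create a zero-length fragment) are discarded. A sequence shorter
#'   than the motif yields no cuts.
#' @examples
#' clai <- enzyme_spec("ClaI", "ATCGAT", 2)
#' find_cut_sites("AAATCGATAA", clai)$cut_coords  # 4
#' @export
find_cut_sites <- function(variant, enzyme, id = NULL) {
  v <- as_variant(variant, id)
  if (!inherits(enzyme, "enzyme_spec")) {
    stop_usage("'enzyme' must be an enzyme_spec")
  }
  chars <- strsplit(v$seq, "")[[1]]
  L <- length(chars)
  m <- nchar(enzyme$recognition)
  cuts <- scan_motif(chars, enzyme$recognition) + enzyme$cut_offset - 1L
  if (!is_palindromic_motif(enzyme$recognition)) {
    # bottom-strand recognition: the top strand carries the reverse
    # complement; the top-strand cut sits cut_offset bases from the motif 3'
    rc <- revcomp_chr(enzyme$recognition)
    cuts <- c(cuts, scan_motif(chars, rc) + (m - enzyme$cut_offset) - 1L)
  }
  cuts <- sort(unique(cuts))
  cuts <- cuts[cuts >= 1L & cuts <= L - 1L]
  structure(
    list(variant_id = v$id, length = L, cut_coords = as.integer(cuts),
         fragments = NULL),
    class = "digest_pattern"
  )
}

#' Digest one or more variants with a restriction enzyme
#'
#' @param variants One variant (as in [find_cut_sites()]) or a collection
#'   (`DNAStringSet` or named character vector).
#' @param enzyme An [enzyme_spec()].
#' @return For a single variant, a `digest_pattern` whose `fragments` are the
#'   successive differences of `c(0, cut_coords, L)` (so they always sum to
#'   the sequence length); for a collection, a named list of patterns.
#' @examples
#' clai <- enzyme_spec("ClaI", "ATCGAT", 2)
#' digest(c(v1 = "AAATCGATAA"), clai)[["v1"]]$fragments  # 4 6
#' @export
digest <- function(variants, enzyme) {
  single_record <- is.list(variants) && !is.null(variants$seq)
  multi <- !single_record &&
    (inherits(variants, "XStringSet") ||
       (is.character(variants) && length(variants) > 1) ||
       is.list(variants))
  if (multi) {
    vs <- as_variant_list(variants)
    return(lapply(vs, digest, enzyme = enzyme))
  }
  pat <- find_cut_sites(variants, enzyme)
  pat$fragments <- as.integer(diff(c(0L, pat$cut_coords, pat$length)))
  stopifnot(sum(pat$fragments) == pat$length)
  pat
}

#' @export
print.digest_pattern <- function(x, ...) {
  cat(sprintf("<digest_pattern> %s (%d bp): %d cut(s)", x$variant_id,
              x$length, length(x$cut_coords)))
  if (length(x$cut_coords)) cat(" at", paste(x$cut_coords, collapse = ", "))
  if (!is.null(x$fragments)) {
    cat("\n  fragments:", paste(sort(x$fragments, decreasing = TRUE),
                                collapse = ", "), "bp")
  }
  cat("\n")
  invisible(x)
}

#' Cluster digest fragments into co-migrating gel band classes
#'
#' Fragments from all variants are clustered by single linkage on relative
#' length difference `|l1 - l2| / mean(l1, l2)`; clusters are cut at the
#' given tolerance, which approximates what an agarose gel can resolve
#' (default 2%). A band class is *diagnostic* when all its member fragments
#' come from a single variant, so its intensity reports on that variant
#' alone.
#'
#' @param patterns A list of `digest_pattern` objects (from [digest()]).
#' @param tolerance Relative length tolerance in `[0, 0.2]`; at 0 only
#'   exactly equal lengths co-migrate.
#' @return A `band_table`: data frame with one row per band class
#'   (`band`, `length` — the representative, i.e. mean, member length —
#'   `n_fragments`, `variants`, `diagnostic`, `detectable`), ordered by
#'   decreasing length, with the per-fragment membership in
#'   `attr(, "members")`. Bands shorter than 50 bp are flagged
#'   `detectable = FALSE` (likely lost on a standard gel).
#' @examples
#' clai <- enzyme_spec("ClaI", "ATCGAT", 2)
#' pats <- digest(make_paralog_set(seed = 1), clai)
#' classify_bands(pats)
#' @export
classify_bands <- function(patterns, tolerance = 0.02) {
  if (inherits(patterns, "digest_pattern")) patterns <- list(patterns)
  if (length(patterns) == 0) stop_usage("no digest patterns supplied")
  if (!all(vapply(patterns, inherits, logical(1), "digest_pattern"))) {
    stop_usage("'patterns' must be digest_pattern objects from digest()")
  }
  if (any(vapply(patterns, function(p) is.null(p$fragments), logical(1)))) {
    stop_usage("patterns carry no fragments; run digest(), not find_cut_sites()")
  }
  if (tolerance < 0 || tolerance > 0.2) {
    stop_usage("tolerance must lie in [0, 0.2]")
  }
  members <- do.call(rbind, lapply(patterns, function(p) {
    data.frame(variant_id = p$variant_id, length = p$fragments)
  }))
  rownames(members) <- NULL
  n <- nrow(members)
  if (n == 1) {
    members$band <- 1L
  } else {
    l <- members$length
    d <- abs(outer(l, l, "-")) / outer(l, l, function(a, b) (a + b) / 2)
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    members$band <- stats::cutree(hc, h = tolerance)
  }
  reps <- tapply(members$length, members$band, mean)
  ord <- order(-reps)                     # heavy bands first, gel-style
  relab <- setNames(seq_along(ord), names(reps)[ord])
  members$band <- unname(relab[as.character(members$band)])
  members <- members[order(members$band), , drop = FALSE]
  rownames(members) <- NULL
  bands <- do.call(rbind, lapply(split(members, members$band), function(mb) {
    vars <- sort(unique(mb$variant_id))
    data.frame(
      band = mb$band[1],
      length = mean(mb$length),
      n_fragments = nrow(mb),
      variants = paste(vars, collapse = ","),
      diagnostic = length(vars) == 1,
      detectable = mean(mb$length) >= 50
    )
  }))
  rownames(bands) <- NULL
  structure(bands, members = members, tolerance = tolerance,
            class = c("band_table", "data.frame"))
}

#' @export
print.band_table <- function(x, ...) {
  cat(sprintf("<band_table> %d band class(es), tolerance %.3g\n", nrow(x),
              attr(x, "tolerance")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Rank candidate enzymes by how well they discriminate a variant set
#'
#' Each enzyme is scored by the number of variants that gain at least one
#' diagnostic band after digestion; an enzyme achieves *full discrimination*
#' when every variant has one. Uncut variants still produce an (undigested)
#' band, so distinct full lengths beyond the co-migration tolerance are
#' themselves diagnostic. Ties are broken in favour of simpler patterns
#' (fewer band classes).
#'
#' @param variants A `DNAStringSet` or named character vector (>= 2).
#' @param enzymes A list of [enzyme_spec()], e.g. [load_enzymes()].
#' @param tolerance Co-migration tolerance passed to [classify_bands()].
#' @return Data frame `enzyme`, `score`, `n_bands`, `full_discrimination`,
#'   sorted best first.
#' @export
screen_enzymes <- function(variants, enzymes, tolerance = 0.02) {
  vs <- as_variant_list(variants)
  if (length(vs) < 2) stop_usage("enzyme screening needs >= 2 variants")
  if (length(enzymes) == 0) stop_usage("empty enzyme table")
  if (inherits(enzymes, "enzyme_spec")) enzymes <- list(enzymes)
  rows <- lapply(enzymes, function(enz) {
    pats <- lapply(vs, digest, enzyme = enz)
    bt <- classify_bands(pats, tolerance)
    diag_vars <- unique(bt$variants[bt$diagnostic])
    data.frame(
      enzyme = enz$name,
      score = length(diag_vars),
      n_bands = nrow(bt),
      full_discrimination = length(diag_vars) == length(vs)
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$n_bands, out$enzyme), , drop = FALSE]
  rownames(out) <- NULL
  out
}
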