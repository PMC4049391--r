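#' @title Per-variant transcript quantification from gel densitometry
#' @description
#' Converts lane densitometry of a restriction digest into per-variant
#' relative transcript abundances. The intensity model is that of an
#' intercalating stain (SYBR): band intensity is proportional to DNA *mass*,
#' i.e. molar amount times fragment length, so dividing a diagnostic band's
#' intensity by its length yields a molar signal. Abundances are normalised
#' to a loading-control (reference gene) intensity, expressed as percent
#' change versus a control condition, and compared across conditions by
#' pairwise Student's t-tests with Bonferroni correction.
#' @name gel_quantification
NULL

#' Build the band-by-variant incidence (mass contribution) matrix
#'
#' Entry `[band, variant]` is the summed length (bp) of that variant's
#' fragments placed in that band class: the mass signal contributed to the
#' band by one transcript copy of the variant. Columns therefore sum to each
#' variant's full sequence length.
#'
#' @param bands A `band_table` from [classify_bands()].
#' @param variants Optional check input: the digest patterns, a
#'   `DNAStringSet`, or a named vector of lengths; column sums are verified
#'   against the variant lengths.
#' @return A numeric matrix with band representative lengths as rownames and
#'   variant ids as colnames, plus attribute `band_length`.
#' @examples
#' clai <- enzyme_spec("ClaI", "ATCGAT", 2)
#' pats <- digest(make_paralog_set(seed = 1), clai)
#' build_incidence(classify_bands(pats), pats)
#' @export
build_incidence <- function(bands, variants = NULL) {
  if (!inherits(bands, "band_table")) {
    stop_usage("'bands' must be a band_table from classify_bands()")
  }
  members <- attr(bands, "members")
  vars <- sort(unique(members$variant_id))
  M <- matrix(0, nrow = nrow(bands), ncol = length(vars),
              dimnames = list(format(bands$length, trim = TRUE), vars))
  for (i in seq_len(nrow(members))) {
    r <- members$band[i]
    M[r, members$variant_id[i]] <- M[r, members$variant_id[i]] +
      members$length[i]
  }
  if (!is.null(variants)) {
    if (inherits(variants, "digest_pattern")) variants <- list(variants)
    lens <- if (is.numeric(variants)) {
      variants
    } else if (is.list(variants) &&
               all(vapply(variants, inherits, logical(1), "digest_pattern"))) {
      vapply(variants, function(p) p$length, numeric(1)) |>
        setNames(vapply(variants, function(p) p$variant_id, character(1)))
    } else {
      vs <- as_variant_list(variants)
      setNames(vapply(vs, function(v) nchar(v$seq), numeric(1)), names(vs))
    }
    if (!setequal(names(lens), vars)) {
      stop_usage("band table and variant set disagree on variant ids")
    }
    if (any(abs(colSums(M)[names(lens)] - lens) > 1e-9)) {
      stop_usage("incidence column sums do not match variant lengths")
    }
  }
  attr(M, "band_length") <- bands$length
  M
}

# Lawson-Hanson active-set nonnegative least squares: min ||A x - b||, x >= 0.
# Hand-rolled because no NNLS solver ships with the available packages;
# problems here are tiny (bands x variants).
nnls_fit <- function(A, b, tol = NULL) {
  n <- ncol(A)
  if (is.null(tol)) tol <- 1e-10 * max(abs(t(A) %*% b), 1)
  x <- rep(0, n)
  passive <- rep(FALSE, n)
  for (iter in seq_len(30 * n)) {
    w <- drop(t(A) %*% (b - A %*% x))
    cand <- which(!passive & w > tol)
    if (!length(cand)) break
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      z <- rep(0, n)
      P <- which(passive)
      z[P] <- drop(qr.coef(qr(A[, P, drop = FALSE]), b))
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > tol)) {
        x <- z
        break
      }
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
    }
  }
  pmax(x, 0)
}

#' Quantify per-variant abundance from one gel lane
#'
#' @param lane A `lane_densitometry` object (see [lane_densitometry()],
#'   [read_lanes_csv()], [simulate_lane()]).
#' @param incidence Incidence matrix from [build_incidence()].
#' @param mode `"diagnostic"` — each variant's molar signal is the mean over
#'   its diagnostic bands of intensity / mass entry, ignoring shared bands
#'   (the assay as published); or `"least_squares"` — nonnegative
#'   least-squares solve of intensity ~ incidence x abundance using all
#'   bands including shared ones (a documented extension). Both are then
#'   divided by the lane's reference intensity.
#' @param tolerance Relative tolerance for matching lane band lengths to
#'   incidence rows.
#' @return Data frame `variant`, `raw` (molar signal), `normalized`
#'   (raw / reference intensity).
#' @export
quantify <- function(lane, incidence,
                     mode = c("diagnostic", "least_squares"),
                     tolerance = 0.02) {
  mode <- match.arg(mode)
  if (!inherits(lane, "lane_densitometry")) {
    stop_usage("'lane' must be a lane_densitometry object")
  }
  if (lane$reference_intensity <= 0) {
    stop_usage("reference intensity of lane '%s' must be > 0", lane$lane)
  }
  band_len <- attr(incidence, "band_length")
  if (is.null(band_len)) band_len <- as.numeric(rownames(incidence))
  y <- rep(0, nrow(incidence))
  for (i in seq_len(nrow(lane$bands))) {
    bl <- lane$bands$band_length[i]
    rel <- abs(bl - band_len) / ((bl + band_len) / 2)
    j <- which.min(rel)
    if (rel[j] > max(tolerance, 1e-9)) {
      stop_usage("lane '%s': band of %g bp matches no incidence band class",
                 lane$lane, bl)
    }
    y[j] <- y[j] + lane$bands$intensity[i]
  }
  vars <- colnames(incidence)
  if (all(y == 0)) {
    warning(sprintf("lane '%s': all band intensities are zero", lane$lane))
    raw <- setNames(rep(0, length(vars)), vars)
  } else if (mode == "diagnostic") {
    diag_rows <- which(rowSums(incidence > 0) == 1)
    raw <- vapply(vars, function(v) {
      rows <- diag_rows[incidence[diag_rows, v] > 0]
      if (!length(rows)) {
        stop_usage("variant '%s' has no diagnostic band; use least_squares", v)
      }
      mean(y[rows] / incidence[rows, v])
    }, numeric(1))
  } else {
    raw <- setNames(nnls_fit(incidence, y), vars)
  }
  data.frame(variant = vars, raw = unname(raw),
             normalized = unname(raw) / lane$reference_intensity,
             row.names = NULL)
}

#' Construct a lane densitometry record
#'
#' @param lane Lane identifier.
#' @param condition Condition label (e.g. `"control"`, `"treated"`).
#' @param band_length,intensity Parallel vectors: band length classes (bp)
#'   and their background-corrected intensities (>= 0). No background
#'   subtraction is applied here; that is the upstream densitometry's job.
#' @param reference_intensity Intensity of the loading-control amplicon (> 0).
#' @param bio Optional biological-replicate label (technical replicates of
#'   one biological sample share it).
#' @return A `lane_densitometry` object.
#' @export
lane_densitometry <- function(lane, condition, band_length, intensity,
                              reference_intensity, bio = NA) {
  if (length(band_length) != length(intensity)) {
    stop_usage("band_length and intensity differ in length")
  }
  if (any(intensity < 0)) stop_usage("negative band intensity in lane '%s'", lane)
  if (!is.finite(reference_intensity) || reference_intensity <= 0) {
    stop_usage("reference_intensity of lane '%s' must be > 0", lane)
  }
  structure(
    list(lane = as.character(lane), condition = as.character(condition),
         bands = data.frame(band_length = band_length, intensity = intensity),
         reference_intensity = reference_intensity, bio = bio),
    class = "lane_densitometry"
  )
}

#' Quantify a set of lanes and summarise by condition
#'
#' Applies [quantify()] to every lane, then aggregates: if lanes carry a
#' biological-replicate label, technical replicates are averaged per
#' biological replicate first (avoiding pseudo-replication), and means / SE
#' are computed over biological replicates.
#'
#' @param lanes List of `lane_densitometry` objects.
#' @param incidence Incidence matrix from [build_incidence()].
#' @param control Condition label used as the reference for percent change;
#'   default the first condition encountered.
#' @inheritParams quantify
#' @return List with `per_lane` (lane-level normalized abundances) and
#'   `summary` (condition x variant: mean normalized abundance, `se`, `n`,
#'   `percent_change` vs control).
#' @export
quantify_lanes <- function(lanes, incidence,
                           mode = c("diagnostic", "least_squares"),
                           control = NULL, tolerance = 0.02) {
  mode <- match.arg(mode)
  if (!length(lanes)) stop_usage("no lanes supplied")
  per_lane <- do.call(rbind, lapply(lanes, function(ln) {
    ab <- quantify(ln, incidence, mode, tolerance)
    data.frame(lane = ln$lane, condition = ln$condition,
               bio = if (is.null(ln$bio)) NA else ln$bio, ab)
  }))
  rownames(per_lane) <- NULL
  if (is.null(control)) control <- per_lane$condition[1]
  if (!control %in% per_lane$condition) {
    stop_usage("control condition '%s' not present in lanes", control)
  }
  reps <- per_lane
  if (!all(is.na(reps$bio))) {
    reps <- stats::aggregate(normalized ~ condition + bio + variant,
                             data = reps, FUN = mean)
  }
  smry <- do.call(rbind, lapply(
    split(reps, list(reps$condition, reps$variant), drop = TRUE),
    function(g) data.frame(
      condition = g$condition[1], variant = g$variant[1],
      normalized = mean(g$normalized),
      se = if (nrow(g) > 1) sd(g$normalized) / sqrt(nrow(g)) else NA_real_,
      n = nrow(g)
    )
  ))
  rownames(smry) <- NULL
  ctrl <- smry[smry$condition == control, c("variant", "normalized")]
  smry$percent_change <- percent_change(
    smry$normalized,
    ctrl$normalized[match(smry$variant, ctrl$variant)]
  )
  list(per_lane = per_lane, replicates = reps, summary = smry,
       control = control)
}

#' Percent change of a treated value versus a control value
#'
#' `100 * (treated/control - 1)`: a doubling is +100%, no change is 0%.
#'
#' @param treated,control Normalized abundances (control must be > 0).
#' @return Percent change (vectorised).
#' @examples
#' percent_change(2, 1)      # +100
#' percent_change(3.17, 1)   # +217
#' @export
percent_change <- function(treated, control) {
  if (any(!is.finite(control)) || any(control <= 0)) {
    stop_usage("percent change undefined: control abundance must be > 0")
  }
  100 * (treated / control - 1)
}

#' Pairwise group comparison with Bonferroni-corrected t-tests
#'
#' All `g(g-1)/2` pairs of conditions are compared by two-sample Student's
#' t-tests (equal variances). With Bonferroni correction the significance
#' threshold is `alpha / m` over the `m` comparisons. Conditions are then
#' assigned compact letters so that two conditions share a letter if and
#' only if they are not significantly different (insert-and-absorb
#' algorithm).
#'
#' @param x Either a named list of numeric replicate vectors (one per
#'   condition) or a data frame with columns `condition` and `value`.
#' @param alpha Familywise significance level (default 0.05).
#' @param correction `"bonferroni"` or `"none"`.
#' @param test Only `"t"` (Student's t-test) is implemented.
#' @return List: `comparisons` (data frame `group1`, `group2`, `p`,
#'   `threshold`, `significant`), `letters` (named character vector),
#'   `m` (number of comparisons).
#' @examples
#' compare_groups(list(ctrl = c(1, 1.1, 0.9), trt = c(5.2, 4.8, 5.1)))
#' @export
compare_groups <- function(x, alpha = 0.05,
                           correction = c("bonferroni", "none"),
                           test = "t") {
  correction <- match.arg(correction)
  if (!identical(test, "t")) stop_usage("only Student's t-test is implemented")
  if (is.data.frame(x)) {
    if (!all(c("condition", "value") %in% names(x))) {
      stop_usage("data frame input needs columns 'condition' and 'value'")
    }
    x <- split(x$value, x$condition)
  }
  if (length(x) < 2) stop_usage("need >= 2 groups to compare")
  if (any(vapply(x, length, integer(1)) < 2)) {
    stop_usage("each group needs >= 2 replicates")
  }
  groups <- names(x)
  pairs <- combn(groups, 2)
  m <- ncol(pairs)
  threshold <- if (correction == "bonferroni") alpha / m else alpha
  pvals <- apply(pairs, 2, function(pr) {
    a <- x[[pr[1]]]; b <- x[[pr[2]]]
    if (sd(a) == 0 && sd(b) == 0) {
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    }
    t.test(a, b, var.equal = TRUE)$p.value
  })
  comparisons <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ], p = pvals,
    threshold = threshold, significant = pvals <= threshold
  )
  list(comparisons = comparisons,
       letters = letter_groups(groups, comparisons), m = m)
}

# Insert-and-absorb letter display: start from one class holding every
# group; each significant pair splits every class containing both; subset
# classes are absorbed.
letter_groups <- function(groups, comparisons) {
  classes <- list(groups)
  sig <- comparisons[comparisons$significant, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$group1[i]; b <- sig$group2[i]
    new <- list()
    for (cl in classes) {
      if (a %in% cl && b %in% cl) {
        new <- c(new, list(setdiff(cl, a)), list(setdiff(cl, b)))
      } else {
        new <- c(new, list(cl))
      }
    }
    new <- new[vapply(new, length, integer(1)) > 0]
    new <- new[!duplicated(lapply(new, sort))]
    # absorb proper subsets
    keep <- vapply(seq_along(new), function(p) {
      !any(vapply(seq_along(new), function(q) {
        q != p && all(new[[p]] %in% new[[q]]) &&
          length(new[[p]]) < length(new[[q]])
      }, logical(1)))
    }, logical(1))
    classes <- new[keep]
  }
  lab <- letters[seq_along(classes)]
  out <- vapply(groups, function(g) {
    paste(lab[vapply(classes, function(cl) g %in% cl, logical(1))],
          collapse = "")
  }, character(1))
  setNames(out, groups)
}
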