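#' @title Seeded synthetic data: paralog trios, growth curves, gel lanes
#' @description
#' Mechanistic simulators for every input the toolkit consumes, so the full
#' pipeline can be exercised and validated without external data. All
#' randomness is controlled through an explicit seed and the caller's RNG
#' state is left untouched.
#' @name synthetic_data
NULL

# Write `motif` into `chars` starting at 1-based position p.
write_motif <- function(chars, motif, p) {
  chars[p:(p + nchar(motif) - 1)] <- strsplit(motif, "")[[1]]
  chars
}

# Mutate one base (outside protected ranges) of each unintended motif
# occurrence until the sequence contains the motif only at `keep_starts`.
enforce_motif_count <- function(chars, motif, keep_starts, protect) {
  for (pass in 1:50) {
    occ <- scan_motif(chars, motif)
    bad <- setdiff(occ, keep_starts)
    if (!length(bad)) return(chars)
    for (p in bad) {
      span <- p:(p + nchar(motif) - 1)
      free <- span[!span %in% protect]
      if (!length(free)) {
        stop_compute("cannot remove motif occurrence at %d: overlaps a placed site", p)
      }
      i <- free[1]
      chars[i] <- if (chars[i] == "G") "C" else "G"
    }
  }
  stop_compute("failed to normalise motif occurrences")
}

#' Generate a paralog trio with controlled ClaI cut-site geometry
#'
#' Builds three near-identical coding-sequence variants over a shared random
#' background, reproducing the published assay geometry by default:
#' \describe{
#'   \item{variant_a}{1968 bp, no ClaI site; equals variant_b with a 9-bp
#'     insertion immediately after the start codon (5' end).}
#'   \item{variant_b}{1959 bp, one ClaI site cutting at coordinate 1752
#'     (fragments 1752 + 207).}
#'   \item{variant_c}{1959 bp, ClaI cuts at 1098 and 1752 (fragments
#'     1098 + 654 + 207).}
#' }
#' The generated sequences are rescanned to guarantee the motif occurs
#' exactly 0/1/2 times; generation is byte-reproducible for a given seed.
#' There is no substitution or codon model: the background is uniform
#' random sequence.
#'
#' @param seed Integer RNG seed.
#' @param base_length Length (bp) of the b/c variants (default 1959).
#' @param cut_coords Cut coordinates for variant_c (variant_b keeps only the
#'   last one); defaults `c(1098, 1752)`.
#' @param insertion The 9-bp 5' insertion distinguishing variant_a.
#' @param enzyme The targeted [enzyme_spec()] (default built-in ClaI).
#' @return A [Biostrings::DNAStringSet] named `variant_a`, `variant_b`,
#'   `variant_c`.
#' @examples
#' trio <- make_paralog_set(seed = 1)
#' width(trio)  # 1968 1959 1959
#' @export
make_paralog_set <- function(seed = 1, base_length = 1959,
                             cut_coords = c(1098, 1752),
                             insertion = "GCTGCTGCT",
                             enzyme = NULL) {
  if (is.null(enzyme)) enzyme <- load_enzymes()$ClaI
  motif <- enzyme$recognition
  m <- nchar(motif)
  cut_coords <- sort(as.integer(cut_coords))
  starts <- cut_coords - enzyme$cut_offset + 1L  # motif start giving cut c
  if (any(starts < 2) || any(starts + m - 1 > base_length - 1)) {
    stop_usage("cut coordinates leave no room for the motif")
  }
  if (length(starts) > 1 && any(diff(starts) < m)) {
    stop_compute("infeasible spec: motif placements overlap")
  }
  if (nchar(insertion) == 0 || grepl("[^ACGT]", insertion)) {
    stop_usage("insertion must be a non-empty A/C/G/T string")
  }
  with_seed(seed, {
    chars <- sample(c("A", "C", "G", "T"), base_length, replace = TRUE)
    chars[1:3] <- c("A", "T", "G")            # start-codon analog
    protect <- unlist(lapply(starts, function(p) p:(p + m - 1)))
    protect <- c(1:3, protect)
    # variant_c: both sites present
    cc <- chars
    for (p in starts) cc <- write_motif(cc, motif, p)
    cc <- enforce_motif_count(cc, motif, starts, protect)
    # variant_b: only the last (3'-most) site
    keep_b <- starts[length(starts)]
    cb <- cc
    drop <- setdiff(starts, keep_b)
    for (p in drop) {
      i <- p + enzyme$cut_offset          # mutate inside the dropped motif
      cb[i] <- if (cb[i] == "G") "C" else "G"
    }
    cb <- enforce_motif_count(cb, motif, keep_b, c(1:3, keep_b:(keep_b + m - 1)))
    # variant_a: no site, 9-bp insertion right after the start codon
    ca <- cb
    i <- keep_b + enzyme$cut_offset
    ca[i] <- if (ca[i] == "G") "C" else "G"
    ca <- c(ca[1:3], strsplit(insertion, "")[[1]], ca[4:length(ca)])
    ca <- enforce_motif_count(ca, motif, integer(0), 1:3)
    out <- Biostrings::DNAStringSet(c(
      variant_a = paste(ca, collapse = ""),
      variant_b = paste(cb, collapse = ""),
      variant_c = paste(cc, collapse = "")
    ))
    # rescan oracle: the geometry must be exact or the spec was infeasible
    got <- lapply(as.character(out), function(s) {
      find_cut_sites(s, enzyme)$cut_coords
    })
    want <- list(integer(0), keep_b + enzyme$cut_offset - 1L,
                 starts + enzyme$cut_offset - 1L)
    if (!all(mapply(identical, got, lapply(want, as.integer)))) {
      stop_compute("generated variants do not reproduce the requested cut geometry")
    }
    out
  })
}

#' Simulate complemented-yeast growth curves with uptake-limited rates
#'
#' Mechanistic forward model of the growth assay: the growth rate at
#' external substrate concentration S follows a Michaelis-Menten hyperbola,
#' `rate(S) = k_max * S / (k_G_true + S)` (dt^-1), the exponential rate
#' constant is `k(S) = ln 2 * rate(S)`, and the optical density is
#' `od(t) = A0 * exp(k(S) t)` times multiplicative log-normal measurement
#' noise. With `plateau` set, growth instead follows a logistic curve with
#' the same initial rate and carrying capacity `plateau` (real cultures
#' saturate; default off so analytic recovery is exact).
#'
#' Defaults mirror the published experimental design: substrate ladder 0,
#' 1, 2.5, 5, 7.5, 10, 25, 50, 100 uM; hourly readings for 25 h; inoculum
#' A0 = 0.1 A600; 6 replicates (two experiments in triplicate); 2%
#' multiplicative OD noise.
#'
#' @param k_max Maximal growth rate (dt^-1, h^-1).
#' @param k_G_true True half-saturation constant (uM).
#' @param concentrations Substrate concentrations (uM); may include 0.
#' @param times Reading times (h).
#' @param A0 Inoculum optical density.
#' @param noise_sd Log-normal sdlog of the multiplicative OD noise.
#' @param replicates Replicate curves per concentration.
#' @param plateau Optional carrying-capacity OD (logistic cap); NULL = off.
#' @param seed Integer RNG seed.
#' @return Tidy data frame `substrate_uM`, `time_h`, `od`, `replicate`.
#' @examples
#' g <- simulate_growth(k_max = 0.35, k_G_true = 5, noise_sd = 0, seed = 1)
#' @export
simulate_growth <- function(k_max = 0.35, k_G_true = 5,
                            concentrations = c(0, 1, 2.5, 5, 7.5, 10, 25, 50, 100),
                            times = 0:25, A0 = 0.1, noise_sd = 0.02,
                            replicates = 6, plateau = NULL, seed = 1) {
  if (k_max <= 0 || k_G_true <= 0 || A0 <= 0 || noise_sd < 0) {
    stop_usage("k_max, k_G_true, A0 must be > 0 and noise_sd >= 0")
  }
  if (any(concentrations < 0)) stop_usage("concentrations must be >= 0")
  grid <- expand.grid(time_h = times, replicate = seq_len(replicates),
                      substrate_uM = concentrations)
  grid <- grid[, c("substrate_uM", "time_h", "replicate")]
  with_seed(seed, {
    rate <- k_max * grid$substrate_uM / (k_G_true + grid$substrate_uM)
    k <- log(2) * rate
    mu <- if (is.null(plateau)) {
      A0 * exp(k * grid$time_h)
    } else {
      plateau * A0 / (A0 + (plateau - A0) * exp(-k * grid$time_h))
    }
    noise <- if (noise_sd > 0) rlnorm(nrow(grid), 0, noise_sd) else 1
    grid$od <- mu * noise
    out <- grid[order(grid$substrate_uM, grid$replicate, grid$time_h), ]
    rownames(out) <- NULL
    out
  })
}

#' Simulate the densitometry of one gel lane
#'
#' Forward model of a stained-gel lane under the mass-proportional intensity
#' model: each band's intensity is the incidence-matrix row times the
#' variants' molar abundances, multiplied by log-normal noise; the
#' loading-control (reference) intensity is noised the same way.
#'
#' @param abundances Named (or incidence-column-ordered) nonnegative molar
#'   abundances per variant.
#' @param incidence Matrix from [build_incidence()].
#' @param reference_intensity Noise-free reference amplicon intensity.
#' @param noise_sd Log-normal sdlog of the multiplicative intensity noise.
#' @param seed Integer RNG seed.
#' @param lane,condition,bio Labels forwarded to [lane_densitometry()].
#' @return A `lane_densitometry` object.
#' @examples
#' clai <- enzyme_spec("ClaI", "ATCGAT", 2)
#' pats <- digest(make_paralog_set(seed = 1), clai)
#' M <- build_incidence(classify_bands(pats), pats)
#' simulate_lane(c(1, 2, 3), M, seed = 1)
#' @export
simulate_lane <- function(abundances, incidence, reference_intensity = 1000,
                          noise_sd = 0.05, seed = 1, lane = "L1",
                          condition = "control", bio = NA) {
  if (any(abundances < 0)) stop_usage("abundances must be >= 0")
  if (length(abundances) != ncol(incidence)) {
    stop_usage("one abundance per incidence column required")
  }
  if (!is.null(names(abundances))) {
    abundances <- abundances[colnames(incidence)]
  }
  with_seed(seed, {
    mu <- drop(incidence %*% abundances)
    noise <- if (noise_sd > 0) rlnorm(length(mu) + 1, 0, noise_sd) else
      rep(1, length(mu) + 1)
    band_len <- attr(incidence, "band_length")
    if (is.null(band_len)) band_len <- as.numeric(rownames(incidence))
    lane_densitometry(
      lane = lane, condition = condition,
      band_length = band_len, intensity = mu * noise[seq_along(mu)],
      reference_intensity = reference_intensity * noise[length(noise)],
      bio = bio
    )
  })
}
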