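#' @title Readers, writers and report serialisation
#' @description
#' File-format surface of the toolkit: FASTA variant sets (via Biostrings),
#' CSV growth and densitometry tables with schema validation, and
#' deterministic JSON/CSV report writers (stable key order, full numeric
#' precision) suitable for diff-based testing.
#' @name cli_io
NULL

#' Read a multi-record FASTA of sequence variants
#'
#' Records are uppercased and whitespace-stripped; ids must be unique and
#' sequences must contain only IUPAC nucleotide codes (offending record and
#' position are named otherwise).
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet], names taken from the record ids
#'   (first whitespace-delimited token).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_usage("FASTA file '%s' not found", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_usage(
                    "cannot parse FASTA '%s': %s", path, conditionMessage(e)))
  if (length(set) == 0) stop_usage("FASTA file '%s' has no records", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop_usage("duplicate FASTA id '%s'", ids[duplicated(ids)][1])
  }
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "")[[1]]
    bad <- which(!chars %in% names(IUPAC_SETS))
    if (length(bad)) {
      stop_usage("record '%s': illegal character '%s' at position %d",
                 ids[i], chars[bad[1]], bad[1])
    }
  }
  Biostrings::DNAStringSet(setNames(seqs, ids))
}

#' Write a variant set to FASTA
#' @param variants A `DNAStringSet` or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(variants, path) {
  vs <- as_variant_list(variants)
  lines <- unlist(lapply(vs, function(v) {
    c(paste0(">", v$id),
      substring(v$seq, seq(1, nchar(v$seq), 70),
                pmin(seq(1, nchar(v$seq), 70) + 69, nchar(v$seq))))
  }))
  writeLines(lines, path)
  invisible(path)
}

check_columns <- function(d, need, path) {
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop_usage("'%s' is missing column(s): %s", path,
               paste(miss, collapse = ", "))
  }
  for (col in need) {
    if (!is.numeric(d[[col]]) && col %in% c("substrate_uM", "time_h", "od",
                                            "band_length", "intensity",
                                            "reference_intensity",
                                            "external_uM",
                                            "store_nmol_per_A600")) {
      stop_usage("'%s': column '%s' must be numeric", path, col)
    }
  }
  if (any(!complete.cases(d[need]))) {
    stop_usage("'%s' contains missing values", path)
  }
  d
}

#' Read a growth-curve CSV
#'
#' Expected columns: `substrate_uM`, `time_h`, `od`, `replicate`. Rows may
#' be in any order; the parsed table is sorted, and duplicated
#' (concentration, time, replicate) triples are rejected.
#'
#' @param path Path to the CSV.
#' @return A validated, sorted data frame ready for
#'   [estimate_growth_constant()].
#' @export
read_growth_csv <- function(path) {
  if (!file.exists(path)) stop_usage("growth CSV '%s' not found", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  d <- check_columns(d, c("substrate_uM", "time_h", "od", "replicate"), path)
  if (any(d$substrate_uM < 0)) stop_usage("'%s': negative concentration", path)
  if (any(d$od < 0)) stop_usage("'%s': negative optical density", path)
  key <- paste(d$substrate_uM, d$time_h, d$replicate)
  if (anyDuplicated(key)) {
    stop_usage("'%s': duplicated (substrate_uM, time_h, replicate) row: %s",
               path, key[duplicated(key)][1])
  }
  d <- d[order(d$substrate_uM, d$replicate, d$time_h), ]
  rownames(d) <- NULL
  d
}

#' Read lane densitometry CSVs
#'
#' `lanes_path` must have columns `lane`, `condition`, `band_length`,
#' `intensity` (one row per band per lane; optional `bio` column for the
#' biological-replicate label); `reference_path` must have `lane`,
#' `reference_intensity`.
#'
#' @param lanes_path,reference_path CSV paths.
#' @return A named list of `lane_densitometry` objects.
#' @export
read_lanes_csv <- function(lanes_path, reference_path) {
  if (!file.exists(lanes_path)) stop_usage("lanes CSV '%s' not found", lanes_path)
  if (!file.exists(reference_path)) {
    stop_usage("reference CSV '%s' not found", reference_path)
  }
  d <- read.csv(lanes_path, stringsAsFactors = FALSE)
  d <- check_columns(d, c("lane", "condition", "band_length", "intensity"),
                     lanes_path)
  r <- read.csv(reference_path, stringsAsFactors = FALSE)
  r <- check_columns(r, c("lane", "reference_intensity"), reference_path)
  if (anyDuplicated(r$lane)) stop_usage("'%s': duplicated lane", reference_path)
  lanes <- lapply(split(d, d$lane), function(g) {
    ref <- r$reference_intensity[match(g$lane[1], r$lane)]
    if (is.na(ref)) {
      stop_usage("lane '%s' has no reference_intensity entry", g$lane[1])
    }
    lane_densitometry(
      lane = g$lane[1], condition = g$condition[1],
      band_length = g$band_length, intensity = g$intensity,
      reference_intensity = ref,
      bio = if ("bio" %in% names(g)) g$bio[1] else NA
    )
  })
  lanes[order(names(lanes))]
}

# Strip non-serialisable members (nls objects, closures) for reporting.
report_ready <- function(x) {
  if (inherits(x, "mm_fit")) x$nls <- NULL
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, report_ready)
    if (!is.null(names(x))) x <- x[order(names(x))]  # stable key order
  }
  x
}

#' Write an analysis report
#'
#' JSON reports are written with stable (sorted) key order and full numeric
#' precision, so identical inputs give byte-identical files; CSV output
#' requires a data frame.
#'
#' @param results A list or data frame of results.
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @param meta Optional named list (seed, config) stored under `"_meta"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv"),
                         meta = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!is.data.frame(results)) stop_usage("CSV output needs a data frame")
    write.csv(results, path, row.names = FALSE)
  } else {
    out <- report_ready(results)
    if (!is.null(meta)) {
      out <- c(list(`_meta` = c(list(package = "capsquant",
                                     version = as.character(
                                       utils::packageVersion("capsquant"))),
                                meta)),
               if (is.data.frame(out)) list(results = out) else out)
    }
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' Digest report for a variant set
#'
#' Convenience wrapper producing the JSON-ready digest summary: per-variant
#' cut coordinates and fragments, plus the band table with diagnostic flags.
#'
#' @param variants `DNAStringSet` or named character vector.
#' @param enzyme An [enzyme_spec()].
#' @param tolerance Band co-migration tolerance.
#' @return List with `enzyme`, `patterns`, `bands`.
#' @export
digest_report <- function(variants, enzyme, tolerance = 0.02) {
  pats <- digest(variants, enzyme)
  bt <- classify_bands(pats, tolerance)
  list(
    enzyme = list(name = enzyme$name, recognition = enzyme$recognition,
                  cut_offset = enzyme$cut_offset),
    patterns = lapply(pats, function(p) {
      list(variant_id = p$variant_id, length = p$length,
           cut_coords = p$cut_coords, fragments = p$fragments)
    }),
    bands = as.data.frame(bt)
  )
}
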