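#' Restriction enzyme specifications
#'
#' An `enzyme_spec` records a restriction enzyme's recognition motif (IUPAC
#' nucleotide codes) and the cut position on the top strand, counted in bases
#' from the 5' end of the motif. ClaI, for example, recognises `ATCGAT` and
#' cuts after the second base (`AT^CGAT`), so `cut_offset = 2`.
#'
#' @param name Enzyme name, e.g. `"ClaI"`.
#' @param recognition Recognition motif over the IUPAC nucleotide alphabet;
#'   at least 4 bases.
#' @param cut_offset Integer in `[0, nchar(recognition)]`: number of bases
#'   5' of the cut within the motif on the top strand.
#' @return An object of class `enzyme_spec` (a named list with fields
#'   `name`, `recognition`, `cut_offset`).
#' @examples
#' enzyme_spec("ClaI", "ATCGAT", 2)
#' @export
enzyme_spec <- function(name, recognition, cut_offset) {
  recognition <- toupper(as.character(recognition))
  if (!nzchar(name)) stop_usage("enzyme name must be non-empty")
  if (nchar(recognition) < 4) {
    stop_usage("recognition motif of '%s' must be at least 4 bases", name)
  }
  bad <- !strsplit(recognition, "")[[1]] %in% names(IUPAC_SETS)
  if (any(bad)) {
    stop_usage(
      "recognition motif of '%s' contains non-IUPAC character '%s'",
      name, strsplit(recognition, "")[[1]][which(bad)[1]]
    )
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0 || cut_offset > nchar(recognition)) {
    stop_usage(
      "cut_offset of '%s' must lie in [0, %d]", name, nchar(recognition)
    )
  }
  structure(
    list(name = name, recognition = recognition, cut_offset = cut_offset),
    class = "enzyme_spec"
  )
}

#' @export
print.enzyme_spec <- function(x, ...) {
  site <- paste0(
    substr(x$recognition, 1, x$cut_offset), "^",
    substr(x$recognition, x$cut_offset + 1, nchar(x$recognition))
  )
  cat(sprintf("<enzyme_spec> %s  %s\n", x$name, site))
  invisible(x)
}

# IUPAC code -> set of plain bases it stands for. Used by the motif scanner
# and by motif-free background generation in the simulator.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Load a restriction enzyme table
#'
#' Reads a tab-separated enzyme table with columns `name`, `recognition` and
#' `cut_offset`. With no argument, the built-in table of common 6+-cutters
#' (shipped in `inst/extdata/enzymes.tsv`, ClaI and EcoRI included) is
#' loaded.
#'
#' @param path Path to a TSV file; `NULL` for the built-in table.
#' @return A named list of [enzyme_spec()] objects.
#' @examples
#' enz <- load_enzymes()
#' enz$ClaI
#' @export
load_enzymes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "enzymes.tsv", package = "capsquant")
  }
  if (!file.exists(path)) stop_usage("enzyme table '%s' not found", path)
  tab <- read.csv(path, sep = "\t", stringsAsFactors = FALSE,
                  comment.char = "#")
  need <- c("name", "recognition", "cut_offset")
  if (!all(need %in% names(tab))) {
    stop_usage("enzyme table must have columns: %s", paste(need, collapse = ", "))
  }
  if (nrow(tab) == 0) stop_usage("enzyme table '%s' is empty", path)
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    enzyme_spec(tab$name[i], tab$recognition[i], tab$cut_offset[i])
  })
  names(specs) <- tab$name
  specs
}
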