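#' Build a locus panel
#'
#' A locus panel describes the autosomal STR markers of an amplification kit:
#' the marker name, its capillary-electrophoresis dye channel, the repeat-unit
#' length in bases, the affine allele-to-fragment-size mapping
#' `size = base_bp + repeat_bp * allele`, whether the marker has a simple
#' repeat structure, and the allele-designation range the synthetic-frequency
#' generator uses.
#'
#' @param loci A data frame with columns `locus`, `dye`, `repeat_bp`,
#'   `base_bp`, `simple`, `allele_min`, `allele_max`.
#' @return A tibble of class `locus_panel`.
#' @seealso [gf_panel()] for the default 21-locus panel.
#' @export
locus_panel <- function(loci) {
  loci <- tibble::as_tibble(loci)
  needed <- c("locus", "dye", "repeat_bp", "base_bp", "simple",
              "allele_min", "allele_max")
  missing <- setdiff(needed, names(loci))
  if (length(missing) > 0) {
    stop("panel is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(loci$locus)) stop("locus names must be unique")
  if (any(loci$repeat_bp <= 0)) stop("repeat_bp must be positive")
  bad_dye <- setdiff(unique(loci$dye), dye_channels())
  if (length(bad_dye) > 0) {
    stop("unknown dye channel(s): ", paste(bad_dye, collapse = ", "))
  }
  structure(loci, class = c("locus_panel", class(tibble::tibble())))
}

#' Dye channel labels recognised by the panel
#' @return Character vector of the five dye labels.
#' @export
dye_channels <- function() c("Blue", "Green", "Yellow", "Red", "Purple")

#' Default 21-locus autosomal panel
#'
#' The default panel covers the 21 autosomal STR markers of a
#' GlobalFiler-style megaplex. Dye assignments, repeat-unit lengths and
#' size offsets are representative values for a five-dye kit; the seven
#' simple-repeat markers used for saturation assessment are flagged.
#'
#' @return A `locus_panel` tibble with 21 rows.
#' @export
gf_panel <- function() {
  simple_loci <- c("D16S539", "CSF1PO", "TPOX", "D5S818", "D13S317",
                   "D7S820", "D10S1248")
  loci <- tibble::tribble(
    ~locus,      ~dye,     ~repeat_bp, ~base_bp, ~allele_min, ~allele_max,
    "D3S1358",   "Blue",   4,  66,  12, 19,
    "vWA",       "Blue",   4, 100,  11, 21,
    "D16S539",   "Blue",   4, 212,   5, 15,
    "CSF1PO",    "Blue",   4, 257,   6, 15,
    "TPOX",      "Blue",   4, 310,   6, 13,
    "D8S1179",   "Green",  4,  72,   8, 18,
    "D21S11",    "Green",  4, 107,  24, 35,
    "D18S51",    "Green",  4, 196,   9, 26,
    "D2S441",    "Green",  4, 330,   9, 16,
    "D19S433",   "Yellow", 4,  55,   9, 17,
    "TH01",      "Yellow", 4, 136,   5, 10,
    "FGA",       "Yellow", 4, 148,  17, 30,
    "D22S1045",  "Red",    3,  58,   8, 19,
    "D5S818",    "Red",    4, 100,   7, 16,
    "D13S317",   "Red",    4, 160,   8, 15,
    "D7S820",    "Red",    4, 222,   6, 14,
    "SE33",      "Purple", 4, 122,  12, 32,
    "D10S1248",  "Purple", 4,  40,   8, 18,
    "D1S1656",   "Purple", 4, 115,   9, 19,
    "D12S391",   "Purple", 4, 200,  15, 26,
    "D2S1338",   "Purple", 4, 300,  15, 27
  )
  loci$simple <- loci$locus %in% simple_loci
  locus_panel(loci[, c("locus", "dye", "repeat_bp", "base_bp", "simple",
                       "allele_min", "allele_max")])
}

#' Fragment size of an allele
#'
#' Applies the panel's affine allele-to-size mapping.
#'
#' @param panel A `locus_panel`.
#' @param locus Locus name (scalar or vector, recycled against `allele`).
#' @param allele Allele designation (repeat number, fractional allowed).
#' @return Numeric fragment size(s) in bp.
#' @export
allele_size <- function(panel, locus, allele) {
  i <- match(locus, panel$locus)
  if (anyNA(i)) {
    stop("unknown locus: ", paste(unique(locus[is.na(i)]), collapse = ", "))
  }
  panel$base_bp[i] + panel$repeat_bp[i] * allele
}

#' Dye channel of a locus
#' @inheritParams allele_size
#' @return Character vector of dye labels.
#' @export
locus_dye <- function(panel, locus) {
  i <- match(locus, panel$locus)
  if (anyNA(i)) {
    stop("unknown locus: ", paste(unique(locus[is.na(i)]), collapse = ", "))
  }
  panel$dye[i]
}
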