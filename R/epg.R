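#' Construct an electropherogram (EPG)
#'
#' An EPG holds the called peaks of one amplified subsample: one row per
#' peak with the locus, allele designation, height in RFU and fragment size
#' in bp. Subsample metadata (sample id, cell count, ground-truth donors for
#' simulated data, whether the analytical threshold has been applied) is
#' carried in attributes so the peak table itself stays a plain tibble.
#'
#' @param peaks A data frame with columns `locus`, `allele`, `height`,
#'   `size` (zero rows allowed).
#' @param sample_id Sample identifier.
#' @param cell_count Number of cells in the subsample (>= 0).
#' @param truth Optional character vector of ground-truth donor ids
#'   (simulated data only).
#' @param at_applied Has the analytical threshold been applied?
#' @param panel Optional `locus_panel`; when supplied, loci are checked
#'   against it and missing sizes are filled from the panel mapping.
#' @return A tibble of class `epg`.
#' @export
epg <- function(peaks, sample_id = "sample", cell_count = NA_integer_,
                truth = NULL, at_applied = FALSE, panel = NULL) {
  peaks <- tibble::as_tibble(peaks)
  if (nrow(peaks) == 0) {
    peaks <- tibble::tibble(locus = character(), allele = double(),
                            height = double(), size = double())
  }
  needed <- c("locus", "allele", "height")
  missing <- setdiff(needed, names(peaks))
  if (length(missing) > 0) {
    stop("epg peaks missing columns: ", paste(missing, collapse = ", "))
  }
  if (!"size" %in% names(peaks)) peaks$size <- NA_real_
  if (!is.null(panel)) {
    bad <- setdiff(unique(peaks$locus), panel$locus)
    if (length(bad) > 0) {
      stop("unknown marker(s) in EPG: ", paste(bad, collapse = ", "))
    }
    fill <- is.na(peaks$size)
    if (any(fill)) {
      peaks$size[fill] <- allele_size(panel, peaks$locus[fill],
                                      peaks$allele[fill])
    }
  }
  if (any(peaks$height <= 0)) stop("peak heights must be positive")
  dup <- duplicated(peaks[, c("locus", "allele")])
  if (any(dup)) {
    stop("duplicate allele designation within a locus: ",
         paste(unique(peaks$locus[dup]), collapse = ", "))
  }
  peaks <- peaks[order(peaks$locus, peaks$allele), , drop = FALSE]
  structure(peaks,
            sample_id = as.character(sample_id),
            cell_count = as.integer(cell_count),
            truth = truth,
            at_applied = isTRUE(at_applied),
            class = c("epg", class(tibble::tibble())))
}

#' @export
print.epg <- function(x, ...) {
  cat(sprintf("<epg> sample %s | %s cells | %d peaks | AT %s\n",
              epg_sample_id(x),
              ifelse(is.na(epg_cell_count(x)), "?", epg_cell_count(x)),
              nrow(x),
              if (epg_at_applied(x)) "applied" else "not applied"))
  NextMethod()
}

#' EPG metadata accessors
#'
#' @param x An `epg`.
#' @return The sample id, cell count, ground-truth donor ids, or the
#'   analytical-threshold flag, respectively.
#' @name epg-accessors
NULL

#' @rdname epg-accessors
#' @export
epg_sample_id <- function(x) attr(x, "sample_id")

#' @rdname epg-accessors
#' @export
epg_cell_count <- function(x) attr(x, "cell_count")

#' @rdname epg-accessors
#' @export
epg_truth <- function(x) attr(x, "truth")

#' @rdname epg-accessors
#' @export
epg_at_applied <- function(x) attr(x, "at_applied")

# Replace the peak table of an epg, keeping metadata.
epg_replace_peaks <- function(x, peaks, at_applied = epg_at_applied(x)) {
  epg(peaks, sample_id = epg_sample_id(x), cell_count = epg_cell_count(x),
      truth = epg_truth(x), at_applied = at_applied)
}

#' Peaks of an EPG at one locus
#'
#' @param x An `epg`.
#' @param locus Locus name.
#' @return A tibble of the peaks at `locus` (possibly zero rows).
#' @export
epg_locus_peaks <- function(x, locus) {
  tibble::as_tibble(x)[x$locus == locus, , drop = FALSE]
}

#' Stack a list of EPGs into one long tibble
#'
#' @param epgs A list of `epg` objects.
#' @return A tibble with columns `sample_id`, `cell_count`, `locus`,
#'   `allele`, `height`, `size`.
#' @export
epg_bind <- function(epgs) {
  purrr::map_dfr(epgs, function(e) {
    tibble::tibble(sample_id = epg_sample_id(e),
                   cell_count = epg_cell_count(e),
                   locus = e$locus, allele = e$allele,
                   height = e$height, size = e$size)
  })
}

#' Count distinct alleles in an EPG
#' @param x An `epg`.
#' @return Integer number of called peaks.
#' @export
epg_allele_count <- function(x) nrow(x)

#' Construct a reference profile
#'
#' A reference profile is a donor's known genotype: an unordered pair of
#' allele designations at every panel locus (an equal pair denotes a
#' homozygote).
#'
#' @param genotypes A data frame with columns `locus`, `a1`, `a2`.
#' @param donor_id Donor identifier.
#' @param panel Optional `locus_panel`; when supplied, completeness against
#'   the panel is enforced.
#' @return A tibble of class `ref_profile`.
#' @export
ref_profile <- function(genotypes, donor_id = "donor", panel = NULL) {
  g <- tibble::as_tibble(genotypes)
  needed <- c("locus", "a1", "a2")
  if (!all(needed %in% names(g))) {
    stop("reference profile needs columns locus, a1, a2")
  }
  if (anyDuplicated(g$locus)) stop("duplicate locus in reference profile")
  if (!is.null(panel)) {
    missing <- setdiff(panel$locus, g$locus)
    if (length(missing) > 0) {
      stop("reference profile missing loci: ",
           paste(missing, collapse = ", "))
    }
  }
  swap <- g$a2 < g$a1
  tmp <- g$a1[swap]; g$a1[swap] <- g$a2[swap]; g$a2[swap] <- tmp
  structure(g[order(g$locus), c("locus", "a1", "a2")],
            donor_id = as.character(donor_id),
            class = c("ref_profile", class(tibble::tibble())))
}

#' @rdname ref_profile
#' @param x A `ref_profile`.
#' @export
profile_donor_id <- function(x) attr(x, "donor_id")

# genotype (a1, a2) of a donor at one locus
profile_genotype <- function(x, locus) {
  i <- match(locus, x$locus)
  if (is.na(i)) stop("locus ", locus, " absent from reference profile")
  c(x$a1[i], x$a2[i])
}

#' Build a noise-free EPG from a reference profile
#'
#' Every allele of the profile appears at a fixed height (homozygotes at
#' twice the height). Useful for constructing clean full profiles and
#' hand-built test cases.
#'
#' @param profile A `ref_profile`.
#' @param panel A `locus_panel`.
#' @param height Height per allele copy in RFU.
#' @param loci Optional locus subset.
#' @param sample_id Sample identifier.
#' @return A thresholded `epg` with the profile's donor as truth.
#' @export
profile_to_epg <- function(profile, panel = gf_panel(), height = 2000,
                           loci = NULL, sample_id = NULL) {
  if (is.null(loci)) loci <- intersect(panel$locus, profile$locus)
  peaks <- purrr::map_dfr(loci, function(loc) {
    g <- profile_genotype(profile, loc)
    al <- unique(g)
    h <- height * vapply(al, function(a) sum(g == a), 0)
    tibble::tibble(locus = loc, allele = al, height = h,
                   size = allele_size(panel, loc, al))
  })
  if (is.null(sample_id)) {
    sample_id <- paste0(profile_donor_id(profile), "-clean")
  }
  epg(peaks, sample_id = sample_id, cell_count = NA_integer_,
      truth = profile_donor_id(profile), at_applied = TRUE, panel = panel)
}
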