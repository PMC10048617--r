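#' Construct an allele-frequency table
#'
#' Per-locus allele frequencies plus the subpopulation co-ancestry
#' coefficient theta and the minimum-frequency policy for alleles unseen in
#' the database. Unobserved alleles are assigned the floor `5 / (2 * db_size)`
#' (standard forensic practice for a database of `db_size` individuals).
#'
#' @param freqs A data frame with columns `locus`, `allele`, `freq`.
#' @param theta Co-ancestry coefficient in `[0, 0.5)`; default 0.01.
#' @param db_size Database size N behind the `5/(2N)` minimum-frequency
#'   policy; default 1000.
#' @return A tibble of class `allele_freqs`.
#' @export
allele_freqs <- function(freqs, theta = 0.01, db_size = 1000) {
  f <- tibble::as_tibble(freqs)
  if (!all(c("locus", "allele", "freq") %in% names(f))) {
    stop("frequency table needs columns locus, allele, freq")
  }
  if (any(f$freq <= 0 | f$freq > 1)) {
    stop("frequencies must lie in (0, 1]")
  }
  dup <- duplicated(f[, c("locus", "allele")])
  if (any(dup)) {
    stop("duplicate (locus, allele) in frequency table: ",
         paste(unique(f$locus[dup]), collapse = ", "))
  }
  sums <- tapply(f$freq, f$locus, sum)
  bad <- names(sums)[sums < 0.99 | sums > 1.01]
  if (length(bad) > 0) {
    stop("per-locus frequencies must sum to 1 (+/- 0.01); offending loci: ",
         paste(bad, collapse = ", "))
  }
  if (theta < 0 || theta >= 0.5) stop("theta must lie in [0, 0.5)")
  structure(f[order(f$locus, f$allele), ],
            theta = theta, db_size = db_size,
            class = c("allele_freqs", class(tibble::tibble())))
}

#' @rdname allele_freqs
#' @param x An `allele_freqs` table.
#' @export
freq_theta <- function(x) attr(x, "theta")

#' @rdname allele_freqs
#' @export
freq_db_size <- function(x) attr(x, "db_size")

#' Set theta on a frequency table
#' @inheritParams freq_theta
#' @param theta New theta value.
#' @return The table with theta replaced.
#' @export
set_theta <- function(x, theta) {
  allele_freqs(tibble::as_tibble(x), theta = theta, db_size = freq_db_size(x))
}

#' Look up allele frequencies with the minimum-frequency policy
#'
#' @param x An `allele_freqs` table.
#' @param locus Locus name (scalar).
#' @param allele Allele designation(s).
#' @return Frequencies; alleles unseen in the database receive `5/(2N)`.
#' @export
allele_freq <- function(x, locus, allele) {
  rows <- x$locus == locus
  if (!any(rows)) stop("locus ", locus, " absent from frequency table")
  loc_al <- x$allele[rows]
  loc_fr <- x$freq[rows]
  i <- match(allele, loc_al)
  out <- loc_fr[i]
  out[is.na(i)] <- 5 / (2 * freq_db_size(x))
  out
}

# alleles listed for a locus
freq_alleles <- function(x, locus) x$allele[x$locus == locus]

#' Read an allele-frequency table from delimited text
#'
#' Expects a header with `locus`, `allele`, `freq` (case-insensitive;
#' `frequency` also accepted), comma- or tab-delimited.
#'
#' @param path File path.
#' @inheritParams allele_freqs
#' @return An `allele_freqs` table.
#' @export
read_frequency_table <- function(path, theta = 0.01, db_size = 1000) {
  df <- readr::read_delim(path, delim = sniff_delim(path),
                          show_col_types = FALSE, progress = FALSE)
  names(df) <- tolower(names(df))
  if ("frequency" %in% names(df) && !"freq" %in% names(df)) {
    df$freq <- df$frequency
  }
  if ("marker" %in% names(df) && !"locus" %in% names(df)) {
    df$locus <- df$marker
  }
  allele_freqs(df[, c("locus", "allele", "freq")],
               theta = theta, db_size = db_size)
}

#' Write an allele-frequency table
#' @param x An `allele_freqs` table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' Generate a synthetic allele-frequency table
#'
#' Draws per-locus frequencies over each locus's allele range from a
#' symmetric Dirichlet (via normalised Gamma draws). This emulates the shape
#' of a population STR database for simulation studies; it is synthetic and
#' matches no real population.
#'
#' @param panel A `locus_panel`.
#' @param concentration Dirichlet concentration per allele; smaller values
#'   give more skewed spectra. Default 2.
#' @param seed RNG seed.
#' @inheritParams allele_freqs
#' @return An `allele_freqs` table.
#' @export
synthetic_frequencies <- function(panel, concentration = 2, seed = 1,
                                  theta = 0.01, db_size = 1000) {
  set.seed(seed)
  rows <- purrr::map_dfr(seq_len(nrow(panel)), function(i) {
    alleles <- seq(panel$allele_min[i], panel$allele_max[i])
    g <- stats::rgamma(length(alleles), shape = concentration)
    f <- g / sum(g)
    # floor very rare alleles so invariants (freq > 0) are comfortably met
    f <- pmax(f, 1e-4)
    f <- f / sum(f)
    tibble::tibble(locus = panel$locus[i], allele = as.numeric(alleles),
                   freq = round(f, 6))
  })
  # renormalise rounding drift within the +/- 0.01 invariant
  allele_freqs(rows, theta = theta, db_size = db_size)
}

# crude delimiter sniffing for delimited text inputs
sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}
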