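#' Read a genotype table into a list of EPGs
#'
#' Two delimited-text dialects are accepted and auto-detected from the
#' header:
#'
#' * **wide** (genotyping-software export style): one row per sample and
#'   marker with columns `Sample Name`, `Marker` and numbered
#'   `Allele 1..k` / `Height 1..k` / `Size 1..k` columns;
#' * **long**: one row per peak with columns `sample_id`, `locus`,
#'   `allele`, `height`, `size` (optional `cell_count`).
#'
#' Loci absent from the file are present in each EPG as empty peak lists.
#' Allele designations are parsed as numbers; fractional designations such
#' as 9.3 are allowed.
#'
#' @param path File path (comma- or tab-delimited, header row, UTF-8).
#' @param panel A `locus_panel`; markers in the file must belong to it.
#' @return A list of `epg` objects, one per sample.
#' @export
read_genotype_table <- function(path, panel) {
  df <- readr::read_delim(path, delim = sniff_delim(path),
                          show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) return(list())
  nm <- tolower(gsub("[ ._]", "", names(df)))
  if (any(grepl("^allele[0-9]+$", nm))) {
    read_genotype_wide(df, nm, panel)
  } else {
    read_genotype_long(df, panel)
  }
}

read_genotype_long <- function(df, panel) {
  names(df) <- tolower(names(df))
  if ("sample" %in% names(df) && !"sample_id" %in% names(df)) {
    df$sample_id <- df$sample
  }
  if ("marker" %in% names(df) && !"locus" %in% names(df)) {
    df$locus <- df$marker
  }
  needed <- c("sample_id", "locus", "allele", "height")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("genotype table missing columns: ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(df$locus), panel$locus)
  if (length(bad) > 0) {
    stop("unknown marker name(s): ", paste(bad, collapse = ", "))
  }
  if (!"size" %in% names(df)) df$size <- NA_real_
  if (!"cell_count" %in% names(df)) df$cell_count <- NA_integer_
  split_idx <- split(seq_len(nrow(df)), df$sample_id)
  purrr::map(split_idx, function(idx) {
    rows <- df[idx, , drop = FALSE]
    epg(rows[, c("locus", "allele", "height", "size")],
        sample_id = rows$sample_id[1],
        cell_count = rows$cell_count[1],
        panel = panel)
  })
}

read_genotype_wide <- function(df, nm, panel) {
  names(df) <- nm
  if (!"samplename" %in% nm && "sample" %in% nm) {
    names(df)[names(df) == "sample"] <- "samplename"
  }
  if (!all(c("samplename", "marker") %in% names(df))) {
    stop("wide genotype table needs Sample Name and Marker columns")
  }
  bad <- setdiff(unique(df$marker), panel$locus)
  if (length(bad) > 0) {
    stop("unknown marker name(s): ", paste(bad, collapse = ", "))
  }
  a_cols <- sort(grep("^allele[0-9]+$", names(df), value = TRUE))
  h_cols <- sort(grep("^height[0-9]+$", names(df), value = TRUE))
  s_cols <- sort(grep("^size[0-9]+$", names(df), value = TRUE))
  if (length(a_cols) != length(h_cols)) {
    stop("allele/height column arity mismatch")
  }
  peaks <- purrr::map_dfr(seq_len(nrow(df)), function(r) {
    al <- suppressWarnings(as.numeric(unlist(df[r, a_cols])))
    ht <- suppressWarnings(as.numeric(unlist(df[r, h_cols])))
    sz <- if (length(s_cols) == length(a_cols)) {
      suppressWarnings(as.numeric(unlist(df[r, s_cols])))
    } else rep(NA_real_, length(al))
    keep <- !is.na(al)
    if (any(is.na(ht[keep]))) {
      stop("height/allele arity mismatch at row ", r)
    }
    tibble::tibble(sample_id = df$samplename[r], locus = df$marker[r],
                   allele = al[keep], height = ht[keep], size = sz[keep])
  })
  split_idx <- split(seq_len(nrow(peaks)), peaks$sample_id)
  purrr::map(split_idx, function(idx) {
    rows <- peaks[idx, , drop = FALSE]
    epg(rows[, c("locus", "allele", "height", "size")],
        sample_id = rows$sample_id[1], panel = panel)
  })
}

#' Write EPGs as a genotype table
#'
#' @param epgs A list of `epg` objects (or a single `epg`).
#' @param path Output file path.
#' @param dialect `"long"` (one row per peak; the default) or `"wide"`
#'   (numbered Allele/Height/Size columns, one row per sample and marker).
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(epgs, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (inherits(epgs, "epg")) epgs <- list(epgs)
  long <- epg_bind(epgs)
  if (dialect == "long") {
    readr::write_csv(long, path)
    return(invisible(path))
  }
  wide <- long |>
    dplyr::group_by(.data$sample_id, .data$locus) |>
    dplyr::mutate(k = dplyr::row_number()) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(id_cols = c("sample_id", "locus"),
                       names_from = "k",
                       values_from = c("allele", "height", "size"),
                       names_glue = "{.value} {k}")
  names(wide)[names(wide) == "sample_id"] <- "Sample Name"
  names(wide)[names(wide) == "locus"] <- "Marker"
  names(wide) <- gsub("^allele", "Allele", names(wide))
  names(wide) <- gsub("^height", "Height", names(wide))
  names(wide) <- gsub("^size", "Size", names(wide))
  readr::write_csv(wide, path)
  invisible(path)
}
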