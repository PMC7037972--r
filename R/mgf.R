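# MGF (Mascot Generic Format) dialect: BEGIN IONS / END IONS blocks; PEPMASS
# required; CHARGE, RTINSECONDS, TITLE optional; unknown `KEY=value` headers
# preserved verbatim; peak lines are whitespace-separated "m/z intensity".
# No installed R package parses MGF, so the reader/writer lives here.

.is_peak_line <- function(lines) grepl("^\\s*[0-9.+-]", lines)

# Parse the lines of one BEGIN..END block (exclusive of the markers) into the
# spectrum fields; `ordinal` numbers blocks in file order.
.parse_mgf_block <- function(lines, ordinal, strict = TRUE) {
  is_peak <- .is_peak_line(lines)
  header <- lines[!is_peak]
  peak_lines <- lines[is_peak]
  kv <- header[grepl("=", header, fixed = TRUE)]
  keys <- toupper(sub("=.*$", "", kv))
  vals <- sub("^[^=]*=", "", kv)
  get <- function(key) if (key %in% keys) vals[match(key, keys)] else NA_character_

  pepmass <- get("PEPMASS")
  precursor_mz <- if (is.na(pepmass)) {
    NA_real_
  } else {
    suppressWarnings(as.numeric(strsplit(trimws(pepmass), "\\s+")[[1]][1]))
  }
  charge_raw <- get("CHARGE")
  charge <- if (is.na(charge_raw)) {
    NA_integer_
  } else {
    suppressWarnings(as.integer(sub("\\+$", "", trimws(charge_raw))))
  }
  rt <- suppressWarnings(as.numeric(get("RTINSECONDS")))
  title <- get("TITLE")

  toks <- strsplit(trimws(peak_lines), "\\s+")
  mz <- suppressWarnings(as.numeric(vapply(toks, `[`, character(1), 1)))
  intensity <- suppressWarnings(as.numeric(vapply(
    toks, function(t) if (length(t) >= 2) t[[2]] else "0", character(1)
  )))
  bad <- is.na(precursor_mz) || anyNA(mz) || anyNA(intensity) ||
    any(mz <= 0) || any(intensity < 0)
  if (bad) {
    if (strict) {
      abort(sprintf(
        "unparseable MGF block %d%s", ordinal,
        if (is.na(title)) "" else sprintf(" (TITLE=%s)", title)
      ))
    }
    return(NULL)
  }
  ord <- order(mz)
  tibble(
    scan_id = if (is.na(title)) sprintf("spectrum_%d", ordinal) else title,
    title = title,
    precursor_mz = precursor_mz,
    precursor_charge = charge,
    rtinseconds = rt,
    peaks = list(tibble(mz = mz[ord], intensity = intensity[ord])),
    header_lines = list(header),
    peak_lines = list(peak_lines)
  )
}

#' Read an MGF peak-list file into a tibble of spectra
#'
#' One row per `BEGIN IONS`/`END IONS` block. Peaks are sorted ascending by
#' m/z in the `peaks` list-column; the original header and peak lines are
#' kept verbatim in `header_lines`/`peak_lines` so that [write_mgf()] can
#' reproduce each block byte for byte.
#'
#' @param path Path to an MGF file.
#' @param strict If `TRUE` (default) an unparseable block is an error naming
#'   the block; if `FALSE` such blocks are skipped and counted in the
#'   `n_skipped` attribute.
#' @return A tibble with columns `scan_id`, `title`, `precursor_mz`,
#'   `precursor_charge`, `rtinseconds`, `peaks`, `header_lines`, `peak_lines`.
#' @export
read_mgf <- function(path, strict = TRUE) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(begins > ends)) {
    abort(sprintf("malformed MGF: unbalanced BEGIN IONS/END IONS in '%s'", path))
  }
  out <- vector("list", length(begins))
  n_skipped <- 0L
  for (i in seq_along(begins)) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    parsed <- .parse_mgf_block(block, i, strict = strict)
    if (is.null(parsed)) {
      n_skipped <- n_skipped + 1L
    } else {
      out[[i]] <- parsed
    }
  }
  res <- bind_rows(out)
  if (!nrow(res)) {
    res <- tibble(
      scan_id = character(), title = character(), precursor_mz = numeric(),
      precursor_charge = integer(), rtinseconds = numeric(),
      peaks = list(), header_lines = list(), peak_lines = list()
    )
  }
  attr(res, "n_skipped") <- n_skipped
  res
}

# Header/peak lines for a spectrum row that was built programmatically
# rather than read from a file.
.mgf_block_lines <- function(row) {
  header <- row$header_lines[[1]]
  if (is.null(header)) {
    header <- c(
      if (!is.na(row$title)) paste0("TITLE=", row$title),
      paste0("PEPMASS=", format(row$precursor_mz, digits = 10)),
      if (!is.na(row$precursor_charge)) paste0("CHARGE=", row$precursor_charge, "+"),
      if (!is.na(row$rtinseconds)) paste0("RTINSECONDS=", format(row$rtinseconds, digits = 10))
    )
  }
  peak_lines <- row$peak_lines[[1]]
  if (is.null(peak_lines)) {
    pk <- row$peaks[[1]]
    peak_lines <- sprintf("%.5f %.2f", pk$mz, pk$intensity)
  }
  c("BEGIN IONS", header, peak_lines, "END IONS", "")
}

#' Write a tibble of spectra to an MGF file
#'
#' Rows read by [read_mgf()] are written back verbatim (original header and
#' peak lines); rows built in code (no `header_lines`) get headers generated
#' from the parsed fields.
#'
#' @param spectra A tibble as returned by [read_mgf()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  stopifnot(is.data.frame(spectra))
  has_lines <- all(c("header_lines", "peak_lines") %in% names(spectra))
  lines <- unlist(lapply(seq_len(nrow(spectra)), function(i) {
    row <- spectra[i, ]
    if (!has_lines) {
      row$header_lines <- list(NULL)
      row$peak_lines <- list(NULL)
    }
    .mgf_block_lines(row)
  }))
  writeLines(lines %||% character(0), path)
  invisible(path)
}
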