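# Diagnostic Ion Data Analysis Reduction: cut an MS/MS peak-list file down to
# the spectra that contain one or more diagnostic fragment ions, before any
# database search sees the file.

# Which ions (rows of `ions`) are present in a peak list? ppm window is
# relative to the theoretical target m/z, not the observed peak.
.ions_present <- function(mz, intensity, ions, min_rel_intensity = 0) {
  floor_abs <- if (min_rel_intensity > 0 && length(intensity)) {
    min_rel_intensity * max(intensity)
  } else {
    0
  }
  vapply(seq_len(nrow(ions)), function(k) {
    target <- ions$target_mz[[k]]
    tol <- ions$tolerance_ppm[[k]]
    any(abs(mz - target) / target * 1e6 <= tol & intensity >= floor_abs)
  }, logical(1))
}

#' Does a spectrum contain a diagnostic ion?
#'
#' `TRUE` iff some peak lies within `tolerance_ppm` parts per million of the
#' ion's target m/z (ppm computed against the theoretical target) and at or
#' above the intensity floor.
#'
#' @param spectrum A one-row tibble as returned by [read_mgf()], or any list
#'   with a `peaks` element holding a tibble of `mz`/`intensity`.
#' @param ion A one-row ion tibble from [diagnostic_ion()] or
#'   [builtin_ion_registry()].
#' @param min_rel_intensity Peaks below this fraction of the spectrum's base
#'   peak are ignored (default 0: any detected peak counts).
#' @return Logical scalar.
#' @export
spectrum_contains_ion <- function(spectrum, ion, min_rel_intensity = 0) {
  peaks <- spectrum$peaks
  if (is.list(peaks) && !is.data.frame(peaks)) peaks <- peaks[[1]]
  stopifnot(is.data.frame(ion), nrow(ion) == 1L)
  if (is.null(peaks) || !nrow(peaks)) {
    return(FALSE)
  }
  .ions_present(peaks$mz, peaks$intensity, ion, min_rel_intensity)[[1]]
}

.new_didar_report <- function(total, matched, per_ion, mode, n_skipped = 0L) {
  structure(
    list(
      total_spectra = as.integer(total),
      matched_spectra = as.integer(matched),
      per_ion_counts = per_ion,
      mode = mode,
      n_skipped = as.integer(n_skipped)
    ),
    class = "didar_report"
  )
}

#' Filter spectra for diagnostic fragment ions
#'
#' Keeps exactly the spectra satisfying the ion predicate: with
#' `mode = "any"` (default) a spectrum passes when at least one ion is
#' present, with `mode = "all"` only when every ion is present. Input order
#' and spectrum content are preserved. The attached report counts, per ion,
#' how many input spectra contain that ion.
#'
#' @param spectra A tibble of spectra from [read_mgf()] or [sim_mgf()].
#' @param ions A non-empty ion tibble ([builtin_ion_registry()] rows or
#'   [diagnostic_ion()] output).
#' @param mode `"any"` (OR over ions) or `"all"` (AND).
#' @param min_rel_intensity Relative intensity floor, see
#'   [spectrum_contains_ion()].
#' @return The matching spectra, with a `didar_report` attached as attribute
#'   `"report"` (retrieve it with [didar_report()]).
#' @export
filter_spectra <- function(spectra, ions, mode = c("any", "all"),
                           min_rel_intensity = 0) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(spectra))
  if (!is.data.frame(ions) || !nrow(ions)) {
    abort("`ions` must be a non-empty diagnostic-ion tibble")
  }
  raw <- vapply(
    spectra$peaks,
    function(pk) .ions_present(pk$mz, pk$intensity, ions, min_rel_intensity),
    logical(nrow(ions))
  )
  hits <- if (is.matrix(raw)) t(raw) else matrix(raw, ncol = nrow(ions))
  if (!nrow(spectra)) hits <- matrix(logical(0), 0L, nrow(ions))
  matched <- if (mode == "any") {
    rowSums(hits) > 0L
  } else {
    rowSums(hits) == nrow(ions)
  }
  out <- spectra[matched, , drop = FALSE]
  per_ion <- colSums(hits)
  names(per_ion) <- ions$name
  attr(out, "report") <- .new_didar_report(
    nrow(spectra), sum(matched), as.integer(per_ion) |>
      stats::setNames(ions$name), mode
  )
  out
}

#' Retrieve the filter report attached to a filtered spectrum tibble
#'
#' @param x The return value of [filter_spectra()].
#' @return A `didar_report` object.
#' @export
didar_report <- function(x) {
  rep <- attr(x, "report")
  if (is.null(rep)) abort("no filter report attached to this object")
  rep
}

#' Stream-filter an MGF file for diagnostic ions
#'
#' File-to-file version of [filter_spectra()]: blocks are processed one at a
#' time, so memory use is independent of file size, and matching blocks are
#' written byte for byte (all lines between and including `BEGIN IONS` and
#' `END IONS`, plus any content outside blocks, are preserved verbatim).
#'
#' @param input Path to the input MGF file.
#' @param output Path for the filtered MGF file.
#' @param ions,mode,min_rel_intensity As in [filter_spectra()].
#' @param skip_invalid If `TRUE`, unparseable blocks are dropped and counted
#'   instead of raising an error.
#' @param report_path Optional path for a per-ion count TSV (`ion`,
#'   `n_spectra`).
#' @return A `didar_report`, invisibly.
#' @export
filter_mgf <- function(input, output, ions, mode = c("any", "all"),
                       min_rel_intensity = 0, skip_invalid = FALSE,
                       report_path = NULL) {
  mode <- match.arg(mode)
  if (!is.data.frame(ions) || !nrow(ions)) {
    abort("`ions` must be a non-empty diagnostic-ion tibble")
  }
  con <- file(input, "r")
  on.exit(close(con), add = TRUE)
  out_con <- file(output, "w")
  on.exit(close(out_con), add = TRUE)

  buffer <- character(0)
  total <- 0L
  matched <- 0L
  n_skipped <- 0L
  per_ion <- stats::setNames(integer(nrow(ions)), ions$name)

  emit <- function(lines) writeLines(lines, out_con)

  process_block <- function(block_lines) {
    total <<- total + 1L
    inner <- block_lines[-c(1L, length(block_lines))]
    parsed <- .parse_mgf_block(inner, total, strict = !skip_invalid)
    if (is.null(parsed)) {
      n_skipped <<- n_skipped + 1L
      return(invisible())
    }
    pk <- parsed$peaks[[1]]
    present <- .ions_present(pk$mz, pk$intensity, ions, min_rel_intensity)
    per_ion <<- per_ion + as.integer(present)
    ok <- if (mode == "any") any(present) else all(present)
    if (ok) {
      matched <<- matched + 1L
      emit(block_lines)
    }
    invisible()
  }

  in_block <- FALSE
  block <- character(0)
  repeat {
    chunk <- readLines(con, n = 65536L)
    if (!length(chunk)) break
    for (line in chunk) {
      if (!in_block) {
        if (line == "BEGIN IONS") {
          in_block <- TRUE
          block <- line
        } else {
          emit(line)
        }
      } else {
        block <- c(block, line)
        if (line == "END IONS") {
          in_block <- FALSE
          process_block(block)
          block <- character(0)
        }
      }
    }
  }
  if (in_block) abort("malformed MGF: file ends inside a BEGIN IONS block")

  report <- .new_didar_report(total, matched, per_ion, mode, n_skipped)
  if (!is.null(report_path)) {
    readr::write_tsv(tidy(report), report_path)
  }
  invisible(report)
}

#' @export
print.didar_report <- function(x, ...) {
  cat(sprintf(
    "D.I.D.A.R. filter report: %d / %d spectra matched (mode = %s)%s\n",
    x$matched_spectra, x$total_spectra, x$mode,
    if (x$n_skipped > 0) sprintf(", %d block(s) skipped", x$n_skipped) else ""
  ))
  for (ion in names(x$per_ion_counts)) {
    cat(sprintf("  %-16s %d\n", ion, x$per_ion_counts[[ion]]))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.didar_report <- function(x, ...) {
  tibble(
    ion = names(x$per_ion_counts),
    n_spectra = as.integer(x$per_ion_counts)
  )
}

#' @exportS3Method generics::glance
glance.didar_report <- function(x, ...) {
  tibble(
    total_spectra = x$total_spectra,
    matched_spectra = x$matched_spectra,
    fraction_matched = ifelse(
      x$total_spectra > 0, x$matched_spectra / x$total_spectra, NA_real_
    ),
    mode = x$mode,
    n_skipped = x$n_skipped
  )
}

#' @describeIn didar_report Bar chart of per-ion spectrum counts.
#' @param object A `didar_report`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.didar_report <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$ion, -.data$n_spectra), y = .data$n_spectra
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(
      yintercept = object$matched_spectra, linetype = "dashed"
    ) +
    ggplot2::labs(
      x = NULL, y = "spectra containing ion",
      title = sprintf(
        "%d / %d spectra matched (mode = %s)",
        object$matched_spectra, object$total_spectra, object$mode
      )
    ) +
    ggplot2::theme_minimal()
}
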