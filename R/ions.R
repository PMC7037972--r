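# Monoisotopic atomic masses (u), CODATA/IUPAC values for the principal
# isotope; electron mass included for cation m/z correction.
.MONOISOTOPIC_MASS <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268,
  F  = 18.99840322,
  Br = 78.9183371,
  I  = 126.904473,
  Se = 79.9165213,
  Fe = 55.9349375,
  Si = 27.9769265325
)

.ELECTRON_MASS <- 0.000548579909

# "C7H12NO" -> c(C = 7, H = 12, N = 1, O = 1); errors on unknown symbols.
.parse_formula <- function(composition) {
  stopifnot(is.character(composition), length(composition) == 1L,
            nzchar(composition))
  m <- gregexpr("([A-Z][a-z]?)(\\d*)", composition)[[1]]
  toks <- regmatches(composition, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(composition)) {
    abort(sprintf("cannot parse elemental formula '%s'", composition))
  }
  sym <- sub("\\d+$", "", toks)
  cnt <- as.integer(ifelse(grepl("\\d", toks), sub("^[A-Za-z]+", "", toks), 1L))
  unknown <- setdiff(sym, names(.MONOISOTOPIC_MASS))
  if (length(unknown)) {
    abort(sprintf("unknown element symbol(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  tapply(cnt, factor(sym, levels = unique(sym)), sum)
}

#' Theoretical m/z of an ion from its elemental composition
#'
#' Computes `(sum of monoisotopic atomic masses - charge * electron mass) /
#' charge` for the intact cation described by `composition`. Monoisotopic
#' masses are embedded constants; the electron-mass correction matters at the
#' fourth decimal place for low-mass diagnostic ions.
#'
#' @param composition Elemental formula of the intact cation, e.g. `"C7H12NO"`
#'   for the acetyllysine immonium-derived fragment or `"C8H14NO5"` for the
#'   HexNAc oxonium ion.
#' @param charge Positive integer charge (default 1).
#' @return The m/z value (Th) as a double.
#' @export
#' @examples
#' compute_ion_mz("C7H12NO") # acetyllysine diagnostic ion, 126.0913
#' compute_ion_mz("C8H14NO5") # HexNAc oxonium ion, ~204.0866
compute_ion_mz <- function(composition, charge = 1L) {
  stopifnot(length(charge) == 1L, charge >= 1, charge == as.integer(charge))
  counts <- .parse_formula(composition)
  mass <- sum(counts * .MONOISOTOPIC_MASS[names(counts)])
  (mass - charge * .ELECTRON_MASS) / charge
}

#' Construct a diagnostic-ion definition
#'
#' A diagnostic ion is a low-mass fragment (immonium- or oxonium-type) whose
#' presence in an MS/MS spectrum flags a modification of interest. Either
#' `composition` or `target_mz` must be given; when both are given they must
#' agree within 0.0005 Th, and when only the composition is given the target
#' is computed from it.
#'
#' @param name Short ion name used in reports.
#' @param composition Elemental formula of the singly charged cation, or `NA`.
#' @param target_mz Target m/z, or `NA` to derive from `composition`.
#' @param tolerance_ppm Matching half-window in parts per million of the
#'   target m/z (default 5, the conventional high-resolution MS/MS accuracy).
#' @return A one-row tibble with columns `name`, `composition`, `target_mz`,
#'   `tolerance_ppm`; rows from several calls can be `rbind`-ed into an ion
#'   set for [filter_spectra()].
#' @export
diagnostic_ion <- function(name, composition = NA_character_,
                           target_mz = NA_real_, tolerance_ppm = 5) {
  stopifnot(is.character(name), nzchar(name), tolerance_ppm > 0)
  if (is.na(composition) && is.na(target_mz)) {
    abort("either `composition` or `target_mz` is required")
  }
  if (!is.na(composition)) {
    computed <- compute_ion_mz(composition, 1L)
    if (is.na(target_mz)) {
      target_mz <- computed
    } else if (abs(target_mz - computed) > 0.0005) {
      abort(sprintf(
        "target_mz %.4f disagrees with composition %s (computed %.4f)",
        target_mz, composition, computed
      ))
    }
  }
  tibble(
    name = name, composition = composition,
    target_mz = as.numeric(target_mz), tolerance_ppm = as.numeric(tolerance_ppm)
  )
}

#' Built-in registry of diagnostic fragment ions
#'
#' Ships the ions used for acetylation and glycosylation screening: the
#' acetyllysine immonium-derived fragment (126.0913), the HexNAc oxonium ion
#' (~204.0866) and its double-water-loss fragment (~168.0655). Targets are
#' derived from elemental composition with [compute_ion_mz()]; all default to
#' a 5 ppm tolerance. Extend the set with [diagnostic_ion()] or load a custom
#' registry with [read_ion_registry()].
#'
#' @return A tibble of diagnostic ions (`name`, `composition`, `target_mz`,
#'   `tolerance_ppm`).
#' @export
#' @examples
#' builtin_ion_registry()
builtin_ion_registry <- function() {
  bind_rows(
    diagnostic_ion("acK", "C7H12NO"),
    diagnostic_ion("HexNAc", "C8H14NO5"),
    diagnostic_ion("HexNAc-2H2O", "C8H10NO3")
  )
}

#' Read a diagnostic-ion registry from a TSV file
#'
#' The file must have a header row and columns `name`, `composition`,
#' `target_mz`, `tolerance_ppm`; empty composition or target cells are
#' allowed (one of the two is required per row) and each row is validated
#' through [diagnostic_ion()].
#'
#' @param path Path to a tab-separated registry file.
#' @return A tibble of diagnostic ions.
#' @export
read_ion_registry <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(),
    composition = readr::col_character(),
    target_mz = readr::col_double(),
    tolerance_ppm = readr::col_double()
  ))
  purrr::pmap_dfr(raw, function(name, composition, target_mz, tolerance_ppm) {
    diagnostic_ion(
      name,
      composition = composition %||% NA_character_,
      target_mz = target_mz %||% NA_real_,
      tolerance_ppm = if (is.na(tolerance_ppm)) 5 else tolerance_ppm
    )
  })
}
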