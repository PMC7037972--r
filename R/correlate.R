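# Protein-metabolite correlation: Pearson and Spearman with two-sided
# p-values from the t transform at n - 2 degrees of freedom, pairwise-complete
# observations, and the disjunctive p <= cutoff significance flag.

#' Read an abundance matrix TSV
#'
#' Expected layout: header row of sample ids, first column the feature id,
#' remaining columns numeric abundances (empty or `NA` cells allowed).
#'
#' @param path Path to a tab-separated abundance table.
#' @return A tibble whose first column is the feature id.
#' @export
read_abundance_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ))
}

#' Write an abundance matrix TSV
#'
#' @param x A tibble whose first column is the feature id.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Roll peptide-group quantities up to protein abundances
#'
#' Per protein and sample, the protein abundance is the arithmetic mean of
#' that protein's peptide-group values; missing values are excluded from the
#' mean, and a protein/sample cell with no observed peptide group at all is
#' missing. Protein order follows first appearance in the peptide table.
#'
#' @param peptides Tibble with columns `peptide_group_id`, `protein_id`, and
#'   one numeric column per sample. Each peptide group must map to exactly
#'   one protein.
#' @return An abundance tibble: `protein_id` plus the sample columns.
#' @export
roll_up_protein_abundance <- function(peptides) {
  stopifnot(
    is.data.frame(peptides), nrow(peptides) > 0,
    all(c("peptide_group_id", "protein_id") %in% names(peptides))
  )
  multi <- peptides |>
    dplyr::distinct(.data$peptide_group_id, .data$protein_id) |>
    dplyr::count(.data$peptide_group_id) |>
    filter(.data$n > 1)
  if (nrow(multi)) {
    abort(sprintf(
      "peptide group(s) mapped to multiple proteins, e.g. '%s'",
      multi$peptide_group_id[1]
    ))
  }
  sample_cols <- setdiff(names(peptides), c("peptide_group_id", "protein_id"))
  mean_or_na <- function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }
  peptides |>
    mutate(protein_id = factor(.data$protein_id,
      levels = unique(.data$protein_id)
    )) |>
    group_by(.data$protein_id) |>
    summarise(across(all_of(sample_cols), mean_or_na), .groups = "drop") |>
    mutate(protein_id = as.character(.data$protein_id))
}

# Two-sided p for a sample correlation r at n observations: t = r *
# sqrt((n-2)/(1-r^2)) referred to Student's t with n - 2 df. Exactly +-1
# gives p = 0.
.p_from_r <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  one <- ok & abs(r) >= 1
  p[one] <- 0
  mid <- ok & !one
  if (any(mid)) {
    t <- abs(r[mid]) * sqrt((n[mid] - 2) / (1 - r[mid]^2))
    p[mid] <- 2 * pt(-t, n[mid] - 2)
  }
  p
}

# Pearson r of two complete vectors, NA when either is constant.
.pearson_r <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    return(NA_real_)
  }
  max(-1, min(1, sum(dx * dy) / sqrt(sxx * syy)))
}

#' Pearson correlation with a two-sided p-value
#'
#' Missing values are removed pairwise; with fewer than `min_n` complete
#' pairs, or a constant vector, the statistics are undefined (`NA`) rather
#' than an error. The p-value is the two-sided tail of Student's t with
#' `n - 2` degrees of freedom at `t = r * sqrt((n-2)/(1-r^2))`.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param min_n Minimum number of complete pairs (default 3).
#' @return A one-row tibble with columns `estimate`, `p_value`, `n_used`.
#' @export
pearson_with_p <- function(x, y, min_n = 3) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < max(min_n, 3)) {
    return(tibble(estimate = NA_real_, p_value = NA_real_, n_used = n))
  }
  r <- .pearson_r(x[ok], y[ok])
  tibble(estimate = r, p_value = .p_from_r(r, n), n_used = n)
}

#' Spearman rank correlation with a two-sided p-value
#'
#' The rank correlation is the Pearson correlation of average ranks (ties
#' averaged), with the p-value from the same t transform as
#' [pearson_with_p()]. Invariant under strictly monotone transforms of either
#' vector.
#'
#' @inheritParams pearson_with_p
#' @return A one-row tibble with columns `estimate`, `p_value`, `n_used`.
#' @export
spearman_with_p <- function(x, y, min_n = 3) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < max(min_n, 3)) {
    return(tibble(estimate = NA_real_, p_value = NA_real_, n_used = n))
  }
  r <- .pearson_r(rank(x[ok]), rank(y[ok]))
  tibble(estimate = r, p_value = .p_from_r(r, n), n_used = n)
}

.abundance_matrix <- function(x, what) {
  stopifnot(is.data.frame(x), ncol(x) >= 2)
  ids <- as.character(x[[1]])
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate feature ids in %s matrix", what))
  }
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Correlate every protein against every small-molecule feature
#'
#' Computes, for each (protein, metabolite) pair across the shared samples,
#' the Pearson and Spearman correlations with two-sided p-values on
#' pairwise-complete observations, and flags the pair when either p-value is
#' at or below `p_cutoff`. Pairs with fewer than `min_n` complete samples or
#' a constant vector get undefined statistics and are never flagged. No
#' multiple-testing correction is applied to the flag; Benjamini-Hochberg
#' adjusted columns can be added with `bh = TRUE` for reference.
#'
#' @param proteins,metabolites Abundance tibbles (first column feature id,
#'   remaining columns samples). Both must have the same sample columns in
#'   the same order.
#' @param p_cutoff Significance cutoff applied disjunctively to the two
#'   p-values (default 0.05).
#' @param min_n Minimum complete pairs per correlation (default 3).
#' @param bh Add BH-adjusted p-value columns (default `FALSE`).
#' @param log2 Log2-transform abundances first (non-positive values become
#'   missing); default `FALSE`.
#' @return A tibble of class `draftmap_corr`, protein-major order, with
#'   columns `protein_id`, `metabolite_id`, `n_used`, `pearson_r`,
#'   `pearson_p`, `spearman_rho`, `spearman_p`, `flagged` (and `pearson_p_bh`,
#'   `spearman_p_bh` when `bh = TRUE`).
#' @export
correlate_all <- function(proteins, metabolites, p_cutoff = 0.05, min_n = 3,
                          bh = FALSE, log2 = FALSE) {
  ps <- names(proteins)[-1]
  ms <- names(metabolites)[-1]
  if (!identical(ps, ms)) {
    abort(sprintf(
      "sample sets differ: only in proteins [%s]; only in metabolites [%s]%s",
      paste(setdiff(ps, ms), collapse = ", "),
      paste(setdiff(ms, ps), collapse = ", "),
      if (setequal(ps, ms)) "; same samples but different order" else ""
    ))
  }
  pm <- .abundance_matrix(proteins, "protein")
  mm <- .abundance_matrix(metabolites, "metabolite")
  if (log2) {
    pm[pm <= 0] <- NA
    mm[mm <= 0] <- NA
    pm <- base::log2(pm)
    mm <- base::log2(mm)
  }
  np <- nrow(pm)
  nm <- nrow(mm)
  ns <- ncol(pm)

  complete <- !anyNA(pm) && !anyNA(mm)
  if (complete && ns >= max(min_n, 3)) {
    r_p <- .row_cor(pm, mm)
    r_s <- .row_cor(
      t(apply(pm, 1, rank)),
      t(apply(mm, 1, rank))
    )
    pearson_r <- as.vector(t(r_p))
    spearman_rho <- as.vector(t(r_s))
    n_used <- rep(ns, np * nm)
  } else {
    pearson_r <- numeric(np * nm)
    spearman_rho <- numeric(np * nm)
    n_used <- integer(np * nm)
    k <- 0L
    for (i in seq_len(np)) {
      for (j in seq_len(nm)) {
        k <- k + 1L
        x <- pm[i, ]
        y <- mm[j, ]
        ok <- !is.na(x) & !is.na(y)
        n <- sum(ok)
        n_used[k] <- n
        if (n < max(min_n, 3)) {
          pearson_r[k] <- NA_real_
          spearman_rho[k] <- NA_real_
        } else {
          pearson_r[k] <- .pearson_r(x[ok], y[ok])
          spearman_rho[k] <- .pearson_r(rank(x[ok]), rank(y[ok]))
        }
      }
    }
  }
  pearson_p <- .p_from_r(pearson_r, n_used)
  spearman_p <- .p_from_r(spearman_rho, n_used)
  flagged <- (!is.na(pearson_p) & pearson_p <= p_cutoff) |
    (!is.na(spearman_p) & spearman_p <= p_cutoff)
  out <- tibble(
    protein_id = rep(rownames(pm), each = nm),
    metabolite_id = rep(rownames(mm), times = np),
    n_used = as.integer(n_used),
    pearson_r = pearson_r,
    pearson_p = pearson_p,
    spearman_rho = spearman_rho,
    spearman_p = spearman_p,
    flagged = flagged
  )
  if (bh) {
    out$pearson_p_bh <- stats::p.adjust(out$pearson_p, method = "BH")
    out$spearman_p_bh <- stats::p.adjust(out$spearman_p, method = "BH")
  }
  structure(
    out,
    class = c("draftmap_corr", class(out)),
    p_cutoff = p_cutoff
  )
}

# All pairwise Pearson correlations between the rows of two complete
# matrices with identical column sets; constant rows give NA.
.row_cor <- function(a, b) {
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  na <- sqrt(rowSums(ac^2))
  nb <- sqrt(rowSums(bc^2))
  r <- tcrossprod(ac, bc) / outer(na, nb)
  r[!is.finite(r)] <- NA_real_
  pmin(pmax(r, -1), 1)
}

#' @exportS3Method generics::glance
glance.draftmap_corr <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    n_defined = sum(!is.na(x$pearson_r)),
    n_flagged = sum(x$flagged),
    flag_rate = ifelse(nrow(x) > 0, sum(x$flagged) / nrow(x), NA_real_),
    p_cutoff = attr(x, "p_cutoff")
  )
}

#' @describeIn correlate_all Scatter of Pearson r against -log10 p, flagged
#'   pairs highlighted.
#' @param object A `draftmap_corr` tibble.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.draftmap_corr <- function(object, ...) {
  dat <- filter(as_tibble(object), !is.na(.data$pearson_p))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$pearson_r, y = -log10(.data$pearson_p), colour = .data$flagged
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick")
    ) +
    ggplot2::labs(
      x = "Pearson r", y = expression(-log[10] ~ p),
      colour = sprintf("p <= %.3g", attr(object, "p_cutoff"))
    ) +
    ggplot2::theme_minimal()
}

#' Top correlated proteins for one metabolite
#'
#' Ranks the proteins whose Pearson correlation with the metabolite has the
#' requested sign, by descending `|r|`, ties broken by ascending Pearson p
#' and then protein id.
#'
#' @param results A `draftmap_corr` tibble from [correlate_all()].
#' @param metabolite_id The metabolite to rank against (must occur in
#'   `results`).
#' @param direction `"positive"` or `"negative"`.
#' @param k Maximum number of rows returned (default all).
#' @return The selected, ranked result rows.
#' @export
top_correlates <- function(results, metabolite_id,
                           direction = c("positive", "negative"), k = Inf) {
  direction <- match.arg(direction)
  stopifnot(length(metabolite_id) == 1L, k >= 0)
  if (!metabolite_id %in% results$metabolite_id) {
    abort(sprintf("unknown metabolite id '%s'", metabolite_id))
  }
  sel <- results |>
    as_tibble() |>
    filter(
      .data$metabolite_id == .env$metabolite_id,
      !is.na(.data$pearson_r),
      if (.env$direction == "positive") .data$pearson_r > 0 else .data$pearson_r < 0
    ) |>
    arrange(
      desc(abs(.data$pearson_r)), .data$pearson_p, .data$protein_id
    )
  head(sel, n = k)
}
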