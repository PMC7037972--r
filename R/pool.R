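#' Concatenation pooling plan for fractionation
#'
#' Assigns collected chromatographic fractions to concatenated pools
#' cyclically, `pool(i) = i mod n_pools`, so each pool contains every
#' `n_pools`-th fraction and spans the whole gradient (maximal orthogonality
#' to the second separation dimension). With 96 collected fractions and 12
#' pools, each pool holds exactly 8 fractions.
#'
#' @param n_fractions Number of collected fractions.
#' @param n_pools Number of concatenated pools; must not exceed
#'   `n_fractions`.
#' @return A tibble of class `pooling_plan` with columns `fraction_index` and
#'   `pool_index` (both 0-based); pool sizes differ by at most one, and the
#'   members of each pool form an arithmetic progression with common
#'   difference `n_pools`.
#' @export
#' @examples
#' make_pooling_plan(96, 12)
make_pooling_plan <- function(n_fractions, n_pools) {
  stopifnot(
    length(n_fractions) == 1L, length(n_pools) == 1L,
    n_fractions >= 1, n_pools >= 1,
    n_fractions == as.integer(n_fractions), n_pools == as.integer(n_pools)
  )
  if (n_pools > n_fractions) {
    abort(sprintf(
      "n_pools (%d) must not exceed n_fractions (%d)", n_pools, n_fractions
    ))
  }
  fraction_index <- seq_len(n_fractions) - 1L
  out <- tibble(
    fraction_index = fraction_index,
    pool_index = fraction_index %% as.integer(n_pools)
  )
  structure(
    out,
    class = c("pooling_plan", class(out)),
    n_fractions = as.integer(n_fractions),
    n_pools = as.integer(n_pools)
  )
}

#' @describeIn make_pooling_plan Tile plot of the fraction-to-pool
#'   assignment.
#' @param object A `pooling_plan`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.pooling_plan <- function(object, ...) {
  n_pools <- attr(object, "n_pools")
  dat <- mutate(
    as_tibble(object),
    slot = .data$fraction_index %/% n_pools
  )
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$slot, y = .data$pool_index, fill = .data$fraction_index
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_y_reverse(breaks = unique(dat$pool_index)) +
    ggplot2::labs(
      x = "position within pool", y = "pool", fill = "fraction",
      title = sprintf(
        "%d fractions concatenated into %d pools",
        attr(object, "n_fractions"), n_pools
      )
    ) +
    ggplot2::theme_minimal()
}
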