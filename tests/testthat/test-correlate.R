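test_that("peptide-group roll-up averages per protein and sample", {
  single <- tibble::tibble(
    peptide_group_id = "pg1", protein_id = "P1", s1 = 7
  )
  expect_identical(roll_up_protein_abundance(single)$s1, 7)

  two <- tibble::tibble(
    peptide_group_id = c("pg1", "pg2"), protein_id = "P1",
    s1 = c(2, 4), s2 = c(3, NA)
  )
  rolled <- roll_up_protein_abundance(two)
  expect_identical(rolled$s1, 3) # mean of 2 and 4
  expect_identical(rolled$s2, 3) # missing excluded from the mean

  all_na <- tibble::tibble(
    peptide_group_id = c("a", "b"), protein_id = "P1",
    s1 = c(NA_real_, NA_real_)
  )
  expect_true(is.na(roll_up_protein_abundance(all_na)$s1))

  conflicted <- tibble::tibble(
    peptide_group_id = c("pg1", "pg1"), protein_id = c("P1", "P2"), s1 = c(1, 2)
  )
  expect_error(roll_up_protein_abundance(conflicted), "multiple proteins")
})

test_that("roll-up equals a naive per-cell averaging oracle", {
  withr::local_seed(19)
  n_prot <- 200L
  rows <- lapply(seq_len(n_prot), function(i) {
    k <- sample(1:5, 1)
    tibble::tibble(
      peptide_group_id = sprintf("P%03d_pg%d", i, seq_len(k)),
      protein_id = sprintf("P%03d", i),
      s1 = round(stats::runif(k, 0.1, 10), 3),
      s2 = ifelse(stats::runif(k) < 0.2, NA, round(stats::runif(k, 0.1, 10), 3)),
      s3 = round(stats::runif(k, 0.1, 10), 3)
    )
  })
  peptides <- dplyr::bind_rows(rows)
  rolled <- roll_up_protein_abundance(peptides)
  expect_identical(nrow(rolled), n_prot)
  for (i in sample(n_prot, 25)) {
    pid <- sprintf("P%03d", i)
    sub <- peptides[peptides$protein_id == pid, ]
    for (s in c("s1", "s2", "s3")) {
      v <- sub[[s]][!is.na(sub[[s]])]
      want <- if (length(v)) mean(v) else NA_real_
      expect_equal(rolled[[s]][rolled$protein_id == pid], want)
    }
  }
})

test_that("pearson_with_p matches its closed form and cor.test", {
  x <- c(1, 2, 3, 4, 5)
  exact <- pearson_with_p(x, 2 * x + 1)
  expect_identical(exact$estimate, 1)
  expect_identical(exact$p_value, 0)

  # r = 0.9997 over 6 samples is significant beyond the published 1.54e-7
  withr::local_seed(3)
  v <- vectors_with_exact_r(0.9997, 6)
  res <- pearson_with_p(v$x, v$y)
  expect_equal(res$estimate, 0.9997, tolerance = 1e-12)
  expect_lte(res$p_value, 1.54e-7)

  # against the independent implementation, 6 significant figures
  withr::local_seed(5)
  for (i in 1:10) {
    a <- stats::rnorm(50)
    b <- 0.4 * a + stats::rnorm(50)
    mine <- pearson_with_p(a, b)
    ref <- stats::cor.test(a, b)
    expect_equal(mine$estimate, unname(ref$estimate), tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-6)
  }
})

test_that("spearman_with_p handles monotone transforms and ties", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  y <- exp(x)
  expect_identical(spearman_with_p(x, y)$estimate, 1)
  expect_identical(spearman_with_p(x, -y)$estimate, -1)

  # rank invariance under a strictly monotone transform
  withr::local_seed(23)
  a <- stats::rnorm(15)
  b <- stats::rnorm(15)
  expect_equal(
    spearman_with_p(a, b)$estimate,
    spearman_with_p(a^3, exp(b))$estimate
  )

  # ties: average ranks, cross-checked against the stats implementation
  xt <- c(1, 2, 2, 3, 4, 4, 5)
  yt <- c(2, 1, 3, 3, 5, 4, 6)
  mine <- spearman_with_p(xt, yt)
  expect_equal(
    mine$estimate,
    unname(stats::cor(xt, yt, method = "spearman"))
  )
  ref <- suppressWarnings(stats::cor.test(xt, yt, method = "spearman", exact = FALSE))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("undefined statistics propagate instead of erroring", {
  const <- rep(2, 6)
  out <- pearson_with_p(const, stats::rnorm(6))
  expect_true(is.na(out$estimate) && is.na(out$p_value))
  short <- pearson_with_p(c(1, 2, NA, NA, NA, NA), c(1, 2, 3, NA, NA, NA))
  expect_true(is.na(short$estimate))
  expect_identical(short$n_used, 2L)
})

test_that("Pearson r is affine-invariant up to sign", {
  withr::local_seed(29)
  x <- stats::rnorm(12)
  y <- stats::rnorm(12)
  r0 <- pearson_with_p(x, y)$estimate
  expect_equal(pearson_with_p(x, 3 * y + 7)$estimate, r0)
  expect_equal(pearson_with_p(x, -2 * y + 1)$estimate, -r0)
})

test_that("correlate_all recovers a planted pair as the top flagged hit", {
  ab <- sim_abundance(
    seed = 83, n_proteins = 100, n_metabolites = 1, planted_r = 0.999
  )
  res <- correlate_all(ab$proteins, ab$metabolites)
  expect_identical(nrow(res), 100L)
  top <- res[which.max(res$pearson_r), ]
  expect_identical(top$protein_id, "P0001")
  expect_true(top$flagged)
  expect_equal(top$pearson_r, 0.999, tolerance = 1e-9)
})

test_that("correlate_all matches cor.test flags on a mixed fixture", {
  ab <- sim_abundance(
    seed = 89, n_proteins = 25, n_metabolites = 20,
    planted_r = c(0.99, -0.98, 0.9)
  )
  res <- correlate_all(ab$proteins, ab$metabolites)
  expect_identical(nrow(res), 500L)
  # protein-major deterministic order
  expect_identical(
    res$protein_id,
    rep(ab$proteins$protein_id, each = nrow(ab$metabolites))
  )
  pmat <- as.matrix(ab$proteins[, -1])
  mmat <- as.matrix(ab$metabolites[, -1])
  for (k in sample(nrow(res), 40)) {
    x <- pmat[match(res$protein_id[k], ab$proteins$protein_id), ]
    y <- mmat[match(res$metabolite_id[k], ab$metabolites$metabolite_id), ]
    refp <- stats::cor.test(x, y)
    refs <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE)
    )
    expect_equal(res$pearson_r[k], unname(refp$estimate), tolerance = 1e-9)
    expect_equal(res$pearson_p[k], refp$p.value, tolerance = 1e-9)
    expect_equal(res$spearman_rho[k], unname(refs$estimate), tolerance = 1e-9)
    expect_equal(res$spearman_p[k], refs$p.value, tolerance = 1e-9)
    expect_identical(
      res$flagged[k],
      refp$p.value <= 0.05 || refs$p.value <= 0.05
    )
  }
  # bounds
  ok <- !is.na(res$pearson_r)
  expect_true(all(abs(res$pearson_r[ok]) <= 1))
  expect_true(all(res$pearson_p[ok] > 0 | res$pearson_r[ok] == 1))
  expect_true(all(res$pearson_p[ok] <= 1))
})

test_that("pairwise-complete and degenerate inputs are handled per pair", {
  proteins <- tibble::tibble(
    protein_id = c("Pconst", "Pmiss", "Pok"),
    s1 = c(5, 1.2, 2.4), s2 = c(5, NA, 3.1), s3 = c(5, NA, 1.8),
    s4 = c(5, NA, 4.4), s5 = c(5, 2.0, 3.9), s6 = c(5, 1.1, 2.2)
  )
  metabolites <- tibble::tibble(
    metabolite_id = "M1",
    s1 = 1.0, s2 = 2.0, s3 = 3.0, s4 = 4.0, s5 = 5.0, s6 = 6.0
  )
  res <- correlate_all(proteins, metabolites)
  const_row <- res[res$protein_id == "Pconst", ]
  expect_true(is.na(const_row$pearson_r))
  expect_false(const_row$flagged)
  miss_row <- res[res$protein_id == "Pmiss", ]
  expect_identical(miss_row$n_used, 3L)
  ok_row <- res[res$protein_id == "Pok", ]
  expect_identical(ok_row$n_used, 6L)
  # the general (missing-data) path agrees with cor.test on complete pairs
  ref <- stats::cor.test(
    c(1.2, 2.0, 1.1), c(1, 5, 6)
  )
  expect_equal(miss_row$pearson_r, unname(ref$estimate), tolerance = 1e-9)

  bad_samples <- dplyr::rename(metabolites, z9 = s6)
  expect_error(correlate_all(proteins, bad_samples), "sample sets differ")
})

test_that("null data is flagged at close to the nominal rate", {
  ab <- sim_abundance(seed = 97, n_proteins = 50, n_metabolites = 10)
  res <- correlate_all(ab$proteins, ab$metabolites)
  g <- glance(res)
  expect_identical(g$n_pairs, 500L)
  # empirical null of the disjunctive Pearson-or-Spearman flag at n = 6,
  # estimated by direct simulation with the reference implementations
  withr::local_seed(98)
  sim_flag <- replicate(4000, {
    x <- stats::rnorm(6)
    y <- stats::rnorm(6)
    stats::cor.test(x, y)$p.value <= 0.05 ||
      suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value
      ) <= 0.05
  })
  null_rate <- mean(sim_flag)
  se <- sqrt(null_rate * (1 - null_rate) * (1 / 500 + 1 / 4000))
  expect_lt(abs(g$flag_rate - null_rate), 2.58 * se + 1e-12)
})

test_that("top_correlates ranks by |r| within the requested sign", {
  ab <- sim_abundance(
    seed = 103, n_proteins = 60, n_metabolites = 1,
    planted_r = 0.97
  )
  # plant two more positive and two negative correlates with metabolite M0001
  m <- as.numeric(ab$metabolites[1, -1])
  ab$proteins[2, -1] <- as.list(m * 1.5 + 10) # r = 1
  ab$proteins[3, -1] <- as.list(m + stats::rnorm(6, sd = 20))
  ab$proteins[4, -1] <- as.list(-m * 2 + 4000) # r = -1
  ab$proteins[5, -1] <- as.list(-m + stats::rnorm(6, sd = 25))
  res <- correlate_all(ab$proteins, ab$metabolites)

  pos <- top_correlates(res, "M0001", "positive", k = 3)
  expect_identical(nrow(pos), 3L)
  expect_identical(pos$protein_id[1], "P0002") # the exact linear copy
  expect_true(all(pos$pearson_r > 0))
  expect_true(all(diff(abs(pos$pearson_r)) <= 0))

  neg <- top_correlates(res, "M0001", "negative", k = Inf)
  expect_identical(neg$protein_id[1], "P0004")
  expect_true(all(neg$pearson_r < 0))

  expect_identical(nrow(top_correlates(res, "M0001", "positive", k = 0)), 0L)
  expect_error(top_correlates(res, "nope", "positive"), "unknown metabolite")

  all_pos <- res[res$pearson_r > 0 & !is.na(res$pearson_r), ]
  expect_identical(
    nrow(top_correlates(res, "M0001", "positive")),
    nrow(all_pos)
  )
})

test_that("BH columns and log2 transform are optional extras", {
  ab <- sim_abundance(seed = 107, n_proteins = 10, n_metabolites = 5)
  res <- correlate_all(ab$proteins, ab$metabolites, bh = TRUE)
  expect_true(all(c("pearson_p_bh", "spearman_p_bh") %in% names(res)))
  expect_true(all(res$pearson_p_bh >= res$pearson_p, na.rm = TRUE))
  res2 <- correlate_all(ab$proteins, ab$metabolites, log2 = TRUE)
  expect_identical(nrow(res2), 50L)
})
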