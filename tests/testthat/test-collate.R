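# Build a count table giving template `tid` a chosen marginal error at one
# position: fraction `err` of counts go to a triplet differing from the
# cognate only at `pos`.
counts_with_error <- function(design, tid, pos, err, n = 10000) {
  cog <- design$cognate[design$template_id == tid]
  wrong <- cog
  substr(wrong, pos, pos) <- setdiff(rna_bases(), substr(cog, pos, pos))[1]
  tibble::tibble(template_id = tid, triplet = c(cog, wrong),
                 count = c(n * (1 - err), n * err))
}

test_that("collation takes unweighted linear averages over the three templates per base", {
  d <- test_design()
  # the three templates encoding A at position 1, with errors 0.01/0.02/0.03
  tpl_a <- d$template_id[substr(d$cognate, 1, 1) == "A"]
  expect_length(tpl_a, 3L)
  rows <- dplyr::bind_rows(
    counts_with_error(d, tpl_a[1], 1, 0.01),
    counts_with_error(d, tpl_a[2], 1, 0.02),
    counts_with_error(d, tpl_a[3], 1, 0.03),
    {
      rest <- d$template_id[!d$template_id %in% tpl_a]
      tibble::tibble(template_id = rest,
                     triplet = d$cognate[match(rest, d$template_id)],
                     count = 10000)
    }
  )
  profile <- collate_positional(triplet_counts(rows, "corrected",
                                               d$template_id), d)
  diag_a1 <- profile$rate[profile$position == 1 &
                            profile$encoded_base == "A" &
                            profile$incorporated_base == "A"]
  expect_equal(diag_a1, 1 - 0.02, tolerance = 1e-12)
  # unweighted even though depths differ
  rows2 <- dplyr::bind_rows(
    counts_with_error(d, tpl_a[1], 1, 0.01, n = 100),
    counts_with_error(d, tpl_a[2], 1, 0.02, n = 100000),
    counts_with_error(d, tpl_a[3], 1, 0.03, n = 1000),
    {
      rest <- d$template_id[!d$template_id %in% tpl_a]
      tibble::tibble(template_id = rest,
                     triplet = d$cognate[match(rest, d$template_id)],
                     count = 10000)
    }
  )
  profile2 <- collate_positional(triplet_counts(rows2, "corrected",
                                                d$template_id), d)
  diag2 <- profile2$rate[profile2$position == 1 &
                           profile2$encoded_base == "A" &
                           profile2$incorporated_base == "A"]
  expect_equal(diag2, 1 - 0.02, tolerance = 1e-12)
})

test_that("cognate-only counts give the identity profile and 100% fidelities", {
  d <- test_design()
  profile <- collate_positional(cognate_only_counts(d), d)
  diag <- profile$rate[profile$encoded_base == profile$incorporated_base]
  off <- profile$rate[profile$encoded_base != profile$incorporated_base]
  expect_true(all(diag == 1))
  expect_true(all(off == 0))
  fid <- positional_fidelity(profile)
  expect_equal(fid$overall_pct, 100)
  expect_true(all(fid$per_base$fidelity_pct == 100))
})

test_that("profile rows sum to one for each (position, encoded base)", {
  d <- test_design()
  m <- incorporation_model(d, positional_error = c(0.05, 0.02, 0.01))
  counts <- count_triplets(gen_fidelity_reads(d, m, 20000, seed = 8), d)
  profile <- collate_positional(counts, d)
  sums <- profile |>
    dplyr::group_by(.data$position, .data$encoded_base) |>
    dplyr::summarise(s = sum(.data$rate), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("collated rates recover a known profile from clean reads", {
  d <- test_design()
  m <- incorporation_model(d, positional_error = c(0.05, 0.03, 0.015),
                           seq_error = 0)
  counts <- count_triplets(gen_fidelity_reads(d, m, 1.2e5, seed = 9), d)
  est <- collate_positional(counts, d)
  truth <- expected_profile(m, d)
  key <- paste(truth$position, truth$encoded_base, truth$incorporated_base)
  est_rate <- est$rate[match(key, paste(est$position, est$encoded_base,
                                        est$incorporated_base))]
  # ~3e4 first-triplet draws per (position, base) cell
  se <- sqrt(pmax(truth$rate * (1 - truth$rate), 1e-6) / 3e4)
  expect_true(all(abs(est_rate - truth$rate) <= 4 * se))
})

test_that("geometric-mean fidelity summaries match hand arithmetic", {
  # positional fidelity from per-base fidelities
  expect_equal(geometric_mean(c(0.99, 0.98, 0.97, 0.96)) * 100, 97.49359,
               tolerance = 1e-5)
  expect_equal(naive_gm(c(0.99, 0.98, 0.97, 0.96)),
               geometric_mean(c(0.99, 0.98, 0.97, 0.96)), tolerance = 1e-12)
  # overall from positional
  expect_equal(geometric_mean(c(97, 98, 99)), 97.9966, tolerance = 1e-4)
  # permutation invariance
  withr::with_seed(1, {
    for (i in 1:10) {
      x <- stats::runif(6, 0.5, 1)
      expect_equal(geometric_mean(x), geometric_mean(sample(x)),
                   tolerance = 1e-12)
    }
  })
})

test_that("fidelity result respects its internal geometric-mean invariants", {
  d <- test_design()
  m <- incorporation_model(d, positional_error = c(0.08, 0.04, 0.02))
  fid <- positional_fidelity(expected_profile(m, d))
  for (p in 1:3) {
    per_base <- fid$per_base$fidelity_pct[fid$per_base$position == p] / 100
    expect_equal(fid$positional$fidelity_pct[fid$positional$position == p],
                 100 * naive_gm(per_base), tolerance = 1e-9)
  }
  expect_equal(fid$overall_pct,
               100 * naive_gm(fid$positional$fidelity_pct / 100),
               tolerance = 1e-9)
  g <- glance(fid)
  expect_equal(g$overall_pct, fid$overall_pct)
  expect_equal(nrow(tidy(fid)), 12)
})

test_that("a zero diagonal is floored, not fatal", {
  d <- test_design()
  # template set where one encoded base is never incorporated correctly
  tpl_a <- d$template_id[substr(d$cognate, 1, 1) == "A"]
  rows <- dplyr::bind_rows(
    lapply(tpl_a, function(t) counts_with_error(d, t, 1, 1.0)),
    list(tibble::tibble(
      template_id = setdiff(d$template_id, tpl_a),
      triplet = d$cognate[match(setdiff(d$template_id, tpl_a),
                                d$template_id)],
      count = 10000))
  )
  profile <- collate_positional(triplet_counts(rows, "corrected",
                                               d$template_id), d)
  fid <- positional_fidelity(profile, floor = 1e-6)
  expect_gt(fid$overall_pct, 0)
  expect_lt(fid$positional$fidelity_pct[1], 5)
})

test_that("contest ratios and reductions follow the printed arithmetic", {
  d <- test_design()
  tid <- d$template_id[1]
  cog <- d$cognate[1]
  t1 <- triplet_counts(tibble::tibble(
    template_id = tid, triplet = c(cog, "GGC"), count = c(900, 100)),
    "experimental", d$template_id[1])
  expect_equal(contest_ratio(t1, tid, cog, "GGC"), 0.10)
  t2 <- triplet_counts(tibble::tibble(
    template_id = tid, triplet = c(cog, "GGC"), count = c(961, 39)),
    "experimental", d$template_id[1])
  expect_equal(contest_reduction(t1, t2, tid, cog, "GGC"), 0.61)
  expect_equal(contest_reduction(t1, t1, tid, cog, "GGC"), 0)
  t0 <- triplet_counts(tibble::tibble(
    template_id = tid, triplet = cog, count = 0),
    "experimental", d$template_id[1])
  expect_warning(r <- contest_ratio(t0, tid, cog, "GGC"), "undefined")
  expect_true(is.na(r))
})
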