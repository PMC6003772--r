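make_tables <- function(design, e_x, e_p, c_x, c_p, err_triplets) {
  tid <- design$template_id[1]
  cog <- design$cognate[1]
  exp_tbl <- tibble::tibble(
    template_id = c(rep(tid, length(err_triplets)), design$template_id),
    triplet = c(err_triplets, design$cognate),
    count = c(e_x, ifelse(design$template_id == tid, c_x, 100))
  )
  ctrl_tbl <- tibble::tibble(
    template_id = c(rep(tid, length(err_triplets)), design$template_id),
    triplet = c(err_triplets, design$cognate),
    count = c(e_p, ifelse(design$template_id == tid, c_p, 100))
  )
  list(
    exp = triplet_counts(exp_tbl, "experimental", design$template_id),
    ctrl = triplet_counts(ctrl_tbl, "control", design$template_id)
  )
}

test_that("the correction formula reproduces its worked examples", {
  d <- test_design()
  tid <- d$template_id[1]
  cog <- d$cognate[1]

  tabs <- make_tables(d, e_x = 10, e_p = 2, c_x = 1000, c_p = 500, "GAU")
  corr <- background_correct(tabs$exp, tabs$ctrl, d)
  expect_equal(corr$count[corr$template_id == tid & corr$triplet == "GAU"], 6)
  expect_equal(corr$count[corr$template_id == tid & corr$triplet == cog],
               1000 + 4)

  # clamping: E_x = 1, E_p = 2 -> E_r = 0 and exactly 1 reallocated
  tabs <- make_tables(d, e_x = 1, e_p = 2, c_x = 1000, c_p = 500, "GAU")
  corr <- background_correct(tabs$exp, tabs$ctrl, d)
  expect_equal(corr$count[corr$template_id == tid & corr$triplet == "GAU"], 0)
  expect_equal(corr$count[corr$template_id == tid & corr$triplet == cog],
               1001)
})

test_that("zero background leaves the experimental table unchanged", {
  d <- test_design()
  m <- incorporation_model(d, seq_error = 0.01)
  exp_counts <- count_triplets(gen_fidelity_reads(d, m, 2000, seed = 3), d)
  ctrl_counts <- cognate_only_counts(d, n = 500, sample_kind = "control")
  corr <- background_correct(exp_counts, ctrl_counts, d)
  expect_equal(corr$count, exp_counts$count)
})

test_that("control-set triplets are never corrected", {
  d <- test_design()
  acc_id <- d$template_id[d$cognate == "ACC"]
  other_id <- d$template_id[d$cognate != "ACC"][1]
  base <- tibble::tibble(template_id = d$template_id, triplet = d$cognate,
                         count = 1000)
  exp_tbl <- triplet_counts(dplyr::bind_rows(
    base,
    tibble::tibble(template_id = c(acc_id, acc_id, other_id),
                   triplet = c("CCC", "UCC", "UCC"), count = c(50, 40, 30))
  ), "experimental", d$template_id)
  ctrl_tbl <- triplet_counts(dplyr::bind_rows(
    base,
    tibble::tibble(template_id = c(acc_id, acc_id, other_id),
                   triplet = c("CCC", "UCC", "UCC"), count = c(25, 20, 15))
  ), "control", d$template_id)
  corr <- background_correct(exp_tbl, ctrl_tbl, d)
  # CCC everywhere and UCC on the ACC template keep raw counts
  expect_equal(corr$count[corr$template_id == acc_id & corr$triplet == "CCC"], 50)
  expect_equal(corr$count[corr$template_id == acc_id & corr$triplet == "UCC"], 40)
  # UCC on a non-ACC template is an error triplet and is corrected
  expect_equal(corr$count[corr$template_id == other_id & corr$triplet == "UCC"],
               30 - 15 * (1000 / 1000))
})

test_that("correction conserves per-template totals on random tables", {
  d <- test_design()
  withr::with_seed(42, {
    for (rep in 1:20) {
      exp_tbl <- triplet_counts(tibble::tibble(
        template_id = rep(d$template_id, each = 64),
        triplet = rep(all_triplets(), 12),
        count = stats::rpois(768, 3) +
          ifelse(rep(all_triplets(), 12) ==
                   rep(d$cognate, each = 64), 500, 0)
      ), "experimental", d$template_id)
      ctrl_tbl <- triplet_counts(tibble::tibble(
        template_id = rep(d$template_id, each = 64),
        triplet = rep(all_triplets(), 12),
        count = stats::rpois(768, 1) +
          ifelse(rep(all_triplets(), 12) ==
                   rep(d$cognate, each = 64), 200, 0)
      ), "control", d$template_id)
      corr <- background_correct(exp_tbl, ctrl_tbl, d)
      tot_exp <- tapply(exp_tbl$count, exp_tbl$template_id, sum)
      tot_corr <- tapply(corr$count, corr$template_id, sum)
      expect_equal(unname(tot_corr), unname(tot_exp), tolerance = 1e-12)
      expect_true(all(corr$count >= 0))
    }
  })
})

test_that("correction agrees with the brute-force formula on exhaustive small tables", {
  d <- test_design()
  err <- c("GAU", "AAA", "GGG", "UAU")
  stopifnot(!any(err %in% unlist(control_sets(d)[1])))
  grid <- expand.grid(e_x = 0:5, e_p = 0:5)
  for (depths in list(c(1000, 500), c(100, 100), c(7, 3))) {
    for (r in seq_len(nrow(grid))) {
      e_x <- rep(grid$e_x[r], 4); e_p <- rep(grid$e_p[r], 4)
      tabs <- make_tables(d, e_x, e_p, depths[1], depths[2], err)
      corr <- background_correct(tabs$exp, tabs$ctrl, d)
      for (i in seq_along(err)) {
        want <- brute_correct_one(e_x[i], e_p[i], depths[1], depths[2])
        got <- corr$count[corr$template_id == d$template_id[1] &
                            corr$triplet == err[i]]
        expect_equal(got, want$e_r, tolerance = 1e-12)
      }
      tot_exp <- tapply(tabs$exp$count, tabs$exp$template_id, sum)
      tot_corr <- tapply(corr$count, corr$template_id, sum)
      expect_equal(unname(tot_corr), unname(tot_exp), tolerance = 1e-12)
    }
  }
})

test_that("a zero control cognate count is a hard error naming the template", {
  d <- test_design()
  exp_tbl <- cognate_only_counts(d, 100)
  ctrl_tbl <- cognate_only_counts(d, 100, "control")
  ctrl_tbl$count[ctrl_tbl$template_id == "T04" &
                   ctrl_tbl$triplet == d$cognate[d$template_id == "T04"]] <- 0
  expect_error(background_correct(exp_tbl, ctrl_tbl, d), "T04")
})

test_that("mismatched template sets are a hard error", {
  d <- test_design()
  exp_tbl <- cognate_only_counts(d, 100)
  ctrl_small <- triplet_counts(
    tibble::tibble(template_id = d$template_id[1:6],
                   triplet = d$cognate[1:6], count = 100),
    "control", d$template_id[1:6]
  )
  expect_error(background_correct(exp_tbl, ctrl_small, d), "template")
})
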