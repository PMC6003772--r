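test_that("incorporation model distributions are valid and wobble-structured", {
  d <- test_design()
  m <- incorporation_model(d, positional_error = c(0.04, 0.02, 0.01),
                           wobble_weight = 0.6)
  expect_true(all(abs(rowSums(m$prob) - 1) < 1e-12))
  expect_true(all(m$prob >= 0))
  # encoded C: wobble partner is U (read through template G:U), gets 60% of
  # the error mass at that position
  tpl <- which(substr(d$cognate, 1, 1) == "C")[1]
  trips <- colnames(m$prob)
  p_u <- sum(m$prob[tpl, substr(trips, 1, 1) == "U"])
  p_err <- 1 - sum(m$prob[tpl, substr(trips, 1, 1) == "C"])
  expect_equal(p_u / p_err, 0.6, tolerance = 1e-9)
  expect_error(incorporation_model(d, seq_error = 0.5), "seq_error")
})

test_that("fidelity read generation is seed-deterministic and balanced", {
  d <- test_design()
  m <- incorporation_model(d)
  r1 <- gen_fidelity_reads(d, m, 500, seed = 3)
  r2 <- gen_fidelity_reads(d, m, 500, seed = 3)
  expect_identical(r1, r2)
  p1 <- withr::local_tempfile(fileext = ".fastq")
  p2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(r1, p1); write_fastq(r2, p2)
  expect_identical(readLines(p1), readLines(p2))

  # uniform template assignment: per-template counts within 4 sd of n/12
  r <- gen_fidelity_reads(d, m, 12000, seed = 5)
  truth <- attr(r, "truth")
  tab <- table(factor(truth$template_id, levels = d$template_id))
  sd_bin <- sqrt(12000 * (1 / 12) * (11 / 12))
  expect_true(all(abs(tab - 1000) <= 4 * sd_bin))
})

test_that("degenerate model with cognate-only mass yields cognate first triplets", {
  d <- test_design()
  prob <- matrix(0, 12, 64, dimnames = list(d$template_id, all_triplets()))
  prob[cbind(seq_len(12), match(d$cognate, all_triplets()))] <- 1
  m <- incorporation_model(d, prob = prob, seq_error = 0)
  r <- gen_fidelity_reads(d, m, 300, seed = 1)
  cls <- classify_read(r$seq, d)
  truth <- attr(r, "truth")
  expect_equal(cls$template_id, truth$template_id)
  expect_equal(cls$first_triplet, d$cognate[match(truth$template_id,
                                                  d$template_id)])
})

test_that("control reads contain only control-set triplets at zero noise", {
  d <- test_design()
  r <- gen_control_reads(d, 600, control_error = 0, seed = 2)
  cls <- classify_read(r$seq, d)
  cs <- control_sets(d)
  for (i in seq_len(nrow(cls))) {
    expect_true(all(cls$triplets[[i]] %in% cs[[cls$template_id[i]]]))
  }
})

test_that("noise-induced off-set counts scale roughly linearly with control_error", {
  d <- test_design()
  rates <- c(0.002, 0.004, 0.006, 0.008, 0.010)
  off <- sapply(seq_along(rates), function(i) {
    r <- gen_control_reads(d, 4000, control_error = rates[i], seed = 20 + i)
    cc <- count_triplets(r, d, sample_kind = "control")
    cs <- control_sets(d)
    in_set <- mapply(function(tid, trip) trip %in% cs[[tid]],
                     cc$template_id, cc$triplet)
    sum(cc$count[!in_set])
  })
  fit <- stats::lm(off ~ rates)
  expect_gt(summary(fit)$r.squared, 0.9)
  expect_gt(stats::coef(fit)[["rates"]], 0)
})

test_that("segment read generation recovers per-position error rates", {
  ref <- "GCCAUCAAAGCUUGAGAGCAUCUU"
  r0 <- gen_segment_reads(ref, rep(0, nchar(ref)), 50, seed = 1)
  expect_true(all(r0$seq == ref))
  expect_identical(gen_segment_reads(ref, rep(0.01, nchar(ref)), 50, seed = 9),
                   gen_segment_reads(ref, rep(0.01, nchar(ref)), 50, seed = 9))

  rates <- rep(0, nchar(ref)); rates[7] <- 0.1
  r <- gen_segment_reads(ref, rates, 10000, seed = 4)
  mismatch <- mean(substr(r$seq, 7, 7) != substr(ref, 7, 7))
  expect_lt(abs(mismatch - 0.1), 4 * sqrt(0.1 * 0.9 / 10000))
  expect_error(gen_segment_reads(ref, rep(0, 3), 10, seed = 1), "one rate per")
})

test_that("ladder generation matches the survival-product expectation", {
  full <- gen_ladder(rep(1, 3), n_molecules = 100)
  expect_equal(full$intensity, c(0, 0, 0, 100))
  none <- gen_ladder(rep(0, 3), n_molecules = 100)
  expect_equal(none$intensity, c(100, 0, 0, 0))
  lad <- gen_ladder(rep(0.78, 70), n_molecules = 1)
  expect_equal(lad$intensity[lad$n_added == 70], 0.78^70)
  expect_equal(sum(lad$intensity), 1)
})

test_that("dose-response generator evaluates the Hill curve", {
  d <- gen_dose_response(0.8, 2, 4, c(0, 2, 18))
  expect_equal(d$response[1], 0)
  expect_equal(d$response[2], 0.4)
  hyp <- gen_dose_response(0.6, 3, 1, c(0, 27))
  expect_equal(hyp$response[2], 0.9 * 0.6)  # y(9K) = 0.9 fmax for n = 1
})

test_that("empirical frequencies match the model (chi-square GOF, alpha 0.001)", {
  d <- test_design()
  m <- incorporation_model(d, positional_error = c(0.05, 0.03, 0.02))
  r <- gen_fidelity_reads(d, m, 1e5, seed = 11)
  truth <- attr(r, "truth")
  # triplet-addition count distribution
  k_tab <- table(factor(truth$k, levels = 1:3))
  expect_gt(stats::chisq.test(k_tab, p = m$k_probs)$p.value, 0.001)
  # first-triplet distribution for one template, pooling rare cells
  tid <- d$template_id[1]
  sel <- truth$template_id == tid
  p <- m$prob[tid, ]
  obs <- table(factor(truth$first_triplet[sel], levels = names(p)))
  big <- p * sum(sel) >= 5
  obs2 <- c(sum(obs[!big]), obs[big])
  p2 <- c(sum(p[!big]), p[big])
  expect_gt(stats::chisq.test(obs2, p = p2)$p.value, 0.001)
})
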