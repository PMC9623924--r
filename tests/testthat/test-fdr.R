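# FDR estimators, curves, q-values, acceptance and FMR.

test_that("classical target-decoy arithmetic", {
  expect_equal(tds_fdr(100, 0), 0.01)
  expect_equal(tds_fdr(200, 1), 0.01)
  expect_equal(tds_fdr(10, 9), 1.0)
  expect_error(tds_fdr(0, 5), "undefined")
  expect_equal(tds_fdr_corrected(100, 0, 1.0), 0.01)
  expect_equal(tds_fdr_corrected(100, 1, 0.5), 0.01)
  expect_equal(tds_fdr_corrected(100, 9, 2.0), 0.2)
})

test_that("correction factor is the rank-5 target/decoy ratio", {
  psms <- dplyr::bind_rows(
    make_psms(score = rnorm(500), label = "target", rank = 5L),
    make_psms(score = rnorm(400), label = "decoy", rank = 5L),
    make_psms(score = rnorm(100), label = "decoy", rank = 2L)
  )
  psms$spectrum_id <- sprintf("S%04d", seq_len(nrow(psms)))
  expect_equal(correction_factor(psms, rank = 5), 1.25)
  psms_eq <- dplyr::bind_rows(
    make_psms(score = rnorm(10), label = "target", rank = 5L),
    make_psms(score = rnorm(10), label = "decoy", rank = 5L)
  )
  expect_equal(correction_factor(psms_eq, rank = 5), 1.0)
  only_t <- make_psms(score = rnorm(5), label = "target", rank = 5L)
  expect_error(correction_factor(only_t, rank = 5), "different rank")
})

test_that("candidate-weighted estimate follows the geometric weights", {
  # 100 targets + 1 decoy, all symmetric counts: reduces to D/T
  psms <- make_psms(score = rnorm(101),
                    label = c(rep("target", 100), "decoy"))
  expect_equal(as.numeric(ctds_fdr(psms)), 0.01)
  # 2 targets p=0.5, 1 decoy p_decoy=0.25 -> (1/0.25)/(2+2) = 1
  psms2 <- make_psms(
    score = c(3, 2, 1), label = c("target", "target", "decoy"),
    target_count = c(1L, 1L, 3L), decoy_count = c(1L, 1L, 1L)
  )
  expect_equal(as.numeric(ctds_fdr(psms2)), 1.0)
  expect_error(ctds_fdr(make_psms(score = 1, label = "decoy")), "target")
})

test_that("candidate-weighted estimate matches a two-pass summation oracle", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 500
    psms <- make_psms(
      score = rnorm(n),
      label = sample(c("target", "decoy"), n, TRUE, prob = c(0.8, 0.2)),
      target_count = 1L + rpois(n, 3),
      decoy_count = 1L + rpois(n, 2)
    )
    # independent oracle: plain loop, no shared code path
    num <- 0; den <- 0
    for (i in seq_len(n)) {
      tot <- psms$target_count[i] + psms$decoy_count[i]
      if (psms$label[i] == "decoy") num <- num + tot / psms$decoy_count[i]
      else den <- den + tot / psms$target_count[i]
    }
    expect_equal(as.numeric(ctds_fdr(psms)), num / den, tolerance = 1e-12)
  }
})

test_that("scale invariance: multiplying all counts leaves cTDS unchanged", {
  set.seed(42)
  psms <- make_psms(
    score = rnorm(200),
    label = sample(c("target", "decoy"), 200, TRUE),
    target_count = 1L + rpois(200, 2), decoy_count = 1L + rpois(200, 2)
  )
  scaled <- psms
  scaled$target_count <- scaled$target_count * 7L
  scaled$decoy_count <- scaled$decoy_count * 7L
  expect_equal(as.numeric(ctds_fdr(psms)), as.numeric(ctds_fdr(scaled)),
               tolerance = 1e-12)
})

test_that("a single target PSM yields a one-row curve with FDR 1", {
  curve <- fdr_curve(make_psms(score = 5, label = "target"))
  expect_equal(nrow(curve), 1)
  expect_equal(curve$fdr_tds, 1.0)
  expect_error(fdr_curve(make_psms(score = 1, label = "target", rank = 2L)),
               "rank-1")
})

test_that("with equal counts cTDS equals D/T at every cutoff, TDS (D+1)/T", {
  set.seed(43)
  psms <- make_psms(
    score = rnorm(300),
    label = sample(c("target", "decoy"), 300, TRUE, prob = c(0.85, 0.15))
  )
  curve <- fdr_curve(psms)
  has_t <- curve$cum_target > 0
  expect_equal(curve$fdr_ctds[has_t],
               curve$cum_decoy[has_t] / curve$cum_target[has_t])
  expect_equal(curve$fdr_tds[has_t],
               (curve$cum_decoy[has_t] + 1) / curve$cum_target[has_t])
})

test_that("cTDS is invariant to the correction factor", {
  set.seed(44)
  psms <- make_psms(
    score = rnorm(400),
    label = sample(c("target", "decoy"), 400, TRUE),
    target_count = 1L + rpois(400, 1), decoy_count = 1L + rpois(400, 3)
  )
  c1 <- fdr_curve(psms, factor = NULL)
  c2 <- fdr_curve(psms, factor = 0.37)
  expect_identical(c1$fdr_ctds, c2$fdr_ctds)
  expect_identical(c1$q_ctds, c2$q_ctds)
  # while corrected TDS scales
  expect_equal(c2$fdr_tds_corrected, c2$fdr_tds * 0.37)
})

test_that("q-values are monotone and capped at 1", {
  set.seed(45)
  for (rep in 1:5) {
    psms <- make_psms(
      score = rnorm(200),
      label = sample(c("target", "decoy"), 200, TRUE),
      target_count = 1L + rpois(200, 2), decoy_count = 1L + rpois(200, 2)
    )
    curve <- fdr_curve(psms)
    expect_true(all(diff(curve$q_tds) >= 0))
    expect_true(all(diff(curve$q_ctds) >= 0))
    expect_true(all(curve$q_tds <= 1 & curve$q_ctds <= 1))
    expect_true(all(curve$q_tds <= pmin(curve$fdr_tds, 1)))
  }
})

test_that("equal-score decoys sort before targets (conservative ties)", {
  psms <- make_psms(
    score = c(5, 5, 5, 1),
    label = c("target", "decoy", "target", "target")
  )
  curve <- fdr_curve(psms)
  expect_equal(curve$label[1], "decoy")
  # the favorable ordering (targets first) can only accept more at the top:
  # with the conservative order the top-1 prefix already contains the decoy
  expect_equal(curve$cum_decoy[1], 1)
  # duplicate rank-1 PSMs per spectrum are rejected
  dup <- make_psms(score = c(1, 2), label = "target",
                   spectrum_id = c("s", "s"))
  expect_error(fdr_curve(dup), "More than one rank-1")
})

test_that("acceptance sweeps the q-threshold correctly", {
  # 99 high-scoring targets, then a decoy, then one more target
  psms <- make_psms(
    score = c(seq(100, 2, length.out = 99), 1.5, 1),
    label = c(rep("target", 99), "decoy", "target")
  )
  curve <- fdr_curve(psms)
  acc <- accept_at(curve, alpha = 0.02, method = "ctds")
  # hand-evaluated sweep: full prefix has D/T = 1/100 <= 0.02
  expect_equal(acc$n_accepted, 100L)
  expect_equal(acc$score_cutoff, 1)
  # alpha below the minimum q accepts nothing
  none <- accept_at(curve, alpha = 1e-6, method = "tds")
  expect_equal(none$n_accepted, 0L)
  expect_true(is.na(none$score_cutoff))
  # alpha = 1 accepts every target
  all_in <- accept_at(curve, alpha = 1, method = "tds")
  expect_equal(all_in$n_accepted, 100L)
})

test_that("entrapment FMR counts target hits by provenance", {
  acc <- tibble::tibble(
    label = c(rep("target", 505), rep("decoy", 3)),
    ref_class = c(rep("reference", 500), rep("entrapment", 5),
                  rep(NA, 3))
  )
  expect_equal(fmr(acc), 0.01)
  no_ent <- tibble::tibble(label = "target", ref_class = "reference")
  expect_equal(fmr(no_ent), 0)
  no_ref <- tibble::tibble(label = "target", ref_class = "entrapment")
  expect_warning(expect_true(is.na(fmr(no_ref))), "undefined")
})

test_that("probability distribution summary partitions below/at/above 0.5", {
  psms <- make_psms(score = rnorm(4), label = "target",
                    target_count = c(1L, 1L, 3L, 1L),
                    decoy_count = c(1L, 1L, 1L, 3L))
  s <- p_distribution_summary(psms)
  expect_equal(s$frac_equal, 0.5)
  expect_equal(s$frac_below, 0.25)
  expect_equal(s$frac_above, 0.25)
  expect_equal(s$frac_below + s$frac_equal + s$frac_above, 1)
  # a correction factor of t/d moves everything to exactly 0.5
  s2 <- p_distribution_summary(
    make_psms(score = rnorm(2), label = "target",
              target_count = c(2L, 4L), decoy_count = c(1L, 2L)),
    factor = 2
  )
  expect_equal(s2$frac_equal, 1)
})
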