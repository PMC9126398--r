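test_that("limits of agreement from per-lesion means: hand-checked case", {
  # 2 readers x 2 lesions: values (10,20) and (30,30)
  tab <- table_from_matrix(rbind(c(10, 20), c(30, 30)))
  ba <- bland_altman_multireader(tab, 1)
  expect_equal(sort(ba$deviations$diff), c(-5, 0, 0, 5))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, sqrt(50 / 3))                 # sample SD
  expect_equal(ba$loa_half_width, 1.96 * sqrt(50 / 3))
  ba_n <- bland_altman_multireader(tab, 1, sd_denominator = "n")
  expect_equal(ba_n$sd_diff, sqrt(50 / 4))
})

test_that("identical readers give zero limits of agreement", {
  m <- matrix(rep(c(700, 900, 1100), 4), 3, 4)
  ba <- bland_altman_multireader(table_from_matrix(m), 1)
  expect_equal(ba$loa_half_width, 0)
})

test_that("limits of agreement are shift-invariant, scale-equivariant and label-invariant", {
  set.seed(3)
  m <- matrix(rnorm(40, 800, 120), 8, 5)
  tab <- table_from_matrix(m)
  base <- bland_altman_multireader(tab, 1)$loa_half_width

  shifted <- tab; shifted$adc_value <- shifted$adc_value + 250
  expect_equal(bland_altman_multireader(shifted, 1)$loa_half_width, base)

  scaled <- tab; scaled$adc_value <- scaled$adc_value * 3
  expect_equal(bland_altman_multireader(scaled, 1)$loa_half_width, 3 * base)

  relabel <- tab
  relabel$reader_id <- c(5, 4, 3, 2, 1)[relabel$reader_id]
  relabel$lesion_id <- sample(100 + 1:8)[relabel$lesion_id]
  expect_equal(bland_altman_multireader(relabel, 1)$loa_half_width, base)
})

test_that("incomplete blocks are refused with the missing cell named", {
  tab <- table_from_matrix(matrix(1:6 * 100, 3, 2))
  expect_error(bland_altman_multireader(tab[-2, ], 1),
               "lesion 2, reader 1")
  dup <- rbind(tab, tab[1, ])
  expect_error(bland_altman_multireader(dup, 1), "duplicate")
})

test_that("ICC matches the frozen two-rater oracle values", {
  # oracle: pingouin intraclass_corr on the same 8 lesions
  reader <- c(720, 810, 650, 900, 1010, 580, 760, 840)
  ref    <- c(700, 790, 700, 870, 980, 600, 730, 870)
  icc2 <- icc_vs_reference(reader, ref, model = "ICC2")
  expect_equal(icc2$estimate, 0.972910, tolerance = 1e-5)
  expect_equal(icc2$ci_low, 0.87, tolerance = 0.01)
  expect_equal(icc2$ci_high, 0.99, tolerance = 0.005)
  icc3 <- icc_vs_reference(reader, ref, model = "ICC3")
  expect_equal(icc3$estimate, 0.969620, tolerance = 1e-5)
  expect_match(icc2$model_tag, "absolute agreement")
})

test_that("ICC is 1 for perfect agreement and penalises fixed bias in the absolute form", {
  x <- c(600, 700, 800, 900, 1000)
  expect_equal(icc_vs_reference(x, x)$estimate, 1.0)

  set.seed(11)
  ref <- rnorm(40, 800, 100)
  shifted <- ref + 50
  abs_form <- icc_vs_reference(shifted, ref, model = "ICC2")$estimate
  con_form <- icc_vs_reference(shifted, ref, model = "ICC3")$estimate
  expect_lt(abs_form, con_form)
  expect_equal(con_form, 1.0, tolerance = 1e-9)

  # consistency form is invariant to a joint affine map; absolute to a shift
  a <- rnorm(40, 800, 120); b <- a + rnorm(40, 30, 60)
  expect_equal(icc_vs_reference(2 * a + 100, 2 * b + 100, "ICC3")$estimate,
               icc_vs_reference(a, b, "ICC3")$estimate)
  expect_equal(icc_vs_reference(a + 100, b + 100, "ICC2")$estimate,
               icc_vs_reference(a, b, "ICC2")$estimate)

  expect_error(icc_vs_reference(c(1, 2), c(1, 2)), ">= 3")
  expect_error(icc_vs_reference(rep(5, 4), rep(5, 4)), "variance")
})

test_that("Friedman statistic: tied and perfectly ordered closed forms", {
  tied <- matrix(rep(c(4, 7, 2, 9), 3), 4, 3)
  expect_equal(friedman_across_methods(tied)$statistic, 0)

  ordered <- matrix(c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 3), 4, 3)
  fr <- friedman_across_methods(ordered)
  expect_equal(fr$statistic, 8.0)
  expect_equal(fr$df, 2)

  expect_error(friedman_across_methods(cbind(1:3)), ">= 2")
})

test_that("Holm adjustment matches the hand-worked step-down", {
  # raw {0.01, 0.04, 0.03}: sorted (0.01, 0.03, 0.04) x (3, 2, 1) =
  # (0.03, 0.06, 0.04); cumulative max -> adjusted {0.03, 0.06, 0.06}
  expect_equal(p.adjust(c(0.01, 0.04, 0.03), "holm"), c(0.03, 0.06, 0.06))

  set.seed(2)
  dev <- cbind(a = abs(rnorm(20)), b = abs(rnorm(20, 1)),
               c = abs(rnorm(20, 1)))
  ph <- posthoc_pairwise(dev)
  expect_equal(nrow(ph), 3)
  expect_true(all(ph$p_adj >= ph$p_raw - 1e-12))
  ord <- order(ph$p_raw)
  expect_true(!is.unsorted(ph$p_adj[ord]))

  same <- cbind(a = 1:10, b = 1:10, c = 1:10)
  expect_true(all(posthoc_pairwise(same)$p_adj == 1))
})

test_that("unpaired group test reproduces the closed-form Welch t", {
  res <- unpaired_group_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-9)  # -3.674235
  expect_equal(res$mean_a, 2)
  expect_equal(res$mean_b, 5)

  same <- unpaired_group_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(unpaired_group_test(1, c(1, 2)), "n >= 2")
  # equal group variances: Welch and Student coincide
  st <- unpaired_group_test(c(1, 2, 3), c(4, 5, 6), var_equal = TRUE)
  expect_equal(st$t, res$t, tolerance = 1e-9)
})

test_that("agreement_report assembles all sections on a small virtual study", {
  sim <- run_virtual_study(n_lesions = 6, n_readers = 3,
                           profiles = default_reader_profiles(3), seed = 5)
  rep <- agreement_report(sim$measurements, sim$reference)
  expect_named(rep, c("loa", "icc", "friedman", "posthoc"))
  expect_length(rep$loa, 3)
  expect_equal(nrow(rep$icc), 9)           # 3 sessions x 3 readers
  expect_true(all(rep$icc$icc >= -1 & rep$icc$icc <= 1))
  expect_true(all(rep$icc$ci_low <= rep$icc$icc + 1e-9))
  expect_true(all(rep$icc$ci_high >= rep$icc$icc - 1e-9))
  expect_equal(nrow(rep$posthoc), 3)
})
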