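test_that("valid placements require full containment", {
  all3 <- matrix(TRUE, 3, 3)
  p9 <- valid_placements(all3, kernel_for_size(9))
  expect_equal(unname(p9), matrix(c(2L, 2L), 1))
  p1 <- valid_placements(all3, kernel_for_size(1))
  expect_equal(nrow(p1), 9)
  # empty slice is allowed and yields nothing
  expect_equal(nrow(valid_placements(matrix(FALSE, 4, 4),
                                     kernel_for_size(1))), 0)
})

test_that("valid placements equal brute-force enumeration on random masks", {
  for (seed in 1:10) {
    set.seed(seed)
    m <- matrix(runif(64) < 0.6, 8, 8)
    for (n in c(5, 9, 17)) {
      k <- kernel_for_size(n)
      got <- valid_placements(m, k)
      want <- oracle_placements(m, k$offsets)
      expect_equal(unname(got), unname(want),
                   info = sprintf("seed %d size %d", seed, n))
    }
  }
})

test_that("minimum sliding mean matches the enumeration oracle exactly", {
  for (seed in 1:8) {
    case <- random_case(seed)
    for (n in c(1, 5, 9)) {
      k <- kernel_for_size(n)
      got <- min_mean_adc(case$volume, case$mask, k)
      want <- brute_force_min_mean(case$volume, case$mask, k)
      if (is_no_fit(want)) {
        expect_true(is_no_fit(got))
      } else {
        expect_identical(got$value, want$value)
        expect_identical(got$anchor, want$anchor)
        expect_equal(got$n_placements, want$n_placements)
      }
    }
  }
})

test_that("minimum mean respects constants, bounds and tie-breaks", {
  const <- adc_volume(array(850, c(6, 6, 2)))
  m <- lesion_mask(array(TRUE, c(6, 6, 2)))
  rv <- min_mean_adc(const, m, kernel_for_size(9))
  expect_equal(rv$value, 850)

  case <- random_case(42)
  rv <- min_mean_adc(case$volume, case$mask, kernel_for_size(5))
  if (!is_no_fit(rv)) {
    expect_gte(rv$value, min(case$volume$values[case$mask$values]))
  }

  # two identical minima: the first in (slice, row, col) order wins
  v <- array(1000, c(5, 5, 2))
  v[2, 2, 1] <- 100
  v[4, 4, 2] <- 100
  vol <- adc_volume(v)
  m <- lesion_mask(array(TRUE, c(5, 5, 2)))
  rv <- min_mean_adc(vol, m, kernel_for_size(1))
  expect_equal(rv$anchor, c(slice = 1, row = 2, col = 2))

  # footprint at the returned anchor lies inside the mask
  case <- random_case(7)
  k <- kernel_for_size(9)
  rv <- min_mean_adc(case$volume, case$mask, k)
  if (!is_no_fit(rv)) {
    sl <- case$mask$values[, , rv$anchor[["slice"]]]
    expect_true(oracle_fits(sl, k$offsets, rv$anchor[["row"]],
                            rv$anchor[["col"]]))
  }
})

test_that("no-fit is a signal, not an error", {
  m <- array(FALSE, c(6, 6, 1))
  m[3, 2:5, 1] <- TRUE                       # 1-pixel-thick line
  vol <- adc_volume(array(1000, c(6, 6, 1)))
  expect_true(is_no_fit(min_mean_adc(vol, lesion_mask(m),
                                     kernel_for_size(9))))
  expect_error(min_mean_adc(vol, lesion_mask(array(TRUE, c(5, 5, 1))),
                            kernel_for_size(1)), "differ")
})

test_that("multi-size fallback carries the next-smaller size", {
  # single voxel: everything falls back to size 1
  m <- array(FALSE, c(6, 6, 1))
  m[3, 3, 1] <- TRUE
  v <- array(1000, c(6, 6, 1))
  v[3, 3, 1] <- 700
  res <- multi_size_reference(adc_volume(v), lesion_mask(m), c(1, 2, 9))
  expect_equal(sapply(res, `[[`, "value"), c("1" = 700, "2" = 700, "9" = 700))
  expect_equal(sapply(res, `[[`, "effective_size"),
               c("1" = 1L, "2" = 1L, "9" = 1L))
  expect_equal(sapply(res, `[[`, "requested_size"),
               c("1" = 1L, "2" = 2L, "9" = 9L))

  # a 3x3 patch fits 9 but not 17: the 17 entry must equal the 9 entry
  m2 <- array(FALSE, c(8, 8, 1))
  m2[3:5, 3:5, 1] <- TRUE
  set.seed(1)
  v2 <- array(runif(64, 500, 1500), c(8, 8, 1))
  res2 <- multi_size_reference(adc_volume(v2), lesion_mask(m2), c(1, 9, 17))
  expect_equal(res2[["17"]]$value, res2[["9"]]$value)
  expect_equal(res2[["17"]]$effective_size, 9L)

  expect_error(multi_size_reference(adc_volume(v2), lesion_mask(m2),
                                    c(9, 1, 17)), "ascending")
  empty <- lesion_mask(array(FALSE, c(8, 8, 1)), allow_empty = TRUE)
  expect_error(multi_size_reference(adc_volume(v2), empty), "empty")
})

test_that("multi-size values match the oracle on a phantom lesion", {
  cfg <- phantom_config(dim = c(24, 24, 3), lesion_radii = c(6, 7, 1.1),
                        noise_sd = 30, seed = 5)
  ph <- generate_phantom(cfg, truth_sizes = roi_study_sizes())
  res <- multi_size_reference(ph$volume, ph$lesion)
  expect_equal(sapply(res, `[[`, "value"), ph$truth, tolerance = 1e-12)
})

test_that("percentiles follow the documented interpolation conventions", {
  v <- adc_volume(array(as.numeric(1:100), c(10, 10, 1)))
  m <- lesion_mask(array(TRUE, c(10, 10, 1)))
  expect_equal(percentile_adc(v, m, 10), 10.9)           # linear, type 7
  expect_equal(percentile_adc(v, m, 0), 1)               # boundary = min
  expect_equal(percentile_adc(v, m, 100), 100)
  expect_equal(percentile_adc(v, m, 10, method = "lower"), 10)
  cv <- adc_volume(array(100, c(4, 4, 1)))
  cm <- lesion_mask(array(TRUE, c(4, 4, 1)))
  for (q in c(0, 10, 50, 90)) expect_equal(percentile_adc(cv, cm, q), 100)
  expect_error(percentile_adc(v, m, 101), "0, 100")
  empty <- lesion_mask(array(FALSE, c(10, 10, 1)), allow_empty = TRUE)
  expect_error(percentile_adc(v, empty, 10), "empty")
})

test_that("median parenchyma ADC is the 50th percentile", {
  v <- adc_volume(array(c(1, 2, 3, 4), c(2, 2, 1)))
  m <- lesion_mask(array(TRUE, c(2, 2, 1)))
  expect_equal(median_pz_adc(v, m), 2.5)
  case <- random_case(9, dims = c(10, 10, 2))
  expect_equal(median_pz_adc(case$volume, case$mask),
               median(sort(case$volume$values[case$mask$values])))
  const <- adc_volume(array(1400, c(3, 3, 1)))
  expect_equal(median_pz_adc(const, lesion_mask(array(TRUE, c(3, 3, 1)))),
               1400)
})

test_that("reference tables use 0-based anchors", {
  m <- array(FALSE, c(6, 6, 1)); m[3, 3, 1] <- TRUE
  v <- array(1000, c(6, 6, 1)); v[3, 3, 1] <- 700
  res <- multi_size_reference(adc_volume(v), lesion_mask(m), c(1, 2))
  tab <- reference_table(res, lesion_id = "L1")
  expect_equal(names(tab),
               c("lesion_id", "size", "effective_size", "value",
                 "anchor_slice", "anchor_row", "anchor_col"))
  expect_equal(tab$anchor_slice, c(0, 0))
  expect_equal(tab$anchor_row, c(2, 2))
})
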