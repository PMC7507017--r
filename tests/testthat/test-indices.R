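recs <- kader_records()
ctrl <- kader_control()

test_that("per-day counts are the first differences of the cumulative record", {
  expect_equal(per_day_counts(recs[["A1"]]),
               c(`1` = 0, `2` = 0, `3` = 0, `4` = 15, `5` = 80,
                 `6` = 0, `7` = 0, `8` = 0, `9` = 0, `10` = 0))
  expect_equal(unname(per_day_counts(recs[["D2"]])[1:3]), c(70, 15, 10))
  const <- germination_record(c(1, 2, 3), c(0.5, 0.5, 0.5), 100L)
  expect_equal(unname(per_day_counts(const)), c(0.5 * 100, 0, 0))
  expect_error(germination_record(c(1, 2), c(0.3, 0.2), 100L), "decreases")
})

test_that("total germination matches the printed values", {
  expect_equal(total_germination(recs[["A1"]]), 0.95)
  expect_equal(total_germination(recs[["C2"]]), 0.75)
  # thirds-of-95 sets carry the printed rounding (94.8, not 95)
  expect_equal(total_germination(recs[["C1"]]), 0.948)
  # half-up rounding to two decimals, matching how the values were printed
  tg2 <- floor(vapply(recs, total_germination, 0) * 100 + 0.5) / 100
  printed_tg <- rep(0.95, 32)
  printed_tg[match(c("C2", "C3", "C4"), names(recs))] <- c(0.75, 0.55, 0.35)
  printed_tg[match(c("G2", "G3", "G4"), names(recs))] <- c(0.75, 0.55, 0.35)
  expect_equal(unname(tg2), printed_tg)
})

test_that("mean germination time follows the count-weighted mean day", {
  expect_equal(mean_germination_time(recs[["B1"]]), 3.0)
  expect_equal(mean_germination_time(recs[["A2"]]), 1.0)
  expect_equal(mean_germination_time(recs[["A1"]]), 460 / 95)
  expect_equal(mean_germination_time(recs[["H3"]]), 780 / 95)
  expect_equal(mean_germination_time(recs[["H4"]]), 115 / 95)
  expect_equal(mean_germination_time(recs[["E4"]]), 1.0)
})

test_that("coefficient of velocity follows 100 * total / weighted-day sum", {
  expect_equal(coefficient_of_velocity(recs[["B2"]]), 100 * 94.8 / 237)  # 40.0
  expect_equal(coefficient_of_velocity(recs[["A2"]]), 100)
  expect_equal(coefficient_of_velocity(recs[["A1"]]), 100 * 95 / 460)
  for (id in c("C1", "C2", "C3", "C4"))
    expect_equal(coefficient_of_velocity(recs[[id]]), 50)
})

test_that("the germination index reproduces the printed row on consistent cells", {
  # printed cells that agree with the (T - t + 1) weighting; the two
  # internally inconsistent cells (A4, G1) are excluded
  printed <- c(A1 = 585.0, A2 = 950, A3 = 800, B1 = 760.0, B2 = 805.8,
               B3 = 853.2, B4 = 902.5, C1 = 853.2, C2 = 675.0, C3 = 494.1,
               C4 = 313.2, D1 = 795.0, D2 = 915.0, D3 = 850.0, D4 = 860.0,
               E1 = 661.5, E2 = 760.0, E3 = 853.2, E4 = 950.0, F1 = 189.6,
               F2 = 379.2, F3 = 568.8, F4 = 758.4, G2 = 635.8, G3 = 522.5,
               G4 = 350.0, H1 = 189.6, H2 = 853.2, H3 = 265.0, H4 = 930.0)
  for (id in names(printed))
    expect_equal(germination_index(recs[[id]], period = 10), unname(printed[id]),
                 tolerance = 1e-12, label = paste("GI", id))
  expect_error(germination_index(recs[["A1"]], period = 3), "period")
})

test_that("LT50 is the first day reaching half the final germination level", {
  printed <- c(C1 = 2, C2 = 2, C3 = 2, C4 = 2, D1 = 3, D2 = 1, D3 = 2, D4 = 2,
               E1 = 4, E2 = 3, E3 = 2, E4 = 1, F1 = 9, F2 = 7, F3 = 5, F4 = 3,
               G1 = 5, G2 = 2, G3 = 1, G4 = 1, H1 = 9, H2 = 2, H3 = 8, H4 = 1,
               B1 = 3, B4 = 1)
  for (id in names(printed))
    expect_equal(lt50(recs[[id]]), unname(printed[id]),
                 label = paste("LT50", id))
  # single event at day d
  one <- germination_record(c(3, 4), c(0, 0.4), 100L)
  expect_equal(lt50(one), 4)
  # interpolated variant crosses between days
  expect_lt(lt50(recs[["B1"]], interpolate = TRUE), 3)
})

test_that("GI, MGT and totals satisfy their algebraic identity on all 32 sets", {
  # GI = sum n_i (T + 1 - t_i) = (T + 1) * sum(n) - sum(n t) = sum(n) * (T + 1 - MGT)
  for (r in recs) {
    n <- per_day_counts(r)
    gi <- germination_index(r, period = 10)
    expect_equal(gi, sum(n) * (11 - mean_germination_time(r)), tolerance = 1e-10)
    expect_equal(gi, 11 * sum(n) - sum(n * as.numeric(names(n))),
                 tolerance = 1e-10)
  }
})

test_that("the continuous index tracks the printed values and the trapezoid rule", {
  fits <- lapply(recs, agdf, control = ctrl)
  cgis <- vapply(fits, cgi, 0)
  expect_equal(unname(cgis), kader_printed_cgi, tolerance = 0.01)
  expect_gt(cor(cgis, kader_printed_cgi), 0.99)
  for (id in c("A1", "E2", "H3"))
    expect_equal(cgi(fits[[id]]), cgi(fits[[id]], method = "trapezoid"),
                 tolerance = 1e-6)
  # linearity: cgi(fit(c y)) = c cgi(fit(y))
  r <- recs[["B3"]]
  f1 <- agdf(r, control = ctrl)
  f03 <- agdf(r$days, 0.3 * r$cumulative, control = ctrl)
  expect_equal(cgi(f03), 0.3 * cgi(f1), tolerance = 1e-8)
})

test_that("shifting germinated mass earlier never decreases the continuous index", {
  shift_pairs <- list(c("F4", "F3"), c("F3", "F2"), c("F2", "F1"),
                      c("E4", "E3"), c("E3", "E2"), c("E2", "E1"))
  for (pr in shift_pairs) {
    early <- cgi(agdf(recs[[pr[1L]]], control = ctrl))
    late <- cgi(agdf(recs[[pr[2L]]], control = ctrl))
    expect_gte(early, late)
  }
})

test_that("the continuous index is bounded by the domain times total germination", {
  for (r in recs) {
    v <- cgi(agdf(r, control = ctrl))
    expect_lte(v, 10 * total_germination(r) * 1.05)
    expect_gte(v, 0)
  }
})

test_that("a zero-germination record yields the documented undefined pattern", {
  z <- germination_record(1:10, rep(0, 10), 100L, accession = "dormant")
  tab <- germination_indices(z, control = ctrl)
  expect_true(is.na(tab$lt50) && is.na(tab$mgt) && is.na(tab$cvg))
  expect_equal(tab$tg, 0)
  expect_equal(tab$gi, 0)
  expect_equal(tab$cgi, 0)
})

test_that("indices are invariant to the seed-count scale except the germination index", {
  # the same proportions observed on 25 vs 100 planted seeds
  y <- cumsum(c(0.1, 0.3, 0.2, 0, 0.2)) / 1
  r25 <- germination_record(1:5, y, total_seeds = 25L)
  r100 <- germination_record(1:5, y, total_seeds = 100L)
  expect_equal(total_germination(r25), total_germination(r100))
  expect_equal(mean_germination_time(r25), mean_germination_time(r100))
  expect_equal(coefficient_of_velocity(r25), coefficient_of_velocity(r100))
  expect_equal(lt50(r25), lt50(r100))
  # GI is defined on the stated count units
  expect_equal(germination_index(r100, 5) / germination_index(r25, 5), 4)
})
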