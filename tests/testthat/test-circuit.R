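test_that("starter QC applies a strict threshold per tracer", {
  expect_true(starter_qc(rule = qc_rule_rabies(),
                         starter_in = 71, starter_out = 29)$pass)
  qc <- starter_qc(rule = qc_rule_rabies(), starter_in = 70, starter_out = 30)
  expect_equal(qc$fraction, 0.70)
  expect_false(qc$pass)                       # "more than" is strict
  expect_false(starter_qc(rule = qc_rule_anterograde(),
                          starter_in = 65, starter_out = 35)$pass)
  expect_error(starter_qc(starter_in = 0, starter_out = 0), "no starter")
})

test_that("input fractions exclude, normalize, and apply the 2% floor", {
  tab <- region_quant_table(data.frame(region = c("PA", "CoA", "BNST"),
                                       count = c(50, 30, 20)))
  fr <- input_fractions(tab)
  expect_equal(unname(fr$fractions), c(0.5, 0.3, 0.2))
  expect_equal(length(fr$reported), 3L)
  expect_lt(abs(sum(fr$fractions) - 1), 1e-9)

  tab2 <- region_quant_table(data.frame(region = c("PA", "CoA", "BNST"),
                                        count = c(98, 1, 1)))
  fr2 <- input_fractions(tab2)
  expect_equal(names(fr2$reported), "PA")     # 1% regions kept in fractions,
  expect_equal(length(fr2$fractions), 3L)     # dropped from the report

  # exclusion happens before normalization
  tab3 <- region_quant_table(data.frame(region = c("PA", "LH"),
                                        count = c(50, 50)))
  fr3 <- input_fractions(tab3)
  expect_equal(unname(fr3$fractions), 1)
  expect_equal(fr3$excluded, "LH")

  tab4 <- region_quant_table(data.frame(region = "LH", count = 10))
  expect_error(input_fractions(tab4), "zero")
})

test_that("fractions are monotone under region merging", {
  tab <- region_quant_table(data.frame(region = c("PA", "CoA", "BNST", "Pir"),
                                       count = c(40, 25, 20, 15)))
  fr <- input_fractions(tab)$fractions
  merged <- region_quant_table(data.frame(region = c("PA", "CoA", "BNST"),
                                          count = c(40, 25, 35)))
  frm <- input_fractions(merged)$fractions
  expect_equal(unname(frm["BNST"]), unname(fr["BNST"] + fr["Pir"]))
})

test_that("projection intensity: background subtraction, clamping, unit max, floor", {
  tab <- region_quant_table(data.frame(region = c("MPOA", "VMHvl"),
                                       i_raw = c(10, 6),
                                       i_background = c(2, 2)),
                            tracer = "anterograde")
  pr <- projection_intensity(tab)
  expect_equal(unname(pr$i_norm), c(1, 0.5))
  expect_equal(sum(pr$i_norm == 1), 1L)

  # I_raw < background clamps to 0
  tab2 <- region_quant_table(data.frame(region = c("MPOA", "PMv"),
                                        i_raw = c(10, 1),
                                        i_background = c(2, 5)),
                             tracer = "anterograde")
  expect_equal(unname(projection_intensity(tab2)$i_norm["PMv"]), 0)

  # 0.19 is reported only for VMHvl (always-include set)
  tab3 <- region_quant_table(data.frame(region = c("MPOA", "VMHvl", "PMv"),
                                        i_raw = c(102, 21.9, 21.9),
                                        i_background = c(2, 2.9, 2.9)),
                             tracer = "anterograde")
  pr3 <- projection_intensity(tab3)
  expect_equal(unname(round(pr3$i_norm[c("VMHvl", "PMv")], 3)), c(0.19, 0.19))
  expect_setequal(names(pr3$reported), c("MPOA", "VMHvl"))
})

test_that("projection ratio handles worked example, unity and undefined cases", {
  inorm <- c(MPOA = 0.6, AVPV = 0.2, VMHvl = 0.3, PMv = 0.1)
  expect_equal(projection_ratio(inorm, c("MPOA", "AVPV"), c("VMHvl", "PMv")), 2)
  expect_equal(projection_ratio(inorm, c("MPOA", "AVPV"), c("MPOA", "AVPV")), 1)
  expect_equal(projection_ratio(inorm, "MPOA", "VMHvl"), 2)
  und <- projection_ratio(c(BNSTpr = 0.5, BNSTif = 0), "BNSTpr", "BNSTif")
  expect_true(is.na(und) && isTRUE(attr(und, "undefined")))
  expect_error(projection_ratio(inorm, "PA", "VMHvl"), "absent")
})

test_that("overlap percentages from double-label counts", {
  ov <- overlap_fractions(only_a = 24, only_b = 0, both = 76)
  expect_equal(ov$pct_a_also_b, 76)
  expect_equal(overlap_fractions(10, 10, 0)$pct_a_also_b, 0)
  expect_equal(overlap_fractions(0, 0, 50)$pct_a_also_b, 100)
  expect_true(is.na(overlap_fractions(0, 5, 0)$pct_a_also_b))
  expect_error(overlap_fractions(-1, 0, 2), "non-negative")
})

test_that("point-to-line distances are perpendicular Euclidean distances", {
  line_x_axis <- rbind(c(0, 0), c(1, 0))
  expect_equal(point_to_line_distances(rbind(c(0, 1)), line_x_axis), 1)
  expect_equal(point_to_line_distances(rbind(c(5, 0)), line_x_axis), 0)
  line_y_axis <- rbind(c(0, 0), c(0, 2))
  expect_equal(point_to_line_distances(rbind(c(3, 4)), line_y_axis), 3)
  # infinite line, not a segment: beyond the endpoints still perpendicular
  expect_equal(point_to_line_distances(rbind(c(10, 2)), line_x_axis), 2)
  expect_error(point_to_line_distances(rbind(c(1, 1)), rbind(c(0, 0), c(0, 0))),
               "coincide")
})

test_that("multinomial fixtures recover true fractions at the binomial rate", {
  p <- c(PA = 0.4, CoA = 0.3, BNST = 0.2, Pir = 0.1)
  for (n in c(500, 5000)) {
    ct <- simulate_count_table(p, n, seed = n)
    fr <- input_fractions(ct$table, qc_rule())$fractions
    expect_true(all(abs(fr[names(p)] - p) <= 3 * sqrt(p * (1 - p) / n)))
  }
})
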