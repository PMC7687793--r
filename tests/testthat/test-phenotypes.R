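test_that("LMS z-score matches the closed-form transform", {
  # linear case: L = 1 reduces to (y - M) / (M * S)
  ref <- flat_lms(L = 1, M = 16, S = 0.1)
  expect_equal(lms_zscore(17.6, "F", 5, ref), 1.0, tolerance = 1e-12)
  # bmi at the median maps to zero for any parameters
  expect_equal(lms_zscore(16, "M", 9, ref), 0, tolerance = 1e-12)
  # general Box-Cox case, checked against direct evaluation
  ref2 <- flat_lms(L = -1.6, M = 16.0, S = 0.12)
  oracle <- ((20 / 16)^(-1.6) - 1) / (-1.6 * 0.12)
  expect_equal(lms_zscore(20.0, "F", 7, ref2), oracle, tolerance = 1e-12)
  expect_equal(oracle, 1.563, tolerance = 1e-3)
  # logarithmic limit when L is numerically zero
  ref0 <- flat_lms(L = 0, M = 16, S = 0.1)
  expect_equal(lms_zscore(20, "F", 7, ref0), log(20 / 16) / 0.1,
               tolerance = 1e-12)
})

test_that("LMS transform round-trips and is monotone across a parameter grid", {
  for (L in c(-3, -1.6, -0.5, 1e-12, 0.5, 1.7, 3)) {
    for (S in c(0.05, 0.12, 0.3)) {
      ref <- flat_lms(L = L, M = 17, S = S)
      bmi <- c(12, 15, 17, 20, 24, 30)
      z <- lms_zscore(bmi, rep("F", 6), rep(8, 6), ref)
      expect_true(all(diff(z) > 0), info = sprintf("L=%g S=%g", L, S))
      back <- lms_inverse(z, rep("F", 6), rep(8, 6), ref)
      expect_equal(back, bmi, tolerance = 1e-9)
    }
  }
})

test_that("LMS parameters are interpolated in age and errors are informative", {
  ref <- rbind(data.frame(sex = "F", age_years = c(4, 6), L = c(1, 1),
                          M = c(16, 18), S = c(0.1, 0.1)),
               data.frame(sex = "M", age_years = c(4, 6), L = 1, M = 17,
                          S = 0.1))
  # midpoint age -> M = 17, so bmi 17 scores zero
  expect_equal(lms_zscore(17, "F", 5, ref), 0, tolerance = 1e-12)
  expect_error(lms_zscore(17, "F", 10, ref), "age outside")
  expect_error(lms_zscore(17, "X", 5, ref), "absent")
  expect_error(lms_zscore(-1, "F", 5, ref), "bmi")
})

test_that("IOTF classification respects the heavier-category boundary rule", {
  cut <- flat_cutoffs(14, 18, 21)
  cls <- iotf_classify(c(13, 16, 19, 22), rep("F", 4), rep(8, 4), cut)
  expect_equal(as.character(cls),
               c("underweight", "normal", "overweight", "obesity"))
  # boundary values go to the category the cutoff names
  expect_equal(as.character(iotf_classify(c(14, 18, 21), rep("M", 3),
                                          rep(8, 3), cut)),
               c("normal", "overweight", "obesity"))
  # classification partitions the sample
  n <- 50
  bmi <- seq(12, 25, length.out = n)
  expect_equal(sum(table(iotf_classify(bmi, rep("F", n), rep(8, n), cut))), n)
})

test_that("puberty categorization matches exhaustive enumeration of the rule", {
  grid <- expand.grid(t1 = 1:5, t2 = 1:5, men = c(FALSE, TRUE))
  got <- categorize_puberty(grid$t1, grid$t2, grid$men)
  want <- ifelse(grid$t1 <= 3 & grid$t2 <= 3 & !grid$men, "early", "late")
  expect_equal(as.character(got), want)
  # spot checks of the stated rule
  expect_equal(as.character(categorize_puberty(2, 3, FALSE)), "early")
  expect_equal(as.character(categorize_puberty(4, 2, FALSE)), "late")
  expect_equal(as.character(categorize_puberty(1, 1, TRUE)), "late")
  expect_error(categorize_puberty(0, 3, FALSE), "1-5")
})

test_that("case-control construction applies the group-size eligibility rule", {
  cut <- flat_cutoffs(14, 18, 21)
  mk <- function(n_under, n_normal, n_case) {
    data.frame(bmi_kg_m2 = c(rep(13, n_under), rep(16, n_normal),
                             rep(19, n_case)),
               sex = "F", age_years = 8)
  }
  cc <- build_case_control(mk(0, 11, 11), cut)
  expect_true(cc$eligible)       # 11 > 10 on both sides
  expect_equal(cc$n_cases, 11)
  cc2 <- build_case_control(mk(0, 500, 10), cut)
  expect_false(cc2$eligible)     # 10 cases is too few
  cc3 <- build_case_control(mk(5, 70, 25), cut)
  expect_equal(sum(!is.na(cc3$assignment)), 95)  # underweight excluded
})

test_that("overweight fraction uses the strict 30% flag after excluding underweight", {
  cut <- flat_cutoffs(14, 18, 21)
  mk <- function(n_over, n_normal, n_under)
    data.frame(bmi_kg_m2 = c(rep(19, n_over), rep(16, n_normal),
                             rep(13, n_under)),
               sex = "F", age_years = 8)
  ov <- overweight_fraction(mk(30, 70, 10), cut)
  expect_equal(ov$fraction, 0.30)
  expect_false(ov$flagged)
  ov2 <- overweight_fraction(mk(31, 69, 0), cut)
  expect_equal(ov2$fraction, 0.31)
  expect_true(ov2$flagged)
  expect_equal(overweight_fraction(mk(0, 50, 0), cut)$fraction, 0)
  expect_error(overweight_fraction(mk(0, 0, 5), cut), "undefined")
})

test_that("measurement selection picks the oldest complete time point in window", {
  tp <- data.frame(age = c(3, 4, 9), bmi_available = TRUE,
                   meth_available = TRUE)
  expect_equal(select_measurement(tp, c(5, 10)), 9)
  tp2 <- data.frame(age = c(6, 8), bmi_available = c(TRUE, TRUE),
                    meth_available = c(FALSE, TRUE))
  expect_equal(select_measurement(tp2, c(5, 10)), 8)
  tp3 <- data.frame(age = c(3, 12), bmi_available = TRUE,
                    meth_available = TRUE)
  expect_true(is.na(select_measurement(tp3, c(5, 10))))
  # window inclusive at both ends
  tp4 <- data.frame(age = c(5, 10), bmi_available = TRUE,
                    meth_available = TRUE)
  expect_equal(select_measurement(tp4, c(5, 10)), 10)
})

test_that("packaged synthetic references load and satisfy their invariants", {
  ref <- ewas_lms_reference()
  expect_true(all(ref$M > 0) && all(ref$S > 0))
  expect_setequal(unique(ref$sex), c("F", "M"))
  cut <- ewas_iotf_cutoffs()
  expect_true(all(cut$bmi_underweight < cut$bmi_overweight))
  expect_true(all(cut$bmi_overweight < cut$bmi_obesity))
})
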