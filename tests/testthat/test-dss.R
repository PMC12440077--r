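# Effective doses, the eleven comparison windows, and the weighted score.

tumor_ll4 <- function(e = 10, c = 0, b = 2) {
  as_drm("LL.4", c(b = b, c = c, d = 1, e = e))
}

test_that("effective doses match closed forms and flag unreachable levels", {
  expect_equal(ed_dose(tumor_ll4(e = 10, b = 1), 50, max_dose = 100), 10,
               tolerance = 1e-6)
  tau <- 30
  exd <- as_drm("EXD.3", c(c = 0, d = 1, e = tau))
  expect_equal(ed_dose(exd, 50, max_dose = 200), tau * log(2),
               tolerance = 1e-6)
  # lower asymptote 0.6: 50 % kill is never reached
  capped <- as_drm("LL.4", c(b = 2, c = 0.6, d = 1, e = 10))
  expect_true(is.na(ed_dose(capped, 50, max_dose = 1000)))
})

test_that("EDxx window follows its piecewise definition", {
  tum <- tumor_ll4(e = 10)
  # slice healthier than 100 % at the tumor ED50 -> max value 1
  lively <- as_drm("BC.5", c(b = 2, c = 0.9, d = 1, e = 50, f = 0.05))
  expect_gt(predict(lively, 10), 100)
  expect_equal(edxx_window(tum, lively, 50, max_dose = 100)$value, 1)

  # slice kill 25 at tumor kill 50 -> (50 - 25)/50 = 0.5
  half <- as_drm("LL.4", c(b = 50, c = 0.5, d = 1, e = 10))
  w <- edxx_window(tum, half, 50, max_dose = 100)
  expect_equal(w$value, 0.5, tolerance = 1e-3)

  # symmetric kills -> 0
  same <- tumor_ll4(e = 10)
  expect_equal(edxx_window(tum, same, 50, max_dose = 100)$value, 0,
               tolerance = 1e-9)

  # unreachable level -> undefined
  capped <- as_drm("LL.4", c(b = 2, c = 0.6, d = 1, e = 10))
  wu <- edxx_window(capped, same, 90, max_dose = 100)
  expect_false(wu$defined)
  expect_true(is.na(wu$value))
})

test_that("AUC window compares integrated survivals with sign symmetry", {
  # constant curves via degenerate LL.4 shapes: use EXD.3 with huge e
  flat_half <- as_drm("EXD.3", c(c = 0.5, d = 0.5, e = 1))   # constant 0.5
  flat_one <- as_drm("EXD.3", c(c = 1, d = 1, e = 1))        # constant 1.0
  expect_equal(auc_window(flat_half, flat_one, max_dose = 50)$value, 0.5,
               tolerance = 1e-8)
  expect_equal(auc_window(flat_one, flat_half, max_dose = 50)$value, -0.5,
               tolerance = 1e-8)
  expect_equal(auc_window(flat_one, flat_one, max_dose = 50)$value, 0)
})

test_that("TGA and IK read the fitted curve against printed cutoffs", {
  mk_peak <- function(target) {
    f <- uniroot(function(f) {
      p <- c(b = 3, c = 0, d = 1, e = 10, f = f)
      max(drm_curve("BC.5", p, seq(0, 100, length.out = 2000))) - target
    }, c(1e-6, 10))$root
    as_drm("BC.5", c(b = 3, c = 0, d = 1, e = 10, f = f))
  }
  expect_equal(tga_window(mk_peak(1.60), max_dose = 100), -1)
  expect_equal(tga_window(mk_peak(1.30), max_dose = 100), 0)
  expect_equal(tga_window(tumor_ll4(), max_dose = 100), 1)

  at_top <- function(s) as_drm("EXD.3", c(c = s, d = 1, e = 5))
  expect_equal(ik_window(at_top(0.30), max_dose = 100), -1)
  expect_equal(ik_window(at_top(0.15), max_dose = 100), 0)
  expect_equal(ik_window(at_top(0.05), max_dose = 100), 1)
})

test_that("max-kill window compares top-dose kills symmetrically", {
  at_top <- function(s) as_drm("EXD.3", c(c = s, d = 1, e = 5))
  w <- mk_window(at_top(0.2), at_top(0.6), max_dose = 100)
  expect_equal(w$value, 0.5, tolerance = 1e-6)     # TK 80, OK 40
  expect_equal(mk_window(at_top(0.6), at_top(0.2), max_dose = 100)$value,
               -0.5, tolerance = 1e-6)
  expect_equal(mk_window(at_top(0.5), at_top(0.5), max_dose = 100)$value, 0)
  none <- as_drm("EXD.3", c(c = 1, d = 1, e = 1))
  expect_true(mk_window(none, none, max_dose = 100)$flag)
})

test_that("biphasic window runs an ANOVA over the three highest doses", {
  set.seed(31)
  sep <- data.frame(dose = rep(c(0, 5, 25, 50, 100), each = 4),
                    survival_pct = c(rnorm(4, 100, 3), rnorm(4, 80, 3),
                                     rnorm(4, 60, 3), rnorm(4, 30, 3),
                                     rnorm(4, 5, 3)))
  w <- bp_window(sep)
  expect_equal(w$value, 1)
  expect_lt(w$p_value, 0.05)

  same <- data.frame(dose = rep(c(0, 25, 50, 100), each = 3),
                     survival_pct = rep(50, 12))
  expect_equal(bp_window(same)$value, -1)

  two <- data.frame(dose = rep(c(0, 10), each = 3),
                    survival_pct = rnorm(6, 50, 2))
  expect_false(bp_window(two)$defined)
})

test_that("slope window compares steepness at the evaluation dose", {
  # linear-in-dose curves via EXD.3 small-dose behaviour are awkward;
  # use LL.4 pairs with known slope ratio at the shared ED50 instead
  t1 <- tumor_ll4(e = 10, b = 2)
  o_flat <- as_drm("EXD.3", c(c = 1, d = 1, e = 1))   # constant 1
  w <- slope_window(t1, o_flat, max_dose = 100)
  expect_equal(w$eval_dose, 10, tolerance = 1e-4)
  expect_equal(w$value, 1, tolerance = 1e-6)          # |T| > 0, |O| = 0

  expect_equal(slope_window(t1, t1, max_dose = 100)$value, 0)

  # both flat at the evaluation dose -> 0 despite no kill anywhere
  expect_equal(slope_window(o_flat, o_flat, max_dose = 100)$value, 0)

  # |T| = 2|O|: doubling b doubles the slope at e when c = 0
  t2 <- tumor_ll4(e = 10, b = 4)
  w2 <- slope_window(t2, t1, max_dose = 100)
  expect_equal(w2$value, 0.5, tolerance = 1e-3)
})

test_that("the weight table carries the standard points and sums to 100", {
  w <- dss_weights()
  expect_equal(sum(w), 100)
  expect_equal(w[["AUC"]], 35)
  expect_equal(w[["ED50"]], 10)
  expect_equal(w[["MK"]], 10)
  expect_equal(w[["IK"]], 10)
  expect_equal(w[["BP"]], 5)
  expect_equal(unname(w[c("ED10", "ED25", "ED75", "ED90")]), rep(5, 4))
})

test_that("the DSS is a linear weighted sum with clamped extremes", {
  w <- dss_weights()
  all1 <- setNames(rep(1, length(w)), names(w))
  expect_equal(compute_dss(all1)$total, 100)
  expect_equal(compute_dss(-all1)$total, -100)
  expect_equal(compute_dss(0 * all1)$total, 0)

  # linear in each window at fixed weights
  base <- setNames(runif(length(w), -1, 1), names(w))
  for (nm in c("AUC", "ED50", "Slope")) {
    lo <- base; lo[nm] <- -0.4
    hi <- base; hi[nm] <- 0.8
    expect_equal(compute_dss(hi)$total - compute_dss(lo)$total,
                 w[[nm]] * 1.2, tolerance = 1e-10)
  }

  # undefined windows contribute 0 and are flagged
  miss <- all1; miss["ED90"] <- NA
  out <- compute_dss(miss)
  expect_equal(out$total, 95)
  expect_equal(out$undefined, "ED90")

  expect_error(compute_dss(all1, weights = w[-1]), "sum to 100")
  expect_error(compute_dss(all1 * 3), "\\[-1, 1\\]")
})

test_that("every defined window stays within [-1, 1] under fuzzing", {
  set.seed(77)
  for (i in 1:30) {
    tum <- as_drm("LL.4", c(b = runif(1, 1.1, 6), c = runif(1, 0, 0.9),
                            d = 1, e = runif(1, 1, 80)))
    obs <- as_drm("BC.5", c(b = runif(1, 1.1, 6), c = runif(1, 0.05, 1.5),
                            d = 1, e = runif(1, 5, 120),
                            f = runif(1, 1e-4, 0.1)))
    tum$data <- data.frame(dose = c(0, 5, 10, 50, 100),
                           y = drm_curve("LL.4", tum$params,
                                         c(0, 5, 10, 50, 100)))
    win <- dss_windows(tum, obs, max_dose = 100)
    vals <- unlist(win)
    vals <- vals[!is.na(vals)]
    expect_true(all(vals >= -1 - 1e-9 & vals <= 1 + 1e-9),
                label = paste("fuzz case", i))
  }
})

test_that("swapping the fits negates the symmetric comparison windows", {
  a <- as_drm("LL.4", c(b = 2, c = 0.1, d = 1, e = 15))
  b <- as_drm("LL.4", c(b = 3, c = 0.4, d = 1, e = 40))
  expect_equal(auc_window(a, b, max_dose = 100)$value,
               -auc_window(b, a, max_dose = 100)$value, tolerance = 1e-9)
  expect_equal(mk_window(a, b, max_dose = 100)$value,
               -mk_window(b, a, max_dose = 100)$value, tolerance = 1e-9)
})
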