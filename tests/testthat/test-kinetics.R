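test_that("standard curve recovers the line and converts signal", {
  sc <- fit_standard_curve(data.frame(concentration = c(0, 10, 20),
                                      signal = c(0, 100, 200)))
  expect_equal(sc$slope, 10)
  expect_equal(sc$intercept, 0)

  conc <- c(0, 5, 10, 20, 40, 80)
  sc2 <- fit_standard_curve(data.frame(concentration = conc,
                                       signal = 8.5 * conc + 12))
  expect_equal(sc2$slope, 8.5)
  expect_equal(sc2$intercept, 12)
  expect_equal(convert_signal(sc2, 8.5 * 30 + 12), 30)

  # noisy fit: compare against the closed-form OLS oracle, and check the
  # estimate sits within 3 standard errors of truth
  set.seed(42)
  sig <- 8.5 * conc + 12 + rnorm(6, sd = 1)
  sc3 <- fit_standard_curve(data.frame(concentration = conc, signal = sig))
  slope_hat <- sum((conc - mean(conc)) * (sig - mean(sig))) /
    sum((conc - mean(conc))^2)
  expect_equal(sc3$slope, slope_hat)
  resid <- sig - (slope_hat * conc + (mean(sig) - slope_hat * mean(conc)))
  se <- sqrt(sum(resid^2) / 4 / sum((conc - mean(conc))^2))
  expect_lt(abs(sc3$slope - 8.5), 3 * se)

  expect_error(fit_standard_curve(data.frame(concentration = c(5, 5, 5),
                                             signal = c(1, 2, 3))),
               "degenerate")
})

test_that("initial velocity is the slope of the sub-10%-conversion window", {
  tc <- data.frame(substrate_conc = 100, enzyme_conc = 0.5,
                   time_s = c(10, 20, 30, 40), product_uM = 0.2 * c(10, 20, 30, 40))
  vp <- initial_velocity(tc)
  expect_equal(vp$v0, 0.2)
  expect_equal(vp$n_used, 4)  # all products <= 10 uM = 10% of 100

  # integrated Michaelis-Menten progress curve (numeric ODE oracle):
  # truncated at 10% conversion the fitted slope stays within 5% of the
  # true initial rate kcat*[E]*[S]/(KM+[S])
  kcat <- 2; km <- 40; E <- 0.5; S0 <- 100
  dt <- 0.01
  tgrid <- seq(0, 15, by = dt)   # 10% conversion is reached near t = 14 s
  S <- numeric(length(tgrid)); S[1] <- S0
  for (i in seq_len(length(tgrid) - 1)) {
    S[i + 1] <- S[i] - dt * kcat * E * S[i] / (km + S[i])
  }
  prod <- S0 - S
  pick <- seq(1, length(tgrid), length.out = 8)
  tc2 <- data.frame(substrate_conc = S0, enzyme_conc = E,
                    time_s = tgrid[pick] + 1e-9, product_uM = prod[pick])
  v0_true <- kcat * E * S0 / (km + S0)
  vp2 <- initial_velocity(tc2)
  expect_lt(abs(vp2$v0 - v0_true) / v0_true, 0.05)
  expect_true(all(prod[pick][seq_len(vp2$n_used)] <= 0.1 * S0 + 1e-9))

  expect_error(initial_velocity(tc[1:2, ]), "3 timepoints")
  tc3 <- tc; tc3$product_uM <- c(5, 15, 20, 25)  # only 1 point below 10 uM
  expect_error(initial_velocity(tc3), "insufficient")
})

test_that("Michaelis-Menten fit reproduces the printed training example", {
  s <- c(5, 10, 25, 50, 100, 250)
  E <- 0.5
  v <- 4.2 * E * s / (19 + s)
  fit <- fit_michaelis_menten(data.frame(substrate_conc = s, v0 = v), E,
                              detection_limit = 10)
  expect_equal(fit$kcat, 4.2, tolerance = 1e-8)
  expect_equal(fit$km, 19, tolerance = 1e-8)
  expect_equal(signif(fit$kcat_over_km, 2), 220000)
  expect_false(fit$capped)
  # v0/[E] at [S] = KM is kcat/2 under the fitted hyperbola
  expect_equal(fit$kcat * 19 / (fit$km + 19), 4.2 / 2, tolerance = 1e-8)
})

test_that("KM below the detection limit caps the fit to a lower bound", {
  s <- c(25, 50, 100, 250, 500)
  v <- 2 * 0.5 * s / (5 + s)                    # true KM 5 uM
  fit <- fit_michaelis_menten(data.frame(substrate_conc = s, v0 = v), 0.5)
  expect_true(fit$capped)
  expect_equal(fit$kcat_over_km_bound, "lower")
  # bound evaluated at km = detection limit (20 uM), conservatively low
  expect_equal(fit$kcat_over_km, 1e6 * fit$kcat / 20)
  expect_lt(fit$kcat_over_km, 1e6 * 2 / 5)
  expect_true("km_below_detection_limit" %in% fit$quality_flags)
})

test_that("fit quality and unit conversion invariants hold", {
  set.seed(7)
  for (i in 1:5) {
    kcat <- runif(1, 0.2, 6); km <- runif(1, 15, 200); E <- 0.5
    s <- km * c(0.25, 0.5, 1, 2, 5, 10)
    v <- kcat * E * s / (km + s)
    fit <- fit_michaelis_menten(data.frame(substrate_conc = s, v0 = v), E,
                                detection_limit = 0)
    # noiseless recovery to < 1e-6 relative error
    expect_lt(abs(fit$kcat - kcat) / kcat, 1e-6)
    expect_lt(abs(fit$km - km) / km, 1e-6)
    # exact unit conversion uM -> M
    expect_equal(fit$kcat_over_km, 1e6 * fit$kcat / fit$km)
    # scaling every v0 by a factor scales kcat, leaves KM unchanged
    fit2 <- fit_michaelis_menten(data.frame(substrate_conc = s, v0 = 3 * v),
                                 E, detection_limit = 0)
    expect_equal(fit2$kcat, 3 * fit$kcat, tolerance = 1e-6)
    expect_equal(fit2$km, fit$km, tolerance = 1e-6)
  }
  # fewer than 2 concentrations below fitted KM raises a quality flag
  s <- c(100, 200, 400, 800)
  v <- 2 * 0.5 * s / (50 + s)
  fit <- fit_michaelis_menten(data.frame(substrate_conc = s, v0 = v), 0.5,
                              detection_limit = 0)
  expect_true("fewer_than_2_points_below_km" %in% fit$quality_flags)
  expect_error(fit_michaelis_menten(data.frame(substrate_conc = s[1:3],
                                               v0 = v[1:3]), 0.5),
               ">= 4 substrate concentrations")
})

test_that("substrate classification applies the efficiency cutoff", {
  expect_equal(classify_substrate(9000), "non-substrate")
  expect_equal(classify_substrate(40000), "substrate")
  expect_equal(classify_substrate(10000), "substrate")  # inclusive boundary
  expect_equal(classify_substrate(10000, classification_config(inclusive = FALSE)),
               "non-substrate")
  expect_equal(classify_substrate(c(1200, 2e5)), c("non-substrate", "substrate"))
  expect_error(classification_config(-1), "positive")
})

test_that("time-course tables read with signal conversion", {
  tmp <- tempfile(fileext = ".tsv")
  curve <- fit_standard_curve(data.frame(concentration = 0:5,
                                         signal = 10 * (0:5) + 3))
  tab <- data.frame(substrate_conc = rep(c(50, 100), each = 3),
                    enzyme_conc = 0.5,
                    time_s = rep(c(10, 20, 30), 2),
                    signal = 10 * (0.1 * rep(c(10, 20, 30), 2)) + 3)
  write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  tcs <- read_timecourse_table(tmp, curve)
  expect_length(tcs, 2)
  expect_equal(tcs[["50"]]$product_uM, 0.1 * c(10, 20, 30))
  expect_error(read_timecourse_table(tmp), "standard curve")
})
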