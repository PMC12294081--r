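test_that("marrow mass model: fraction product times density", {
  expect_equal(rbm_mass(100, 0.5, 0.8, 0.5), 20.6)
  expect_equal(rbm_mass(100, 0.5, 0.8, 0), 0)
  expect_error(rbm_mass(100, 1.2, 0.8, 0.5), "\\[0, 1\\]")
  set.seed(5)
  for (r in 1:20) {
    v <- runif(1, 1, 500); fs <- runif(1); fm <- runif(1); cc <- runif(1)
    expect_equal(rbm_mass(v, fs, fm, cc), v * fs * fm * cc * 1.03)
  }
  comp <- marrow_composition(c("vertebra_2", "pelvis", "femur_left"))
  expect_equal(comp$class, c("vertebra_like", "pelvis_like", "long_bone_like"))
  expect_true(all(comp$f_s * comp$f_m * comp$c >= 0 &
                    comp$f_s * comp$f_m * comp$c <= 1))
})

test_that("mono-exponential fit recovers noiseless parameters exactly", {
  t <- c(24, 48, 72)
  lam <- log(2) / 50
  fit <- fit_monoexp(t, 100 * exp(-lam * t))
  expect_equal(fit$A0_MBq, 100, tolerance = 1e-8)
  expect_equal(fit$lambda_per_h, lam, tolerance = 1e-8)
  expect_equal(fit$lambda_per_h, 0.013863, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_true(fit$included)
  expect_equal(unname(coef(fit)), c(fit$A0_MBq, fit$lambda_per_h))
  expect_equal(predict(fit), 100 * exp(-lam * t), tolerance = 1e-8)
  expect_error(fit_monoexp(24, 100), "2 paired")
  expect_error(fit_monoexp(t, c(1, -1, 1)), "positive")
})

test_that("the R^2 > 0.95 gate excludes distorted TACs", {
  t <- c(24, 48, 72, 96)
  a <- 100 * exp(-0.02 * t)
  a[2] <- a[2] * 2.5  # distort one point
  fit <- fit_monoexp(t, a)
  expect_lt(fit$r_squared, 0.95)
  expect_false(fit$included)
  expect_error(tia_monoexp(fit), "excluded")
})

test_that("lambda recovery is unbiased within 2% over noisy replicates", {
  t <- c(24, 48, 72)
  lam <- log(2) / 50
  truth <- 100 * exp(-lam * t)
  set.seed(2024)
  lams <- replicate(1000, {
    a <- truth * (1 + rnorm(3, 0, 0.05))
    if (any(a <= 0)) return(NA_real_)
    fit_monoexp(t, a)$lambda_per_h
  })
  expect_lt(abs(mean(lams, na.rm = TRUE) - lam) / lam, 0.02)
})

test_that("TIA closed form matches quadrature and propagates covariance", {
  fit <- fit_monoexp(c(24, 48, 72), 100 * exp(-0.01 * c(24, 48, 72)))
  tia <- tia_monoexp(fit)
  expect_equal(tia$tia_MBq_h, 100 / 0.01, tolerance = 1e-6)
  quad <- integrate(function(t) fit$A0_MBq * exp(-fit$lambda_per_h * t),
                    0, Inf, rel.tol = 1e-10)$value
  expect_equal(tia$tia_MBq_h, quad, tolerance = 1e-6)
  expect_equal(tia$u_tia_MBq_h, 0)  # exact fit: zero covariance
})

test_that("self dose: scaling, mass weighting, convexity", {
  sv <- svalue_table()
  one <- data.frame(tia_MBq_h = 500, u_tia_MBq_h = 0, mass_g = sv$m_ref_rbm_g)
  sd1 <- self_dose(one, sv, injected_GBq = 7.4)
  expect_equal(sd1$patient_mGy_per_GBq, 500 * sv$s_rbm_self / 7.4)
  two <- data.frame(tia_MBq_h = c(100, 300), u_tia_MBq_h = 0, mass_g = c(50, 50))
  sd2 <- self_dose(two, sv, 7.4)
  d <- sd2$per_site$dose_mGy_per_GBq
  expect_equal(d[2], 3 * d[1])
  expect_equal(sd2$patient_mGy_per_GBq, mean(d))  # equal masses -> plain mean
  set.seed(11)
  for (r in 1:10) {
    n <- sample(2:6, 1)
    tab <- data.frame(tia_MBq_h = runif(n, 10, 1000), u_tia_MBq_h = 0,
                      mass_g = runif(n, 5, 80))
    s <- self_dose(tab, sv, 7.4)
    expect_gte(s$patient_mGy_per_GBq, min(s$per_site$dose_mGy_per_GBq) - 1e-12)
    expect_lte(s$patient_mGy_per_GBq, max(s$per_site$dose_mGy_per_GBq) + 1e-12)
  }
  expect_error(self_dose(one[0, ], sv, 7.4), "no evaluable sites")
})

test_that("cross dose: remainder subtraction, reference-mass identity, linearity", {
  sv <- svalue_table()
  # total = kidneys + marrow -> remainder term vanishes
  cd0 <- cross_dose(800, 500, 300, sv, sv$m_ref_totalbody_g, 7.4)
  expect_equal(cd0$remainder_term, 0)
  expect_equal(cd0$mGy_per_GBq, 500 * sv$s_rbm_from_kidney / 7.4)
  # at reference masses the scaled S-values equal the reference S-values
  s_rem <- (sv$m_ref_totalbody_g * sv$s_rbm_from_totalbody -
              sv$m_ref_kidneys_g * sv$s_rbm_from_kidney -
              sv$m_ref_rbm_g * sv$s_rbm_self) /
    (sv$m_ref_totalbody_g - sv$m_ref_kidneys_g - sv$m_ref_rbm_g)
  cd <- cross_dose(2000, 500, 300, sv, sv$m_ref_totalbody_g, 7.4)
  expect_equal(cd$mGy_per_GBq,
               (500 * sv$s_rbm_from_kidney + 1200 * s_rem) / 7.4)
  # doubling the kidney TIA doubles the kidney term only
  cd2 <- cross_dose(2500, 1000, 300, sv, sv$m_ref_totalbody_g, 7.4)
  expect_equal(cd2$kidney_term, 2 * cd$kidney_term)
  expect_equal(cd2$remainder_term, cd$remainder_term)
  expect_error(cross_dose(700, 500, 300, sv, 70000, 7.4), "negative")
})

test_that("dose normalization: doubling injected activity halves dose per GBq", {
  sv <- svalue_table()
  tab <- data.frame(tia_MBq_h = c(200, 350), u_tia_MBq_h = c(5, 8),
                    mass_g = c(30, 60))
  a <- self_dose(tab, sv, 7.4); b <- self_dose(tab, sv, 14.8)
  expect_equal(b$patient_mGy_per_GBq, a$patient_mGy_per_GBq / 2)
  expect_equal(b$u_patient_mGy_per_GBq, a$u_patient_mGy_per_GBq / 2)
})

test_that("delta-method site uncertainty matches a Monte Carlo oracle", {
  t <- c(24, 48, 72, 96, 120)
  lam <- log(2) / 45
  set.seed(77)
  a <- 80 * exp(-lam * t) * (1 + rnorm(5, 0, 0.03))
  fit <- fit_monoexp(t, a)
  expect_true(fit$included)
  sv <- svalue_table()
  u <- propagate_site_uncertainty(fit, mass_g = 40, u_mass_g = 0,
                                  svalues = sv, injected_GBq = 7.4)
  # Monte Carlo: resample (A0, lambda) from the fit covariance
  n_mc <- 1e5
  ch <- chol(fit$covariance + diag(1e-15, 2))
  z <- matrix(rnorm(2 * n_mc), n_mc, 2) %*% ch
  A0s <- fit$A0_MBq + z[, 1]; lams <- fit$lambda_per_h + z[, 2]
  k <- sv$s_rbm_self * (sv$m_ref_rbm_g / 40) / 7.4
  doses <- (A0s / lams) * k
  expect_lt(sd(doses) / mean(doses), 0.10)  # small-noise regime
  expect_equal(u, sd(doses), tolerance = 0.10)
  # zero covariance and zero mass uncertainty -> zero dose uncertainty
  exact <- fit_monoexp(t, 80 * exp(-lam * t))
  expect_equal(propagate_site_uncertainty(exact, 40, 0, sv, 7.4), 0)
  # homogeneity: scaling the activities scales the uncertainty
  fit2 <- fit_monoexp(t, 3 * a)
  u2 <- propagate_site_uncertainty(fit2, 40, 0, sv, 7.4)
  expect_equal(u2, 3 * u, tolerance = 1e-6)
  bad <- fit; bad$covariance <- matrix(c(1, 2, 2, 1), 2)
  expect_error(propagate_site_uncertainty(bad, 40, 0, sv, 7.4),
               "positive semi-definite")
})

test_that("cumulative dose and blood correlation: monotone, null and tie cases", {
  doses <- data.frame(patient = rep(1:4, each = 3), cycle = rep(1:3, 4),
                      total_mGy_per_GBq = rep(c(10, 20, 30, 40), each = 3),
                      injected_GBq = 7.4)
  blood <- expand.grid(patient = 1:4, cycle = 0:3, analyte = "thrombocytes")
  # strictly decreasing in cumulative dose
  key <- order(blood$patient, blood$cycle)
  blood <- blood[key, ]
  doses_sorted <- doses[order(doses$patient, doses$cycle), ]
  cum <- ave(doses_sorted$total_mGy_per_GBq * doses_sorted$injected_GBq,
             doses_sorted$patient, FUN = cumsum)
  blood$value <- 250
  for (i in seq_len(nrow(blood))) {
    if (blood$cycle[i] > 0) {
      j <- which(doses_sorted$patient == blood$patient[i] &
                   doses_sorted$cycle == blood$cycle[i])
      blood$value[i] <- 250 - 0.1 * cum[j]
    }
  }
  res <- cumulative_dose_and_blood_correlation(doses, blood)
  expect_equal(res$correlations$rho, -1)
  expect_true(all(diff(res$table$cumulative_mGy[res$table$patient == 1]) > 0))
  # permutation null: mean rho over seeded repeats is near zero
  set.seed(123)
  rhos <- replicate(2000, {
    x <- rnorm(8); y <- rnorm(8)
    cor(x, y, method = "spearman")
  })
  expect_lt(abs(mean(rhos)), 3 * sd(rhos) / sqrt(length(rhos)))
  # ties: midrank recomputation oracle
  xs <- c(1, 2, 2, 3, 4, 4); ys <- c(5, 4, 4, 3, 2, 1)
  expect_equal(unname(cor.test(xs, ys, method = "spearman",
                               exact = FALSE)$estimate),
               cor(rank(xs), rank(ys)))
  # constant input is flagged, not an error
  blood2 <- blood; blood2$value <- 100
  res2 <- cumulative_dose_and_blood_correlation(doses, blood2)
  expect_true(res2$correlations$degenerate)
  expect_true(is.na(res2$correlations$rho))
})

test_that("dose report: total = self + cross, self fraction in [0, 1]", {
  sv <- svalue_table()
  tab <- data.frame(tia_MBq_h = c(120, 80), u_tia_MBq_h = c(3, 2),
                    mass_g = c(25, 35))
  sdz <- self_dose(tab, sv, 7.4)
  cd <- cross_dose(5000, 800, 200, sv, 70000, 7.4)
  rep <- dose_report(sdz, cd, 7.4)
  expect_equal(rep$total_mGy_per_GBq, rep$self_mGy_per_GBq + rep$cross_mGy_per_GBq)
  expect_gte(rep$self_fraction, 0); expect_lte(rep$self_fraction, 1)
  expect_equal(rep$cycle_dose_mGy, rep$total_mGy_per_GBq * 7.4)
})
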