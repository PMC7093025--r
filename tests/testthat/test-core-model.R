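# Cell-level forward model: photosynthesis law, chlorophyll linearity,
# allocation rules, quadratic closed forms, and maximum growth rate.

p0 <- model_params()
r0 <- default_ratios()

test_that("photosynthesis saturates with light and honors its identities", {
  expect_equal(photosynthesis_rate(0, p0), 0)
  expect_equal(photosynthesis_rate(1e9, p0), p0$v_I_max)
  expect_equal(photosynthesis_rate(log(2) / p0$A_I, p0), p0$v_I_max / 2)
  I <- seq(5, 500, by = 5)
  expect_true(all(diff(photosynthesis_rate(I, p0)) > 0))
  expect_error(photosynthesis_rate(-1, p0), class = "phytoalloc_domain_error")
})

test_that("Chl:C is the steady-state solution of the carbon balance, linear in mu", {
  I <- c(20, 80, 250)
  cf <- chl_coefficients(I, p0)
  # zero-growth intercept is the maintenance term
  expect_equal(chl_to_c(0, I, p0), p0$m / photosynthesis_rate(I, p0))
  # with no maintenance, mu = v_I / (1+E) demands all-chlorophyll carbon
  pm0 <- update_params(p0, m = 0)
  vI <- photosynthesis_rate(100, pm0)
  expect_equal(chl_to_c(vI / (1 + pm0$E), 100, pm0), 1)
  # steady-state residual of the carbon balance is identically zero
  for (mu in c(0, 0.3, 1.1)) {
    q <- chl_to_c(mu, I, p0)
    resid <- photosynthesis_rate(I, p0) * q - (1 + p0$E) * mu - p0$m
    expect_equal(max(abs(resid)), 0, tolerance = 1e-14)
  }
  # exactly linear: second finite differences vanish at machine precision
  mu <- seq(0, 1.5, by = 0.25)
  for (i in I) {
    expect_equal(max(abs(diff(diff(chl_to_c(mu, i, p0))))), 0,
                 tolerance = 1e-15)
  }
  # both coefficients fall as light rises
  expect_true(all(diff(cf$A_Chl) < 0) && all(diff(cf$B_Chl) < 0))
})

test_that("Chl:C matches an independent second evaluation of the law", {
  # independent arithmetic, written out from scratch
  m <- 0.1; v_I_max <- 10; A_I <- 0.01; E <- 0.5; I <- 100; mu <- 1
  v_I <- v_I_max * (1 - exp(-A_I * I))
  expected <- (1 + E) / v_I * mu + m / v_I
  p <- model_params(m = m, v_I_max = v_I_max, A_I = A_I, E = E)
  expect_equal(chl_to_c(mu, I, p), expected, tolerance = 1e-14)
})

test_that("allocation rules are proportional with the stated intercepts", {
  al0 <- allocation_rules(0, 0.02, 0.4, p0, r0)
  expect_equal(al0$Q_P_RNA, p0$Q_P_min_RNA)
  al <- allocation_rules(0.5, 0, 0.4, p0, r0)
  expect_equal(al$Q_C_Pro_Pho, 0)
  expect_equal(al$Q_P_Thy, 0)
  a1 <- allocation_rules(0.4, 0.02, 0.4, p0, r0)
  a2 <- allocation_rules(0.8, 0.02, 0.4, p0, r0)
  expect_equal(a2$Q_C_Pro_Bio, 2 * a1$Q_C_Pro_Bio)
  # carbon equivalents through the C:P conversions
  expect_equal(a1$Q_C_RNA, r0$Y_RNA_CP * a1$Q_P_RNA)
  expect_equal(a1$Q_C_Plip_Thy, r0$Y_Plip_CP * a1$Q_P_Thy)
})

test_that("mu_max is the positive quadratic root, checked against bisection", {
  for (case in random_cases(50, seed = 11)) {
    co <- mu_max_coefficients(case$I, case$params, r0)
    expect_true(co$a_M > 0 && co$c_M < 0)
    oracle <- uniroot(function(mu) co$a_M * mu^2 + co$b_M * mu + co$c_M,
                      c(0, 20), tol = 1e-12)$root
    expect_equal(mu_max(case$I, case$params, r0), oracle, tolerance = 1e-8)
  }
  # residual at the root
  co <- mu_max_coefficients(120, p0, r0)
  mm <- mu_max(120, p0, r0)
  expect_lt(abs(co$a_M * mm^2 + co$b_M * mm + co$c_M), 1e-10)
})

test_that("infeasible fixed pools raise a typed error instead of returning 0", {
  p_bad <- update_params(p0, Q_C_Other0 = 0.78)  # fixed pools ~0.99
  expect_error(mu_max(5, p_bad, r0), class = "phytoalloc_infeasible_error")
  expect_error(n_to_c(2.5, 15, p0, r0), class = "phytoalloc_infeasible_error")
})

test_that("pool-sum and closed-form N:C and P:C agree to machine precision", {
  for (case in random_cases(40, seed = 12)) {
    st <- allocation_state(case$mu, case$I, case$params, r0)
    expect_equal(sum(st$q_n),
                 n_to_c(case$mu, case$I, case$params, r0, check = FALSE),
                 tolerance = 1e-12)
    expect_equal(sum(st$q_p),
                 p_to_c(case$mu, case$I, case$params, r0, check = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("N:C degenerates to the linear protein-only form as RNA vanishes", {
  p_lin <- update_params(p0, A_RNA_P = 0)
  co <- nc_coefficients(80, p_lin, r0)
  expect_equal(co$a, 0)
  # the full form always equals the linear form plus the chlorophyll,
  # RNA, and DNA nitrogen contributions
  mu <- seq(0, 1.2, by = 0.3)
  st <- lapply(mu, function(m) allocation_state(m, 80, p0, r0))
  full <- n_to_c(mu, 80, p0, r0, check = FALSE)
  lin <- n_to_c_linear(mu, 80, p0, r0)
  extra <- sapply(st, function(s) s$q_n[["Chl"]] + s$q_n[["RNA"]] + s$q_n[["DNA"]])
  expect_equal(full, lin + extra, tolerance = 1e-14)
})

test_that("P:C is constant in mu when both growth-linked P pools are off", {
  p_flat <- update_params(p0, A_RNA_P = 0, A_Pho_PChl = 0)
  vals <- p_to_c(c(0, 0.4, 0.9), 150, p_flat, r0, check = FALSE)
  expect_equal(max(vals) - min(vals), 0, tolerance = 1e-15)
  co <- pc_coefficients(150, p_flat, r0)
  expect_equal(co$a, 0)
  expect_equal(co$b, 0)
  expect_equal(p_to_c(0, 150, p0, r0), pc_coefficients(150, p0, r0)$c)
})

test_that("N:P is the quotient of the two ratios and falls with mu under P limitation", {
  expect_equal(0.15 / 0.01, 15)
  mu <- seq(0.05, 0.95, by = 0.1) * mu_max(120, p0, r0)
  np <- n_to_p(mu, 120, p0, r0, check = FALSE)  # zero storage = P-limited form
  expect_true(all(diff(np) < 0))
})

test_that("mu_max rises with light, saturates, and saturates earlier than photosynthesis", {
  I <- c(10, 25, 60, 150, 400, 1000)
  mms <- sapply(I, function(i) mu_max(i, p0, r0))
  expect_true(all(diff(mms) > 0))
  mm_inf <- mu_max(1e7, p0, r0)
  expect_lt(mms[length(mms)], mm_inf)
  expect_lt(mm_inf, 20)  # finite asymptote
  # light at 95% of the asymptote: growth saturates at or below the light
  # at which photosynthesis itself reaches 95% of its maximum
  I95_v <- -log(0.05) / p0$A_I
  I95_mu <- uniroot(function(i) mu_max(i, p0, r0) - 0.95 * mm_inf,
                    c(1, 5000), tol = 1e-10)$root
  expect_lte(I95_mu, I95_v)
})

test_that("approximate mu solution matches the quadratic root when the neglected pools vanish", {
  # the approximate budget drops RNA carbon, thylakoid lipid carbon, AND
  # pigment carbon; with the first two zeroed, feeding the pigment quota
  # back through the storage slot recovers the full solution exactly
  p_small <- update_params(p0, A_RNA_P = 0, Q_P_min_RNA = 0, A_Pho_PChl = 0)
  for (I in c(30, 90, 250)) {
    mm <- mu_max(I, p_small, r0)
    expect_equal(
      mu_max_approx(I, p_small, r0, Q_C_Csto = chl_to_c(mm, I, p_small)),
      mm, tolerance = 1e-12)
    # the neglected pigment pool is the entire discrepancy, a few percent
    expect_equal(mu_max_approx(I, p_small, r0), mm, tolerance = 0.2)
  }
  # for the full set the approximation overestimates: ignoring the RNA,
  # thylakoid-lipid, and pigment carbon frees up budget for growth
  expect_gt(mu_max_approx(120, p0, r0), mu_max(120, p0, r0))
})

test_that("model_curves flags infeasible grid points instead of dropping them", {
  curves <- model_curves(c(0.2, 5), c(50, 200), p0, r0)
  expect_equal(nrow(curves), 4L)
  expect_true(all(curves$infeasible[curves$mu == 5]))
  expect_true(all(is.na(curves$n_to_c[curves$infeasible])))
  expect_false(any(is.na(curves$n_to_c[!curves$infeasible])))
})
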