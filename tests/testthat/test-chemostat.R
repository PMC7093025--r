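# Culture-level steady state: biomass, limitation, luxury storage, closure.

p0 <- model_params()
r0 <- default_ratios()

test_that("biomass under a given limitation is feed over non-storage quota", {
  env <- chemostat_env(I = 100, N_in = 0.5, P_in = 0.01, D = 0.5)
  expect_equal(biomass_if_limited("N", env, 0.1), 5.0)
  expect_equal(biomass_if_limited("P", env, 0.005), 2.0)
  expect_error(biomass_if_limited("N", env, 0), class = "phytoalloc_domain_error")
  # biomass falls as growth (hence quota) rises at fixed feed
  mu <- seq(0.1, 1.2, by = 0.1)
  qn <- n_to_c(mu, 150, p0, r0, check = FALSE)
  expect_true(all(diff(env$N_in / qn) < 0))
})

test_that("limitation follows feed N:P vs required N:P with an N tie-break", {
  env <- function(np) chemostat_env(100, np * 0.01, 0.01, 0.5)
  expect_equal(determine_limitation(env(10), 0.15, 0.01), "N")  # required 15
  expect_equal(determine_limitation(env(20), 0.15, 0.01), "P")
  expect_equal(determine_limitation(env(15), 0.15, 0.01), "N")  # tie
  expect_error(determine_limitation(chemostat_env(100, 0, 0, 0.5), 0.1, 0.01),
               class = "phytoalloc_domain_error")
})

test_that("limitation rule agrees with the biomass argmin on random cases", {
  set.seed(99)
  for (i in 1:300) {
    env <- chemostat_env(100, runif(1, 0.01, 1), runif(1, 0.001, 0.1), 0.5)
    qn <- runif(1, 0.05, 0.25)
    qp <- runif(1, 0.002, 0.03)
    lim <- determine_limitation(env, qn, qp)
    bm <- c(N = biomass_if_limited("N", env, qn),
            P = biomass_if_limited("P", env, qp))
    expect_equal(lim, names(which.min(bm)))
  }
})

test_that("storage caps bind as specified and carry cyanophycin carbon", {
  # N-limited: the excess-P rule with a binding total-P cap
  env <- chemostat_env(100, N_in = 0.1, P_in = 0.1, D = 0.3)  # lots of feed P
  p_cap <- update_params(p0, Q_P_max = 0.012)
  sol <- solve_culture(env, p_cap, r0)
  expect_equal(sol$state$limitation, "N")
  expect_equal(sum(sol$state$q_p), p_cap$Q_P_max)  # cap binds on TOTAL P
  expect_equal(sol$state$q_n[["Sto"]], 0)          # limiting element: none
  # exact exhaustion leaves zero storage
  st <- allocation_state(0.3, 100, p0, r0, limitation = "N")
  qp_non <- sum(st$q_p)
  env2 <- chemostat_env(100, N_in = 0.1, P_in = qp_non * (0.1 / sum(st$q_n)),
                        D = 0.3)
  sol2 <- solve_culture(env2, p0, r0)
  expect_equal(sol2$state$q_p[["Sto"]], 0, tolerance = 1e-12)
  # cyanophycin carbon conversion
  expect_equal(r0$Y_Nsto_CN * 0.02, 0.04)
})

test_that("storage accrues only for the non-limiting element", {
  env_n <- chemostat_env(120, 0.25, 0.025, 0.5)   # feed N:P = 10
  env_p <- chemostat_env(120, 0.40, 0.010, 0.5)   # feed N:P = 40
  sol_n <- solve_culture(env_n, p0, r0)
  sol_p <- solve_culture(env_p, p0, r0)
  expect_equal(sol_n$state$limitation, "N")
  expect_equal(sol_n$state$q_n[["Sto"]], 0)
  expect_gt(sol_n$state$q_p[["Sto"]], 0)
  expect_equal(sol_p$state$limitation, "P")
  expect_equal(sol_p$state$q_p[["Sto"]], 0)
  expect_gt(sol_p$state$q_n[["Sto"]], 0)
})

test_that("carbon closes exactly, with the zero-growth storage given in closed form", {
  st0 <- allocation_state(0, 80, p0, r0)
  cf <- chl_coefficients(80, p0)
  expected_csto <- 1 -
    cf$B_Chl * (1 + p0$A_Pho + r0$Y_Plip_CP * p0$A_Pho_PChl) -
    p0$Q_C_Pro_Other - p0$Q_C_DNA - p0$Q_C_Other0 -
    r0$Y_RNA_CP * p0$Q_P_min_RNA
  expect_equal(st0$q_c[["Csto"]], expected_csto, tolerance = 1e-14)
  expect_equal(sum(st0$q_c), 1)
  # at the maximum growth rate the storage pool closes to zero
  mm <- mu_max(80, p0, r0)
  expect_lt(allocation_state(mm, 80, p0, r0)$q_c[["Csto"]], 1e-10)
})

test_that("steady-state culture balances hold for the returned state", {
  env <- chemostat_env(150, 0.25, 0.025, 0.7)
  sol <- solve_culture(env, p0, r0)
  st <- sol$state
  q_n_nonsto <- sum(st$q_n) - st$q_n[["Sto"]]
  V_N <- st$mu * q_n_nonsto                      # uptake = growth x quota
  expect_equal(env$D * env$N_in - V_N * sol$biomass, 0, tolerance = 1e-12)
  expect_equal(st$mu, env$D)                     # dX/dt = (mu - D) X = 0
  expect_equal(V_N - st$mu * q_n_nonsto, 0)      # dQ_N/dt = 0
})

test_that("washout raises a typed error carrying the attainable maximum", {
  mm <- mu_max(40, p0, r0)
  env <- chemostat_env(40, 0.25, 0.025, mm * 1.05)
  err <- tryCatch(solve_culture(env, p0, r0), phytoalloc_washout_error = identity)
  expect_s3_class(err, "phytoalloc_washout_error")
  expect_equal(err$mu_max, mm)
  # just below washout the culture is valid with near-zero carbon storage
  sol <- solve_culture(chemostat_env(40, 0.25, 0.025, mm * 0.999), p0, r0)
  expect_lt(sol$state$q_c[["Csto"]], 0.01)
})

test_that("biomass declines with dilution rate under N limitation", {
  D <- seq(0.1, 1.0, by = 0.1)
  envs <- data.frame(I = 150, D = D, N_in = 0.25, P_in = 0.025)
  out <- simulate_chemostat(envs, p0, r0)
  expect_true(all(out$limitation == "N"))
  expect_true(all(diff(out$biomass) < 0))
})

test_that("batch evaluation flags washout rows instead of dropping them", {
  mm <- mu_max(15, p0, r0)
  envs <- data.frame(I = 15, D = c(0.5 * mm, 2 * mm), N_in = 0.25, P_in = 0.025)
  out <- simulate_chemostat(envs, p0, r0)
  expect_equal(out$washout, c(FALSE, TRUE))
  expect_true(is.na(out$biomass[2]))
  expect_error(simulate_chemostat(data.frame(I = 1), p0, r0),
               class = "phytoalloc_domain_error")
})

test_that("all pools stay nonnegative and conserve mass across random cultures", {
  for (case in random_cases(60, seed = 21)) {
    sol <- solve_culture(case$env, case$params, r0)
    st <- sol$state
    expect_true(all(st$q_c >= 0) && all(st$q_n >= 0) && all(st$q_p >= 0))
    expect_equal(sum(st$q_c), 1, tolerance = 1e-12)
    expect_equal(st$n_to_c, sum(st$q_n))
    expect_equal(st$p_to_c, sum(st$q_p))
  }
})
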