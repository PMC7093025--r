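# Cell-level forward model.
#
# Photosynthesis saturates with light; the chlorophyll quota needed to
# sustain a growth rate mu at irradiance I follows from the steady-state
# carbon balance and is exactly linear in mu. Photosynthetic protein and
# thylakoid phospholipid scale with chlorophyll (fixed thylakoid makeup),
# biosynthetic protein scales with growth rate, and RNA phosphorus scales
# with (protein x growth rate) plus a minimum. Summing pools gives closed
# quadratic forms for N:C and P:C in mu, and setting the flexible carbon
# storage to zero gives the light-dependent maximum growth rate as the
# positive root of a quadratic.
#
# All the vectorized internals below recycle over `I` and `mu`; exported
# wrappers validate scalar/vector domains.

#' Gross photosynthesis rate per chlorophyll carbon
#'
#' `v_I(I) = v_I_max * (1 - exp(-A_I * I))`: a saturating function of
#' irradiance, strictly increasing and bounded by `v_I_max`.
#'
#' @param I Irradiance (umol photons m^-2 s^-1); may be a vector.
#' @param params A [model_params()] object.
#' @return Photosynthesis rate(s), mol C (mol Chl C)^-1 d^-1.
#' @export
photosynthesis_rate <- function(I, params) {
  if (any(!is.finite(I)) || any(I < 0)) {
    abort_domain("irradiance `I` must be finite and >= 0")
  }
  params$v_I_max * (1 - exp(-params$A_I * I))
}

#' Chlorophyll-to-carbon ratio and its light-dependent coefficients
#'
#' At steady state the chlorophyll quota is linear in growth rate:
#' `Q_C_Chl = A_Chl(I) * mu + B_Chl(I)` with `A_Chl = (1 + E) / v_I` and
#' `B_Chl = m / v_I`. The intercept is the pigment needed to cover
#' maintenance respiration at zero net growth; both coefficients increase
#' as light decreases.
#'
#' @param mu Growth rate (d^-1); may be a vector.
#' @inheritParams photosynthesis_rate
#' @return For `chl_coefficients()`, a list with vectors `A_Chl`, `B_Chl`;
#'   for `chl_to_c()`, the chlorophyll carbon quota (mol Chl C (mol C)^-1).
#' @export
chl_coefficients <- function(I, params) {
  v_I <- photosynthesis_rate(I, params)
  if (any(v_I <= 0)) {
    abort_domain("`I` gives zero photosynthesis (I = 0): Chl:C is singular")
  }
  list(A_Chl = (1 + params$E) / v_I, B_Chl = params$m / v_I)
}

#' @rdname chl_coefficients
#' @export
chl_to_c <- function(mu, I, params) {
  if (any(!is.finite(mu)) || any(mu < 0)) abort_domain("`mu` must be finite and >= 0")
  cf <- chl_coefficients(I, params)
  cf$A_Chl * mu + cf$B_Chl
}

#' Allocation rules linking pools to chlorophyll and growth rate
#'
#' Given the chlorophyll quota and total protein quota, applies the
#' proportionality rules: photosynthetic protein and thylakoid
#' phospholipid-P scale with chlorophyll, biosynthetic protein scales with
#' growth rate, and RNA-P is linear in (protein x growth rate) with a
#' minimum at zero growth. Carbon equivalents of the P-containing pools
#' use the phospholipid and RNA C:P ratios.
#'
#' @param mu Growth rate (d^-1).
#' @param Q_C_Chl Chlorophyll carbon quota.
#' @param Q_C_Pro Total protein carbon quota.
#' @param params A [model_params()] object.
#' @param ratios A [stoich_ratios()] object.
#' @return Named list of quotas: `Q_C_Pro_Pho`, `Q_P_Thy`, `Q_C_Pro_Bio`,
#'   `Q_P_RNA`, `Q_C_Plip_Thy`, `Q_C_RNA`.
#' @export
allocation_rules <- function(mu, Q_C_Chl, Q_C_Pro, params, ratios = default_ratios()) {
  if (any(c(mu, Q_C_Chl, Q_C_Pro) < 0)) abort_domain("allocation inputs must be >= 0")
  Q_P_Thy <- params$A_Pho_PChl * Q_C_Chl
  Q_P_RNA <- params$A_RNA_P * mu * Q_C_Pro + params$Q_P_min_RNA
  list(
    Q_C_Pro_Pho = params$A_Pho * Q_C_Chl,
    Q_P_Thy = Q_P_Thy,
    Q_C_Pro_Bio = params$A_Bio * mu,
    Q_P_RNA = Q_P_RNA,
    Q_C_Plip_Thy = ratios$Y_Plip_CP * Q_P_Thy,
    Q_C_RNA = ratios$Y_RNA_CP * Q_P_RNA
  )
}

# ---- closed-form coefficients ------------------------------------------

#' Quadratic coefficients of the carbon-closure equation in mu
#'
#' With carbon and nitrogen storage set to zero, substituting all
#' allocation rules into the carbon budget (pools sum to 1) gives
#' `a_M mu^2 + b_M mu + c_M = 0`. Feasible parameter sets have `c_M < 0`
#' (fixed pools plus maintenance leave room to grow), and the positive
#' root is the light-dependent maximum growth rate.
#'
#' @inheritParams chl_coefficients
#' @param ratios A [stoich_ratios()] object.
#' @return List with vectors `a_M`, `b_M`, `c_M` (recycled over `I`).
#' @export
mu_max_coefficients <- function(I, params, ratios = default_ratios()) {
  cf <- chl_coefficients(I, params)
  thyla <- 1 + params$A_Pho + ratios$Y_Plip_CP * params$A_Pho_PChl
  Q_C_Other <- params$Q_C_Pro_Other + params$Q_C_DNA + params$Q_C_Other0
  list(
    a_M = ratios$Y_RNA_CP * params$A_RNA_P *
      (params$A_Pho * cf$A_Chl + params$A_Bio),
    b_M = thyla * cf$A_Chl + params$A_Bio +
      ratios$Y_RNA_CP * params$A_RNA_P *
        (params$A_Pho * cf$B_Chl + params$Q_C_Pro_Other),
    c_M = thyla * cf$B_Chl + Q_C_Other +
      ratios$Y_RNA_CP * params$Q_P_min_RNA - 1
  )
}

#' Maximum growth rate at a given light intensity
#'
#' The nutrient-replete maximum growth rate: the growth rate at which all
#' flexible carbon has been allocated to photosynthetic and biosynthetic
#' machinery and carbon storage vanishes. Computed as the positive root of
#' the carbon-closure quadratic, using the cancellation-free form
#' `mu = -2 c_M / (b_M + sqrt(b_M^2 - 4 a_M c_M))` (`b_M > 0`, `c_M < 0`).
#'
#' @inheritParams mu_max_coefficients
#' @return Maximum growth rate(s), d^-1.
#' @section Errors: raises a `phytoalloc_infeasible_error` when `c_M >= 0`
#'   (fixed pools and maintenance exceed the cell's capacity at this
#'   light), so that calibration can penalize such parameter sets.
#' @export
mu_max <- function(I, params, ratios = default_ratios()) {
  if (any(I <= 0)) abort_domain("`I` must be > 0 for mu_max")
  co <- mu_max_coefficients(I, params, ratios)
  if (any(co$c_M >= 0)) {
    abort_infeasible(paste0(
      "no positive growth rate: fixed pools + maintenance exceed capacity ",
      "at I = ", paste(signif(I[co$c_M >= 0], 4), collapse = ", ")))
  }
  .quad_positive_root(co$a_M, co$b_M, co$c_M)
}

# Positive root of a x^2 + b x + c = 0 with b > 0, c < 0, a >= 0.
# The conventional (-b + sqrt(disc)) / (2a) cancels when |4ac| << b^2 and
# degenerates at a = 0; the rationalized form handles both.
.quad_positive_root <- function(a, b, c) {
  disc <- b^2 - 4 * a * c
  -2 * c / (b + sqrt(disc))
}

#' Quadratic coefficients of N:C and P:C in growth rate
#'
#' Closed forms from substituting the allocation rules into the nitrogen
#' and phosphorus pool sums. N:C is almost linear (the tiny quadratic term
#' comes from RNA nitrogen); P:C is visibly quadratic because RNA
#' dominates cellular phosphorus.
#'
#' @inheritParams mu_max_coefficients
#' @param Q_N_Sto,Q_P_Sto Storage quotas entering the intercepts
#'   (default 0; filled by the chemostat layer for the non-limiting
#'   element).
#' @return List with vectors `a`, `b`, `c` such that the ratio equals
#'   `a mu^2 + b mu + c`.
#' @export
nc_coefficients <- function(I, params, ratios = default_ratios(), Q_N_Sto = 0) {
  cf <- chl_coefficients(I, params)
  pro_slope <- params$A_Bio + params$A_Pho * cf$A_Chl
  pro_int <- params$A_Pho * cf$B_Chl + params$Q_C_Pro_Other
  list(
    a = ratios$Y_RNA_NP * params$A_RNA_P * pro_slope,
    b = ratios$Y_Chl_NC * cf$A_Chl + ratios$Y_Pro_NC * pro_slope +
      ratios$Y_RNA_NP * params$A_RNA_P * pro_int,
    c = ratios$Y_Chl_NC * cf$B_Chl + ratios$Y_Pro_NC * pro_int +
      ratios$Y_RNA_NP * params$Q_P_min_RNA +
      ratios$Y_DNA_NC * params$Q_C_DNA + Q_N_Sto
  )
}

#' @rdname nc_coefficients
#' @export
pc_coefficients <- function(I, params, ratios = default_ratios(), Q_P_Sto = 0) {
  cf <- chl_coefficients(I, params)
  pro_slope <- params$A_Bio + params$A_Pho * cf$A_Chl
  pro_int <- params$A_Pho * cf$B_Chl + params$Q_C_Pro_Other
  list(
    a = params$A_RNA_P * pro_slope,
    b = params$A_RNA_P * pro_int + params$A_Pho_PChl * cf$A_Chl,
    c = params$Q_P_min_RNA + ratios$Y_DNA_PC * params$Q_C_DNA +
      params$A_Pho_PChl * cf$B_Chl + params$Q_P_Other0 + Q_P_Sto
  )
}

.check_mu_feasible <- function(mu, I, params, ratios) {
  mm <- mu_max(I, params, ratios)
  bad <- mu > mm * (1 + 1e-12)
  if (any(bad)) {
    abort_infeasible(sprintf(
      "mu = %.4g d^-1 exceeds mu_max = %.4g d^-1 at I = %.4g",
      max(mu[bad]), min(mm[bad]), I[which(bad)[1]]), mu_max = mm)
  }
  invisible(mm)
}

#' Steady-state N:C, P:C, and N:P ratios
#'
#' Evaluates the closed quadratic forms at growth rate `mu` and irradiance
#' `I`. Storage of the non-limiting element, if any, enters additively.
#' `n_to_p()` is the quotient of the two.
#'
#' @param mu Growth rate (d^-1), `0 <= mu <= mu_max(I)`.
#' @inheritParams nc_coefficients
#' @param check Verify `mu <= mu_max` (set `FALSE` to skip inside tight
#'   loops where the caller has already checked).
#' @return Ratio(s), mol:mol.
#' @export
n_to_c <- function(mu, I, params, ratios = default_ratios(), Q_N_Sto = 0,
                   check = TRUE) {
  if (any(mu < 0)) abort_domain("`mu` must be >= 0")
  if (check) .check_mu_feasible(mu, I, params, ratios)
  co <- nc_coefficients(I, params, ratios, Q_N_Sto = Q_N_Sto)
  co$a * mu^2 + co$b * mu + co$c
}

#' @rdname n_to_c
#' @export
p_to_c <- function(mu, I, params, ratios = default_ratios(), Q_P_Sto = 0,
                   check = TRUE) {
  if (any(mu < 0)) abort_domain("`mu` must be >= 0")
  if (check) .check_mu_feasible(mu, I, params, ratios)
  co <- pc_coefficients(I, params, ratios, Q_P_Sto = Q_P_Sto)
  co$a * mu^2 + co$b * mu + co$c
}

#' @rdname n_to_c
#' @export
n_to_p <- function(mu, I, params, ratios = default_ratios(),
                   Q_N_Sto = 0, Q_P_Sto = 0, check = TRUE) {
  pc <- p_to_c(mu, I, params, ratios, Q_P_Sto = Q_P_Sto, check = check)
  if (any(pc <= 0)) abort_domain("P:C is zero; N:P undefined")
  n_to_c(mu, I, params, ratios, Q_N_Sto = Q_N_Sto, check = FALSE) / pc
}

# ---- diagnostic approximations -----------------------------------------

#' Approximate linear N:C (protein-only nitrogen)
#'
#' Diagnostic form keeping only the protein contribution to nitrogen:
#' `N:C ~ Y_Pro_NC * ((A_Chl A_Pho + A_Bio) mu + (B_Chl A_Pho +
#' Q_C_Pro_Other))`. It differs from the full form only by the RNA,
#' chlorophyll, and DNA nitrogen terms.
#'
#' @inheritParams n_to_c
#' @return Approximate N:C ratio(s).
#' @export
n_to_c_linear <- function(mu, I, params, ratios = default_ratios()) {
  cf <- chl_coefficients(I, params)
  ratios$Y_Pro_NC * ((cf$A_Chl * params$A_Pho + params$A_Bio) * mu +
                       (cf$B_Chl * params$A_Pho + params$Q_C_Pro_Other))
}

#' Approximate maximum growth rate ignoring RNA and thylakoid-lipid carbon
#'
#' Diagnostic linear solution of the carbon budget when the (small) RNA
#' carbon and thylakoid phospholipid carbon pools are neglected:
#' `mu ~ ((1 - Q_C_Other - Q_C_Csto) v_I - A_Pho m) / (A_Bio v_I +
#' A_Pho (1 + E))`. Agrees with the quadratic root when those pools are
#' zeroed in the parameter set.
#'
#' @inheritParams mu_max
#' @param Q_C_Csto Carbon storage quota held fixed (0 at maximum growth).
#' @return Approximate growth rate(s), d^-1.
#' @export
mu_max_approx <- function(I, params, ratios = default_ratios(), Q_C_Csto = 0) {
  v_I <- photosynthesis_rate(I, params)
  Q_C_Other <- params$Q_C_Pro_Other + params$Q_C_DNA + params$Q_C_Other0
  ((1 - Q_C_Other - Q_C_Csto) * v_I - params$A_Pho * params$m) /
    (params$A_Bio * v_I + params$A_Pho * (1 + params$E))
}

#' Export model curves over a (mu, I) grid
#'
#' Evaluates Chl:C, N:C, P:C, and N:P over the outer grid of the supplied
#' growth rates and irradiances (zero storage). Rows with `mu > mu_max(I)`
#' are flagged `infeasible` and carry `NA` ratios rather than being
#' dropped.
#'
#' @param mu,I Numeric vectors defining the grid.
#' @inheritParams mu_max
#' @return A tibble with columns `mu`, `I`, `mu_max`, `infeasible`,
#'   `chl_to_c`, `n_to_c`, `p_to_c`, `n_to_p`.
#' @export
model_curves <- function(mu, I, params, ratios = default_ratios()) {
  grid <- expand.grid(mu = mu, I = I, KEEP.OUT.ATTRS = FALSE)
  mm <- mu_max(grid$I, params, ratios)
  ok <- grid$mu <= mm
  out <- tibble::tibble(
    mu = grid$mu, I = grid$I, mu_max = mm, infeasible = !ok,
    chl_to_c = NA_real_, n_to_c = NA_real_, p_to_c = NA_real_,
    n_to_p = NA_real_
  )
  if (any(ok)) {
    out$chl_to_c[ok] <- chl_to_c(grid$mu[ok], grid$I[ok], params)
    out$n_to_c[ok] <- n_to_c(grid$mu[ok], grid$I[ok], params, ratios, check = FALSE)
    out$p_to_c[ok] <- p_to_c(grid$mu[ok], grid$I[ok], params, ratios, check = FALSE)
    out$n_to_p[ok] <- out$n_to_c[ok] / out$p_to_c[ok]
  }
  out
}
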