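# Synthetic chemostat datasets.
#
# Emulates the classic design of dilution-gradient chemostat studies:
# several acclimation light levels, a grid of dilution rates per light
# level, one feed recipe chosen to impose N limitation and one to impose
# P limitation, and the nutrient-replete maximum growth rate read off per
# light level. Vessels diluted faster than the light-limited maximum wash
# out and are omitted, as published dilution series only report vessels
# where the limiting nutrient was fully consumed.

#' Experimental design for the synthetic generator
#'
#' Defaults describe a realistic low-to-moderate light design for a
#' freshwater cyanobacterium: four light levels spanning strongly
#' light-limited to near-saturating, dilution rates from 0.1 to 1.5 d^-1,
#' a feed with N:P = 10 (N-limiting; required N:P is ~14-27) and one with
#' N:P = 40 (P-limiting), and 5% relative measurement noise on every
#' observable.
#'
#' @param light_levels Irradiances (umol photons m^-2 s^-1).
#' @param dilution_grid Dilution rates (d^-1), applied at every light
#'   level; rows above the light-limited maximum wash out.
#' @param feeds Named list of scenarios, each a list with `N_in`, `P_in`
#'   (mol m^-3).
#' @param noise_sd Named relative (multiplicative) noise standard
#'   deviations per variable; names among `chl_to_c`, `n_to_c`, `p_to_c`,
#'   `biomass`, `mu_max`. A single unnamed number applies to all.
#' @param replicates Replicate observations per condition.
#' @param seed Integer seed driving all noise.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(light_levels = c(15, 40, 120, 300),
                        dilution_grid = seq(0.1, 1.5, by = 0.2),
                        feeds = list(
                          nlim = list(N_in = 0.25, P_in = 0.025),
                          plim = list(N_in = 0.40, P_in = 0.010)
                        ),
                        noise_sd = 0.05,
                        replicates = 1L,
                        seed = 1L) {
  vars <- c("chl_to_c", "n_to_c", "p_to_c", "biomass", "mu_max")
  if (is.null(names(noise_sd))) {
    noise_sd <- stats::setNames(rep(noise_sd[[1]], length(vars)), vars)
  } else {
    full <- stats::setNames(rep(0, length(vars)), vars)
    full[names(noise_sd)] <- noise_sd
    noise_sd <- full
  }
  if (any(dilution_grid <= 0)) abort_domain("dilution rates must be positive")
  if (any(noise_sd < 0)) abort_domain("noise_sd must be >= 0")
  if (replicates < 1) abort_domain("replicates must be >= 1")
  structure(list(light_levels = light_levels, dilution_grid = dilution_grid,
                 feeds = feeds, noise_sd = noise_sd,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "design_spec")
}

# Multiplicative Gaussian noise on the relative scale, truncated at zero
# by redrawing (all observables are positive ratios or concentrations).
.noisy <- function(truth, rel_sd) {
  if (rel_sd == 0) return(truth)
  out <- truth * (1 + stats::rnorm(length(truth), 0, rel_sd))
  bad <- out <= 0
  while (any(bad)) {
    out[bad] <- truth[bad] * (1 + stats::rnorm(sum(bad), 0, rel_sd))
    bad <- out <= 0
  }
  out
}

#' Generate a synthetic chemostat dataset from known parameters
#'
#' Runs the forward model over the design, applies multiplicative Gaussian
#' observation noise, and packages the rows in the observation schema the
#' fitter consumes. Datasets are grouped per (scenario, variable, light
#' level) -- the granularity at which a lab reports one curve -- except
#' the maximum-growth-rate datasets, which span light levels. Each
#' dataset carries the generator's error scale `sigma`: the noise sd times
#' the dataset's mean true value. For noiseless designs a vanishingly
#' small relative scale (1e-6) stands in so the error function stays
#' finite; the Metropolis-Hastings acceptance rule then reduces to strict
#' descent, which is the intended behavior when the data carry no noise.
#'
#' @param true_params A [model_params()] object (the ground truth).
#' @param design A [design_spec()].
#' @param ratios A [stoich_ratios()] object.
#' @param keep_truth Keep a `value_true` column (useful in tests).
#' @return A tibble with columns `dataset_id`, `scenario`, `variable`,
#'   `light`, `mu`, `value`, `limitation`, `N_in`, `P_in`, `sigma`,
#'   and optionally `value_true`. `mu` is `NA` for `mu_max` rows.
#' @export
generate_dataset <- function(true_params, design = design_spec(),
                             ratios = default_ratios(), keep_truth = FALSE) {
  set.seed(design$seed)
  rows <- list()
  for (scen in names(design$feeds)) {
    feed <- design$feeds[[scen]]
    envs <- expand.grid(D = design$dilution_grid, I = design$light_levels,
                        KEEP.OUT.ATTRS = FALSE)
    envs$N_in <- feed$N_in
    envs$P_in <- feed$P_in
    sim <- simulate_chemostat(envs, true_params, ratios)
    sim <- sim[!sim$washout, , drop = FALSE]
    for (v in c("chl_to_c", "n_to_c", "p_to_c", "biomass")) {
      for (rep_i in seq_len(design$replicates)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          dataset_id = sprintf("%s_%s_I%g", scen, v, sim$I),
          scenario = scen, variable = v, light = sim$I, mu = sim$D,
          value_true = sim[[v]], limitation = sim$limitation,
          N_in = feed$N_in, P_in = feed$P_in
        )
      }
    }
    mm <- mu_max(design$light_levels, true_params, ratios)
    # label the mu_max dataset with the limitation this feed imposes
    scen_lim <- names(which.max(table(sim$limitation)))
    for (rep_i in seq_len(design$replicates)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        dataset_id = sprintf("%s_mu_max", scen),
        scenario = scen, variable = "mu_max", light = design$light_levels,
        mu = NA_real_, value_true = mm, limitation = scen_lim,
        N_in = feed$N_in, P_in = feed$P_in
      )
    }
  }
  out <- do.call(rbind, rows)
  sds <- design$noise_sd[out$variable]
  # draw noise row-wise in a fixed order for reproducibility
  out$value <- vapply(seq_len(nrow(out)),
                      function(i) .noisy(out$value_true[i], sds[[i]]), 0)
  # per-dataset error scale, in value units
  ds_mean <- tapply(abs(out$value_true), out$dataset_id, mean)
  rel <- pmax(design$noise_sd[out$variable], 1e-6)
  out$sigma <- unname(rel * ds_mean[out$dataset_id])
  if (!keep_truth) out$value_true <- NULL
  tibble::as_tibble(out)
}

#' Per-dataset observation counts
#'
#' @param data A dataset in the observation schema.
#' @return Named integer vector of row counts per `dataset_id`.
#' @export
dataset_counts <- function(data) {
  tab <- table(data$dataset_id)
  stats::setNames(as.integer(tab), names(tab))
}
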