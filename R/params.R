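# Forward-model parameterization.
#
# Units convention, package-wide: rates d^-1, light umol photons m^-2 s^-1,
# all quotas mol per mol cellular C.

# The 11 parameters calibrated from data, in the order the staged fit
# estimates them. E and the remaining pools are fixed configuration.
FITTED_PARAM_NAMES <- c(
  "m", "v_I_max", "A_I",                                    # stage 1
  "A_Pho", "A_Bio", "Q_C_Pro_Other", "Q_N_Sto_max", "Q_C_Other0", # stage 2
  "A_RNA_P", "A_Pho_PChl", "Q_P_Other0"                     # stage 3
)

#' Construct a forward-model parameter set
#'
#' Defaults are the packaged "default organism": a synthetic, order-of-
#' magnitude-plausible parameterization of a freshwater cyanobacterium,
#' used as the ground truth in tests and examples. It is not a fit to any
#' published data set.
#'
#' @param m Maintenance respiration rate (d^-1).
#' @param v_I_max Maximum photosynthesis rate per chlorophyll carbon
#'   (mol C (mol Chl C)^-1 d^-1).
#' @param A_I Light-saturation coefficient ((umol photons m^-2 s^-1)^-1).
#' @param E Respiratory cost of synthesis (mol C respired per mol C
#'   synthesized), dimensionless. The default is derived by
#'   electron-equivalent bookkeeping for biomass C5H7O2NP(1/30) grown on
#'   nitrate at energy transfer efficiency 0.6; see
#'   `system.file("scripts", "derive_respiratory_cost.R", package = "phytoalloc")`.
#' @param A_Pho Photosynthetic protein C per chlorophyll C (dimensionless).
#' @param A_Bio Biosynthetic protein C per unit growth rate (d).
#' @param Q_C_Pro_Other Constant "essential" protein pool (mol C (mol C)^-1).
#' @param A_RNA_P RNA phosphorus per (protein C x growth rate)
#'   (mol P (mol C)^-1 d).
#' @param Q_P_min_RNA Minimum RNA phosphorus at zero growth
#'   (mol P (mol C)^-1).
#' @param A_Pho_PChl Thylakoid phospholipid P per chlorophyll C
#'   (mol P (mol Chl C)^-1).
#' @param Q_P_Other0 Constant other-phosphorus pool (mol P (mol C)^-1).
#' @param Q_C_DNA DNA carbon pool (mol C (mol C)^-1).
#' @param Q_C_Other0 Constant essential carbohydrate + lipid pool
#'   (mol C (mol C)^-1).
#' @param Q_N_Sto_max Maximum nitrogen storage (mol N (mol C)^-1); caps the
#'   storage component only.
#' @param Q_P_max Maximum total phosphorus quota (mol P (mol C)^-1); caps
#'   the whole P quota, storage included.
#' @return An object of class `model_params` (named list).
#' @examples
#' p <- model_params()
#' mu_max(100, p, default_ratios())
#' @export
model_params <- function(m = 0.1,
                         v_I_max = 100,
                         A_I = 0.015,
                         E = 0.936,
                         A_Pho = 4,
                         A_Bio = 0.15,
                         Q_C_Pro_Other = 0.2,
                         A_RNA_P = 0.012,
                         Q_P_min_RNA = 5e-4,
                         A_Pho_PChl = 0.03,
                         Q_P_Other0 = 5e-4,
                         Q_C_DNA = 0.01,
                         Q_C_Other0 = 0.25,
                         Q_N_Sto_max = 0.03,
                         Q_P_max = 0.015) {
  p <- list(
    m = m, v_I_max = v_I_max, A_I = A_I, E = E,
    A_Pho = A_Pho, A_Bio = A_Bio, Q_C_Pro_Other = Q_C_Pro_Other,
    A_RNA_P = A_RNA_P, Q_P_min_RNA = Q_P_min_RNA,
    A_Pho_PChl = A_Pho_PChl, Q_P_Other0 = Q_P_Other0,
    Q_C_DNA = Q_C_DNA, Q_C_Other0 = Q_C_Other0,
    Q_N_Sto_max = Q_N_Sto_max, Q_P_max = Q_P_max
  )
  validate_params(p)
  structure(p, class = "model_params")
}

#' @keywords internal
validate_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), TRUE)
  if (!all(num)) {
    abort_domain(paste0("non-finite or non-scalar parameter(s): ",
                        paste(names(p)[!num], collapse = ", ")))
  }
  vals <- unlist(p)
  if (any(vals < 0)) {
    abort_domain(paste0("negative parameter(s): ",
                        paste(names(vals)[vals < 0], collapse = ", ")))
  }
  if (p$v_I_max <= 0) abort_domain("`v_I_max` must be > 0")
  if (p$A_I <= 0) abort_domain("`A_I` must be > 0")
  fixed_c <- p$Q_C_Pro_Other + p$Q_C_DNA + p$Q_C_Other0
  if (fixed_c >= 1) {
    abort_domain(sprintf(
      "fixed carbon pools sum to %.3f; must be < 1 (they cannot exceed the cell)",
      fixed_c))
  }
  invisible(p)
}

#' Update a parameter set
#'
#' Replaces named fields of a `model_params` object and revalidates.
#'
#' @param params A [model_params()] object.
#' @param ... Named scalar replacements, e.g. `A_Bio = 0.2`.
#' @return A new `model_params` object.
#' @export
update_params <- function(params, ...) {
  repl <- list(...)
  unknown <- setdiff(names(repl), names(params))
  if (length(unknown)) {
    abort_domain(paste0("unknown parameter(s): ", paste(unknown, collapse = ", ")))
  }
  params[names(repl)] <- repl
  validate_params(params)
  structure(params, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Forward-model parameters (rates d^-1, quotas mol:mol C)\n")
  for (nm in names(x)) cat(sprintf("  %-14s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' Read and write parameter sets as flat JSON or YAML
#'
#' Parameter files are flat mappings keyed by the field names of
#' [model_params()]. Missing keys take the package defaults, so partial
#' files (e.g. only the fitted parameters) are accepted.
#'
#' @param path File path; format chosen by extension (`.json`, `.yml`,
#'   `.yaml`).
#' @param params A `model_params` object (for writing).
#' @return `read_model_params()` returns a `model_params` object;
#'   `write_model_params()` returns `path` invisibly.
#' @export
read_model_params <- function(path) {
  if (!file.exists(path)) abort_domain(paste0("parameter file not found: ", path))
  vals <- read_config_file(path)
  unknown <- setdiff(names(vals), names(formals(model_params)))
  if (length(unknown)) {
    abort_domain(paste0("unknown parameter key(s) in ", path, ": ",
                        paste(unknown, collapse = ", ")))
  }
  do.call(model_params, lapply(vals, as.numeric))
}

#' @rdname read_model_params
#' @export
write_model_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Shared config reader: JSON or YAML by extension.
read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort_domain("reading YAML config requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
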