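# Typed conditions. Downstream code (the fitter in particular) needs to tell
# "this parameter set cannot grow here" apart from programming errors, so all
# model-domain failures carry a subclass of "phytoalloc_error".

abort_phytoalloc <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "phytoalloc_error"), ...)
}

#' @keywords internal
abort_washout <- function(D, mu_max) {
  abort_phytoalloc(
    sprintf("washout: dilution rate D = %.4g d^-1 exceeds mu_max = %.4g d^-1", D, mu_max),
    class = "phytoalloc_washout_error",
    D = D, mu_max = mu_max
  )
}

abort_infeasible <- function(message, ...) {
  abort_phytoalloc(message, class = "phytoalloc_infeasible_error", ...)
}

abort_domain <- function(message, ...) {
  abort_phytoalloc(message, class = "phytoalloc_domain_error", ...)
}

#' Test whether a condition is a model-domain failure
#'
#' Returns `TRUE` for conditions raised by the model itself (washout,
#' infeasible allocation, bad domain), as opposed to ordinary R errors.
#'
#' @param cnd A condition object.
#' @return Logical scalar.
#' @export
is_phytoalloc_error <- function(cnd) inherits(cnd, "phytoalloc_error")
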