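#' Kinetic parameters for CELIA circuits
#'
#' Lumped phenomenological rate constants for the PEN-toolbox reaction
#' modules. Each template's polymerase/nickase cycle is collapsed into a
#' single production term (saturating in the loading strand, first order in
#' template); enzymes are not explicit species. All concentrations are in nM
#' and all times in minutes.
#'
#' @param r_exp Net exponential growth rate of the trigger strand alpha at
#'   low alpha (min^-1). The default 0.017 corresponds to about 135 min of
#'   amplification-time shift per decade of input (ln(10)/r_exp).
#' @param K_exp Half-saturation constant of amplification-template occupancy
#'   (nM). Together with `k_deg` it sets the alpha plateau,
#'   `K_exp * ((r_exp + k_deg)/k_deg - 1)` (about 100 nM at defaults).
#' @param k_deact Pseudotemplate-mediated deactivation rate constant
#'   (per nM pseudotemplate per min); used for both pTalpha on alpha and
#'   pTbeta on beta.
#' @param k_deg First-order exonuclease degradation rate of unprotected
#'   signal strands (min^-1).
#' @param k_act Loading rate of alpha onto the alpha-to-omega template
#'   (per nM per min); activation is irreversible (type IIS nicking design).
#'   The template hybridizes only a few bases of alpha, so loading is slow:
#'   the default 0.0025 places the activation onset (`alpha ~ r_exp/k_act`)
#'   at the alpha detection threshold, making the downstream linear stage
#'   kick in quasi-instantaneously at the amplification time with a small
#'   constant onset delay.
#' @param k_lin Omega throughput per nM of activated alpha-to-omega template
#'   (and per beta-occupied beta-to-omega template), min^-1. Sets the linear
#'   amplification gain, `k_lin * [template]`.
#' @param k_rep Irreversible omega reporting rate constant (per nM per min);
#'   reporting consumes omega and one intact reporter.
#' @param K_r Half-saturation constant of the quasi-equilibrium alpha
#'   reporter (nM).
#' @param K_beta Half-constant of reversible beta occupancy on beta-to-omega
#'   (nM).
#' @param k_kill pTbeta production rate per nM killer template at saturating
#'   alpha (min^-1).
#' @param leak_kill Alpha-independent (leak) pTbeta production per nM killer
#'   template (min^-1).
#' @param k_degP Degradation rate of the degradable pseudotemplate pTbeta
#'   (min^-1).
#' @param k_conv Alpha production per nM converter template at saturating
#'   microRNA (min^-1).
#' @param K_conv Converter half-saturation constant (nM).
#' @param s_F Fluorescence scale, signal units per nM of reacted (or bound)
#'   reporter.
#'
#' @return An object of class `celia_params` (named list).
#' @export
#' @examples
#' p <- celia_params()
#' p$r_exp
celia_params <- function(r_exp = 0.017,
                         K_exp = 60,
                         k_deact = 0.005,
                         k_deg = 0.01,
                         k_act = 0.0025,
                         k_lin = 0.05,
                         k_rep = 0.1,
                         K_r = 10,
                         K_beta = 5,
                         k_kill = 0.2,
                         leak_kill = 1e-3,
                         k_degP = 0.02,
                         k_conv = 1e-3,
                         K_conv = 1,
                         s_F = 1) {
  p <- list(r_exp = r_exp, K_exp = K_exp, k_deact = k_deact, k_deg = k_deg,
            k_act = k_act, k_lin = k_lin, k_rep = k_rep, K_r = K_r,
            K_beta = K_beta, k_kill = k_kill, leak_kill = leak_kill,
            k_degP = k_degP, k_conv = k_conv, K_conv = K_conv, s_F = s_F)
  for (nm in names(p)) {
    v <- p[[nm]]
    lo_ok <- if (nm == "leak_kill") v >= 0 else v > 0  # leak may be absent
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || !lo_ok)
      stop("celia_params: '", nm, "' must be a single strictly positive number",
           call. = FALSE)
  }
  class(p) <- "celia_params"
  p
}

#' @export
print.celia_params <- function(x, ...) {
  cat("CELIA kinetic parameters (nM, min):\n")
  print(unlist(unclass(x)))
  invisible(x)
}

# merge user overrides (named list) into defaults, rejecting unknown names
update_params <- function(params = NULL, overrides = NULL) {
  if (is.null(params)) params <- celia_params()
  if (is.null(overrides) || length(overrides) == 0L) return(params)
  bad <- setdiff(names(overrides), names(unclass(params)))
  if (length(bad))
    stop("unknown kinetic parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  args <- utils::modifyList(unclass(params), overrides)
  do.call(celia_params, args)
}

check_conc <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop("'", field, "' must be a single non-negative concentration",
         call. = FALSE)
  invisible(x)
}
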