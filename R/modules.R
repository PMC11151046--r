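#' Exponential amplification switch (EXPAR-like module)
#'
#' Builds the autocatalytic trigger-amplification module: a dual-repeat
#' amplification template encodes exponential replication of the signal
#' strand alpha through polymerization/nicking cycles; a pseudotemplate
#' deactivates alpha (alpha -> alpha_i) by directing a short extension; an
#' exonuclease degrades free alpha; a quenched hairpin reporter probes alpha
#' in the `"alpha"` channel via fast quasi-equilibrium hybridization.
#'
#' The gross autocatalytic production rate is
#' `(r_exp + k_deg) * K_exp * alpha/(K_exp + alpha)`, so the *net* low-alpha
#' growth rate is exactly `r_exp` and production saturates as the template
#' pool fills. The amplification template gates the reaction structurally:
#' with `aT_alpha_conc = 0` no production reaction is present.
#'
#' @param aT_alpha_conc Amplification template concentration (nM).
#' @param pT_alpha_conc Pseudotemplate (threshold/inhibitor) concentration
#'   (nM); treated as protected (non-degradable).
#' @param rT_alpha_conc Alpha reporter total (nM).
#' @param alpha0 Initial free alpha (nM).
#' @param params [celia_params()].
#' @return A [celia_network()].
#' @export
build_exponential_module <- function(aT_alpha_conc, pT_alpha_conc,
                                     rT_alpha_conc, alpha0,
                                     params = celia_params()) {
  check_conc(aT_alpha_conc, "aT_alpha_conc")
  check_conc(pT_alpha_conc, "pT_alpha_conc")
  check_conc(rT_alpha_conc, "rT_alpha_conc")
  check_conc(alpha0, "alpha0")
  sp <- rbind(
    celia_species("alpha", "signal-strand", alpha0),
    celia_species("alpha_i", "inert", 0),
    celia_species("aT_alpha", "template-state", aT_alpha_conc),
    celia_species("pT_alpha", "template-state", pT_alpha_conc))
  rx <- list()
  if (aT_alpha_conc > 0)
    rx <- c(rx, list(celia_reaction(
      "alpha_autocatalysis",
      products = c(alpha = 1), modifiers = "alpha",
      rate_constant = (params$r_exp + params$k_deg) * params$K_exp,
      form = "saturating", driver = "alpha",
      half_saturation = params$K_exp)))
  rx <- c(rx, list(
    celia_reaction("alpha_deactivation",
                   reactants = c(alpha = 1), products = c(alpha_i = 1),
                   modifiers = "pT_alpha", rate_constant = params$k_deact),
    celia_reaction("alpha_degradation",
                   reactants = c(alpha = 1), rate_constant = params$k_deg)))
  celia_network(
    sp, rx,
    reporters = list(alpha = list(type = "hyperbolic", driver = "alpha",
                                  total = rT_alpha_conc, K = params$K_r,
                                  s_F = params$s_F)),
    templates = list(
      list(kind = "aT_alpha", total = aT_alpha_conc, states = "aT_alpha"),
      list(kind = "pT_alpha", total = pT_alpha_conc, states = "pT_alpha")))
}

#' Linear amplification module
#'
#' The linear template takes alpha as input and, once irreversibly activated
#' (type IIS nicking design), constitutively produces the secondary strand
#' omega; omega reacts irreversibly with its reporter, so the `"omega"`
#' channel saturates at `s_F * rT_omega_conc` and the slope before
#' saturation (the gain) is `k_lin * [active template]`. Activation is
#' catalytic in alpha (no sequestration of the trigger).
#'
#' @param alpha_to_omega_conc Linear template concentration (nM).
#' @param rT_omega_conc Omega reporter total (nM).
#' @param params [celia_params()].
#' @param preactivated_frac Fraction of the template already active at t = 0
#'   (1 reproduces the preloaded-template characterization experiments).
#' @return A [celia_network()].
#' @export
build_linear_module <- function(alpha_to_omega_conc, rT_omega_conc,
                                params = celia_params(),
                                preactivated_frac = 0) {
  check_conc(alpha_to_omega_conc, "alpha_to_omega_conc")
  check_conc(rT_omega_conc, "rT_omega_conc")
  stopifnot(preactivated_frac >= 0, preactivated_frac <= 1)
  act0 <- preactivated_frac * alpha_to_omega_conc
  sp <- rbind(
    celia_species("alpha", "signal-strand", 0),
    celia_species("ato_inactive", "template-state",
                  alpha_to_omega_conc - act0),
    celia_species("ato_active", "template-state", act0),
    celia_species("omega", "signal-strand", 0),
    celia_species("rTo_intact", "reporter-state", rT_omega_conc),
    celia_species("rTo_reacted", "reporter-state", 0))
  rx <- list(
    celia_reaction("ato_activation",
                   reactants = c(ato_inactive = 1),
                   products = c(ato_active = 1),
                   modifiers = "alpha", rate_constant = params$k_act),
    celia_reaction("omega_production",
                   products = c(omega = 1), modifiers = "ato_active",
                   rate_constant = params$k_lin),
    celia_reaction("omega_reporting",
                   reactants = c(omega = 1, rTo_intact = 1),
                   products = c(rTo_reacted = 1),
                   rate_constant = params$k_rep),
    celia_reaction("omega_degradation",
                   reactants = c(omega = 1), rate_constant = params$k_deg))
  celia_network(
    sp, rx,
    reporters = list(omega = list(type = "species", species = "rTo_reacted",
                                  s_F = params$s_F)),
    templates = list(
      list(kind = "alpha_to_omega", total = alpha_to_omega_conc,
           states = c("ato_inactive", "ato_active")),
      list(kind = "rT_omega", total = rT_omega_conc,
           states = c("rTo_intact", "rTo_reacted"))))
}

#' Inverter (NOT gate) module
#'
#' A constitutive linear amplifier driven by beta (reversible occupancy of
#' the beta-to-omega template, quasi-equilibrium with half-constant
#' `K_beta`) produces omega from the start of the incubation. Alpha
#' amplification triggers, via the killer template, production of the
#' degradable pseudotemplate pTbeta which deactivates beta
#' (beta -> beta_i), stopping omega production: the sooner the exponential
#' amplification, the lower the endpoint omega signal. The killer template
#' also leaks pTbeta at a small alpha-independent rate.
#'
#' @param beta_to_omega_conc Constitutive linear template concentration (nM).
#' @param beta0 Initial beta strand concentration (nM).
#' @param alpha_k_beta_conc Killer template concentration (nM).
#' @param rT_omega_conc Omega reporter total (nM).
#' @param params [celia_params()].
#' @return A [celia_network()].
#' @export
build_inverter_module <- function(beta_to_omega_conc, beta0,
                                  alpha_k_beta_conc, rT_omega_conc,
                                  params = celia_params()) {
  check_conc(beta_to_omega_conc, "beta_to_omega_conc")
  check_conc(beta0, "beta0")
  check_conc(alpha_k_beta_conc, "alpha_k_beta_conc")
  check_conc(rT_omega_conc, "rT_omega_conc")
  sp <- rbind(
    celia_species("alpha", "signal-strand", 0),
    celia_species("beta", "signal-strand", beta0),
    celia_species("beta_i", "inert", 0),
    celia_species("pT_beta", "template-state", 0),
    celia_species("bto", "template-state", beta_to_omega_conc),
    celia_species("akb", "template-state", alpha_k_beta_conc),
    celia_species("omega", "signal-strand", 0),
    celia_species("rTo_intact", "reporter-state", rT_omega_conc),
    celia_species("rTo_reacted", "reporter-state", 0))
  rx <- list(
    celia_reaction("omega_constitutive_production",
                   products = c(omega = 1), modifiers = c("bto", "beta"),
                   rate_constant = params$k_lin,
                   form = "saturating", driver = "beta",
                   half_saturation = params$K_beta),
    celia_reaction("ptbeta_production",
                   products = c(pT_beta = 1), modifiers = c("akb", "alpha"),
                   rate_constant = params$k_kill,
                   form = "saturating", driver = "alpha",
                   half_saturation = params$K_exp),
    celia_reaction("beta_deactivation",
                   reactants = c(beta = 1), products = c(beta_i = 1),
                   modifiers = "pT_beta", rate_constant = params$k_deact),
    celia_reaction("ptbeta_degradation",
                   reactants = c(pT_beta = 1),
                   rate_constant = params$k_degP),
    celia_reaction("omega_reporting",
                   reactants = c(omega = 1, rTo_intact = 1),
                   products = c(rTo_reacted = 1),
                   rate_constant = params$k_rep),
    celia_reaction("omega_degradation",
                   reactants = c(omega = 1), rate_constant = params$k_deg))
  if (params$leak_kill > 0)
    rx <- c(rx, list(celia_reaction(
      "ptbeta_leak", products = c(pT_beta = 1), modifiers = "akb",
      rate_constant = params$leak_kill)))
  celia_network(
    sp, rx,
    reporters = list(omega = list(type = "species", species = "rTo_reacted",
                                  s_F = params$s_F)),
    templates = list(
      list(kind = "beta_to_omega", total = beta_to_omega_conc,
           states = "bto"),
      list(kind = "alpha_k_beta", total = alpha_k_beta_conc,
           states = "akb"),
      list(kind = "rT_omega", total = rT_omega_conc,
           states = c("rTo_intact", "rTo_reacted"))))
}

#' MicroRNA-to-trigger converter module
#'
#' A converter template transduces the presence of an input microRNA into a
#' constitutive source of alpha strands at rate
#' `k_conv * [converter] * miR/(K_conv + miR)`. The microRNA acts as a
#' recycled catalyst (modifier, unconsumed). Converter templates for
#' different microRNAs differ only by label.
#'
#' @param miR_to_alpha_conc Converter template concentration (nM).
#' @param miR_molar MicroRNA target concentration (M).
#' @param params [celia_params()].
#' @return A [celia_network()].
#' @export
build_converter <- function(miR_to_alpha_conc, miR_molar,
                            params = celia_params()) {
  check_conc(miR_to_alpha_conc, "miR_to_alpha_conc")
  check_conc(miR_molar, "miR_molar")
  sp <- rbind(
    celia_species("alpha", "signal-strand", 0),
    celia_species("miR", "signal-strand", miR_molar * 1e9),
    celia_species("mta", "template-state", miR_to_alpha_conc))
  rx <- list(celia_reaction(
    "alpha_conversion",
    products = c(alpha = 1), modifiers = c("mta", "miR"),
    rate_constant = params$k_conv,
    form = "saturating", driver = "miR",
    half_saturation = params$K_conv))
  celia_network(
    sp, rx,
    templates = list(list(kind = "miR_to_alpha", total = miR_to_alpha_conc,
                          states = "mta")))
}

# shipped default template concentrations (nM)
default_templates <- function() {
  list(aT_alpha = 20, pT_alpha = 0, rT_alpha = 50,
       alpha_to_omega = 2, rT_omega = 200,
       beta_to_omega = 2, alpha_k_beta = 2, beta0 = 50,
       miR_to_alpha = 10)
}

#' Assemble a full CELIA circuit
#'
#' Convenience wrapper composing the module builders into the three circuit
#' architectures studied by the package:
#' \describe{
#'   \item{`"coupled"`}{exponential switch + downstream linear amplifier
#'     (negative endpoint-vs-At correlation);}
#'   \item{`"inverter"`}{exponential switch + inverter (positive
#'     correlation);}
#'   \item{`"assay"`}{microRNA converter + exponential switch + linear
#'     amplifier — the endpoint quantification circuit.}
#' }
#'
#' The `"assay"` circuit includes a small background initiator
#' (`alpha0 = 1e-5` nM by default) modelling nonspecific priming, so blank
#' wells amplify late rather than never — the behaviour that makes a
#' blank-based limit of detection meaningful.
#'
#' @param type Circuit architecture.
#' @param target_molar MicroRNA target concentration (M; `"assay"` only).
#' @param alpha0 Initial free alpha (nM). Defaults: 0.01 for `"coupled"` and
#'   `"inverter"`, 1e-5 (background priming) for `"assay"`.
#' @param templates Named list overriding entries of the default template
#'   concentrations (see [build_exponential_module()] and friends):
#'   `aT_alpha`, `pT_alpha`, `rT_alpha`, `alpha_to_omega`, `rT_omega`,
#'   `beta_to_omega`, `alpha_k_beta`, `beta0`, `miR_to_alpha`.
#' @param params [celia_params()].
#' @return A [celia_network()].
#' @export
#' @examples
#' net <- celia_circuit("coupled", alpha0 = 0.1)
#' net
celia_circuit <- function(type = c("coupled", "inverter", "assay"),
                          target_molar = 0, alpha0 = NULL,
                          templates = list(), params = celia_params()) {
  type <- match.arg(type)
  tpl <- default_templates()
  bad <- setdiff(names(templates), names(tpl))
  if (length(bad))
    stop("unknown template key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  tpl <- utils::modifyList(tpl, templates)
  if (is.null(alpha0)) alpha0 <- if (type == "assay") 1e-5 else 0.01
  expo <- build_exponential_module(tpl$aT_alpha, tpl$pT_alpha, tpl$rT_alpha,
                                   alpha0, params)
  switch(type,
    coupled = compose_networks(
      expo, build_linear_module(tpl$alpha_to_omega, tpl$rT_omega, params)),
    inverter = compose_networks(
      expo, build_inverter_module(tpl$beta_to_omega, tpl$beta0,
                                  tpl$alpha_k_beta, tpl$rT_omega, params)),
    assay = compose_networks(
      build_converter(tpl$miR_to_alpha, target_molar, params),
      expo,
      build_linear_module(tpl$alpha_to_omega, tpl$rT_omega, params)))
}
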