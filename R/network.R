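#' Declare a chemical species
#'
#' @param name Species name (unique within a network).
#' @param role One of `"signal-strand"`, `"template-state"`,
#'   `"reporter-state"`, `"inert"`.
#' @param init Initial concentration (nM).
#' @return A one-row data.frame.
#' @export
celia_species <- function(name, role = c("signal-strand", "template-state",
                                         "reporter-state", "inert"),
                          init = 0) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_conc(init, paste0("init[", name, "]"))
  data.frame(name = name, role = role, init = init,
             stringsAsFactors = FALSE)
}

#' Declare a reaction with a mass-action or saturating rate law
#'
#' Rate laws: `mass-action` evaluates
#' `rate_constant * prod(conc(reactants)^stoich) * prod(conc(modifiers))`;
#' `saturating` replaces the driver's linear factor by a Michaelis-Menten
#' occupancy term, `rate_constant * driver/(half_saturation + driver) *
#' prod(conc(others))`, i.e. the rate in nM/min per unit of the remaining
#' factors. Modifiers are catalytic (unconsumed).
#'
#' @param name Reaction label (used in error messages).
#' @param reactants Named integer vector of consumed species (stoichiometry).
#' @param products Named integer vector of produced species.
#' @param modifiers Character vector of catalytic species.
#' @param rate_constant Strictly positive rate constant (units depend on the
#'   law's molecularity; min^-1 with nM concentrations).
#' @param form `"mass-action"` or `"saturating"`.
#' @param driver Species whose occupancy saturates (saturating form only).
#' @param half_saturation Half-saturation constant (nM, saturating form).
#' @return An object of class `celia_reaction`.
#' @export
celia_reaction <- function(name, reactants = NULL, products = NULL,
                           modifiers = character(),
                           rate_constant,
                           form = c("mass-action", "saturating"),
                           driver = NULL, half_saturation = NULL) {
  form <- match.arg(form)
  as_stoich <- function(x, what) {
    if (is.null(x) || length(x) == 0L) return(integer(0))
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("reaction '", name, "': ", what, " must be a named vector",
           call. = FALSE)
    if (any(x != round(x)) || any(x <= 0))
      stop("reaction '", name, "': stoichiometries must be positive integers",
           call. = FALSE)
    stats::setNames(as.integer(x), names(x))
  }
  reactants <- as_stoich(reactants, "reactants")
  products <- as_stoich(products, "products")
  if (!is.numeric(rate_constant) || rate_constant <= 0)
    stop("reaction '", name, "': rate_constant must be > 0", call. = FALSE)
  if (length(intersect(names(reactants), modifiers)))
    stop("reaction '", name,
         "': a species cannot be both reactant and modifier", call. = FALSE)
  if (form == "saturating") {
    if (is.null(driver) || !driver %in% c(names(reactants), modifiers))
      stop("reaction '", name,
           "': saturating law needs a driver among reactants/modifiers",
           call. = FALSE)
    if (is.null(half_saturation) || half_saturation <= 0)
      stop("reaction '", name, "': half_saturation must be > 0",
           call. = FALSE)
  }
  structure(list(name = name, reactants = reactants, products = products,
                 modifiers = as.character(modifiers),
                 rate_constant = rate_constant, form = form,
                 driver = driver, half_saturation = half_saturation),
            class = "celia_reaction")
}

#' Assemble a reaction network
#'
#' @param species data.frame with columns `name`, `role`, `init` (rbind of
#'   [celia_species()] rows).
#' @param reactions List of [celia_reaction()] objects.
#' @param reporters Named list mapping channel name to a reporter
#'   description: either `list(type = "species", species = <reacted reporter
#'   species>, s_F = <signal per nM>)` for irreversible reporters, or
#'   `list(type = "hyperbolic", driver = <signal strand>, total = <reporter
#'   total nM>, K = <half constant>, s_F = ...)` for fast quasi-equilibrium
#'   hybridization probes.
#' @param templates List of template bookkeeping records,
#'   `list(kind =, total =, states = <species names>)`, used by conservation
#'   checks.
#' @return An object of class `celia_network`.
#' @export
celia_network <- function(species, reactions = list(), reporters = list(),
                          templates = list()) {
  stopifnot(is.data.frame(species),
            all(c("name", "role", "init") %in% names(species)))
  if (anyDuplicated(species$name))
    stop("species names must be unique within a network", call. = FALSE)
  if (any(species$init < 0))
    stop("initial concentrations must be >= 0", call. = FALSE)
  for (rx in reactions) {
    stopifnot(inherits(rx, "celia_reaction"))
    ref <- c(names(rx$reactants), names(rx$products), rx$modifiers)
    missing <- setdiff(ref, species$name)
    if (length(missing))
      stop("reaction '", rx$name, "' references unknown species: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(reporters)) {
    if (is.null(names(reporters)) || anyDuplicated(names(reporters)))
      stop("reporter channels must be uniquely named", call. = FALSE)
    for (ch in names(reporters)) {
      rp <- reporters[[ch]]
      sp <- if (identical(rp$type, "species")) rp$species else rp$driver
      if (!sp %in% species$name)
        stop("reporter channel '", ch, "' references unknown species '",
             sp, "'", call. = FALSE)
    }
  }
  for (tp in templates) {
    if (!all(tp$states %in% species$name))
      stop("template '", tp$kind, "' references unknown state species",
           call. = FALSE)
    tot0 <- sum(species$init[match(tp$states, species$name)])
    if (abs(tot0 - tp$total) > 1e-9 * max(1, tp$total))
      stop("template '", tp$kind,
           "' state concentrations do not sum to total_conc at t = 0",
           call. = FALSE)
  }
  structure(list(species = species, reactions = reactions,
                 reporters = reporters, templates = templates),
            class = "celia_network")
}

#' @export
print.celia_network <- function(x, ...) {
  cat("CELIA reaction network:", nrow(x$species), "species,",
      length(x$reactions), "reactions,",
      length(x$reporters), "reporter channel(s)\n")
  cat("species:", paste(x$species$name, collapse = ", "), "\n")
  if (length(x$reporters))
    cat("channels:", paste(names(x$reporters), collapse = ", "), "\n")
  invisible(x)
}

#' Compose reaction networks into one simulatable network
#'
#' Species shared between modules (matched by name) must agree in role;
#' their initial concentrations are summed. Reactions are concatenated,
#' reporter channels merged (duplicate channel names are an error) and
#' template records merged (identical state sets have their totals summed).
#'
#' @param ... `celia_network` objects (or a single list of them).
#' @return A `celia_network`.
#' @export
compose_networks <- function(...) {
  nets <- list(...)
  if (length(nets) == 1L && !inherits(nets[[1L]], "celia_network"))
    nets <- nets[[1L]]
  stopifnot(length(nets) >= 1L,
            all(vapply(nets, inherits, TRUE, "celia_network")))
  species <- nets[[1L]]$species
  reactions <- nets[[1L]]$reactions
  reporters <- nets[[1L]]$reporters
  templates <- nets[[1L]]$templates
  for (net in nets[-1L]) {
    for (i in seq_len(nrow(net$species))) {
      nm <- net$species$name[i]
      j <- match(nm, species$name)
      if (is.na(j)) {
        species <- rbind(species, net$species[i, ])
      } else {
        if (species$role[j] != net$species$role[i])
          stop("conflicting role for species '", nm, "' during composition",
               call. = FALSE)
        species$init[j] <- species$init[j] + net$species$init[i]
      }
    }
    reactions <- c(reactions, net$reactions)
    dup <- intersect(names(reporters), names(net$reporters))
    if (length(dup))
      stop("duplicate reporter channel(s): ", paste(dup, collapse = ", "),
           call. = FALSE)
    reporters <- c(reporters, net$reporters)
    for (tp in net$templates) {
      hit <- FALSE
      for (k in seq_along(templates)) {
        if (setequal(templates[[k]]$states, tp$states)) {
          templates[[k]]$total <- templates[[k]]$total + tp$total
          hit <- TRUE
          break
        }
      }
      if (!hit) templates <- c(templates, list(tp))
    }
  }
  rownames(species) <- NULL
  celia_network(species, reactions, reporters, templates)
}
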