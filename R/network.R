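#' Read a kinetic model configuration
#'
#' Loads a YAML model description with `compartments`, `species`, `parameters`,
#' `reactions`, optional `moieties`, and `solver` blocks. The packaged default
#' (`model_default.yaml` under `extdata`) describes the cytosolic H2O2
#' clearance network (peroxiredoxin/thioredoxin/thioredoxin reductase/
#' sulfiredoxin, glutathione peroxidase/glutathione/glutathione reductase,
#' catalase, free protein thiols, NADPH regeneration) together with the nine
#' beta-lapachone quinone-cycling reactions.
#'
#' @param path Path to a YAML config. Defaults to the packaged model.
#' @return A nested list suitable for [build_network()].
#' @export
read_model_config <- function(path = default_model_path()) {
  yaml::read_yaml(path)
}

#' @rdname read_model_config
#' @export
default_model_path <- function() {
  system.file("extdata", "model_default.yaml", package = "redoxcell",
              mustWork = TRUE)
}

rate_templates <- c("mass_action", "second_order_self",
                    "gradient_permeation", "unidirectional_permeation")

# The C right-hand side is used when the package DLL is loaded (installed
# package or load_all with compilation); the pure-R RHS is the fallback.
compiled_rhs_available <- function() {
  !inherits(tryCatch(getNativeSymbolInfo("rx_derivs", PACKAGE = "redoxcell"),
                     error = identity), "error")
}

#' Build a validated reaction network
#'
#' Assembles a compartmental mass-action reaction network from a configuration
#' list. Every reaction's rate constant must be present in the parameter
#' table, every species referenced by a rate law or stoichiometry must be
#' declared, and compartment volumes must be strictly positive. Permeation
#' rate terms are divided by the respective compartment volume of each species
#' they move.
#'
#' @param config A configuration list as returned by [read_model_config()].
#' @return An object of class `redox_network`.
#' @export
build_network <- function(config) {
  geom <- config$compartments
  for (fld in c("volume_extracellular", "volume_cytosol", "membrane_area_factor")) {
    v <- geom[[fld]]
    if (is.null(v) || !is.finite(v) || v <= 0)
      stop("configuration error: compartment geometry field '", fld,
           "' must be strictly positive", call. = FALSE)
  }

  sp <- do.call(rbind, lapply(config$species, function(s) {
    data.frame(name = s$name, compartment = s$compartment,
               initial = as.numeric(s$initial),
               clamped = isTRUE(s$clamped), stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(sp$name))
    stop("configuration error: duplicated species names", call. = FALSE)
  if (any(!sp$compartment %in% c("extracellular", "cytosol")))
    stop("configuration error: unknown compartment", call. = FALSE)
  if (any(sp$initial < 0))
    stop("configuration error: negative initial concentration", call. = FALSE)

  params <- unlist(config$parameters)

  for (rx in config$reactions) {
    if (!rx$template %in% rate_templates)
      stop("configuration error: unknown rate-law template '", rx$template,
           "' in reaction '", rx$name, "'", call. = FALSE)
    if (is.null(params[rx$k]) || is.na(params[rx$k]))
      stop("configuration error: missing parameter '", rx$k,
           "' required by reaction '", rx$name, "'", call. = FALSE)
    refd <- union(unlist(rx$species), names(rx$stoichiometry))
    bad <- setdiff(refd, sp$name)
    if (length(bad))
      stop("configuration error: unknown species ", paste(bad, collapse = ", "),
           " in reaction '", rx$name, "'", call. = FALSE)
    npart <- length(unlist(rx$species))
    if (rx$template == "second_order_self" && npart != 1)
      stop("configuration error: second_order_self needs one species", call. = FALSE)
    if (rx$template == "gradient_permeation" && npart != 2)
      stop("configuration error: gradient_permeation needs two species", call. = FALSE)
    if (rx$template == "unidirectional_permeation" && npart != 1)
      stop("configuration error: unidirectional_permeation needs one species", call. = FALSE)
  }

  net <- structure(list(
    species   = sp,
    reactions = config$reactions,
    geometry  = geom,
    params    = params,
    moieties  = config$moieties,
    solver    = solver_settings(config$solver)
  ), class = "redox_network")
  net$compiled <- compile_network(net)
  net
}

#' Solver settings
#'
#' Default settings follow the study conditions: 2 h of simulated time,
#' maximum step 1 s, absolute tolerance 1e-8, with a variable-order implicit
#' (stiff) integrator.
#'
#' @param x Optional list with `end_time`, `max_step`, `atol`, `rtol`.
#' @return A list of validated solver settings.
#' @export
solver_settings <- function(x = NULL) {
  s <- list(end_time = 7200, max_step = 1, atol = 1e-8, rtol = 1e-6)
  for (nm in names(x)) s[[nm]] <- as.numeric(x[[nm]])
  if (s$end_time <= 0) stop("end_time must be > 0", call. = FALSE)
  if (s$atol <= 0 || s$rtol <= 0 || s$max_step <= 0)
    stop("solver tolerances and max step must be > 0", call. = FALSE)
  s
}

# Precompute index structures so the ODE right-hand side is a handful of
# vectorized operations: rates as k * prod of up to three state entries
# (index n+1 is a constant 1), gradient permeation overwritten as a signed
# difference, then a dense stoichiometry matrix-vector product. Permeation
# columns carry the per-species volume division; clamped rows are zeroed.
compile_network <- function(net) {
  sp <- net$species
  n <- nrow(sp)
  m <- length(net$reactions)
  idx <- stats::setNames(seq_len(n), sp$name)
  vol <- ifelse(sp$compartment == "extracellular",
                net$geometry$volume_extracellular,
                net$geometry$volume_cytosol)
  A <- net$geometry$membrane_area_factor

  i1 <- i2 <- i3 <- rep(n + 1L, m)
  k <- numeric(m)
  S <- matrix(0, n, m, dimnames = list(sp$name, vapply(net$reactions, `[[`, "", "name")))
  gp <- integer(0); gout <- integer(0); gin <- integer(0)

  for (j in seq_len(m)) {
    rx <- net$reactions[[j]]
    kj <- unname(net$params[rx$k])
    parts <- idx[unlist(rx$species)]
    perm <- rx$template %in% c("gradient_permeation", "unidirectional_permeation")
    if (perm) kj <- kj * A
    k[j] <- kj
    if (rx$template == "gradient_permeation") {
      gp <- c(gp, j); gout <- c(gout, parts[[1]]); gin <- c(gin, parts[[2]])
    } else if (rx$template == "second_order_self") {
      i1[j] <- parts[[1]]; i2[j] <- parts[[1]]
    } else if (length(parts)) {
      if (length(parts) > 3) stop("more than three rate-law participants", call. = FALSE)
      slots <- c("i1", "i2", "i3")
      for (q in seq_along(parts)) assign(slots[q], `[<-`(get(slots[q]), j, parts[[q]]))
    }
    st <- unlist(rx$stoichiometry)
    for (s in names(st)) {
      S[s, j] <- S[s, j] + if (perm) st[[s]] / vol[idx[[s]]] else st[[s]]
    }
  }
  S[sp$clamped, ] <- 0
  list(n = n, m = m, idx = idx, vol = vol, k = k, i1 = i1, i2 = i2, i3 = i3,
       S = S, gp = gp, gout = gout, gin = gin)
}

#' Evaluate per-reaction rates at a state
#'
#' Mass-action rates are `k` times the product of participant concentrations,
#' superoxide dismutation is `k [S]^2`, gradient permeation is the signed
#' `k A ([out] - [in])`, and conjugate export is `k A [S]`; the per-volume
#' division of permeation terms is applied when rates are mapped onto species
#' derivatives, not here.
#'
#' @param network A `redox_network`.
#' @param state Named numeric vector covering all species (molar).
#' @return Named numeric vector of reaction rates.
#' @export
evaluate_rates <- function(network, state) {
  cm <- network$compiled
  y <- state[network$species$name]
  if (anyNA(y)) stop("state does not cover all species", call. = FALSE)
  if (min(y) < -network$solver$atol)
    stop("evaluation error: negative concentration beyond tolerance", call. = FALSE)
  ye <- c(unname(y), 1)
  v <- cm$k * ye[cm$i1] * ye[cm$i2] * ye[cm$i3]
  if (length(cm$gp)) v[cm$gp] <- cm$k[cm$gp] * (ye[cm$gout] - ye[cm$gin])
  stats::setNames(v, colnames(cm$S))
}

#' Assemble the derivative function of a network
#'
#' Returns `f(state)` computing `d[state]/dt` as the stoichiometry-weighted
#' sum of reaction rates, with permeation fluxes divided by each species'
#' compartment volume and clamped species held at zero derivative.
#'
#' @param network A `redox_network`.
#' @return A function mapping a named state vector to a named derivative vector.
#' @export
assemble_derivatives <- function(network) {
  cm <- network$compiled
  nm <- network$species$name
  function(state) {
    ye <- c(unname(state[nm]), 1)
    v <- cm$k * ye[cm$i1] * ye[cm$i2] * ye[cm$i3]
    if (length(cm$gp)) v[cm$gp] <- cm$k[cm$gp] * (ye[cm$gout] - ye[cm$gin])
    stats::setNames(as.vector(cm$S %*% v), nm)
  }
}

#' Initial state of a network
#'
#' @param network A `redox_network`.
#' @param dose Optional initial extracellular beta-lapachone concentration
#'   (molar) assigned to the `blap_ext` species.
#' @return Named numeric vector of initial concentrations.
#' @export
initial_state <- function(network, dose = NULL) {
  y0 <- stats::setNames(network$species$initial, network$species$name)
  if (!is.null(dose)) {
    if (!"blap_ext" %in% names(y0))
      stop("network has no 'blap_ext' species to dose", call. = FALSE)
    y0[["blap_ext"]] <- dose
  }
  y0
}

#' Simulate a reaction network
#'
#' Integrates the stiff ODE system with a variable-order implicit method
#' (`deSolve::ode`, `lsoda`), by default for 2 h with a maximum step of 1 s
#' and absolute tolerance 1e-8. A run is flagged `unstable` -- returned, not
#' raised -- when the solver fails, any concentration is NaN/Inf, or any
#' concentration falls below minus the absolute tolerance.
#'
#' @param network A `redox_network`.
#' @param state Named initial state; defaults to the network's initial values.
#' @param settings Solver settings (see [solver_settings()]).
#' @param n_out Number of output time points (evenly spaced).
#' @return A `redox_trajectory`: list with `times`, `conc` (time x species
#'   matrix), `status` (`"stable"` or `"unstable"`), and `message`.
#' @export
simulate_network <- function(network, state = initial_state(network),
                             settings = network$solver, n_out = 241) {
  settings <- solver_settings(settings)
  cm <- network$compiled
  nm <- network$species$name
  y0 <- unname(state[nm])
  if (anyNA(y0)) stop("initial state does not cover all species", call. = FALSE)
  if (min(y0) < 0) stop("initial state must be nonnegative", call. = FALSE)
  times <- seq(0, settings$end_time, length.out = max(2L, n_out))
  # capture.output silences the integrator's console chatter on runs that
  # stall and get flagged unstable below
  log <- utils::capture.output(
  out <- tryCatch(suppressWarnings(
    if (compiled_rhs_available()) {
      .Call("rx_set_network", list(
        as.numeric(cm$k), as.integer(cm$i1), as.integer(cm$i2),
        as.integer(cm$i3), cm$S, as.integer(cm$gp), as.integer(cm$gout),
        as.integer(cm$gin)), PACKAGE = "redoxcell")
      deSolve::ode(
        y = y0, times = times, func = "rx_derivs", parms = NULL,
        dllname = "redoxcell", initfunc = NULL, method = "lsoda",
        hmax = settings$max_step, atol = settings$atol, rtol = settings$rtol)
    } else {
      rhs <- function(t, y, p) {
        ye <- c(y, 1)
        v <- p$k * ye[p$i1] * ye[p$i2] * ye[p$i3]
        if (length(p$gp)) v[p$gp] <- p$k[p$gp] * (ye[p$gout] - ye[p$gin])
        list(p$S %*% v)
      }
      deSolve::ode(
        y = y0, times = times, func = rhs, parms = cm, method = "lsoda",
        hmax = settings$max_step, atol = settings$atol, rtol = settings$rtol)
    }), error = function(e) e))

  status <- "stable"; msg <- "ok"
  if (inherits(out, "error")) {
    return(structure(list(times = times, conc = NULL, status = "unstable",
                          message = conditionMessage(out)),
                     class = "redox_trajectory"))
  }
  istate <- attr(out, "istate")
  conc <- out[, -1, drop = FALSE]
  colnames(conc) <- nm
  if (!is.null(istate) && istate[1] < 0) {
    status <- "unstable"; msg <- "solver failure"
  } else if (nrow(out) < length(times) || anyNA(conc) || any(!is.finite(conc))) {
    status <- "unstable"; msg <- "non-finite concentrations"
  } else if (min(conc) < -settings$atol) {
    status <- "unstable"; msg <- "concentration below -abstol"
  }
  structure(list(times = out[, 1], conc = conc, status = status, message = msg),
            class = "redox_trajectory")
}

#' @export
print.redox_trajectory <- function(x, ...) {
  cat("<redox_trajectory> status:", x$status,
      if (!is.null(x$conc)) sprintf("(%d times x %d species)",
                                    nrow(x$conc), ncol(x$conc)), "\n")
  invisible(x)
}

#' Pre-equilibrate a network without drug
#'
#' Integrates the drug-free system over a long horizon (default 5e5 s) with
#' an unconstrained step size and returns the final state, which serves as
#' the resting initial condition for treatment simulations.
#'
#' @param network A `redox_network`.
#' @param time Equilibration horizon in seconds.
#' @return Named numeric state vector at the end of the horizon.
#' @export
equilibrate_network <- function(network, time = 5e5) {
  s <- network$solver
  s$end_time <- time
  s$max_step <- time
  y0 <- initial_state(network, dose = 0)
  tr <- simulate_network(network, y0, s, n_out = 11)
  if (tr$status != "stable")
    stop("equilibration failed: ", tr$message, call. = FALSE)
  st <- tr$conc[nrow(tr$conc), ]
  pmax(st, 0)
}

#' Volume-weighted moiety totals
#'
#' Computes conserved-moiety amounts (mol) as the sum over species of
#' moiety count x compartment volume x concentration, using the `moieties`
#' block of the model config (e.g. total beta-lapachone across all redox
#' forms and both compartments, total NADP(H), Trx, Prx, glutathione).
#'
#' @param network A `redox_network`.
#' @param state Named state vector, or a trajectory concentration matrix.
#' @return Named vector (or time x moiety matrix) of amounts in mol.
#' @export
moiety_totals <- function(network, state) {
  if (is.null(network$moieties)) stop("network declares no moieties", call. = FALSE)
  cm <- network$compiled
  W <- vapply(network$moieties, function(mo) {
    w <- numeric(cm$n)
    w[cm$idx[names(mo)]] <- unlist(mo)
    w * cm$vol
  }, numeric(cm$n))
  if (is.matrix(state)) state[, network$species$name, drop = FALSE] %*% W
  else as.vector(t(W) %*% unname(state[network$species$name])) |>
    stats::setNames(colnames(W))
}

#' Endpoint summary of a trajectory
#'
#' Extracts the four redox outputs at the final time point: cytosolic H2O2
#' (molar), NADPH:NADP+, Trx-SH:Trx-SS, and GSH:GSSG ratios.
#'
#' @param trajectory A `redox_trajectory`.
#' @return Named numeric vector `h2o2`, `nadph_ratio`, `trx_ratio`, `gsh_ratio`
#'   (all `NA` for unstable runs).
#' @export
endpoint_summary <- function(trajectory) {
  out <- c(h2o2 = NA_real_, nadph_ratio = NA_real_,
           trx_ratio = NA_real_, gsh_ratio = NA_real_)
  if (trajectory$status != "stable") return(out)
  fin <- trajectory$conc[nrow(trajectory$conc), ]
  c(h2o2 = unname(fin["H2O2"]),
    nadph_ratio = unname(fin["NADPH"] / fin["NADP"]),
    trx_ratio = unname(fin["TRX_SH"] / fin["TRX_SS"]),
    gsh_ratio = unname(fin["GSH"] / fin["GSSG"]))
}

#' Time-integrated concentration of one species
#'
#' Trapezoidal integral of a species concentration over the trajectory,
#' in molar x seconds.
#'
#' @param trajectory A stable `redox_trajectory`.
#' @param species Species name (default cytosolic H2O2).
#' @return Scalar integral.
#' @export
integrated_concentration <- function(trajectory, species = "H2O2") {
  stopifnot(trajectory$status == "stable")
  x <- trajectory$conc[, species]
  t <- trajectory$times
  sum(diff(t) * (utils::head(x, -1) + utils::tail(x, -1)) / 2)
}

#' Export a trajectory as a tidy table
#'
#' @param trajectory A stable `redox_trajectory`.
#' @param cell_id Identifier recorded in the `cell_id` column.
#' @param path Optional CSV path; when given the table is also written.
#' @return A data.frame with columns time, species, concentration, cell_id.
#' @export
trajectory_to_tidy <- function(trajectory, cell_id = NA_character_, path = NULL) {
  stopifnot(trajectory$status == "stable")
  df <- data.frame(
    time = rep(trajectory$times, times = ncol(trajectory$conc)),
    species = rep(colnames(trajectory$conc), each = nrow(trajectory$conc)),
    concentration = as.vector(trajectory$conc),
    cell_id = cell_id, stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
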