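## Nash-equilibrium engine: equilibrium initialization, perturbation,
## inner feedback loops, outer successive substitution on transport
## fluxes, convergence logging, iteration -> time mapping.

#' Default mM <-> pmol/cell conversion volume (litres per cell)
#'
#' Back-computed from paired published statements of an ATP change in
#' pmol/cell and in mM; exposed so other cell sizes can be configured.
#' @keywords internal
.VOLUME_BASIS <- 3.81e-14

#' Convert an amount in pmol/cell to a concentration in mM
#' @param amount_pmol amount, pmol/cell.
#' @param volume_basis cell water volume, litres (default 3.81e-14).
#' @return concentration in mM.
#' @export
amount_to_mM <- function(amount_pmol, volume_basis = .VOLUME_BASIS) {
  if (volume_basis <= 0) stop("volume_basis must be positive")
  amount_pmol * 1e-9 / volume_basis
}

#' Convert a concentration in mM to an amount in pmol/cell
#' @param conc_mM concentration, mM.
#' @inheritParams amount_to_mM
#' @return amount in pmol/cell.
#' @export
mM_to_amount <- function(conc_mM, volume_basis = .VOLUME_BASIS) {
  if (volume_basis <= 0) stop("volume_basis must be positive")
  conc_mM * volume_basis * 1e9
}

#' Scenario configuration
#'
#' Bundles the temperature, loop tolerances, iteration -> time mapping,
#' flush composition and unit conversion basis of one simulation
#' scenario.  Defaults follow the packaged study settings: outer
#' tolerance 1e-3 on the transport-flux 2-norm (mM scale), inner
#' feedback tolerance 1e-5, reference temperature 298.15 K.
#'
#' @param temp absolute temperature, K.
#' @param outer_tol outer-loop tolerance on the transport-flux 2-norm.
#' @param inner_tol inner feedback-loop tolerance (mM scale).
#' @param max_outer outer iteration cap.
#' @param time_per_iteration scenario time units per outer iteration.
#' @param time_unit label for the time axis (e.g. `"day"`, `"min"`).
#' @param flush named numeric vector of flush additions in mM (applied
#'   to the model's entry node by [perturb()]).
#' @param volume_basis litres per cell for mM conversions.
#' @param seed integer seed (used by stochastic callers; the core solver
#'   is deterministic).
#' @param t0 reference temperature for Gibbs-Helmholtz, K.
#' @param retention fraction-free floor (pmol/cell) of net production a
#'   donor node keeps back from its outgoing transport offer.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(temp = 298.15, outer_tol = 1e-3,
                            inner_tol = 1e-5, max_outer = 50L,
                            time_per_iteration = 1,
                            time_unit = "iteration",
                            flush = numeric(0),
                            volume_basis = .VOLUME_BASIS,
                            seed = 1L, t0 = .T_REF, retention = 0) {
  if (outer_tol <= 0 || inner_tol <= 0) stop("tolerances must be positive")
  if (max_outer < 1L) stop("max_outer must be >= 1")
  if (temp <= 0) stop("temperature must be positive (kelvin)")
  structure(list(temp = temp, outer_tol = outer_tol, inner_tol = inner_tol,
                 max_outer = as.integer(max_outer),
                 time_per_iteration = time_per_iteration,
                 time_unit = time_unit, flush = flush,
                 volume_basis = volume_basis, seed = as.integer(seed),
                 t0 = t0, retention = retention),
            class = "scenario_config")
}

#' Construct a network state
#'
#' @param amounts named list: node id -> named numeric vector of species
#'   amounts (pmol/cell).
#' @param temp absolute temperature, K.
#' @param iteration outer iteration index the state belongs to.
#' @param in_transit named numeric vector of amounts currently on
#'   transport links (link id -> pmol/cell).
#' @return object of class `network_state`.
#' @export
network_state <- function(amounts, temp, iteration = 0L,
                          in_transit = numeric(0)) {
  for (nd in names(amounts)) {
    a <- amounts[[nd]]
    if (any(!is.finite(a)) || any(a < 0)) {
      stop("node '", nd, "': amounts must be finite and non-negative")
    }
  }
  structure(list(amounts = amounts, temp = temp,
                 iteration = as.integer(iteration), in_transit = in_transit),
            class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cat("<network_state> ", length(x$amounts), " nodes, T = ", x$temp,
      " K, iteration ", x$iteration, "\n", sep = "")
  invisible(x)
}

#' Total amount of one species over all nodes (plus in-transit)
#' @param state a `network_state`.
#' @param species_id species token.
#' @param model the owning `network_model` (to resolve link species).
#' @return total amount in pmol/cell.
#' @export
state_total <- function(state, species_id, model = NULL) {
  tot <- sum(vapply(state$amounts, function(a) {
    if (species_id %in% names(a)) a[[species_id]] else 0
  }, numeric(1)))
  if (!is.null(model) && length(state$in_transit)) {
    for (lid in names(state$in_transit)) {
      if (model$transports[[lid]]$species_id == species_id) {
        tot <- tot + state$in_transit[[lid]]
      }
    }
  }
  tot
}

## per-node species formation terms at temperature, cached per call
.node_g_rt <- function(node, db, temp, t0) {
  species_dg0_rt(db, node$species_ids, temp, t0)
}

## per-reaction dimensionless standard changes at temperature
.node_dg0_rt <- function(node, g_rt_species) {
  S <- stoichiometric_matrix(node)
  drop(crossprod(S, g_rt_species[rownames(S)]))
}

## Inner feedback loop: re-minimize the node until successive amounts
## (mM scale) differ by less than inner_tol.  All of a node's reactions
## are solved simultaneously, so pathway-internal recycle loops
## (oxaloacetate, ornithine, ...) typically settle in two sweeps.
.solve_node_inner <- function(node, n0, g_rt_species, temp, config) {
  S <- stoichiometric_matrix(node)
  dg0 <- drop(crossprod(S, g_rt_species[rownames(S)]))
  rev_flags <- vapply(node$reactions, `[[`, logical(1), "reversible")
  n <- pmax(n0, 0)
  inner <- 0L
  repeat {
    inner <- inner + 1L
    sol <- minimize_node(gibbs_problem(n, S, dg0, temp,
                                       reversible = rev_flags))
    if (!sol$converged) {
      stop("node '", node$node_id, "': Gibbs solve did not converge (kkt ",
           format(sol$kkt_residual, digits = 4), ")")
    }
    delta <- max(abs(amount_to_mM(sol$n_eq - n, config$volume_basis)))
    n <- sol$n_eq
    if (delta < config$inner_tol || inner >= 25L) break
  }
  list(n = n, inner_iters = inner)
}

#' Compute the node-wise chemical equilibrium initial state
#'
#' Distributes a total composition over the nodes (each species is split
#' equally among the nodes listing it, unless a per-node list is given),
#' then Gibbs-minimizes every node with its inner feedback loop.  The
#' result is a fixed point of the engine under zero perturbation.
#'
#' @param model a `network_model`.
#' @param composition either a named numeric vector of total species
#'   amounts (pmol/cell) to distribute, or a named list node id ->
#'   named amounts used as-is.
#' @param temp absolute temperature, K.
#' @param db a [thermo_db()].
#' @param config a [scenario_config()] (tolerances, conversions).
#' @return a `network_state`.
#' @export
initialize_equilibrium <- function(model, composition, temp, db,
                                   config = scenario_config(temp = temp)) {
  if (is.list(composition)) {
    amounts <- lapply(names(model$nodes), function(nid) {
      nd <- model$nodes[[nid]]
      a <- stats::setNames(numeric(length(nd$species_ids)), nd$species_ids)
      given <- composition[[nid]]
      if (!is.null(given)) {
        bad <- setdiff(names(given), nd$species_ids)
        if (length(bad)) {
          stop("node '", nid, "': composition names unknown species: ",
               paste(bad, collapse = ", "))
        }
        a[names(given)] <- given
      }
      a
    })
    names(amounts) <- names(model$nodes)
  } else {
    if (any(composition < 0)) stop("composition must be non-negative")
    carriers <- lapply(names(composition), function(sp) {
      names(model$nodes)[vapply(model$nodes, function(nd)
        sp %in% nd$species_ids, logical(1))]
    })
    names(carriers) <- names(composition)
    empty <- names(carriers)[lengths(carriers) == 0L]
    if (length(empty)) {
      stop("composition species absent from every node: ",
           paste(empty, collapse = ", "))
    }
    amounts <- lapply(names(model$nodes), function(nid) {
      nd <- model$nodes[[nid]]
      stats::setNames(numeric(length(nd$species_ids)), nd$species_ids)
    })
    names(amounts) <- names(model$nodes)
    for (sp in names(composition)) {
      share <- composition[[sp]] / length(carriers[[sp]])
      for (nid in carriers[[sp]]) amounts[[nid]][[sp]] <- share
    }
  }
  for (nid in names(model$nodes)) {
    nd <- model$nodes[[nid]]
    if (sum(amounts[[nid]]) <= 0) next
    g <- .node_g_rt(nd, db, temp, config$t0)
    res <- tryCatch(.solve_node_inner(nd, amounts[[nid]], g, temp, config),
                    error = function(e) {
                      stop("initialize_equilibrium: ", conditionMessage(e))
                    })
    amounts[[nid]] <- res$n
  }
  network_state(amounts, temp = temp, iteration = 0L)
}

#' Apply a flush perturbation to a state
#'
#' Adds flush species (given in mM, converted through the volume basis)
#' to the model's entry node.  All other amounts are untouched.
#'
#' @param state a `network_state`.
#' @param flush named numeric vector of additions in mM.
#' @param model the `network_model` (for the entry node).
#' @param volume_basis litres per cell.
#' @return the perturbed `network_state`.
#' @export
perturb <- function(state, flush, model, volume_basis = .VOLUME_BASIS) {
  if (!length(flush)) return(state)
  entry <- model$entry_node
  known <- names(state$amounts[[entry]])
  bad <- setdiff(names(flush), known)
  if (length(bad)) {
    stop("flush species not present in entry node '", entry, "': ",
         paste(bad, collapse = ", "))
  }
  add <- mM_to_amount(flush, volume_basis)
  state$amounts[[entry]][names(flush)] <-
    state$amounts[[entry]][names(flush)] + add
  state
}

## Split a donor's transport offer among several outgoing links for the
## same species, proportionally to recipient thermodynamic demand (the
## finite-difference drop in the recipient's Gibbs energy per unit
## transferred); falls back to an equal split when no recipient shows
## demand.  This update rule is the engine's central modeling choice and
## is isolated here.
.split_transport <- function(links, amount, state, model, db, temp, t0) {
  if (length(links) == 1L) return(stats::setNames(amount, links[[1]]$link_id))
  demand <- vapply(links, function(tr) {
    nd <- model$nodes[[tr$to_node]]
    a <- state$amounts[[tr$to_node]]
    if (sum(a) <= 0) return(0)
    g <- .node_g_rt(nd, db, temp, t0)
    eps <- max(1e-9 * sum(a), 1e-12)
    a2 <- a
    a2[[tr$species_id]] <- a2[[tr$species_id]] + eps
    max(0, (node_gibbs(a, g) - node_gibbs(a2, g)) / eps)
  }, numeric(1))
  ids <- vapply(links, `[[`, character(1), "link_id")
  if (sum(demand) <= 0) {
    return(stats::setNames(rep(amount / length(links), length(links)), ids))
  }
  stats::setNames(amount * demand / sum(demand), ids)
}

#' Run the Nash-equilibrium outer loop
#'
#' Visits nodes in model order; each visit delivers pending incoming
#' transports, re-minimizes the node's Gibbs energy (inner feedback loop
#' to `inner_tol`), then offers the node's net production of transported
#' species on its outgoing links.  The outer loop terminates when the
#' 2-norm (mM scale) of the change in transport fluxes falls to
#' `outer_tol`, or `max_outer` is reached (flagged, never an error).
#'
#' @param model a `network_model`.
#' @param state0 initial `network_state`.
#' @param config a [scenario_config()].
#' @param db a [thermo_db()].
#' @return a `nash_trajectory`: data.frame of per-iteration observables
#'   with attributes `convergence` (a `convergence_log`), `final_state`,
#'   and `config`.
#' @export
run_nash <- function(model, state0, config, db) {
  state <- state0
  temp <- config$temp
  links_by_id <- model$transports
  link_ids <- names(links_by_id)
  tau_old <- stats::setNames(numeric(length(link_ids)), link_ids)
  in_transit <- stats::setNames(numeric(length(link_ids)), link_ids)
  ## outgoing links grouped by (donor node, species)
  out_links <- list()
  for (tr in links_by_id) {
    key <- paste(tr$from_node, tr$species_id, sep = "\r")
    out_links[[key]] <- c(out_links[[key]], list(tr))
  }
  in_links <- split(unname(links_by_id),
                    vapply(links_by_id, `[[`, character(1), "to_node"))
  g_cache <- lapply(model$nodes, .node_g_rt, db = db, temp = temp,
                    t0 = config$t0)

  log_rows <- list()
  traj_rows <- list()
  converged <- FALSE
  iters_used <- config$max_outer
  for (iter in seq_len(config$max_outer)) {
    tau_new <- stats::setNames(numeric(length(link_ids)), link_ids)
    inner_total <- 0L
    for (nid in names(model$nodes)) {
      nd <- model$nodes[[nid]]
      a <- state$amounts[[nid]]
      ## deliver pending incoming transports
      for (tr in in_links[[nid]]) {
        lid <- tr$link_id
        if (in_transit[[lid]] > 0) {
          a[[tr$species_id]] <- a[[tr$species_id]] + in_transit[[lid]]
          in_transit[[lid]] <- 0
        }
      }
      pre <- a
      if (sum(a) > 0 && length(nd$reactions)) {
        res <- .solve_node_inner(nd, a, g_cache[[nid]], temp, config)
        a <- res$n
        inner_total <- inner_total + res$inner_iters
      }
      ## offer the post-minimization stock above the retention floor on
      ## outgoing links (retention 0: the donor's standing amount moves)
      for (key in names(out_links)) {
        parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
        if (parts[1] != nid) next
        sp <- parts[2]
        produced <- max(0, a[[sp]] - config$retention)
        if (produced <= 0) next
        shares <- .split_transport(out_links[[key]], produced, state, model,
                                  db, temp, config$t0)
        for (lid in names(shares)) {
          tau_new[[lid]] <- tau_new[[lid]] + shares[[lid]]
          in_transit[[lid]] <- in_transit[[lid]] + shares[[lid]]
          a[[sp]] <- a[[sp]] - shares[[lid]]
        }
        a[[sp]] <- max(a[[sp]], 0)  # guard float round-off
      }
      state$amounts[[nid]] <- a
    }
    state$in_transit <- in_transit
    state$iteration <- iter
    norm <- sqrt(sum(amount_to_mM(tau_new - tau_old,
                                  config$volume_basis)^2))
    log_rows[[iter]] <- data.frame(iteration = iter, norm = norm,
                                   inner_iters = inner_total)
    traj_rows[[iter]] <- cbind(
      data.frame(iteration = iter,
                 time = iteration_to_time(iter, config)),
      state_observables(state, model, config$volume_basis),
      data.frame(transport_norm = norm))
    tau_old <- tau_new
    if (norm <= config$outer_tol) {
      converged <- TRUE
      iters_used <- iter
      break
    }
  }
  traj <- do.call(rbind, traj_rows)
  conv <- structure(list(log = do.call(rbind, log_rows),
                         converged = converged,
                         iterations_used = iters_used,
                         outer_tol = config$outer_tol),
                    class = "convergence_log")
  structure(traj, convergence = conv, final_state = state, config = config,
            class = c("nash_trajectory", "data.frame"))
}

#' @export
print.convergence_log <- function(x, ...) {
  cat("<convergence_log> ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations_used, " outer iterations (tol ",
      format(x$outer_tol), ")\n", sep = "")
  print(x$log, row.names = FALSE)
  invisible(x)
}

#' @export
print.nash_trajectory <- function(x, ...) {
  conv <- attr(x, "convergence")
  cat("<nash_trajectory> ", nrow(x), " outer iterations",
      if (!is.null(conv) && conv$converged) ", converged" else
        ", not converged", "\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Map an outer iteration index to scenario time
#'
#' A linear per-scenario calibration: `time = iteration *
#' time_per_iteration` (static cold storage defaults to 1 day per outer
#' iteration; warm ischemia to 5 minutes).
#'
#' @param iteration iteration index (>= 0).
#' @param config a [scenario_config()].
#' @return scenario time in the config's time unit.
#' @export
iteration_to_time <- function(iteration, config) {
  if (any(iteration < 0)) stop("iteration must be >= 0")
  iteration * config$time_per_iteration
}

#' Write a trajectory (and its convergence log) to CSV
#'
#' The header carries a comment line with package version and config
#' digest so outputs are traceable.
#'
#' @param traj a `nash_trajectory`.
#' @param path trajectory CSV path.
#' @param convergence_path optional path for the convergence-log CSV.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, convergence_path = NULL) {
  config <- attr(traj, "config")
  hdr <- sprintf("# nashmet %s | T=%g K | outer_tol=%g | seed=%d",
                 as.character(utils::packageVersion("nashmet")),
                 config$temp, config$outer_tol, config$seed)
  con <- file(path, "w")
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(traj), con, row.names = FALSE)
  close(con)
  if (!is.null(convergence_path)) {
    conv <- attr(traj, "convergence")
    con2 <- file(convergence_path, "w")
    writeLines(hdr, con2)
    utils::write.csv(conv$log, con2, row.names = FALSE)
    close(con2)
  }
  invisible(path)
}
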