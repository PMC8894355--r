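## Pathway-structured network model: reactions, nodes, transport links,
## YAML model files, stoichiometric matrices, DOT export.

#' Parse a reaction arrow string
#'
#' Reactions are written as readable arrow strings, e.g.
#' `"gly + 2 atp + glu + cys -> 2 adp + 2 pi + gsh + 2 h"`.
#' Coefficients may be integers, decimals or rationals (`"1/2 o2"`);
#' reactants acquire negative signs, products positive.  `"<->"` and
#' `"="` are accepted as synonyms of `"->"` (direction bookkeeping is
#' carried by the reaction's `reversible` flag, not the arrow).
#'
#' @param text reaction string.
#' @return named numeric vector, species id to signed coefficient.
#' @examples
#' parse_reaction_string("glucose + atp -> g6p + adp + h")
#' @export
parse_reaction_string <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  sides <- strsplit(text, "<->|->|=", perl = TRUE)[[1]]
  if (length(sides) != 2L) stop("reaction needs exactly one arrow: '", text, "'")
  parse_side <- function(s, sign) {
    terms <- strsplit(s, "+", fixed = TRUE)[[1]]
    terms <- trimws(terms)
    terms <- terms[terms != ""]
    if (!length(terms)) stop("empty reaction side in '", text, "'")
    out <- numeric(0)
    for (tm in terms) {
      parts <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(parts) == 1L) {
        coef <- 1; sp <- parts[1]
      } else if (length(parts) == 2L) {
        coef <- .parse_coef(parts[1]); sp <- parts[2]
      } else {
        stop("cannot parse term '", tm, "' in '", text, "'")
      }
      if (!grepl("^[A-Za-z][A-Za-z0-9_]*$", sp)) {
        stop("bad species token '", sp, "' in '", text, "'")
      }
      out[sp] <- (if (is.na(out[sp])) 0 else out[sp]) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  all_sp <- union(names(lhs), names(rhs))
  coefs <- stats::setNames(numeric(length(all_sp)), all_sp)
  coefs[names(lhs)] <- coefs[names(lhs)] + lhs
  coefs[names(rhs)] <- coefs[names(rhs)] + rhs
  coefs[coefs != 0]
}

.parse_coef <- function(tok) {
  if (grepl("^[0-9]+/[0-9]+$", tok)) {
    ab <- as.numeric(strsplit(tok, "/", fixed = TRUE)[[1]])
    return(ab[1] / ab[2])
  }
  v <- suppressWarnings(as.numeric(tok))
  if (is.na(v) || v <= 0) stop("bad stoichiometric coefficient '", tok, "'")
  v
}

#' Render signed coefficients back into an arrow string
#' @param stoichiometry named numeric vector (products positive).
#' @return character scalar arrow string.
#' @export
format_reaction_string <- function(stoichiometry) {
  fmt_side <- function(v) {
    paste(vapply(names(v), function(sp) {
      cf <- v[[sp]]
      if (cf == 1) sp else paste(format(cf, digits = 15), sp)
    }, character(1)), collapse = " + ")
  }
  lhs <- -stoichiometry[stoichiometry < 0]
  rhs <- stoichiometry[stoichiometry > 0]
  paste(fmt_side(lhs), "->", fmt_side(rhs))
}

#' Construct a reaction
#'
#' @param reaction_id token naming the reaction.
#' @param stoichiometry named numeric vector or arrow string
#'   (see [parse_reaction_string()]).
#' @param reversible logical; may the net extent be negative?
#' @return object of class `nm_reaction`.
#' @export
reaction <- function(reaction_id, stoichiometry, reversible = TRUE) {
  if (is.character(stoichiometry)) {
    stoichiometry <- parse_reaction_string(stoichiometry)
  }
  if (!any(stoichiometry < 0) || !any(stoichiometry > 0)) {
    stop("reaction '", reaction_id,
         "' needs at least one reactant and one product")
  }
  structure(list(reaction_id = as.character(reaction_id),
                 stoichiometry = stoichiometry,
                 reversible = isTRUE(reversible)),
            class = "nm_reaction")
}

#' @export
print.nm_reaction <- function(x, ...) {
  cat(x$reaction_id, ": ", format_reaction_string(x$stoichiometry),
      if (x$reversible) "  (reversible)" else "  (forward only)", "\n", sep = "")
  invisible(x)
}

#' Construct a pathway node
#'
#' A node groups the reactions catalyzed within one pathway
#' (glycolysis, TCA cycle, urea cycle, ...) and owns a local species
#' pool.  `feedback_links` names species recycled within the pathway's
#' own loop (e.g. oxaloacetate in the TCA cycle, ornithine in the urea
#' cycle), which the inner convergence loop iterates on.
#'
#' @param node_id token.
#' @param reactions list of [reaction()] objects.
#' @param species_ids species present at this node; defaults to the union
#'   of all species in `reactions`.
#' @param feedback_links character vector of recycled species ids.
#' @return object of class `nm_node`.
#' @export
pathway_node <- function(node_id, reactions, species_ids = NULL,
                         feedback_links = character(0)) {
  if (length(reactions) && !all(vapply(reactions, inherits, logical(1),
                                       "nm_reaction"))) {
    stop("reactions must be nm_reaction objects")
  }
  used <- unique(unlist(lapply(reactions, function(r) names(r$stoichiometry))))
  if (is.null(species_ids)) species_ids <- used
  species_ids <- unique(as.character(species_ids))
  if (length(setdiff(used, species_ids))) {
    stop("node '", node_id, "': reaction species not in species_ids: ",
         paste(setdiff(used, species_ids), collapse = ", "))
  }
  if (length(species_ids) < 1L) stop("node '", node_id, "' has no species")
  bad_fb <- setdiff(feedback_links, species_ids)
  if (length(bad_fb)) {
    stop("node '", node_id, "': feedback species not present: ",
         paste(bad_fb, collapse = ", "))
  }
  names(reactions) <- vapply(reactions, `[[`, character(1), "reaction_id")
  structure(list(node_id = as.character(node_id), reactions = reactions,
                 species_ids = species_ids,
                 feedback_links = as.character(feedback_links)),
            class = "nm_node")
}

#' Construct an inter-pathway transport link
#'
#' Transport is directional (donor to recipient); reversible transport is
#' modeled as two opposing links.
#'
#' @param link_id token.
#' @param from_node donor node id.
#' @param to_node recipient node id.
#' @param species_id transported species.
#' @return object of class `nm_transport`.
#' @export
transport_link <- function(link_id, from_node, to_node, species_id) {
  if (from_node == to_node) stop("transport '", link_id, "': from == to")
  structure(list(link_id = as.character(link_id),
                 from_node = as.character(from_node),
                 to_node = as.character(to_node),
                 species_id = as.character(species_id)),
            class = "nm_transport")
}

#' Construct and validate a network model
#'
#' Checks id uniqueness, transport topology (both endpoints exist and
#' carry the transported species) and, when a thermodynamic database is
#' given, element/charge balance of every reaction.
#'
#' @param nodes list of [pathway_node()] objects (visit order matters:
#'   the Nash engine sweeps nodes in this order).
#' @param transports list of [transport_link()] objects.
#' @param modes named logical flags, at least `fatty_acid_synthesis` and
#'   `beta_oxidation`.
#' @param db optional [thermo_db()] to validate against.
#' @param entry_node node receiving scenario flush additions; defaults to
#'   the first node.
#' @param balance_tol absolute residual tolerated per element (default
#'   1e-9; packaged models balance exactly in integer arithmetic).
#' @return object of class `network_model`.
#' @export
network_model <- function(nodes, transports = list(),
                          modes = list(fatty_acid_synthesis = TRUE,
                                       beta_oxidation = FALSE),
                          db = NULL, entry_node = NULL, balance_tol = 1e-9) {
  stopifnot(length(nodes) >= 1L)
  node_ids <- vapply(nodes, `[[`, character(1), "node_id")
  if (anyDuplicated(node_ids)) stop("duplicate node ids")
  names(nodes) <- node_ids
  for (tr in transports) {
    for (side in c("from_node", "to_node")) {
      if (!tr[[side]] %in% node_ids) {
        stop("transport '", tr$link_id, "' references unknown node '",
             tr[[side]], "'")
      }
      if (!tr$species_id %in% nodes[[tr[[side]]]]$species_ids) {
        stop("transport '", tr$link_id, "': species '", tr$species_id,
             "' absent from node '", tr[[side]], "'")
      }
    }
  }
  link_ids <- vapply(transports, `[[`, character(1), "link_id")
  if (anyDuplicated(link_ids)) stop("duplicate transport link ids")
  names(transports) <- link_ids
  if (is.null(entry_node)) entry_node <- node_ids[1]
  if (!entry_node %in% node_ids) stop("unknown entry_node '", entry_node, "'")
  model <- structure(list(nodes = nodes, transports = transports,
                          modes = modes, entry_node = entry_node),
                     class = "network_model")
  if (!is.null(db)) validate_model(model, db, balance_tol = balance_tol)
  model
}

#' Validate a model against a thermodynamic database
#'
#' Every species of every node must resolve in `db` and every reaction
#' must balance in all elements and charge.
#'
#' @param model a `network_model`.
#' @param db a `thermo_db`.
#' @param balance_tol absolute residual tolerance.
#' @return `TRUE` invisibly; errors name the offending reaction.
#' @export
validate_model <- function(model, db, balance_tol = 1e-9) {
  for (nd in model$nodes) {
    db_lookup(db, nd$species_ids)
    for (rx in nd$reactions) {
      res <- validate_reaction_balance(rx$stoichiometry, db)
      if (any(abs(res) > balance_tol)) {
        bad <- res[abs(res) > balance_tol]
        stop("reaction '", rx$reaction_id, "' in node '", nd$node_id,
             "' is unbalanced: ",
             paste(names(bad), round(bad, 6), sep = "=", collapse = ", "))
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.network_model <- function(x, ...) {
  nrx <- sum(vapply(x$nodes, function(n) length(n$reactions), integer(1)))
  cat("<network_model> ", length(x$nodes), " nodes, ", nrx, " reactions, ",
      length(x$transports), " transport links\n", sep = "")
  cat("  nodes: ", paste(names(x$nodes), collapse = ", "), "\n", sep = "")
  cat("  modes: fatty_acid_synthesis=", isTRUE(x$modes$fatty_acid_synthesis),
      ", beta_oxidation=", isTRUE(x$modes$beta_oxidation), "\n", sep = "")
  invisible(x)
}

#' @export
summary.network_model <- function(object, ...) {
  for (nd in object$nodes) {
    cat(nd$node_id, " (", length(nd$species_ids), " species)\n", sep = "")
    for (rx in nd$reactions) {
      cat("  ", rx$reaction_id, ": ",
          format_reaction_string(rx$stoichiometry), "\n", sep = "")
    }
  }
  if (length(object$transports)) {
    cat("transports:\n")
    for (tr in object$transports) {
      cat("  ", tr$link_id, ": ", tr$from_node, " -> ", tr$to_node,
          " [", tr$species_id, "]\n", sep = "")
    }
  }
  invisible(object)
}

#' Stoichiometric matrix of a node
#'
#' @param node a `nm_node`.
#' @return numeric matrix, rows = the node's species (in `species_ids`
#'   order), columns = reactions; zero-column matrix for a reaction-free
#'   node.
#' @export
stoichiometric_matrix <- function(node) {
  sp <- node$species_ids
  S <- matrix(0, nrow = length(sp), ncol = length(node$reactions),
              dimnames = list(sp, names(node$reactions)))
  for (k in seq_along(node$reactions)) {
    st <- node$reactions[[k]]$stoichiometry
    S[names(st), k] <- st
  }
  S
}

## ---- model file I/O (YAML dialect) ----

#' Load a network model from a YAML model file
#'
#' The document has sections `modes`, `entry_node`, `nodes` (each node:
#' `id`, `species`, `feedback`, `reactions` as arrow strings with
#' `reversible` flags) and `transports`.  When `db` is supplied the model
#' is validated reaction-by-reaction on load.
#'
#' @param path model file path.
#' @param db optional [thermo_db()] for balance validation.
#' @return a [network_model()].
#' @export
load_model <- function(path, db = NULL) {
  if (!file.exists(path)) stop("no such model file: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$nodes)) stop("model file '", path, "': missing 'nodes'")
  nodes <- lapply(doc$nodes, function(nd) {
    if (is.null(nd$id)) stop("model file '", path, "': node without 'id'")
    rxs <- lapply(nd$reactions, function(rx) {
      if (is.null(rx$id) || is.null(rx$equation)) {
        stop("model file '", path, "': node '", nd$id,
             "': reaction needs 'id' and 'equation'")
      }
      reaction(rx$id, rx$equation,
               reversible = if (is.null(rx$reversible)) TRUE else rx$reversible)
    })
    pathway_node(nd$id, rxs,
                 species_ids = if (is.null(nd$species)) NULL else
                   as.character(nd$species),
                 feedback_links = if (is.null(nd$feedback)) character(0) else
                   as.character(nd$feedback))
  })
  transports <- lapply(doc$transports, function(tr) {
    if (is.null(tr$id)) stop("model file '", path, "': transport without 'id'")
    transport_link(tr$id, tr$from, tr$to, tr$species)
  })
  modes <- doc$modes
  if (is.null(modes)) modes <- list(fatty_acid_synthesis = TRUE,
                                    beta_oxidation = FALSE)
  network_model(nodes, transports, modes = modes, db = db,
                entry_node = doc$entry_node)
}

#' Save a network model to a YAML model file
#' @param model a `network_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  doc <- list(
    modes = model$modes,
    entry_node = model$entry_node,
    nodes = lapply(unname(model$nodes), function(nd) {
      list(id = nd$node_id,
           species = as.list(nd$species_ids),
           feedback = as.list(nd$feedback_links),
           reactions = lapply(unname(nd$reactions), function(rx) {
             list(id = rx$reaction_id,
                  equation = format_reaction_string(rx$stoichiometry),
                  reversible = rx$reversible)
           }))
    }),
    transports = lapply(unname(model$transports), function(tr) {
      list(id = tr$link_id, from = tr$from_node, to = tr$to_node,
           species = tr$species_id)
    }))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Export the node/transport graph to DOT
#'
#' Writes a Graphviz DOT text file of pathway nodes (boxes) and transport
#' links (directed edges labeled by species), optionally weighted by a
#' flux vector so heavier fluxes draw thicker edges.
#'
#' @param model a `network_model`.
#' @param path output `.dot` path.
#' @param fluxes optional named numeric vector (by link id) of fluxes.
#' @return `path`, invisibly.
#' @export
export_dot <- function(model, path, fluxes = NULL) {
  lines <- c("digraph metabolic_network {", "  rankdir=LR;",
             "  node [shape=box];")
  for (nd in model$nodes) {
    lines <- c(lines, sprintf('  "%s";', nd$node_id))
  }
  mx <- if (!is.null(fluxes) && any(fluxes > 0)) max(fluxes) else 1
  for (tr in model$transports) {
    w <- if (is.null(fluxes)) 1 else 1 + 4 * (fluxes[[tr$link_id]] %||% 0) / mx
    lines <- c(lines, sprintf('  "%s" -> "%s" [label="%s", penwidth=%.2f];',
                              tr$from_node, tr$to_node, tr$species_id, w))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
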