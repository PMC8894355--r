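## Thermodynamic species database: formation energies, Gibbs-Helmholtz
## temperature correction, reaction-level standard changes, balance checks.

#' Universal gas constant in J/(mol K)
#' @keywords internal
.R_GAS <- 8.314

#' Reference temperature in kelvin
#' @keywords internal
.T_REF <- 298.15

#' Parse a Hill-style molecular formula
#'
#' Converts a formula token such as `"C10H12N5O13P3"` into a named integer
#' vector of element counts.  A count of 1 may be omitted (`"H2O"` means
#' H = 2, O = 1).  The empty string (or `"-"`) denotes a species with no
#' atoms, used for pure charge-bookkeeping entries such as the electron.
#'
#' @param formula character scalar, Hill-style element/count tokens.
#' @return named integer vector of element counts (possibly empty).
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("HPO4")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  formula <- trimws(formula)
  if (formula == "" || formula == "-") {
    return(stats::setNames(integer(0), character(0)))
  }
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  parts <- regmatches(formula, list(tokens))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("malformed formula: '", formula, "'")
  }
  el <- sub("[0-9]+$", "", parts)
  n <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", parts)))
  n[is.na(n)] <- 1L
  counts <- tapply(n, el, sum)
  out <- stats::setNames(as.integer(counts), names(counts))
  out[order(names(out))]
}

#' Render an element-count vector as a Hill-style formula string
#' @param counts named integer vector of element counts.
#' @return character scalar.
#' @export
format_formula <- function(counts) {
  counts <- counts[counts != 0]
  if (length(counts) == 0L) return("")
  els <- names(counts)
  ## Hill order: C first, H second, rest alphabetical
  ord <- order(match(els, c("C", "H"), nomatch = 3L), els)
  paste0(els[ord], ifelse(counts[ord] == 1L, "", counts[ord]), collapse = "")
}

#' Construct a thermodynamic species database
#'
#' A `thermo_db` holds one row per chemical species: elemental formula,
#' charge, standard Gibbs free energy and enthalpy of formation at
#' 298.15 K (kJ/mol), and the standard deviation of the formation energy
#' (kJ/mol) as reported by curated sources in the eQuilibrator style.
#'
#' @param records data.frame with columns `species_id`, `name`, `formula`,
#'   `charge`, `dgf0_kj_mol`, `dhf0_kj_mol`, `sd_kj_mol`.
#' @return object of class `thermo_db`: the validated data.frame plus a
#'   parsed `composition` attribute (list of element-count vectors).
#' @export
thermo_db <- function(records) {
  needed <- c("species_id", "name", "formula", "charge",
              "dgf0_kj_mol", "dhf0_kj_mol", "sd_kj_mol")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("thermo records lack column(s): ", paste(missing, collapse = ", "))
  }
  records <- as.data.frame(records)[needed]
  records$species_id <- as.character(records$species_id)
  records$name <- as.character(records$name)
  records$formula <- as.character(records$formula)
  records$charge <- as.integer(records$charge)
  for (col in c("dgf0_kj_mol", "dhf0_kj_mol", "sd_kj_mol")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  if (anyDuplicated(records$species_id)) {
    stop("duplicate species_id: ",
         paste(unique(records$species_id[duplicated(records$species_id)]),
               collapse = ", "))
  }
  if (any(records$sd_kj_mol < 0)) stop("sd_kj_mol must be non-negative")
  if (any(!is.finite(records$dgf0_kj_mol))) stop("non-finite dgf0")
  comp <- lapply(records$formula, parse_formula)
  if (any(vapply(comp, function(x) any(x < 0), logical(1)))) {
    stop("negative element counts")
  }
  names(comp) <- records$species_id
  structure(records, composition = comp, class = c("thermo_db", "data.frame"))
}

#' @export
print.thermo_db <- function(x, ...) {
  cat("<thermo_db> ", nrow(x), " species\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Number of species in a thermodynamic database
#' @param db a `thermo_db`.
#' @return integer count.
#' @export
n_species <- function(db) nrow(db)

#' Look up database rows by species id
#' @param db a `thermo_db`.
#' @param species_ids character vector of ids.
#' @return data.frame subset in the order requested.
#' @export
db_lookup <- function(db, species_ids) {
  idx <- match(species_ids, db$species_id)
  if (anyNA(idx)) {
    stop("unknown species: ",
         paste(species_ids[is.na(idx)], collapse = ", "))
  }
  as.data.frame(db)[idx, , drop = FALSE]
}

#' Read a species thermodynamics table from TSV
#'
#' The dialect mirrors eQuilibrator-style exports: UTF-8, tab-separated,
#' one header row with the exact column order `species_id`, `name`,
#' `formula`, `charge`, `dgf0_kj_mol`, `dhf0_kj_mol`, `sd_kj_mol`;
#' lines starting with `#` are comments.
#'
#' @param path file path.
#' @return a [thermo_db()].
#' @export
read_thermo_tsv <- function(path) {
  if (!file.exists(path)) stop("no such thermo table: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          quote = "", fileEncoding = "UTF-8")
  thermo_db(df)
}

#' Write a species thermodynamics table to TSV
#' @param db a `thermo_db`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_thermo_tsv <- function(db, path) {
  utils::write.table(as.data.frame(db), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Gibbs-Helmholtz temperature correction
#'
#' Propagates a standard Gibbs free energy change from the reference
#' temperature `T0` to temperature `temp` using the standard enthalpy
#' change, returning the dimensionless quantity \eqn{\Delta G^0(T)/RT}:
#' \deqn{\frac{\Delta G^0(T)}{RT} = \frac{\Delta G^0(T_0)}{R T_0}
#'   + \frac{\Delta H^0(T_0)}{R}\,\frac{T - T_0}{T\,T_0}.}
#'
#' @param dg0_t0 standard Gibbs change at `T0`, kJ/mol.
#' @param dh0_t0 standard enthalpy change at `T0`, kJ/mol.
#' @param temp target absolute temperature, K.
#' @param t0 reference temperature, K (default 298.15).
#' @param r_gas gas constant, J/(mol K) (default 8.314).
#' @return dimensionless \eqn{\Delta G^0(T)/RT} (vectorized over inputs).
#' @examples
#' gibbs_helmholtz(-30, -20, temp = 277.15)
#' @export
gibbs_helmholtz <- function(dg0_t0, dh0_t0, temp, t0 = .T_REF, r_gas = .R_GAS) {
  if (any(temp <= 0) || any(t0 <= 0)) {
    stop("temperatures must be positive (kelvin)")
  }
  ## inputs kJ/mol, R in J/(mol K): factor 1000
  1000 * dg0_t0 / (r_gas * t0) + (1000 * dh0_t0 / r_gas) * (temp - t0) / (temp * t0)
}

#' Per-species dimensionless formation term at temperature
#'
#' Applies [gibbs_helmholtz()] to each species' formation energy/enthalpy.
#'
#' @param db a `thermo_db`.
#' @param species_ids ids to evaluate.
#' @inheritParams gibbs_helmholtz
#' @return named numeric vector of \eqn{\Delta G^0_f(T)/RT}.
#' @export
species_dg0_rt <- function(db, species_ids, temp, t0 = .T_REF, r_gas = .R_GAS) {
  rows <- db_lookup(db, species_ids)
  stats::setNames(
    gibbs_helmholtz(rows$dgf0_kj_mol, rows$dhf0_kj_mol, temp, t0, r_gas),
    species_ids)
}

#' Standard Gibbs or enthalpy change of a reaction
#'
#' Signed-coefficient inner product of the stoichiometry with the species
#' formation energies: products (positive coefficients) minus reactants
#' (negative coefficients).
#'
#' @param stoichiometry named numeric vector, species id to signed
#'   coefficient (products positive).
#' @param db a `thermo_db`.
#' @param property `"gibbs"` or `"enthalpy"`.
#' @return scalar change in kJ/mol.
#' @export
reaction_standard_change <- function(stoichiometry, db,
                                     property = c("gibbs", "enthalpy")) {
  property <- match.arg(property)
  rows <- db_lookup(db, names(stoichiometry))
  col <- if (property == "gibbs") rows$dgf0_kj_mol else rows$dhf0_kj_mol
  sum(stoichiometry * col)
}

#' Element/charge matrix of a species set
#'
#' @param db a `thermo_db`.
#' @param species_ids species columns, in order.
#' @return numeric matrix, rows = elements present plus `"charge"`,
#'   columns = species.
#' @export
element_matrix <- function(db, species_ids) {
  db_lookup(db, species_ids)  # existence check
  comp <- attr(db, "composition")[species_ids]
  elements <- sort(unique(unlist(lapply(comp, names))))
  m <- matrix(0, nrow = length(elements) + 1L, ncol = length(species_ids),
              dimnames = list(c(elements, "charge"), species_ids))
  for (j in seq_along(species_ids)) {
    cj <- comp[[j]]
    if (length(cj)) m[names(cj), j] <- cj
  }
  m["charge", ] <- db_lookup(db, species_ids)$charge
  m
}

#' Element and charge residuals of a reaction
#'
#' For a balanced reaction every residual is zero; non-zero entries show
#' which element (or the net charge) fails to balance and by how much,
#' counted on the product side.
#'
#' @inheritParams reaction_standard_change
#' @return named numeric vector of per-element residuals plus `"charge"`.
#' @export
validate_reaction_balance <- function(stoichiometry, db) {
  m <- element_matrix(db, names(stoichiometry))
  drop(m %*% stoichiometry)
}
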