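## Deterministic toy fixtures: tiny networks and databases with known
## ground truth, so the solver, engine and statistics are testable
## without any external data.

#' Isomer-pair fixture with closed-form equilibrium
#'
#' One node, one reaction `A <-> B` between isomers, with the requested
#' dimensionless standard change.  The analytic equilibrium is
#' `x_B / x_A = exp(-dg0_rt)`.
#'
#' @param dg0_rt dimensionless standard reaction change at the fixture
#'   temperature (298.15 K).
#' @param n_total total initial amount placed on A (default 1).
#' @return list: `model`, `db`, `composition` (list by node),
#'   `prediction` (named vector of equilibrium amounts), `dg0_rt`.
#' @export
make_isomer_pair <- function(dg0_rt, n_total = 1) {
  stopifnot(is.finite(dg0_rt))
  dg_b <- dg0_rt * .R_GAS * 298.15 / 1000  # kJ/mol difference
  db <- thermo_db(data.frame(
    species_id = c("iso_a", "iso_b"),
    name = c("isomer A", "isomer B"),
    formula = c("C3H6O3", "C3H6O3"),
    charge = c(0L, 0L),
    dgf0_kj_mol = c(-100, -100 + dg_b),
    dhf0_kj_mol = c(0, 0),
    sd_kj_mol = c(0.5, 0.5)))
  model <- network_model(
    list(pathway_node("pair", list(reaction("iso", "iso_a -> iso_b")))),
    db = db)
  k <- exp(-dg0_rt)
  prediction <- c(iso_a = n_total / (1 + k), iso_b = n_total * k / (1 + k))
  list(model = model, db = db,
       composition = list(pair = c(iso_a = n_total)),
       prediction = prediction, dg0_rt = dg0_rt)
}

#' Two-node transport fixture
#'
#' Node `source` produces species A from a precursor; node `sink`
#' consumes A through an isomerization `A <-> B`.  A single transport
#' link carries A.  The engine's fixed point can be cross-checked
#' against a scalar successive-substitution oracle.
#'
#' @param dg_produce kJ/mol standard change of the production step
#'   (default -10, favourable).
#' @param dg_convert kJ/mol standard change of the sink conversion
#'   (default -5).
#' @return list: `model`, `db`, `composition`.
#' @export
make_two_node_transport <- function(dg_produce = -10, dg_convert = -5) {
  db <- thermo_db(data.frame(
    species_id = c("pre", "spa", "spb"),
    name = c("precursor", "species A", "species B"),
    formula = c("C6H12O6", "C6H12O6", "C6H12O6"),
    charge = 0L,
    dgf0_kj_mol = c(-100, -100 + dg_produce, -100 + dg_produce + dg_convert),
    dhf0_kj_mol = 0,
    sd_kj_mol = 0.5))
  model <- network_model(
    list(pathway_node("source", list(reaction("prod", "pre -> spa"))),
         pathway_node("sink", list(reaction("conv", "spa -> spb")))),
    transports = list(transport_link("t_a", "source", "sink", "spa")),
    db = db)
  list(model = model, db = db,
       composition = list(source = c(pre = 1),
                          sink = c(spa = 0.01, spb = 0.01)))
}

#' Adenylate-pool toy model
#'
#' A miniature of the energy-depletion dynamics: a supply node
#' regenerates ATP by substrate-level phosphorylation from a finite
#' phosphoenolpyruvate pool, a load node hydrolyzes ATP and carries
#' adenylate kinase (`2 ADP <-> ATP + AMP`).  ATP and ADP circulate on
#' transport links.  Under the consumption-dominant default the energy
#' charge decreases across outer iterations, and the total adenylate
#' pool is conserved exactly.
#'
#' @return list: `model`, `db`, `composition`.
#' @export
make_adenylate_toy <- function() {
  db <- thermo_db(data.frame(
    species_id = c("atp", "adp", "amp", "pi", "pep", "pyr", "h", "h2o"),
    name = c("ATP", "ADP", "AMP", "orthophosphate",
             "phosphoenolpyruvate", "pyruvate", "proton", "water"),
    formula = c("C10H12N5O13P3", "C10H12N5O10P2", "C10H12N5O7P", "HO4P",
                "C3H2O6P", "C3H3O3", "H", "H2O"),
    charge = c(-4L, -3L, -2L, -2L, -3L, -1L, 1L, 0L),
    dgf0_kj_mol = c(-2295.1, -1425.1, -555.1, -1056.6, -1182.3, -350.8,
                    54.3, -157.6),
    dhf0_kj_mol = 0,
    sd_kj_mol = c(3, 2.4, 1.4, 1, 1.3, 0.8, 0, 0.1)))
  model <- network_model(
    list(
      pathway_node("supply", list(
        reaction("pk", "pep + adp + h -> pyr + atp")),
        species_ids = c("pep", "adp", "h", "pyr", "atp", "h2o")),
      pathway_node("load", list(
        reaction("atpase", "atp + h2o -> adp + pi + h"),
        reaction("ak", "atp + amp -> 2 adp")),
        species_ids = c("atp", "h2o", "adp", "pi", "h", "amp"))),
    transports = list(
      transport_link("t_atp", "supply", "load", "atp"),
      transport_link("t_adp", "load", "supply", "adp")),
    db = db)
  list(model = model, db = db,
       composition = list(
         supply = c(pep = 0.4, adp = 0.5, atp = 0.1, pyr = 0.05,
                    h = 1e-6, h2o = 100),
         load = c(atp = 1, adp = 0.3, amp = 0.2, pi = 2, h = 1e-6,
                  h2o = 100)))
}

#' Random element-balanced network fixture
#'
#' Species are built on a `CH2O` monomer family (species `i` has
#' formula `(CH2O)^k_i`, optionally deprotonated once to exercise
#' charge balancing); reactions are integer combinations in the null
#' space of the monomer-count vector, so every reaction balances every
#' element and the charge exactly.  Fully reproducible by seed.
#'
#' @param n_species number of species (>= 3).
#' @param n_reactions number of reactions (>= 1).
#' @param seed integer seed.
#' @param charged include deprotonated (anionic) variants and explicit
#'   protons (default FALSE).
#' @return list: `model`, `db`, `composition`.
#' @export
make_random_balanced <- function(n_species, n_reactions, seed,
                                 charged = FALSE) {
  if (n_species < 3L) stop("need at least 3 species")
  if (n_reactions < 1L) stop("need at least 1 reaction")
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(as.integer(seed))
  k <- sample(1:6, n_species, replace = TRUE)
  deprot <- if (charged) stats::runif(n_species) < 0.4 else
    rep(FALSE, n_species)
  ids <- sprintf("s%02d", seq_len(n_species))
  formula <- vapply(seq_len(n_species), function(i) {
    cnt <- c(C = k[i], H = 2L * k[i] - as.integer(deprot[i]), O = k[i])
    format_formula(cnt)
  }, character(1))
  db_df <- data.frame(
    species_id = ids, name = ids, formula = formula,
    charge = ifelse(deprot, -1L, 0L),
    dgf0_kj_mol = -80 * k + stats::rnorm(n_species, 0, 10),
    dhf0_kj_mol = 0,
    sd_kj_mol = stats::runif(n_species, 0.2, 3))
  if (charged) {
    db_df <- rbind(db_df, data.frame(
      species_id = "h", name = "proton", formula = "H", charge = 1L,
      dgf0_kj_mol = 0, dhf0_kj_mol = 0, sd_kj_mol = 0))
  }
  db <- thermo_db(db_df)
  rxs <- vector("list", n_reactions)
  for (r in seq_len(n_reactions)) {
    trio <- sample(n_species, 3L)
    i <- trio[1]; j <- trio[2]; l <- trio[3]
    ## integer null-space combination of the monomer-count vector:
    ## k_l*(e_i + e_j) - (k_i + k_j)*e_l balances all elements
    st <- stats::setNames(c(k[l], k[l], -(k[i] + k[j])), ids[trio])
    st <- tapply(st, names(st), sum)         # merge duplicate picks
    st <- stats::setNames(as.numeric(st), names(st))
    st <- st[st != 0]
    if (length(st) < 2L || !any(st > 0) || !any(st < 0)) {
      st <- stats::setNames(c(k[j], -k[i]), ids[c(i, j)])
      st <- st[st != 0]
    }
    if (charged) {
      res <- validate_reaction_balance(st, db)
      if (abs(res[["charge"]]) > 0) st[["h"]] <- -res[["charge"]]
    }
    rxs[[r]] <- reaction(sprintf("r%02d", r), st)
  }
  node <- pathway_node("random", rxs)
  model <- network_model(list(node), db = db)
  comp <- stats::setNames(stats::runif(length(node$species_ids), 0.2, 2),
                          node$species_ids)
  if ("h" %in% names(comp)) comp[["h"]] <- 1e-6
  list(model = model, db = db,
       composition = list(random = comp))
}
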