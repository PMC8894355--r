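# Shared helpers: independent summation/element oracles and cached
# liver runs (computed once per test session, reused across files).

R_GAS <- 8.314
T_REF <- 298.15

# independent per-element summation oracle for reaction residuals
oracle_balance <- function(stoich, db) {
  rows <- db_lookup(db, names(stoich))
  comps <- lapply(rows$formula, parse_formula)
  elements <- sort(unique(unlist(lapply(comps, names))))
  res <- stats::setNames(numeric(length(elements) + 1L),
                         c(elements, "charge"))
  for (i in seq_along(stoich)) {
    cnt <- comps[[i]]
    for (el in names(cnt)) res[el] <- res[el] + stoich[i] * cnt[[el]]
    res["charge"] <- res["charge"] + stoich[i] * rows$charge[i]
  }
  res
}

# total amount of each element (plus charge) over a network state
element_totals <- function(state, model, db) {
  tot <- NULL
  add <- function(tot, v) {
    if (is.null(tot)) return(v)
    allel <- union(names(tot), names(v))
    out <- stats::setNames(numeric(length(allel)), allel)
    out[names(tot)] <- tot
    out[names(v)] <- out[names(v)] + v
    out
  }
  for (nid in names(state$amounts)) {
    a <- state$amounts[[nid]]
    em <- element_matrix(db, names(a))
    tot <- add(tot, drop(em %*% a))
  }
  if (length(state$in_transit)) {
    for (lid in names(state$in_transit)) {
      sp <- model$transports[[lid]]$species_id
      em <- element_matrix(db, sp)
      tot <- add(tot, em[, 1] * state$in_transit[[lid]])
    }
  }
  tot
}

# cached packaged-model runs (static cold storage / warm ischemia)
.liver_cache <- new.env(parent = emptyenv())

liver_db <- function() {
  if (is.null(.liver_cache$db)) .liver_cache$db <- liver_thermo()
  .liver_cache$db
}

liver_model_cached <- function() {
  if (is.null(.liver_cache$model)) {
    .liver_cache$model <- build_liver_model(db = liver_db())
  }
  .liver_cache$model
}

scs_run_cached <- function() {
  if (is.null(.liver_cache$scs)) {
    .liver_cache$scs <- run_scs(liver_model_cached(), liver_db())
  }
  .liver_cache$scs
}

wi_run_cached <- function() {
  if (is.null(.liver_cache$wi)) {
    .liver_cache$wi <- run_wi(liver_model_cached(), liver_db())
  }
  .liver_cache$wi
}

scs_init_state <- function() {
  if (is.null(.liver_cache$scs0)) {
    cfg <- scs_config()
    .liver_cache$scs0 <- initialize_equilibrium(
      liver_model_cached(), attr(liver_model_cached(), "composition"),
      cfg$temp, liver_db(), cfg)
  }
  .liver_cache$scs0
}

wi_init_state <- function() {
  if (is.null(.liver_cache$wi0)) {
    cfg <- wi_config()
    .liver_cache$wi0 <- initialize_equilibrium(
      liver_model_cached(), attr(liver_model_cached(), "composition"),
      cfg$temp, liver_db(), cfg)
  }
  .liver_cache$wi0
}
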