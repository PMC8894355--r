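test_that("Gibbs-Helmholtz correction reproduces direct arithmetic", {
  # T = T0 collapses the enthalpy term
  expect_equal(gibbs_helmholtz(-30, -20, temp = 298.15),
               -30000 / (R_GAS * 298.15), tolerance = 1e-12)
  # zero enthalpy keeps the dimensionless value flat across temperature
  expect_equal(gibbs_helmholtz(-30, 0, temp = 277.15),
               gibbs_helmholtz(-30, 0, temp = 298.15), tolerance = 1e-12)
  # direct evaluation as the oracle
  expected <- -30000 / (R_GAS * 298.15) +
    (-20000 / R_GAS) * (277.15 - 298.15) / (277.15 * 298.15)
  expect_equal(gibbs_helmholtz(-30, -20, temp = 277.15), expected,
               tolerance = 1e-12)
  expect_equal(expected, -11.491, tolerance = 1e-4)
  expect_error(gibbs_helmholtz(-30, -20, temp = -1), "positive")
})

test_that("Gibbs-Helmholtz is linear in both arguments", {
  set.seed(11)
  for (i in 1:20) {
    g1 <- stats::runif(1, -300, 100); h1 <- stats::runif(1, -300, 100)
    g2 <- stats::runif(1, -300, 100); h2 <- stats::runif(1, -300, 100)
    a <- stats::runif(1, -2, 2); temp <- stats::runif(1, 260, 320)
    expect_equal(gibbs_helmholtz(g1 + a * g2, h1 + a * h2, temp),
                 gibbs_helmholtz(g1, h1, temp) +
                   a * gibbs_helmholtz(g2, h2, temp),
                 tolerance = 1e-9)
  }
})

test_that("formula parsing handles Hill tokens and round-trips", {
  expect_equal(parse_formula("C10H12N5O13P3"),
               c(C = 10L, H = 12L, N = 5L, O = 13L, P = 3L))
  expect_equal(parse_formula("H2O"), c(H = 2L, O = 1L))
  expect_equal(parse_formula("HPO4"), c(H = 1L, O = 4L, P = 1L))
  expect_length(parse_formula(""), 0)
  expect_error(parse_formula("C6?"), "malformed")
  cnt <- parse_formula("C6H12O6")
  expect_equal(parse_formula(format_formula(cnt)), cnt)
})

test_that("reaction standard change is a signed inner product", {
  db <- liver_db()
  # null reaction (same species as reactant and product) cancels to zero
  expect_equal(reaction_standard_change(c(atp = 0), db), 0)
  # glucokinase: algebraic identity on the formation energies
  st <- parse_reaction_string("glucose + atp -> g6p + adp + h")
  rows <- db_lookup(db, names(st))
  expect_equal(reaction_standard_change(st, db),
               sum(st * rows$dgf0_kj_mol), tolerance = 1e-12)
  # reversal negates
  expect_equal(reaction_standard_change(-st, db),
               -reaction_standard_change(st, db), tolerance = 1e-12)
  # enthalpy uses the same contract
  expect_equal(reaction_standard_change(st, db, "enthalpy"),
               sum(st * rows$dhf0_kj_mol), tolerance = 1e-12)
  expect_error(reaction_standard_change(c(nosuch = 1, atp = -1), db),
               "nosuch")
})

test_that("per-element constant offsets leave balanced reactions unchanged", {
  set.seed(7)
  for (s in 1:3) {
    fx <- make_random_balanced(6, 3, seed = s)
    db <- fx$db
    offsets <- c(C = stats::runif(1, -50, 50), H = stats::runif(1, -50, 50),
                 O = stats::runif(1, -50, 50))
    shifted <- as.data.frame(db)
    for (i in seq_len(nrow(shifted))) {
      cnt <- parse_formula(shifted$formula[i])
      shifted$dgf0_kj_mol[i] <- shifted$dgf0_kj_mol[i] +
        sum(offsets[names(cnt)] * cnt)
    }
    db2 <- thermo_db(shifted)
    for (rx in fx$model$nodes$random$reactions) {
      expect_equal(reaction_standard_change(rx$stoichiometry, db2),
                   reaction_standard_change(rx$stoichiometry, db),
                   tolerance = 1e-9)
    }
  }
})

test_that("balance residuals localize the missing atoms and charge", {
  db <- liver_db()
  ok <- parse_reaction_string("glucose + atp -> g6p + adp + h")
  expect_true(all(abs(validate_reaction_balance(ok, db)) < 1e-12))
  # deliberately dropping the proton leaves H and charge residuals of -1
  broken <- parse_reaction_string("glucose + atp -> g6p + adp")
  res <- validate_reaction_balance(broken, db)
  expect_equal(unname(res["H"]), -1)
  expect_equal(unname(res["charge"]), -1)
  # random stoichiometries match the independent summation oracle
  set.seed(3)
  ids <- as.data.frame(db)$species_id
  for (i in 1:10) {
    pick <- sample(ids, 4)
    st <- stats::setNames(stats::rnorm(4), pick)
    expect_equal(validate_reaction_balance(st, db),
                 oracle_balance(st, db)[names(validate_reaction_balance(st, db))],
                 tolerance = 1e-9)
  }
})

test_that("every packaged liver reaction balances elements and charge", {
  db <- liver_db()
  for (beta in c(FALSE, TRUE)) {
    model <- build_liver_model(beta_oxidation = beta, db = db)
    for (nd in model$nodes) {
      for (rx in nd$reactions) {
        res <- validate_reaction_balance(rx$stoichiometry, db)
        expect_true(all(abs(res) < 1e-9),
                    info = paste(nd$node_id, rx$reaction_id))
      }
    }
  }
})

test_that("thermo TSV reader round-trips and validates", {
  db <- liver_db()
  expect_gt(n_species(db), 50)
  path <- tempfile(fileext = ".tsv")
  write_thermo_tsv(db, path)
  db2 <- read_thermo_tsv(path)
  expect_equal(as.data.frame(db2), as.data.frame(db))
  expect_error(db_lookup(db, "unobtainium"), "unobtainium")
  bad <- as.data.frame(db)
  bad$sd_kj_mol[1] <- -1
  expect_error(thermo_db(bad), "non-negative")
  dup <- as.data.frame(db)
  dup$species_id[2] <- dup$species_id[1]
  expect_error(thermo_db(dup), "duplicate")
})
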