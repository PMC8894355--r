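test_that("reaction strings parse with rational coefficients", {
  st <- parse_reaction_string("gly + 2 atp + glu + cys -> 2 adp + 2 pi + gsh + 2 h")
  expect_equal(st[["atp"]], -2)
  expect_equal(st[["gsh"]], 1)
  st2 <- parse_reaction_string("nadh + 1/2 o2 -> nad + h2o")
  expect_equal(st2[["o2"]], -0.5)
  rt <- parse_reaction_string(format_reaction_string(st))
  expect_equal(rt[sort(names(rt))], st[sort(names(st))])
  expect_error(parse_reaction_string("a + b"), "arrow")
  expect_error(parse_reaction_string("a -> "), "empty")
  expect_error(reaction("r", "a + b -> a + b"), "reactant and one product")
})

test_that("model construction validates topology and balance", {
  db <- liver_db()
  # transport naming a species absent from an endpoint is rejected
  n1 <- pathway_node("a", list(reaction("r1", "glucose -> f6p")))
  n2 <- pathway_node("b", list(reaction("r2", "f6p -> g6p")))
  expect_error(
    network_model(list(n1, n2),
                  list(transport_link("t", "a", "b", "glucose")),
                  db = db),
    "absent from node")
  # unbalanced reaction caught at validation, named
  bad <- pathway_node("a", list(reaction("broken", "glucose -> pyr")))
  expect_error(network_model(list(bad), db = db), "broken")
  # feedback species must be present
  expect_error(pathway_node("a", list(reaction("r1", "glucose -> f6p")),
                            feedback_links = "oaa"), "feedback")
})

test_that("stoichiometric matrix columns are reaction coefficient vectors", {
  nd <- pathway_node("iso", list(reaction("fwd", "glucose -> f6p")))
  S <- stoichiometric_matrix(nd)
  expect_equal(drop(S[, "fwd"]),
               c(glucose = -1, f6p = 1)[rownames(S)])
  empty <- pathway_node("pool", list(), species_ids = c("glucose"))
  expect_equal(ncol(stoichiometric_matrix(empty)), 0L)
  # liver glycolysis: element-matrix times stoich-matrix vanishes exactly
  db <- liver_db()
  model <- liver_model_cached()
  Sg <- stoichiometric_matrix(model$nodes$glycolysis)
  em <- element_matrix(db, rownames(Sg))
  expect_true(all(abs(em %*% Sg) < 1e-9))
})

test_that("model YAML round-trip is lossless", {
  db <- liver_db()
  model <- liver_model_cached()
  path <- tempfile(fileext = ".yaml")
  save_model(model, path)
  m2 <- load_model(path, db = db)
  expect_identical(names(m2$nodes), names(model$nodes))
  expect_identical(names(m2$transports), names(model$transports))
  expect_identical(m2$entry_node, model$entry_node)
  expect_equal(m2$modes, model$modes)
  for (nid in names(model$nodes)) {
    s1 <- stoichiometric_matrix(model$nodes[[nid]])
    s2 <- stoichiometric_matrix(m2$nodes[[nid]])
    expect_equal(s2[rownames(s1), colnames(s1), drop = FALSE], s1)
  }
  # second serialization is byte-identical
  path2 <- tempfile(fileext = ".yaml")
  save_model(m2, path2)
  expect_identical(readLines(path), readLines(path2))
  expect_error(load_model(tempfile()), "no such model")
})

test_that("packaged model file loads with all liver pathways", {
  db <- liver_db()
  path <- system.file("extdata", "liver_model.yaml", package = "nashmet")
  model <- load_model(path, db = db)
  expect_setequal(
    names(model$nodes),
    c("glutathione", "glycogen", "glycolysis", "fermentation",
      "glutaminolysis", "tca", "oxphos", "urea_cycle", "serine_glycine",
      "citrate_shuttle", "fatty_acid_synthesis"))
  # minimal one-node document
  mini <- tempfile(fileext = ".yaml")
  save_model(network_model(list(pathway_node("solo",
    list(reaction("iso", "g6p -> f6p"))))), mini)
  m <- load_model(mini, db = db)
  expect_length(m$nodes, 1L)
  expect_length(m$transports, 0L)
})

test_that("fatty-acid mode flags gate nodes and links", {
  db <- liver_db()
  off <- build_liver_model(fatty_acid_synthesis = FALSE, db = db)
  expect_false("fatty_acid_synthesis" %in% names(off$nodes))
  expect_false("citrate_shuttle" %in% names(off$nodes))
  expect_false("t_cit" %in% names(off$transports))
  both <- build_liver_model(beta_oxidation = TRUE, db = db)
  expect_true("beta_oxidation" %in% names(both$nodes))
  expect_true("t_butcoa" %in% names(both$transports))
})

test_that("DOT export writes a graph with every transport edge", {
  model <- liver_model_cached()
  path <- tempfile(fileext = ".dot")
  export_dot(model, path)
  txt <- readLines(path)
  expect_true(any(grepl("digraph", txt)))
  n_edges <- sum(grepl("->", txt, fixed = TRUE))
  expect_equal(n_edges, length(model$transports))
})
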