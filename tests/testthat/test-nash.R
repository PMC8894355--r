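test_that("equilibrium initialization reaches a fixed point", {
  fx <- make_isomer_pair(0)
  st <- initialize_equilibrium(fx$model, fx$composition, 298.15, fx$db)
  expect_equal(unname(st$amounts$pair), c(0.5, 0.5), tolerance = 1e-6)
  # idempotence: re-initializing from the output changes nothing
  st2 <- initialize_equilibrium(fx$model,
                                list(pair = st$amounts$pair),
                                298.15, fx$db)
  expect_equal(st2$amounts$pair, st$amounts$pair, tolerance = 1e-5)
  # a vector composition is distributed over carrier nodes
  tx <- make_two_node_transport()
  stv <- initialize_equilibrium(tx$model, c(spa = 1), 298.15, tx$db)
  expect_equal(state_total(stv, "pre") + state_total(stv, "spa") +
                 state_total(stv, "spb"), 1, tolerance = 1e-9)
  # the shared species is split over both carrier nodes before solving
  expect_gt(sum(stv$amounts$sink), 0.4)
  expect_error(initialize_equilibrium(tx$model, c(nosuch = 1), 298.15,
                                      tx$db), "absent from every node")
})

test_that("flush perturbation adds exactly the requested species", {
  st <- scs_init_state()
  model <- liver_model_cached()
  # empty flush is the identity
  expect_identical(perturb(st, numeric(0), model), st)
  flush <- c(gsh = 0.33, adenosine = 0.55, h2o = 5.54)
  p1 <- perturb(st, flush, model)
  changed <- names(which(abs(p1$amounts$glutathione -
                               st$amounts$glutathione) > 0))
  expect_setequal(changed, c("gsh", "adenosine", "h2o"))
  expect_equal(p1$amounts$glutathione[["gsh"]] -
                 st$amounts$glutathione[["gsh"]],
               mM_to_amount(0.33), tolerance = 1e-12)
  # other nodes untouched
  expect_identical(p1$amounts$glycolysis, st$amounts$glycolysis)
  # additivity: double flush equals flushing twice
  p2a <- perturb(p1, flush, model)
  p2b <- perturb(st, 2 * flush, model)
  expect_equal(p2a$amounts$glutathione, p2b$amounts$glutathione,
               tolerance = 1e-12)
  expect_error(perturb(st, c(unobtainium = 1), model), "unobtainium")
})

test_that("a transport-free model terminates in one outer iteration", {
  fx <- make_isomer_pair(-log(2))
  cfg <- scenario_config(temp = 298.15, max_outer = 10L)
  st <- initialize_equilibrium(fx$model, fx$composition, 298.15, fx$db,
                               cfg)
  traj <- run_nash(fx$model, st, cfg, fx$db)
  conv <- attr(traj, "convergence")
  expect_true(conv$converged)
  expect_equal(conv$iterations_used, 1L)
  expect_equal(conv$log$norm, 0)
})

test_that("two-node transport matches a scalar fixed-point oracle", {
  tx <- make_two_node_transport()
  cfg <- scenario_config(temp = 298.15, outer_tol = 1e-8, max_outer = 60L)
  st0 <- initialize_equilibrium(tx$model, tx$composition, 298.15, tx$db,
                                cfg)
  traj <- run_nash(tx$model, st0, cfg, tx$db)
  fin <- attr(traj, "final_state")

  # independent oracle: the same mechanics as scalar recursions.
  # source holds {pre, spa} with x_spa/x_pre -> K1 each visit, then
  # ships all spa; sink accumulates and converts at x_spb/x_spa -> K2.
  rt <- R_GAS * 298.15 / 1000
  K1 <- exp(10 / rt)   # production step, -10 kJ/mol
  K2 <- exp(5 / rt)    # conversion step, -5 kJ/mol
  pre <- st0$amounts$source[["pre"]]
  spa_src <- st0$amounts$source[["spa"]]
  spa_snk <- st0$amounts$sink[["spa"]]
  spb <- st0$amounts$sink[["spb"]]
  tau_old <- 0
  for (iter in 1:60) {
    total <- pre + spa_src
    spa_eq <- total * K1 / (1 + K1)
    pre <- total - spa_eq
    tau <- spa_eq              # ship everything
    spa_src <- 0
    stot <- spa_snk + tau + spb
    spa_snk <- stot / (1 + K2)
    spb <- stot * K2 / (1 + K2)
    if (abs(amount_to_mM(tau - tau_old)) <= 1e-8) break
    tau_old <- tau
  }
  expect_equal(fin$amounts$source[["pre"]], pre, tolerance = 1e-8)
  expect_equal(fin$amounts$sink[["spb"]], spb, tolerance = 1e-8)
  conv <- attr(traj, "convergence")
  expect_true(conv$converged)
  expect_lte(conv$log$norm[conv$iterations_used], 1e-8)
})

test_that("the engine is bit-deterministic", {
  tx <- make_adenylate_toy()
  cfg <- scenario_config(temp = 298.15, max_outer = 15L)
  st0 <- initialize_equilibrium(tx$model, tx$composition, 298.15, tx$db,
                                cfg)
  t1 <- run_nash(tx$model, st0, cfg, tx$db)
  t2 <- run_nash(tx$model, st0, cfg, tx$db)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("adenylate toy conserves the pool while energy charge falls", {
  ad <- make_adenylate_toy()
  cfg <- scenario_config(temp = 298.15, max_outer = 12L)
  st0 <- initialize_equilibrium(ad$model, ad$composition, 298.15, ad$db,
                                cfg)
  pool0 <- state_total(st0, "atp") + state_total(st0, "adp") +
    state_total(st0, "amp")
  traj <- run_nash(ad$model, st0, cfg, ad$db)
  fin <- attr(traj, "final_state")
  pool1 <- state_total(fin, "atp", ad$model) +
    state_total(fin, "adp", ad$model) + state_total(fin, "amp", ad$model)
  expect_equal(pool1, pool0, tolerance = 1e-9)
  # consumption-dominant: EC strictly decreasing over >= 3 iterations
  ec <- traj$energy_charge
  expect_gte(length(ec), 3L)
  expect_true(all(diff(ec[1:min(6, length(ec))]) < 0))
})

test_that("iteration-to-time mapping is the configured linear calibration", {
  cfg <- scs_config()
  expect_equal(iteration_to_time(0, cfg), 0)
  expect_equal(iteration_to_time(6, cfg), 6)      # days
  expect_equal(cfg$time_unit, "day")
  wi <- wi_config()
  expect_equal(iteration_to_time(0:6, wi), seq(0, 30, by = 5))  # minutes
  expect_lte(iteration_to_time(6, wi), 30)
  expect_error(iteration_to_time(-1, cfg), ">= 0")
})

test_that("trajectory CSV carries the reproducibility header", {
  tx <- make_isomer_pair(0)
  cfg <- scenario_config(temp = 298.15)
  st <- initialize_equilibrium(tx$model, tx$composition, 298.15, tx$db,
                               cfg)
  traj <- run_nash(tx$model, st, cfg, tx$db)
  path <- tempfile(fileext = ".csv")
  cpath <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path, cpath)
  expect_match(readLines(path, n = 1), "^# nashmet .*seed=")
  df <- utils::read.csv(path, comment.char = "#")
  expect_true(all(c("iteration", "time", "atp_mM", "transport_norm")
                  %in% names(df)))
  conv_df <- utils::read.csv(cpath, comment.char = "#")
  expect_true(all(c("iteration", "norm", "inner_iters") %in%
                    names(conv_df)))
})

test_that("state JSON round-trips losslessly", {
  st <- scs_init_state()
  path <- tempfile(fileext = ".json")
  write_state_json(st, path)
  st2 <- read_state_json(path)
  expect_equal(st2$amounts, st$amounts, tolerance = 1e-12)
  expect_equal(st2$temp, st$temp)
  expect_error(read_state_json(tempfile()), "no such state")
})
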