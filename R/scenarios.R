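## Scenario runners (static cold storage, warm ischemia) and derived
## observables: adenylate energy charge, pH, NAD+/NADH, concentrations.

#' Adenylate energy charge
#'
#' Atkinson convention:
#' \eqn{EC = (ATP + ADP/2) / (ATP + ADP + AMP)}; 1 means a fully charged
#' adenylate pool, 0 fully depleted.
#'
#' @param atp,adp,amp non-negative amounts (any common unit).
#' @return dimensionless value in \[0, 1\].
#' @examples
#' energy_charge(1, 0, 0)  # 1
#' energy_charge(1, 1, 1)  # 0.5
#' @export
energy_charge <- function(atp, adp, amp) {
  if (any(c(atp, adp, amp) < 0)) stop("adenylate amounts must be >= 0")
  pool <- atp + adp + amp
  if (any(pool <= 0)) stop("zero adenylate pool: energy charge undefined")
  (atp + adp / 2) / pool
}

#' pH of a network state
#'
#' Computed from explicit proton bookkeeping: the total H+ amount over
#' all nodes, converted to mol/L through the volume basis.
#'
#' @param state a `network_state`.
#' @param volume_basis litres per cell.
#' @param h_species id of the proton species (default `"h"`).
#' @return dimensionless pH.
#' @export
compute_ph <- function(state, volume_basis = .VOLUME_BASIS, h_species = "h") {
  h <- state_total(state, h_species)
  if (h <= 0) stop("no positive H+ amount in state: pH undefined")
  conc_mol_l <- h * 1e-12 / volume_basis
  -log10(conc_mol_l)
}

#' Derived observables of a network state
#'
#' Sums each tracked species over all nodes (including amounts in
#' transit on links) and converts to mM.  Ammonia is reported as total
#' NH3 + NH4+.
#'
#' @param state a `network_state`.
#' @param model the owning `network_model`.
#' @param volume_basis litres per cell.
#' @return one-row data.frame: `atp_mM`, `adp_mM`, `amp_mM`,
#'   `energy_charge`, `lactate_mM`, `ammonia_mM`, `urea_mM`, `ph`,
#'   `nad_ratio`.
#' @export
state_observables <- function(state, model, volume_basis = .VOLUME_BASIS) {
  tot <- function(sp) state_total(state, sp, model)
  atp <- tot("atp"); adp <- tot("adp"); amp <- tot("amp")
  nadh <- tot("nadh")
  data.frame(
    atp_mM = amount_to_mM(atp, volume_basis),
    adp_mM = amount_to_mM(adp, volume_basis),
    amp_mM = amount_to_mM(amp, volume_basis),
    energy_charge = if (atp + adp + amp > 0)
      energy_charge(atp, adp, amp) else NA_real_,
    lactate_mM = amount_to_mM(tot("lac"), volume_basis),
    ammonia_mM = amount_to_mM(tot("nh3") + tot("nh4"), volume_basis),
    urea_mM = amount_to_mM(tot("urea"), volume_basis),
    ph = if (tot("h") > 0) compute_ph(state, volume_basis) else NA_real_,
    nad_ratio = if (nadh > 0) tot("nad") / nadh else NA_real_)
}

#' Simulate static cold storage
#'
#' Pipeline: node-wise chemical equilibrium at 4 degrees C, University
#' of Wisconsin solution flush into the entry node, then the
#' Nash-equilibrium outer loop.  Time is mapped at 1 day per outer
#' iteration by default.
#'
#' @param model a `network_model` (see [build_liver_model()]).
#' @param db a [thermo_db()].
#' @param composition initial composition (see
#'   [initialize_equilibrium()]); defaults to the packaged liver
#'   composition when `model` carries one.
#' @param config a [scenario_config()]; defaults to
#'   [scs_config()].
#' @return a `nash_trajectory` (time axis in days).
#' @export
run_scs <- function(model, db, composition = NULL,
                    config = scs_config()) {
  if (is.null(composition)) composition <- attr(model, "composition")
  if (is.null(composition)) stop("no initial composition given")
  state0 <- initialize_equilibrium(model, composition, config$temp, db,
                                   config)
  state0 <- perturb(state0, config$flush, model, config$volume_basis)
  run_nash(model, state0, config, db)
}

#' Simulate warm ischemia
#'
#' Identical pipeline to [run_scs()] but at 37 degrees C and without
#' the preservation-solution flush; glycogenolysis and glycolysis
#' accelerate through the Gibbs-Helmholtz temperature correction alone.
#' Time is mapped at 5 minutes per outer iteration by default.
#'
#' @inheritParams run_scs
#' @return a `nash_trajectory` (time axis in minutes).
#' @export
run_wi <- function(model, db, composition = NULL,
                   config = wi_config()) {
  if (is.null(composition)) composition <- attr(model, "composition")
  if (is.null(composition)) stop("no initial composition given")
  state0 <- initialize_equilibrium(model, composition, config$temp, db,
                                   config)
  state0 <- perturb(state0, config$flush, model, config$volume_basis)
  run_nash(model, state0, config, db)
}

#' Default static cold storage configuration (4 degrees C, UW flush)
#'
#' Flush composition: glutathione 0.33 mM, adenosine 0.55 mM, water
#' 5.54 (basis units read as mM), the University of Wisconsin solution
#' components that matter for ATP regeneration.
#'
#' @param ... overrides passed to [scenario_config()].
#' @return a `scenario_config`.
#' @export
scs_config <- function(...) {
  defaults <- list(temp = 277.15, time_per_iteration = 1, time_unit = "day",
                   flush = c(gsh = 0.33, adenosine = 0.55, h2o = 5.54),
                   max_outer = 80L)
  args <- utils::modifyList(defaults, list(...))
  do.call(scenario_config, args)
}

#' Default warm ischemia configuration (37 degrees C, no flush)
#' @param ... overrides passed to [scenario_config()].
#' @return a `scenario_config`.
#' @export
wi_config <- function(...) {
  defaults <- list(temp = 310.15, time_per_iteration = 5, time_unit = "min",
                   flush = numeric(0), max_outer = 80L)
  args <- utils::modifyList(defaults, list(...))
  do.call(scenario_config, args)
}

#' Least-squares fit of a trajectory
#'
#' Fits either an exponential decay `a * exp(-b * t) + c` or a logistic
#' `a / (1 + exp(-b * (t - t0)))` to `(time, value)` points by nonlinear
#' least squares (Nelder-Mead on the residual sum of squares with a
#' Gauss-Newton polish via [stats::nls()] when it converges).
#'
#' @param times numeric vector of times.
#' @param values numeric vector of observations (same length, >= 3).
#' @param form `"exp_decay"` or `"logistic"`.
#' @return list: `form`, `par` (named parameters), `rss`, `fitted`,
#'   `converged`.
#' @export
fit_trajectory <- function(times, values, form = c("exp_decay", "logistic")) {
  form <- match.arg(form)
  stopifnot(length(times) == length(values))
  if (length(times) < 3L) stop("need at least 3 points")
  if (form == "exp_decay") {
    fn <- function(p, t) p[1] * exp(-exp(p[2]) * t) + p[3]
    p0 <- c(a = max(values) - min(values) + 1e-12, logb = log(0.5),
            c = min(values))
    nm_obj <- function(p) sum((values - fn(p, times))^2)
    opt <- stats::optim(p0, nm_obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    par <- c(a = unname(opt$par[1]), b = unname(exp(opt$par[2])),
             c = unname(opt$par[3]))
    fit <- tryCatch(
      suppressWarnings(
        stats::nls(values ~ a * exp(-b * times) + c,
                   start = as.list(par),
                   control = stats::nls.control(maxiter = 200,
                                                warnOnly = TRUE))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      if (sum(stats::resid(fit)^2) <= opt$value) par <- cf
    }
    fitted <- par[["a"]] * exp(-par[["b"]] * times) + par[["c"]]
  } else {
    fn <- function(p, t) p[1] / (1 + exp(-p[2] * (t - p[3])))
    p0 <- c(a = max(values), b = 1, t0 = stats::median(times))
    opt <- stats::optim(p0, function(p) sum((values - fn(p, times))^2),
                        method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    par <- stats::setNames(opt$par, c("a", "b", "t0"))
    fitted <- fn(par, times)
  }
  rss <- sum((values - fitted)^2)
  list(form = form, par = par, rss = rss, fitted = fitted,
       converged = is.finite(rss))
}

#' Convert a specific content (pmol per mg protein) to mM
#'
#' Experimental ATP assays report pmol per mg protein; converting to an
#' intracellular concentration needs the protein mass per cell and the
#' cell water volume.
#'
#' @param value content in pmol per mg protein.
#' @param protein_per_cell mg protein per cell (default 2e-7, a
#'   literature-style hepatocyte value).
#' @param volume_basis litres per cell.
#' @return concentration in mM.
#' @export
specific_content_to_mM <- function(value, protein_per_cell = 2e-7,
                                   volume_basis = .VOLUME_BASIS) {
  if (protein_per_cell <= 0 || volume_basis <= 0) {
    stop("conversion constants must be positive")
  }
  amount_to_mM(value * protein_per_cell, volume_basis)
}

#' Inverse of [specific_content_to_mM()]
#' @param conc_mM concentration in mM.
#' @inheritParams specific_content_to_mM
#' @return content in pmol per mg protein.
#' @export
mM_to_specific_content <- function(conc_mM, protein_per_cell = 2e-7,
                                   volume_basis = .VOLUME_BASIS) {
  if (protein_per_cell <= 0 || volume_basis <= 0) {
    stop("conversion constants must be positive")
  }
  mM_to_amount(conc_mM, volume_basis) / protein_per_cell
}

#' Plot a trajectory's headline observables
#'
#' Base-graphics 2x2 panel: ATP/ADP/AMP content, energy charge, lactate
#' and ammonia, pH over scenario time.
#'
#' @param x a `nash_trajectory`.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.nash_trajectory <- function(x, ...) {
  config <- attr(x, "config")
  xlab <- paste0("time (", config$time_unit, ")")
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(x$time, cbind(x$atp_mM, x$adp_mM, x$amp_mM),
                    type = "b", pch = 1:3, lty = 1, xlab = xlab,
                    ylab = "content (mM)", main = "adenylates", ...)
  graphics::legend("topright", c("ATP", "ADP", "AMP"), pch = 1:3,
                   col = 1:3, bty = "n")
  graphics::plot(x$time, x$energy_charge, type = "b", xlab = xlab,
                 ylab = "energy charge", main = "energy charge", ...)
  graphics::matplot(x$time, cbind(x$lactate_mM, x$ammonia_mM, x$urea_mM),
                    type = "b", pch = 1:3, lty = 1, xlab = xlab,
                    ylab = "conc (mM)", main = "metabolites", ...)
  graphics::legend("topleft", c("lactate", "ammonia", "urea"), pch = 1:3,
                   col = 1:3, bty = "n")
  graphics::plot(x$time, x$ph, type = "b", xlab = xlab, ylab = "pH",
                 main = "pH", ...)
  invisible(x)
}
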