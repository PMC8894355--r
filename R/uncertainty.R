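## Monte-Carlo propagation of formation-energy uncertainty through full
## network simulations; summary statistics and generalized-gamma fits.

#' Perturb a thermodynamic database within its stated uncertainties
#'
#' Each standard formation energy is replaced by
#' `dgf0 + sd * (2u - 1)` with `u` drawn uniformly from (0, 1]
#' independently per species, so every perturbed value stays within one
#' stated standard deviation of its source.  A truncated-normal
#' alternative (`method = "normal"`, clipped at +/- sd) is available.
#'
#' @param db a [thermo_db()].
#' @param seed integer seed (fully determines the draw).
#' @param method `"uniform"` (default) or `"normal"`.
#' @return a perturbed `thermo_db` of identical shape.
#' @export
sample_formation_energies <- function(db, seed, method = c("uniform",
                                                           "normal")) {
  method <- match.arg(method)
  out <- as.data.frame(db)
  n <- nrow(out)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(as.integer(seed))
  if (method == "uniform") {
    u <- stats::runif(n)            # (0,1) draws; endpoint measure zero
    shift <- out$sd_kj_mol * (2 * u - 1)
  } else {
    z <- stats::rnorm(n)
    shift <- out$sd_kj_mol * pmax(pmin(z, 1), -1)
  }
  out$dgf0_kj_mol <- out$dgf0_kj_mol + shift
  thermo_db(out)
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Percent variance of a Monte-Carlo quantity
#'
#' The summary statistic `100 * variance / average` used for the
#' parameter-uncertainty tables.
#'
#' @param average mean value of the quantity (non-zero).
#' @param variance its variance (same squared units).
#' @return percent variance.
#' @examples
#' percent_variance(0.73101, 5.28047e-8)
#' @export
percent_variance <- function(average, variance) {
  if (any(average == 0)) stop("percent variance undefined for zero average")
  100 * variance / average
}

#' Quartile summary of Monte-Carlo samples
#'
#' Linear-interpolation (type-7) quartiles; both the absolute
#' interquartile range and its ratio to the median are reported.
#'
#' @param samples numeric vector, length >= 4.
#' @return list: `median`, `q1`, `q3`, `iqr_absolute`, `iqr_relative`.
#' @export
interquartile_stats <- function(samples) {
  if (length(samples) < 4L) stop("need at least 4 samples")
  q <- stats::quantile(samples, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3],
       iqr_absolute = q[3] - q[1],
       iqr_relative = if (q[2] != 0) (q[3] - q[1]) / q[2] else NA_real_)
}

## Stacy generalized gamma: density p/theta^d / Gamma(d/p) x^(d-1)
## exp(-(x/theta)^p); p = 1 recovers gamma(shape d, scale theta).
.dgengamma_log <- function(x, d, p, theta) {
  log(p) - (d) * log(theta) - lgamma(d / p) + (d - 1) * log(x) -
    (x / theta)^p
}

#' Fit a generalized gamma distribution by maximum likelihood
#'
#' Three-parameter Stacy form with density proportional to
#' \eqn{x^{d-1} \exp(-(x/\theta)^p)}; `p = 1` recovers the ordinary
#' gamma.  When the extra shape parameter is not supported by the data
#' (likelihood-ratio statistic below 3.84 against the gamma submodel)
#' the gamma fit is returned with `family = "gamma"`.
#'
#' @param samples positive numeric vector, length >= 20.
#' @return list: `family` (`"gengamma"` or `"gamma"`), `shape` (d),
#'   `shape2` (p; 1 for the gamma fallback), `scale` (theta),
#'   `loglik`, `loglik_gamma`, `lrt`.
#' @export
fit_generalized_gamma <- function(samples) {
  if (length(samples) < 20L) stop("need at least 20 samples")
  if (any(samples <= 0)) stop("generalized gamma requires positive samples")
  if (stats::sd(samples) == 0) stop("degenerate (constant) samples")
  ## gamma submodel by method-of-moments start + optim MLE
  m <- mean(samples); v <- stats::var(samples)
  k0 <- m^2 / v; th0 <- v / m
  nll_gamma <- function(par) {
    -sum(stats::dgamma(samples, shape = exp(par[1]),
                       scale = exp(par[2]), log = TRUE))
  }
  og <- stats::optim(log(c(k0, th0)), nll_gamma, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
  gam <- exp(og$par)
  ll_gamma <- -og$value
  nll_gg <- function(par) {
    d <- exp(par[1]); p <- exp(par[2]); theta <- exp(par[3])
    -sum(.dgengamma_log(samples, d, p, theta))
  }
  ogg <- stats::optim(c(og$par[1], 0, og$par[2]), nll_gg,
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  ll_gg <- -ogg$value
  lrt <- 2 * (ll_gg - ll_gamma)
  if (!is.finite(lrt) || lrt < 3.84) {
    list(family = "gamma", shape = gam[1], shape2 = 1, scale = gam[2],
         loglik = ll_gamma, loglik_gamma = ll_gamma,
         lrt = max(lrt, 0))
  } else {
    pars <- exp(ogg$par)
    list(family = "gengamma", shape = pars[1], shape2 = pars[2],
         scale = pars[3], loglik = ll_gg, loglik_gamma = ll_gamma,
         lrt = lrt)
  }
}

#' Monte-Carlo uncertainty propagation through the SCS scenario
#'
#' Runs `n` full static-cold-storage simulations, each with its own
#' perturbed formation-energy database (see
#' [sample_formation_energies()]) but the identical initial state, and
#' summarizes the final-state observables.
#'
#' @param model a `network_model`.
#' @param db the unperturbed [thermo_db()].
#' @param config a [scenario_config()] (default [scs_config()]).
#' @param n number of Monte-Carlo runs (>= 2).
#' @param seed master seed; run `i` uses `seed + i`.
#' @param composition initial composition (default: the model's).
#' @return list of class `uncertainty_result`:
#'   `samples` (data.frame, one row of final observables per converged
#'   run), `table` (an `uncertainty_table` data.frame with average,
#'   variance, percent variance, quartiles and distribution fit per
#'   quantity), `n_failed` (non-converged runs, excluded).
#' @export
run_uncertainty <- function(model, db, config = scs_config(), n = 100L,
                            seed = 1L, composition = NULL) {
  if (n < 2L) stop("need n >= 2 Monte-Carlo runs")
  if (is.null(composition)) composition <- attr(model, "composition")
  ## identical initial state for every run: computed once from the
  ## unperturbed database
  state0 <- initialize_equilibrium(model, composition, config$temp, db,
                                   config)
  state0 <- perturb(state0, config$flush, model, config$volume_basis)
  rows <- vector("list", n)
  failed <- 0L
  for (i in seq_len(n)) {
    db_i <- sample_formation_energies(db, seed = seed + i)
    traj <- tryCatch(run_nash(model, state0, config, db_i),
                     error = function(e) NULL)
    conv <- if (is.null(traj)) NULL else attr(traj, "convergence")
    if (is.null(traj) || !conv$converged) {
      failed <- failed + 1L
      next
    }
    rows[[i]] <- cbind(data.frame(sample_id = i), traj[nrow(traj),
                       c("atp_mM", "adp_mM", "amp_mM", "energy_charge",
                         "lactate_mM", "ammonia_mM", "urea_mM", "ph",
                         "nad_ratio")])
  }
  samples <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(samples) || nrow(samples) < 2L) {
    stop("fewer than 2 converged Monte-Carlo runs (", failed, " failed)")
  }
  quantities <- setdiff(names(samples), "sample_id")
  tab <- do.call(rbind, lapply(quantities, function(q) {
    x <- samples[[q]]
    iq <- if (length(x) >= 4L) interquartile_stats(x) else
      list(median = stats::median(x), q1 = NA_real_, q3 = NA_real_,
           iqr_absolute = NA_real_)
    fit <- tryCatch(fit_generalized_gamma(x), error = function(e) NULL)
    data.frame(quantity = q, average = mean(x), variance = stats::var(x),
               percent_variance = percent_variance(mean(x), stats::var(x)),
               median = iq$median, q1 = iq$q1, q3 = iq$q3,
               iqr = iq$iqr_absolute,
               fit_family = if (is.null(fit)) NA_character_ else fit$family,
               fit_shape = if (is.null(fit)) NA_real_ else fit$shape,
               fit_shape2 = if (is.null(fit)) NA_real_ else fit$shape2,
               fit_scale = if (is.null(fit)) NA_real_ else fit$scale)
  }))
  class(tab) <- c("uncertainty_table", "data.frame")
  structure(list(samples = samples, table = tab, n_failed = failed,
                 n = n, seed = seed),
            class = "uncertainty_result")
}

#' @export
print.uncertainty_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$average <- signif(df$average, 6)
  df$variance <- signif(df$variance, 6)
  df$percent_variance <- signif(df$percent_variance, 6)
  print.data.frame(df[c("quantity", "average", "variance",
                        "percent_variance", "median", "iqr")],
                   row.names = FALSE)
  invisible(x)
}

#' @export
print.uncertainty_result <- function(x, ...) {
  cat("<uncertainty_result> ", nrow(x$samples), " converged runs (",
      x$n_failed, " failed), seed ", x$seed, "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Write Monte-Carlo samples and statistics to CSV
#' @param result an `uncertainty_result`.
#' @param samples_path CSV path for per-run observables.
#' @param stats_path CSV path for the summary table.
#' @return `result`, invisibly.
#' @export
write_uncertainty_csv <- function(result, samples_path, stats_path) {
  hdr <- sprintf("# nashmet %s | n=%d | seed=%d",
                 as.character(utils::packageVersion("nashmet")),
                 result$n, result$seed)
  for (pair in list(list(result$samples, samples_path),
                    list(as.data.frame(result$table), stats_path))) {
    con <- file(pair[[2]], "w")
    writeLines(hdr, con)
    utils::write.csv(pair[[1]], con, row.names = FALSE)
    close(con)
  }
  invisible(result)
}
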