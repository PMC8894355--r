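## Single-node Gibbs free energy minimization over reaction extents.
##
## The node NLP is: minimize G(n)/RT over n = n0 + S %*% xi, n >= 0,
## where G/RT = sum_i n_i (dGf_i(T)/RT + ln x_i) with x = n / sum(n).
## Parameterizing in extents xi makes every elemental balance hold by
## construction, so no explicit balance constraints are needed.  In
## extent space the objective is, up to an additive constant,
##   f(xi) = sum_k xi_k * dG0_k/RT + sum_i n_i ln x_i ,
## which only needs the per-reaction standard changes dG0_k/RT.

.N_FLOOR <- 1e-12  # mole-fraction floor inside the (rescaled) objective

#' Define a single-node Gibbs minimization problem
#'
#' @param n0 named non-negative initial amounts (pmol/cell), one per
#'   node species.
#' @param S stoichiometric matrix (species x reactions), rows matching
#'   `names(n0)`.
#' @param dg0_rt per-reaction dimensionless standard change
#'   \eqn{\Delta G^0(T)/RT}.
#' @param temp absolute temperature, K.
#' @param reversible logical per reaction; `FALSE` constrains the extent
#'   to be non-negative.
#' @return object of class `gibbs_problem`.
#' @export
gibbs_problem <- function(n0, S, dg0_rt, temp = 298.15,
                          reversible = rep(TRUE, ncol(S))) {
  S <- as.matrix(S)
  stopifnot(length(n0) == nrow(S), length(dg0_rt) == ncol(S),
            length(reversible) == ncol(S))
  if (any(!is.finite(n0)) || any(n0 < 0)) {
    stop("initial amounts must be finite and non-negative")
  }
  if (any(!is.finite(dg0_rt))) stop("dg0_rt must be finite")
  structure(list(n0 = n0, S = S, dg0_rt = as.numeric(dg0_rt),
                 temp = temp, reversible = as.logical(reversible)),
            class = "gibbs_problem")
}

#' Dimensionless Gibbs free energy of a species pool
#'
#' Extensive ideal-solution form
#' \eqn{G/RT = \sum_i n_i(\Delta G^0_{f,i}/RT + \ln x_i)} with mole
#' fractions \eqn{x_i = n_i/\sum n} and the convention
#' \eqn{0 \ln 0 \equiv 0}.
#'
#' @param n non-negative amounts.
#' @param dg0_rt_species per-species dimensionless formation terms,
#'   same length as `n`.
#' @return dimensionless scalar.
#' @export
node_gibbs <- function(n, dg0_rt_species) {
  stopifnot(length(n) == length(dg0_rt_species))
  if (any(n < 0)) stop("amounts must be non-negative")
  total <- sum(n)
  if (total <= 0) stop("all-zero amounts: Gibbs energy undefined")
  pos <- n > 0
  sum(n[pos] * (dg0_rt_species[pos] + log(n[pos] / total)))
}

## objective in extent space (up to the constant sum(n0 * g)).  Bound
## violations beyond 1e-9 (scaled units) are an Inf wall for the line
## search; smaller excursions -- the active-set pins keep them at the
## 1e-13 level -- carry a quadratic penalty so the wall never traps an
## iterate sitting numerically on the boundary.
.gibbs_f <- function(xi, prob, feas_tol) {
  n <- prob$n0 + drop(prob$S %*% xi)
  if (any(n < -1e-9)) return(Inf)
  if (any((!prob$reversible) & (xi < -1e-9))) return(Inf)
  nf <- pmax(n, .N_FLOOR)
  pen <- sum(pmin(n, 0)^2) + sum(pmin(xi[!prob$reversible], 0)^2)
  sum(xi * prob$dg0_rt) + sum(nf * log(nf / sum(nf))) + 1e8 * pen
}

.gibbs_grad <- function(xi, prob) {
  n <- prob$n0 + drop(prob$S %*% xi)
  nf <- pmax(n, .N_FLOOR)
  lx <- log(nf / sum(nf))
  prob$dg0_rt + drop(crossprod(prob$S, lx))
}

.gibbs_hess <- function(xi, prob) {
  n <- prob$n0 + drop(prob$S %*% xi)
  nf <- pmax(n, .N_FLOOR)
  DS <- prob$S / nf
  crossprod(prob$S, DS) - tcrossprod(colSums(prob$S)) / sum(nf)
}

#' Minimize a node's Gibbs free energy over reaction extents
#'
#' Primal active-set Newton method.  The problem is first rescaled to
#' unit total amount (the objective is homogeneous of degree one, so
#' the minimizer scales), making floors and tolerances mole-fraction
#' based.  Species whose amounts reach the numerical floor (mole
#' fraction 1e-12) are pinned to zero as equality constraints inside a
#' Newton KKT system and released when their Lagrange multipliers turn
#' the wrong sign; irreversible reactions are pinned the same way at
#' zero extent.  The ideal-mixing entropy terms repel the boundary, so
#' minima are interior unless an equilibrium mole fraction falls below
#' the floor, in which case the species is reported boundary-active.
#'
#' @param problem a [gibbs_problem()].
#' @param tol stationarity tolerance on the reduced gradient
#'   (default 1e-9; the solution contract is 1e-6).
#' @param max_iter iteration cap per solve (default 200).
#' @return object of class `gibbs_solution`: `n_eq` (equilibrium
#'   amounts, tiny negatives clipped to 0), `extents`, `g_rt` (objective
#'   value in extent form), `converged`, `kkt_residual`, `iterations`,
#'   `boundary_active` (species at the floor).
#' @export
minimize_node <- function(problem, tol = 1e-9, max_iter = 200L) {
  prob <- problem
  m <- ncol(prob$S)
  if (sum(prob$n0) <= 0) stop("all-zero initial amounts")
  scale <- sum(prob$n0)
  prob$n0 <- prob$n0 / scale
  feas_tol <- 1e-13
  if (m == 0L) {
    return(structure(list(n_eq = problem$n0, extents = numeric(0),
                          g_rt = scale * .gibbs_f(numeric(0), prob, feas_tol),
                          converged = TRUE, kkt_residual = 0,
                          iterations = 0L,
                          boundary_active = character(0)),
                     class = "gibbs_solution"))
  }
  xi <- numeric(m)
  f <- .gibbs_f(xi, prob, feas_tol)
  iter <- 0L
  g <- .gibbs_grad(xi, prob)
  kkt <- .kkt_residual(xi, g, prob, feas_tol)
  f_stationary <- FALSE
  ## Rounds of (Newton descent on f) + (KKT polish) + (coordinate
  ## probe).  The probe guards against floored-gradient artifacts: when
  ## trace species sit at the amount floor the gradient can report a
  ## large norm although no feasible move improves the objective beyond
  ## machine precision -- such a point is stationary in the objective
  ## and accepted as converged.
  for (round in 1:8) {
    ## phase 1: damped active-set Newton, f-descent line search
    repeat {
      iter <- iter + 1L
      if (kkt <= tol || iter > max_iter) break
      step <- .active_set_step(xi, g, prob, feas_tol)
      if (is.null(step) || sqrt(sum(step^2)) == 0) break
      alpha <- 1
      improved <- FALSE
      for (ls in 1:60) {
        f_new <- .gibbs_f(xi + alpha * step, prob, feas_tol)
        if (is.finite(f_new) && f_new < f - 1e-15 * max(1, abs(f))) {
          xi <- xi + alpha * step
          f <- f_new
          improved <- TRUE
          break
        }
        alpha <- alpha / 2
      }
      if (!improved) break
      g <- .gibbs_grad(xi, prob)
      kkt <- .kkt_residual(xi, g, prob, feas_tol)
    }
    if (kkt <= tol || iter > max_iter) break
    ## phase 2: accept Newton steps on KKT-residual descent (objective
    ## flat to precision along stiff directions near the optimum)
    polish <- 0L
    while (kkt > tol && polish < 60L) {
      polish <- polish + 1L
      step <- .active_set_step(xi, g, prob, feas_tol)
      if (is.null(step) || sqrt(sum(step^2)) == 0) break
      alpha <- 1
      accepted <- FALSE
      for (ls in 1:40) {
        xi_try <- xi + alpha * step
        if (is.finite(.gibbs_f(xi_try, prob, feas_tol))) {
          g_try <- .gibbs_grad(xi_try, prob)
          kkt_try <- .kkt_residual(xi_try, g_try, prob, feas_tol)
          if (kkt_try < kkt) {
            xi <- xi_try; g <- g_try; kkt <- kkt_try
            accepted <- TRUE
            break
          }
        }
        alpha <- alpha / 2
      }
      if (!accepted) break
    }
    f <- .gibbs_f(xi, prob, feas_tol)
    if (kkt <= tol) break
    ## phase 3: coordinate probe
    cd <- .coord_descent(xi, f, g, prob, feas_tol)
    if (is.null(cd)) {
      f_stationary <- TRUE
      break
    }
    xi <- cd$xi
    f <- cd$f
    g <- .gibbs_grad(xi, prob)
    kkt <- .kkt_residual(xi, g, prob, feas_tol)
  }
  n_eq <- prob$n0 + drop(prob$S %*% xi)
  boundary <- names(prob$n0)[n_eq <= .PIN_TOL]
  n_eq <- pmax(n_eq, 0) * scale
  structure(list(n_eq = n_eq,
                 extents = stats::setNames(xi * scale, colnames(prob$S)),
                 g_rt = f * scale, converged = kkt <= 1e-6 || f_stationary,
                 kkt_residual = kkt, iterations = iter,
                 boundary_active = boundary),
            class = "gibbs_solution")
}

.PIN_TOL <- 1e-11  # scaled amount below which a species counts as zero

## One pass of exact coordinate descent: for each reaction (worst
## gradient first) search along its own extent axis, capped at the step
## that exhausts the first reactant in that direction.
.coord_descent <- function(xi, f, g, prob, feas_tol) {
  n <- prob$n0 + drop(prob$S %*% xi)
  ord <- order(-abs(g))
  for (k in ord) {
    if (abs(g[k]) < 1e-12) next
    dir <- -sign(g[k])
    if (!prob$reversible[k] && dir < 0 && xi[k] <= feas_tol) next
    s <- prob$S[, k] * dir
    lim <- if (any(s < 0)) min(n[s < 0] / -s[s < 0]) else 1
    if (!prob$reversible[k] && dir < 0) lim <- min(lim, xi[k])
    if (lim <= 0) next
    alpha <- lim
    for (ls in 1:50) {
      xi_try <- xi
      xi_try[k] <- xi_try[k] + alpha * dir
      f_try <- .gibbs_f(xi_try, prob, feas_tol)
      if (is.finite(f_try) && f_try < f - 1e-15 * max(1, abs(f))) {
        return(list(xi = xi_try, f = f_try))
      }
      alpha <- alpha / 2
    }
  }
  NULL
}

## Constrained Newton step: pins near-zero species (and irreversible
## extents at their bound) as equality constraints in the KKT system
##   [H C'; C 0] [dxi; lambda] = [-g; r],
## driving pinned quantities exactly to zero (r = -current value).
## Multipliers with the wrong sign (constraint no longer binding at the
## optimum) trigger release; species a trial step would push negative
## are pinned and the step recomputed.
.active_set_step <- function(xi, g, prob, feas_tol) {
  n <- prob$n0 + drop(prob$S %*% xi)
  ns <- length(n)
  m <- length(xi)
  H <- .gibbs_hess(xi, prob)
  act_sp <- n <= .PIN_TOL
  act_rx <- (!prob$reversible) & (xi <= feas_tol)
  solve_kkt <- function(act_sp, act_rx) {
    C <- rbind(prob$S[act_sp, , drop = FALSE],
               diag(m)[act_rx, , drop = FALSE])
    r <- c(-n[act_sp], -xi[act_rx])
    nc <- nrow(C)
    K <- rbind(cbind(H + diag(1e-11, m), t(C)),
               cbind(C, diag(-1e-15, nc)))
    sol <- tryCatch(solve(K, c(-g, r), tol = 0), error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    list(step = sol[seq_len(m)],
         lam_sp = sol[m + seq_len(sum(act_sp))],
         lam_rx = sol[m + sum(act_sp) + seq_len(sum(act_rx))])
  }
  for (pass in 1:25) {
    res <- solve_kkt(act_sp, act_rx)
    if (is.null(res)) return(NULL)
    ## release at most one constraint whose multiplier has the wrong
    ## sign (mu = -lambda must be >= 0 for an active n_i >= 0 bound)
    rel_tol <- 1e-7
    lam_all <- c(res$lam_sp, res$lam_rx)
    if (length(lam_all) && max(lam_all) > rel_tol) {
      sp_idx <- which(act_sp)
      rx_idx <- which(act_rx)
      labels <- c(paste0("s", sp_idx), paste0("r", rx_idx))
      worst <- labels[which.max(lam_all)]
      if (startsWith(worst, "s")) {
        act_sp[as.integer(substring(worst, 2))] <- FALSE
      } else {
        act_rx[as.integer(substring(worst, 2))] <- FALSE
      }
      next
    }
    ## pin species the full step would push below zero
    n_new <- n + drop(prob$S %*% res$step)
    viol_sp <- (n_new < -.PIN_TOL) & !act_sp & (n <= 100 * .PIN_TOL)
    viol_rx <- (!prob$reversible) & (xi + res$step < -feas_tol) & !act_rx &
      (xi <= 100 * feas_tol)
    if (any(viol_sp) || any(viol_rx)) {
      act_sp <- act_sp | viol_sp
      act_rx <- act_rx | viol_rx
      next
    }
    return(res$step)
  }
  res <- solve_kkt(act_sp, act_rx)
  if (is.null(res)) NULL else res$step
}

## Non-negative least squares (Lawson-Hanson active set), small dense
## problems only: minimize ||A x - b||_2 subject to x >= 0.
.nnls <- function(A, b, max_pass = 200L) {
  p <- ncol(A)
  x <- numeric(p)
  passive <- logical(p)
  w <- drop(crossprod(A, b - A %*% x))
  pass <- 0L
  while (any(!passive & w > 1e-12) && pass < max_pass) {
    pass <- pass + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      z <- numeric(p)
      z[passive] <- tryCatch(
        qr.solve(A[, passive, drop = FALSE], b),
        error = function(e) rep(0, sum(passive)))
      if (all(z[passive] > 0)) { x <- z; break }
      neg <- passive & (z <= 0)
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & (x <= 1e-14)] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) break
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

## First-order optimality residual: min over multipliers mu >= 0 on the
## active bounds of || g - C' mu ||_inf, solved by non-negative least
## squares.
.kkt_residual <- function(xi, g, prob, feas_tol) {
  n <- prob$n0 + drop(prob$S %*% xi)
  m <- length(xi)
  act_sp <- n <= .PIN_TOL
  act_rx <- (!prob$reversible) & (xi <= feas_tol)
  C <- rbind(prob$S[act_sp, , drop = FALSE],
             diag(m)[act_rx, , drop = FALSE])
  if (nrow(C) == 0L) return(if (m) max(abs(g)) else 0)
  mu <- .nnls(t(C), g)
  max(abs(g - drop(t(C) %*% mu)))
}

#' @export
print.gibbs_solution <- function(x, ...) {
  cat("<gibbs_solution> G/RT = ", format(x$g_rt, digits = 10),
      if (x$converged) "  (converged)" else "  (NOT converged)",
      "\n", sep = "")
  cat("  kkt residual: ", format(x$kkt_residual, digits = 4),
      ", iterations: ", x$iterations, "\n", sep = "")
  if (length(x$boundary_active)) {
    cat("  boundary-active species: ",
        paste(x$boundary_active, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Brute-force grid search for small equilibrium problems
#'
#' Independent test oracle: exhaustively evaluates the Gibbs objective
#' over a dense grid on the feasible extent box.  Supports at most two
#' reactions.
#'
#' @param problem a [gibbs_problem()] with <= 2 reactions.
#' @param grid points per extent dimension (default 201).
#' @param refine number of zoom passes: after each pass the grid is
#'   rebuilt on a box of +/- 2 grid steps around the incumbent minimum
#'   (still exhaustive, so the oracle stays search-based).
#' @return a `gibbs_solution` (grid minimum; `kkt_residual` is `NA`).
#' @export
brute_force_equilibrium <- function(problem, grid = 201L, refine = 0L) {
  prob <- problem
  m <- ncol(prob$S)
  if (m > 2L) stop("brute_force_equilibrium supports at most 2 reactions")
  feas_tol <- 1e-13 * max(1, sum(prob$n0))
  if (m == 0L) return(minimize_node(problem))
  ## box guaranteed to contain the feasible polytope: with several
  ## reactions one extent can replenish a species and extend another's
  ## range beyond its single-reaction bound, so use a generous mass
  ## bound rather than per-reaction ratios (infeasible grid points
  ## evaluate to +Inf and drop out)
  lo <- hi <- numeric(m)
  for (k in seq_len(m)) {
    s <- prob$S[, k]
    hi[k] <- 2 * sum(prob$n0) / min(abs(s[s != 0]))
    lo[k] <- if (!prob$reversible[k]) 0 else -hi[k]
  }
  lo0 <- lo; hi0 <- hi
  best_f <- Inf
  best_xi <- numeric(m)
  for (pass in seq_len(1L + max(0L, refine))) {
    axes <- lapply(seq_len(m), function(k) seq(lo[k], hi[k],
                                               length.out = grid))
    if (m == 1L) {
      for (a in axes[[1]]) {
        f <- .gibbs_f(a, prob, feas_tol)
        if (f < best_f) { best_f <- f; best_xi <- a }
      }
    } else {
      for (a in axes[[1]]) for (b in axes[[2]]) {
        f <- .gibbs_f(c(a, b), prob, feas_tol)
        if (f < best_f) { best_f <- f; best_xi <- c(a, b) }
      }
    }
    step <- (hi - lo) / (grid - 1)
    lo <- pmax(lo0, best_xi - 2 * step)
    hi <- pmin(hi0, best_xi + 2 * step)
  }
  n_eq <- pmax(prob$n0 + drop(prob$S %*% best_xi), 0)
  structure(list(n_eq = n_eq,
                 extents = stats::setNames(best_xi, colnames(prob$S)),
                 g_rt = best_f, converged = TRUE, kkt_residual = NA_real_,
                 iterations = grid^m, boundary_active = character(0)),
            class = "gibbs_solution")
}
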