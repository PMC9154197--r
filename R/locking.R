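#' Stroboscopic map of the phase equation
#'
#' Advances the phase by one forcing period `T` (or `q*T` for the composed
#' map) by integrating the phase equation; returns both the wrapped phase
#' and the unwrapped lift.  For a symbolic [pulse_train()] the map is the
#' closed form `theta + T + A*T*Z_ei(theta)`, with no integration.
#'
#' @param theta initial phase (time units; interpreted as a lift value).
#' @param iprc a `ping_iprc`.
#' @param forcing a [forcing_spec()] whose combined drive has period `T`, or
#'   a [pulse_train()].
#' @param T the forcing period (ms); required for `pulse_train`, otherwise
#'   taken from the first input if missing.
#' @param q compose the map `q` times.
#' @param tol phase-integration tolerance.
#' @param deriv also return `dP^q/dtheta` from the variational equation.
#' @return List with `theta` (wrapped to `[0, T*)`), `lift`, and optionally
#'   `deriv`.
#' @export
stroboscopic_map <- function(theta, iprc, forcing, T = NULL, q = 1,
                             tol = 1e-10, deriv = FALSE) {
  if (inherits(forcing, "pulse_train")) {
    A <- forcing$A; Tp <- forcing$T
    th <- theta; dv <- 1
    for (k in seq_len(q)) {
      if (deriv) dv <- dv * (1 + A * Tp * periodic_hermite(
        th, iprc$dZei, iprc$d2Zei, iprc$Tstar))
      th <- th + Tp + A * Tp * iprc_eval(iprc, th)
    }
    return(list(theta = th %% iprc$Tstar, lift = th,
                deriv = if (deriv) dv else NULL))
  }
  if (is.null(T)) T <- forcing$inputs[[1]]$T
  fl <- phase_flow(theta, 0, q * T, numeric(0), iprc, forcing,
                   tol = tol, with_var = deriv)
  list(theta = fl$theta_end %% iprc$Tstar, lift = fl$theta_end,
       deriv = if (deriv) fl$v_end else NULL)
}

# weighted Birkhoff average of the lift increments: the exponential bump
# weights give superpolynomial convergence for irrational rotation and do
# no harm on plateaus.
wba_rotation <- function(lift) {
  d <- diff(lift)
  N <- length(d)
  x <- seq_len(N) / (N + 1)
  w <- exp(-1 / (x * (1 - x)))
  sum(w * d) / sum(w)
}

#' Rotation number of the stroboscopic map
#'
#' Average phase advance per iterate of the time-`T` map, computed from one
#' continuous integration of the phase equation (the lift is accumulated
#' from the monotone ODE solution, never reconstructed from wrapped values)
#' with weighted-Birkhoff convergence acceleration.  The normalized rotation
#' number `rho_hat = rho / T*` reads `p/q` on a `p:q` plateau.
#'
#' @param iprc a `ping_iprc`.
#' @param forcing a [forcing_spec()] with combined period `T`, or a
#'   [pulse_train()].
#' @param T forcing period; defaults to the first input's period.
#' @param N number of iterates (default 750).
#' @param theta0 initial phase.
#' @param tol phase-integration tolerance.
#' @return List of class `rotation_result`: `rho_hat`, `rho` (time units),
#'   `N`, `lift`.
#' @export
rotation_number <- function(iprc, forcing, T = NULL, N = 750, theta0 = 0,
                            tol = 1e-10) {
  if (inherits(forcing, "pulse_train")) {
    T <- forcing$T
    lift <- numeric(N + 1); lift[1] <- theta0
    th <- theta0
    for (k in seq_len(N)) {
      th <- th + T + forcing$A * T * iprc_eval(iprc, th)
      lift[k + 1] <- th
    }
  } else {
    if (is.null(T)) T <- forcing$inputs[[1]]$T
    fl <- phase_flow(theta0, 0, N * T, (0:N) * T, iprc, forcing, tol = tol)
    lift <- fl$theta
  }
  rho <- wba_rotation(lift)
  structure(list(rho_hat = rho / iprc$Tstar, rho = rho, N = N,
                 theta0 = theta0, lift = lift),
            class = "rotation_result")
}

#' @export
print.rotation_result <- function(x, ...) {
  cat(sprintf("rotation number: rho_hat = %.8f (N = %d iterates)\n",
              x$rho_hat, x$N))
  invisible(x)
}

# single von Mises forcing helper used by the scan functions
vm_forcing <- function(A, T, kappa, mu = 0, target = c("e", "i"))
  forcing_spec(von_mises_input(A = A, T = T, kappa = kappa, mu = mu),
               target = target)

#' Devil's staircase: rotation number versus forcing period
#'
#' @param iprc a `ping_iprc`.
#' @param A input strength.
#' @param kappa input coherence.
#' @param T_rel grid of `T/T*` values (sorted).
#' @param N iterates per rotation number.
#' @param tol phase-integration tolerance.
#' @param target populations receiving the drive.
#' @return data.frame with columns `T_rel`, `rho_hat`.
#' @export
devils_staircase <- function(iprc, A, kappa, T_rel, N = 750, tol = 1e-9,
                             target = c("e", "i")) {
  stopifnot(!is.unsorted(T_rel))
  rho <- vapply(T_rel, function(tr) {
    rotation_number(iprc, vm_forcing(A, tr * iprc$Tstar, kappa,
                                     target = target),
                    N = N, tol = tol)$rho_hat
  }, numeric(1))
  data.frame(T_rel = T_rel, rho_hat = rho)
}

#' Plateau interval of a p:q locking on the staircase
#'
#' Scans the rotation number over a `T/T*` grid, finds the maximal
#' contiguous run with `|rho_hat - p/q| < tol`, and sharpens both edges by
#' bisection between the bracketing grid points.
#'
#' @param iprc a `ping_iprc`.
#' @param A,kappa forcing strength and coherence.
#' @param p,q locking ratio.
#' @param T_range scanned `T/T*` interval.
#' @param step grid step in `T/T*` (default 0.002).
#' @param tol plateau tolerance on `rho_hat` (default 1e-4).
#' @param refine_tol bisection tolerance on the edge location.
#' @param N iterates per rotation number.
#' @param target populations receiving the drive.
#' @return List with `left`, `right` (plateau edges in `T/T*`) and the
#'   `staircase` scan; `NULL` edges if the plateau is not found.
#' @export
plateau_interval <- function(iprc, A, kappa, p = 1, q = 1,
                             T_range = c(0.8, 1.2), step = 0.002,
                             tol = 1e-4, refine_tol = 5e-4, N = 750,
                             target = c("e", "i")) {
  grid <- seq(T_range[1], T_range[2], by = step)
  sc <- devils_staircase(iprc, A, kappa, grid, N = N, target = target)
  on_pl <- abs(sc$rho_hat - p / q) < tol
  if (!any(on_pl))
    return(list(left = NULL, right = NULL, staircase = sc))
  runs <- rle(on_pl)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  k <- which(runs$values)[which.max(runs$lengths[runs$values])]
  i1 <- starts[k]; i2 <- ends[k]

  rho_at <- function(tr) rotation_number(
    iprc, vm_forcing(A, tr * iprc$Tstar, kappa, target = target),
    N = N)$rho_hat
  bisect_edge <- function(t_in, t_out) {
    while (abs(t_out - t_in) > refine_tol) {
      mid <- (t_in + t_out) / 2
      if (abs(rho_at(mid) - p / q) < tol) t_in <- mid else t_out <- mid
    }
    (t_in + t_out) / 2
  }
  left <- if (i1 > 1) bisect_edge(grid[i1], grid[i1 - 1]) else grid[i1]
  right <- if (i2 < length(grid)) bisect_edge(grid[i2], grid[i2 + 1]) else
    grid[i2]
  list(left = left, right = right, staircase = sc)
}

# --- Arnold tongue boundaries -----------------------------------------------

# G(w) = (P^q(theta) - theta - p T*, dP^q/dtheta - 1), w = (theta, T, A)
tongue_G <- function(w, p, q, iprc, kappa, tol = 1e-10, target = c("e", "i")) {
  th <- w[1]; T <- w[2]; A <- w[3]
  sm <- stroboscopic_map(th, iprc, vm_forcing(A, T, kappa, target = target),
                         T = T, q = q, tol = tol, deriv = TRUE)
  c(sm$lift - th - p * iprc$Tstar, sm$deriv - 1)
}

tongue_G_jac <- function(w, p, q, iprc, kappa, tol = 1e-10,
                         target = c("e", "i")) {
  h <- c(1e-6 * iprc$Tstar, 1e-6 * iprc$Tstar, 1e-7)
  J <- matrix(0, 2, 3)
  for (j in 1:3) {
    wp <- w; wm <- w
    wp[j] <- w[j] + h[j]; wm[j] <- w[j] - h[j]
    J[, j] <- (tongue_G(wp, p, q, iprc, kappa, tol, target) -
               tongue_G(wm, p, q, iprc, kappa, tol, target)) / (2 * h[j])
  }
  J
}

newton_tongue <- function(w, p, q, iprc, kappa, fixed = NULL, tol = 1e-10,
                          gtol = 1e-10, max_iter = 12, tangent = NULL,
                          target = c("e", "i")) {
  # fixed: index held constant (corrector in the remaining 2 variables);
  # tangent: bordered pseudo-arclength corrector row
  for (it in seq_len(max_iter)) {
    G <- tongue_G(w, p, q, iprc, kappa, tol, target)
    if (max(abs(G)) < gtol) return(list(w = w, ok = TRUE, G = G))
    J <- tongue_G_jac(w, p, q, iprc, kappa, tol, target)
    if (!is.null(fixed)) {
      free <- setdiff(1:3, fixed)
      dz <- tryCatch(solve(J[, free], -G), error = function(e) NULL)
      if (is.null(dz)) return(list(w = w, ok = FALSE))
      w[free] <- w[free] + dz
    } else {
      A <- rbind(J, tangent)
      dz <- tryCatch(solve(A, c(-G, 0)), error = function(e) NULL)
      if (is.null(dz)) return(list(w = w, ok = FALSE))
      w <- w + dz
    }
  }
  G <- tongue_G(w, p, q, iprc, kappa, tol, target)
  list(w = w, ok = max(abs(G)) < gtol, G = G)
}

#' Closed-form Arnold tongue boundaries for pulsatile input
#'
#' In the delta-train (`kappa -> infinity`) limit the stroboscopic map is
#' explicit and the `p:q` tongue boundaries are straight lines
#' `T*/T = (q/p) (1 + A * Z)` with `Z` the maximum (left boundary) or
#' minimum (right boundary) of `Z_ei`.
#'
#' @param p,q locking ratio.
#' @param iprc a `ping_iprc`.
#' @param A_max largest amplitude on the boundary curves.
#' @param nA number of amplitude samples.
#' @return Object of class `arnold_tongue` with `left` and `right`
#'   data.frames (`T_over_Tstar`, `A`, `theta`).
#' @export
pulsatile_tongue_analytic <- function(p, q, iprc, A_max = 0.2, nA = 101) {
  A <- seq(0, A_max, length.out = nA)
  Zmax <- max(iprc$Zei); Zmin <- min(iprc$Zei)
  th_max <- iprc$theta[which.max(iprc$Zei)]
  th_min <- iprc$theta[which.min(iprc$Zei)]
  left <- data.frame(T_over_Tstar = (p / q) / (1 + A * Zmax), A = A,
                     theta = th_max)
  right <- data.frame(T_over_Tstar = (p / q) / (1 + A * Zmin), A = A,
                      theta = th_min)
  structure(list(p = p, q = q, left = left, right = right,
                 provenance = "analytic-pulsatile", kappa = Inf,
                 Tstar = iprc$Tstar),
            class = "arnold_tongue")
}

#' Arnold tongue boundaries by numerical continuation
#'
#' The `p:q` tongue boundaries are loci of saddle-node bifurcations of the
#' composed stroboscopic map: `P^q(theta) = theta + p T*` and
#' `dP^q/dtheta = 1`.  Starting from a seed near the tip, both boundary
#' curves are traced in `(theta, T, A)` by pseudo-arclength continuation
#' with a bordered Newton corrector; the map derivative comes from the
#' variational equation of the phase ODE, which uses the FFT-based
#' derivative of the iPRC.
#'
#' @param p,q locking ratio.
#' @param iprc a `ping_iprc`.
#' @param kappa forcing coherence.
#' @param A_max continue until this amplitude.
#' @param A_start seed amplitude.
#' @param ds0,ds_max initial and maximal arclength steps.
#' @param gtol Newton tolerance on `G`.
#' @param target populations receiving the drive.
#' @return Object of class `arnold_tongue` (`left`, `right` data.frames with
#'   `T_over_Tstar`, `A`, `theta`, plus `status` per side).
#' @export
tongue_boundary_continuation <- function(p, q, iprc, kappa, A_max = 0.2,
                                         A_start = 0.005, ds0 = 1e-3,
                                         ds_max = 1e-2, gtol = 1e-10,
                                         target = c("e", "i")) {
  Tstar <- iprc$Tstar
  sides <- list(left = which.max(iprc$Zei), right = which.min(iprc$Zei))
  out <- list(p = p, q = q, provenance = "continuation", kappa = kappa,
              Tstar = Tstar)
  for (side in names(sides)) {
    Zext <- iprc$Zei[sides[[side]]]
    th0 <- iprc$theta[sides[[side]]]
    T0 <- (p / q) * Tstar / (1 + A_start * Zext)  # pulsatile-limit seed
    sol <- newton_tongue(c(th0, T0, A_start), p, q, iprc, kappa,
                         fixed = 3, gtol = gtol, target = target)
    if (!sol$ok) {
      # fall back: seed from a small staircase bracket at A_start
      pl <- plateau_interval(iprc, A_start, kappa, p, q,
                             T_range = (p / q) * c(0.9, 1.1), step = 0.002,
                             target = target)
      Tseed <- if (side == "left") pl$left else pl$right
      if (!is.null(Tseed))
        sol <- newton_tongue(c(th0, Tseed * Tstar, A_start), p, q, iprc,
                             kappa, fixed = 3, gtol = gtol, target = target)
    }
    if (!sol$ok) {
      out[[side]] <- data.frame(T_over_Tstar = numeric(0), A = numeric(0),
                                theta = numeric(0))
      out[[paste0(side, "_status")]] <- "seed failed"
      next
    }
    # scale (theta, T) by T* so arclength treats coordinates comparably
    scale <- c(Tstar, Tstar, 1)
    w <- sol$w
    pts <- list(w)
    tang_prev <- NULL
    ds <- ds0
    status <- "reached A_max"
    while (tail(pts, 1)[[1]][3] < A_max) {
      J <- tongue_G_jac(w, p, q, iprc, kappa, target = target)
      Js <- J * rep(scale, each = 2)
      tv <- svd(Js, nu = 0, nv = 3)$v[, 3]
      if (!is.null(tang_prev) && sum(tv * tang_prev) < 0) tv <- -tv
      if (is.null(tang_prev) && tv[3] < 0) tv <- -tv  # head toward larger A
      tang_prev <- tv
      repeat {
        wp <- w + ds * tv * scale
        sol <- newton_tongue(wp, p, q, iprc, kappa,
                             tangent = tv / scale, gtol = gtol,
                             target = target)
        if (sol$ok) break
        ds <- ds / 2
        if (ds < 1e-6) break
      }
      if (!sol$ok) { status <- "step underflow"; break }
      w <- sol$w
      pts <- c(pts, list(w))
      ds <- min(ds * 1.4, ds_max)
      if (length(pts) > 3000) { status <- "max points"; break }
    }
    m <- do.call(rbind, pts)
    out[[side]] <- data.frame(T_over_Tstar = m[, 2] / Tstar, A = m[, 3],
                              theta = m[, 1] %% Tstar)
    out[[paste0(side, "_status")]] <- status
  }
  structure(out, class = "arnold_tongue")
}

#' @export
print.arnold_tongue <- function(x, ...) {
  cat(sprintf("%d:%d Arnold tongue (%s, kappa = %g)\n", x$p, x$q,
              x$provenance, x$kappa))
  for (s in c("left", "right")) {
    b <- x[[s]]
    if (nrow(b))
      cat(sprintf("  %s boundary: %d points, A in [%g, %g], T/T* %.4f -> %.4f\n",
                  s, nrow(b), min(b$A), max(b$A),
                  b$T_over_Tstar[1], b$T_over_Tstar[nrow(b)]))
  }
  invisible(x)
}

#' Interpolate tongue boundaries at a given amplitude
#' @param tongue an `arnold_tongue`.
#' @param A amplitude.
#' @return `c(left, right)` boundary positions in `T/T*`.
#' @export
tongue_section <- function(tongue, A) {
  gi <- function(b) stats::approx(b$A, b$T_over_Tstar, xout = A,
                                  ties = "ordered")$y
  c(left = gi(tongue$left), right = gi(tongue$right))
}

# --- full-model locking -----------------------------------------------------

#' Locked periodic orbit of the forced full model
#'
#' Newton shooting for a `qT`-periodic orbit of the forced 8-dimensional
#' system, seeded from the unperturbed cycle at a phase predicted by the
#' phase reduction (the attracting fixed point of the stroboscopic map).
#' Stability is read off the monodromy matrix.
#'
#' @param cycle the unperturbed `ping_cycle`.
#' @param forcing a [forcing_spec()] with combined period `T`.
#' @param T forcing period (ms); defaults to the first input's period.
#' @param p,q locking ratio (orbit period is `qT`).
#' @param iprc optional `ping_iprc` used to seed the initial phase.
#' @param x_init optional explicit initial state (overrides the seed).
#' @param settle_periods forced periods integrated from the seed before the
#'   Newton stage, letting the trajectory relax toward the attracting locked
#'   orbit (the strobe stays aligned with the forcing period).
#' @param tol integration tolerance.
#' @param max_iter Newton iterations.
#' @param n_samples samples stored along the locked orbit.
#' @return A `ping_orbit` (fields `x0`, `period`, `T_input`, `states`,
#'   `multipliers`, `converged`, `stable`) or, if shooting fails, a list
#'   with `converged = FALSE` of class `ping_unlocked`.
#' @export
full_model_locking <- function(cycle, forcing, T = NULL, p = 1, q = 1,
                               iprc = NULL, x_init = NULL,
                               settle_periods = 30, tol = 1e-11,
                               max_iter = 25, n_samples = 1024) {
  if (is.null(T)) T <- forcing$inputs[[1]]$T
  if (is.null(x_init)) {
    th <- 0.3 * cycle$period
    if (!is.null(iprc)) {
      for (k in 1:200)
        th <- stroboscopic_map(th, iprc, forcing, T = T, q = q)$theta
    }
    x_init <- as.numeric(interp_cycle(cycle, th))
  }
  pars <- unclass(cycle$params)
  cf <- as_cpp_forcing(forcing)
  x <- as.numeric(x_init)
  if (settle_periods > 0) {
    x <- tryCatch(
      cpp_mf_flow(x, 0, settle_periods * q * T, pars, cf, NULL,
                  1e-10, FALSE)$y,
      error = function(e) x)
  }
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    fl <- tryCatch(cpp_mf_flow(x, 0, q * T, pars, cf, NULL, tol, TRUE),
                   error = function(e) NULL)
    if (is.null(fl)) break
    FX <- fl$y - x
    if (max(abs(FX)) < 1e-9) { converged <- TRUE; M <- fl$M; break }
    dz <- tryCatch(solve(fl$M - diag(8), -FX), error = function(e) NULL)
    if (is.null(dz) || any(!is.finite(dz))) break
    if (max(abs(dz)) > 5) break  # diverging far off the cycle: give up
    x <- x + dz
  }
  if (!converged)
    return(structure(list(converged = FALSE, T_input = T, p = p, q = q),
                     class = "ping_unlocked"))
  mult <- eigen(M, only.values = TRUE)$values
  ts <- seq(0, q * T, length.out = n_samples + 1)[1:n_samples]
  states <- cpp_mf_integrate(x, ts, pars, cf, NULL, tol)
  colnames(states) <- state_names
  structure(list(x0 = setNames(x, state_names), period = q * T, T_input = T,
                 p = p, q = q, t = ts, states = states,
                 forcing = forcing, params = cycle$params,
                 multipliers = mult, converged = TRUE,
                 stable = max(Mod(mult)) < 1 + 1e-7),
            class = "ping_orbit")
}

#' @export
print.ping_orbit <- function(x, ...) {
  cat(sprintf("locked %d:%d orbit, period %.4f ms (input T = %.4f), %s\n",
              x$p, x$q, x$period, x$T_input,
              if (x$stable) "stable" else "unstable"))
  invisible(x)
}

#' @export
print.ping_unlocked <- function(x, ...) {
  cat(sprintf("no locked %d:%d orbit found at T = %.4f ms\n",
              x$p, x$q, x$T_input))
  invisible(x)
}

#' Locking interval of the forced full model
#'
#' Sweeps `T/T*` outward from a point inside the `p:q` tongue, continuing
#' the locked orbit of the full forced system from point to point, and
#' brackets each edge of the locking interval by bisection (an edge is the
#' last `T/T*` with a convergent stable orbit).
#'
#' @param cycle the unperturbed `ping_cycle`.
#' @param iprc a `ping_iprc` (for seeding).
#' @param kappa,A forcing coherence and strength.
#' @param p,q locking ratio.
#' @param T_start starting `T/T*` inside the tongue; defaults to `p/q`
#'   shifted slightly left.
#' @param step sweep step in `T/T*`.
#' @param bisect_tol edge bisection tolerance in `T/T*`.
#' @param target populations receiving the drive.
#' @return List `left`, `right` (edges in `T/T*`) plus the sweep table.
#' @export
locking_interval <- function(cycle, iprc, kappa, A, p = 1, q = 1,
                             T_start = NULL, step = 0.005,
                             bisect_tol = 1e-3, target = c("e", "i")) {
  Tstar <- cycle$period
  if (is.null(T_start)) T_start <- (p / q) * 0.97
  probe <- function(T_rel, x_guess = NULL) {
    fo <- vm_forcing(A, T_rel * Tstar, kappa, target = target)
    ob <- full_model_locking(cycle, fo, T = T_rel * Tstar, p = p, q = q,
                             iprc = if (is.null(x_guess)) iprc else NULL,
                             x_init = x_guess)
    ob
  }
  rows <- list()
  edge <- c(left = NA_real_, right = NA_real_)
  base <- probe(T_start)
  if (!inherits(base, "ping_orbit") || !base$stable)
    stop("T_start is not inside the locked region")
  for (dir in c(-1, 1)) {
    T_in <- T_start; x_in <- base$x0
    repeat {
      T_next <- T_in + dir * step
      ob <- probe(T_next, x_guess = x_in)
      ok <- inherits(ob, "ping_orbit") && ob$stable
      rows <- c(rows, list(data.frame(T_rel = T_next, locked = ok)))
      if (!ok) break
      T_in <- T_next; x_in <- ob$x0
    }
    T_out <- T_in + dir * step
    while (abs(T_out - T_in) > bisect_tol) {
      mid <- (T_in + T_out) / 2
      ob <- probe(mid, x_guess = x_in)
      if (inherits(ob, "ping_orbit") && ob$stable) {
        T_in <- mid; x_in <- ob$x0
      } else T_out <- mid
    }
    edge[if (dir < 0) "left" else "right"] <- (T_in + T_out) / 2
  }
  list(left = edge[["left"]], right = edge[["right"]],
       sweep = do.call(rbind, rows))
}
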