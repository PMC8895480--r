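#' Assemble acceleration-level constraint equations
#'
#' Each inelastic distance constraint `||p_i - p_j||^2 = d^2` is
#' differentiated twice to the acceleration-level form `A qdd = b`.  The row
#' for a node pair is `2 (p_i - p_j)` on node i's columns and the negative on
#' node j's; `b` collects the centripetal term `-2 ||v_i - v_j||^2`.  Ground
#' constraints contribute one row on a single node (anchor velocity and
#' acceleration enter `b`; the supported ground frames are static so those
#' terms are zero).  Baumgarte stabilisation terms `-2*alpha*Cdot - beta^2*C`
#' are folded into `b` to suppress position-level drift, which pure
#' acceleration-level enforcement cannot control.
#'
#' @param system A [system_model()].
#' @param q,qdot Stacked coordinates / velocities (2 per node, node order of
#'   `system$nodes`).
#' @param t Time (for moving ground frames).
#' @param baumgarte Length-2 `c(alpha, beta)` gains in 1/s; `c(0, 0)`
#'   disables stabilisation.
#' @param cache Internal precomputed index cache; rebuilt when `NULL`.
#' @return List with matrix `A` (0 rows when unconstrained) and vector `b`.
#' @export
assemble_constraints <- function(system, q, qdot, t = 0,
                                 baumgarte = c(20, 20), cache = NULL) {
  if (is.null(cache)) cache <- .make_cache(system)
  n <- cache$n
  ncon <- cache$n_inelastic + cache$n_ground
  A <- matrix(0, ncon, 2 * n)
  b <- numeric(ncon)
  if (ncon == 0L) return(list(A = A, b = b))
  al <- baumgarte[1]; be <- baumgarte[2]
  r <- 0L
  for (k in seq_len(cache$n_inelastic)) {
    r <- r + 1L
    i <- cache$con_i[k]; j <- cache$con_j[k]
    ci <- c(2 * i - 1, 2 * i); cj <- c(2 * j - 1, 2 * j)
    dp <- q[ci] - q[cj]; dv <- qdot[ci] - qdot[cj]
    A[r, ci] <- 2 * dp
    A[r, cj] <- -2 * dp
    C <- sum(dp^2) - cache$con_target[k]^2
    Cdot <- 2 * sum(dp * dv)
    b[r] <- -2 * sum(dv^2) - 2 * al * Cdot - be^2 * C
  }
  for (k in seq_len(cache$n_ground)) {
    r <- r + 1L
    i <- cache$gc_i[k]
    ci <- c(2 * i - 1, 2 * i)
    g <- cache$gc_anchor[[k]]
    dp <- q[ci] - g$p; dv <- qdot[ci] - g$v
    A[r, ci] <- 2 * dp
    C <- sum(dp^2) - cache$gc_target[k]^2
    Cdot <- 2 * sum(dp * dv)
    b[r] <- -2 * sum(dv^2) + 2 * sum(dp * g$a) - 2 * al * Cdot - be^2 * C
  }
  list(A = A, b = b)
}

# Moore-Penrose pseudo-inverse via SVD (small dense matrices)
.pinv <- function(X, tol = NULL) {
  s <- svd(X)
  if (is.null(tol)) tol <- max(dim(X)) * max(s$d, 0) * .Machine$double.eps
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Constrained accelerations by the Udwadia-Kalaba equation
#'
#' `qdd = M^-1 Q + M^-1/2 (A M^-1/2)^+ (b - A M^-1 Q)` with `+` the
#' Moore-Penrose pseudo-inverse, so redundant (rank-deficient) constraint
#' sets are handled without modification.  With no constraints the
#' unconstrained accelerations `M^-1 Q` are returned.
#'
#' @param M Inertia: a positive diagonal, given as a vector of diagonal
#'   entries or a diagonal matrix.
#' @param Q Applied (non-constraint) generalized force vector.
#' @param A,b Acceleration-level constraints from [assemble_constraints()].
#' @param tol Relative tolerance for the consistency check `A qdd = b`.
#' @return The acceleration vector.  Inconsistent constraints (b outside the
#'   range of A) raise an error reporting the residual.
#' @export
uk_acceleration <- function(M, Q, A, b, tol = 1e-8) {
  m <- if (is.matrix(M)) diag(M) else as.numeric(M)
  if (any(m <= 0)) stop("inertia must be positive")
  a_free <- Q / m
  if (is.null(A) || nrow(A) == 0L) return(a_free)
  sm <- sqrt(m)
  B <- A / rep(sm, each = nrow(A))                # A M^-1/2
  corr <- .pinv(B) %*% (b - as.vector(A %*% a_free))
  qdd <- a_free + as.vector(corr) / sm
  res <- as.vector(A %*% qdd) - b
  scale <- max(1, max(abs(b)), max(abs(A %*% a_free)))
  if (max(abs(res)) > tol * scale)
    stop("inconsistent constraints: A qdd = b unsatisfiable, residual ",
         format(max(abs(res)), digits = 4))
  qdd
}

# ---- applied load cases -----------------------------------------------------

#' Ramp-and-hold scalar profile
#'
#' @param value Plateau value reached at `ramp_time` and held after.
#' @param ramp_time Ramp duration, s (`0` = step).
#' @return A function of time.
#' @export
ramp_hold <- function(value, ramp_time = 0.05) {
  force(value); force(ramp_time)
  if (ramp_time <= 0) return(function(t) rep(value, length(t)))
  function(t) value * pmin(1, t / ramp_time)
}

#' Define an applied load case
#'
#' @param node_forces List of `list(node = id, force = function(t) c(fx, fy))`.
#' @param body_moments List of `list(nodes = c(a, b), moment = function(t) M)`:
#'   a pure couple `M` (N m, counter-clockwise positive) applied to a rigid
#'   body as an equal-and-opposite force pair on two of its nodes.
#' @return A `load_case` object.
#' @export
load_case <- function(node_forces = list(), body_moments = list()) {
  structure(list(node_forces = node_forces, body_moments = body_moments),
            class = "load_case")
}

# applied generalized forces (everything except constraint reactions)
.system_forces <- function(system, q, qdot, t, load = NULL, cache) {
  n <- cache$n
  Q <- numeric(2 * n)
  if (system$gravity)
    Q[seq(2, 2 * n, by = 2)] <- -9.81 * system$nodes$mass
  for (k in seq_along(system$elastic_links)) {
    l <- system$elastic_links[[k]]
    ca <- cache$link_ca[[k]]
    pa <- q[ca]; va <- qdot[ca]
    cb <- cache$link_cb[[k]]
    if (!is.null(cb)) {
      pb <- q[cb]; vb <- qdot[cb]
    } else {
      g <- cache$link_anchor[[k]]
      pb <- g$p; vb <- g$v
    }
    lf <- .link_axial_force(l, pa, pb, va, vb)
    Q[ca] <- Q[ca] + lf$force_on_a
    if (!is.null(cb)) Q[cb] <- Q[cb] - lf$force_on_a
  }
  for (k in seq_along(system$phrii_units)) {
    u <- system$phrii_units[[k]]
    if (u$inert) next
    ci <- cache$unit_ci[[k]]
    g <- cache$unit_anchor[[k]]
    pf <- phrii_force(u, q[ci], qdot[ci], g$p, g$v)
    Q[ci] <- Q[ci] + pf$force
  }
  if (!is.null(load)) {
    for (nf in load$node_forces) {
      i <- cache$id2idx[[as.character(nf$node)]]
      ci <- c(2 * i - 1, 2 * i)
      Q[ci] <- Q[ci] + nf$force(t)
    }
    for (bm in load$body_moments) {
      ia <- cache$id2idx[[as.character(bm$nodes[1])]]
      ib <- cache$id2idx[[as.character(bm$nodes[2])]]
      ca <- c(2 * ia - 1, 2 * ia); cb <- c(2 * ib - 1, 2 * ib)
      r <- q[cb] - q[ca]
      len2 <- sum(r^2)
      Fpair <- bm$moment(t) / len2 * c(-r[2], r[1])
      Q[cb] <- Q[cb] + Fpair
      Q[ca] <- Q[ca] - Fpair
    }
  }
  Q
}

# precomputed indices and (static-frame) anchor states for the hot loop
.make_cache <- function(system) {
  ids <- as.character(system$nodes$id)
  id2idx <- as.list(seq_along(ids))
  names(id2idx) <- ids
  n <- nrow(system$nodes)
  con_i <- match(system$inelastic$node_a, system$nodes$id)
  con_j <- match(system$inelastic$node_b, system$nodes$id)
  gc_i <- match(system$ground_constraints$node, system$nodes$id)
  gc_anchor <- lapply(seq_len(nrow(system$ground_constraints)), function(k)
    ground_frame_point(system, system$ground_constraints$frame[k],
                       c(system$ground_constraints$ax[k],
                         system$ground_constraints$ay[k]), 0))
  link_ca <- list(); link_cb <- list(); link_anchor <- list()
  for (k in seq_along(system$elastic_links)) {
    l <- system$elastic_links[[k]]
    ia <- id2idx[[as.character(l$node_a)]]
    link_ca[[k]] <- c(2 * ia - 1, 2 * ia)
    if (!is.na(l$node_b)) {
      ib <- id2idx[[as.character(l$node_b)]]
      link_cb[[k]] <- c(2 * ib - 1, 2 * ib)
      link_anchor[k] <- list(NULL)
    } else {
      link_cb[k] <- list(NULL)
      link_anchor[[k]] <- ground_frame_point(system, l$frame, l$anchor, 0)
    }
  }
  unit_ci <- list(); unit_anchor <- list()
  for (k in seq_along(system$phrii_units)) {
    u <- system$phrii_units[[k]]
    i <- id2idx[[as.character(u$node)]]
    unit_ci[[k]] <- c(2 * i - 1, 2 * i)
    unit_anchor[[k]] <- ground_frame_point(system, u$frame, u$ground_anchor, 0)
  }
  list(id2idx = id2idx, n = n, mass2 = rep(system$nodes$mass, each = 2),
       n_inelastic = nrow(system$inelastic), con_i = con_i, con_j = con_j,
       con_target = system$inelastic$target,
       n_ground = nrow(system$ground_constraints), gc_i = gc_i,
       gc_target = system$ground_constraints$target, gc_anchor = gc_anchor,
       link_ca = link_ca, link_cb = link_cb, link_anchor = link_anchor,
       unit_ci = unit_ci, unit_anchor = unit_anchor)
}

# crude stiffness-ratio estimate: max tangent stiffness over mass
.stiffness_estimate <- function(system) {
  kmax <- 0
  for (u in system$phrii_units) {
    if (u$inert) next
    kmax <- max(kmax, max(tangent_stiffness(u$normal_curve,
                                            c(0, u$normal_curve$breakpoints))))
  }
  for (l in system$elastic_links) {
    ks <- max(tangent_stiffness(l$stiffness_curve,
                                c(0, l$stiffness_curve$breakpoints)))
    kmax <- max(kmax, ks / l$rest_length)
  }
  mmin <- min(system$nodes$mass)
  kmax / mmin
}

#' Integrate the constrained system through time
#'
#' Wraps adaptive ODE integration of the first-order state `(q, qdot)` with
#' accelerations from [uk_acceleration()].  `solver_policy = "explicit"`
#' uses an adaptive Runge-Kutta pair (Dormand-Prince 4/5), `"implicit"` a
#' BDF multistep method, and `"auto"` picks the implicit method when the
#' estimated stiffness ratio `max(k/m)` exceeds `stiff_threshold` (stiff
#' contact laws force explicit methods into very small steps).
#'
#' @param system A [system_model()].
#' @param load A [load_case()] or `NULL`.
#' @param t_span Length-2 integration interval, s.
#' @param solver_policy `"auto"`, `"explicit"` or `"implicit"`.
#' @param rtol,atol Solver tolerances.
#' @param baumgarte Stabilisation gains, see [assemble_constraints()].
#' @param n_out Number of saved output samples.
#' @param state Optional initial state list `(q, qdot)`; defaults to the
#'   construction state of the system.
#' @param stiff_threshold Stiffness-ratio estimate (1/s^2) above which the
#'   `"auto"` policy switches to the implicit method.
#' @return A `phrisim_trajectory`: times, state matrix, per-unit normal and
#'   tangential force series, link tensions, lift-off event log, constraint
#'   drift and solver diagnostics (method, accepted steps).
#' @export
integrate_system <- function(system, load = NULL, t_span = c(0, 1),
                             solver_policy = c("auto", "explicit", "implicit"),
                             rtol = 1e-6, atol = 1e-9, baumgarte = c(20, 20),
                             n_out = 201, state = NULL, stiff_threshold = 1e6) {
  solver_policy <- match.arg(solver_policy)
  stopifnot(inherits(system, "system_model"))
  cache <- .make_cache(system)
  n <- nrow(system$nodes)
  if (is.null(state))
    state <- list(q = as.vector(t(as.matrix(system$nodes[, c("x", "y")]))),
                  qdot = as.vector(t(as.matrix(system$nodes[, c("vx", "vy")]))))
  y0 <- c(state$q, state$qdot)
  mass2 <- cache$mass2
  rhs <- function(t, y, parms) {
    q <- y[seq_len(2 * n)]
    v <- y[2 * n + seq_len(2 * n)]
    Q <- .system_forces(system, q, v, t, load, cache)
    con <- assemble_constraints(system, q, v, t, baumgarte, cache)
    qdd <- uk_acceleration(mass2, Q, con$A, con$b)
    list(c(v, qdd))
  }
  method <- switch(solver_policy,
    explicit = "ode45",
    implicit = "bdf",
    auto = if (.stiffness_estimate(system) > stiff_threshold) "bdf" else "ode45")
  times <- seq(t_span[1], t_span[2], length.out = n_out)
  out <- deSolve::ode(y0, times, rhs, NULL, method = method,
                      rtol = rtol, atol = atol)
  istate <- attr(out, "istate")
  steps <- if (!is.null(istate) && length(istate) >= 2) istate[2] else NA_integer_
  traj <- .postprocess_trajectory(system, load, cache, out, n, baumgarte)
  traj$diagnostics <- list(method = method, solver_policy = solver_policy,
                           steps = steps, rtol = rtol, atol = atol)
  traj
}

.postprocess_trajectory <- function(system, load, cache, out, n, baumgarte) {
  times <- out[, 1]
  nt <- length(times)
  nu <- length(system$phrii_units)
  nl <- length(system$elastic_links)
  Fn <- matrix(0, nt, nu)
  Ft <- matrix(0, nt, nu)
  Gap <- matrix(0, nt, nu)
  contact <- matrix(TRUE, nt, nu)
  tension <- matrix(0, nt, nl)
  drift <- numeric(nt)
  for (s in seq_len(nt)) {
    q <- out[s, 1 + seq_len(2 * n)]
    v <- out[s, 1 + 2 * n + seq_len(2 * n)]
    for (k in seq_len(nu)) {
      u <- system$phrii_units[[k]]
      i <- cache$id2idx[[as.character(u$node)]]
      g <- ground_frame_point(system, u$frame, u$ground_anchor, times[s])
      pf <- phrii_force(u, q[c(2 * i - 1, 2 * i)], v[c(2 * i - 1, 2 * i)],
                        g$p, g$v)
      Fn[s, k] <- pf$normal_force
      Ft[s, k] <- pf$tangential_force
      Gap[s, k] <- -pf$delta
      contact[s, k] <- pf$in_contact
    }
    for (k in seq_len(nl)) {
      l <- system$elastic_links[[k]]
      ia <- cache$id2idx[[as.character(l$node_a)]]
      pa <- q[c(2 * ia - 1, 2 * ia)]; va <- v[c(2 * ia - 1, 2 * ia)]
      if (!is.na(l$node_b)) {
        ib <- cache$id2idx[[as.character(l$node_b)]]
        pb <- q[c(2 * ib - 1, 2 * ib)]; vb <- v[c(2 * ib - 1, 2 * ib)]
      } else {
        g <- ground_frame_point(system, l$frame, l$anchor, times[s])
        pb <- g$p; vb <- g$v
      }
      tension[s, k] <- .link_axial_force(l, pa, pb, va, vb)$tension
    }
    if (nrow(system$inelastic)) {
      dmax <- 0
      for (r in seq_len(nrow(system$inelastic))) {
        i <- cache$id2idx[[as.character(system$inelastic$node_a[r])]]
        j <- cache$id2idx[[as.character(system$inelastic$node_b[r])]]
        d <- sqrt(sum((q[c(2 * i - 1, 2 * i)] - q[c(2 * j - 1, 2 * j)])^2))
        dmax <- max(dmax, abs(d - system$inelastic$target[r]))
      }
      drift[s] <- dmax
    }
  }
  events <- list()
  if (nu && nt > 1) {
    labels <- vapply(system$phrii_units, `[[`, character(1), "label")
    for (k in seq_len(nu)) {
      ch <- which(diff(contact[, k]) != 0)
      for (s in ch)
        events <- c(events, list(list(
          time = times[s + 1], unit = labels[k],
          type = if (contact[s + 1, k]) "recontact" else "liftoff")))
    }
  }
  structure(
    list(times = times, states = out[, -1, drop = FALSE],
         normal_force = Fn, tangential_force = Ft, gap = Gap,
         in_contact = contact, link_tension = tension,
         constraint_drift = drift, events = events, n_nodes = n),
    class = "phrisim_trajectory")
}

#' @export
print.phrisim_trajectory <- function(x, ...) {
  cat("<phrisim_trajectory> ", length(x$times), " samples over [",
      format(min(x$times)), ", ", format(max(x$times)), "] s; ",
      length(x$events), " contact events; max constraint drift ",
      format(max(x$constraint_drift), digits = 3), " m\n", sep = "")
  invisible(x)
}

#' Export a trajectory as a long-format data frame
#'
#' @param x A `phrisim_trajectory`.
#' @param ... Unused.
#' @return Data frame with columns `time_s`, `entity_id`, `quantity`, `value`.
#' @export
as.data.frame.phrisim_trajectory <- function(x, ...) {
  nu <- ncol(x$normal_force)
  pieces <- list()
  for (k in seq_len(nu)) {
    pieces[[length(pieces) + 1L]] <- data.frame(
      time_s = x$times, entity_id = paste0("unit_", k),
      quantity = "normal_force_N", value = x$normal_force[, k])
    pieces[[length(pieces) + 1L]] <- data.frame(
      time_s = x$times, entity_id = paste0("unit_", k),
      quantity = "tangential_force_N", value = x$tangential_force[, k])
  }
  for (k in seq_len(ncol(x$link_tension)))
    pieces[[length(pieces) + 1L]] <- data.frame(
      time_s = x$times, entity_id = paste0("link_", k),
      quantity = "tension_N", value = x$link_tension[, k])
  do.call(rbind, pieces)
}

#' Settle the system to steady state under a constant (post-ramp) load
#'
#' Integrates in chunks until the largest nodal speed falls below `v_tol`
#' and the largest net nodal force residual (mass times acceleration) falls
#' below `f_tol`.  Steady-state interface forces are independent of the
#' nodal masses (masses only scale the transient).
#'
#' @param system A [system_model()].
#' @param load A [load_case()] or `NULL`; any ramps should finish before
#'   settling is assessed.
#' @param v_tol Speed tolerance, m/s.
#' @param f_tol Net-force tolerance, N.
#' @param t_max Give up after this simulated time, s.
#' @param chunk Chunk length between convergence checks, s.
#' @inheritParams integrate_system
#' @return List with the equilibrium `state`, per-unit `normal_force`,
#'   `tangential_force`, `gap`, `in_contact`, `link_tension`, the settling
#'   time and solver diagnostics.
#' @export
steady_state <- function(system, load = NULL, v_tol = 1e-5, f_tol = 1e-4,
                         t_max = 20, chunk = 0.25,
                         solver_policy = "auto", rtol = 1e-5, atol = 1e-8,
                         baumgarte = c(20, 20), stiff_threshold = 1e6) {
  cache <- .make_cache(system)
  n <- nrow(system$nodes)
  state <- list(q = as.vector(t(as.matrix(system$nodes[, c("x", "y")]))),
                qdot = as.vector(t(as.matrix(system$nodes[, c("vx", "vy")]))))
  t0 <- 0
  history <- data.frame(t = numeric(), max_speed = numeric(),
                        max_residual = numeric())
  steps_total <- 0
  diag <- NULL
  repeat {
    traj <- integrate_system(system, load, c(t0, t0 + chunk),
                             solver_policy = solver_policy, rtol = rtol,
                             atol = atol, baumgarte = baumgarte, n_out = 11,
                             state = state, stiff_threshold = stiff_threshold)
    diag <- traj$diagnostics
    steps_total <- steps_total + traj$diagnostics$steps
    last <- nrow(traj$states)
    state <- list(q = traj$states[last, seq_len(2 * n)],
                  qdot = traj$states[last, 2 * n + seq_len(2 * n)])
    t0 <- t0 + chunk
    vmax <- max(abs(state$qdot))
    Q <- .system_forces(system, state$q, state$qdot, t0, load, cache)
    con <- assemble_constraints(system, state$q, state$qdot, t0, baumgarte,
                                cache)
    qdd <- uk_acceleration(cache$mass2, Q, con$A, con$b)
    fres <- max(abs(qdd * cache$mass2))
    history <- rbind(history, data.frame(t = t0, max_speed = vmax,
                                         max_residual = fres))
    if (vmax < v_tol && fres < f_tol) break
    if (vmax < 10 * v_tol) {
      # near-settled: polish with tight tolerances so the residual check is
      # not limited by the working integration accuracy
      traj <- integrate_system(system, load, c(t0, t0 + chunk),
                               solver_policy = solver_policy,
                               rtol = min(rtol, 1e-8), atol = min(atol, 1e-11),
                               baumgarte = baumgarte, n_out = 3,
                               state = state, stiff_threshold = stiff_threshold)
      steps_total <- steps_total + traj$diagnostics$steps
      last <- nrow(traj$states)
      state <- list(q = traj$states[last, seq_len(2 * n)],
                    qdot = traj$states[last, 2 * n + seq_len(2 * n)])
      t0 <- t0 + chunk
      vmax <- max(abs(state$qdot))
      Q <- .system_forces(system, state$q, state$qdot, t0, load, cache)
      con <- assemble_constraints(system, state$q, state$qdot, t0, baumgarte,
                                  cache)
      qdd <- uk_acceleration(cache$mass2, Q, con$A, con$b)
      fres <- max(abs(qdd * cache$mass2))
      history <- rbind(history, data.frame(t = t0, max_speed = vmax,
                                           max_residual = fres))
      if (vmax < v_tol && fres < f_tol) break
    }
    if (t0 >= t_max)
      stop("no settling within t_max = ", t_max, " s; residual history:\n",
           paste(utils::capture.output(print(history)), collapse = "\n"))
  }
  nu <- length(system$phrii_units)
  Fn <- numeric(nu); Ft <- numeric(nu); Gp <- numeric(nu); Ic <- logical(nu)
  for (k in seq_len(nu)) {
    u <- system$phrii_units[[k]]
    i <- cache$id2idx[[as.character(u$node)]]
    g <- ground_frame_point(system, u$frame, u$ground_anchor, t0)
    pf <- phrii_force(u, state$q[c(2 * i - 1, 2 * i)],
                      state$qdot[c(2 * i - 1, 2 * i)], g$p, g$v)
    Fn[k] <- pf$normal_force; Ft[k] <- pf$tangential_force
    Gp[k] <- -pf$delta; Ic[k] <- pf$in_contact
  }
  tensions <- numeric(length(system$elastic_links))
  for (k in seq_along(system$elastic_links)) {
    l <- system$elastic_links[[k]]
    ia <- cache$id2idx[[as.character(l$node_a)]]
    pa <- state$q[c(2 * ia - 1, 2 * ia)]
    va <- state$qdot[c(2 * ia - 1, 2 * ia)]
    if (!is.na(l$node_b)) {
      ib <- cache$id2idx[[as.character(l$node_b)]]
      pb <- state$q[c(2 * ib - 1, 2 * ib)]
      vb <- state$qdot[c(2 * ib - 1, 2 * ib)]
    } else {
      g <- ground_frame_point(system, l$frame, l$anchor, t0)
      pb <- g$p; vb <- g$v
    }
    tensions[k] <- .link_axial_force(l, pa, pb, va, vb)$tension
  }
  list(state = state, normal_force = Fn, tangential_force = Ft, gap = Gp,
       in_contact = Ic, link_tension = tensions, settle_time = t0,
       history = history,
       diagnostics = c(diag, list(steps_total = steps_total)))
}

#' Total mechanical energy of the current state
#'
#' Kinetic energy plus elastic potential stored in links and contact units
#' plus gravitational potential when gravity is on.  Elastic potentials use
#' the unsmoothed piecewise-linear laws (exact when curves have
#' `smoothing_halfwidth = 0`), which is how the undamped energy-audit tests
#' are configured.
#'
#' @param system A [system_model()].
#' @param q,qdot State vectors; default the construction state.
#' @return Energy in J.
#' @export
total_energy <- function(system, q = NULL, qdot = NULL) {
  cache <- .make_cache(system)
  n <- nrow(system$nodes)
  if (is.null(q))
    q <- as.vector(t(as.matrix(system$nodes[, c("x", "y")])))
  if (is.null(qdot))
    qdot <- as.vector(t(as.matrix(system$nodes[, c("vx", "vy")])))
  ke <- 0.5 * sum(cache$mass2 * qdot^2)
  pe <- 0
  if (system$gravity)
    pe <- pe + 9.81 * sum(system$nodes$mass * q[seq(2, 2 * n, by = 2)])
  pot_curve <- function(curve, x) {
    if (x <= 0) return(0)
    bp <- curve$breakpoints; sl <- curve$slopes
    cum <- .curve_cumforce(curve)
    i <- findInterval(x, bp)
    e <- 0
    if (i > 1)
      for (s in seq_len(i - 1))
        e <- e + cum[s] * (bp[s + 1] - bp[s]) +
          0.5 * sl[s] * (bp[s + 1] - bp[s])^2
    e + cum[i] * (x - bp[i]) + 0.5 * sl[i] * (x - bp[i])^2
  }
  for (l in system$elastic_links) {
    ia <- cache$id2idx[[as.character(l$node_a)]]
    pa <- q[c(2 * ia - 1, 2 * ia)]
    pb <- if (!is.na(l$node_b)) {
      ib <- cache$id2idx[[as.character(l$node_b)]]
      q[c(2 * ib - 1, 2 * ib)]
    } else ground_frame_point(system, l$frame, l$anchor, 0)$p
    len <- sqrt(sum((pa - pb)^2))
    stretch <- len - l$rest_length
    pe <- pe + l$pretension * stretch +
      l$rest_length * pot_curve(l$stiffness_curve,
                                max(0, stretch / l$rest_length))
  }
  for (u in system$phrii_units) {
    if (u$inert) next
    i <- cache$id2idx[[as.character(u$node)]]
    g <- ground_frame_point(system, u$frame, u$ground_anchor, 0)
    delta <- u$rest_thickness - sum((q[c(2 * i - 1, 2 * i)] - g$p) * u$contact_normal)
    if (delta > 0) pe <- pe + pot_curve(u$normal_curve, delta)
  }
  ke + pe
}
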