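# Independent reference implementations used as oracles.  These deliberately
# avoid the package's own solution paths: constrained accelerations come from
# the KKT (Lagrange-multiplier) linear system instead of the pseudo-inverse
# formula, and the min-peak-pressure optimum from a linear program.

# accelerations from the saddle-point system [M A'; A 0] [qdd; -lambda] = [Q; b]
lm_acceleration <- function(m, Q, A, b) {
  n <- length(Q)
  if (nrow(A) == 0L) return(Q / m)
  K <- rbind(cbind(diag(m, n), t(A)),
             cbind(A, matrix(0, nrow(A), nrow(A))))
  sol <- qr.solve(K, c(Q, b), tol = 1e-13)
  sol[seq_len(n)]
}

# reference trajectory of a constrained point-mass system using deSolve with
# Lagrange-multiplier accelerations and Baumgarte terms assembled by hand
lm_reference_trajectory <- function(masses, q0, v0, con, force_fn, times,
                                    baumgarte = c(20, 20),
                                    rtol = 1e-10, atol = 1e-12) {
  n <- length(q0)
  rhs <- function(t, y, p) {
    q <- y[seq_len(n)]
    v <- y[n + seq_len(n)]
    rows <- lapply(con, function(cn) {
      ia <- cn$i; a <- numeric(n)
      pi <- q[c(2 * ia - 1, 2 * ia)]
      vi <- v[c(2 * ia - 1, 2 * ia)]
      if (is.null(cn$j)) {
        dp <- pi - cn$point; dv <- vi
      } else {
        jb <- cn$j
        dp <- pi - q[c(2 * jb - 1, 2 * jb)]
        dv <- vi - v[c(2 * jb - 1, 2 * jb)]
        a[c(2 * jb - 1, 2 * jb)] <- -2 * dp
      }
      a[c(2 * ia - 1, 2 * ia)] <- 2 * dp
      C <- sum(dp^2) - cn$d^2
      Cd <- 2 * sum(dp * dv)
      list(a = a, b = -2 * sum(dv^2) - 2 * baumgarte[1] * Cd -
             baumgarte[2]^2 * C)
    })
    A <- do.call(rbind, lapply(rows, `[[`, "a"))
    b <- vapply(rows, `[[`, numeric(1), "b")
    Q <- force_fn(t, q, v)
    list(c(v, lm_acceleration(masses, Q, A, b)))
  }
  deSolve::ode(c(q0, v0), times, rhs, NULL, method = "ode45",
               rtol = rtol, atol = atol)
}

# minimum peak line pressure over n free pressure points under force and
# moment balance (linear program, boot::simplex)
lp_min_peak <- function(F_total, M_L, L, n = 15) {
  s <- L / n
  x <- (seq_len(n) - (n + 1) / 2) * s
  a_obj <- c(rep(0, n), 1)
  A1 <- cbind(diag(n), -1)              # p_i <= t
  b1 <- rep(0, n)
  A3 <- rbind(c(rep(s, n), 0), c(x * s, 0))
  b3 <- c(F_total, M_L)
  r <- boot::simplex(a = a_obj, A1 = A1, b1 = b1, A3 = A3, b3 = b3,
                     maxi = FALSE)
  r$value
}

# random valid stiffness curve for property tests
random_curve <- function(n_seg = sample(1:4, 1), smooth = FALSE) {
  bp <- c(0, sort(runif(n_seg - 1, 0.05, 0.95)))
  stiffness_curve(bp, runif(n_seg, 0, 5),
                  smoothing_halfwidth = if (smooth) runif(1, 0, 0.02) else 0)
}

# compact hand scenario used across dynamics/scenario tests
test_hand_system <- function(pretension = 8, ...)
  build_hand_system(hand_geometry(), hand_materials(), pretension = pretension,
                    ...)

settle_opts <- list(rtol = 1e-4, atol = 1e-7)

settle <- function(system, load = NULL, ...)
  do.call(steady_state, c(list(system, load), settle_opts, list(...)))
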