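# Independent dense-matrix integrator of the semi-discrete moving-boundary
# system. Deliberately coded with full matrices and base::solve (no Thomas
# algorithm, no shared code with the package stepper) so it can arbitrate
# the stepper's linear algebra and indexing.
dense_stefan_step <- function(state, p, dt, gamma2_scale = 1,
                              far = c("mirror", "paper")) {
  far <- match.arg(far)
  N <- state$N; h <- state$h; M <- state$M
  cc <- state$c; Z <- state$Z; t <- state$t
  g2 <- gamma2_at(t, p, scale = gamma2_scale)
  c_ghost <- 3 * cc[1] - 3 * cc[2] + cc[3]          # c_{-1}
  grad0 <- (cc[2] - c_ghost) / (2 * h)
  Zdot <- max(0, -grad0 / (g2 * (1 + t / M) * (1 - Z)))
  Z_new <- Z + dt * Zdot
  t_new <- t + dt
  far_ghost <- if (far == "mirror") cc[N + 1] else cc[N]
  cpad <- c(cc, far_ghost)
  adv <- vapply(2:(N + 2), function(j)
    -Zdot * (state$delta[j] - 1) / (1 - Z) *
      (cpad[j + 1] - cpad[j - 1]) / (2 * h), numeric(1))
  rhs <- cc[2:(N + 2)] + dt * adv
  g2n <- gamma2_at(t_new, p, scale = gamma2_scale)
  r <- dt / (g2n * (1 - Z_new)^2 * h^2)
  c0_new <- 1 + t_new / M
  n <- N + 1
  A <- diag(1 + 2 * r, n)
  for (i in 1:(n - 1)) { A[i, i + 1] <- -r; A[i + 1, i] <- -r }
  rhs[1] <- rhs[1] + r * c0_new
  if (far == "mirror") A[n, n - 1] <- A[n, n - 1] - r
  else A[n, n - 2] <- A[n, n - 2] - r
  x <- solve(A, rhs)
  state$t <- t_new; state$Z <- Z_new; state$c <- c(c0_new, x)
  state
}

# noiseless model release curves at the given rates on a uniform grid
make_model_curves <- function(params, rates, n = 100, span = 40) {
  grid <- seq(params$Tph, params$Tph - span, length.out = n)
  lapply(rates, function(B)
    release_curve(grid, latent_heat_fraction(grid, params, B), B))
}
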