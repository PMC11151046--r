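# Independent fixed-step Euler oracles, hand-coded per module (never routed
# through the package's generic network RHS).

# isolated linear module, template fully pre-activated:
#   d omega/dt = k_lin*ato - k_rep*omega*rT - k_deg*omega
#   d rT/dt    = -k_rep*omega*rT ; reacted = rT0 - rT
euler_linear_module <- function(ato, rT0, t_end, dt, p = celia_params(),
                                record_at = NULL) {
  n <- round(t_end / dt)
  omega <- 0
  rT <- rT0
  rec_t <- if (is.null(record_at)) seq(0, t_end, by = 2) else record_at
  out <- matrix(NA_real_, length(rec_t), 3,
                dimnames = list(NULL, c("omega", "rT", "reacted")))
  nxt <- 1L
  t <- 0
  for (i in 0:n) {
    while (nxt <= length(rec_t) && rec_t[nxt] <= t + dt / 2) {
      out[nxt, ] <- c(omega, rT, rT0 - rT)
      nxt <- nxt + 1L
    }
    if (i == n) break
    rep_flux <- p$k_rep * omega * rT
    domega <- p$k_lin * ato - rep_flux - p$k_deg * omega
    omega <- omega + dt * domega
    rT <- rT - dt * rep_flux
    t <- t + dt
  }
  list(times = rec_t, omega = out[, "omega"], rT = out[, "rT"],
       reacted = out[, "reacted"])
}

# exponential switch (alpha, alpha_i) with pseudotemplate inhibition:
#   d alpha/dt = (r+kdeg)*Kexp*alpha/(Kexp+alpha) - kdeact*pT*alpha
#                - kdeg*alpha
euler_exponential <- function(alpha0, pT, t_end, dt, p = celia_params(),
                              record_at = seq(0, t_end, by = 2)) {
  n <- round(t_end / dt)
  a <- alpha0
  out <- numeric(length(record_at))
  nxt <- 1L
  t <- 0
  for (i in 0:n) {
    while (nxt <= length(record_at) && record_at[nxt] <= t + dt / 2) {
      out[nxt] <- a
      nxt <- nxt + 1L
    }
    if (i == n) break
    prod <- (p$r_exp + p$k_deg) * p$K_exp * a / (p$K_exp + a)
    a <- a + dt * (prod - p$k_deact * pT * a - p$k_deg * a)
    t <- t + dt
  }
  list(times = record_at, alpha = out)
}

# relative deviation with an absolute floor
rel_dev <- function(a, b, floor = 1e-9) max(abs(a - b) / (abs(b) + floor))
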