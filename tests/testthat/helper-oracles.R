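# Independent oracles and samplers shared across the suite.
# These deliberately avoid the package's extraction/simulation helpers where
# they serve as the reference side of a dual-route check.

# dense closed-form evaluation of the two-term whole-blood model
dense_wb_amplitude <- function(p, tt, area = 1) {
  s1 <- pmax(tt - p$K_d1, 0); s2 <- pmax(tt - p$K_d2, 0)
  a <- area * (p$K_n1 * (1 - exp(-s1 / p$K_p1)) * (tt >= p$K_d1) -
               p$K_n2 * (1 - exp(-s2 / p$K_p2)) * (tt >= p$K_d2))
  pmax(a, 0)
}

# brute-force TEG properties from a dense grid by plain indexing/argmax
dense_features <- function(tt, amp) {
  dt <- tt[2L] - tt[1L]
  ma_i <- which.max(amp)
  MA <- amp[ma_i]; t_MA <- tt[ma_i]
  cross <- function(level) {
    i <- which(amp >= level)[1L]
    if (is.na(i)) return(NA_real_)
    if (i == 1L) return(tt[1L])
    tt[i - 1L] + (level - amp[i - 1L]) / (amp[i] - amp[i - 1L]) * dt
  }
  R <- cross(2); t20 <- cross(20)
  K <- if (is.na(R) || is.na(t20)) NA_real_ else t20 - R
  alpha <- atan(max(diff(amp) / dt)) * 180 / pi
  Ly30 <- if (tt[length(tt)] >= t_MA + 30 && MA > 0) {
    a30 <- amp[which.min(abs(tt - (t_MA + 30)))]
    min(max(100 * (MA - a30) / MA, 0), 100)
  } else if (MA > 0 && amp[length(amp)] >= MA - 1e-9) 0
  else NA_real_
  list(R = R, K = K, alpha = alpha, MA = MA, t_MA = t_MA, Ly30 = Ly30)
}

# random valid whole-blood parameter sets with ordered delays and gains
sample_wb_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    K_n1 <- stats::runif(1, 40, 80)
    whole_blood_params(
      K_n1 = K_n1,
      K_p1 = stats::runif(1, 4, 12),
      K_d1 = stats::runif(1, 4, 12),
      K_n2 = stats::runif(1, 2, 0.5 * K_n1),
      K_p2 = stats::runif(1, 10, 40),
      K_d2 = stats::runif(1, 16, 42))
  })
}

sample_plasma_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    plasma_params(K_np = stats::runif(1, 20, 80),
                  K_p = stats::runif(1, 2, 15),
                  K_dp = stats::runif(1, 2, 15)))
}

# unit-area triangular pulse of width w (a Dirac approximant centred at w/2)
triangle_pulse <- function(w) {
  suppressWarnings(thrombin_curve(c(0, w / 2, w, 60), c(0, 2 / w, 0, 0)))
}

max_rel_err <- function(a, b) max(abs(a - b)) / max(abs(b))

# delayed-ODE oracle for the plasma response: K_p x'' + x' = K_np y(t - K_dp)
ode_plasma_response <- function(params, input, grid) {
  yfun <- stats::approxfun(input$time, input$thrombin, yleft = 0, yright = 0)
  rhs <- function(t, st, parms) {
    td <- t - params$K_dp
    y <- if (td < input$time[1L] || td > input$time[length(input$time)]) 0
         else yfun(td)
    list(c(st[2L], (params$K_np * y - st[2L]) / params$K_p))
  }
  sol <- deSolve::ode(c(0, 0), grid, rhs, NULL, rtol = 1e-11, atol = 1e-13)
  sol[, 2L]
}

# ODE oracle for one saturating term: dz/dt = (K_n - z)/K_p from t = K_d
ode_sat_term <- function(K_n, K_p, K_d, grid) {
  out <- numeric(length(grid))
  act <- grid >= K_d
  if (any(act)) {
    tt <- c(K_d, grid[act])
    sol <- deSolve::ode(c(z = 0), tt, function(t, st, p)
      list((K_n - st[1L]) / K_p), NULL, rtol = 1e-11, atol = 1e-13)
    out[act] <- sol[-1L, 2L]
  }
  out
}
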