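# Independent oracles used by the dual-route checks. Everything here is
# deliberately naive (dense grids, brute-force enumeration, explicit
# risk-set sums) and shares no code with the package's computation paths.

# classic 4th-order Runge-Kutta solution of the 2TC ODE system, stepping on
# the same grid the input is sampled on (input interpolated linearly)
oracle_rk4_2tc <- function(p, t, cb) {
  f <- approxfun(t, cb)
  deriv <- function(tt, y) c(p$K1 * f(tt) - (p$k2 + p$k3) * y[1] + p$k4 * y[2],
                             p$k3 * y[1] - p$k4 * y[2])
  n <- length(t)
  cf <- cm <- numeric(n)
  y <- c(0, 0)
  for (i in 2:n) {
    h <- t[i] - t[i - 1]
    k1 <- deriv(t[i - 1], y)
    k2 <- deriv(t[i - 1] + h / 2, y + h / 2 * k1)
    k3 <- deriv(t[i - 1] + h / 2, y + h / 2 * k2)
    k4 <- deriv(t[i], y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    cf[i] <- y[1]
    cm[i] <- y[2]
  }
  list(cf = cf, cm = cm)
}

# numerical convolution y(t) = int_0^t g(t - s) f(s) ds by direct trapezoid
# discretization at spacing h and h/2, Richardson-extrapolated to O(h^4);
# returns values on the coarse uniform grid
oracle_conv <- function(impulse, cb_fun, t_end, h = 0.01) {
  direct <- function(step) {
    t2 <- seq(0, t_end, by = step)
    f <- cb_fun(t2)
    g <- impulse(t2)
    n <- length(t2)
    y <- numeric(n)
    for (i in 2:n) {
      integrand <- g[i:1] * f[1:i]
      y[i] <- sum((integrand[-1] + integrand[-i]) / 2) * step
    }
    y
  }
  y_h <- direct(h)
  y_h2 <- direct(h / 2)
  idx <- seq(1, length(y_h2), by = 2)
  (4 * y_h2[idx] - y_h) / 3
}

# brute-force Cox log partial likelihood (Efron ties) by explicit risk-set
# summation; x is a matrix, beta a vector
oracle_cox_loglik <- function(beta, x, time, status) {
  eta <- as.vector(x %*% beta)
  ll <- 0
  for (tt in sort(unique(time[status == 1]))) {
    D <- which(time == tt & status == 1)
    R <- which(time >= tt)
    d <- length(D)
    sum_r <- sum(exp(eta[R]))
    sum_d <- sum(exp(eta[D]))
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1)
      ll <- ll - log(sum_r - l / d * sum_d)
  }
  ll
}

# manual product-limit estimator returning the full step table
oracle_km <- function(time, status) {
  ev <- sort(unique(time[status == 1]))
  s <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (tt in ev) {
    r <- sum(time >= tt)
    d <- sum(time == tt & status == 1)
    s <- s * (1 - d / r)
    out <- rbind(out, data.frame(time = tt, surv = s))
  }
  out
}

# manual two-group log-rank chi-square by observed-minus-expected risk sets
oracle_logrank <- function(time, status, group) {
  g <- as.integer(as.factor(group))
  o_minus_e <- 0
  v <- 0
  for (tt in sort(unique(time[status == 1]))) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == tt & status == 1)
    d1 <- sum(time == tt & status == 1 & g == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# empirical rank statistic (Mann-Whitney with 0.5 tie credit) between cases
# by the horizon and survivors past it; only valid without censoring
oracle_rank_auc <- function(marker, time, horizon) {
  case <- marker[time <= horizon]
  ctrl <- marker[time > horizon]
  cmp <- outer(case, ctrl, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# small helpers for building fixtures ----------------------------------------

quick_input <- function(step = 0.05, t_end = 65)
  gen_input_function(aif_params(), seq(0, t_end, by = step))

# fast survival-only dataset with exponential hazards tied to a marker
quick_surv <- function(n, beta = 0, seed = 1, h0 = 0.002, cmax = 1500) {
  set.seed(seed)
  z <- rnorm(n)
  tt <- rexp(n, h0 * exp(beta * z))
  cc <- runif(n, 0, cmax)
  list(z = z, time = pmin(tt, cc), status = as.integer(tt <= cc))
}
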