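# Window integration. The workhorse is the C++ Dormand-Prince core; a
# pure-R twin of the same scheme serves as cross-check oracle in the tests
# and as fallback for mortality kinds added to the registry at run time
# (which the C++ core does not know about).

integrate_window <- function(params, y0, t_len, rtol = 1e-10, atol = 1e-12,
                             max_steps = 5e6) {
  stopifnot(inherits(params, "community_params"))
  if (anyNA(params$mortality$code)) {
    integrate_window_r(params, y0, t_len, rtol, atol, max_steps)
  } else {
    integrate_window_cpp(params$comp, params$ri, params$delta, params$d,
                         params$mortality$code, params$mortality$s,
                         params$mortality$ref, y0, t_len, rtol, atol,
                         max_steps)
  }
}

# Dormand-Prince 5(4) with FSAL, identical coefficients and step control to
# the C++ core.
integrate_window_r <- function(params, y0, t_len, rtol = 1e-10,
                               atol = 1e-12, max_steps = 5e6) {
  A <- list(
    c(1/5),
    c(3/40, 9/40),
    c(44/45, -56/15, 32/9),
    c(19372/6561, -25360/2187, 64448/6561, -212/729),
    c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656))
  b <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84)
  e <- c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)

  f <- function(y) rhs_community_r(params, y)
  y <- as.numeric(y0)
  t <- 0; steps <- 0; success <- TRUE
  k <- vector("list", 7)
  k[[1]] <- f(y)
  h <- min(1e-4, t_len)
  while (t < t_len) {
    if (steps >= max_steps) { success <- FALSE; break }
    if (t + h > t_len) h <- t_len - t
    for (st in 1:5) {
      acc <- y
      for (j in seq_len(st)) acc <- acc + h * A[[st]][j] * k[[j]]
      k[[st + 1]] <- f(pmax(acc, 0))
    }
    ynew <- y
    for (j in 1:6) ynew <- ynew + h * b[j] * k[[j]]
    ynew <- pmax(ynew, 0)
    k[[7]] <- f(ynew)
    y4 <- y
    for (j in 1:7) y4 <- y4 + h * e[j] * (if (j <= 6) k[[j]] else k[[7]])
    sc <- atol + rtol * pmax(abs(y), abs(ynew))
    err <- sqrt(mean(((ynew - y4) / sc)^2))
    steps <- steps + 1
    if (!is.nan(err) && err <= 1) {
      t <- t + h
      y <- ynew
      k[[1]] <- k[[7]]
    }
    fac <- if (is.nan(err)) 0.2 else if (err > 0) 0.9 * err^-0.2 else 5
    h <- h * min(5, max(0.2, fac))
    if (!is.finite(h) || h < 1e-14 * max(1, t)) { success <- FALSE; break }
  }
  dy <- f(y)
  list(y = y, dy = dy, t = t, steps = steps, max_abs_rhs = max(abs(dy)),
       success = success)
}
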