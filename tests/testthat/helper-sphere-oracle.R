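# Independent 1-D oracle for the thick-walled sphere benchmark: spherically
# symmetric inflation of a compressible shell. The constitutive response is
# evaluated from the strain energy by numeric differentiation of principal
# stretches (a code path fully separate from the package's tensor stress
# evaluation), the radial equilibrium ODE is integrated with deSolve, and
# the inner radius is found by shooting on the zero-traction outer surface.

sphere_oracle <- function(R_in, R_out, p_kPa, B, C0, D0, n_out = 40) {
  psi <- function(lr, lt) {
    J <- lr * lt^2
    Eb <- 0.5 * (J^(-2 / 3) * c(lr^2, lt^2, lt^2) - 1)
    q <- B * sum(Eb^2)   # all-equal weights, diagonal strain
    (J^2 - 2 * log(J)) / (2 * D0) + C0 / 2 * (exp(q) - 1)
  }
  sig_rr <- function(lr, lt) {
    h <- 1e-6
    (psi(lr + h, lt) - psi(lr - h, lt)) / (2 * h) * lr / (lr * lt^2)
  }
  sig_tt <- function(lr, lt) {
    h <- 1e-6
    (psi(lr, lt + h) - psi(lr, lt - h)) / (2 * h) * lt / (lr * lt^2) / 2
  }
  lr_of <- function(s, lt) {
    uniroot(function(lr) sig_rr(lr, lt) - s, c(0.2, 3), tol = 1e-12)$root
  }
  deriv <- function(R, y, parms) {
    r <- y[1]; s <- y[2]
    lt <- r / R
    lr <- lr_of(s, lt)
    list(c(lr, -2 * (s - sig_tt(lr, lt)) / r * lr))
  }
  shoot <- function(rin) {
    deSolve::lsoda(c(rin, -p_kPa), seq(R_in, R_out, length.out = n_out),
                   deriv, NULL, rtol = 1e-9, atol = 1e-10)
  }
  f <- function(rin) { o <- shoot(rin); o[nrow(o), 3] }
  a <- R_in; b <- R_in * 1.2
  fa <- f(a); fb <- f(b)
  for (i in 1:60) {
    c_ <- b - fb * (b - a) / (fb - fa)
    fc <- f(c_)
    a <- b; fa <- fb; b <- c_; fb <- fc
    if (abs(fc) < 1e-10) break
  }
  o <- shoot(b)
  data.frame(R = o[, 1], r = o[, 2], u = o[, 2] - o[, 1], sig_rr = o[, 3])
}
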