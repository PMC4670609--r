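# Orthotropic Fung constitutive model: parameter scaling, energies,
# stresses and the consistent tangent.

test_that("two-parameter weight scaling reproduces the healthy-heart set", {
  p <- scale_weights(0.115, 14.4)
  expect_equal(p$B$Bff, 14.4)
  expect_equal(p$B$Bss, 5.76)
  expect_equal(p$B$Bnn, 5.76)
  expect_equal(p$B$Bfs, 5.04)
  expect_equal(p$B$Bfn, 5.04)
  expect_equal(p$B$Bsn, 2.88)

  p10 <- scale_weights(0.115, 10)
  expect_equal(p10$B$Bss, 4.0)
  expect_equal(p10$B$Bsn, 2.0)
  expect_equal(p10$B$Bfs, 3.5)

  p0 <- scale_weights(1, 0)
  expect_true(all(unlist(p0$B) == 0))
  expect_error(scale_weights(-1, 14.4), "parameter error")
  expect_error(material_parameters(D0 = 0), "parameter error")
})

test_that("volumetric energy is stationary at unit Jacobian", {
  p <- default_params()
  v <- volumetric_energy(1, p)
  expect_equal(v$dU, 0)
  expect_equal(v$U, 1 / (2 * p$D0))   # energy is defined up to a constant
  # direct evaluation of the ansatz in a second code path
  Je <- 1.1
  expect_equal(volumetric_energy(Je, p)$U,
               (Je^2 - 2 * log(Je)) / (2 * 0.001), tolerance = 1e-14)
  expect_error(volumetric_energy(-0.1, p), "inverted-element")
})

test_that("isochoric Fung energy matches scalar closed forms", {
  p <- default_params()
  fr <- fiber_frame(c(1, 0, 0), c(0, 1, 0))
  expect_equal(fung_energy(matrix(0, 3, 3), fr, p), 0)

  # rank-one fiber-fiber strain: psi = C0/2 (exp(Bff e^2) - 1)
  for (e in c(0.05, 0.1, -0.08)) {
    E <- diag(c(e, 0, 0))
    expect_equal(fung_energy(E, fr, p),
                 0.115 / 2 * (exp(14.4 * e^2) - 1), tolerance = 1e-12)
  }

  # small-strain limit: psi -> C0/2 E:B:E
  set.seed(21)
  E <- matrix(rnorm(9), 3, 3); E <- 1e-4 * (E + t(E)) / (2 * max(abs(E)))
  quad <- sum(p$W * E * E)
  expect_equal(fung_energy(E, fr, p), 0.115 / 2 * quad,
               tolerance = 1e-6)

  bad <- fr; bad$s0 <- c(0.5, 0.9, 0)
  expect_error(fung_energy(E, bad, p), "frame error")
})

test_that("stress vanishes in the fully grown, unloaded state", {
  set.seed(22)
  p <- default_params()
  for (mode in c("transverse", "longitudinal")) {
    fr <- random_frame()
    Fg <- growth_tensor(1.25, fr$f0, mode)
    st <- stresses(Fg, Fg, fr, p)
    # roundoff floor scales with the volumetric penalty stiffness 1/D0
    expect_lt(max(abs(st$S)) * p$D0, 1e-12)
    expect_lt(max(abs(st$sigma)) * p$D0, 1e-12)
  }
})

test_that("stress is the energy gradient (finite-difference oracle)", {
  set.seed(23)
  p <- default_params()
  # independent energy route: psi as a function of total C
  psi_of_C <- function(C, Fg, fr, p) {
    Fgi <- solve(Fg)
    Ce <- t(Fgi) %*% C %*% Fgi
    Je <- sqrt(det(Ce))
    Ebar <- (Je^(-2 / 3) * Ce - diag(3)) / 2
    fung_energy((Ebar + t(Ebar)) / 2, fr, p) + volumetric_energy(Je, p)$U
  }
  for (i in 1:100) {
    fr <- random_frame()
    mode <- if (i %% 2) "transverse" else "longitudinal"
    Fg <- growth_tensor(runif(1, 0.9, 1.3), fr$f0, mode)
    F <- random_F(0.1)
    st <- stresses(F, Fg, fr, p)
    C <- crossprod(F)
    h <- 1e-6
    Sfd <- matrix(0, 3, 3)
    for (k in 1:3) for (l in 1:3) {
      dC <- matrix(0, 3, 3)
      dC[k, l] <- dC[k, l] + h
      dC[l, k] <- dC[l, k] + h
      Sfd[k, l] <- (psi_of_C(C + dC, Fg, fr, p) -
                    psi_of_C(C - dC, Fg, fr, p)) / (2 * h)
    }
    expect_lt(max(abs(Sfd - st$S)) / max(abs(st$S)), 1e-6)
  }
})

test_that("energy is objective and fiber stress is monotone in stretch", {
  set.seed(24)
  p <- default_params()
  fr <- random_frame()
  F <- random_F(0.1)
  st <- stresses(F, diag(3), fr, p)
  for (i in 1:20) {
    R <- random_rotation()
    st_rot <- stresses(R %*% F, diag(3), fr, p)
    expect_lt(abs(st_rot$psi - st$psi), 1e-10 * max(1, st$psi))
    expect_lt(max(abs(st_rot$S - st$S)), 1e-10)
  }
  # uniaxial fiber stretch: sigma_11 positive, strictly increasing
  fr <- fiber_frame(c(1, 0, 0), c(0, 1, 0))
  lams <- seq(1.02, 1.3, by = 0.02)
  s11 <- vapply(lams, function(l) {
    stresses(diag(c(l, 1, 1)), diag(3), fr, p)$sigma[1, 1]
  }, 1)
  expect_true(all(s11 > 0))
  expect_true(all(diff(s11) > 0))
})

test_that("material tangent is consistent and scales with the stress scale", {
  set.seed(25)
  p <- default_params()
  fr <- random_frame()
  Fg <- transverse_growth_tensor(1.15, fr$f0)
  F <- random_F(0.08)
  A <- material_tangent(F, Fg, fr, p)
  # minor symmetries
  for (i in 1:3) for (j in 1:3) {
    expect_lt(max(abs(A[i, j, , ] - t(A[i, j, , ]))), 1e-8 * max(abs(A)))
    expect_lt(max(abs(A[, , i, j] - A[, , j, i])), 1e-8 * max(abs(A)))
  }
  # directional derivative agrees with finite differences of the stress
  dE <- matrix(rnorm(9), 3, 3); dE <- (dE + t(dE)) / 2
  dE <- dE / max(abs(dE))
  eps <- 1e-5
  C <- crossprod(F)
  # any F with the right C gives the same referential S; chol(C) is one
  F_of_C <- function(C) chol(C)
  Sp <- stresses(F_of_C(C + eps * 2 * dE), Fg, fr, p)$S
  Sm <- stresses(F_of_C(C - eps * 2 * dE), Fg, fr, p)$S
  dS_fd <- (Sp - Sm) / (2 * eps)
  dS_tan <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) dS_tan[i, j] <- sum(A[i, j, , ] * dE)
  expect_lt(max(abs(dS_fd - dS_tan)) / max(abs(dS_fd)), 1e-5)

  # doubling C0 while halving D0 doubles stress and tangent
  p2 <- material_parameters(C0 = 2 * p$C0, D0 = p$D0 / 2)
  A2 <- material_tangent(F, Fg, fr, p2)
  expect_equal(A2, 2 * A, tolerance = 1e-6)
  # tangent at identity with isotropic weights has cubic symmetry
  iso <- material_parameters(C0 = 0.115, D0 = 0.001, Bff = 5, Bss = 5,
                             Bnn = 5, Bfs = 5, Bfn = 5, Bsn = 5)
  A0 <- material_tangent(diag(3), diag(3), fr, iso)
  expect_equal(A0[1, 1, 1, 1], A0[2, 2, 2, 2], tolerance = 1e-8 * abs(A0[1, 1, 1, 1]))
  expect_equal(A0[1, 2, 1, 2], A0[2, 3, 2, 3], tolerance = 1e-8 * abs(A0[1, 1, 1, 1]))
})
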