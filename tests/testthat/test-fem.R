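# FE spaces, quadrature exactness, BDF coefficients and convergence,
# operator assembly.

test_that("BDF coefficients match the Lagrange-interpolation oracle", {
  # oracle: alpha and history weights from differentiating the polynomial
  # interpolating (t_{n+1}, ..., t_{n+1-sigma}) at t_{n+1}, and the
  # extrapolation weights from evaluating the history interpolant there.
  for (sigma in 1:3) {
    ts <- -(0:sigma)                      # t_{n+1} = 0, spacing 1
    lagr_deriv0 <- function(j, nodes) {
      others <- nodes[-j]
      denom <- prod(nodes[j] - others)
      # d/dt prod(t - others) at 0 = sum over k of prod(0 - others[-k])
      num <- sum(vapply(seq_along(others), function(k) prod(-others[-k]), 0))
      num / denom
    }
    w <- vapply(seq_along(ts), lagr_deriv0, 0, nodes = ts)
    alpha_o <- w[1]
    bdf_o <- -w[-1]
    lagr_eval0 <- function(j, nodes) {
      others <- nodes[-j]
      prod(0 - others) / prod(nodes[j] - others)
    }
    ext_o <- vapply(seq_len(sigma), function(j) lagr_eval0(j, ts[-1]), 0)
    sch <- bdf_scheme(sigma)
    expect_equal(sch$alpha, alpha_o, tolerance = 1e-12)
    expect_equal(sch$bdf_weights, bdf_o, tolerance = 1e-12)
    expect_equal(sch$ext_weights, ext_o, tolerance = 1e-12)
  }
  expect_error(bdf_scheme(4), "order")
})

test_that("BDF integration of du/dt = -u shows the nominal orders", {
  integrate_bdf <- function(sigma, dt) {
    sch <- bdf_scheme(sigma)
    n <- round(1 / dt)
    # exact-history bootstrap: most recent first, u(t) = exp(-t)
    hist <- lapply(seq_len(sigma), function(k) exp(-(sigma - k) * dt))
    for (step in seq.int(sigma, n)) {
      ubdf <- monodomain:::bdf_combine(sch$bdf_weights, hist)
      unew <- ubdf / (sch$alpha + dt)      # implicit: alpha u + dt u = ubdf
      hist <- c(list(unew), hist[seq_len(sigma - 1)])
    }
    abs(hist[[1]] - exp(-1))
  }
  for (sigma in 1:3) {
    e1 <- integrate_bdf(sigma, 0.01)
    e2 <- integrate_bdf(sigma, 0.005)
    rate <- log2(e1 / e2)
    expect_gt(rate, sigma - 0.1)
    expect_lt(rate, sigma + 0.1)
  }
})

test_that("quadrature integrates monomials to the required degree", {
  exact_tet <- function(a, b, c_) {
    factorial(a) * factorial(b) * factorial(c_) / factorial(a + b + c_ + 3)
  }
  for (p in 1:2) {
    q <- quadrature_rule("tetrahedron", p)
    for (deg in 0:(2 * p)) for (a in 0:deg) for (b in 0:(deg - a)) {
      c_ <- deg - a - b
      got <- sum(q$w * q$x[, 1]^a * q$x[, 2]^b * q$x[, 3]^c_)
      expect_equal(got, exact_tet(a, b, c_), tolerance = 1e-13)
    }
    qh <- quadrature_rule("hexahedron", p)
    expect_identical(length(qh$w), as.integer((p + 1)^3))
    for (a in c(0L, 2L * p, 2L * p + 1L)) {
      got <- sum(qh$w * qh$x[, 1]^a)
      expect_equal(got, 1 / (a + 1), tolerance = 1e-13)
    }
  }
})

test_that("mass matrices: partition of unity, Q1 diagonal, additivity", {
  ext <- c(2, 1, 1) * 1e-3
  m <- build_slab_mesh(ext, 0.5e-3)
  for (p in 1:2) {
    sp <- fe_space(m, p)
    M <- assemble_mass(sp)
    expect_lt(abs(sum(M) - prod(ext)) / prod(ext), 1e-12)
  }
  # unit cube, one Q1 element: vertex diagonal entry is 1/27
  mc <- build_slab_mesh(c(1, 1, 1), 1)
  Mc <- assemble_mass(fe_space(mc, 1))
  expect_equal(Mc[1, 1], 1 / 27, tolerance = 1e-14)
  # per-subdomain masses sum to the global mass
  m$material_id <- rep(c(0L, 1L), length.out = nrow(m$elements))
  sp <- fe_space(m, 1)
  M <- assemble_mass(sp)
  M1 <- assemble_mass(sp, which(m$material_id == 0L))
  M2 <- assemble_mass(sp, which(m$material_id == 1L))
  expect_lt(max(abs(M - (M1 + M2))), 1e-18)
})

test_that("stiffness: kernel, hand-assembled oracle, anisotropic scaling", {
  set.seed(3)
  m <- hex_to_tet(build_slab_mesh(c(1, 1, 1), 1))
  m$elements <- m$elements[1:2, , drop = FALSE]
  m$material_id <- m$material_id[1:2]
  sp <- fe_space(m, 1)
  fr <- axis_fiber_frame(m)
  sig <- 2.5
  K <- assemble_stiffness(sp, fr, sigma = rep(sig, 3))
  expect_lt(max(abs(K %*% rep(1, nrow(m$nodes)))), 1e-14)
  expect_lt(max(abs(K - Matrix::t(K))), 1e-15)
  # brute-force per-element oracle with constant P1 gradients
  Kh <- matrix(0, nrow(m$nodes), nrow(m$nodes))
  for (e in 1:2) {
    vid <- m$elements[e, ]
    v <- m$nodes[vid, ]
    C <- solve(cbind(1, v))
    G <- C[2:4, ]
    vol <- abs(det(v[2:4, ] - matrix(v[1, ], 3, 3, byrow = TRUE))) / 6
    Kh[vid, vid] <- Kh[vid, vid] + sig * vol * t(G) %*% G
  }
  expect_lt(max(abs(as.matrix(K) - Kh)), 1e-14)
  # doubling sigma_l doubles the fiber-aligned quadratic form
  slab <- build_slab_mesh(c(1, 1, 2) * 1e-3, 0.5e-3)
  ssp <- fe_space(slab, 1)
  sfr <- axis_fiber_frame(slab, f0 = c(0, 0, 1))
  x <- slab$nodes[, 3]  # linear along f0: gradient purely fiber-aligned
  K1 <- assemble_stiffness(ssp, sfr, sigma = c(1e-4, 3e-5, 3e-5))
  K2 <- assemble_stiffness(ssp, sfr, sigma = c(2e-4, 3e-5, 3e-5))
  q1 <- as.numeric(t(x) %*% K1 %*% x)
  q2 <- as.numeric(t(x) %*% K2 %*% x)
  expect_equal(q2 / q1, 2, tolerance = 1e-12)
})

test_that("non-conductive subdomains contribute nothing to the stiffness", {
  m <- build_slab_mesh(c(2, 1, 1) * 1e-3, 0.5e-3)
  m$material_id <- as.integer(m$nodes[m$elements[, 1], 1] > 0.9e-3)
  sp <- fe_space(m, 1)
  sA <- subdomain_spec("A", 0L, 1e-4, 1e-5, 1e-5)
  sB <- subdomain_spec("B", 1L, 1e-4, 1e-5, 1e-5, conductive = FALSE)
  part <- build_subdomains(m, list(sA, sB), sp)
  fr <- axis_fiber_frame(m)
  K <- assemble_stiffness(sp, fr, part)
  KA <- assemble_stiffness(sp, fr,
                           build_subdomains(m, list(sA,
                             subdomain_spec("B", 1L, 0, 0, 0,
                                            conductive = TRUE)), sp))
  expect_lt(max(abs(K - KA)), 1e-18)
  onlyB <- which(m$material_id == 1L)
  bdofs <- setdiff(unique(as.vector(m$elements[onlyB, ])), part$active_dofs)
  expect_true(all(Matrix::rowSums(abs(K))[bdofs] == 0))
})

test_that("system matrix combines mass and stiffness and is SPD", {
  m <- build_slab_mesh(c(1, 1, 1) * 1e-3, 0.5e-3)
  sp <- fe_space(m, 1)
  M <- assemble_mass(sp)
  K <- assemble_stiffness(sp, axis_fiber_frame(m), sigma = c(1e-4, 1e-5, 1e-5))
  sch <- bdf_scheme(2)
  dt <- 1e-4
  A <- build_system_matrix(sch, dt, M, K)
  expect_lt(max(abs(A - ((sch$alpha / dt) * M + K))), 1e-18)
  A0 <- build_system_matrix(sch, dt, M, 0 * K)
  expect_lt(max(abs(A0 - (sch$alpha / dt) * M)), 1e-18)
  ev <- eigen(as.matrix(A), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_error(build_system_matrix(sch, 0, M, K), "positive")
})

test_that("degenerate elements are rejected with their index", {
  m <- build_slab_mesh(c(1, 1, 1) * 1e-3, 0.5e-3)
  # invert one element (swap bottom and top faces -> negative Jacobian)
  m$elements[3, ] <- m$elements[3, c(5:8, 1:4)]
  sp <- fe_space(m, 1)
  expect_error(assemble_mass(sp), "Jacobian")
})
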