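# independent dense tet10 stiffness oracle (pure R, direct assembly)
tet10_oracle_K <- function(nodes, elems, E, nu) {
  pairs <- rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(2, 4), c(3, 4))
  ga <- 0.5854101966249685; gb <- 0.1381966011250105
  gp <- rbind(c(ga, gb, gb, gb), c(gb, ga, gb, gb),
              c(gb, gb, ga, gb), c(gb, gb, gb, ga))
  ndof <- 3 * nrow(nodes)
  K <- matrix(0, ndof, ndof)
  for (e in seq_len(nrow(elems))) {
    X <- nodes[elems[e, 1:4], ]
    A <- cbind(1, X)
    Ainv <- solve(A)
    V <- det(A) / 6
    gL <- t(Ainv[2:4, ])
    lam <- E[e] * nu[e] / ((1 + nu[e]) * (1 - 2 * nu[e]))
    mu <- E[e] / (2 * (1 + nu[e]))
    D <- matrix(0, 6, 6)
    D[1:3, 1:3] <- lam
    diag(D)[1:3] <- lam + 2 * mu
    diag(D)[4:6] <- mu
    Ke <- matrix(0, 30, 30)
    for (g in 1:4) {
      L <- gp[g, ]
      dN <- matrix(0, 10, 3)
      for (i in 1:4) dN[i, ] <- (4 * L[i] - 1) * gL[i, ]
      for (m in 1:6) {
        i <- pairs[m, 1]; j <- pairs[m, 2]
        dN[4 + m, ] <- 4 * (L[i] * gL[j, ] + L[j] * gL[i, ])
      }
      B <- matrix(0, 6, 30)
      for (i in 1:10) {
        c0 <- 3 * (i - 1)
        B[1, c0 + 1] <- dN[i, 1]; B[2, c0 + 2] <- dN[i, 2]
        B[3, c0 + 3] <- dN[i, 3]
        B[4, c0 + 1] <- dN[i, 2]; B[4, c0 + 2] <- dN[i, 1]
        B[5, c0 + 2] <- dN[i, 3]; B[5, c0 + 3] <- dN[i, 2]
        B[6, c0 + 1] <- dN[i, 3]; B[6, c0 + 3] <- dN[i, 1]
      }
      Ke <- Ke + (V / 4) * t(B) %*% D %*% B
    }
    gd <- as.vector(t(outer(elems[e, ], c(1, 2, 3),
                            function(n, c_) 3 * (n - 1) + c_)))
    K[gd, gd] <- K[gd, gd] + Ke
  }
  K
}

test_that("sparse assembly matches the dense direct-assembly oracle", {
  mesh <- tetrahedralize(assembly(bone = make_box(c(0, 0, 0), c(2, 1, 1))), 1)
  mesh$E[] <- 750; mesh$nu[] <- 0.28
  Ks <- as.matrix(sacronav:::assemble_stiffness(mesh))
  Ko <- tet10_oracle_K(mesh$nodes, mesh$elements, mesh$E, mesh$nu)
  expect_lt(max(abs(Ks - Ko)) / max(abs(Ko)), 1e-8)
})

test_that("uniaxial bar tip displacement reproduces FL/EA", {
  bm <- bar_model()
  mesh <- bm$mesh; K <- bm$K
  n <- mesh$nodes; ndof <- 3 * nrow(n)
  x0 <- which(abs(n[, 1]) < 1e-8)
  x1 <- which(abs(n[, 1] - 40) < 1e-8)
  f <- consistent_face_load(mesh, x1, 100, c(1, 0, 0))
  fix <- c(3 * (x0 - 1) + 1,
           3 * (x0[which.min(rowSums(n[x0, 2:3]^2))] - 1) + c(2, 3),
           3 * (x0[which.max(n[x0, 2])] - 1) + 3)
  free <- setdiff(seq_len(ndof), fix)
  u <- numeric(ndof)
  u[free] <- as.numeric(Matrix::solve(K[free, free], f[free]))
  tip <- mean(u[3 * (x1 - 1) + 1])
  exact <- 100 * 40 / (1000 * 16)
  expect_lt(abs(tip - exact) / exact, 0.001)
})

test_that("slender cantilever tip deflection matches Euler-Bernoulli", {
  bm <- bar_model()
  mesh <- bm$mesh; K <- bm$K
  n <- mesh$nodes; ndof <- 3 * nrow(n)
  x0 <- which(abs(n[, 1]) < 1e-8)
  x1 <- which(abs(n[, 1] - 40) < 1e-8)
  f <- consistent_face_load(mesh, x1, 10, c(0, 0, 1))
  fix <- as.vector(outer(1:3, 3 * (x0 - 1), `+`))
  free <- setdiff(seq_len(ndof), fix)
  u <- numeric(ndof)
  u[free] <- as.numeric(Matrix::solve(K[free, free], f[free]))
  tip <- mean(u[3 * (x1 - 1) + 3])
  exact <- 10 * 40^3 / (3 * 1000 * (4 * 4^3 / 12))
  expect_lt(abs(tip - exact) / exact, 0.05)
})

test_that("solve_static: zero load gives zero displacement", {
  model <- toy_screw_model()
  r0 <- solve_static(model$mesh, model$sets,
                     structure(list(magnitude = 0, direction = c(0, 0, 1)),
                               class = "load_case"))
  expect_equal(max(abs(r0$displacement)), 0)
})

test_that("stiffness definition, linearity in E, and force balance hold", {
  model <- toy_screw_model()
  load <- load_case(500, c(0, 0, 1))
  r <- solve_static(model$mesh, model$sets, load)
  expect_equal(r$stiffness, 500 / r$mean_u_head, tolerance = 1e-12)
  expect_equal(compute_stiffness(r, load), r$stiffness)
  # global force balance: reactions cancel the applied load
  R3 <- matrix(r$reactions, ncol = 3, byrow = TRUE)
  expect_lt(max(abs(colSums(R3) + 500 * c(0, 0, 1))) / 500, 1e-6)
  # doubling every modulus doubles the stiffness
  m2 <- model$mesh
  m2$E <- 2 * m2$E
  r2 <- solve_static(m2, model$sets, load)
  expect_equal(r2$stiffness / r$stiffness, 2, tolerance = 1e-9)
})

test_that("stiffness is invariant to rigid translation of the model", {
  model <- toy_screw_model()
  load <- load_case(500, c(0, 0, 1))
  k1 <- solve_static(model$mesh, model$sets, load)$stiffness
  m2 <- model$mesh
  m2$nodes <- m2$nodes + matrix(c(11.3, -7.9, 23.1), nrow(m2$nodes), 3,
                                byrow = TRUE)
  k2 <- solve_static(m2, model$sets, load)$stiffness
  expect_equal(k2 / k1, 1, tolerance = 1e-9)
})

test_that("under-constrained systems and missing materials error", {
  model <- toy_screw_model()
  m <- model$mesh
  m$E[] <- NA_real_
  expect_error(solve_static(m, model$sets, load_case(1, c(0, 0, 1))),
               "not assigned")
  sets0 <- model$sets
  sets0$fixed_endplate <- integer(0)
  sets0$fixed_caudal <- integer(0)
  expect_error(solve_static(model$mesh, sets0, load_case(1, c(0, 0, 1))),
               "rigid-body|no fixed")
})

test_that("h-refinement of a toy block converges in mean head displacement", {
  sweep_fix <- toy_sweep()
  u <- sweep_fix$mean_u_head_mm
  n <- length(u)
  # two finest meshes agree within 2 %; the coarsest differs more
  expect_lt(abs(u[n] - u[n - 1]) / u[n - 1], 0.02)
  expect_gt(abs(u[2] - u[1]) / u[1], abs(u[n] - u[n - 1]) / u[n - 1])
  expect_true(all(diff(sweep_fix$n_elements) > 0))
})

test_that("the default sweep produces nine rows per scenario", {
  sweep_fix <- toy_sweep()
  expect_equal(nrow(sweep_fix), 9)
  expect_setequal(sweep_fix$size_mm, seq(2, 6, by = 0.5))
})
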