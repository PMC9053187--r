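test_that("a single tet stiffness is symmetric with zero rigid rows", {
  m <- list(nodes = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
            tets = matrix(1:4, 1))
  mod <- solid_model(m, E = 1, nu = 0.3)
  K <- as.matrix(assemble(mod))
  expect_equal(K, t(K), tolerance = 1e-12)
  # uniform translation in each direction produces no force
  for (comp in 1:3) {
    u <- rep(0, 12); u[seq(comp, 12, by = 3)] <- 1
    expect_lt(max(abs(K %*% u)), 1e-12)
  }
})

test_that("the patch test yields constant interior stress to 1e-8", {
  m <- box_mesh(2, 2, 2, 3, 3, 3)
  bnodes <- sort(unique(as.vector(check_mesh(m)$boundary_faces)))
  mod <- solid_model(m, E = 1000, nu = 0.3, fixed_nodes = bnodes)
  K <- assemble(mod)
  A <- matrix(c(1, 0.2, 0, 0.3, -1, 0.1, 0, 0.5, 2), 3, 3) * 1e-3
  uc <- as.vector(t(m$nodes[bnodes, ] %*% t(A)))
  u <- solve_prescribed(mod, K, fixed_values = uc)
  st <- element_von_mises(mod, u)
  expect_lt(max(st$vm_stress) - min(st$vm_stress), 1e-8)
})

test_that("doubling every modulus exactly doubles the stiffness", {
  m <- box_mesh(5, 5, 10, 2, 2, 4)
  mod <- solid_model(m, E = 1234, nu = 0.3)
  K1 <- assemble(mod)
  K2 <- assemble(mod, E = 2 * mod$E)
  expect_equal(as.matrix(K2), 2 * as.matrix(K1), tolerance = 1e-12)
})

test_that("the uniaxial bar reproduces P/A and PL/AE", {
  Lb <- 100; W <- 10; E <- 2000; P <- 500
  m <- box_mesh(W, W, Lb, 4, 4, 20)
  mod <- solid_model(m, E = E, nu = 0,
                     fixed_nodes = which(m$nodes[, 3] < 1e-9))
  K <- assemble(mod)
  f <- traction_forces(mod, function(nd) nd[, 3] > Lb - 1e-9,
                       c(0, 0, P / W^2))
  sol <- solve_load_steps(mod, K, matrix(f, ncol = 1))
  expect_true(sol$solved)
  st <- element_von_mises(mod, sol$U[, 1])
  expect_lt(max(abs(st$s1 - P / W^2)) / (P / W^2), 0.01)
  uz <- sol$U[, 1][seq(3, mod$n_dof, 3)]
  tip <- mean(uz[m$nodes[, 3] > Lb - 1e-9])
  expect_lt(abs(tip - P * Lb / (W^2 * E)) / (P * Lb / (W^2 * E)), 0.01)
})

test_that("zero loads give zero displacement and stress", {
  m <- box_mesh(5, 5, 10, 2, 2, 4)
  mod <- solid_model(m, E = 100, nu = 0.3,
                     fixed_nodes = which(m$nodes[, 3] < 1e-9))
  K <- assemble(mod)
  sol <- solve_load_steps(mod, K, matrix(0, mod$n_dof, 1))
  expect_equal(max(abs(sol$U[, 1])), 0)
  expect_equal(max(element_von_mises(mod, sol$U[, 1])$vm_stress), 0)
})

test_that("an unconstrained system raises a constraint error", {
  m <- box_mesh(5, 5, 10, 2, 2, 4)
  mod <- solid_model(m, E = 100, nu = 0.3, fixed_nodes = 1L)
  K <- assemble(mod)
  expect_error(solve_load_steps(mod, K, matrix(1, mod$n_dof, 1)),
               "constraint error")
})

test_that("von Mises follows the principal-stress definition", {
  # hydrostatic: sigma_vm = 0; uniaxial: sigma_vm = |sigma|
  ev <- osteotrial:::sym3_eigenvalues
  h <- ev(100, 100, 100, 0, 0, 0)
  expect_equal(sqrt(0.5 * ((h$l1 - h$l2)^2 + (h$l2 - h$l3)^2 +
                             (h$l3 - h$l1)^2)), 0)
  u <- ev(100, 0, 0, 0, 0, 0)
  expect_equal(sqrt(0.5 * ((u$l1 - u$l2)^2 + (u$l2 - u$l3)^2 +
                             (u$l3 - u$l1)^2)), 100)
  # random symmetric tensors vs the eigen() oracle
  set.seed(11)
  for (i in 1:50) {
    a <- rnorm(6, 0, 50)
    S <- matrix(c(a[1], a[4], a[6],
                  a[4], a[2], a[5],
                  a[6], a[5], a[3]), 3, 3)
    lam <- sort(eigen(S, symmetric = TRUE)$values, decreasing = TRUE)
    got <- ev(a[1], a[2], a[3], a[4], a[5], a[6])
    expect_equal(c(got$l1, got$l2, got$l3), lam, tolerance = 1e-10)
  }
})

test_that("principal stresses come out sorted s1 >= s2 >= s3", {
  fx <- fixture_construct("Generic")
  K <- assemble(fx$model)
  sol <- solve_load_steps(fx$model, K, fx$F[, 1, drop = FALSE])
  st <- element_von_mises(fx$model, sol$U[, 1])
  expect_true(all(st$s1 >= st$s2 - 1e-9 & st$s2 >= st$s3 - 1e-9))
})

test_that("rigid translation of the construct zeroes all outcomes", {
  fx <- fixture_construct("Generic")
  model <- fx$model
  u <- numeric(model$n_dof)
  u[seq_len(model$n_solid_dof)] <- rep(c(1, 2, 3), nrow(model$nodes))
  if (model$n_beam > 0)
    u[model$n_solid_dof + as.vector(outer(1:3,
                                          (seq_len(model$n_beam) - 1) * 6,
                                          "+"))] <- rep(c(1, 2, 3),
                                                        model$n_beam)
  oc <- extract_outcomes(model, u)
  expect_lt(oc$max_plate_vm_stress, 1e-9)
  expect_lt(oc$max_periscrew_bone_vm_strain, 1e-12)
  expect_lt(oc$ifm, 1e-12)
})

test_that("outcomes scale exactly with load magnitude", {
  fx <- fixture_construct("Generic")
  K <- assemble(fx$model)
  s1 <- solve_load_steps(fx$model, K, fx$F[, 3, drop = FALSE])
  s2 <- solve_load_steps(fx$model, K, 2 * fx$F[, 3, drop = FALSE])
  o1 <- extract_outcomes(fx$model, s1$U[, 1])
  o2 <- extract_outcomes(fx$model, s2$U[, 1])
  expect_equal(o2$max_plate_vm_stress, 2 * o1$max_plate_vm_stress,
               tolerance = 1e-7)
  expect_equal(o2$max_periscrew_bone_vm_strain,
               2 * o1$max_periscrew_bone_vm_strain, tolerance = 1e-7)
  expect_equal(o2$ifm, 2 * o1$ifm, tolerance = 1e-7)
})

test_that("a prescribed gap-face offset is read back as the IFM", {
  fx <- fixture_construct("Generic")
  model <- fx$model
  d <- c(0.12, -0.05, 0.3)
  u <- numeric(model$n_dof)
  dn <- model$ost$distal_node
  nb <- nrow(model$ost$nodes)
  u[seq_len(3 * nb)] <-
    as.vector(t(matrix(d, nb, 3, byrow = TRUE) * dn))
  expect_equal(osteotrial:::interfragmentary_motion(model, u),
               sqrt(sum(d^2)), tolerance = 1e-12)
})

test_that("the convergence rule is strict at 5%", {
  expect_true(convergence_check(100, 103.92))
  expect_false(convergence_check(100, 105.1))
  expect_false(convergence_check(100, 105))
})

test_that("a strain probe without screws is an error", {
  fx <- fixture_construct("Generic")
  model <- fx$model
  model$screws <- model$screws[0, ]
  u <- numeric(model$n_dof)
  expect_error(extract_outcomes(model, u), "strain probe error")
})
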