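test_that("the default schedule has 15 steps, 5 instances per activity", {
  lt <- default_load_table()
  expect_setequal(unique(lt$table$step), 1:15)
  tab <- table(unique(lt$table[, c("activity", "instance")])$activity)
  expect_true(all(tab == 5))
  res <- osteotrial:::resultant_by_step(lt)
  m <- tapply(res$magnitude, res$activity, mean)
  expect_gt(m[["ACT2"]], m[["ACT1"]])
  expect_gt(m[["ACT3"]], m[["ACT1"]])
})

test_that("identity landmarks recover the identity transform", {
  lt <- default_load_table()
  fit <- fit_similarity(lt$landmarks, lt$landmarks)
  expect_equal(fit$s, 1, tolerance = 1e-12)
  expect_equal(fit$R, diag(3), tolerance = 1e-12)
  expect_equal(as.numeric(fit$t), c(0, 0, 0), tolerance = 1e-9)
})

test_that("constructed similarity transforms are recovered to 1e-9", {
  src <- unclass(default_load_table()$landmarks)
  R <- rotation_about_axis(c(0, 0, 1), 90)
  tgt <- 2 * src %*% t(R) + matrix(c(1, 2, 3), 5, 3, byrow = TRUE)
  fit <- fit_similarity(src, tgt)
  expect_equal(fit$s, 2, tolerance = 1e-9)
  expect_equal(fit$R, R, tolerance = 1e-9)
  expect_equal(as.numeric(fit$t), c(1, 2, 3), tolerance = 1e-9)
  expect_lt(fit$residual, 1e-9)
  # a second transform with a skew axis
  R2 <- rotation_about_axis(c(1, 2, 3), 37)
  tgt2 <- 0.7 * src %*% t(R2) + matrix(c(-4, 0, 11), 5, 3, byrow = TRUE)
  fit2 <- fit_similarity(src, tgt2)
  expect_equal(fit2$s, 0.7, tolerance = 1e-9)
  expect_equal(fit2$R, R2, tolerance = 1e-9)
})

test_that("the fitted transform beats 1000 random perturbations", {
  src <- unclass(default_load_table()$landmarks)
  R <- rotation_about_axis(c(1, 1, 0), 20)
  set.seed(4)
  tgt <- 1.5 * src %*% t(R) + matrix(c(5, -2, 1), 5, 3, byrow = TRUE) +
    matrix(rnorm(15, 0, 2), 5, 3)
  fit <- fit_similarity(src, tgt)
  sse <- function(s, Rm, t) {
    f <- s * src %*% t(Rm) + matrix(t, 5, 3, byrow = TRUE)
    sum((f - tgt)^2)
  }
  best <- sse(fit$s, fit$R, fit$t)
  for (i in 1:1000) {
    Rp <- fit$R %*% rotation_about_axis(rnorm(3), rnorm(1, 0, 2))
    expect_gte(sse(fit$s * exp(rnorm(1, 0, 0.02)), Rp,
                   fit$t + rnorm(3, 0, 0.5)), best)
  }
})

test_that("collinear landmarks raise a rank-deficiency error", {
  src <- cbind(0, 0, seq(0, 100, length.out = 5))
  expect_error(fit_similarity(src, src), "collinear")
  expect_error(fit_similarity(src[1:2, ], src[1:2, ]), "at least 3")
})

test_that("body-weight scaling is linear and unit-consistent", {
  lt <- default_load_table()
  f1 <- as.matrix(scale_loads(lt, 50)$table[, c("fx", "fy", "fz")])
  f2 <- as.matrix(scale_loads(lt, 100)$table[, c("fx", "fy", "fz")])
  expect_equal(2 * f1, f2, tolerance = 1e-12)
  # mass 1/g kg: forces numerically equal the template
  fid <- as.matrix(scale_loads(lt, 1 / 9.81)$table[, c("fx", "fy", "fz")])
  expect_equal(fid, as.matrix(lt$table[, c("fx", "fy", "fz")]),
               tolerance = 1e-12)
  lt0 <- lt; lt0$table[1, c("fx", "fy", "fz")] <- 0
  expect_equal(as.numeric(scale_loads(lt0, 80)$table[1, c("fx", "fy",
                                                          "fz")]),
               c(0, 0, 0))
  expect_error(scale_loads(lt, 0), "input error")
  expect_error(scale_loads(lt, -3), "input error")
})

test_that("registration rotates forces without scaling them", {
  lt <- default_load_table()
  idt <- list(s = 1, R = diag(3), t = c(0, 0, 0))
  expect_equal(register_loads(lt, idt)$points, lt$points)
  rot <- list(s = 3, R = rotation_about_axis(c(0, 1, 0), 45), t = c(1, 1, 1))
  reg <- register_loads(lt, rot)
  n0 <- sqrt(rowSums(as.matrix(lt$table[, c("fx", "fy", "fz")])^2))
  n1 <- sqrt(rowSums(as.matrix(reg$table[, c("fx", "fy", "fz")])^2))
  expect_equal(n0, n1, tolerance = 1e-12)
  # inverse composition returns the template to 1e-9
  inv <- list(s = 1 / rot$s, R = t(rot$R),
              t = -as.numeric(t(rot$R) %*% rot$t) / rot$s)
  back <- register_loads(reg, inv)
  expect_equal(as.matrix(back$points[, c("x", "y", "z")]),
               as.matrix(lt$points[, c("x", "y", "z")]), tolerance = 1e-9)
  expect_equal(back$table$fx, lt$table$fx, tolerance = 1e-9)
})
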