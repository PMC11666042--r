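test_that("linearization extracts the affine parameter coefficients", {
  sys <- exponential_system(0.5, learn = TRUE)
  lin <- linearize_in_params(sys, t = 0, u = 2, dudt = -1, unknown = "theta")
  expect_equal(unname(lin$A), matrix(-2, 1, 1))
  expect_equal(unname(lin$b), -1)
  # zero state kills the coefficient
  lin0 <- linearize_in_params(sys, 0, u = 0, dudt = 0, unknown = "theta")
  expect_equal(unname(lin0$A), matrix(0, 1, 1))
})

test_that("non-affine parameter dependence is detected by the probe check", {
  sys <- ode_system("quad", 1, function(t, u, th) -th[, 1]^2 * u,
                    list(param_spec("k", "learn_constant", 1)))
  expect_error(linearize_in_params(sys, 0, 1, -1, "k"), "not affine")
})

test_that("mosquito zero state makes every parameter free", {
  sys <- mosquito_system()
  unk <- c("f_E", "f_L", "f_P", "f_Ag", "m_L", "m_P", "m_A",
           "gamma_Aem", "gamma_Ab", "gamma_Ao")
  lin <- linearize_in_params(sys, 0, rep(0, 10), rep(0, 10), unk)
  expect_equal(max(abs(lin$A)), 0)
  rr <- rref_analysis(lin$A)
  expect_equal(rr$rank, 0L)
  expect_equal(rr$free_cols, 1:10)
})

test_that("rref analysis matches hand cases and the rounding rule", {
  rr <- rref_analysis(diag(3))
  expect_equal(rr$rank, 3L)
  expect_equal(rr$free_cols, integer(0))
  rr2 <- rref_analysis(matrix(c(1, 2, 2, 4), 2, byrow = TRUE))
  expect_equal(rr2$rank, 1L)
  expect_equal(rr2$free_cols, 2L)
  # entries below the rounding precision are zero
  rr3 <- rref_analysis(matrix(c(1e-9, 0, 0, 1), 2), precision_digits = 6)
  expect_equal(rr3$rank, 1L)
  expect_equal(rr3$free_cols, 1L)
})

test_that("rref rank agrees with the svd rank on random matrices", {
  set.seed(20)
  for (i in 1:100) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    r <- sample(1:min(m, n), 1)
    A <- matrix(rnorm(m * r), m, r) %*% matrix(rnorm(r * n), r, n)
    rr <- rref_analysis(A, precision_digits = 6)
    sv <- svd(A)$d
    svd_rank <- sum(sv > 1e-6 * max(1, max(sv)))
    expect_equal(rr$rank, svd_rank)
  }
})

test_that("identifiability is invariant to row scaling and duplicated rows", {
  set.seed(21)
  A <- matrix(rnorm(12), 4, 3)
  A[, 3] <- A[, 1] + A[, 2]        # force one free column
  base <- rref_analysis(A)
  scaled <- rref_analysis(A * c(2, -0.5, 3, 1))
  expect_equal(scaled$free_cols, base$free_cols)
  dup <- rref_analysis(rbind(A, A[2, ]))
  expect_equal(dup$free_cols, base$free_cols)
})

test_that("cross-check against an independent rref implementation", {
  skip_if_not_installed("pracma")
  set.seed(22)
  for (i in 1:20) {
    A <- round(matrix(rnorm(20), 4, 5), 3)
    rr <- rref_analysis(A, precision_digits = 6)
    R2 <- pracma::rref(A)
    rank2 <- sum(apply(abs(R2) > 1e-9, 1, any))
    expect_equal(rr$rank, rank2)
  }
})

test_that("m_L and m_P are flagged free in the collapsed winter state", {
  sys <- mosquito_system()
  unk <- c("f_E", "f_L", "f_P", "f_Ag", "m_L", "m_P", "m_A",
           "gamma_Aem", "gamma_Ab", "gamma_Ao")
  # midwinter state: aquatic stages and active adults at zero, only the
  # gestating adults persist
  tcold <- 365 * 2 + 365 * 0.75     # tau = 0 C
  u <- setNames(rep(0, 10), c("E", "L", "P", "Aem", "Ab1", "Ag1", "Ao1",
                              "Ab2", "Ag2", "Ao2"))
  u[c("Ag1", "Ag2")] <- c(2e4, 1e4)
  th <- evaluate_params(sys, tcold, use_truth = TRUE)
  dudt <- as.numeric(sys$rhs(tcold, matrix(u, 1), th))
  lin <- linearize_in_params(sys, tcold, u, dudt, unk)
  rr <- rref_analysis(lin$A)
  free_names <- unk[rr$free_cols]
  expect_true(all(c("m_L", "m_P") %in% free_names))
  # the gestating-adult rates still carry information
  expect_true(all(c("m_A", "f_Ag") %in% unk[rr$pivot_cols]))
})

test_that("warm-season state identifies the full rate set (svd oracle)", {
  sys <- mosquito_system()
  u0 <- c(1e6, 1e6, 1e5, 1e4, 1e4, 1e4, 1e4, 1e4, 1e4, 1e4)
  traj <- integrate_system(sys, u0, seq(730, 1096, length.out = 150),
                           rtol = 1e-8, atol = 1e-6)
  unk <- c("f_E", "f_L", "f_P", "f_Ag", "m_L", "m_P", "m_A",
           "gamma_Aem", "gamma_Ab", "gamma_Ao")
  twarm <- 730 + 365 / 4            # tau = 20 C, all stages active
  prof <- profile_over_time(sys, traj, unk, times = twarm)
  st <- make_observations(traj, twarm)$values
  th <- evaluate_params(sys, twarm, use_truth = TRUE)
  dudt <- as.numeric(sys$rhs(twarm, st, th))
  lin <- linearize_in_params(sys, twarm, as.numeric(st), dudt, unk)
  # svd oracle on the same equilibrated matrix the profile analyzes
  sv <- svd(odepinn:::equilibrate(lin$A))$d
  expect_equal(prof$rank, sum(sv > 1e-6 * max(sv)))
})

test_that("empty unknown set is vacuously identifiable", {
  sys <- exponential_system(1)
  traj <- integrate_system(sys, 1, seq(0, 1, length.out = 11))
  prof <- profile_over_time(sys, traj, character(0), times = 0.5)
  expect_equal(prof$rank, 0L)
  expect_equal(prof$n_free, 0L)
})
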