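# Peleg-Fermi survival law and its pulse-number parameter decay

test_that("fermi_survival matches the logistic form and its landmarks", {
  # S = 0.5 exactly at E = Ec, for any width
  for (A in c(1e3, 1e4, 5e4))
    expect_identical(fermi_survival(1.5e5, Ec = 1.5e5, A = A), 0.5)
  # deep sub-threshold field: survival within 1e-6 of 1 (exponent -15)
  expect_lt(abs(fermi_survival(0, Ec = 1.5e5, A = 1e4) - 1), 1e-6)
  # independent scalar evaluation: exponent = +2
  expect_equal(fermi_survival(2e5, Ec = 1e5, A = 5e4), 1 / (1 + exp(2)),
               tolerance = 1e-12)
})

test_that("fermi_survival is strictly decreasing, bounded, and saturates", {
  set.seed(11)
  for (rep in 1:20) {
    Ec <- runif(1, 1e4, 3e5)
    A <- runif(1, 1e3, 8e4)
    # within ~30 widths of the midpoint the logistic is strictly inside
    # (0,1); farther out it saturates to 0/1 at double precision
    E <- sort(runif(50, max(0, Ec - 30 * A), Ec + 30 * A))
    S <- fermi_survival(E, Ec, A)
    expect_true(all(diff(S) < 0))
    expect_true(all(S > 0 & S < 1))
    wide <- fermi_survival(sort(runif(50, 0, 6e5)), Ec, A)
    expect_true(all(diff(wide) <= 0))
    expect_true(all(wide >= 0 & wide <= 1))
  }
  # |exponent| ~ 750: no overflow warning, clean saturation
  expect_no_warning(lo <- fermi_survival(8e7, Ec = 1e5, A = 1e2))
  expect_identical(lo, 0)
  expect_identical(fermi_survival(0, Ec = 8e7, A = 1e2), 1)
})

test_that("fermi_survival rejects out-of-domain parameters", {
  expect_error(fermi_survival(1e5, Ec = 1e5, A = 0), "positive")
  expect_error(fermi_survival(1e5, Ec = 1e5, A = -1), "positive")
  expect_error(fermi_survival(-1, Ec = 1e5, A = 1e4), "non-negative")
  expect_error(fermi_survival(1e5, Ec = -2, A = 1e4), "positive")
})

test_that("parameter decay curves have exact intercepts and exponential form", {
  expect_identical(ec_of_n(0, Eco = 1e5, k1 = 0.1), 1e5)
  expect_equal(ec_of_n(10, Eco = 1e5, k1 = 0.1), 1e5 * exp(-1),
               tolerance = 1e-14)
  expect_identical(ec_of_n(c(0, 3, 17), Eco = 2e5, k1 = 0),
                   rep(2e5, 3))
  expect_identical(a_of_n(0, Ao = 4e4, k2 = 0.05), 4e4)
  expect_equal(a_of_n(20, Ao = 4e4, k2 = 0.05), 4e4 * exp(-1),
               tolerance = 1e-14)
  # real-valued n supported for extrapolated curves; negative rejected
  expect_silent(ec_of_n(2.5, 1e5, 0.1))
  expect_error(ec_of_n(-1, 1e5, 0.1), ">= 0")
  expect_error(a_of_n(1, 4e4, -0.1), ">= 0")
  # monotone non-increasing, always positive
  n <- 0:200
  expect_true(all(diff(ec_of_n(n, 1e5, 0.03)) <= 0))
  expect_true(all(ec_of_n(n, 1e5, 0.03) > 0))
})

test_that("protocol_survival composes the three scalar formulas", {
  m <- fermi_protocol_model(Eco = 1e5, k1 = 0.03, Ao = 4e4, k2 = 0.03,
                            pulse_length = 1e-4)
  # at E = Ec(n) the survival is the 50% split point, for any n
  for (n in c(1, 5, 50))
    expect_identical(protocol_survival(ec_of_n(n, 1e5, 0.03), n, m), 0.5)
  # independent composed evaluation at E = 2 Eco, n = 50
  n <- 50
  expected <- 1 / (1 + exp((2e5 - 1e5 * exp(-0.03 * n)) /
                             (4e4 * exp(-0.03 * n))))
  expect_equal(protocol_survival(2e5, n, m), expected, tolerance = 1e-14)
  # n = 0 diagnostic reduces to the intercept parameters
  expect_identical(protocol_survival(1e5, 0, m),
                   fermi_survival(1e5, 1e5, 4e4))
  # strictly decreasing in n at fixed supra-threshold field
  S <- protocol_survival(1.6e5, 1:80, m)
  expect_true(all(diff(S) < 0))
})

test_that("predict/coef methods agree with the scalar path", {
  m <- fermi_protocol_model(1.5e5, 0.03, 4e4, 0.03, 1e-4)
  expect_identical(coef(m),
                   c(Eco = 1.5e5, k1 = 0.03, Ao = 4e4, k2 = 0.03))
  E <- c(5e4, 1.2e5, 2e5)
  expect_identical(predict(m, field = E, n_pulses = 10),
                   protocol_survival(E, 10, m))
})

test_that("model constructor enforces the parameter domain", {
  expect_error(fermi_protocol_model(-1, 0.03, 4e4, 0.03, 1e-4), "Eco")
  expect_error(fermi_protocol_model(1e5, -0.1, 4e4, 0.03, 1e-4),
               "must not increase")
  expect_error(fermi_protocol_model(1e5, 0.03, 4e4, 0.03, 0),
               "pulse_length")
})

test_that("normalization by Eco preserves survival and pins Ec*(0) = 1", {
  m <- fermi_protocol_model(Eco = 1e5, k1 = 0.03, Ao = 4e4, k2 = 0.05,
                            pulse_length = 1e-4)
  dm <- normalize_model(m)
  expect_identical(dm$Ec_star(0), 1)
  # Ao/Eco = 0.4, k2 = 0.05: A*(20) = 0.4 exp(-1)
  expect_equal(dm$A_star(20), 0.4 * exp(-1), tolerance = 1e-14)
  # scale invariance of the logistic argument
  set.seed(21)
  for (rep in 1:10) {
    E <- runif(1, 0, 4e5); n <- sample(1:60, 1)
    expect_equal(protocol_survival(E, n, m),
                 fermi_survival(E / m$Eco, dm$Ec_star(n), dm$A_star(n)),
                 tolerance = 1e-12)
  }
})

test_that("classical inactivation models hit their zero-dose points", {
  # first-order kinetics: zero rate leaves everything alive
  m1 <- classical_model_params("first_order", c(k = 0))
  expect_identical(classical_survival(m1, E = 1e5, t = 10), 1)
  expect_equal(classical_survival(
    classical_model_params("first_order", c(k = 0.5)), E = 0, t = 2),
    exp(-1), tolerance = 1e-14)
  # threshold field: S = 1 at E = E_c
  m2 <- classical_model_params("hulsheger", c(b_e = 2e-5, E_c = 1e5))
  expect_identical(classical_survival(m2, E = 1e5, t = 1), 1)
  expect_identical(classical_survival(m2, E = 5e4, t = 1), 1)  # clamped
  # extended form: S = 1 at t = t_c for any field
  m3 <- classical_model_params("hulsheger_extended",
                               c(t_c = 1e-4, E_c = 1e5, k = 5e4))
  expect_identical(classical_survival(m3, E = 2e5, t = 1e-4), 1)
  expect_lt(classical_survival(m3, E = 2e5, t = 1e-3), 1)
  # Weibull: scalar evaluation
  m4 <- classical_model_params("weibull", c(b = 0.5, shape = 1))
  expect_equal(classical_survival(m4, E = 1e5, t = 2), exp(-1),
               tolerance = 1e-14)
  expect_error(classical_model_params("logistic", c(a = 1)), "model_id")
  expect_error(classical_model_params("weibull", c(b = 0.5)), "shape")
})
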