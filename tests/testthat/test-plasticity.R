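test_that("dopamine-dependence factors match their closed forms", {
  lin <- plasticity_rule("linear")
  rect <- plasticity_rule("rectified")
  sig <- plasticity_rule("offset_sigmoid")
  expect_equal(dopamine_factor(lin, "direct", 0.5), 0.5)
  expect_equal(dopamine_factor(lin, "indirect", 0.5), -0.5)
  expect_equal(dopamine_factor(rect, "indirect", -1.0), 1.0)
  expect_equal(dopamine_factor(rect, "direct", -1.0), 0.0)
  # sigmoid asymptote (a + b)/2 with a = -3.5, b = 11.5
  expect_equal(dopamine_factor(sig, "direct", 1e9), 4.0)
  expect_equal(dopamine_factor(sig, "indirect", -1e9), 4.0)
  # frozen value of the offset sigmoid at zero dopamine
  expect_equal(dopamine_factor(sig, "direct", 0), -0.0816183558,
               tolerance = 1e-8)
})

test_that("factor monotonicity and symmetry invariants hold on a grid", {
  grid <- seq(-5, 5, by = 0.25)
  for (kind in c("linear", "rectified", "offset_sigmoid")) {
    rule <- plasticity_rule(kind)
    fd <- dopamine_factor(rule, "direct", grid)
    fi <- dopamine_factor(rule, "indirect", grid)
    expect_true(all(diff(fd) >= 0), info = kind)
    expect_true(all(diff(fi) <= 0), info = kind)
    # equal-and-opposite arguments make the two factors agree at zero
    expect_equal(dopamine_factor(rule, "direct", 0),
                 dopamine_factor(rule, "indirect", 0))
  }
  expect_true(all(dopamine_factor(plasticity_rule("rectified"), "direct",
                                  grid) >= 0))
  expect_true(all(dopamine_factor(plasticity_rule("rectified"), "indirect",
                                  grid) >= 0))
  same <- plasticity_rule("same_sign_indirect")
  expect_equal(dopamine_factor(same, "indirect", grid),
               dopamine_factor(same, "direct", grid))
})

test_that("weight updates are exact three-factor outer products", {
  lin <- plasticity_rule("linear", alpha = 0.05)
  expect_equal(weight_update(lin, "direct", 1, 1, 1),
               matrix(0.05, 1, 1))
  expect_equal(weight_update(lin, "indirect", 1, 1, 1),
               matrix(-0.05, 1, 1))
  rect <- plasticity_rule("rectified", alpha = 0.05)
  y <- c(0.3, 2); x <- c(1, 0, 0.5)
  expect_equal(weight_update(rect, "indirect", 1, y, x),
               matrix(0, 2, 3))
  # outer-product structure and linearity in alpha and delta
  set.seed(4)
  y <- runif(3); x <- runif(4); d <- 0.7
  expect_equal(weight_update(lin, "direct", d, y, x),
               lin$alpha * d * outer(y, x))
  lin2 <- plasticity_rule("linear", alpha = 0.1)
  expect_equal(weight_update(lin2, "direct", d, y, x),
               2 * weight_update(lin, "direct", d, y, x))
  expect_equal(weight_update(lin, "direct", 2 * d, y, x),
               2 * weight_update(lin, "direct", d, y, x))
  expect_error(weight_update(lin, "direct", NaN, y, x))
})

test_that("TD critic returns pre-update error and converges geometrically", {
  cr <- critic_state(2, alpha_v = 0.05)
  out <- td_error_and_update(cr, 1, 1)
  expect_equal(out$delta, 1)
  expect_equal(out$critic$values[1], 0.05)
  # never-visited state stays exactly 0
  expect_identical(out$critic$values[2], 0)
  # fixed point: value equal to reward leaves the critic unchanged
  cr2 <- out$critic
  cr2$values[1] <- 1
  out2 <- td_error_and_update(cr2, 1, 1)
  expect_equal(out2$delta, 0)
  expect_equal(out2$critic$values[1], 1)
  # closed form after n constant-reward updates: V = 1 - (1 - alpha_v)^n
  cr3 <- critic_state(1, alpha_v = 0.2)
  for (n in 1:25) {
    cr3 <- td_error_and_update(cr3, 1, 1)$critic
    expect_equal(cr3$values[1], 1 - (1 - 0.2)^n)
  }
})

test_that("Q error reads the prediction off the striatal logit", {
  expect_equal(q_error(0, 1), 1)
  expect_equal(q_error(1, 1), 0)
  expect_equal(q_error(0.3, 0), -0.3)
})

test_that("unknown rule kinds are rejected", {
  expect_error(plasticity_rule("hebbian"))
  r <- plasticity_rule("linear")
  r$kind <- "bogus"
  expect_error(dopamine_factor(r, "direct", 1), "unknown")
})
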