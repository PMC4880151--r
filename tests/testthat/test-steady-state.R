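test_that("Model I closed form matches the reference point and a Newton oracle", {
  p <- model_params()  # (0.5, 0.43, 0.14, 0.44) + fixed leukaemia rates
  fp <- fixed_point_model1(p)
  # frozen values, independently reproduced by Newton refinement below
  expect_equal(unname(fp$state),
               c(0.72, 0.8297561, 1.3276098, -0.5704968, -0.3803312),
               tolerance = 1e-6)
  expect_lt(max(abs(model_rhs("I", p, fp$state))), 1e-9)
  # independent oracle: damped Newton on the rhs from a perturbed start
  ref <- newton_refine("I", p, fp$state + c(0.02, -0.03, 0.01, 0.04, -0.02))
  expect_equal(unname(fp$state), unname(ref), tolerance = 1e-7)
  expect_identical(fp$branch, "unique")
  expect_false(fp$is_nonnegative)  # L* < 0: this point is not coexistent
})

test_that("rhs residual vanishes at every real analytic fixed point", {
  set.seed(1000)
  n_m2_real <- 0
  for (k in 1:1000) {
    p <- random_params()
    fp <- tryCatch(fixed_point_model1(p), hscniche_singular = function(e) NULL)
    # scale by the squared state magnitude: the rhs terms are quadratic
    # in the state, so rounding grows as |state|^2 near the A* pole
    if (!is.null(fp))
      expect_lt(max(abs(model_rhs("I", p, fp$state))) /
                  max(1, max(abs(fp$state)))^2, 1e-9)
    for (b in fixed_points_model2(p)) {
      if (!b$is_real) next
      n_m2_real <- n_m2_real + 1
      expect_lt(max(abs(model_rhs("II", p, b$state))) /
                  max(1, max(abs(b$state)))^2, 1e-9)
      # the progenitor/differentiated-cell balance relation
      expect_equal(b$state[["A"]],
                   p$mu_D * b$state[["D"]] * (1 + b$state[["D"]]) / p$delta_A,
                   tolerance = 1e-9)
    }
  }
  expect_gt(n_m2_real, 100)  # the draw range does reach real branches
})

test_that("stem-cell washout forces the healthy lineage out", {
  p <- model_params(rho_S = 0.3, delta_S = 0.3)
  fp <- fixed_point_model1(p)
  expect_equal(unname(fp$state[["S"]]), 0)
  expect_equal(unname(fp$state[["A"]]), 0)
  expect_equal(unname(fp$state[["L"]]), 1 - p$delta_L / p$rho_L)
})

test_that("occupancy identity holds at fixed points with leukaemia present", {
  set.seed(21)
  for (k in 1:200) {
    p <- random_params()
    fp <- tryCatch(fixed_point_model1(p), hscniche_singular = function(e) NULL)
    if (is.null(fp)) next
    expect_equal(fp$state[["A"]] + fp$state[["L"]],
                 p$K2 - p$delta_L / p$rho_L, tolerance = 1e-12)
    for (b in fixed_points_model2(p))
      if (b$is_real)
        expect_equal(b$state[["A"]] + b$state[["L"]],
                     p$K2 - p$delta_L / p$rho_L, tolerance = 1e-12)
  }
})

test_that("A* and D* peak at delta_S = rho_S / 2", {
  set.seed(31)
  for (k in 1:20) {
    # coexistence-typical regime: delta_A above the asymptote so A* > 0
    p <- model_params(rho_S = runif(1, 0.2, 0.5), rho_A = runif(1, 0.1, 0.3),
                      delta_A = runif(1, 0.35, 0.5))
    grid <- seq(0.02, p$rho_S - 0.02, length.out = 41)
    A <- vapply(grid, function(ds) {
      p$delta_S <- ds; fixed_point_model1(p)$state[["A"]]
    }, 0)
    D <- vapply(grid, function(ds) {
      p$delta_S <- ds; fixed_point_model1(p)$state[["D"]]
    }, 0)
    p$delta_S <- p$rho_S / 2
    st <- fixed_point_model1(p)$state
    expect_true(all(st[["A"]] >= A))
    expect_true(all(st[["D"]] >= D))
  }
})

test_that("Model II branches handle the complex region and coincide at zero discriminant", {
  # deep in the complex region: moderate delta_A, large stem-cell influx
  p <- model_params(rho_S = 0.5, delta_S = 0.25, rho_A = 0.43, delta_A = 0.3,
                    mu_D = 0.275)
  disc_of <- function(delta_S) {
    p$delta_S <- delta_S
    S <- p$K1 - delta_S / p$rho_S
    beta <- p$delta_A * p$rho_L / (p$rho_A * p$delta_L)
    (beta - 1)^2 / 4 - delta_S * p$delta_A * p$rho_L * S /
      (p$rho_A * p$delta_L * p$mu_D)
  }
  expect_lt(disc_of(0.25), 0)  # the sign oracle, computed symbolically
  fps <- fixed_points_model2(p)
  expect_false(fps$minus$is_real)
  expect_false(fps$plus$is_real)
  expect_null(fps$minus$state)  # no fabricated real part

  # tune delta_S to the zero-discriminant boundary: branches coincide
  ds0 <- uniroot(disc_of, c(1e-4, 0.25), tol = 1e-14)$root
  p$delta_S <- ds0
  fps <- fixed_points_model2(p)
  expect_true(fps$minus$is_real && fps$plus$is_real)
  expect_equal(fps$minus$state, fps$plus$state, tolerance = 1e-5)
})

test_that("branch order is (minus, plus) and plus admits coexistence", {
  p <- model_params(rho_S = 0.103, delta_S = 0.1, rho_A = 0.3, delta_A = 0.278)
  fps <- fixed_points_model2(p)
  expect_identical(names(fps), c("minus", "plus"))
  expect_lte(fps$minus$state[["D"]], fps$plus$state[["D"]])
  f <- classify_region(p, fps$plus)
  expect_true(f[["coexistence"]])
})

test_that("critical values satisfy their defining root properties", {
  set.seed(55)
  tried <- 0
  for (k in 1:200) {
    p <- random_params()
    cv <- critical_values(p)
    # always: S* crosses zero exactly at rho_S = delta_S
    expect_identical(cv$rho_S_crit, p$delta_S)
    p_at <- p; p_at$rho_S <- cv$rho_S_crit
    expect_equal(fixed_point_model1(p_at)$state[["S"]], 0, tolerance = 1e-12)
    # the asymptote of A*
    expect_equal(cv$delta_A_asymp, p$rho_A * p$delta_L / p$rho_L,
                 tolerance = 1e-12)
    # xi's defining quadratic relation
    if (cv$xi_real) {
      phi <- p$K2 - p$delta_L / p$rho_L
      d <- p$rho_A * p$delta_L / p$rho_L - p$delta_A
      expect_equal(cv$xi^2, p$rho_S^2 / 4 + p$rho_S * phi * d,
                   tolerance = 1e-12)
    }
    # Brent oracles on the L* crossings (where they lie in a usable bracket)
    if (!is.finite(cv$rho_S_Lzero) || cv$rho_S_Lzero <= 0.02) next
    f_rs <- function(x) lstar_model1(p, "rho_S", x)
    lo <- cv$rho_S_Lzero * 0.5; hi <- cv$rho_S_Lzero * 1.5
    if (is.finite(f_rs(lo)) && is.finite(f_rs(hi)) &&
        sign(f_rs(lo)) != sign(f_rs(hi))) {
      tried <- tried + 1
      root <- uniroot(f_rs, c(lo, hi), tol = 1e-12)$root
      expect_equal(root, cv$rho_S_Lzero, tolerance = 1e-6)
      expect_equal(f_rs(cv$rho_S_Lzero), 0, tolerance = 1e-9)
    }
    if (cv$rho_A_crit > 0.02) {
      f_ra <- function(x) lstar_model1(p, "rho_A", x)
      lo <- cv$rho_A_crit * 0.9; hi <- cv$rho_A_crit * 1.1
      if (sign(f_ra(lo)) != sign(f_ra(hi))) {
        root <- uniroot(f_ra, c(lo, hi), tol = 1e-12)$root
        expect_equal(root, cv$rho_A_crit, tolerance = 1e-6)
      }
    }
    if (is.finite(cv$delta_A_crit) && cv$delta_A_crit > cv$delta_A_asymp + 0.01)
      expect_equal(lstar_model1(p, "delta_A", cv$delta_A_crit), 0,
                   tolerance = 1e-9)
    if (cv$xi_real && cv$delta_S_crit > 0.01 && cv$delta_S_crit < p$rho_S)
      expect_equal(lstar_model1(p, "delta_S", cv$delta_S_crit), 0,
                   tolerance = 1e-9)
  }
  expect_gt(tried, 20)
})

test_that("the A* pole sits at the delta_A asymptote (bisection oracle)", {
  p <- model_params()
  cv <- critical_values(p)
  # frozen arithmetic: 0.43 * 0.2 / 0.27
  expect_equal(cv$delta_A_asymp, 0.3185185185, tolerance = 1e-9)
  inv_A <- function(da) tryCatch(
    1 / fixed_point_model1(modifyList(p, list(delta_A = da)))$state[["A"]],
    hscniche_singular = function(e) 0)  # the limit at the pole
  pole <- uniroot(inv_A, c(cv$delta_A_asymp - 0.05, cv$delta_A_asymp + 0.05),
                  tol = 1e-12)$root
  expect_equal(pole, cv$delta_A_asymp, tolerance = 1e-8)
  # inside the guard band the closed form refuses to evaluate
  p$delta_A <- cv$delta_A_asymp
  expect_error(fixed_point_model1(p), class = "hscniche_singular")
})

test_that("classification flags follow the eps boundary conventions", {
  p <- model_params()
  mk <- function(A, L) list(state = population_state(0.5, A, 0.1, L, 0.1),
                            is_real = TRUE)
  f <- classify_region(p, mk(0.1, 0.05))
  expect_equal(unname(flags_logical(f)), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  f <- classify_region(p, mk(0.1, -0.2))
  expect_equal(unname(flags_logical(f)), c(TRUE, FALSE, FALSE, FALSE, FALSE))
  f <- classify_region(p, mk(5e-7, 0.1))  # below threshold counts as extinct
  expect_equal(unname(flags_logical(f)), c(FALSE, TRUE, FALSE, FALSE, FALSE))
  f <- classify_region(p, list(state = NULL, is_real = FALSE))
  expect_false(any(flags_logical(f)))
})

test_that("classification agrees with the critical-value interval conditions", {
  set.seed(77)
  checked <- 0
  for (k in 1:400) {
    p <- random_params()
    cv <- critical_values(p)
    fp <- tryCatch(fixed_point_model1(p), hscniche_singular = function(e) NULL)
    if (is.null(fp)) next
    # the interval characterisation describes the regime with a viable
    # stem-cell pool; below rho_S_crit the closed form can still produce
    # a formally positive (A*, L*) pair with S* < 0
    if (p$rho_S <= cv$rho_S_crit + 1e-3) next
    f <- classify_region(p, fp, eps = 1e-12)
    # keep away from the boundaries so eps conventions cannot bite
    margins <- c(p$rho_S - cv$rho_S_crit, p$rho_S - cv$rho_S_Lzero,
                 p$rho_A - cv$rho_A_crit, p$delta_A - cv$delta_A_crit,
                 p$delta_A - cv$delta_A_asymp)
    if (!all(is.finite(margins)) || min(abs(margins)) < 1e-3) next
    checked <- checked + 1
    in_rhoS_interval <- p$rho_S >= cv$rho_S_crit & p$rho_S <= cv$rho_S_Lzero
    expect_identical(unname(f[["coexistence"]]), unname(in_rhoS_interval))
    if (f[["coexistence"]]) {
      expect_lt(cv$rho_S_crit, cv$rho_S_Lzero)
      expect_lt(p$rho_A, cv$rho_A_crit)
      expect_gt(p$delta_A, cv$delta_A_crit)
    }
  }
  expect_gt(checked, 100)
})
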