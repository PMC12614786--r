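test_that("rhs matches hand-evaluated derivatives", {
  sys <- monoculture_system(c = 10, m = 1, K = 3, gamma = 1, l = 0)
  d <- cr_rhs(cr_state(0.1, 0.1), sys$traits, sys$env)
  expect_equal(d$dN, 0)          # 0.1 * (10 * 0.1 - 1)
  expect_equal(d$dR, 2.8)        # 3 - 0.1 * (1 + 10 * 0.1)
})

test_that("rhs of an empty community reduces to supply minus dissipation", {
  sys <- toy_system(matrix(c(5, 5), 1, 2), supply = c(2, 0), l = 0.5)
  d <- cr_rhs(cr_state(0, c(0.3, 0.4)), sys$traits, sys$env)
  expect_equal(d$dN, 0)
  expect_equal(d$dR, sys$env$supply - 1 * c(0.3, 0.4))
})

test_that("summed resource derivative obeys the leakage energy budget", {
  # summing the resource equation over types with a column-stochastic D:
  # sum dR = sum K - gamma sum R - (1 - l) sum_i,a c_ia R_a N_i
  set.seed(5)
  cfg <- generation_config(U = 6, E = 4, S0 = 8)
  for (rep in 1:10) {
    sys <- sample_viable_system(cfg)
    st <- cr_state(runif(8, 0, 1), runif(18, 0, 1))
    d <- cr_rhs(st, sys$pool, sys$env)
    lhs <- sum(d$dR)
    consumed <- sum((sys$pool$uptake %*% st$resources) * st$populations)
    rhs <- sum(sys$env$supply) - sum(st$resources) -
      (1 - sys$env$leakage) * consumed
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("monoculture steady state matches the closed form", {
  for (prm in list(c(10, 1, 3, 1), c(5, 0.5, 2, 2), c(8, 2, 6, 0.5))) {
    sys <- monoculture_system(prm[1], prm[2], prm[3], prm[4], l = 0)
    ref <- mono_closed_form(prm[1], prm[2], prm[3], prm[4])
    ss <- integrate_to_steady_state(cr_state(0.05, prm[3]), sys$traits,
                                    sys$env)
    expect_equal(ss$populations, ref$N, tolerance = 1e-6)
    expect_equal(ss$resources, ref$R, tolerance = 1e-6)
    expect_true(attr(ss, "converged"))
  }
})

test_that("empty community equilibrates resources at K / gamma", {
  env <- cr_env(c(4, 0, 1), diag(3), leakage = 0.8, dissipation = 2)
  tr <- cr_traits(matrix(0, 0, 3), numeric(0), character(0))
  ss <- integrate_to_steady_state(cr_state(numeric(0), c(0, 0, 0)), tr, env)
  expect_equal(ss$resources, c(2, 0, 0.5), tolerance = 1e-6)
})

test_that("a nonviable monoculture is removed by thresholding", {
  # (1 - l) c K / gamma < m: growth is negative even at untouched resources
  sys <- monoculture_system(c = 10, m = 1, K = 0.05, gamma = 1, l = 0)
  ss <- integrate_to_steady_state(cr_state(0.05, 0.05), sys$traits, sys$env)
  expect_equal(ss$populations, 0)
  expect_equal(ss$resources, 0.05, tolerance = 1e-6)
})

test_that("steady states agree with an independent deSolve oracle", {
  set.seed(42)
  cfg <- generation_config(U = 8, E = 3, S0 = 6)
  sys <- sample_viable_system(cfg)
  st <- cr_state(rep(0.01, 6), sys$env$supply)
  ss <- integrate_to_steady_state(st, sys$pool, sys$env)
  ref <- oracle_steady_state(st, sys$pool, sys$env, t_end = 20000)
  keep <- ss$populations > 0 | ref$populations > 1e-3
  expect_equal(ss$populations[keep], ref$populations[keep],
               tolerance = 1e-4)
  expect_equal(ss$resources, ref$resources, tolerance = 1e-4)
})

test_that("energy balance holds at returned steady states", {
  set.seed(99)
  cfg <- generation_config(U = 12, E = 5, S0 = 12)
  for (rep in 1:10) {
    sys <- sample_viable_system(cfg)
    ss <- integrate_to_steady_state(
      cr_state(rep(0.01, 12), sys$env$supply), sys$pool, sys$env)
    U <- sum(sys$env$supply)
    consumed <- sum((sys$pool$uptake %*% ss$resources) * ss$populations)
    balance <- U - sum(ss$resources) - (1 - sys$env$leakage) * consumed
    expect_lt(abs(balance), 1e-6 * U)
  }
})

test_that("returned states are nonnegative and free of oscillations", {
  set.seed(17)
  cfg <- generation_config(U = 10, E = 6, S0 = 10)
  scfg <- solver_config()
  for (rep in 1:5) {
    sys <- sample_viable_system(cfg)
    ss <- integrate_to_steady_state(
      cr_state(rep(0.01, 10), sys$env$supply), sys$pool, sys$env, scfg)
    expect_true(all(ss$populations >= 0) && all(ss$resources >= 0))
    # re-integrating one more horizon moves nothing beyond ss_rel_change
    again <- integrate_to_steady_state(ss, sys$pool, sys$env,
                                       solver_config(max_windows = 1))
    y0 <- c(ss$populations, ss$resources)
    y1 <- c(again$populations, again$resources)
    rel <- max(abs(y1 - y0) / pmax(abs(y1), scfg$extinction_threshold))
    expect_lt(rel, scfg$ss_rel_change)
  }
})

test_that("extinction thresholding is idempotent", {
  st <- cr_state(c(0.5, 5e-4, 0, 0.002), c(1, 2))
  once <- threshold_extinct(st, 0.001)
  twice <- threshold_extinct(once, 0.001)
  expect_equal(once, twice)
  expect_equal(once$populations, c(0.5, 0, 0, 0.002))
})

test_that("dilution-propagation fixes stable monocultures and is identity at zero passages", {
  sys <- monoculture_system()
  ref <- mono_closed_form(10, 1, 3, 1)
  ss <- integrate_to_steady_state(cr_state(0.05, 3), sys$traits, sys$env)
  same <- dilution_propagation(ss, sys$traits, sys$env, passages = 0)
  expect_identical(same, ss)
  after <- dilution_propagation(ss, sys$traits, sys$env,
                                passages = 3, dilution_factor = 100)
  expect_equal(after$populations, ref$N, tolerance = 1e-6)
  expect_equal(after$resources, ref$R, tolerance = 1e-6)
})

test_that("dilution removes species that fall below the threshold without regrowth", {
  # marginal species: steady density below dilution_factor * L_ext, so one
  # dilution pushes it under the threshold; with no resources left to
  # regrow on quickly it is zeroed on the spot
  sys <- monoculture_system(c = 10, m = 1, K = 0.11, gamma = 1, l = 0)
  scfg <- solver_config(extinction_mode = "absolute")
  ss <- integrate_to_steady_state(cr_state(0.02, 0.11), sys$traits,
                                  sys$env, scfg)
  expect_gt(ss$populations, 0)
  expect_lt(ss$populations, 0.1)  # below 100 * L_ext
  after <- dilution_propagation(ss, sys$traits, sys$env, scfg,
                                passages = 1, dilution_factor = 100)
  expect_equal(after$populations, 0)
})

test_that("perturbation filtering keeps a stable monoculture and is identity at zero rounds", {
  sys <- monoculture_system()
  ref <- mono_closed_form(10, 1, 3, 1)
  ss <- integrate_to_steady_state(cr_state(0.05, 3), sys$traits, sys$env)
  expect_identical(perturbation_filter(ss, sys$traits, sys$env, rounds = 0),
                   ss)
  set.seed(1)
  for (mag in c(0.2, 0.5, 0.9)) {
    out <- perturbation_filter(ss, sys$traits, sys$env,
                               rounds = 3, magnitude = mag)
    expect_equal(out$populations, ref$N, tolerance = 1e-6)
  }
})

test_that("invasion growth rate matches hand evaluations", {
  tr1 <- cr_traits(matrix(c(10, 0), 1, 2), 1)
  expect_equal(invasion_growth_rate(tr1, c(0, 0), leakage = 0.3), -1)
  expect_equal(invasion_growth_rate(tr1, c(0.5, 9), leakage = 0.8), 0)
  # zero uptake on every present resource: -m regardless of R
  tr0 <- cr_traits(matrix(c(0, 10), 1, 2), 2)
  expect_equal(invasion_growth_rate(tr0, c(5, 0), leakage = 0), -2)
})
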