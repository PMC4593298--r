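test_that("the registry returns pristine definitions and names valid choices", {
  expect_true(all(c("sixcurrent_demo", "sixcurrent_demo_totalito") %in%
                    list_models()))
  m1 <- get_model("sixcurrent_demo")
  expect_length(m1$conductance_keys, 6)
  expect_identical(length(m1$default_initial_state),
                   length(m1$state_names))
  # no state leakage: mutate one copy, fetch again
  pristine <- m1$default_parameters
  m1$default_parameters[["g_Kr"]] <- 0
  m2 <- get_model("sixcurrent_demo")
  expect_identical(m2$default_parameters, pristine)
  expect_gt(m2$default_parameters[["g_Kr"]], 0)
  expect_error(get_model("no_such_model"), "sixcurrent_demo")
})

test_that("demo model parameters are frozen (regression)", {
  p <- get_model("sixcurrent_demo")$default_parameters
  expect_equal(p[["g_Na"]], 11)
  expect_equal(p[["g_CaL"]], 0.12)
  expect_equal(p[["g_Kr"]], 0.042)
  expect_equal(p[["g_Ks"]], 0.012)
  expect_equal(p[["g_K1"]], 0.5)
  expect_equal(p[["g_to"]], 0.12)
  expect_equal(p[["E_K"]], -88)
  expect_equal(p[["f_tau"]], 200)
})

test_that("apply_block scales mapped conductances multiplicatively", {
  m <- get_model("sixcurrent_demo")
  p <- m$default_parameters
  cmp <- compound_spec("x", channel_block("hERG", pic50 = 6))

  # all-ones factors are the identity
  expect_identical(apply_block(m, p, block_factors(compound_spec("e"), 5)), p)

  f <- block_factors(cmp, 1)
  p2 <- apply_block(m, p, f)
  expect_equal(p2[["g_Kr"]], 0.5 * p[["g_Kr"]])
  expect_identical(p2[names(p2) != "g_Kr"], p[names(p) != "g_Kr"])
  expect_identical(p, m$default_parameters)  # input untouched

  # sequential block composes multiplicatively (idempotence in the product)
  f1 <- block_factors(cmp, 0.5)
  f2 <- block_factors(cmp, 2)
  seq_applied <- apply_block(m, apply_block(m, p, f1), f2)
  prod_f <- structure(unclass(f1) * unclass(f2), class = "ap_block_factors")
  expect_equal(seq_applied, apply_block(m, p, prod_f))
})

test_that("Ito aliasing: total-Ito models scale the total conductance", {
  mt <- get_model("sixcurrent_demo_totalito")
  expect_true(mt$ito_is_total)
  cmp <- compound_spec("x", channel_block("Kv4.3", pic50 = 6))
  f <- block_factors(cmp, pic50_to_ic50(6) * 3)  # 25% remaining
  expect_equal(f[["Ito"]], 0.25)
  p2 <- apply_block(mt, mt$default_parameters, f)
  expect_equal(p2[["g_to"]], 0.25 * mt$default_parameters[["g_to"]])
})

test_that("block on a channel the model lacks warns instead of dropping silently", {
  m <- get_model("sixcurrent_demo")
  m$conductance_keys <- m$conductance_keys[names(m$conductance_keys) != "IKs"]
  f <- block_factors(compound_spec("x", channel_block("IKs", pic50 = 7)), 10)
  expect_warning(p2 <- apply_block(m, m$default_parameters, f),
                 "IKs")
  expect_identical(p2, m$default_parameters)
})

test_that("the RHS vanishes at the root-found resting equilibrium", {
  m <- get_model("sixcurrent_demo")
  eq <- six_equilibrium_oracle(m$default_parameters)
  d <- evaluate_rhs(m, 0, eq, stim = 0)
  expect_lt(max(abs(d)), 1e-8)
  # the frozen default initial state is that equilibrium
  expect_equal(unname(eq), unname(m$default_initial_state), tolerance = 1e-7)
})

test_that("a depolarising stimulus raises V and conductances act linearly", {
  m <- get_model("sixcurrent_demo")
  eq <- six_equilibrium_oracle(m$default_parameters)
  d0 <- evaluate_rhs(m, 0, eq, stim = 0)
  d1 <- evaluate_rhs(m, 0, eq, stim = 40)
  expect_gt(d1[1], 0)
  expect_equal(d1[1] - d0[1], 40)  # stimulus enters dV/dt as +stim/C_m

  # doubling g_Kr doubles the I_Kr contribution to dV/dt
  st <- eq
  st[["V"]] <- -20; st[["xr"]] <- 0.5  # make I_Kr visibly active
  p <- m$default_parameters
  p2 <- p; p2[["g_Kr"]] <- 2 * p[["g_Kr"]]
  p0 <- p; p0[["g_Kr"]] <- 0
  dv <- function(pp) evaluate_rhs(m, 0, st, pp)[1]
  expect_equal(dv(p2) - dv(p), dv(p) - dv(p0), tolerance = 1e-12)
})

test_that("non-finite states are rejected with the state index", {
  m <- get_model("sixcurrent_demo")
  st <- m$default_initial_state
  st[["h"]] <- NaN
  expect_error(evaluate_rhs(m, 0, st), "index 3")
  expect_error(evaluate_rhs(m, 0, st), "h")
})

test_that("demo model pharmacology has the expected current roles", {
  m <- get_model("sixcurrent_demo")
  prot <- pacing_protocol(frequency = 1)
  ctrl <- demo_control_steady()
  b0 <- compute_biomarkers(ctrl$final_trace)

  half_block <- function(ch) {
    f <- block_factors(compound_spec("t", channel_block(ch, pic50 = 6)), 1)
    ss <- pace_to_steady(m, apply_block(m, m$default_parameters, f), prot,
                         initial_state = ctrl$end_state)
    compute_biomarkers(ss$final_trace)
  }
  expect_gt(half_block("IKr")$apd90, b0$apd90)      # IKr block prolongs
  expect_lt(half_block("ICaL")$apd90, b0$apd90)     # ICaL block shortens
  expect_lt(half_block("INa")$dvdt_max, b0$dvdt_max) # INa block slows upstroke
})

test_that("demo model AP morphology is within the physiological windows", {
  ctrl <- demo_control_steady()
  b <- compute_biomarkers(ctrl$final_trace)
  expect_true(b$rest_v >= -90 && b$rest_v <= -75)
  expect_true(b$peak_v >= 10 && b$peak_v <= 50)
  expect_true(b$apd90 >= 200 && b$apd90 <= 350)
  expect_true(ctrl$converged)
  expect_lte(ctrl$paces_run, 1000)
})
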