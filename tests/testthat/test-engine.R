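test_that("pacing_protocol validates its fields", {
  p <- pacing_protocol(frequency = 1)
  expect_equal(p$period, 1000)
  expect_equal(p$abs_tol, 1e-6)
  expect_equal(p$rel_tol, 1e-8)
  expect_equal(p$output_step, 0.1)
  expect_equal(p$steady_norm_tol, 1e-6)
  expect_equal(p$max_paces, 300L)               # 5 simulated minutes at 1 Hz
  expect_equal(pacing_protocol(frequency = 10)$max_paces, 1800L)
  expect_error(pacing_protocol(frequency = 0), "frequency")
  expect_error(pacing_protocol(stim_offset = 990, stim_duration = 20),
               "fit inside")
  expect_error(pacing_protocol(output_step = 0.3), "divide")
})

test_that("the output grid is exactly 0, 0.1, ..., period", {
  m <- get_model("sixcurrent_demo")
  pr <- pacing_protocol(frequency = 1)
  pace <- simulate_pace(m, state = m$default_initial_state, protocol = pr)
  expect_length(pace$trace$times, 10001)
  expect_equal(pace$trace$times, seq(0, 1000, by = 0.1))
  expect_true(all(is.finite(pace$trace$voltages)))
  expect_named(pace$end_state, m$state_names)
})

test_that("an unstimulated cell at equilibrium stays at equilibrium", {
  m <- get_model("sixcurrent_demo")
  eq <- six_equilibrium_oracle(m$default_parameters)
  pr <- pacing_protocol(frequency = 1, stim_amplitude = 0)
  pace <- simulate_pace(m, state = eq, protocol = pr)
  expect_lt(max(abs(pace$trace$voltages - eq[["V"]])), 1e-4)

  # stimulus conservation: pacing terminates after 2 paces, converged
  ss <- pace_to_steady(m, protocol = pr, initial_state = eq)
  expect_true(ss$converged)
  expect_equal(ss$paces_run, 2)
})

test_that("pace_to_steady applies the L2 pace-to-pace criterion", {
  ss <- demo_control_steady()
  expect_true(ss$converged)
  expect_lt(ss$final_norm, 1e-6)
  expect_lte(ss$paces_run, 300)

  # norm sequence crosses each decade threshold in nondecreasing pace order
  first_below <- vapply(c(1e-2, 1e-4, 1e-6),
                        function(th) which(ss$norms < th)[1], numeric(1))
  expect_false(anyNA(first_below))
  expect_true(all(diff(first_below) >= 0))
})

test_that("restarting from a converged state re-converges within 2 paces", {
  m <- get_model("sixcurrent_demo")
  ss <- demo_control_steady()
  again <- pace_to_steady(m, protocol = pacing_protocol(frequency = 1),
                          initial_state = ss$end_state)
  expect_true(again$converged)
  expect_lte(again$paces_run, 2)
})

test_that("max_paces = 1 returns one pace, unconverged, with no previous trace", {
  m <- get_model("sixcurrent_demo")
  pr <- pacing_protocol(frequency = 1, max_paces = 1)
  ss <- pace_to_steady(m, protocol = pr)
  expect_equal(ss$paces_run, 1)
  expect_false(ss$converged)
  expect_null(ss$previous_trace)
  expect_true(is.na(ss$final_norm))
})

test_that("identical inputs reproduce bit-identical traces", {
  m <- get_model("sixcurrent_demo")
  pr <- pacing_protocol(frequency = 1)
  a <- simulate_pace(m, state = m$default_initial_state, protocol = pr)
  b <- simulate_pace(m, state = m$default_initial_state, protocol = pr)
  expect_identical(a$trace$voltages, b$trace$voltages)
  expect_identical(a$end_state, b$end_state)
})

test_that("tightening tolerances 100x barely moves APD90", {
  m <- get_model("sixcurrent_demo")
  ss <- demo_control_steady()
  run_from_steady <- function(abs_tol, rel_tol) {
    pr <- pacing_protocol(frequency = 1, abs_tol = abs_tol, rel_tol = rel_tol)
    compute_biomarkers(simulate_pace(m, state = ss$end_state,
                                     protocol = pr)$trace)$apd90
  }
  apd_default <- run_from_steady(1e-6, 1e-8)
  apd_tight <- run_from_steady(1e-8, 1e-10)
  expect_lt(abs(apd_default - apd_tight), 0.5)
})

test_that("solver failures carry the failure context", {
  m <- get_model("sixcurrent_demo")
  st <- m$default_initial_state
  st[["V"]] <- Inf
  expect_error(simulate_pace(m, state = st,
                             protocol = pacing_protocol(frequency = 1)),
               "non-finite")
})

test_that("trace CSV export writes the two-column layout", {
  ss <- demo_control_steady()
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(ss$final_trace, path, step = 1)
  df <- utils::read.csv(path)
  expect_identical(names(df), c("time_ms", "V_mV"))
  expect_equal(nrow(df), 1001)
  expect_equal(df$time_ms[2] - df$time_ms[1], 1)
})
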