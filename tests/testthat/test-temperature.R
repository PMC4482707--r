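beta_fit <- strobilation_response()

test_that("the Gaussian strobilation curve evaluates as printed", {
  expect_equal(eval_response(beta_fit, 16.8108), 0.1430)
  expect_equal(eval_response(beta_fit, 16.8108 + 10.5302,
                             warn_outside = FALSE),
               0.1430 * exp(-1))
  expect_equal(eval_response(beta_fit, 16.8108 - 10.5302,
                             warn_outside = FALSE),
               0.1430 * exp(-1))
  expect_equal(eval_response(beta_fit, 7), 0.06003, tolerance = 1e-4)
  expect_warning(eval_response(beta_fit, 25), "outside")
})

test_that("the cubic budding curve evaluates exactly as printed", {
  alpha_fit <- budding_response_printed()
  expect_equal(eval_response(alpha_fit, 0, warn_outside = FALSE),
               -871.29 + 0.0378)
  expect_equal(eval_response(alpha_fit, 12),
               1.9272 * 1728 - 30.3904 * 144 + 294.7234 * 12 -
                 871.29 + 0.0378)
  offset_only <- cubic_offset_response(0, 0, 0, 0, offset = 0.0378)
  expect_equal(eval_response(offset_only, 15), 0.0378)
})

test_that("the Gaussian peak sits exactly at the fitted center", {
  Tg <- seq(7, 22, by = 1e-3)
  v <- eval_response(beta_fit, Tg, warn_outside = FALSE)
  expect_equal(Tg[which.max(v)], 16.811, tolerance = 1e-6)
  # analytic argmax
  expect_equal(beta_fit$center, 16.8108)
  expect_true(all(v <= beta_fit$amplitude))
})

test_that("per-degree growth stairs follow the relative-change
          definition", {
  st <- growth_stairs(beta_fit, 7, 15)
  expect_equal(st$T_from, 7:14)
  manual <- 100 * (eval_response(beta_fit, 8) -
                     eval_response(beta_fit, 7)) /
    eval_response(beta_fit, 7)
  expect_equal(st$relative_growth_pct[1], manual)
  # below the thermal peak the stairs are positive and decreasing
  expect_true(all(st$relative_growth_pct > 0))
  expect_true(all(diff(st$relative_growth_pct) < 0))

  flat <- gaussian_response(0.1, 16, 1e9, domain = c(7, 22))
  expect_lt(max(abs(growth_stairs(flat, 7, 15)$relative_growth_pct)),
            1e-6)

  zero_cross <- cubic_offset_response(0, 0, 1, -8, 0)
  expect_error(growth_stairs(zero_cross, 7, 10), "zero")
  expect_error(growth_stairs(beta_fit, 7.5, 9), "integer")
})

test_that("least squares recovers generating parameters from noiseless
          samples", {
  obs <- data.frame(T = 7:22,
                    rate = eval_response(beta_fit, 7:22))
  fit <- fit_response(obs, "gaussian")
  expect_equal(fit$response$amplitude, 0.1430, tolerance = 1e-6)
  expect_equal(fit$response$center, 16.8108, tolerance = 1e-6)
  expect_equal(fit$response$width, 10.5302, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-20)

  truth <- cubic_offset_response(2e-4, -0.01, 0.15, -0.6, 0.0378)
  obs_c <- data.frame(T = 7:22,
                      rate = pmax(eval_response(truth, 7:22), 0))
  fit_c <- fit_response(obs_c, "cubic_offset")
  expect_equal(fit_c$response$c3, 2e-4, tolerance = 1e-6)
  expect_equal(fit_c$response$c2, -0.01, tolerance = 1e-6)
  expect_equal(fit_c$response$c1, 0.15, tolerance = 1e-6)
  # additive offset is absorbed into the fitted intercept
  expect_equal(fit_c$response$c0 + fit_c$response$offset,
               -0.6 + 0.0378, tolerance = 1e-6)
  expect_lt(fit_c$sse, 1e-20)
})

test_that("fitting rejects under-determined and degenerate inputs", {
  expect_error(fit_response(data.frame(T = c(10, 12),
                                       rate = c(0.1, 0.12)),
                            "gaussian"), "at least 3")
  expect_error(fit_response(data.frame(T = rep(10, 5),
                                       rate = runif(5)),
                            "gaussian"), "distinct temperatures")
  expect_error(fit_response(data.frame(T = 7:10, rate = c(-0.1, 1, 1, 1)),
                            "gaussian"), "nonnegative")
})

test_that("a noisy fixture still yields a usable Gaussian fit", {
  sp <- fixture_spec(20240601, "gaussian", noise_sd = 0.005,
                     grid = 7:22, truth = beta_fit)
  fit <- fit_response(make_rate_dataset(sp), "gaussian")
  expect_lt(abs(fit$response$center - 16.8108), 0.5)
  expect_lt(abs(fit$response$amplitude - 0.1430) / 0.1430, 0.10)
})

test_that("rate observation files are read with the T,rate contract", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("T,rate", "7,0.06", "12,0.11", "16,0.14"), f)
  obs <- read_rate_observations(f)
  expect_equal(obs$T, c(7, 12, 16))
  writeLines(c("temp,rate", "7,0.06"), f)
  expect_error(read_rate_observations(f), "header")
})

test_that("steady-state sweeps reduce, classify, and report the
          attractor per grid value", {
  sw <- sweep_steady_state(scypho_preset("V2"), "d4",
                           grid = c(0.0001, 0.01, 0.05, 0.1, 0.3))
  expect_true(all(sw$valid))
  expect_true(all(sw$regime == "COEXISTENCE_GAS"))
  # predation release: both stages decrease along increasing d4
  expect_true(all(diff(sw$P_star) < 0))
  expect_true(all(diff(sw$M_star) < 0))
  # every row satisfies its own steady-state condition
  for (k in seq_len(nrow(sw))) {
    p <- unclass(scypho_preset("V2")); p$d4 <- sw$param_value[k]
    rp <- reduce_params(do.call(scypho_params, p))
    f <- vector_field(rp, sw$P_star[k], sw$M_star[k])
    expect_lt(max(abs(f)),
              1e-6 * (1 + max(sw$P_star[k], sw$M_star[k])))
  }
})

test_that("invalid grid points are flagged and the sweep continues", {
  sw <- sweep_steady_state(scypho_preset("V1"), "b1",
                           grid = c(-0.01, 0, 0.01))
  expect_equal(sw$valid, c(FALSE, FALSE, TRUE))
  expect_true(is.na(sw$P_star[1]) && !is.na(sw$P_star[3]))
  expect_error(sweep_steady_state(scypho_preset("V1"), "b1",
                                  grid = c(0.01, 0.01)), "monotone")
  expect_error(sweep_steady_state(scypho_preset("V1"), "bogus",
                                  grid = c(0.01)), "unknown parameter")
})

test_that("temperature sweeps draw the vital rates from the response
          curves", {
  tsw <- sweep_steady_state(scypho_preset("V2"), "temperature",
                            grid = seq(7, 22, by = 1))
  expect_true(all(tsw$valid))
  # warm mid-range temperatures support larger medusa populations than
  # either domain edge
  mid <- tsw$M_star[tsw$param_value == 16]
  expect_gt(mid, tsw$M_star[tsw$param_value == 7])
  expect_gt(mid, tsw$M_star[tsw$param_value == 22])
  # the synthetic budding curve stays in the biological range
  a <- budding_response_synthetic()
  v <- eval_response(a, seq(7, 22, 0.1), warn_outside = FALSE)
  expect_gt(min(v), 0.02)
  expect_lt(max(v), 0.16)
})

test_that("sweep CSV export uses the documented columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  sw <- sweep_steady_state(scypho_preset("V1"), "d4",
                           grid = c(0.01, 0.05))
  write_sweep(sw, f)
  expect_identical(readLines(f, n = 1L),
                   "param_value,P_star,M_star,regime,valid")
})
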