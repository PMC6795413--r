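test_that("the state layout has 11 variables with 2 phytoplankton groups", {
  expect_length(nemuro_variables(), 11L)
  expect_identical(nemuro_phytoplankton(), c("PS", "PL"))
  grid <- small_grid(3)
  expect_length(nemuro_default_state(grid), 33L)
  expect_true(all(nemuro_default_state(grid) >= 0))
})

test_that("biology conserves nitrogen per cell and silicon in its sub-cycle", {
  grid <- small_grid(4)
  p <- nemuro_params()
  for (x in random_states(grid, 3)) {
    light <- light_attenuation(x, p, grid, 150)
    y <- bgc_source_step(x, p, light, grid$dt)
    inv0 <- nutrient_inventory(x, p)
    inv1 <- nutrient_inventory(y, p)
    expect_lt(rel_diff(inv1$nitrogen, inv0$nitrogen), 1e-12)
    expect_lt(rel_diff(inv1$silicon, inv0$silicon), 1e-12)
  }
  # no spontaneous generation from an empty ocean
  zero <- numeric(44)
  expect_identical(bgc_source_step(zero, p, rep(100, 4), grid$dt), zero)
})

test_that("negative concentrations are rejected with cell and variable named", {
  grid <- small_grid(2)
  p <- nemuro_params()
  x <- nemuro_default_state(grid)
  x[flat_index(state_index(2, nemuro_variables()), "NH4", 2)] <- -0.1
  expect_error(bgc_source_step(x, p, rep(100, 2), grid$dt), "NH4.*cell 2")
})

test_that("grazing responds only to the plankton variables", {
  grid <- small_grid(2)
  p <- nemuro_params()
  model <- nemuro_model(p, grid)
  seg <- Filter(function(s) s$name == "grazing", model$segments)[[1]]
  x <- nemuro_default_state(grid)
  index <- model$index
  y0 <- seg$fn(x)
  x2 <- x
  nut <- c("NO3", "NH4", "DON", "SiOH4")
  x2[flat_index(index, nut)] <- x2[flat_index(index, nut)] * 1.7
  y2 <- seg$fn(x2)
  # the grazing transfers are bitwise unchanged by a nutrient-only change
  zoo <- flat_index(index, c("PS", "PL", "ZS", "ZL", "ZP", "PON", "Opal"))
  expect_identical(y2[zoo], y0[zoo])
})

test_that("light attenuates monotonically and responds to shading with the right sign", {
  grid <- column_grid(n_layers = 6, dz = 4, dt = 3600)
  p <- nemuro_params()
  x <- nemuro_default_state(grid)
  irr <- light_attenuation(x, p, grid, 200)
  expect_true(all(diff(irr) < 0))
  # no phytoplankton: pure water-only exponential to the layer midpoints
  x0 <- numeric(length(x))
  irr0 <- light_attenuation(x0, p, grid, 200)
  mid <- cumsum(grid$dz) - grid$dz / 2
  expect_equal(irr0, 200 * exp(-p$att_w * mid), tolerance = 1e-14)
  # more phytoplankton in the surface layer dims every layer below
  index <- state_index(6, nemuro_variables())
  x2 <- x
  x2[flat_index(index, "PS", 1)] <- x2[flat_index(index, "PS", 1)] + 1
  irr2 <- light_attenuation(x2, p, grid, 200)
  expect_true(all(irr2 < irr))
})

test_that("sinking is a conservative linear upwind transport with reported bottom flux", {
  grid <- small_grid(4)
  p <- nemuro_params()
  x <- nemuro_default_state(grid)
  index <- state_index(4, nemuro_variables())
  y <- sinking_step(x, p, grid)
  flux <- attr(y, "bottom_flux")
  for (v in c("PON", "Opal")) {
    inv_before <- sum(x[flat_index(index, v)] * grid$dz)
    inv_after <- sum(y[flat_index(index, v)] * grid$dz)
    expect_equal(inv_after - inv_before, -flux[[v]], tolerance = 1e-12)
  }
  # linear: step(alpha x) = alpha step(x); zero speed is the identity
  y2 <- sinking_step(2.5 * x, p, grid)
  expect_equal(as.numeric(y2), 2.5 * as.numeric(y), tolerance = 1e-13)
  p0 <- nemuro_params(w_pon = 0, w_opal = 0)
  expect_equal(as.numeric(sinking_step(x, p0, grid)), x, tolerance = 0)
  # CFL guard
  expect_error(sinking_step(x, nemuro_params(w_pon = 500), grid), "CFL")
})

test_that("vertical diffusion conserves volume-weighted totals and fixes uniform columns", {
  grid <- column_grid(n_layers = 5, dz = c(2, 3, 5, 8, 10), kv = 2e-4, dt = 1800)
  index <- state_index(5, nemuro_variables())
  x <- nemuro_default_state(grid)
  y <- transport_step(x, grid)
  for (v in nemuro_variables()) {
    expect_lt(abs(sum(y[flat_index(index, v)] * grid$dz) -
                  sum(x[flat_index(index, v)] * grid$dz)) /
              sum(x[flat_index(index, v)] * grid$dz + 1e-30), 1e-12)
  }
  u <- rep(rep(1.7, 11), 5)
  expect_equal(transport_step(u, grid), u, tolerance = 1e-14)
  expect_error(column_grid(n_layers = 4, dz = 0.5, kv = 1e-3, dt = 3600), "stability")
})

test_that("hand-coded linear adjoints equal the dual-number brute force", {
  grid <- small_grid(3)
  p <- nemuro_params()
  model <- nemuro_model(p, grid)             # hand-coded transport/sinking/light
  x <- nemuro_default_state(grid)
  w <- withr::with_seed(9, rnorm(model$n))
  for (nm in c("transport", "sinking")) {
    seg <- Filter(function(s) s$name == nm, model$segments)[[1]]
    seg_model <- model_function(seg$fn, model$index)
    expect_lt(rel_diff(seg$adjoint_fn(x, w), adjoint_bruteforce(seg_model, x, w)), 1e-12)
    expect_lt(rel_diff(seg$tlm_fn(x, w), as.numeric(evaluate_tlm(seg_model, x, w))), 1e-12)
  }
  # the special-treatment photosynthesis path against its dual-only twin
  model_dual <- nemuro_model(p, grid, hand_coded = FALSE)
  expect_lt(rel_diff(adjoint_segmented(model, x, w),
                     adjoint_segmented(model_dual, x, w)), 1e-12)
  expect_lt(rel_diff(tlm_segmented(model, x, w),
                     as.numeric(evaluate_tlm(model, x, w))), 1e-12)
})

test_that("the full model step passes adjoint verification on random states", {
  grid <- small_grid(5, dt = 3600)
  p <- nemuro_params()
  model <- nemuro_model(p, grid)
  for (x in random_states(grid, 3, seed = 21)) {
    dp <- dot_product_test(model, x, trials = 5, seed = 17)
    expect_true(attr(dp, "pass"))
  }
  expect_true(check_footprints(model, nemuro_default_state(grid)))
})

test_that("segmentation reproduces the brute-force adjoint with far fewer seeds", {
  grid <- small_grid(2)
  p <- nemuro_params()
  model <- nemuro_model(p, grid)
  x <- nemuro_default_state(grid)
  w <- withr::with_seed(13, rnorm(model$n))
  expect_lt(rel_diff(adjoint_segmented(model, x, w),
                     adjoint_bruteforce(model, x, w)), 1e-12)
  reset_counter(model)
  adjoint_segmented(model, x, w)
  sd <- seed_dims(model)
  expect_identical(unname(sd["grazing"]), 5L)        # plankton only, not 22
  expect_identical(unname(sd["mortality"]), 5L)
  expect_identical(unname(sd["remineralization"]), 4L)
  expect_true(all(sd < model$n))
})

test_that("chlorophyll is the fixed-ratio sum of the phytoplankton", {
  grid <- small_grid(1)
  p1 <- nemuro_params(chl2n = 1)
  x <- numeric(11); names11 <- nemuro_variables()
  x[match("PS", names11)] <- 0.3
  x[match("PL", names11)] <- 0.7
  expect_equal(chlorophyll_diagnostic(x, p1), 1.0)
  expect_equal(chlorophyll_diagnostic(2 * x, p1), 2.0)
  expect_identical(chlorophyll_diagnostic(numeric(11), nemuro_params()), 0)
})

test_that("with all biological rates at zero the step reduces to transport", {
  grid <- small_grid(4)
  p0 <- nemuro_params(vmax_ps = 0, vmax_pl = 0, gr_zs_ps = 0, gr_zl_ps = 0,
                      gr_zl_pl = 0, gr_zl_zs = 0, gr_zp_zl = 0, mort_p = 0,
                      mort_p2 = 0, mort_z = 0, mort_z2 = 0, vp2n = 0, vp2d = 0,
                      vd2n = 0, nitrif = 0, opal_diss = 0, w_pon = 0, w_opal = 0)
  x <- nemuro_default_state(grid)
  expect_equal(model_step(x, p0, grid), transport_step(x, grid), tolerance = 1e-14)
})
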