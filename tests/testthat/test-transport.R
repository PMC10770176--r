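test_that("masked diffusion matches the split-stencil hand oracle on 5x5 grids", {
  dom <- toy_masked_domain() # unit grid, node (3,3) inside a cell
  expect_equal(sum(dom$interior), 1L)
  expect_true(dom$interior[3, 3])
  set.seed(4)
  for (case in 1:5) {
    v0 <- matrix(runif(25), 5, 5)
    v0[dom$interior] <- 0
    for (bnd in list(c(TRUE, TRUE), c(FALSE, FALSE))) {
      fld <- scalar_field("tracer", dom, v0, D = 1)
      dt <- 0.4 # s = dt * D / h^2 = 0.4
      got <- masked_diffusion_step(fld, dom, dt,
                                   left = if (bnd[1]) "dirichlet" else "reflect",
                                   right = if (bnd[2]) "dirichlet" else "reflect")
      ref <- reference_diffusion_step(v0, !dom$interior, 0.4, bnd[1], bnd[2])
      expect_equal(got$values, ref, tolerance = 1e-14)
    }
  }
})

test_that("diffusion leaves a uniform field unchanged and rejects unstable steps", {
  dom <- toy_masked_domain()
  fld <- scalar_field("tracer", dom, 3.7, D = 1)
  out <- masked_diffusion_step(fld, dom, 0.3, left = "reflect",
                               right = "reflect")
  expect_equal(out$values, fld$values, tolerance = 1e-15)
  expect_error(masked_diffusion_step(fld, dom, 0.6), "0.600")
})

test_that("diffusion conserves interstitial mass under reflecting boundaries", {
  fx <- small_tissue()
  set.seed(9)
  v <- matrix(runif(prod(dim(fx$dom$interior)), 0, 10),
              nrow(fx$dom$interior))
  v[fx$dom$interior] <- 0
  fld <- scalar_field("tracer", fx$dom, v, D = 1000)
  m0 <- interstitial_mass(fld$values, fx$dom)
  for (k in 1:20) {
    fld <- masked_diffusion_step(fld, fx$dom, 1.5e-3, left = "reflect",
                                 right = "reflect")
    m1 <- interstitial_mass(fld$values, fx$dom)
    expect_lt(abs(m1 - m0) / m0, 1e-12)
    m0 <- m1
  }
  # maximum principle: no new extrema
  expect_lte(max(fld$values), max(v) + 1e-12)
  expect_gte(min(fld$values[!fx$dom$interior]), min(v[!fx$dom$interior]) - 1e-12)
})

test_that("upwind advection is the identity at zero velocity and monotone", {
  fx <- small_tissue()
  flow0 <- uniform_flow(fx$dom, 0)
  set.seed(2)
  v <- matrix(runif(prod(dim(fx$dom$interior))), nrow(fx$dom$interior))
  v[fx$dom$interior] <- 0
  fld <- scalar_field("tracer", fx$dom, v, D = 0)
  expect_equal(upwind_advection_step(fld, flow0, fx$dom, 0.01)$values,
               fld$values, tolerance = 1e-15)

  # rightward transport of a held left-edge value on a cell-free channel
  emp <- empty_tissue()$dom
  flowr <- uniform_flow(emp, 30)
  fld <- scalar_field("tracer", emp, 0, D = 0)
  fld$values[1, ] <- 5
  tv0 <- NULL
  for (k in 1:400) {
    fld$values[1, ] <- 5
    fld <- upwind_advection_step(fld, flowr, emp, 0.005)
    prof <- strip_average_profile(fld, emp)
    tv <- sum(abs(diff(prof)))
    if (!is.null(tv0)) expect_lte(tv, tv0 + 1e-12)
    tv0 <- tv
  }
  prof <- strip_average_profile(fld, emp)
  expect_gt(prof[10], 0.5) # front has advanced past x = 18 um
  expect_true(all(diff(prof) <= 1e-12)) # monotone front
  expect_error(upwind_advection_step(fld, uniform_flow(emp, 500), emp, 0.01),
               "CFL")
})

test_that("upwind transport tracks a semi-Lagrangian reference at low CFL", {
  emp <- suppressMessages(generate_synthetic_tissue(
    grid_spec(0, 200, 0, 8, h = 2), 0, seed = 1))
  u <- 20; dt <- 0.01 # CFL = 0.1
  flow <- uniform_flow(emp, u)
  xs <- seq(0, 200, by = 2)
  gauss <- exp(-((xs - 50) / 15)^2)
  v <- matrix(gauss, emp$grid$N_i, emp$grid$N_j)
  fld <- scalar_field("tracer", emp, v, D = 0)
  nst <- 200 # advect by 40 um
  for (k in seq_len(nst)) fld <- upwind_advection_step(fld, flow, emp, dt)
  # independent semi-Lagrangian reference: interpolate back-traced profile
  prof_ref <- gauss
  for (k in seq_len(nst))
    prof_ref <- approx(xs, prof_ref, xout = pmax(xs - u * dt, 0),
                       rule = 2)$y
  got <- strip_average_profile(fld, emp)
  l1 <- sum(abs(got - prof_ref)) / sum(prof_ref)
  expect_lt(l1, 0.05)
  # and both are near the exact translate, within first-order smearing
  exact <- exp(-((xs - 90) / 15)^2)
  expect_lt(sum(abs(got - exact)) / sum(exact), 0.35)
})

test_that("oxygen uptake law reproduces its tier arithmetic in both branch forms", {
  p <- transport_params() # normalized (continuous) severe branch
  expect_equal(oxygen_uptake_rate(60, 0, p), 0.85)
  expect_equal(oxygen_uptake_rate(60, 50, p), 0.85 * 7.5 / 3) # 2.125
  expect_equal(oxygen_uptake_rate(60, 5, p), 0.85)
  expect_equal(oxygen_uptake_rate(60, 9, p), 0.85 * 5 / 3)  # inclusive tier edge
  expect_equal(oxygen_uptake_rate(60, 88, p), 0.85 * 12.5 / 3)
  expect_equal(oxygen_uptake_rate(4, 0, p), 0.85 * 4 / 5) # tapers to zero
  expect_equal(oxygen_uptake_rate(5, 77, p), 0.85 * 7.5 / 3)
  # the branch is continuous at the knee
  expect_equal(oxygen_uptake_rate(5 - 1e-9, 0, p), oxygen_uptake_rate(5, 0, p),
               tolerance = 1e-6)
  # bare-product branch arithmetic
  pp <- transport_params(severe_uptake = "bare")
  expect_equal(oxygen_uptake_rate(4, 0, pp), 3.4)
  expect_equal(oxygen_uptake_rate(4, 100, pp), 3.4) # sensitizer ignored here
})

test_that("activation is gated at the hypoxia threshold, boundary inclusive", {
  p <- transport_params()
  expect_equal(activation_rate(5, p), 0.9)
  expect_equal(activation_rate(60, p), 0)
  expect_equal(activation_rate(10, p), 0.9) # gamma == gamma_hyp activates
  expect_equal(activation_rate(10 + 1e-12, p), 0)
})

test_that("steady-state oxygen matches 1D closed forms on a cell-free channel", {
  g <- grid_spec(0, 100, 0, 20, h = 2)
  emp <- generate_synthetic_tissue(g, 0, seed = 1)
  p <- transport_params()
  bcv <- vessel_bc()
  # pure diffusion: linear profile
  oxy <- steady_state_oxygen(emp, NULL, p, bcv, tol = 1e-12)
  xs <- seq(0, 100, by = 2)
  expect_equal(strip_average_profile(oxy, emp), 60 * (100 - xs) / 100,
               tolerance = 1e-6)
  # constant advection: c(x) = g_in (e^{uL/D} - e^{ux/D}) / (e^{uL/D} - 1)
  u <- 5
  oxy2 <- steady_state_oxygen(emp, uniform_flow(emp, u), p, bcv, tol = 1e-12)
  ref <- 60 * (exp(u * 100 / 1000) - exp(u * xs / 1000)) /
    (exp(u * 100 / 1000) - 1)
  expect_equal(strip_average_profile(oxy2, emp), ref, tolerance = 0.01)
})

test_that("dense tissue develops a monotone gradient with a hypoxic margin", {
  fx <- small_tissue()
  prof <- strip_average_profile(fx$oxy, fx$dom)
  # strip means decrease with distance from the vessel (allow node noise)
  sm <- stats::filter(prof, rep(1 / 5, 5), sides = 2)
  expect_true(all(diff(sm[!is.na(sm)]) < 0.5))
  b <- hypoxia_border(fx$oxy, fx$dom)
  expect_gt(b, 0)
  expect_lt(b, 100) # hypoxic region exists at the distal side
  expect_true(all(fx$oxy$values >= 0))
})

test_that("active drug decays with a ten-minute half-life in pure decay", {
  emp <- generate_synthetic_tissue(grid_spec(0, 40, 0, 20, h = 2), 0, seed = 1)
  p <- transport_params(dt = 0.01)
  cells <- cell_states(emp)
  ei <- scalar_field("inactive_drug", emp, 0, D = p$D_eta_i)
  ea <- scalar_field("active_drug", emp, 8, D = p$D_eta_a)
  oxy <- scalar_field("oxygen", emp, 60, D = p$D_gamma) # normoxic: no activation
  nst <- round(10 / p$dt)
  for (k in seq_len(nst)) {
    st <- drug_step(ei, ea, oxy, NULL, emp, cells, p, p$dt)
    ei <- st$eta_i; ea <- st$eta_a
  }
  inner <- as.vector(ea$values[2:(emp$grid$N_i - 1), ])
  expect_equal(unique(round(inner, 10)), 4, tolerance = 1e-3)
})

test_that("activation transfers mass exactly and only under hypoxia", {
  fx <- small_tissue()
  p <- transport_params(omega_a = 0, D_eta_i = 0, D_eta_a = 0)
  cells0 <- cell_states(fx$dom)
  cells0$alive <- FALSE # disable uptake to isolate activation
  set.seed(5)
  vi0 <- matrix(runif(prod(dim(fx$dom$interior))), nrow(fx$dom$interior))
  vi0[fx$dom$interior] <- 0
  ei <- scalar_field("inactive_drug", fx$dom, vi0, D = 0)
  ea <- scalar_field("active_drug", fx$dom, 0, D = 0)
  st <- drug_step(ei, ea, fx$oxy, NULL, fx$dom, cells0, p, p$dt)
  hyp <- fx$oxy$values <= 10 & !fx$dom$interior
  # node-wise conservation of eta_i + eta_a
  expect_equal(st$eta_i$values + st$eta_a$values, vi0, tolerance = 1e-14)
  # 90% converted at hypoxic nodes, nothing elsewhere
  expect_equal(st$eta_a$values[hyp], 0.9 * vi0[hyp], tolerance = 1e-14)
  expect_true(all(st$eta_a$values[!hyp] == 0))
})

test_that("sensitizer evolves exactly like an equal-diffusivity passive tracer", {
  fx <- small_tissue()
  p <- transport_params()
  set.seed(6)
  v0 <- matrix(runif(prod(dim(fx$dom$interior)), 0, 101),
               nrow(fx$dom$interior))
  v0[fx$dom$interior] <- 0
  xi <- scalar_field("sensitizer", fx$dom, v0, D = p$D_xi)
  tr <- scalar_field("oxygen_tracer", fx$dom, v0, D = p$D_gamma)
  for (k in 1:50) {
    xi <- sensitizer_step(xi, fx$flow, fx$dom, p$dt)
    tr <- masked_diffusion_step(tr, fx$dom, p$dt)
    tr <- upwind_advection_step(tr, fx$flow, fx$dom, p$dt)
  }
  expect_identical(xi$values, tr$values)
  # with open (Dirichlet zero) edges and no source, mass cannot increase
  m <- interstitial_mass(v0, fx$dom)
  expect_lte(interstitial_mass(xi$values, fx$dom), m)
})

test_that("vessel boundary values follow the bolus windows and vasodilator", {
  bcv <- vessel_bc(hap_window = c(5, 15), sens_window = c(40, 65),
                   vaso_window = c(10, 35))
  v <- hapflow:::vessel_values(bcv, 2) # baseline before any window
  expect_equal(unlist(v), c(gamma = 60, eta_i = 0, eta_a = 0, xi = 0,
                            lambda_flow = 1))
  v <- hapflow:::vessel_values(bcv, 12) # HAP bolus overlapping vasodilator
  expect_equal(v$eta_i, 25)
  expect_equal(v$gamma, 30)
  expect_equal(v$lambda_flow, 0.5)
  v <- hapflow:::vessel_values(bcv, 50) # sensitizer alone
  expect_equal(v$xi, 101)
  expect_equal(v$gamma, 60)
  # applied to fields: left edge takes the Dirichlet data
  fx <- small_tissue()
  flds <- list(oxygen = fx$oxy,
               xi = scalar_field("sensitizer", fx$dom, 0, D = 1000))
  out <- apply_vessel_boundary(flds, bcv, 12)
  expect_true(all(out$oxygen$values[1, ] == 30))
  expect_equal(attr(out, "lambda_flow"), 0.5)
})

test_that("duplicate boluses of one compound are rejected", {
  expect_error(treatment_schedule(bolus("HAP", 5), bolus("HAP", 50)),
               "duplicate bolus.*HAP")
  expect_error(treatment_schedule(bolus("Sens", 170)), "horizon")
})
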