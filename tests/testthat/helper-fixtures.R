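# Shared fixtures, built in code and memoised for the session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

# Small tissue (40 cells on a 100 x 50 um patch) with solved flow and
# steady-state oxygen; enough structure for hypoxia without full-scale cost.
small_tissue <- function() memo("small", function() {
  dom <- suppressMessages(generate_synthetic_tissue(
    grid_spec(0, 100, 0, 50, h = 2), n_cells = 40, mean_radius = 4, seed = 7))
  sys <- solve_boundary_forces(stokes_system(dom))
  flow <- compute_velocity_field(dom, sys)
  oxy <- steady_state_oxygen(dom, flow)
  list(dom = dom, sys = sys, flow = flow, oxy = oxy)
})

# Cell-free channel on the same patch (vessel + walls only).
empty_tissue <- function() memo("empty", function() {
  dom <- generate_synthetic_tissue(grid_spec(0, 100, 0, 50, h = 2),
                                   n_cells = 0, seed = 1)
  sys <- solve_boundary_forces(stokes_system(dom))
  list(dom = dom, sys = sys, flow = compute_velocity_field(dom, sys))
})

# A 5x5 unit-spaced domain whose center node is inside a small square cell;
# the masked-stencil hand oracle runs here.
toy_masked_domain <- function() memo("toy", function() {
  f <- tempfile(fileext = ".txt")
  writeLines(c("1 1.5 1.5", "1 2.5 1.5", "1 2.5 2.5", "1 1.5 2.5"), f)
  dom <- suppressMessages(load_tissue(f, grid_spec(0, 4, 0, 4, h = 1),
                                      epsilon = 0.5))
  unlink(f)
  dom
})

# Uniform translating flow for advection tests.
uniform_flow <- function(domain, ux, uy = 0) {
  g <- domain$grid
  mx <- matrix(ux, g$N_i, g$N_j); my <- matrix(uy, g$N_i, g$N_j)
  mx[domain$interior] <- 0; my[domain$interior] <- 0
  structure(list(ux = mx, uy = my, base_ux = mx, base_uy = my, lambda = 1),
            class = "flow_field")
}

# Independent split-sweep reference update for the masked diffusion stencil
# (plain R loops; the oracle for the compiled kernel).
reference_diffusion_step <- function(v, open, s, dl = TRUE, dr = TRUE) {
  ni <- nrow(v); nj <- ncol(v)
  held <- function(i) (dl && i == 1) || (dr && i == ni)
  out <- v
  for (j in seq_len(nj)) for (i in seq_len(ni)) {
    if (!open[i, j] || held(i)) next
    lap <- 0
    if (i > 1 && open[i - 1, j]) lap <- lap + v[i - 1, j] - v[i, j]
    if (i < ni && open[i + 1, j]) lap <- lap + v[i + 1, j] - v[i, j]
    out[i, j] <- v[i, j] + s * lap
  }
  v <- out
  for (j in seq_len(nj)) for (i in seq_len(ni)) {
    if (!open[i, j] || held(i)) next
    lap <- 0
    if (j > 1 && open[i, j - 1]) lap <- lap + v[i, j - 1] - v[i, j]
    if (j < nj && open[i, j + 1]) lap <- lap + v[i, j + 1] - v[i, j]
    out[i, j] <- v[i, j] + s * lap
  }
  out
}

interstitial_mass <- function(values, domain) sum(values[!domain$interior])
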