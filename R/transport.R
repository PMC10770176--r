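#' A diffusible species on the masked grid
#'
#' Container for one scalar field (oxygen, inactive pro-drug, active drug or
#' sensitizer): node values on the \code{N_i x N_j} grid (zero inside cells),
#' its diffusion coefficient and first-order decay rate.
#'
#' @param name one of \code{"oxygen"}, \code{"inactive_drug"},
#'   \code{"active_drug"}, \code{"sensitizer"} (free names allowed for
#'   tracers)
#' @param domain a \code{tissue_domain}
#' @param values initial node values: a scalar or an \code{N_i x N_j} matrix
#' @param D diffusion coefficient (um^2/min)
#' @param decay first-order decay rate (1/min)
#' @return an object of class \code{scalar_field}
#' @export
scalar_field <- function(name, domain, values = 0, D, decay = 0) {
  g <- domain$grid
  v <- matrix(0, g$N_i, g$N_j)
  if (length(values) == 1) v[!domain$interior] <- values
  else {
    stopifnot(all(dim(values) == c(g$N_i, g$N_j)))
    v <- values
    v[domain$interior] <- 0
  }
  if (D < 0) stop("negative diffusion coefficient")
  if (any(v < 0)) stop("negative concentrations")
  structure(list(name = name, values = v, D = D, decay = decay),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field> %s: D = %g um^2/min, decay = %g /min, range [%.3g, %.3g]\n",
              x$name, x$D, x$decay, min(x$values), max(x$values)))
  invisible(x)
}

#' Transport and reaction parameters
#'
#' All rate constants of the kinetic model with their physiological defaults:
#' hypoxia threshold 10 mmHg, baseline oxygen uptake 0.85 mmHg/min,
#' sensitizer enhancement tiers (1, 5/3, 7.5/3, 12.5/3) at tier thresholds
#' (9, 22, 88) ag/um^3, 90% per-step pro-drug conversion in hypoxia, active
#' drug uptake 0.5/min and half-life 10 min, lethal threshold 1 ag/um^3,
#' explicit time step 1.5e-3 min, and diffusion coefficients
#' \eqn{D_\gamma = 10^3}, \eqn{D_{\eta i} = D_\gamma/50},
#' \eqn{D_{\eta a} = D_\gamma/25}, \eqn{D_\xi = D_\gamma} um^2/min.
#'
#' @param gamma_hyp hypoxia threshold (mmHg)
#' @param gamma0 baseline cellular oxygen uptake rate (mmHg/min)
#' @param psi enhancement factors for the four sensitizer tiers
#' @param xi_breaks sensitizer tier thresholds (ag/um^3), length 3
#' @param phi_conv pro-drug activation level: fraction converted per step
#'   (\code{phi_mode = "per_step"}, the default reading of the published
#'   0.9/dt rate) or a continuous rate in 1/min (\code{phi_mode = "per_min"})
#' @param phi_mode \code{"per_step"} or \code{"per_min"}
#' @param severe_uptake form of the severe-hypoxia uptake branch
#'   (\eqn{\gamma < \gamma_{hyp}/2}): \code{"normalized"} (default) tapers
#'   the normoxic rate linearly to zero,
#'   \eqn{\gamma_0\,\gamma/(0.5\gamma_{hyp})}, continuous at the knee;
#'   \code{"bare"} uses the unnormalized product \eqn{\gamma_0\,\gamma},
#'   which jumps discontinuously at the knee (see the methods vignette)
#' @param alpha active drug cellular uptake rate (1/min)
#' @param omega_a active drug decay rate (1/min); default log(2)/10
#' @param omega_i optional interstitial decay of the inactive drug (1/min)
#' @param eta_thr lethal mean accumulated concentration (ag/um^3)
#' @param dt explicit time step (min)
#' @param D_gamma,D_eta_i,D_eta_a,D_xi diffusion coefficients (um^2/min)
#' @return an object of class \code{transport_params}
#' @export
transport_params <- function(gamma_hyp = 10, gamma0 = 0.85,
                             psi = c(1, 5 / 3, 7.5 / 3, 12.5 / 3),
                             xi_breaks = c(9, 22, 88),
                             phi_conv = 0.9, phi_mode = c("per_step", "per_min"),
                             severe_uptake = c("normalized", "bare"),
                             alpha = 0.5, omega_a = log(2) / 10, omega_i = 0,
                             eta_thr = 1, dt = 1.5e-3,
                             D_gamma = 1e3, D_eta_i = 1e3 / 50,
                             D_eta_a = 1e3 / 25, D_xi = 1e3) {
  phi_mode <- match.arg(phi_mode)
  severe_uptake <- match.arg(severe_uptake)
  stopifnot(gamma_hyp > 0, gamma0 > 0, length(psi) == 4, length(xi_breaks) == 3,
            !is.unsorted(xi_breaks), phi_conv >= 0, alpha >= 0, omega_a >= 0,
            omega_i >= 0, eta_thr > 0, dt > 0)
  if (any(c(D_gamma, D_eta_i, D_eta_a, D_xi) < 0))
    stop("negative diffusion coefficient")
  if (phi_mode == "per_step" && phi_conv > 1)
    stop("per-step conversion fraction must be at most 1")
  structure(list(gamma_hyp = gamma_hyp, gamma0 = gamma0, psi = psi,
                 xi_breaks = xi_breaks, phi_conv = phi_conv,
                 phi_mode = phi_mode, severe_uptake = severe_uptake,
                 alpha = alpha, omega_a = omega_a,
                 omega_i = omega_i, eta_thr = eta_thr, dt = dt,
                 D_gamma = D_gamma, D_eta_i = D_eta_i, D_eta_a = D_eta_a,
                 D_xi = D_xi),
            class = "transport_params")
}

#' Vessel boundary condition with bolus windows and vasodilator modulation
#'
#' Baseline Dirichlet values on the left (vessel) edge and the time windows
#' during which each compound is present in circulation. While the
#' vasodilator circulates, every influx (oxygen, inactive drug, sensitizer)
#' and the interstitial flow are reduced by the factor \code{lambda}. The
#' active drug influx is always zero.
#'
#' @param gamma_in oxygen vascular level (mmHg)
#' @param eta_i_in inactive drug vascular concentration (ag/um^3)
#' @param xi_in sensitizer vascular concentration (ag/um^3)
#' @param lambda vasodilator flow/influx reduction factor in \code{[0, 1]}
#' @param hap_window,sens_window,vaso_window numeric \code{c(start, end)}
#'   windows (min) or NULL when the compound is not administered
#' @return an object of class \code{vessel_bc}
#' @export
vessel_bc <- function(gamma_in = 60, eta_i_in = 50, xi_in = 101, lambda = 0.5,
                      hap_window = NULL, sens_window = NULL,
                      vaso_window = NULL) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  stopifnot(gamma_in >= 0, eta_i_in >= 0, xi_in >= 0)
  chk <- function(w) {
    if (!is.null(w) && (length(w) != 2 || w[2] < w[1] || w[1] < 0))
      stop("windows must be c(start, end) with 0 <= start <= end")
    w
  }
  structure(list(gamma_in = gamma_in, eta_i_in = eta_i_in, xi_in = xi_in,
                 lambda = lambda, hap_window = chk(hap_window),
                 sens_window = chk(sens_window), vaso_window = chk(vaso_window)),
            class = "vessel_bc")
}

in_window <- function(t, w) !is.null(w) && t >= w[1] && t <= w[2]

# Current vessel values and flow scale at time t (Dirichlet data on the
# left edge; all baseline influxes and the flow drop by lambda while the
# vasodilator circulates).
vessel_values <- function(bc, t) {
  lam <- if (in_window(t, bc$vaso_window)) bc$lambda else 1
  list(gamma = lam * bc$gamma_in,
       eta_i = if (in_window(t, bc$hap_window)) lam * bc$eta_i_in else 0,
       eta_a = 0,
       xi = if (in_window(t, bc$sens_window)) lam * bc$xi_in else 0,
       lambda_flow = lam)
}

#' Apply the vessel boundary condition to a set of fields
#'
#' Writes the time-dependent Dirichlet values onto the left (vessel) edge of
#' each field: baseline vascular values inside each compound's bolus window
#' (zero outside), all reduced by \code{lambda} while the vasodilator
#' circulates. The attribute \code{"lambda_flow"} of the returned list gives
#' the concurrent flow scale.
#'
#' @param fields named list with any of \code{oxygen}, \code{eta_i},
#'   \code{eta_a}, \code{xi}, each a \code{scalar_field}
#' @param bc a [vessel_bc()]
#' @param t current time (min)
#' @return the updated list of fields, with attribute \code{lambda_flow}
#' @export
apply_vessel_boundary <- function(fields, bc, t) {
  vv <- vessel_values(bc, t)
  set_left <- function(fld, value) {
    if (is.null(fld)) return(NULL)
    fld$values[1, ] <- value
    fld
  }
  fields$oxygen <- set_left(fields$oxygen, vv$gamma)
  fields$eta_i <- set_left(fields$eta_i, vv$eta_i)
  fields$eta_a <- set_left(fields$eta_a, vv$eta_a)
  fields$xi <- set_left(fields$xi, vv$xi)
  attr(fields, "lambda_flow") <- vv$lambda_flow
  fields
}

#' One explicit masked-stencil diffusion step
#'
#' Forward-Euler update of the 4-neighbor Laplacian in which any stencil
#' point lying inside a cell is omitted: cell interiors are impermeable and
#' interstitial mass can change only through the domain boundaries. The top
#' and bottom rows are no-flux; the left and right edges are Dirichlet
#' (values held) by default, or reflecting when requested (used to verify
#' discrete mass conservation).
#'
#' @param field a \code{scalar_field}
#' @param domain a \code{tissue_domain}
#' @param dt time step (min); must satisfy \code{dt * D / h^2 <= 0.5}
#' @param D diffusion coefficient; defaults to the field's own
#' @param left,right \code{"dirichlet"} or \code{"reflect"}
#' @return the updated \code{scalar_field}
#' @export
masked_diffusion_step <- function(field, domain, dt, D = field$D,
                                  left = "dirichlet", right = "dirichlet") {
  h <- domain$grid$h
  s <- dt * D / h^2
  if (s > 0.5)
    stop(sprintf("explicit stability violated: dt*D/h^2 = %.3f > 0.5", s))
  v <- field$values + 0 # fresh copy: the kernel updates in place
  buf <- matrix(0, nrow(v), ncol(v))
  diffuse_masked_inplace(v, buf, !domain$interior, s,
                         identical(left, "dirichlet"),
                         identical(right, "dirichlet"))
  field$values <- v
  field
}

#' One first-order upwind advection step
#'
#' Donor-cell upwind transport along the precomputed interstitial velocity
#' field. Velocities vanish on cell boundaries and masked nodes are skipped,
#' so no advective flux enters cell interiors.
#'
#' @param field a \code{scalar_field}
#' @param flow a \code{flow_field}
#' @param domain a \code{tissue_domain}
#' @param dt time step (min); must satisfy \code{max|u| dt / h <= 1}
#' @param left,right \code{"dirichlet"} or \code{"open"} edge handling
#' @return the updated \code{scalar_field}
#' @export
upwind_advection_step <- function(field, flow, domain, dt,
                                  left = "dirichlet", right = "dirichlet") {
  h <- domain$grid$h
  cfl <- max(abs(c(flow$ux, flow$uy))) * dt / h
  if (cfl > 1) stop(sprintf("CFL violated: max|u| dt/h = %.3f > 1", cfl))
  v <- field$values + 0
  buf <- matrix(0, nrow(v), ncol(v))
  advect_upwind_inplace(v, buf, flow$ux, flow$uy, !domain$interior, dt / h,
                        identical(left, "dirichlet"),
                        identical(right, "dirichlet"))
  field$values <- v
  field
}

#' Cellular oxygen uptake rate
#'
#' Piecewise uptake law: under severe hypoxia (\eqn{\gamma < \gamma_{hyp}/2})
#' the rate is proportional to oxygen, \eqn{\gamma_0 \gamma}; otherwise it is
#' the constant \eqn{\gamma_0} amplified by the sensitizer tier
#' (\eqn{\psi_0..\psi_3} over \eqn{[0,\xi_0), [\xi_0,\xi_1), [\xi_1,\xi_2),
#' [\xi_2,\infty)}).
#'
#' @param gamma oxygen (mmHg), vectorized
#' @param xi sensitizer (ag/um^3), vectorized or scalar
#' @param params a [transport_params()]
#' @return uptake rate (mmHg/min) per receptor
#' @export
#' @examples
#' oxygen_uptake_rate(60, 0, transport_params())  # 0.85
oxygen_uptake_rate <- function(gamma, xi = 0, params = transport_params()) {
  stopifnot(all(gamma >= 0), all(xi >= 0))
  xi <- rep_len(xi, length(gamma))
  tier <- findInterval(xi, params$xi_breaks) + 1L
  ifelse(gamma < 0.5 * params$gamma_hyp,
         severe_slope(params) * gamma,
         params$gamma0 * params$psi[tier])
}

# proportionality constant of the severe-hypoxia uptake branch
severe_slope <- function(params) {
  if (params$severe_uptake == "bare") params$gamma0
  else params$gamma0 / (0.5 * params$gamma_hyp)
}

#' Hypoxia-gated pro-drug activation level
#'
#' Returns the conversion level \eqn{\varphi^{conv}} where oxygen is at or
#' below the hypoxia threshold (inclusive), and zero elsewhere. Under the
#' default \code{phi_mode = "per_step"} the value is the fraction of local
#' inactive drug converted per time step.
#'
#' @param gamma oxygen (mmHg), vectorized
#' @param params a [transport_params()]
#' @return conversion level (per step or 1/min depending on
#'   \code{phi_mode})
#' @export
activation_rate <- function(gamma, params = transport_params()) {
  stopifnot(all(gamma >= 0))
  ifelse(gamma <= params$gamma_hyp, params$phi_conv, 0)
}

# per-step conversion fraction under either phi reading
conversion_fraction <- function(params) {
  if (params$phi_mode == "per_step") params$phi_conv
  else min(1, params$phi_conv * params$dt)
}

#' Steady-state oxygen gradient
#'
#' Iterates the oxygen update (vessel Dirichlet influx, masked diffusion,
#' advection, receptor-localized uptake with all cells alive and no
#' sensitizer) until the iterate-to-iterate L2 change per grid node drops
#' below \code{tol}. The converged gradient is the initial condition of
#' every simulation.
#'
#' @param domain a \code{tissue_domain}
#' @param flow a \code{flow_field}, or NULL for no advection
#' @param params a [transport_params()]
#' @param bc a [vessel_bc()]
#' @param tol convergence threshold on \code{||g_n - g_{n-1}||_2 / (N_i N_j)}
#' @param max_iter iteration cap
#' @return a \code{scalar_field} named \code{"oxygen"}; attributes
#'   \code{iterations} and \code{residual}
#' @export
steady_state_oxygen <- function(domain, flow, params = transport_params(),
                                bc = vessel_bc(), tol = 1e-10,
                                max_iter = 500000L) {
  g <- domain$grid
  s <- params$dt * params$D_gamma / g$h^2
  if (s > 0.5)
    stop(sprintf("explicit stability violated: dt*D/h^2 = %.3f > 0.5", s))
  open <- !domain$interior
  cnt <- receptor_count_matrix(domain)
  xi0 <- matrix(0, g$N_i, g$N_j)
  # linear profile initial guess speeds convergence
  prof <- bc$gamma_in * (g$x_max - node_x(g)) / (g$x_max - g$x_min)
  gamma <- matrix(prof, g$N_i, g$N_j)
  gamma[!open] <- 0
  gamma[1, ] <- bc$gamma_in
  gamma[g$N_i, ] <- 0
  buf <- matrix(0, g$N_i, g$N_j)
  prev <- matrix(0, g$N_i, g$N_j)
  dtdh <- params$dt / g$h
  nn <- as.double(g$N_i) * g$N_j
  res <- Inf
  for (it in seq_len(max_iter)) {
    prev[] <- gamma
    gamma[1, open[1, ]] <- bc$gamma_in
    diffuse_masked_inplace(gamma, buf, open, s, TRUE, TRUE)
    if (!is.null(flow))
      advect_upwind_inplace(gamma, buf, flow$ux, flow$uy, open, dtdh,
                            TRUE, TRUE)
    oxygen_uptake_inplace(gamma, xi0, cnt, params$gamma0, params$gamma_hyp,
                          params$xi_breaks, params$psi, params$dt,
                          severe_slope(params))
    res <- sqrt(sum((gamma - prev)^2)) / nn
    if (res < tol) {
      fld <- scalar_field("oxygen", domain, gamma, D = params$D_gamma)
      attr(fld, "iterations") <- it
      attr(fld, "residual") <- res
      return(fld)
    }
  }
  stop(sprintf("steady state not reached in %d iterations (residual %.3e)",
               max_iter, res))
}

#' One combined pro-drug / active-drug kinetic step
#'
#' Advances the inactive and active drug fields by one time step: masked
#' diffusion and upwind advection for both, hypoxia-gated activation (exact
#' node-wise mass transfer from inactive to active), receptor-localized
#' uptake of the active drug by live cells, and first-order decay. The
#' per-cell accumulation increments matching the uptake flux are returned in
#' the attribute \code{"cell_increments"} (same quantity that
#' [accumulate_drug()] computes).
#'
#' @param eta_i,eta_a \code{scalar_field}s for the inactive and active drug
#' @param oxygen oxygen \code{scalar_field} (gates activation)
#' @param flow a \code{flow_field} or NULL
#' @param domain a \code{tissue_domain}
#' @param cells a cell-state data frame from [cell_states()]
#' @param params a [transport_params()]
#' @param dt time step (min)
#' @return list with updated \code{eta_i} and \code{eta_a}; attribute
#'   \code{"cell_increments"} holds per-cell accumulated-drug increments
#' @export
drug_step <- function(eta_i, eta_a, oxygen, flow, domain, cells,
                      params = transport_params(), dt = params$dt) {
  g <- domain$grid
  open <- !domain$interior
  vi <- eta_i$values + 0
  va <- eta_a$values + 0
  buf <- matrix(0, g$N_i, g$N_j)
  diffuse_masked_inplace(vi, buf, open, dt * params$D_eta_i / g$h^2, TRUE, TRUE)
  diffuse_masked_inplace(va, buf, open, dt * params$D_eta_a / g$h^2, TRUE, TRUE)
  if (!is.null(flow)) {
    advect_upwind_inplace(vi, buf, flow$ux, flow$uy, open, dt / g$h, TRUE, TRUE)
    advect_upwind_inplace(va, buf, flow$ux, flow$uy, open, dt / g$h, TRUE, TRUE)
  }
  activation_inplace(vi, va, oxygen$values, open, params$gamma_hyp,
                     conversion_fraction(params))
  cnt <- receptor_count_matrix(domain, cells$alive)
  nodes0 <- lapply(domain$cell_nodes, function(ix) ix - 1L)
  inc <- drug_uptake_inplace(va, cnt, nodes0, cells$alive, params$alpha, dt)
  va <- va * (1 - dt * params$omega_a)
  if (params$omega_i > 0) vi <- vi * (1 - dt * params$omega_i)
  eta_i$values <- vi
  eta_a$values <- va
  out <- list(eta_i = eta_i, eta_a = eta_a)
  attr(out, "cell_increments") <- as.numeric(inc)
  out
}

#' One sensitizer kinetic step
#'
#' The sensitizer is a passive tracer: masked diffusion and upwind advection
#' only, with neither uptake nor decay. Its vessel influx is handled by
#' [apply_vessel_boundary()].
#'
#' @param xi sensitizer \code{scalar_field}
#' @param flow a \code{flow_field} or NULL
#' @param domain a \code{tissue_domain}
#' @param dt time step (min)
#' @return the updated \code{scalar_field}
#' @export
sensitizer_step <- function(xi, flow, domain, dt) {
  xi <- masked_diffusion_step(xi, domain, dt)
  if (!is.null(flow)) xi <- upwind_advection_step(xi, flow, domain, dt)
  xi
}
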