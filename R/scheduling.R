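#' A bolus injection window
#'
#' A compound present in plasma at its vascular concentration from
#' \code{start} for \code{duration} minutes, entering the tissue through the
#' vessel boundary condition. Default durations are the plasma clearance
#' times: 10 min for the pro-drug, 25 min for sensitizer and vasodilator.
#'
#' @param compound \code{"HAP"}, \code{"Sens"} or \code{"Vaso"}
#' @param start injection time (min, non-negative)
#' @param duration plasma residence time (min); compound default if missing
#' @return an object of class \code{bolus}
#' @export
bolus <- function(compound = c("HAP", "Sens", "Vaso"), start, duration) {
  compound <- match.arg(compound)
  if (missing(duration))
    duration <- c(HAP = 10, Sens = 25, Vaso = 25)[[compound]]
  if (start < 0) stop("bolus start must be non-negative")
  if (duration <= 0) stop("bolus duration must be positive")
  structure(list(compound = compound, start = start, duration = duration),
            class = "bolus")
}

#' A treatment schedule
#'
#' At most one bolus per compound within the simulation horizon (default
#' three hours).
#'
#' @param ... \code{bolus} objects
#' @param t_end horizon (min)
#' @return an object of class \code{treatment_schedule}
#' @export
#' @examples
#' treatment_schedule(bolus("HAP", start = 5)) # the baseline monotherapy
treatment_schedule <- function(..., t_end = 180) {
  boluses <- list(...)
  if (length(boluses) == 1 && is.list(boluses[[1]]) &&
      !inherits(boluses[[1]], "bolus"))
    boluses <- boluses[[1]]
  stopifnot(all(vapply(boluses, inherits, logical(1), "bolus")))
  comp <- vapply(boluses, `[[`, character(1), "compound")
  if (anyDuplicated(comp))
    stop(sprintf("duplicate bolus for compound %s", comp[duplicated(comp)][1]))
  ends <- vapply(boluses, function(b) b$start + b$duration, numeric(1))
  if (length(ends) && any(ends > t_end))
    stop("bolus window extends past the horizon t_end")
  structure(list(boluses = boluses, t_end = t_end),
            class = "treatment_schedule")
}

#' @export
print.treatment_schedule <- function(x, ...) {
  cat(sprintf("<treatment_schedule> horizon %g min\n", x$t_end))
  for (b in x$boluses)
    cat(sprintf("  %-4s [%g, %g] min\n", b$compound, b$start,
                b$start + b$duration))
  invisible(x)
}

schedule_window <- function(schedule, compound) {
  for (b in schedule$boluses)
    if (b$compound == compound) return(c(b$start, b$start + b$duration))
  NULL
}

#' Strip-averaged profile of a field
#'
#' Mean over the interstitial nodes of each vertical tissue strip (fixed x),
#' the 1-D summary used to visualize gradients. Strips with no interstitial
#' node are reported as \code{NA}, not zero.
#'
#' @param field a \code{scalar_field} or plain values matrix
#' @param domain a \code{tissue_domain}
#' @return numeric vector of length \code{N_i}
#' @export
strip_average_profile <- function(field, domain) {
  v <- if (inherits(field, "scalar_field")) field$values else field
  open <- !domain$interior
  n <- rowSums(open)
  out <- rowSums(v * open) / n
  out[n == 0] <- NA_real_
  out
}

#' Normoxia/hypoxia border distance
#'
#' The smallest distance from the vessel at which the strip-averaged oxygen
#' first falls below the hypoxia threshold; the domain length when no strip
#' qualifies (no-hypoxia convention). Strips without interstitial nodes are
#' skipped.
#'
#' @param oxygen oxygen \code{scalar_field} or values matrix
#' @param domain a \code{tissue_domain}
#' @param gamma_hyp hypoxia threshold (mmHg)
#' @return distance (um) from the vessel edge
#' @export
hypoxia_border <- function(oxygen, domain, gamma_hyp = 10) {
  prof <- strip_average_profile(oxygen, domain)
  hyp <- which(!is.na(prof) & prof < gamma_hyp)
  g <- domain$grid
  if (!length(hyp)) return(g$x_max - g$x_min)
  (hyp[1] - 1) * g$h
}

#' Run a full treatment simulation
#'
#' Executes the explicit loop (vessel boundary values, masked diffusion,
#' upwind advection, reactions, cell death) at the model time step up to the
#' schedule horizon. The run is fully deterministic for fixed inputs.
#' Recorded every \code{record_dt}: time, dead-cell count, normoxia/hypoxia
#' border, tissue-mean oxygen and mean active drug.
#'
#' @param domain a \code{tissue_domain}
#' @param schedule a [treatment_schedule()]
#' @param params a [transport_params()]
#' @param bc a [vessel_bc()] (its windows are overwritten from the schedule)
#' @param flow a solved \code{flow_field}, or NULL for no advection
#' @param oxygen_init steady-state oxygen \code{scalar_field}; computed on
#'   the fly when NULL
#' @param record_dt sampling interval of the time series (min)
#' @param snapshot_times times (min) at which full field snapshots are kept
#'   (nearest step is used and recorded)
#' @return an object of class \code{simulation_result}: \code{series} (data
#'   frame over time), \code{cells} (final per-cell states), \code{n_dead},
#'   \code{dead_fraction}, \code{snapshots}, \code{counters}
#' @export
run_simulation <- function(domain, schedule, params = transport_params(),
                           bc = vessel_bc(), flow = NULL, oxygen_init = NULL,
                           record_dt = 0.5, snapshot_times = numeric(0)) {
  g <- domain$grid
  open <- !domain$interior
  dt <- params$dt
  if (dt * max(params$D_gamma, params$D_xi) / g$h^2 > 0.5)
    stop("explicit stability violated for the fastest-diffusing species")
  if (!is.null(flow) && max(abs(c(flow$base_ux, flow$base_uy))) * dt / g$h > 1)
    stop("CFL violated")
  bc$hap_window <- schedule_window(schedule, "HAP")
  bc$sens_window <- schedule_window(schedule, "Sens")
  bc$vaso_window <- schedule_window(schedule, "Vaso")
  if (is.null(oxygen_init))
    oxygen_init <- steady_state_oxygen(domain, flow, params, bc)

  n_steps <- as.integer(round(schedule$t_end / dt))
  rec_every <- max(1L, as.integer(round(record_dt / dt)))
  snap_steps <- if (length(snapshot_times))
    pmin(pmax(as.integer(round(snapshot_times / dt)), 0L), n_steps) else integer(0)

  ncell <- length(domain$cells)
  alive <- rep(TRUE, ncell)
  accumulated <- numeric(ncell)
  death_time <- rep(NA_real_, ncell)
  areas <- cell_areas(domain)
  nodes0 <- lapply(domain$cell_nodes, function(ix) ix - 1L)
  cnt <- receptor_count_matrix(domain, alive)

  gamma <- oxygen_init$values + 0
  vi <- matrix(0, g$N_i, g$N_j)
  va <- matrix(0, g$N_i, g$N_j)
  xi <- matrix(0, g$N_i, g$N_j)
  buf <- matrix(0, g$N_i, g$N_j)
  xi_zero <- xi + 0

  lam_prev <- 1
  fx <- if (!is.null(flow)) flow$base_ux else NULL
  fy <- if (!is.null(flow)) flow$base_uy else NULL
  sg <- dt * params$D_gamma / g$h^2
  si <- dt * params$D_eta_i / g$h^2
  sa <- dt * params$D_eta_a / g$h^2
  sx <- dt * params$D_xi / g$h^2
  dtdh <- dt / g$h
  frac <- conversion_fraction(params)
  hap_on <- FALSE; sens_on <- FALSE

  nrec <- n_steps %/% rec_every + 1L +
    as.integer(n_steps %% rec_every != 0L) # final state always recorded
  rec <- list(t = numeric(nrec), n_dead = integer(nrec), border = numeric(nrec),
              mean_oxygen = numeric(nrec), mean_eta_a = numeric(nrec))
  open_n <- sum(open)
  record_at <- function(k, r) {
    rec$t[r] <<- k * dt
    rec$n_dead[r] <<- sum(!alive)
    rec$border[r] <<- hypoxia_border(gamma, domain, params$gamma_hyp)
    rec$mean_oxygen[r] <<- sum(gamma[open]) / open_n
    rec$mean_eta_a[r] <<- sum(va[open]) / open_n
  }
  record_at(0L, 1L); r_next <- 2L
  snapshots <- list()
  counters <- c(oxygen_clamps = 0, uptake_removed = 0, accumulated_total = 0,
                node_steps = 0)

  for (k in seq_len(n_steps)) {
    t_now <- (k - 1) * dt
    vv <- vessel_values(bc, t_now)
    if (!hap_on && in_window(t_now, bc$hap_window)) hap_on <- TRUE
    if (!sens_on && in_window(t_now, bc$sens_window)) sens_on <- TRUE
    if (!is.null(flow) && vv$lambda_flow != lam_prev) {
      fx <- flow$base_ux * vv$lambda_flow
      fy <- flow$base_uy * vv$lambda_flow
      lam_prev <- vv$lambda_flow
    }
    # (1) vessel boundary values (open left-edge nodes only)
    gamma[1, open[1, ]] <- vv$gamma
    if (hap_on) { vi[1, open[1, ]] <- vv$eta_i; va[1, open[1, ]] <- 0 }
    if (sens_on) xi[1, open[1, ]] <- vv$xi
    # (2) masked diffusion
    diffuse_masked_inplace(gamma, buf, open, sg, TRUE, TRUE)
    if (hap_on) {
      diffuse_masked_inplace(vi, buf, open, si, TRUE, TRUE)
      diffuse_masked_inplace(va, buf, open, sa, TRUE, TRUE)
    }
    if (sens_on) diffuse_masked_inplace(xi, buf, open, sx, TRUE, TRUE)
    # (3) upwind advection
    if (!is.null(flow)) {
      advect_upwind_inplace(gamma, buf, fx, fy, open, dtdh, TRUE, TRUE)
      if (hap_on) {
        advect_upwind_inplace(vi, buf, fx, fy, open, dtdh, TRUE, TRUE)
        advect_upwind_inplace(va, buf, fx, fy, open, dtdh, TRUE, TRUE)
      }
      if (sens_on) advect_upwind_inplace(xi, buf, fx, fy, open, dtdh, TRUE, TRUE)
    }
    # (4) reactions: activation, uptake, decay
    if (hap_on)
      activation_inplace(vi, va, gamma, open, params$gamma_hyp, frac)
    counters["oxygen_clamps"] <- counters["oxygen_clamps"] +
      oxygen_uptake_inplace(gamma, if (sens_on) xi else xi_zero, cnt,
                            params$gamma0, params$gamma_hyp,
                            params$xi_breaks, params$psi, dt,
                            severe_slope(params))
    if (hap_on) {
      pre <- sum(va)
      inc <- drug_uptake_inplace(va, cnt, nodes0, alive, params$alpha, dt)
      counters["uptake_removed"] <- counters["uptake_removed"] + (pre - sum(va))
      counters["accumulated_total"] <- counters["accumulated_total"] + sum(inc)
      accumulated <- accumulated + inc
      va <- va * (1 - dt * params$omega_a)
      if (params$omega_i > 0) vi <- vi * (1 - dt * params$omega_i)
      # (5) death check (threshold inclusive, once per step, irreversible)
      newly <- alive & (accumulated * g$h^2 / areas >= params$eta_thr)
      if (any(newly)) {
        for (l in which(newly)) {
          idx <- nodes0[[l]]
          if (length(idx)) {
            tb <- tabulate(idx + 1L, nbins = length(cnt))
            cnt <- cnt - matrix(as.integer(tb), g$N_i, g$N_j)
          }
        }
        alive[newly] <- FALSE
        death_time[newly] <- k * dt
      }
    }
    counters["node_steps"] <- counters["node_steps"] +
      open_n * (1 + 2 * hap_on + sens_on)
    # (6) recording
    if (k %% rec_every == 0L) { record_at(k, r_next); r_next <- r_next + 1L }
    if (k %in% snap_steps)
      snapshots[[length(snapshots) + 1L]] <-
        list(t = k * dt, oxygen = gamma + 0, eta_i = vi + 0, eta_a = va + 0,
             xi = xi + 0)
  }
  if (n_steps %% rec_every != 0L) record_at(n_steps, r_next)

  cells <- data.frame(
    cell_id = vapply(domain$cells, function(c) as.character(c$id), character(1)),
    area = areas, accumulated = accumulated, alive = alive,
    death_time = death_time, stringsAsFactors = FALSE)
  structure(list(
    series = data.frame(t = rec$t, n_dead = rec$n_dead, border = rec$border,
                        mean_oxygen = rec$mean_oxygen,
                        mean_eta_a = rec$mean_eta_a),
    cells = cells, n_dead = sum(!alive),
    dead_fraction = if (ncell) sum(!alive) / ncell else 0,
    n_cells = ncell, schedule = schedule, params = params,
    counters = counters, snapshots = snapshots,
    final = list(oxygen = gamma, eta_i = vi, eta_a = va, xi = xi)),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d/%d cells dead (%.1f%%) at t = %g min\n",
              x$n_dead, x$n_cells, 100 * x$dead_fraction,
              max(x$series$t)))
  cat(sprintf("  final border %g um, mean oxygen %.2f mmHg; %d oxygen clamps over %.3g node-steps\n",
              x$series$border[nrow(x$series)],
              x$series$mean_oxygen[nrow(x$series)],
              as.integer(x$counters["oxygen_clamps"]), x$counters["node_steps"]))
  invisible(x)
}

#' Locate plateau-aware local maxima on an offset lattice
#'
#' Finds connected components (4-neighborhood) of equal value all of whose
#' outside neighbors are strictly smaller; plateaus are reported as index
#' ranges. Works on a vector (1-D sweep) or matrix (2-D sweep); \code{NA}
#' entries (infeasible points) never belong to a maximum.
#'
#' @param values numeric vector or matrix of dead-cell counts
#' @return list of maxima, each with \code{indices} (matrix of array
#'   indices), \code{value}
#' @export
find_local_maxima <- function(values) {
  v <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  ni <- nrow(v); nj <- ncol(v)
  comp <- matrix(0L, ni, nj)
  ncomp <- 0L
  nbrs <- function(i, j) {
    out <- rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
    out[out[, 1] >= 1 & out[, 1] <= ni & out[, 2] >= 1 & out[, 2] <= nj, ,
        drop = FALSE]
  }
  for (j in seq_len(nj)) for (i in seq_len(ni)) {
    if (comp[i, j] != 0L || is.na(v[i, j])) next
    ncomp <- ncomp + 1L
    queue <- list(c(i, j)); comp[i, j] <- ncomp
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in seq_len(nrow(nbrs(p[1], p[2])))) {
        nb <- nbrs(p[1], p[2])[q, ]
        if (comp[nb[1], nb[2]] == 0L && !is.na(v[nb[1], nb[2]]) &&
            v[nb[1], nb[2]] == v[p[1], p[2]]) {
          comp[nb[1], nb[2]] <- ncomp
          queue[[length(queue) + 1L]] <- nb
        }
      }
    }
  }
  out <- list()
  for (cc in seq_len(ncomp)) {
    idx <- which(comp == cc, arr.ind = TRUE)
    val <- v[idx[1, 1], idx[1, 2]]
    is_max <- TRUE
    for (q in seq_len(nrow(idx))) {
      nb <- nbrs(idx[q, 1], idx[q, 2])
      for (m in seq_len(nrow(nb))) {
        ov <- v[nb[m, 1], nb[m, 2]]
        if (comp[nb[m, 1], nb[m, 2]] != cc && (is.na(ov) || ov >= val)) {
          is_max <- FALSE; break
        }
      }
      if (!is_max) break
    }
    if (is_max)
      out[[length(out) + 1L]] <- list(indices = idx, value = val)
  }
  out
}

#' Sweep enhancer injection offsets against the pro-drug schedule
#'
#' Runs one independent simulation per lattice point of enhancer offsets
#' relative to the pro-drug injection (negative = enhancer before the
#' pro-drug). When an offset would start a window before t = 0, the whole
#' schedule is shifted right so the earliest bolus starts at 0, preserving
#' relative timing; points whose windows would overrun the horizon are
#' flagged infeasible rather than skipped silently. All runs share the
#' precomputed flow and steady-state oxygen.
#'
#' @param domain a \code{tissue_domain}
#' @param base a [treatment_schedule()] containing the HAP bolus (its start
#'   anchors the offsets) and the enhancer durations
#' @param axes named list of offset vectors (min), names among
#'   \code{"Sens"}, \code{"Vaso"}; one entry for a 1-D sweep, two for 2-D
#' @param params,bc,flow,oxygen_init as in [run_simulation()]
#' @return an object of class \code{sweep_result}: \code{grid} (offsets,
#'   dead counts, feasibility), \code{dead} (vector or matrix), and
#'   \code{maxima} from [find_local_maxima()]
#' @export
sweep_offsets <- function(domain, base, axes, params = transport_params(),
                          bc = vessel_bc(), flow = NULL, oxygen_init = NULL) {
  hapw <- schedule_window(base, "HAP")
  if (is.null(hapw)) stop("base schedule must contain a HAP bolus")
  stopifnot(length(axes) >= 1, length(axes) <= 2,
            all(names(axes) %in% c("Sens", "Vaso")))
  durations <- c(HAP = hapw[2] - hapw[1],
                 Sens = 25, Vaso = 25)
  for (b in base$boluses) durations[b$compound] <- b$duration
  if (is.null(oxygen_init))
    oxygen_init <- steady_state_oxygen(domain, flow, params, bc)
  pts <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(pts)
  dead <- integer(n); feasible <- logical(n); shifted <- numeric(n)
  for (p in seq_len(n)) {
    starts <- c(HAP = hapw[1])
    for (cmp in names(axes)) starts[cmp] <- hapw[1] + pts[p, cmp]
    shift <- max(0, -min(starts))
    starts <- starts + shift
    shifted[p] <- shift
    ends <- starts + durations[names(starts)]
    if (any(ends > base$t_end)) { feasible[p] <- FALSE; dead[p] <- NA; next }
    feasible[p] <- TRUE
    sched <- treatment_schedule(lapply(names(starts), function(cmp)
      bolus(cmp, start = starts[[cmp]], duration = durations[[cmp]])),
      t_end = base$t_end)
    res <- run_simulation(domain, sched, params, bc, flow, oxygen_init)
    dead[p] <- res$n_dead
  }
  grid_df <- cbind(pts, n_dead = dead, feasible = feasible, shift = shifted)
  dead_arr <- if (length(axes) == 1) {
    setNames(dead, pts[[1]])
  } else {
    matrix(dead, nrow = length(axes[[1]]), ncol = length(axes[[2]]),
           dimnames = list(axes[[1]], axes[[2]]))
  }
  structure(list(grid = grid_df, dead = dead_arr, axes = axes,
                 maxima = find_local_maxima(if (is.matrix(dead_arr)) dead_arr
                                            else as.numeric(dead_arr))),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d schedules over %s\n", nrow(x$grid),
              paste(names(x$axes), collapse = " x ")))
  for (m in x$maxima) {
    first <- m$indices[1, ]
    offs <- vapply(seq_along(x$axes), function(a)
      x$axes[[a]][m$indices[, a]][1], numeric(1))
    cat(sprintf("  local maximum: %d dead at offset (%s)%s\n", m$value,
                paste(sprintf("%s %+g", names(x$axes), offs), collapse = ", "),
                if (nrow(m$indices) > 1)
                  sprintf(" [plateau of %d points]", nrow(m$indices)) else ""))
  }
  invisible(x)
}
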