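#' Regularized blob (cutoff) function
#'
#' The radially symmetric density over which each point force is smoothed,
#' \eqn{\phi_\epsilon(r) = 2\epsilon^4 / (\pi (r^2 + \epsilon^2)^3)}. It is
#' strictly decreasing in \eqn{r} and integrates to one over the plane.
#'
#' @param r distance (um), vectorized
#' @param epsilon regularization radius (um)
#' @return density (1/um^2)
#' @export
#' @examples
#' cutoff_phi(0, 2) # 1/(2*pi)
cutoff_phi <- function(r, epsilon) {
  if (epsilon <= 0) stop("epsilon must be positive")
  if (any(r < 0)) stop("r must be non-negative")
  2 * epsilon^4 / (pi * (r^2 + epsilon^2)^3)
}

#' Assemble the Stokeslet boundary-force system for a tissue
#'
#' Places force points along the vessel (left edge, imposed influx velocity
#' \code{u_in} in +x), along the top and bottom walls (no-slip), and on every
#' cell boundary point (immobile cells), all at spacing \code{epsilon};
#' corner points are deduplicated and the right edge is left unconstrained
#' (open outflow).
#'
#' @param domain a \code{tissue_domain}
#' @param u_in vessel influx speed (um/min; the physiological 1 um/s is 60)
#' @param mu interstitial fluid viscosity (mg/(um min))
#' @return an object of class \code{stokeslet_system} with fields
#'   \code{points} (M x 2), \code{velocities} (M x 2), \code{kind}
#'   (vessel/wall/cell), \code{mu}, \code{epsilon}, \code{u_in}
#' @export
stokes_system <- function(domain, u_in = 60, mu = 0.04) {
  g <- domain$grid
  eps <- domain$epsilon
  yv <- seq(g$y_min, g$y_max, by = eps)
  vessel <- cbind(g$x_min, yv)
  xw <- seq(g$x_min + eps, g$x_max, by = eps)  # skip left corners (dedup)
  walls <- rbind(cbind(xw, g$y_min), cbind(xw, g$y_max))
  cellpts <- do.call(rbind, lapply(domain$cells, `[[`, "xy"))
  pts <- rbind(vessel, walls, if (!is.null(cellpts)) cellpts)
  kind <- c(rep("vessel", nrow(vessel)), rep("wall", nrow(walls)),
            rep("cell", if (is.null(cellpts)) 0 else nrow(cellpts)))
  vel <- matrix(0, nrow(pts), 2)
  vel[kind == "vessel", 1] <- u_in
  structure(list(points = pts, velocities = vel, kind = kind,
                 mu = mu, epsilon = eps, u_in = u_in, forces = NULL),
            class = "stokeslet_system")
}

#' @export
print.stokeslet_system <- function(x, ...) {
  cat(sprintf("<stokeslet_system> M = %d force points (%d vessel, %d wall, %d cell)\n",
              nrow(x$points), sum(x$kind == "vessel"), sum(x$kind == "wall"),
              sum(x$kind == "cell")))
  cat(sprintf("  mu = %g mg/(um min), epsilon = %g um, u_in = %g um/min, forces %s\n",
              x$mu, x$epsilon, x$u_in,
              if (is.null(x$forces)) "unsolved" else "solved"))
  invisible(x)
}

#' Evaluate the regularized-Stokeslet velocity at arbitrary points
#'
#' Sums the exact regularized-Stokeslet kernel over all force points:
#' \deqn{u(x) = \frac{1}{8\pi\mu}\sum_k \Big(\frac{2\epsilon^2}{R_k}
#'   - \ln R_k - 1\Big) f_k +
#'   \frac{2 [f_k \cdot (x - x_k)](x - x_k)}{R_k}, \quad
#'   R_k = r_k^2 + \epsilon^2,}
#' with \eqn{r_k = \|x - x_k\|}. This is the Stokes solution for forces
#' smoothed by the blob [cutoff_phi()]: it is exactly divergence-free,
#' regular at \eqn{r = 0}, and reduces to the classical two-dimensional
#' Stokeslet as \eqn{\epsilon \to 0}.
#'
#' @param x points at which to evaluate, n x 2 matrix (um)
#' @param system a solved or manually populated \code{stokeslet_system}
#'   (fields \code{points}, \code{forces}, \code{mu}, \code{epsilon})
#' @return n x 2 matrix of velocities (um/min)
#' @export
stokeslet_velocity <- function(x, system) {
  if (is.null(system$forces)) stop("forces not set; run solve_boundary_forces()")
  x <- matrix(x, ncol = 2)
  rs_velocity(x, system$points, system$forces, system$mu, system$epsilon)
}

#' Solve for boundary forces reproducing the imposed velocities
#'
#' Inverts the dense 2M x 2M mobility matrix so that the Stokeslet sum
#' reproduces every imposed boundary velocity. The promised contract is the
#' residual: the maximum boundary-velocity error relative to \code{u_in}
#' must not exceed \code{tol}, enforced with iterative refinement and
#' verified after the solve.
#'
#' @param system a \code{stokeslet_system}
#' @param tol maximum relative boundary-velocity residual (default 1e-8)
#' @return the system with \code{forces} (M x 2) and \code{residual} set
#' @export
solve_boundary_forces <- function(system, tol = 1e-8) {
  uk <- system$velocities
  scale <- max(sqrt(rowSums(uk^2)))
  if (scale == 0) {
    system$forces <- matrix(0, nrow(system$points), 2)
    system$residual <- 0
    return(system)
  }
  f <- rs_solve_forces(system$points, uk, system$mu, system$epsilon, 1L)
  ubk <- rs_velocity(system$points, system$points, f, system$mu, system$epsilon)
  res <- max(sqrt(rowSums((ubk - uk)^2))) / scale
  if (res > tol) {
    f <- rs_solve_forces(system$points, uk, system$mu, system$epsilon, 3L)
    ubk <- rs_velocity(system$points, system$points, f, system$mu, system$epsilon)
    res <- max(sqrt(rowSums((ubk - uk)^2))) / scale
  }
  if (res > tol)
    stop(sprintf("force solve did not meet the residual contract: %.3e > %.3e",
                 res, tol))
  system$forces <- f
  system$residual <- res
  system
}

#' Compute the interstitial velocity field on the grid
#'
#' Evaluates the Stokeslet sum once at every interstitial grid node; nodes
#' inside cells carry zero velocity. The field is time-invariant (cells are
#' immobile) and is cached by callers; the vasodilator only rescales it.
#'
#' @param domain a \code{tissue_domain}
#' @param system a solved \code{stokeslet_system}
#' @return an object of class \code{flow_field} with matrices \code{ux},
#'   \code{uy} (um/min), the unscaled copies \code{base_ux}, \code{base_uy},
#'   and the current scale \code{lambda}
#' @export
compute_velocity_field <- function(domain, system) {
  if (is.null(system$forces)) stop("forces not solved")
  g <- domain$grid
  open <- !domain$interior
  idx <- which(open)
  xs <- node_x(g); ys <- node_y(g)
  pts <- cbind(xs[(idx - 1L) %% g$N_i + 1L], ys[(idx - 1L) %/% g$N_i + 1L])
  u <- rs_velocity(pts, system$points, system$forces, system$mu, system$epsilon)
  ux <- matrix(0, g$N_i, g$N_j); uy <- matrix(0, g$N_i, g$N_j)
  ux[idx] <- u[, 1]; uy[idx] <- u[, 2]
  structure(list(ux = ux, uy = uy, base_ux = ux, base_uy = uy, lambda = 1),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %d x %d nodes, max |u| = %.2f um/min, lambda = %g\n",
              nrow(x$ux), ncol(x$ux), max(sqrt(x$ux^2 + x$uy^2)), x$lambda))
  invisible(x)
}

#' Rescale the flow field (vasodilator modulation)
#'
#' During a vasodilator window the tumor-vessel blood flow drops by the
#' factor \code{lambda}; by Stokes linearity the whole interstitial field
#' scales with it. \code{lambda = 1} restores the baseline exactly.
#'
#' @param field a \code{flow_field}
#' @param lambda scale factor in \code{[0, 1]}
#' @return the rescaled \code{flow_field}
#' @export
scale_flow <- function(field, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  field$ux <- field$base_ux * lambda
  field$uy <- field$base_uy * lambda
  field$lambda <- lambda
  field
}

#' Export a flow field as a delimited table
#'
#' @param field a \code{flow_field}
#' @param domain the \code{tissue_domain} it was computed on
#' @param path output file (tab-separated: x, y, ux, uy)
#' @export
write_flow_field <- function(field, domain, path) {
  g <- domain$grid
  df <- data.frame(x = rep(node_x(g), times = g$N_j),
                   y = rep(node_y(g), each = g$N_i),
                   ux = as.vector(field$ux), uy = as.vector(field$uy))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
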