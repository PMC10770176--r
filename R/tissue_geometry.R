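#' Regular grid specification for the tissue domain
#'
#' Defines the rectangular computational domain and its uniform finite
#' difference grid. Nodes sit at \code{x_min + (i-1) h}, \code{y_min + (j-1) h}
#' (1-based node indexing), so the extents must be integer multiples of the
#' spacing. The default is the 200 x 100 um tissue patch discretized at
#' h = 2 um (101 x 51 nodes) with the vessel along the left edge.
#'
#' @param x_min,x_max,y_min,y_max domain extents (um)
#' @param h grid spacing (um)
#' @return an object of class \code{grid_spec}
#' @export
#' @examples
#' g <- grid_spec()
#' g$N_i # 101
grid_spec <- function(x_min = 0, x_max = 200, y_min = 0, y_max = 100, h = 2) {
  if (h <= 0) stop("grid spacing h must be positive")
  if (x_max <= x_min || y_max <= y_min) stop("degenerate domain extents")
  ni <- (x_max - x_min) / h
  nj <- (y_max - y_min) / h
  if (abs(ni - round(ni)) > 1e-9 || abs(nj - round(nj)) > 1e-9)
    stop("domain extents must be integer multiples of h")
  structure(list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max,
                 h = h, N_i = as.integer(round(ni)) + 1L,
                 N_j = as.integer(round(nj)) + 1L),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> [%g, %g] x [%g, %g] um, h = %g um (%d x %d nodes)\n",
              x$x_min, x$x_max, x$y_min, x$y_max, x$h, x$N_i, x$N_j))
  invisible(x)
}

node_x <- function(grid) grid$x_min + (seq_len(grid$N_i) - 1) * grid$h
node_y <- function(grid) grid$y_min + (seq_len(grid$N_j) - 1) * grid$h

# Shoelace area of an open ring (first point not repeated); positive for
# counter-clockwise orientation.
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  nxt <- c(2:n, 1)
  0.5 * sum(x * y[nxt] - x[nxt] * y)
}

# Resample a closed contour (open ring) to uniform arc-length spacing
# approximately `spacing`; at least 3 points are kept.
resample_contour <- function(xy, spacing) {
  n <- nrow(xy)
  ring <- rbind(xy, xy[1, , drop = FALSE])
  seg <- sqrt(diff(ring[, 1])^2 + diff(ring[, 2])^2)
  L <- sum(seg)
  # already uniformly spaced at ~spacing: keep coordinates untouched so that
  # write/load round-trips are exact
  if (all(abs(seg - spacing) < 0.1 * spacing)) return(xy)
  m <- max(3L, as.integer(round(L / spacing)))
  s_cum <- c(0, cumsum(seg))
  s_new <- (seq_len(m) - 1) * L / m
  out <- cbind(approx(s_cum, ring[, 1], xout = s_new)$y,
               approx(s_cum, ring[, 2], xout = s_new)$y)
  out
}

# Interior mask by even-odd point-in-polygon over each cell's bounding box;
# nodes exactly on a contour are counted as interior (cells are obstacles).
build_interior_mask <- function(grid, cells) {
  interior <- matrix(FALSE, grid$N_i, grid$N_j)
  xs <- node_x(grid); ys <- node_y(grid)
  for (cell in cells) {
    xy <- cell$xy
    irange <- which(xs >= min(xy[, 1]) - grid$h & xs <= max(xy[, 1]) + grid$h)
    jrange <- which(ys >= min(xy[, 2]) - grid$h & ys <= max(xy[, 2]) + grid$h)
    if (!length(irange) || !length(jrange)) next
    gx <- rep(xs[irange], times = length(jrange))
    gy <- rep(ys[jrange], each = length(irange))
    inp <- pracma::inpolygon(gx, gy, xy[, 1], xy[, 2], boundary = TRUE)
    if (any(inp)) {
      sub <- matrix(inp, length(irange), length(jrange))
      interior[irange, jrange] <- interior[irange, jrange] | sub
    }
  }
  interior
}

#' Map cell pseudo-receptors to nearby grid nodes
#'
#' For every cell boundary point (pseudo-receptor), finds the interstitial
#' grid nodes strictly within the regularization radius \code{epsilon}
#' (the indicator of the receptor neighborhood). Nodes inside cells are
#' excluded. Receptors at tight cell-cell contacts may cover no node at all;
#' their number is reported in \code{domain$n_orphan_receptors}.
#'
#' @param domain a \code{tissue_domain}
#' @return nested list: per cell, per boundary point, an integer vector of
#'   linear node indices (column-major over the \code{N_i x N_j} grid)
#' @export
build_receptor_map <- function(domain) {
  grid <- domain$grid
  xs <- node_x(grid); ys <- node_y(grid)
  eps <- domain$epsilon
  open <- !domain$interior
  lapply(domain$cells, function(cell) {
    lapply(seq_len(nrow(cell$xy)), function(p) {
      px <- cell$xy[p, 1]; py <- cell$xy[p, 2]
      ii <- which(abs(xs - px) < eps)
      jj <- which(abs(ys - py) < eps)
      if (!length(ii) || !length(jj)) return(integer(0))
      d2 <- outer((xs[ii] - px)^2, (ys[jj] - py)^2, "+")
      hit <- which(d2 < eps^2 & open[ii, jj, drop = FALSE], arr.ind = TRUE)
      if (!nrow(hit)) return(integer(0))
      as.integer((jj[hit[, 2]] - 1L) * grid$N_i + ii[hit[, 1]])
    })
  })
}

# Assemble a tissue_domain from grid + cell contours (internal workhorse of
# both the loader and the synthetic generator).
new_tissue_domain <- function(grid, cells, epsilon, resample = TRUE) {
  if (epsilon <= 0) stop("epsilon must be positive")
  cells <- lapply(cells, function(cell) {
    xy <- cell$xy
    if (resample) xy <- resample_contour(xy, epsilon)
    a <- polygon_area(xy)
    if (a < 0) { xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]; a <- -a }
    if (a <= 0) stop(sprintf("cell %s has non-positive area", cell$id))
    list(id = cell$id, xy = xy, area = a)
  })
  dom <- structure(list(grid = grid, cells = cells, epsilon = epsilon,
                        vessel_edge = list(x = grid$x_min,
                                           y = c(grid$y_min, grid$y_max)),
                        interior = build_interior_mask(grid, cells)),
                   class = "tissue_domain")
  dom$receptor_map <- build_receptor_map(dom)
  dom$cell_nodes <- lapply(dom$receptor_map, function(cl) as.integer(unlist(cl)))
  dom$n_orphan_receptors <- sum(vapply(dom$receptor_map, function(cl)
    sum(!lengths(cl)), integer(1)))
  if (dom$n_orphan_receptors > 0)
    message(sprintf("%d pseudo-receptor(s) cover no interstitial node (tight cell contacts)",
                    dom$n_orphan_receptors))
  dom
}

#' @export
print.tissue_domain <- function(x, ...) {
  npts <- sum(vapply(x$cells, function(c) nrow(c$xy), integer(1)))
  cat(sprintf("<tissue_domain> %d cells, %d boundary points, epsilon = %g um\n",
              length(x$cells), npts, x$epsilon))
  print(x$grid)
  cat(sprintf("  interstitial node fraction: %.1f%%; total cell area %.0f um^2\n",
              100 * mean(!x$interior),
              sum(vapply(x$cells, `[[`, numeric(1), "area"))))
  invisible(x)
}

#' Load a digitized tissue geometry from a delimited file
#'
#' Reads per-cell ordered boundary coordinates from a delimited text file
#' with columns \code{cell_id, x, y} (whitespace or comma separated, optional
#' header), one row per boundary point, rows of one cell contiguous.
#' Rings close implicitly (the last point need not repeat the first), but a
#' closing gap exceeding both the grid spacing and 1.25 times the median
#' vertex spacing is rejected as an open contour. Boundary points are
#' resampled to uniform spacing \code{epsilon} on load, matching the
#' Stokeslet regularization radius.
#'
#' @param path geometry file
#' @param grid a [grid_spec()]
#' @param epsilon regularization radius / receptor reach (um)
#' @return a \code{tissue_domain} with masks and receptor map built
#' @export
#' @examples
#' f <- system.file("extdata", "synthetic_tissue_small.txt", package = "hapflow")
#' dom <- load_tissue(f, grid_spec(0, 100, 0, 50, h = 2))
#' dom
load_tissue <- function(path, grid = grid_spec(), epsilon = 2) {
  first <- readLines(path, n = 1)
  has_header <- grepl("[A-Za-z]", first)
  tab <- read.table(path, header = has_header, sep = "",
                    col.names = c("cell_id", "x", "y"))
  if (grepl(",", first)) # comma dialect
    tab <- read.table(path, header = has_header, sep = ",",
                      col.names = c("cell_id", "x", "y"))
  ids <- rle(as.character(tab$cell_id))$values
  if (anyDuplicated(ids))
    stop(sprintf("duplicate cell_id: %s", ids[duplicated(ids)][1]))
  out_x <- tab$x < grid$x_min | tab$x > grid$x_max
  out_y <- tab$y < grid$y_min | tab$y > grid$y_max
  if (any(out_x | out_y))
    stop(sprintf("out-of-domain coordinates for cell_id %s",
                 tab$cell_id[which(out_x | out_y)[1]]))
  cells <- lapply(split(tab, factor(tab$cell_id, levels = unique(tab$cell_id))),
                  function(df) {
    xy <- as.matrix(df[, c("x", "y")])
    if (nrow(xy) >= 2 &&
        sqrt(sum((xy[1, ] - xy[nrow(xy), ])^2)) < 1e-6 * grid$h)
      xy <- xy[-nrow(xy), , drop = FALSE] # explicit closure: drop duplicate
    if (nrow(xy) < 3) stop(sprintf("cell %s has fewer than 3 points", df$cell_id[1]))
    gap <- sqrt(sum((xy[1, ] - xy[nrow(xy), ])^2))
    seg <- sqrt(rowSums((xy[-1, , drop = FALSE] -
                         xy[-nrow(xy), , drop = FALSE])^2))
    # rings close implicitly; a closing gap far larger than the contour's
    # own vertex spacing (and the grid spacing) marks a digitization gap
    if (gap > max(grid$h, 1.25 * stats::median(seg)))
      stop(sprintf("open contour for cell_id %s (closure gap %.2f um)",
                   df$cell_id[1], gap))
    list(id = df$cell_id[1], xy = xy)
  })
  dom <- new_tissue_domain(grid, unname(cells), epsilon)
  message(sprintf("loaded %d cells with %d boundary points", length(dom$cells),
                  sum(vapply(dom$cells, function(c) nrow(c$xy), integer(1)))))
  dom
}

#' Write a tissue geometry to the delimited format read by [load_tissue()]
#'
#' @param domain a \code{tissue_domain}
#' @param path output file
#' @export
write_tissue <- function(domain, path) {
  rows <- do.call(rbind, lapply(domain$cells, function(cell)
    data.frame(cell_id = cell$id, x = cell$xy[, 1], y = cell$xy[, 2])))
  write.table(format(rows, digits = 15, trim = TRUE), path,
              quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Generate a synthetic tumor tissue
#'
#' Packs irregular, pairwise non-overlapping closed cell contours (perturbed
#' polygons) into the domain, leaving a cell-free strip of at least
#' \code{2 * epsilon} along the left (vessel) edge so the vascular influx is
#' unobstructed. Cells are seeded on a jittered hexagonal lattice whose
#' spacing adapts to \code{n_cells}; each contour's radial extent is capped by
#' half the distance to its nearest neighbor (minus a fixed interstitial gap),
#' which guarantees non-overlap while keeping the packing dense, as in tumor
#' histology. Boundary points are spaced approximately \code{epsilon} apart.
#' The construction is fully deterministic for a fixed seed.
#'
#' @param grid a [grid_spec()]
#' @param n_cells number of cells to place
#' @param mean_radius nominal mean cell radius (um); must be at least twice
#'   the grid spacing so cells are resolved by the mask
#' @param seed integer RNG seed
#' @param epsilon regularization radius / boundary point spacing (um)
#' @return a \code{tissue_domain}
#' @export
generate_synthetic_tissue <- function(grid = grid_spec(), n_cells = 300,
                                      mean_radius = 4, seed, epsilon = 2) {
  if (n_cells < 0) stop("n_cells must be non-negative")
  if (mean_radius < 2 * grid$h)
    stop("mean_radius must be at least twice the grid spacing")
  if (missing(seed)) stop("seed is required (determinism contract)")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  if (n_cells == 0) return(new_tissue_domain(grid, list(), epsilon))

  strip <- 2 * epsilon                       # cell-free margin at the vessel
  x_lo <- grid$x_min + strip; x_hi <- grid$x_max
  amp <- 0.15                                # contour perturbation amplitude
  gap <- 0.6                                 # guaranteed interstitial gap (um)

  # hexagonal lattice sized to the request; the spacing shrinks (down to a
  # floor that keeps cells resolvable) until enough sites fit the region
  A_region <- (x_hi - x_lo) * (grid$y_max - grid$y_min)
  s <- sqrt(2 * A_region / (sqrt(3) * n_cells))
  s_floor <- 1.6 * mean_radius
  make_sites <- function(s) {
    yc <- seq(grid$y_min + 0.45 * s, grid$y_max - 0.45 * s,
              by = s * sqrt(3) / 2)
    do.call(rbind, lapply(seq_along(yc), function(r) {
      off <- if (r %% 2 == 0) s / 2 else 0
      xv <- seq(x_lo + 0.55 * s + off, x_hi - 0.45 * s, by = s)
      cbind(xv, yc[r])
    }))
  }
  s <- max(s, s_floor)
  sites <- make_sites(s)
  while (nrow(sites) < n_cells && s > s_floor) {
    s <- max(0.97 * s, s_floor)
    sites <- make_sites(s)
  }
  if (nrow(sites) < n_cells)
    stop(sprintf("packing failure: only %d of %d cells can be placed",
                 nrow(sites), n_cells))
  jit <- 0.08 * s
  sites <- sites + matrix(runif(2 * nrow(sites), -jit, jit), ncol = 2)
  sel <- sites[sample.int(nrow(sites), n_cells), , drop = FALSE]

  dmin <- if (n_cells > 1) {
    dm <- as.matrix(dist(sel)); diag(dm) <- Inf; apply(dm, 1, min)
  } else rep(Inf, 1)
  wall <- pmin(sel[, 1] - x_lo, x_hi - sel[, 1],
               sel[, 2] - grid$y_min, grid$y_max - sel[, 2])
  allowed <- pmin(0.5 * (dmin - gap), wall - 0.2)
  r_des <- mean_radius * runif(n_cells, 0.85, 1.15)
  r_ext <- pmin(r_des * (1 + amp), allowed)
  if (any(r_ext < 1))
    stop(sprintf("packing failure: only %d of %d cells have viable room",
                 sum(r_ext >= 1), n_cells))
  cells <- lapply(seq_len(n_cells), function(l) {
    r_base <- r_ext[l] / (1 + amp)
    nth <- max(16L, as.integer(round(2 * pi * r_base / (epsilon / 2))))
    th <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
    w <- runif(3); ph <- runif(3, 0, 2 * pi)
    g <- w[1] * cos(2 * th + ph[1]) + w[2] * cos(3 * th + ph[2]) +
         w[3] * cos(4 * th + ph[3])
    g <- g / max(abs(g))
    r <- r_base * (1 + amp * g)
    list(id = l, xy = cbind(sel[l, 1] + r * cos(th), sel[l, 2] + r * sin(th)))
  })
  new_tissue_domain(grid, cells, epsilon)
}

# Per-node receptor multiplicity over live cells (integer N_i x N_j matrix).
receptor_count_matrix <- function(domain, alive = rep(TRUE, length(domain$cells))) {
  cnt <- matrix(0L, domain$grid$N_i, domain$grid$N_j)
  for (l in seq_along(domain$cells)) {
    if (!alive[l]) next
    idx <- domain$cell_nodes[[l]]
    if (length(idx)) {
      t <- tabulate(idx, nbins = length(cnt))
      cnt <- cnt + matrix(as.integer(t), domain$grid$N_i, domain$grid$N_j)
    }
  }
  cnt
}

#' Per-cell areas of a tissue domain
#' @param domain a \code{tissue_domain}
#' @return numeric vector of polygon areas (um^2)
#' @export
cell_areas <- function(domain)
  vapply(domain$cells, `[[`, numeric(1), "area")
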