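#' Initialize per-cell pharmacodynamic state
#'
#' One row per cell: accumulated active drug (node-summed concentration
#' units), alive flag and death time. Accumulation is non-decreasing while a
#' cell lives and frozen after death; death is irreversible and dead cells
#' are excluded from all uptake sums while remaining physical obstacles.
#'
#' @param domain a \code{tissue_domain}
#' @return data frame with columns \code{cell_id}, \code{area},
#'   \code{accumulated}, \code{alive}, \code{death_time}
#' @export
cell_states <- function(domain) {
  n <- length(domain$cells)
  data.frame(cell_id = vapply(domain$cells, function(c) as.character(c$id),
                              character(1)),
             area = cell_areas(domain),
             accumulated = numeric(n),
             alive = rep(TRUE, n),
             death_time = rep(NA_real_, n),
             stringsAsFactors = FALSE)
}

#' Accumulate active drug into live cells
#'
#' Each live cell gains \code{dt * alpha * sum(eta_a)} over all grid nodes in
#' its pseudo-receptor neighborhoods (nodes covered by several receptors
#' count once per receptor). This is the cell-side view of the same flux that
#' the transport uptake term removes from the active drug field; dead cells
#' absorb nothing.
#'
#' @param cells cell-state data frame from [cell_states()]
#' @param eta_a active drug \code{scalar_field} (pre-uptake values)
#' @param domain a \code{tissue_domain}
#' @param alpha uptake rate (1/min)
#' @param dt time step (min)
#' @return the updated cell-state data frame
#' @export
accumulate_drug <- function(cells, eta_a, domain, alpha, dt) {
  inc <- vapply(seq_along(domain$cells), function(l) {
    if (!cells$alive[l]) return(0)
    idx <- domain$cell_nodes[[l]]
    if (!length(idx)) return(0)
    dt * alpha * sum(eta_a$values[idx])
  }, numeric(1))
  cells$accumulated <- cells$accumulated + inc
  cells
}

#' Trigger irreversible cell death past the lethal threshold
#'
#' A cell dies when its accumulated drug, converted to a mean concentration
#' over the cell (node sum times \code{h^2}, divided by the cell area),
#' reaches the lethal threshold (inclusive). Death is irreversible: the
#' death time is recorded once and the cell is excluded from oxygen and drug
#' uptake from the next step on, while its contour remains an obstacle.
#'
#' @param cells cell-state data frame
#' @param domain a \code{tissue_domain} (provides areas and grid spacing)
#' @param threshold lethal mean concentration (ag/um^3)
#' @param t current time (min), recorded as death time for new deaths
#' @return the updated cell-state data frame
#' @export
update_death <- function(cells, domain, threshold = 1, t) {
  h2 <- domain$grid$h^2
  newly <- cells$alive & (cells$accumulated * h2 / cells$area >= threshold)
  cells$alive[newly] <- FALSE
  cells$death_time[newly] <- t
  cells
}
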