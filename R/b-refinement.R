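#' Refinement configuration
#'
#' Parameters of the a-priori (right-hand-side driven) mesh refinement and
#' the subsequent solve.
#'
#' @param k selection threshold constant (dimensionless, the study range is
#'   5-10; default 7).
#' @param steps number of refine iterations (>= 0; 4 for the sphere
#'   validation, 3 suffices for spheres, 4-5 for realistic heads).
#' @param smooth_passes Taubin pass pairs applied to newly created vertices
#'   after each step.
#' @param shrink_factor,inflate_factor Taubin factors (see [taubin_smooth()]).
#' @param analytic_radius analytic-integration ball radius in original
#'   average-edge-length units (see [facet_normal_field()]).
#' @param neighbor_count analytic neighbor integrals for the solve.
#' @param per_compartment_mean if `TRUE`, the selection mean `|q|` is taken
#'   per compartment instead of over all facets jointly (off by default).
#' @return A `refinement_config` list.
#' @export
refinement_config <- function(k = 7, steps = 4, smooth_passes = 1,
                              shrink_factor = -0.62, inflate_factor = 0.60,
                              analytic_radius = 3, neighbor_count = 64,
                              per_compartment_mean = FALSE) {
  if (k <= 0) stop("k must be > 0")
  if (steps < 0) stop("steps must be >= 0")
  structure(list(k = k, steps = steps, smooth_passes = smooth_passes,
                 shrink_factor = shrink_factor,
                 inflate_factor = inflate_factor,
                 analytic_radius = analytic_radius,
                 neighbor_count = neighbor_count,
                 per_compartment_mean = per_compartment_mean),
            class = "refinement_config")
}

#' Select facets for refinement
#'
#' A facet is selected when its total charge magnitude `|q_m| = |A_m c_m|`
#' exceeds `k` times the mean `|q|` over all facets.
#'
#' @param areas per-facet areas (m^2).
#' @param c_estimate per-facet charge estimate (the right-hand side `b`).
#' @param k threshold constant.
#' @param groups optional grouping (e.g. compartment ids) over which the mean
#'   is taken separately; default a single joint mean over all facets.
#' @return Integer vector of selected facet indices (empty when all `q` are
#'   zero or no facet exceeds the threshold).
#' @export
select_facets <- function(areas, c_estimate, k, groups = NULL) {
  if (length(areas) != length(c_estimate)) stop("length mismatch")
  q <- abs(areas * c_estimate)
  if (all(q == 0)) return(integer(0))
  if (is.null(groups)) {
    thr <- k * mean(q)
  } else {
    thr <- k * stats::ave(q, groups, FUN = mean)
  }
  which(q > thr)
}

# map global facet ids to per-compartment local ids
split_by_compartment <- function(model, ids) {
  offs <- c(0L, cumsum(model$facets_per_compartment))
  lapply(seq_along(model$compartments), function(i) {
    sel <- ids[ids > offs[i] & ids <= offs[i + 1]]
    sel - offs[i]
  })
}

#' One b-refinement step
#'
#' Recomputes the right-hand-side charge estimate on the current mesh,
#' selects facets whose total charge exceeds the threshold, applies the 4:1
#' subdivision with border closure, smooths the newly created vertices, and
#' reassembles the model. Child facets inherit their compartment (and hence
#' its conductivity contrast).
#'
#' @param model a `head_model`.
#' @param dipoles a [dipole_set()].
#' @param config a [refinement_config()].
#' @param orig_avg_edge average edge length of the unrefined mesh (m); the
#'   analytic-integration ball stays fixed in these units across steps.
#' @return The refined `head_model` (unchanged if nothing is selected), with
#'   attribute `"n_selected"`.
#' @export
refine_step <- function(model, dipoles, config, orig_avg_edge = NULL) {
  if (is.null(orig_avg_edge)) orig_avg_edge <- model$avg_edge
  Ein <- facet_normal_field(dipoles, model, config$analytic_radius,
                            avg_edge = orig_avg_edge)
  b <- initial_estimate(model, Ein)
  groups <- if (config$per_compartment_mean) model$facet_compartment else NULL
  sel <- select_facets(model$areas, b, config$k, groups)
  if (length(sel) == 0) {
    attr(model, "n_selected") <- 0L
    return(model)
  }
  local <- split_by_compartment(model, sel)
  comps <- model$compartments
  for (i in seq_along(comps)) {
    if (length(local[[i]]) == 0) next
    rr <- subdivide_4to1(comps[[i]]$mesh, local[[i]])
    mesh <- rr$mesh
    if (config$smooth_passes > 0 && length(rr$new_vertices) > 0) {
      mesh <- taubin_smooth(mesh, rr$new_vertices,
                            passes = config$smooth_passes,
                            shrink_factor = config$shrink_factor,
                            inflate_factor = config$inflate_factor)
    }
    comps[[i]] <- compartment(comps[[i]]$name, mesh, comps[[i]]$sigma_in,
                              comps[[i]]$sigma_out)
  }
  out <- assemble(comps)
  attr(out, "n_selected") <- length(sel)
  out
}

#' a-priori b-refinement
#'
#' Applies [refine_step()] exactly `config$steps` times before any solve; no
#' refinement happens once the Krylov iteration starts. Deterministic: the
#' loop contains no randomness.
#'
#' @inheritParams refine_step
#' @return The refined `head_model`, with attribute `"refinement_history"`
#'   (facet count after each step, starting at the input count).
#' @export
b_refine <- function(model, dipoles, config) {
  orig_avg_edge <- model$avg_edge
  history <- model$n_facets
  for (s in seq_len(config$steps)) {
    model <- refine_step(model, dipoles, config, orig_avg_edge = orig_avg_edge)
    history <- c(history, model$n_facets)
  }
  attr(model, "refinement_history") <- history
  model
}

#' Parameter sweep over (k, steps, neighbor count)
#'
#' For each grid point: b-refine, solve, evaluate skin potential and the
#' offset magnetic field, and tabulate RDM / relative-L2 errors against the
#' supplied reference fields. Cells that fail are flagged and left `NA`.
#'
#' @param model the unrefined `head_model`.
#' @param dipoles a [dipole_set()].
#' @param k_grid,steps_grid,neighbors_grid sweep values.
#' @param reference list with `eeg_points`, `eeg` (reference potentials),
#'   and optionally `meg_points`, `meg` (n x 3 reference B field).
#' @param tol,max_iter solver settings.
#' @param analytic_radius see [facet_normal_field()].
#' @return A data frame with one row per grid cell: `k`, `steps`,
#'   `neighbors`, `rdm_potential`, `l2_potential`, `rdm_B`, `l2_B`, `ok`.
#' @export
parameter_sweep <- function(model, dipoles, k_grid, steps_grid,
                            neighbors_grid = 64, reference,
                            tol = 1e-6, max_iter = 200, analytic_radius = 3) {
  grid <- expand.grid(k = k_grid, steps = steps_grid,
                      neighbors = neighbors_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    out <- data.frame(k = row$k, steps = row$steps, neighbors = row$neighbors,
                      rdm_potential = NA_real_, l2_potential = NA_real_,
                      rdm_B = NA_real_, l2_B = NA_real_, ok = FALSE)
    tryCatch({
      cfg <- refinement_config(k = row$k, steps = row$steps,
                               analytic_radius = analytic_radius,
                               neighbor_count = row$neighbors)
      rmodel <- b_refine(model, dipoles, cfg)
      nf <- precompute_nearfield(rmodel, row$neighbors)
      Ein <- facet_normal_field(dipoles, rmodel, analytic_radius,
                                avg_edge = model$avg_edge)
      sol <- solve_charge(rmodel, initial_estimate(rmodel, Ein), nf,
                          tol = tol, max_iter = max_iter)
      phi <- potential_at(sol, rmodel, dipoles, reference$eeg_points,
                          zero_mean = TRUE)
      ep <- error_report(phi, reference$eeg, type = "potential")
      out$rdm_potential <- ep$rdm
      out$l2_potential <- ep$relative_l2
      if (!is.null(reference$meg)) {
        B <- magnetic_field_at(sol, rmodel, dipoles, reference$meg_points)
        eb <- error_report(B, reference$meg, type = "field")
        out$rdm_B <- eb$rdm
        out$l2_B <- eb$relative_l2
      }
      out$ok <- TRUE
      out
    }, error = function(e) out)
  })
  do.call(rbind, rows)
}
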