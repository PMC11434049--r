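# End-to-end phantom pipeline: render both respiratory states of a
# generated unit, segment and split them, measure morphometry, and pair the
# states into dynamics records with ground truth attached.

#' Run the full measurement chain on a phantom unit
#'
#' Voxelizes both states on a common grid, renders grayscale with the
#' spec's noise, segments air, splits instances by watershed, measures all
#' structures, and pairs the two states. Structures are paired by nearest
#' centroid (instance labels are rank-ordered by size per state and can
#' swap); the whole-unit record uses the union-mask isosurface, which is
#' robust to the irregular aperture boundaries a watershed split produces.
#'
#' Inspiration-state meshes are extracted with the smoothing scaled by the
#' measured linear expansion (cube root of the air-voxel-count ratio), so
#' both states are measured at matched relative resolution and the
#' scale-dependent surface biases cancel in ratio statistics such as q.
#'
#' @param unit a [generate_unit] result.
#' @param noise_seed RNG seed for the rendering noise.
#' @param sigma base mesh-extraction smoothing, voxels.
#' @param persistence,min_volume forwarded to [split_instances].
#' @param angles also measure theta for the ground-truth neighbor pairs
#'   (matched to measured labels by centroid).
#' @return list: `labels_exp`, `labels_insp` ([labeled_volume]s),
#'   `rec_exp`, `rec_insp` (morphometry tables), `dynamics`
#'   ([pair_dynamics] table), `angles` (per-pair theta table or `NULL`),
#'   `q`, `q_true`.
#' @export
run_chain <- function(unit, noise_seed = 1, sigma = 1, persistence = 2,
                      min_volume = 500, angles = TRUE) {
  stopifnot(inherits(unit, "phantom_unit"))
  one_state <- function(state) {
    v <- phantom_volume(unit, state)
    img <- render_grayscale(v, unit$spec$noise_sd, seed = noise_seed +
                              (state == "inspiration"))
    split_instances(segment_air(img), spacing = v$spacing, state = state,
                    origin = v$origin, persistence = persistence,
                    min_volume = min_volume)
  }
  le <- one_state("expiration")
  li <- one_state("inspiration")
  shat <- (sum(li$voxels > 0L) / sum(le$voxels > 0L))^(1 / 3)
  me <- measure_structures(le, walls = FALSE, unit_method = "union",
                           sigma = sigma)
  mi <- measure_structures(li, walls = FALSE, unit_method = "union",
                           sigma = sigma * shat)
  dyn <- pair_dynamics(me, mi, by = "centroid",
                       max_displacement = 10 * mean(le$spacing) +
                         0.3 * unit$spec$alveolar_radius)
  ang <- NULL
  if (angles && nrow(unit$truth$pairs) > 0) {
    tr <- unit$truth$structures
    tr <- tr[tr$state == "expiration" & tr$role == "alveolus", ]
    malv <- me[me$role == "alveolus", ]
    map <- vapply(tr$structure_id, function(tid) {
      t <- tr[tr$structure_id == tid, ]
      d <- sqrt((malv$cx - t$cx)^2 + (malv$cy - t$cy)^2 +
                  (malv$cz - t$cz)^2)
      malv$structure_id[which.min(d)]
    }, character(1))
    pr <- unit$truth$pairs
    alvdyn <- dyn[dyn$role == "alveolus", ]
    id_map <- stats::setNames(alvdyn$structure_id_insp,
                              alvdyn$structure_id)
    # pairs whose members went unmatched across states are not measurable
    ok <- map[pr$id_a] %in% names(id_map) & map[pr$id_b] %in% names(id_map)
    pr <- pr[ok, , drop = FALSE]
    if (nrow(pr) > 0) {
      ang <- pair_angles(me, mi, data.frame(a = map[pr$id_a],
                                            b = map[pr$id_b]),
                         id_map = id_map)
      ang$d_theta_true <- pr$d_theta_true
    }
  }
  q <- dyn$q[dyn$role == "unit_AAD"]
  list(labels_exp = le, labels_insp = li, rec_exp = me, rec_insp = mi,
       dynamics = dyn, angles = ang, q = q, q_true = unit$truth$q_true)
}

#' Replicated phantom study for one deformation mode
#'
#' Generates `n` feasible phantom replicates (placement seeds are drawn
#' sequentially from `seed`; seeds whose rejection-sampling placement is
#' infeasible are skipped and recorded) and runs [run_chain] on each.
#'
#' @param mode deformation mode passed to [phantom_spec].
#' @param n number of replicates.
#' @param seed base seed; replicate r uses placement seed `seed + r`.
#' @param spec_args named list of further [phantom_spec] arguments.
#' @param ... forwarded to [run_chain].
#' @return data.frame with one row per replicate: `seed`, `q`, `q_true`,
#'   `mean_d_theta`, `mean_d_theta_true`, `n_instances`; attribute
#'   `skipped` lists infeasible seeds.
#' @export
phantom_replicates <- function(mode, n = 7, seed = 1, spec_args = list(),
                               ...) {
  rows <- list()
  skipped <- integer(0)
  s <- seed
  while (length(rows) < n) {
    s <- s + 1
    unit <- tryCatch(
      generate_unit(do.call(phantom_spec, c(
        list(deformation_mode = mode, placement_seed = s), spec_args))),
      error = function(e) {
        if (grepl("placement failure", conditionMessage(e))) NULL
        else stop(e)
      })
    if (is.null(unit)) {
      skipped <- c(skipped, s)
      next
    }
    res <- run_chain(unit, noise_seed = s, ...)
    rows[[length(rows) + 1]] <- data.frame(
      seed = s, q = res$q, q_true = res$q_true,
      mean_d_theta = if (!is.null(res$angles))
        mean(res$angles$d_theta) else NA_real_,
      mean_d_theta_true = if (!is.null(res$angles))
        mean(res$angles$d_theta_true) else NA_real_,
      n_instances = length(label_counts(res$labels_exp)))
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}
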