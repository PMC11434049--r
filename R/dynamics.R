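# Tidal-cycle dynamics: the dimensionless shape factor k = S / V^(2/3),
# the shape-change statistic q = k_insp / k_exp of a gas-exchange unit,
# area and linear strains of the alveolar membrane and entrance ring, and
# the inter-alveolar angle change.

#' Dimensionless shape factor k
#'
#' `k = S / V^(2/3)`. Scale-invariant: a cube gives 6 for any edge length,
#' a sphere the isoperimetric minimum `6^(2/3) pi^(1/3)` (about 4.8360);
#' larger k means more surface per volume.
#'
#' @param S surface area, square micrometres.
#' @param V volume, cubic micrometres.
#' @return k (dimensionless).
#' @export
shape_factor <- function(S, V) {
  if (any(S <= 0) || any(V <= 0)) stop("S and V must be positive")
  S / V^(2 / 3)
}

#' Isoperimetric lower bound of the shape factor
#' @return `6^(2/3) * pi^(1/3)`, the k of a sphere.
#' @export
k_sphere <- function() 6^(2 / 3) * pi^(1 / 3)

#' Shape-change statistic q of a gas-exchange unit
#'
#' `q = k_insp / k_exp` over a tidal cycle. `q = 1` indicates geometrically
#' similar (balloon-like) expansion, `q > 1` alveolus-dominant expansion
#' (deepening alveoli), `q < 1` duct-dominant expansion (widening duct).
#'
#' @param unit_exp,unit_insp one-row `unit_AAD` morphometry records of the
#'   same structure at expiration and inspiration.
#' @return q (dimensionless).
#' @export
q_statistic <- function(unit_exp, unit_insp) {
  stopifnot(nrow(unit_exp) == 1, nrow(unit_insp) == 1)
  if (unit_exp$role != "unit_AAD" || unit_insp$role != "unit_AAD")
    stop("pairing error: q is defined on unit_AAD records")
  if (unit_exp$structure_id != unit_insp$structure_id)
    stop("pairing error: structure ids differ")
  shape_factor(unit_insp$S_um2, unit_insp$V_um3) /
    shape_factor(unit_exp$S_um2, unit_exp$V_um3)
}

#' Area strain
#'
#' `dS = (S_insp - S_exp) / S_exp`; negative values (shrinking area) are
#' permitted.
#'
#' @param S_exp,S_insp surface areas, square micrometres.
#' @return dimensionless area strain.
#' @export
area_strain <- function(S_exp, S_insp) {
  if (any(S_exp <= 0)) stop("S_exp must be positive")
  (S_insp - S_exp) / S_exp
}

#' Linear strain from an area strain
#'
#' `eps = sqrt(1 + dS) - 1`, the length-scale strain equivalent to an
#' isotropic area strain dS.
#'
#' @param dS area strain (> -1).
#' @return dimensionless linear strain.
#' @export
linear_strain <- function(dS) {
  if (any(dS <= -1)) stop("dS must be > -1")
  sqrt(1 + dS) - 1
}

#' Entrance-ring strain
#'
#' `eps_ER = (P_insp - P_exp) / P_exp`; the ring perimeter is already a
#' length scale, so no area conversion is applied.
#'
#' @param P_exp,P_insp ring perimeters, micrometres.
#' @return dimensionless linear strain.
#' @export
ring_strain <- function(P_exp, P_insp) {
  if (any(P_exp <= 0)) stop("P_exp must be positive")
  (P_insp - P_exp) / P_exp
}

#' Inter-alveolar angle change
#'
#' `d_theta = theta_insp - theta_exp` in degrees; its sign diagnoses the
#' expansion mode (positive for duct-dominant, negative for
#' alveolus-dominant, zero for isotropic).
#'
#' @param theta_exp,theta_insp angles in degrees, each in \[0, 180\].
#' @return signed difference in degrees.
#' @export
delta_theta <- function(theta_exp, theta_insp) {
  if (any(theta_exp < 0 | theta_exp > 180) ||
      any(theta_insp < 0 | theta_insp > 180))
    stop("angles must lie in [0, 180] degrees")
  theta_insp - theta_exp
}

#' Pair two single-state morphometry tables into dynamics records
#'
#' Structures are paired by persistent `structure_id` when the two tables
#' share their id sets, otherwise by nearest centroid within
#' `max_displacement`; unmatched structures are reported in the `unmatched`
#' attribute (never silently dropped).
#'
#' @param rec_exp,rec_insp morphometry tables from [measure_structures] at
#'   expiration and inspiration.
#' @param max_displacement centroid matching radius, micrometres.
#' @param by `"auto"` pairs by id when the two tables share their id sets
#'   and falls back to centroids otherwise; `"id"` and `"centroid"` force a
#'   route (centroid pairing is safer when instance labels are assigned by
#'   size rank, which can swap between states).
#' @return data.frame with one row per paired structure (`structure_id` is
#'   the expiration id, `structure_id_insp` its inspiration partner):
#'   `k_exp`, `k_insp` and `q` for the unit row; `dS`, `eps_A` (membrane)
#'   and `eps_ER` (ring) for alveoli.
#' @export
pair_dynamics <- function(rec_exp, rec_insp, max_displacement = 25,
                          by = c("auto", "id", "centroid")) {
  by <- match.arg(by)
  ids_e <- rec_exp$structure_id
  ids_i <- rec_insp$structure_id
  if (by == "id" && !setequal(ids_e, ids_i))
    stop("pairing by id requires identical id sets")
  if (by != "centroid" && setequal(ids_e, ids_i)) {
    matched <- data.frame(id_exp = ids_e, id_insp = ids_e,
                          stringsAsFactors = FALSE)
    unmatched <- character(0)
  } else {
    # greedy assignment over globally ascending centroid distance (within
    # role), so close competing structures cannot steal each other's partner
    cand <- expand.grid(ie = seq_len(nrow(rec_exp)),
                        ii = seq_len(nrow(rec_insp)))
    cand <- cand[rec_exp$role[cand$ie] == rec_insp$role[cand$ii], ,
                 drop = FALSE]
    cand$d <- sqrt((rec_exp$cx[cand$ie] - rec_insp$cx[cand$ii])^2 +
                     (rec_exp$cy[cand$ie] - rec_insp$cy[cand$ii])^2 +
                     (rec_exp$cz[cand$ie] - rec_insp$cz[cand$ii])^2)
    cand <- cand[cand$d <= max_displacement, , drop = FALSE]
    cand <- cand[order(cand$d), , drop = FALSE]
    used_e <- used_i <- logical(0)
    pairs_e <- character(0); pairs_i <- character(0)
    for (k in seq_len(nrow(cand))) {
      ie <- rec_exp$structure_id[cand$ie[k]]
      ii <- rec_insp$structure_id[cand$ii[k]]
      if (ie %in% pairs_e || ii %in% pairs_i) next
      pairs_e <- c(pairs_e, ie); pairs_i <- c(pairs_i, ii)
    }
    matched <- data.frame(id_exp = pairs_e, id_insp = pairs_i,
                          stringsAsFactors = FALSE)
    unmatched <- c(setdiff(ids_e, matched$id_exp),
                   setdiff(ids_i, matched$id_insp))
    if (length(unmatched) > 0)
      warning(sprintf("unmatched structures: %s",
                      paste(unmatched, collapse = ", ")))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(matched)), function(m) {
    re <- rec_exp[rec_exp$structure_id == matched$id_exp[m], ]
    ri <- rec_insp[rec_insp$structure_id == matched$id_insp[m], ]
    ke <- shape_factor(re$S_um2, re$V_um3)
    ki <- shape_factor(ri$S_um2, ri$V_um3)
    ds <- area_strain(re$S_um2, ri$S_um2)
    er <- if (!is.na(re$ring_perimeter_um) && !is.na(ri$ring_perimeter_um))
      ring_strain(re$ring_perimeter_um, ri$ring_perimeter_um) else NA_real_
    data.frame(structure_id = re$structure_id,
               structure_id_insp = ri$structure_id, role = re$role,
               PEEP = re$PEEP, IPP = ri$IPP,
               V_exp = re$V_um3, V_insp = ri$V_um3,
               S_exp = re$S_um2, S_insp = ri$S_um2,
               k_exp = ke, k_insp = ki, q = ki / ke,
               dS = ds, eps_A = linear_strain(ds), eps_ER = er,
               dD_A = ri$D_A_um - re$D_A_um,
               dT_A = ri$T_A_um - re$T_A_um,
               stringsAsFactors = FALSE)
  }))
  attr(out, "unmatched") <- unmatched
  out
}

#' Angle dynamics for neighboring alveolar pairs
#'
#' Computes theta at both states for each given pair and the change
#' `d_theta = theta_insp - theta_exp`.
#'
#' @param rec_exp,rec_insp paired morphometry tables (with `rings`
#'   attributes from [measure_structures]).
#' @param pairs two-column matrix or data.frame of alveolar structure ids
#'   (expiration-state ids).
#' @param id_map named character vector mapping expiration ids to
#'   inspiration ids (as produced by [pair_dynamics]); identity when
#'   `NULL`. Required whenever instance labels are assigned per state.
#' @return data.frame with `theta_exp`, `theta_insp`, `d_theta` per pair.
#' @export
pair_angles <- function(rec_exp, rec_insp, pairs, id_map = NULL) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  rings_e <- attr(rec_exp, "rings"); rings_i <- attr(rec_insp, "rings")
  if (is.null(rings_e) || is.null(rings_i))
    stop("morphometry tables must carry entrance rings (rings = TRUE)")
  lookup <- function(id) {
    if (is.null(id_map)) id else unname(id_map[id])
  }
  one <- function(ia, ib) {
    re_a <- rec_exp[rec_exp$structure_id == ia, ]
    re_b <- rec_exp[rec_exp$structure_id == ib, ]
    ri_a <- rec_insp[rec_insp$structure_id == lookup(ia), ]
    ri_b <- rec_insp[rec_insp$structure_id == lookup(ib), ]
    te <- angle_between_alveoli(re_a, re_b, rings_e[[ia]], rings_e[[ib]])
    ti <- angle_between_alveoli(ri_a, ri_b, rings_i[[lookup(ia)]],
                                rings_i[[lookup(ib)]])
    c(theta_exp = te, theta_insp = ti)
  }
  th <- t(mapply(one, as.character(pairs[[1]]), as.character(pairs[[2]])))
  data.frame(id_a = as.character(pairs[[1]]), id_b = as.character(pairs[[2]]),
             theta_exp = th[, 1], theta_insp = th[, 2],
             d_theta = delta_theta(th[, 1], th[, 2]),
             stringsAsFactors = FALSE, row.names = NULL)
}
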