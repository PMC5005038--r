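# Labels for every unordered trial pair: the quantities all similarity
# contrasts, exclusion filters and distance controls condition on.

#' Label all unordered trial pairs
#'
#' For every pair of trials (i < j) computes the minimal angular difference
#' between the sampled directions, its remainders modulo 60 and modulo 90, the
#' design flags used by the exclusion controls, and three pair distance
#' measures: (I) the mean length of the two start-to-target vectors, (II) the
#' absolute difference of the two lengths, and (III) the "neighborhood
#' distance", the mean Euclidean length of the six vectors connecting the four
#' buildings of the pair.
#'
#' On the 30-degree direction grid every pair falls in exactly one of the
#' modulo-60 conditions (remainder 0 or 30), and pairs probing the same
#' direction (delta 0) belong to the 0-mod-60 (and one-fold "similar")
#' condition.
#'
#' @param trials A 96-trial design tibble (see [generate_design()]).
#' @param layout The `city_layout` the design was built from.
#' @return A tibble with one row per unordered pair: `i`, `j` (trial ids),
#'   `delta_deg`, `rem60`, `rem90`, `same_start`, `same_target`, `same_combo`,
#'   `same_block`, `both_inner_target`, `both_cardinal`, `both_ns_street`,
#'   `dist_mean`, `dist_absdiff`, `dist_neighborhood`.
#' @export
label_pairs <- function(trials, layout) {
  validate_layout(layout)
  n <- nrow(trials)
  if (n < 2L) abort("need at least two trials to label pairs.")
  idx <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  i <- idx[, 1L]
  j <- idx[, 2L]

  dir <- trials$direction_deg
  delta <- delta_deg(dir[i], dir[j])
  b <- layout$buildings
  onstreet <- abs(b$x - layout$ns_street_x) < 1e-8
  is_cardinal <- dir %% 90 == 0
  is_ns_street <- dir %% 180 == 90 &
    onstreet[trials$start_id] & onstreet[trials$target_id]
  len <- trials$distance
  D <- building_distances(layout)
  si <- trials$start_id[i]; ti <- trials$target_id[i]
  sj <- trials$start_id[j]; tj <- trials$target_id[j]
  neigh <- (D[cbind(si, ti)] + D[cbind(si, sj)] + D[cbind(si, tj)] +
              D[cbind(ti, sj)] + D[cbind(ti, tj)] + D[cbind(sj, tj)]) / 6

  tibble(
    i = trials$trial_id[i],
    j = trials$trial_id[j],
    delta_deg = delta,
    rem60 = delta %% 60,
    rem90 = delta %% 90,
    same_start = si == sj,
    same_target = ti == tj,
    same_combo = si == sj & ti == tj,
    same_block = trials$block[i] == trials$block[j],
    both_inner_target = trials$target_ring[i] == "inner" &
      trials$target_ring[j] == "inner",
    both_cardinal = is_cardinal[i] & is_cardinal[j],
    both_ns_street = is_ns_street[i] & is_ns_street[j],
    dist_mean = (len[i] + len[j]) / 2,
    dist_absdiff = abs(len[i] - len[j]),
    dist_neighborhood = neigh
  )
}
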