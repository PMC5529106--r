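#' Match detected spots against a planted truth table
#'
#' Greedy nearest-centroid matching between detected spots of a class and
#' planted spots of the same class: pairs are accepted in order of
#' increasing 3-D distance while both members are unused and the distance
#' stays below `max_dist`. Reports recall (matched truth / all truth) and
#' precision (matched detections / all detections).
#'
#' @param spots Classified spot tibble from [classify_spots()].
#' @param truth Truth tibble from [simulate_field()].
#' @param class Spot class to score (default `"internalized"`).
#' @param max_dist Maximum centroid distance (um) for a match. Default 0.7.
#' @return One-row tibble: `class`, `n_truth`, `n_detected`, `n_matched`,
#'   `recall`, `precision`.
#' @export
match_truth <- function(spots, truth, class = "internalized", max_dist = 0.7) {
  det <- dplyr::filter(spots, .data$class == !!class)
  tru <- dplyr::filter(truth, .data$class == !!class)
  n_d <- nrow(det); n_t <- nrow(tru)
  if (n_d == 0L || n_t == 0L) {
    return(tibble::tibble(class = class, n_truth = n_t, n_detected = n_d,
                          n_matched = 0L,
                          recall = ifelse(n_t == 0L, NA_real_, 0),
                          precision = ifelse(n_d == 0L, NA_real_, 0)))
  }
  dz <- outer(det$z_um, tru$z_um, "-")
  dy <- outer(det$y_um, tru$y_um, "-")
  dx <- outer(det$x_um, tru$x_um, "-")
  dist <- sqrt(dz^2 + dy^2 + dx^2)
  ord <- order(dist)
  used_d <- logical(n_d); used_t <- logical(n_t)
  matched <- 0L
  for (k in ord) {
    if (dist[k] > max_dist) break
    i <- (k - 1L) %% n_d + 1L
    j <- (k - 1L) %/% n_d + 1L
    if (used_d[i] || used_t[j]) next
    used_d[i] <- TRUE; used_t[j] <- TRUE
    matched <- matched + 1L
  }
  tibble::tibble(class = class, n_truth = n_t, n_detected = n_d,
                 n_matched = matched,
                 recall = matched / n_t, precision = matched / n_d)
}
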