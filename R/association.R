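# Cost construction, gating, fusion and optimal assignment for one
# matching round. Motion costs come from pairwise_cost(); appearance costs
# are cosine distances between L2-normalised re-identification embeddings.

#' Cosine distance between appearance embeddings
#'
#' @param a,b Unit-norm feature vectors of equal dimension.
#' @return `1 - <a, b>`, a distance in \[0, 2\].
#' @export
appearance_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("embedding dimensions differ", call. = FALSE)
  }
  1 - sum(a * b)
}

# Pairwise cosine-distance matrix between track features (n x d) and
# detection features (m x d). Rows with any NA give distance 2 (no
# information: worst case, gated out by the appearance gate).
appearance_cost_matrix <- function(track_feats, det_feats) {
  if (ncol(track_feats) != ncol(det_feats)) {
    stop("embedding dimensions differ", call. = FALSE)
  }
  d <- 1 - track_feats %*% t(det_feats)
  d[!is.finite(d)] <- 2
  d
}

#' Fuse motion and appearance costs for one matching round
#'
#' BoT-SORT style minimum fusion: the appearance cost is halved and kept
#' only where it is confident (`< appearance_gate`) and the candidate is
#' spatially plausible (motion cost `< proximity_gate`); elsewhere it is
#' neutralised to 1. The fused cost is the elementwise minimum of the motion
#' cost and the gated appearance cost. Entries whose motion cost exceeds the
#' hard `motion_gate` are forbidden (`+Inf`). A weighted-sum alternative
#' `lambda * motion + (1 - lambda) * appearance` is available via `method`.
#'
#' @param motion_cost Matrix of motion costs (1 - similarity).
#' @param appearance_cost Matrix of cosine distances, same shape, or `NULL`
#'   when no embeddings are available (motion cost passes through, gated).
#' @param appearance_gate Appearance distances at or above this are ignored.
#' @param proximity_gate Motion costs at or above this disable appearance.
#' @param motion_gate Hard gate: larger motion costs are forbidden.
#' @param method `"min"` (default) or `"weighted"`.
#' @param lambda Motion weight for `method = "weighted"`.
#' @return Fused cost matrix, same shape as `motion_cost`.
#' @export
fuse_costs <- function(motion_cost, appearance_cost = NULL,
                       appearance_gate = 0.25, proximity_gate = 0.5,
                       motion_gate = 1.0, method = c("min", "weighted"),
                       lambda = 0.98) {
  method <- match.arg(method)
  cm <- as.matrix(motion_cost)
  if (is.null(appearance_cost)) {
    fused <- cm
  } else {
    ca <- as.matrix(appearance_cost)
    if (!identical(dim(ca), dim(cm))) {
      stop("motion and appearance cost shapes differ", call. = FALSE)
    }
    if (method == "min") {
      ca_gated <- ifelse(ca < appearance_gate & cm < proximity_gate,
                         ca / 2, 1)
      fused <- pmin(cm, ca_gated)
    } else {
      fused <- lambda * cm + (1 - lambda) * ca
    }
  }
  fused[cm > motion_gate] <- Inf
  fused
}

#' Solve one matching round as a minimum-cost assignment
#'
#' Finds the one-to-one assignment of minimum total cost (Jonker-Volgenant
#' shortest augmenting path), then demotes pairs whose cost exceeds
#' `accept_threshold` (or is `+Inf`) to unmatched. Deterministic for
#' identical inputs.
#'
#' @param cost Numeric matrix (rows = tracks, columns = detections);
#'   `+Inf` marks forbidden pairs. May have zero rows or columns.
#' @param accept_threshold Pairs with cost above this are rejected.
#' @return An `assignment_result`: list with `matches` (tibble of `track`,
#'   `det`, `cost`), `unmatched_tracks`, `unmatched_dets` (integer indices).
#' @export
solve_assignment <- function(cost, accept_threshold = Inf) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  empty <- tibble::tibble(track = integer(0), det = integer(0),
                          cost = numeric(0))
  if (n == 0L || m == 0L) {
    return(structure(list(matches = empty,
                          unmatched_tracks = seq_len(n),
                          unmatched_dets = seq_len(m)),
                     class = "assignment_result"))
  }
  finite <- cost[is.finite(cost)]
  big <- if (length(finite)) max(abs(finite)) * (max(n, m) + 1) + 1 else 1
  sq <- matrix(big, max(n, m), max(n, m))
  sq[seq_len(n), seq_len(m)] <- ifelse(is.finite(cost), cost, big)
  sq <- sq - min(sq)  # shift so reduced costs stay non-negative
  col_of_row <- lap_jv_cpp(sq)
  track <- integer(0); det <- integer(0)
  for (i in seq_len(n)) {
    j <- col_of_row[i]
    if (j <= m && is.finite(cost[i, j]) && cost[i, j] <= accept_threshold) {
      track <- c(track, i); det <- c(det, j)
    }
  }
  structure(
    list(matches = tibble::tibble(track = track, det = det,
                                  cost = cost[cbind(track, det)]),
         unmatched_tracks = setdiff(seq_len(n), track),
         unmatched_dets = setdiff(seq_len(m), det)),
    class = "assignment_result"
  )
}
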