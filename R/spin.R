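# Spherical spin-test nulls: random rotations of parcel centroids on the
# spherical surface projection, mapped back to parcels by one-to-one nearest
# neighbour assignment, preserving spatial contiguity and hemispheric
# symmetry.

# Haar-uniform rotation in SO(3): QR of a Gaussian matrix with the R-diagonal
# sign fix, then a determinant fix.
random_rotation_matrix <- function() {
  qd <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  Q <- qr.Q(qd) %*% diag(sign(diag(qr.R(qd))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# Greedy one-to-one assignment of original parcels to rotated parcels,
# sorted by ascending distance.  Unlike independent nearest-neighbour
# matching this cannot duplicate parcels, so null maps are value-preserving.
greedy_assignment <- function(orig, rotated) {
  n <- nrow(orig)
  # squared distances; clamped at 0 against rounding, ordering is the same
  D <- pmax(outer(rowSums(orig^2), rep(1, n)) +
            outer(rep(1, n), rowSums(rotated^2)) -
            2 * orig %*% t(rotated), 0)
  ord <- order(D)
  perm <- integer(n)
  used_j <- logical(n); used_k <- logical(n)
  left <- n
  for (idx in ord) {
    j <- (idx - 1L) %% n + 1L
    k <- (idx - 1L) %/% n + 1L
    if (used_j[j] || used_k[k]) next
    perm[j] <- k
    used_j[j] <- TRUE; used_k[k] <- TRUE
    left <- left - 1L
    if (left == 0L) break
  }
  perm
}

#' Spin permutation for a single rotation
#'
#' Applies `rotation` to the left-hemisphere centroids and its x-mirrored
#' counterpart to the right hemisphere, then maps each original parcel to a
#' distinct rotated parcel within its hemisphere by greedy one-to-one
#' nearest-neighbour assignment.
#'
#' @param geometry A [parcel_geometry()].
#' @param rotation A 3x3 rotation matrix (determinant +1).
#' @return Integer permutation `perm` such that a spun map is
#'   `map[perm]`.
#' @export
spin_permutation <- function(geometry, rotation) {
  xyz <- as.matrix(geometry[, c("x", "y", "z")])
  perm <- integer(nrow(geometry))
  mirror <- diag(c(-1, 1, 1))
  for (h in unique(geometry$hemisphere)) {
    idx <- which(geometry$hemisphere == h)
    if (length(idx) < 2L) stop("hemisphere '", h, "' has < 2 parcels", call. = FALSE)
    R <- if (h == "L") rotation else mirror %*% rotation %*% mirror
    rotated <- xyz[idx, , drop = FALSE] %*% t(R)
    perm[idx] <- idx[greedy_assignment(xyz[idx, , drop = FALSE], rotated)]
  }
  perm
}

#' Generate a table of spin permutations
#'
#' Draws `n_rotations` Haar-uniform rotations and converts each to a
#' within-hemisphere parcel permutation via [spin_permutation()].  For
#' left-hemisphere-only geometries only the left rotation is used.
#'
#' @inheritParams spin_permutation
#' @param n_rotations Number of rotations (default 10000).
#' @param seed Integer seed for the rotation stream.
#' @return A `spin_null` object: list with `permutations` (n_rotations x
#'   n_parcels integer matrix), `region`, `n_rotations`, `seed`.
#' @export
generate_spins <- function(geometry, n_rotations = 10000L, seed = 1L) {
  stop_if_not_count(n_rotations, "n_rotations", min = 1L)
  geometry <- parcel_geometry(as.data.frame(geometry))
  perms <- matrix(0L, n_rotations, nrow(geometry))
  with_seed(seed, {
    for (b in seq_len(n_rotations)) {
      perms[b, ] <- spin_permutation(geometry, random_rotation_matrix())
    }
  })
  structure(list(permutations = perms, region = geometry$region,
                 n_rotations = n_rotations, seed = seed),
            class = "spin_null")
}

#' Spin-test p-value for the correlation of two cortical maps
#'
#' Compares the empirical correlation of two maps to the null distribution
#' obtained by spinning `map_a` only.  Default is the two-tailed add-one
#' estimator `(1 + #{|null| >= |rho_emp|}) / (n_rotations + 1)`; the
#' one-tailed variant counts `null >= rho_emp`.
#'
#' @param map_a,map_b Numeric maps aligned to the spin geometry's region
#'   order (`map_a` is the one spun).
#' @param spins A `spin_null` from [generate_spins()].
#' @param statistic `"spearman"` (default) or `"pearson"`.
#' @param alternative `"two_sided"` (default) or `"greater"`.
#' @return List with `rho` (empirical), `p_spin` and `null` (the null
#'   statistics).
#' @export
spin_p <- function(map_a, map_b, spins,
                   statistic = c("spearman", "pearson"),
                   alternative = c("two_sided", "greater")) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  n <- ncol(spins$permutations)
  if (length(map_a) != n || length(map_b) != n) {
    stop("maps must match the spin geometry's parcel count", call. = FALSE)
  }
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0) {
    stop("correlation undefined for constant map", call. = FALSE)
  }
  rho <- stats::cor(map_a, map_b, method = statistic)
  nulls <- apply(spins$permutations, 1L, function(perm) {
    stats::cor(map_a[perm], map_b, method = statistic)
  })
  k <- if (alternative == "two_sided") sum(abs(nulls) >= abs(rho))
       else sum(nulls >= rho)
  list(rho = rho, p_spin = (1 + k) / (spins$n_rotations + 1), null = nulls)
}
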