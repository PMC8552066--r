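# Forward problem: transmembrane potentials -> body-surface potentials in a
# homogeneous, unbounded, quasi-static medium.  Per-node gradients come from
# a quadratic least-squares fit on the local stencil; each node contributes
# an area-weighted current dipole; the resulting linear map is assembled
# once as an M x N transfer matrix and corrected to the Wilson Central
# Terminal reference.

# Quadratic design matrix for displacements dx (m x 3): columns
# x, y, z, x^2, y^2, z^2, xy, yz, xz.
.quad_design <- function(dx) {
  cbind(dx, dx^2, dx[, 1] * dx[, 2], dx[, 2] * dx[, 3], dx[, 1] * dx[, 3])
}

# Stencil around a node: 1-ring, expanded ring by ring until >= 9 points.
.gradient_stencil <- function(mesh, node) {
  ring <- mesh$neighbors[[node]]
  seen <- c(node, ring)
  while (length(ring) < 9L) {
    nxt <- setdiff(unique(unlist(mesh$neighbors[ring])), seen)
    if (!length(nxt)) break
    ring <- c(ring, nxt)
    seen <- c(seen, nxt)
  }
  ring
}

#' Least-squares quadratic gradient of a nodal field
#'
#' Fits `V_i - V_node = c1 x + c2 y + c3 z + c4 x^2 + ... + c9 xz` over at
#' least nine stencil points (1-ring expanded as needed) and returns the
#' gradient `(c1, c2, c3)`.  Rank-deficient stencils fall back to a linear
#' fit and are flagged.
#'
#' @param mesh atrial_mesh
#' @param vm_frame numeric vector of nodal values (length N)
#' @param node node index
#' @return list with `gradient` (length 3), `n_stencil`, `residual_norm`,
#'   `fallback_linear`
#' @export
fit_quadratic_gradient <- function(mesh, vm_frame, node) {
  op <- .gradient_fit_operator(mesh, node)
  b <- vm_frame[op$stencil] - vm_frame[node]
  g <- drop(op$E %*% b)
  fitted <- drop(op$X %*% op$coef_op %*% b)
  list(gradient = g, n_stencil = length(op$stencil),
       residual_norm = sqrt(sum((b - fitted)^2)),
       fallback_linear = op$fallback)
}

# Linear operator extracting the gradient at `node` from stencil value
# differences; shared by fit_quadratic_gradient and the transfer matrix
# assembly so both paths are literally the same math.
.gradient_fit_operator <- function(mesh, node) {
  stencil <- .gradient_stencil(mesh, node)
  dx <- mesh$node_coords[stencil, , drop = FALSE] -
    matrix(mesh$node_coords[node, ], length(stencil), 3, byrow = TRUE)
  X <- .quad_design(dx)
  qrX <- qr(X)
  fallback <- FALSE
  if (qrX$rank < 9L) {
    X <- dx                       # linear fall-back
    qrX <- qr(X)
    fallback <- TRUE
    if (qrX$rank < 3L)
      stop_af("degenerate stencil at node %d (rank %d)", node, qrX$rank)
  }
  # minimum-norm least squares via the pseudoinverse
  sv <- svd(X)
  pos <- sv$d > max(sv$d) * 1e-10
  pinv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  list(stencil = stencil, X = X, coef_op = pinv,
       E = pinv[1:3, , drop = FALSE], fallback = fallback)
}

# Sparse 3N x N operator mapping nodal values to stacked per-node gradients.
gradient_operator <- function(mesh) {
  n <- nrow(mesh$node_coords)
  ii <- list(); jj <- list(); xx <- list()
  flags <- logical(n)
  for (k in seq_len(n)) {
    op <- .gradient_fit_operator(mesh, k)
    E <- op$E
    m <- length(op$stencil)
    rows <- 3L * (k - 1L) + 1:3
    ii[[k]] <- c(rep(rows, m), rows)
    jj[[k]] <- c(rep(op$stencil, each = 3L), rep(k, 3L))
    xx[[k]] <- c(as.numeric(E), -rowSums(E))
    flags[k] <- op$fallback
  }
  list(G = Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                x = unlist(xx), dims = c(3L * n, n)),
       fallback_linear = flags)
}

#' Extracellular potential of the dipole field at one observation point
#'
#' `V(r_obs) = sum_k w_k (r_vec_k / r_k^3) . grad_k` with `r_vec_k` the
#' vector from node k to the observation point and `w_k` the node's surface
#' area weight (amplitudes in arbitrary consistent units).
#'
#' @param mesh atrial_mesh
#' @param gradient_field N x 3 matrix of nodal gradients
#' @param obs_point length-3 observation point (mm)
#' @param weights optional node weights; defaults to barycentric area
#'   thirds, `"none"` for an unweighted sum
#' @param guard_radius minimum allowed distance to any source node (mm)
#' @return scalar potential
#' @export
dipole_potential <- function(mesh, gradient_field, obs_point,
                             weights = NULL, guard_radius = 1) {
  rvec <- matrix(obs_point, nrow(mesh$node_coords), 3, byrow = TRUE) -
    mesh$node_coords
  r <- sqrt(rowSums(rvec^2))
  if (min(r) <= guard_radius)
    stop_af("observation point within guard radius of node %d (r = %.3g mm)",
            which.min(r), min(r))
  w <- if (is.null(weights)) node_area_weights(mesh)
       else if (identical(weights, "none")) rep(1, length(r)) else weights
  sum(w * rowSums(rvec * gradient_field) / r^3)
}

#' Assemble the transfer matrix from atria to torso electrodes
#'
#' Composes the quadratic-LS gradient operator with the dipole kernel at
#' every electrode, yielding `a` with `a %*% vm_frame` equal to the direct
#' per-frame forward evaluation, plus the WCT-corrected `a_wct` whose
#' output averages to zero over the WCT leads for any input.
#'
#' @param mesh atrial_mesh
#' @param torso torso_geometry
#' @param weights as in [dipole_potential()]
#' @return `transfer_matrix` object: `a`, `a_wct` (M x N), `wct_indices`,
#'   provenance fingerprints
#' @export
build_transfer_matrix <- function(mesh, torso, weights = NULL) {
  stopifnot(inherits(mesh, "atrial_mesh"), inherits(torso, "torso_geometry"))
  guard <- 0.01 * torso$radius
  n <- nrow(mesh$node_coords)
  M <- nrow(torso$electrode_coords)
  w <- if (is.null(weights)) node_area_weights(mesh)
       else if (identical(weights, "none")) rep(1, n) else weights
  D <- matrix(0, M, 3L * n)
  for (m in seq_len(M)) {
    rvec <- matrix(torso$electrode_coords[m, ], n, 3, byrow = TRUE) -
      mesh$node_coords
    r <- sqrt(rowSums(rvec^2))
    if (min(r) <= guard)
      stop_af("electrode '%s' lies within the guard radius (%.3g mm)",
              torso$electrode_names[m], guard)
    K <- (w / r^3) * rvec          # N x 3
    D[m, ] <- as.numeric(t(K))     # interleave per node (x,y,z)
  }
  gop <- gradient_operator(mesh)
  a <- as.matrix(D %*% gop$G)
  a_wct <- wct_correct_matrix(a, torso$wct_indices)
  structure(list(a = a, a_wct = a_wct,
                 wct_indices = torso$wct_indices,
                 gradient_fallback = gop$fallback_linear,
                 provenance = list(mesh = fingerprint(mesh$node_coords),
                                   torso = fingerprint(torso$electrode_coords))),
            class = "transfer_matrix")
}

#' WCT correction of a transfer matrix
#'
#' Subtracts from every row the average of the WCT rows, so that the
#' referenced potentials `a_wct %*% x` always average to zero over the WCT
#' leads.
#' @param a M x N transfer matrix
#' @param wct_indices WCT row indices
#' @return corrected matrix
#' @export
wct_correct_matrix <- function(a, wct_indices) {
  if (!length(wct_indices)) stop_af("empty WCT lead set")
  if (any(wct_indices < 1 | wct_indices > nrow(a)))
    stop_af("wct_indices outside the rows of the transfer matrix")
  wct_mean <- colMeans(a[wct_indices, , drop = FALSE])
  sweep(a, 2, wct_mean, "-")
}

#' Apply the WCT-referenced forward map to a potential series
#'
#' @param tm transfer_matrix
#' @param x_series N x S matrix of transmembrane potentials
#' @return M x S matrix of referenced body-surface potentials
#' @export
wct_reference <- function(tm, x_series) {
  if (!length(tm$wct_indices)) stop_af("empty WCT lead set")
  tm$a_wct %*% x_series
}

#' Forward-project a simulated episode to body-surface potentials
#'
#' @param tm transfer_matrix
#' @param vm vm_series (or N x S matrix)
#' @return `bsp_recording` with all torso electrodes
#' @export
forward_bsp <- function(tm, vm) {
  x <- if (inherits(vm, "vm_series")) vm$vm else vm
  pot <- wct_reference(tm, x)
  new_bsp_recording(pot,
                    fs = if (inherits(vm, "vm_series")) vm$fs else NA_real_,
                    snr_db = NULL, filter = NULL,
                    labels = if (inherits(vm, "vm_series")) vm$labels else NULL,
                    provenance = list(tm = tm$provenance))
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("transfer_matrix: %d electrodes x %d nodes (WCT leads: %s)\n",
              nrow(x$a), ncol(x$a),
              paste(x$wct_indices, collapse = ",")))
  invisible(x)
}
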