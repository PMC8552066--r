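# Synthetic atrial surface geometry: two fused ellipsoidal chambers with
# pulmonary-vein stubs, labeled into the seven clinically used driver
# regions, plus fiber directions and anisotropic diffusion metadata.

#' Atrial region names
#'
#' Region ids 1..7 in the order used throughout the package: posterior left
#' atrial wall, the four pulmonary veins, right atrial appendage, right
#' atrial free wall.  Label 0 means "no driver".
#' @export
ATRIAL_REGIONS <- c("PLAW", "LIPV", "LSPV", "RIPV", "RSPV", "RAA", "RAFW")

# Unit seed directions defining the seven regions as a spherical Voronoi
# partition.  Frame: +x toward the right atrium, -y posterior, +z superior.
.region_seeds <- function() {
  s <- rbind(
    PLAW = c(-0.25, -1.00,  0.00),
    LIPV = c(-0.90, -0.45, -0.55),
    LSPV = c(-0.90, -0.45,  0.55),
    RIPV = c(-0.10, -0.75, -0.75),
    RSPV = c(-0.10, -0.75,  0.75),
    RAA  = c( 0.60,  0.90,  0.35),
    RAFW = c( 1.00,  0.10, -0.25))
  s / sqrt(rowSums(s^2))
}

# Radius of the synthetic atrial surface along unit direction u (rows).
# Ellipsoid base, a waist between the chambers, and Gaussian bumps for the
# four vein stubs.
.atrial_radius <- function(u, gp) {
  ax <- gp$semi_axes
  r0 <- 1 / sqrt((u[, 1] / ax[1])^2 + (u[, 2] / ax[2])^2 + (u[, 3] / ax[3])^2)
  waist <- 1 - gp$waist_depth * exp(-(u[, 1] / gp$waist_width)^2)
  bump <- rep(0, nrow(u))
  seeds <- .region_seeds()
  for (v in gp$stub_regions) {
    ca <- pmin(1, pmax(-1, u %*% seeds[v, ]))
    ang <- acos(drop(ca))
    bump <- bump + gp$stub_height * exp(-(ang / gp$stub_width)^2)
  }
  r0 * waist * (1 + bump)
}

default_geometry_params <- function() {
  list(semi_axes = c(50, 40, 45),     # mm, left-right / ant-post / sup-inf
       waist_depth = 0.12, waist_width = 0.35,
       stub_height = 0.18, stub_width = 0.30,
       stub_regions = c("LIPV", "LSPV", "RIPV", "RSPV"))
}

# Triangulated UV sphere with poles on the +/- x axis; exactly
# rows*cols + 2 nodes.  Returns unit directions and triangle index matrix.
.uv_sphere <- function(rows, cols) {
  theta <- pi * seq_len(rows) / (rows + 1)
  phi <- 2 * pi * (seq_len(cols) - 1) / cols
  n <- rows * cols + 2L
  dirs <- matrix(0, n, 3)
  dirs[1, ] <- c(1, 0, 0)
  dirs[n, ] <- c(-1, 0, 0)
  idx <- function(i, j) 1L + (i - 1L) * cols + ((j - 1L) %% cols) + 1L
  for (i in seq_len(rows)) for (j in seq_len(cols))
    dirs[idx(i, j), ] <- c(cos(theta[i]),
                           sin(theta[i]) * cos(phi[j]),
                           sin(theta[i]) * sin(phi[j]))
  tri <- vector("list", 2L * cols * rows)
  t_i <- 0L
  add <- function(a, b, c) { t_i <<- t_i + 1L; tri[[t_i]] <<- c(a, b, c) }
  for (j in seq_len(cols)) add(1L, idx(1L, j), idx(1L, j + 1L))
  for (i in seq_len(rows - 1L)) for (j in seq_len(cols)) {
    a <- idx(i, j); b <- idx(i, j + 1L)
    c <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
    add(a, c, d); add(a, d, b)
  }
  for (j in seq_len(cols)) add(n, idx(rows, j + 1L), idx(rows, j))
  list(dirs = dirs, triangles = do.call(rbind, tri[seq_len(t_i)]))
}

.edges_from_triangles <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

.adjacency_list <- function(tri, n) {
  e <- .edges_from_triangles(tri)
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1]]] <- c(adj[[e[k, 1]]], e[k, 2])
    adj[[e[k, 2]]] <- c(adj[[e[k, 2]]], e[k, 1])
  }
  lapply(adj, function(v) sort(unique(v)))
}

# Split edge (a,b): insert the midpoint (re-projected onto the surface) and
# replace the two incident triangles by four.  Keeps the surface closed.
.split_edge <- function(tri, dirs, a, b, gp) {
  hit <- which(apply(tri, 1, function(t) a %in% t && b %in% t))
  if (length(hit) != 2L) stop_af("edge (%d,%d) is not interior-manifold", a, b)
  m_dir <- dirs[a, ] + dirs[b, ]
  m_dir <- m_dir / sqrt(sum(m_dir^2))
  dirs <- rbind(dirs, m_dir)
  m <- nrow(dirs)
  new_tris <- list()
  for (h in hit) {
    t <- tri[h, ]
    ta <- t; ta[ta == b] <- m
    tb <- t; tb[tb == a] <- m
    new_tris <- c(new_tris, list(ta, tb))
  }
  tri <- rbind(tri[-hit, , drop = FALSE], do.call(rbind, new_tris))
  list(tri = tri, dirs = dirs)
}

#' Build a synthetic atrial surface mesh
#'
#' Constructs a closed triangulated surface shaped as two fused ellipsoidal
#' chambers with four pulmonary-vein stubs, partitions it into the seven
#' driver regions (spherical Voronoi sectors around anatomical seed
#' directions), and attaches circumferential fiber directions and global
#' longitudinal/transverse diffusion coefficients.
#'
#' @param n_nodes number of mesh nodes (exact); must be at least 128
#' @param geometry_params optional list overriding the default shape
#'   (semi-axes in mm, waist and vein-stub parameters)
#' @param rng_seed integer seed (geometry is deterministic; the seed is kept
#'   in the provenance record and consumed by downstream stochastic stages)
#' @param d_long,d_trans longitudinal / transverse diffusion coefficients
#'   (mm^2/ms); `NULL` (default) scales them with the squared mean edge
#'   length (`0.042 h^2` and half of that) so that planar conduction
#'   velocity stays near 0.6 mm/ms longitudinally and roughly half that
#'   transversally across mesh resolutions, while staying above the
#'   discrete propagation-block threshold
#' @return an `atrial_mesh` object
#' @export
build_synthetic_atria <- function(n_nodes = 2048, geometry_params = NULL,
                                  rng_seed = 1L,
                                  d_long = NULL, d_trans = NULL) {
  check_scalar(n_nodes, "n_nodes")
  if (n_nodes < 128)
    stop_af(paste("n_nodes = %d is too small to host 7 regions with a",
                  "well-formed closed surface; need at least 128"), n_nodes)
  gp <- utils::modifyList(default_geometry_params(), geometry_params %||% list())
  base <- n_nodes - 2L
  cols <- max(8L, round(sqrt(base / 1.9)))
  rows <- base %/% cols
  k_extra <- base - rows * cols            # nodes still missing (< cols)
  sph <- .uv_sphere(rows, cols)
  dirs <- sph$dirs; tri <- sph$triangles
  if (k_extra > 0L) {
    for (s in seq_len(k_extra)) {
      # split the currently longest edge (in final coordinates)
      coords <- dirs * .atrial_radius(dirs, gp)
      e <- .edges_from_triangles(tri)
      len <- rowSums((coords[e[, 1], , drop = FALSE] -
                      coords[e[, 2], , drop = FALSE])^2)
      top <- e[which.max(len), ]
      sp <- .split_edge(tri, dirs, top[1], top[2], gp)
      tri <- sp$tri; dirs <- sp$dirs
    }
  }
  n <- nrow(dirs)
  stopifnot(n == n_nodes)
  coords <- unname(dirs * .atrial_radius(dirs, gp))
  storage.mode(tri) <- "integer"

  # region labels: nearest seed direction (spherical Voronoi)
  seeds <- .region_seeds()
  region_id <- max.col(dirs %*% t(seeds))
  if (length(unique(region_id)) < 7L)
    stop_af("n_nodes = %d cannot be partitioned into 7 non-empty regions",
            n_nodes)

  # circumferential fibers: tangent to latitude circles around the x axis
  fiber <- cbind(0, -dirs[, 3], dirs[, 2])
  nrm <- sqrt(rowSums(fiber^2))
  deg <- nrm < 1e-8
  fiber[deg, ] <- matrix(c(0, 1, 0), sum(deg), 3, byrow = TRUE)
  nrm[deg] <- 1
  fiber <- fiber / nrm
  # project onto the tangent plane of the surface normal (approximate by
  # radial direction) and renormalize
  rad <- dirs
  fiber <- fiber - rad * rowSums(fiber * rad)
  fiber <- unname(fiber / sqrt(rowSums(fiber^2)))

  if (is.null(d_long)) {
    e <- .edges_from_triangles(tri)
    h <- mean(sqrt(rowSums((coords[e[, 1], , drop = FALSE] -
                            coords[e[, 2], , drop = FALSE])^2)))
    d_long <- 0.042 * h^2
  }
  if (is.null(d_trans)) d_trans <- d_long / 2

  mesh <- structure(list(
    node_coords = coords,
    triangles = tri,
    neighbors = .adjacency_list(tri, n),
    fiber_dir = fiber,
    region_id = as.integer(region_id),
    region_names = ATRIAL_REGIONS,
    d_long = d_long, d_trans = d_trans,
    fibrotic = rep(FALSE, n),
    geometry_params = gp,
    rng_seed = as.integer(rng_seed)), class = "atrial_mesh")
  validate_atrial_mesh(mesh)
  mesh
}

#' Validate the structural invariants of an atrial mesh
#'
#' Checks closed-manifold edges, minimum neighbor counts, unit fiber norms
#' and complete region coverage.  Called by the constructor; exported for
#' meshes read from disk.
#' @param mesh atrial_mesh
#' @return the mesh, invisibly; errors on violation
#' @export
validate_atrial_mesh <- function(mesh) {
  n <- nrow(mesh$node_coords)
  tri <- mesh$triangles
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt != 2L))
    stop_af("mesh is not a closed manifold (%d boundary/odd edges)",
            sum(cnt != 2L))
  if (any(lengths(mesh$neighbors) < 3L))
    stop_af("some nodes have fewer than 3 neighbors")
  if (!all(seq_len(7L) %in% mesh$region_id))
    stop_af("region labels do not cover all 7 regions")
  if (any(abs(rowSums(mesh$fiber_dir^2) - 1) > 1e-9))
    stop_af("fiber directions are not unit-norm")
  invisible(mesh)
}

#' @export
print.atrial_mesh <- function(x, ...) {
  cat(sprintf("atrial_mesh: %d nodes, %d triangles, %d fibrotic\n",
              nrow(x$node_coords), nrow(x$triangles), sum(x$fibrotic)))
  cat(sprintf("  d_long=%.3g d_trans=%.3g mm^2/ms; regions: %s\n",
              x$d_long, x$d_trans,
              paste(sprintf("%s=%d", x$region_names,
                            tabulate(x$region_id, 7)), collapse = " ")))
  invisible(x)
}

#' Angle-dependent diffusion coefficient
#'
#' Anisotropic diffusion between two coupled nodes as a function of the
#' angle between the local fiber direction and the internode vector:
#' `d_long * cos(alpha)^2 + d_trans * sin(alpha)^2`.
#'
#' @param d_long longitudinal coefficient (>= d_trans >= 0)
#' @param d_trans transverse coefficient
#' @param alpha angle(s) in radians
#' @return diffusion coefficient(s), same length as `alpha`
#' @export
diffusion_coefficient <- function(d_long, d_trans, alpha) {
  if (any(d_long < 0) || any(d_trans < 0))
    stop_af("diffusion coefficients must be non-negative")
  if (any(d_trans > d_long))
    stop_af("d_long must be >= d_trans")
  d_long * cos(alpha)^2 + d_trans * sin(alpha)^2
}

#' Disconnect a random fraction of nodes (fibrosis / scar)
#'
#' Marks `round(fraction * N)` nodes as fibrotic; all diffusion terms
#' incident to a fibrotic node are set to zero when the coupling
#' coefficients are assembled, so the node is electrically isolated.
#'
#' @param mesh atrial_mesh
#' @param fraction fraction of nodes in `[0, 1)`
#' @param rng_seed integer seed for the node selection
#' @return modified mesh
#' @export
apply_fibrosis <- function(mesh, fraction, rng_seed = 1L) {
  check_scalar(fraction, "fraction")
  if (fraction < 0 || fraction >= 1)
    stop_af("fibrosis fraction must be in [0, 1), got %g", fraction)
  n <- nrow(mesh$node_coords)
  k <- round(fraction * n)
  if (k == 0L) return(mesh)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(rng_seed)
  sel <- sample.int(n, k)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  mesh$fibrotic[sel] <- TRUE
  mesh
}

# Directed coupling coefficients D_{k,i} / d_{k,i}^2 in CSR form for the
# monodomain integrator; fibrotic nodes are fully decoupled.
mesh_coupling <- function(mesh) {
  n <- nrow(mesh$node_coords)
  nb <- mesh$neighbors
  row_ptr <- integer(n + 1L)
  col_idx <- integer(0)
  coef <- numeric(0)
  cols <- unlist(nb, use.names = FALSE)
  reps <- lengths(nb)
  rows <- rep.int(seq_len(n), reps)
  dvec <- mesh$node_coords[cols, , drop = FALSE] -
          mesh$node_coords[rows, , drop = FALSE]
  dist <- sqrt(rowSums(dvec^2))
  ca <- rowSums((dvec / dist) * mesh$fiber_dir[rows, , drop = FALSE])
  alpha <- acos(pmin(1, pmax(-1, abs(ca))))
  dcoef <- diffusion_coefficient(mesh$d_long, mesh$d_trans, alpha)
  dcoef[mesh$fibrotic[rows] | mesh$fibrotic[cols]] <- 0
  coef <- dcoef / dist^2
  row_ptr <- c(0L, cumsum(reps))
  list(row_ptr = as.integer(row_ptr), col_idx = as.integer(cols - 1L),
       coef = as.numeric(coef), dist = dist)
}

#' Per-node surface area weights
#'
#' One third of the area of each incident triangle (barycentric lumping),
#' used to weight the dipole contribution of each node in the forward model.
#' @param mesh atrial_mesh
#' @return numeric vector of areas (mm^2)
#' @export
node_area_weights <- function(mesh) {
  tri <- mesh$triangles
  p1 <- mesh$node_coords[tri[, 1], , drop = FALSE]
  p2 <- mesh$node_coords[tri[, 2], , drop = FALSE]
  p3 <- mesh$node_coords[tri[, 3], , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))
  w <- numeric(nrow(mesh$node_coords))
  for (c in 1:3) {
    t <- tapply(area, tri[, c], sum)
    w[as.integer(names(t))] <- w[as.integer(names(t))] + t / 3
  }
  w
}

# Regular open strip mesh (nx x ny grid, spacing mm) used for conduction
# velocity calibration and tests; shares the atrial_mesh field layout but is
# not a closed surface (skips validation).
build_strip_mesh <- function(nx, ny, spacing = 1, d_long = 1.8,
                             d_trans = 0.45, fiber = c(1, 0, 0)) {
  coords <- as.matrix(expand.grid(x = seq_len(nx), y = seq_len(ny)))
  coords <- cbind((coords[, 1] - 1) * spacing, (coords[, 2] - 1) * spacing, 0)
  idx <- function(i, j) (j - 1L) * nx + i
  tri <- list()
  for (j in seq_len(ny - 1L)) for (i in seq_len(nx - 1L)) {
    a <- idx(i, j); b <- idx(i + 1L, j); c <- idx(i, j + 1L); d <- idx(i + 1L, j + 1L)
    tri <- c(tri, list(c(a, b, d), c(a, d, c)))
  }
  tri <- do.call(rbind, tri)
  n <- nx * ny
  structure(list(
    node_coords = coords, triangles = tri,
    neighbors = .adjacency_list(tri, n),
    fiber_dir = matrix(fiber / sqrt(sum(fiber^2)), n, 3, byrow = TRUE),
    region_id = rep(1L, n), region_names = ATRIAL_REGIONS,
    d_long = d_long, d_trans = d_trans,
    fibrotic = rep(FALSE, n),
    geometry_params = list(kind = "strip", nx = nx, ny = ny, spacing = spacing),
    rng_seed = 0L), class = "atrial_mesh")
}

#' Nodes belonging to an atrial region
#' @param mesh atrial_mesh
#' @param region region id 1..7 or region name
#' @return integer node indices
#' @export
region_nodes <- function(mesh, region) {
  if (is.character(region)) region <- match(region, mesh$region_names)
  which(mesh$region_id == region)
}

# Node whose direction is closest to the centroid direction of a region.
region_center_node <- function(mesh, region) {
  nodes <- region_nodes(mesh, region)
  dirs <- mesh$node_coords[nodes, , drop = FALSE]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  ctr <- colMeans(dirs)
  ctr <- ctr / sqrt(sum(ctr^2))
  nodes[which.max(dirs %*% ctr)]
}
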