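# Tissue-level AF simulation: stimulus protocols, rotor induction, and the
# VmSeries container produced by the monodomain integrator.

#' Construct a stimulus protocol
#'
#' @param kind one of `"planar_wave"` (single wavefront sweeping the
#'   surface, no driver), `"cross_field_rotor"` (re-entrant rotor anchored
#'   at a target region), `"focal"` (periodic point pacing; labeled as no
#'   driver, consistent with the region-label scheme that tracks re-entrant
#'   drivers), `"none"` (quiescent tissue)
#' @param target_region region id 1..7 (rotor core / focal site); ignored
#'   for planar and none
#' @param fibrosis_fraction fraction of randomly disconnected nodes, `[0,1)`
#' @param rng_seed integer seed for fibrosis placement and any protocol
#'   randomness
#' @param stim_times,stim_amp,stim_dur stimulus train (ms, 1/ms, ms); for
#'   focal pacing the default is a 140 ms cycle
#' @param rotor_method `"phase_seed"` (default; spiral phase-distribution
#'   initial condition around the target region, the robust equivalent of
#'   cross-field S1-S2 induction on coarse synthetic geometry) or `"s1s2"`
#'   (explicit two-pulse cross-field stimulation)
#' @param anchor_radius angular radius (radians) of a small fibrotic core
#'   patch at the rotor target that anchors the re-entry (0 disables);
#'   fibrosis is a recognized anchoring substrate, and an anchored rotor
#'   keeps the ground-truth core inside the labeled region
#' @return `stimulus_protocol` object
#' @export
stimulus_protocol <- function(kind = c("planar_wave", "cross_field_rotor",
                                       "focal", "none"),
                              target_region = 1L,
                              fibrosis_fraction = 0,
                              rng_seed = 1L,
                              stim_times = NULL, stim_amp = 0.8,
                              stim_dur = 2,
                              rotor_method = c("phase_seed", "s1s2"),
                              anchor_radius = 0.15) {
  kind <- match.arg(kind)
  rotor_method <- match.arg(rotor_method)
  if (fibrosis_fraction < 0 || fibrosis_fraction >= 1)
    stop_af("fibrosis_fraction must be in [0, 1)")
  if (kind %in% c("cross_field_rotor", "focal") &&
      (target_region < 1 || target_region > 7))
    stop_af("target_region must be in 1..7")
  structure(list(kind = kind, target_region = as.integer(target_region),
                 fibrosis_fraction = fibrosis_fraction,
                 rng_seed = as.integer(rng_seed),
                 stim_times = stim_times, stim_amp = stim_amp,
                 stim_dur = stim_dur, rotor_method = rotor_method,
                 anchor_radius = anchor_radius),
            class = "stimulus_protocol")
}

# Spiral-wave initial condition: states along one single-cell cycle are laid
# out as a phase pinwheel around the target region's center direction.  The
# free end of the resulting wavefront curls into a rotor whose core sits at
# the target region (a mirror-image rotor appears near the antipode, as
# required on a closed surface).
.spiral_init <- function(mesh, model, target_region, dt_ms) {
  cyc <- single_cell_cycle(model, cycle_ms = 180, dt_ms = 0.1)
  n_cyc <- nrow(cyc)
  dirs <- mesh$node_coords / sqrt(rowSums(mesh$node_coords^2))
  core <- mesh$node_coords[region_center_node(mesh, target_region), ]
  core <- core / sqrt(sum(core^2))
  # tangent basis at the core direction
  a <- if (abs(core[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - core * sum(a * core); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(core[2] * e1[3] - core[3] * e1[2],
          core[3] * e1[1] - core[1] * e1[3],
          core[1] * e1[2] - core[2] * e1[1])
  beta <- atan2(drop(dirs %*% e2), drop(dirs %*% e1))
  rho <- acos(pmin(1, pmax(-1, drop(dirs %*% core))))
  # pure phase pinwheel: the free wavefront end curls into a spiral on its
  # own; adding an archimedean twist packs the arms tighter than one
  # wavelength and extinguishes the wave on coarse meshes
  phase <- beta %% (2 * pi)
  tau_idx <- 1L + as.integer(floor(phase / (2 * pi) * (n_cyc - 1L)))
  st <- cyc[tau_idx, , drop = FALSE]
  # quench a small disk at the core so the singularity is well-defined
  st[rho < 0.08, ] <- matrix(rep(c(0, 1, 1), each = sum(rho < 0.08)),
                             ncol = 3)
  st
}

# Node sets for the built-in stimuli.
.planar_cap <- function(mesh, frac = 0.06) {
  x <- mesh$node_coords[, 1]
  which(x >= quantile(x, 1 - frac))
}

.protocol_stimuli <- function(mesh, protocol, duration_ms) {
  spec <- matrix(numeric(0), 0, 3)
  nodes <- list()
  add <- function(t0, dur, amp, nd) {
    spec <<- rbind(spec, c(t0, dur, amp))
    nodes[[length(nodes) + 1L]] <<- as.integer(nd - 1L)
  }
  switch(protocol$kind,
    planar_wave = add(2, protocol$stim_dur, protocol$stim_amp,
                      .planar_cap(mesh)),
    focal = {
      ctr <- region_center_node(mesh, protocol$target_region)
      nd <- c(ctr, mesh$neighbors[[ctr]])
      times <- protocol$stim_times %||% seq(5, duration_ms - 10, by = 140)
      for (t0 in times) add(t0, protocol$stim_dur, protocol$stim_amp, nd)
    },
    cross_field_rotor = if (protocol$rotor_method == "s1s2") {
      add(2, protocol$stim_dur, protocol$stim_amp, .planar_cap(mesh))
      ctr <- region_center_node(mesh, protocol$target_region)
      dirs <- mesh$node_coords / sqrt(rowSums(mesh$node_coords^2))
      cd <- mesh$node_coords[ctr, ] / sqrt(sum(mesh$node_coords[ctr, ]^2))
      half <- which(drop(dirs %*% cd) > 0.2)
      t2 <- protocol$stim_times %||% 130
      add(t2[1], protocol$stim_dur * 2, protocol$stim_amp, half)
    },
    none = NULL)
  list(spec = spec, nodes = nodes)
}

#' Simulate anisotropic propagation on an atrial mesh
#'
#' Integrates the monodomain reaction-diffusion system with RK4 at fixed
#' step `dt_ms` and records the transmembrane potential at `fs` Hz.
#' The per-frame ground-truth driver label is filled from the protocol:
#' the target region id while a rotor is established and the tissue remains
#' active, 0 for planar/focal/quiescent frames.
#'
#' @param mesh atrial_mesh (fibrosis from the protocol is applied on a copy)
#' @param model ionic_model
#' @param protocol stimulus_protocol
#' @param duration_s episode duration in seconds (default 2.5)
#' @param fs output sampling rate, Hz (default 500)
#' @param dt_ms integrator step in ms (default 0.05); must divide 1000/fs
#'   and satisfy the diffusion stability bound, checked before integrating
#' @return a `vm_series` object: `vm` (N x S), `fs`, `duration_s`, `labels`
#'   (per-frame ground truth 0..7), protocol echo and seed
#' @export
simulate_propagation <- function(mesh, model = ionic_model(),
                                 protocol = stimulus_protocol("planar_wave"),
                                 duration_s = 2.5, fs = 500, dt_ms = 0.05) {
  stopifnot(inherits(mesh, "atrial_mesh"), inherits(model, "ionic_model"),
            inherits(protocol, "stimulus_protocol"))
  if (duration_s * fs < 2) stop_af("need at least 2 output frames")
  if (protocol$fibrosis_fraction > 0)
    mesh <- apply_fibrosis(mesh, protocol$fibrosis_fraction,
                           protocol$rng_seed)
  if (protocol$kind == "cross_field_rotor" &&
      (protocol$anchor_radius %||% 0) > 0) {
    dirs <- mesh$node_coords / sqrt(rowSums(mesh$node_coords^2))
    core <- mesh$node_coords[region_center_node(mesh,
                                                protocol$target_region), ]
    core <- core / sqrt(sum(core^2))
    rho <- acos(pmin(1, pmax(-1, drop(dirs %*% core))))
    mesh$fibrotic[rho < protocol$anchor_radius] <- TRUE
  }
  cp <- mesh_coupling(mesh)
  # RK4 stability for the diffusion operator: |lambda_max| ~ 2 max_k sum_i c_ki
  row_sum <- diff(cp$row_ptr)
  csum <- rep(0, length(row_sum))
  if (length(cp$coef))
    csum <- as.numeric(tapply(cp$coef,
                              rep(seq_along(row_sum), row_sum), sum))
  lam <- 2 * max(csum, 0)
  dt_max <- if (lam > 0) 2.6 / lam else Inf
  if (dt_ms > dt_max)
    stop_af("dt = %g ms is unstable for this mesh/diffusion; use dt <= %.4g ms",
            dt_ms, 0.9 * dt_max)
  record_every <- round((1000 / fs) / dt_ms)
  if (abs(record_every * dt_ms - 1000 / fs) > 1e-9)
    stop_af("dt_ms must divide the output sample interval 1000/fs")
  n_steps <- round(duration_s * 1000 / dt_ms)

  init <- matrix(rep(model$rest, each = nrow(mesh$node_coords)),
                 ncol = 3)
  rotor_from_start <- FALSE
  if (protocol$kind == "cross_field_rotor" &&
      protocol$rotor_method == "phase_seed") {
    init <- .spiral_init(mesh, model, protocol$target_region, dt_ms)
    rotor_from_start <- TRUE
  }
  st <- .protocol_stimuli(mesh, protocol, duration_s * 1000)
  res <- .sim_monodomain(cp$row_ptr, cp$col_idx, cp$coef,
                         unlist(model$params), init, dt_ms,
                         as.integer(n_steps), as.integer(record_every),
                         st$spec, st$nodes)
  vm <- res$vm
  s <- ncol(vm)
  labels <- integer(s)
  if (protocol$kind == "cross_field_rotor") {
    active <- apply(vm, 2, max) > 0.15
    t_frames <- (seq_len(s) - 1L) / fs * 1000
    established <- if (rotor_from_start) rep(TRUE, s) else {
      t2 <- (protocol$stim_times %||% 130)[1]
      t_frames > t2 + 80
    }
    labels[active & established] <- protocol$target_region
    # once re-entry has died, activity may persist briefly; a driver label
    # requires activity from here to at least 150 ms onward
    last_active <- if (any(active)) max(which(active)) else 0L
    if (last_active > 0 && last_active < s) {
      labels[seq_len(s) > last_active] <- 0L
    }
  }
  structure(list(vm = vm, fs = fs, duration_s = duration_s,
                 labels = labels, protocol = protocol,
                 seed = protocol$rng_seed,
                 mesh_fingerprint = fingerprint(mesh$node_coords)),
            class = "vm_series")
}

#' @export
print.vm_series <- function(x, ...) {
  cat(sprintf("vm_series: %d nodes x %d frames @ %g Hz (%s, driver labels: %s)\n",
              nrow(x$vm), ncol(x$vm), x$fs, x$protocol$kind,
              paste(unique(x$labels), collapse = ",")))
  invisible(x)
}

#' Largest stable integration step for a mesh
#' @param mesh atrial_mesh
#' @return dt bound in ms
#' @export
stable_dt <- function(mesh) {
  cp <- mesh_coupling(mesh)
  n <- nrow(mesh$node_coords)
  row_sum <- diff(cp$row_ptr)
  csum <- as.numeric(tapply(cp$coef, rep(seq_len(n), row_sum), sum))
  lam <- 2 * max(csum, 0)
  if (lam > 0) 2.6 / lam else Inf
}
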