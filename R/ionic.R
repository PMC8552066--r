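# Phenomenological atrial ionic model.  A three-variable reaction model
# (fast inward, slow outward, slow inward currents gated by two recovery
# variables) reproduces human-atrial-like action potentials and sustains
# re-entrant spiral waves at desk-scale cost; full biophysical current sets
# are out of scope.

#' Construct an ionic model
#'
#' Currently one family is provided: `"atrial3v"`, a three-variable
#' phenomenological model with transmembrane potential `u` (normalized,
#' 0 = rest, ~1 = peak) and two gates `v`, `w`.  The object carries the rhs
#' contract used by both the single-cell reference integrator and the C++
#' tissue integrator: `rhs(V, gates, params)` returns
#' `list(dV = -I_ion/C_m, dgates = ...)`.
#'
#' @param name model family name
#' @param params named list overriding default parameters (time constants in
#'   ms; `C_m` is a dimensionless capacitance scale applied to I_ion)
#' @return an `ionic_model` object
#' @export
ionic_model <- function(name = "atrial3v", params = list()) {
  if (!identical(name, "atrial3v"))
    stop_af("unknown ionic model '%s'", name)
  p <- utils::modifyList(default_atrial3v_params(), params)
  structure(list(
    name = name,
    n_state = 3L,
    state_names = c("u", "v", "w"),
    rest = c(u = 0, v = 1, w = 1),
    params = p,
    rhs = atrial3v_rhs), class = "ionic_model")
}

# Defaults tuned for AF-like behavior at the package's default mesh
# resolution: short action potential (~110 ms APD90 single cell) so that
# re-entry fits on a ~50 mm atrial chamber, steep restitution kept mild so
# rotors stay stable rather than breaking up.
default_atrial3v_params <- function() {
  list(tau_d = 0.25, tau_0 = 8.3, tau_r = 48, tau_si = 45,
       tau_vp = 3.33, tau_vm1 = 12, tau_vm2 = 2,
       tau_wp = 1000, tau_wm = 100,
       u_c = 0.13, u_v = 0.055, u_csi = 0.85, k_si = 10,
       C_m = 1)
}

# Right-hand side shared (formula-identical) with the C++ tissue kernel.
atrial3v_rhs <- function(V, gates, params) {
  p <- params
  u <- V; v <- gates[, 1]; w <- gates[, 2]
  on <- as.numeric(u >= p$u_c)           # excited
  qv <- as.numeric(u >= p$u_v)
  J_fi <- -v * on * (1 - u) * (u - p$u_c) / p$tau_d
  J_so <- u * (1 - on) / p$tau_0 + on / p$tau_r
  J_si <- -w * (1 + tanh(p$k_si * (u - p$u_csi))) / (2 * p$tau_si)
  du <- -(J_fi + J_so + J_si) / p$C_m
  tau_vm <- qv * p$tau_vm1 + (1 - qv) * p$tau_vm2
  dv <- (1 - on) * (1 - v) / tau_vm - on * v / p$tau_vp
  dw <- (1 - on) * (1 - w) / p$tau_wm - on * w / p$tau_wp
  list(dV = du, dgates = cbind(dv, dw))
}

#' @export
print.ionic_model <- function(x, ...) {
  cat(sprintf("ionic_model '%s': %d state variables (%s)\n", x$name,
              x$n_state, paste(x$state_names, collapse = ", ")))
  invisible(x)
}

#' Reference single-cell / small-network integrator (pure R)
#'
#' Fixed-step RK4 integration of the ionic model on `n` nodes coupled by an
#' explicit coefficient matrix.  Deliberately independent of the C++ tissue
#' kernel so it can serve as its oracle on tiny problems.
#'
#' @param model ionic_model
#' @param coupling n x n matrix of coefficients `D_{k,i}/d_{k,i}^2`
#'   (0 for uncoupled); diffusion term is
#'   `sum_i coupling[k,i] * (V_i - V_k)`
#' @param dt_ms time step (ms)
#' @param n_steps number of steps
#' @param stim function(t_ms) returning the stimulus current vector (length
#'   n), or NULL
#' @param init optional n x 3 initial state (columns u, v, w)
#' @return list with `vm` (n x (n_steps+1)) and final `state`
#' @export
integrate_reference <- function(model, coupling, dt_ms, n_steps,
                                stim = NULL, init = NULL) {
  n <- nrow(coupling)
  st <- if (is.null(init))
    matrix(rep(model$rest, each = n), n, 3) else init
  vm <- matrix(0, n, n_steps + 1L)
  vm[, 1] <- st[, 1]
  deriv <- function(s, t) {
    r <- model$rhs(s[, 1], s[, 2:3, drop = FALSE], model$params)
    diff_term <- drop(coupling %*% s[, 1]) - rowSums(coupling) * s[, 1]
    dV <- r$dV + diff_term
    if (!is.null(stim)) dV <- dV + stim(t)
    cbind(dV, r$dgates)
  }
  t <- 0
  for (s in seq_len(n_steps)) {
    k1 <- deriv(st, t)
    k2 <- deriv(st + dt_ms / 2 * k1, t + dt_ms / 2)
    k3 <- deriv(st + dt_ms / 2 * k2, t + dt_ms / 2)
    k4 <- deriv(st + dt_ms * k3, t + dt_ms)
    st <- st + dt_ms / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt_ms
    vm[, s + 1L] <- st[, 1]
  }
  list(vm = vm, state = st)
}

#' Single-cell action potential trajectory over one paced cycle
#'
#' Stimulates a resting cell and records the full state over `cycle_ms`.
#' Used both as a sanity check of the model and to seed spiral-wave initial
#' conditions (states along the cycle are laid out in space as a phase
#' distribution).
#'
#' @param model ionic_model
#' @param cycle_ms cycle length to record (ms)
#' @param dt_ms integration step
#' @param stim_amp,stim_dur stimulus amplitude (1/ms) and duration (ms)
#' @return matrix (n_samples x 3) of states at each dt
#' @export
single_cell_cycle <- function(model, cycle_ms = 250, dt_ms = 0.05,
                              stim_amp = 0.8, stim_dur = 2) {
  n_steps <- round(cycle_ms / dt_ms)
  st <- matrix(model$rest, 1, 3)
  out <- matrix(0, n_steps + 1L, 3)
  out[1, ] <- st
  t <- 0
  deriv <- function(s, t) {
    r <- model$rhs(s[, 1], s[, 2:3, drop = FALSE], model$params)
    dV <- r$dV + if (t < stim_dur) stim_amp else 0
    cbind(dV, r$dgates)
  }
  for (s in seq_len(n_steps)) {
    k1 <- deriv(st, t)
    k2 <- deriv(st + dt_ms / 2 * k1, t + dt_ms / 2)
    k3 <- deriv(st + dt_ms / 2 * k2, t + dt_ms / 2)
    k4 <- deriv(st + dt_ms * k3, t + dt_ms)
    st <- st + dt_ms / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt_ms
    out[s + 1L, ] <- st
  }
  colnames(out) <- c("u", "v", "w")
  out
}

#' Action potential duration at 90% repolarization
#' @param trace u(t) samples
#' @param dt_ms sample interval
#' @return APD90 in ms (NA if no action potential)
#' @export
apd90 <- function(trace, dt_ms) {
  peak <- max(trace)
  if (peak < 0.5) return(NA_real_)
  thr <- 0.1 * peak
  up <- which(trace > thr)
  if (!length(up)) return(NA_real_)
  (max(up) - min(up)) * dt_ms
}
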