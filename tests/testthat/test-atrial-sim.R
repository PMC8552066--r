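# Synthetic atrial geometry, anisotropic diffusion, fibrosis, and the
# monodomain integrator.

test_that("build_synthetic_atria yields exact node counts and 7 regions", {
  m <- build_synthetic_atria(2048)
  expect_equal(nrow(m$node_coords), 2048L)
  expect_setequal(unique(m$region_id), 1:7)
  expect_equal(sort(unique(as.vector(m$triangles))), 1:2048)
  # closed orientable surface and unit fibers are enforced by the validator
  expect_silent(validate_atrial_mesh(m))
  expect_true(all(lengths(m$neighbors) >= 3))
  expect_true(all(abs(rowSums(m$fiber_dir^2) - 1) < 1e-9))
})

test_that("mesh construction is deterministic and rejects tiny inputs", {
  a <- build_synthetic_atria(128, rng_seed = 3)
  b <- build_synthetic_atria(128, rng_seed = 3)
  expect_identical(a$node_coords, b$node_coords)
  expect_identical(a$triangles, b$triangles)
  expect_error(build_synthetic_atria(16), "too small")
})

test_that("diffusion_coefficient matches the anisotropy law", {
  expect_equal(diffusion_coefficient(1.0, 0.2, 0), 1.0)
  expect_equal(diffusion_coefficient(1.0, 0.2, pi / 2), 0.2)
  expect_equal(diffusion_coefficient(1.0, 0.2, pi / 4), 0.6)
  expect_error(diffusion_coefficient(-1, 0.2, 0), "non-negative")
  expect_error(diffusion_coefficient(0.1, 0.2, 0), "d_long")
  # endpoints, monotone non-increasing on [0, pi/2], isotropic limit
  al <- seq(0, pi / 2, length.out = 50)
  d <- diffusion_coefficient(1.7, 0.4, al)
  expect_equal(d[1], 1.7)
  expect_equal(d[50], 0.4)
  expect_true(all(diff(d) <= 1e-12))
  expect_equal(diffusion_coefficient(0.9, 0.9, al), rep(0.9, 50))
})

test_that("apply_fibrosis disconnects the right nodes reproducibly", {
  m <- small_mesh()
  expect_identical(apply_fibrosis(m, 0), m)
  f <- apply_fibrosis(m, 0.25, rng_seed = 2)
  expect_equal(sum(f$fibrotic), round(0.25 * 256))
  f2 <- apply_fibrosis(m, 0.25, rng_seed = 2)
  expect_identical(f$fibrotic, f2$fibrotic)
  f3 <- apply_fibrosis(m, 0.25, rng_seed = 9)
  expect_false(identical(f$fibrotic, f3$fibrotic))
  expect_error(apply_fibrosis(m, 1), "fraction")
  # all coupling coefficients incident to fibrotic nodes are zero
  cp <- afdriverloc:::mesh_coupling(f)
  rows <- rep(seq_along(f$fibrotic), diff(cp$row_ptr))
  bad <- f$fibrotic[rows] | f$fibrotic[cp$col_idx + 1L]
  expect_true(all(cp$coef[bad] == 0))
  expect_true(all(cp$coef[!bad] > 0))
})

test_that("resting tissue is a fixed point of the simulation", {
  m <- small_mesh()
  vs <- simulate_propagation(m, protocol = stimulus_protocol("none"),
                             duration_s = 0.2, fs = 500)
  expect_lt(max(abs(vs$vm)), 1e-6)
  expect_true(all(vs$labels == 0))
})

test_that("fully fibrotic tissue confines a focal stimulus to its source", {
  m <- small_mesh()
  m$fibrotic[] <- TRUE   # every node disconnected
  prot <- stimulus_protocol("focal", target_region = 2, rng_seed = 1)
  vs <- simulate_propagation(m, protocol = prot, duration_s = 0.4, fs = 500)
  stim_nodes <- {
    ctr <- afdriverloc:::region_center_node(m, 2)
    c(ctr, m$neighbors[[ctr]])
  }
  moved <- which(apply(abs(vs$vm), 1, max) > 1e-6)
  expect_true(all(moved %in% stim_nodes))
  expect_gt(max(vs$vm[stim_nodes[1], ]), 0.5)  # the source itself fires
})

test_that("tissue integrator matches the independent R reference", {
  # two coupled nodes, brute-force RK4 at dt/20 as oracle
  model <- ionic_model()
  coup <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  stim <- function(t) if (t < 2) c(0.8, 0) else c(0, 0)
  dt <- 0.05                       # production step; oracle at dt/20
  n_cpp <- 1200L                   # 60 ms: upstroke + early plateau
  ref <- integrate_reference(model, coup, dt / 20, 20L * n_cpp,
                             stim = stim)
  # C++ path: strip mesh replaced by a hand-built 2-node coupling
  cpp <- afdriverloc:::.sim_monodomain(
    row_ptr = c(0L, 1L, 2L), col_idx = c(1L, 0L), coef = c(0.5, 0.5),
    params = unlist(model$params),
    init_state = matrix(rep(model$rest, each = 2), 2),
    dt_ms = dt, n_steps = n_cpp, record_every = 1L,
    stim_spec = matrix(c(0, 2, 0.8), 1), stim_nodes_list = list(0L))
  ref_at <- ref$vm[, seq(1, 20L * n_cpp + 1L, by = 20)]
  err <- max(abs(cpp$vm - ref_at))
  expect_lt(err / max(abs(ref_at)), 0.01)
})

test_that("zero diffusion decouples nodes to the single-cell solution", {
  model <- ionic_model()
  n <- 5
  cpp <- afdriverloc:::.sim_monodomain(
    row_ptr = integer(n + 1), col_idx = integer(0), coef = numeric(0),
    params = unlist(model$params),
    init_state = matrix(rep(model$rest, each = n), n),
    dt_ms = 0.05, n_steps = 2000L, record_every = 1L,
    stim_spec = matrix(c(0, 2, 0.8), 1),
    stim_nodes_list = list(as.integer(0:(n - 1))))
  single <- single_cell_cycle(model, cycle_ms = 100, dt_ms = 0.05,
                              stim_amp = 0.8, stim_dur = 2)
  for (k in seq_len(n))
    expect_lt(max(abs(cpp$vm[k, ] - single[, 1])), 1e-8)
})

test_that("planar wave activation time grows with distance from stimulus", {
  m <- afdriverloc:::build_strip_mesh(40, 6, spacing = 2, d_long = 0.7,
                                      d_trans = 0.7)
  vs <- simulate_propagation(m, protocol = stimulus_protocol("planar_wave"),
                             duration_s = 0.5, fs = 1000)
  act <- apply(vs$vm, 1, function(tr) {
    i <- which(tr > 0.5)
    if (length(i)) i[1] else NA_real_
  })
  x <- m$node_coords[, 1]
  ok <- !is.na(act)
  expect_gt(mean(ok), 0.95)
  # wave starts from the max-x cap; activation ~ distance from it
  expect_gt(cor(max(x) - x[ok], act[ok], method = "spearman"), 0.99)
})

test_that("doubling diffusion increases conduction velocity", {
  cv <- function(d) {
    m <- afdriverloc:::build_strip_mesh(40, 6, spacing = 2, d_long = d,
                                        d_trans = d)
    vs <- simulate_propagation(m, protocol = stimulus_protocol("planar_wave"),
                               duration_s = 0.5, fs = 1000)
    act <- apply(vs$vm, 1, function(tr) {
      i <- which(tr > 0.5)
      if (length(i)) i[1] else NA_real_
    })
    x <- m$node_coords[, 1]
    ok <- !is.na(act) & x > 8 & x < 70
    -1 / coef(stats::lm(act[ok] ~ x[ok]))[2]
  }
  expect_gt(cv(1.4), 1.25 * cv(0.7))
})

test_that("unstable dt is rejected with a suggestion", {
  m <- small_mesh()
  err <- tryCatch(simulate_propagation(m, duration_s = 0.1, dt_ms = 50),
                  error = function(e) conditionMessage(e))
  expect_match(err, "unstable")
  expect_match(err, "use dt")
})

test_that("ionic model invariants hold", {
  model <- ionic_model()
  r <- model$rhs(model$rest[1], matrix(model$rest[2:3], 1), model$params)
  expect_lt(abs(r$dV), 1e-6)            # rest is (numerically) fixed
  expect_true(all(abs(r$dgates) < 1e-6))
  cyc <- single_cell_cycle(model, cycle_ms = 400, dt_ms = 0.05)
  expect_gt(max(cyc[, 1]), 0.9)          # suprathreshold stimulus fires
  expect_lt(cyc[nrow(cyc), 1], 0.05)     # and recovers
  apd <- apd90(cyc[, 1], 0.05)
  expect_gt(apd, 60)                     # atrial-like action potential
  expect_lt(apd, 250)
})

test_that("vm_series container is well-formed", {
  vs <- rotor_episode()
  expect_equal(vs$fs, 500)
  expect_equal(ncol(vs$vm), 601)
  expect_true(all(is.finite(vs$vm)))
  expect_true(all(vs$labels %in% 0:7))
})
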