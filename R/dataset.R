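# Labeled dataset construction: ground-truth driver labels (protocol-based,
# cross-checked by phase-singularity detection), the two split schemes, and
# inverse-frequency class weights.

#' Per-node instantaneous phase of a transmembrane series
#'
#' Analytic-signal (Hilbert) phase of the mean-subtracted signal, computed
#' per node over the whole episode.
#' @param vm N x S matrix (or vm_series)
#' @return N x S matrix of phases in (-pi, pi]
#' @export
instantaneous_phase <- function(vm) {
  x <- if (inherits(vm, "vm_series")) vm$vm else vm
  s <- ncol(x)
  xc <- x - rowMeans(x)
  X <- t(stats::mvfft(t(xc)))
  h <- numeric(s)
  if (s %% 2 == 0) {
    h[c(1, s / 2 + 1)] <- 1
    h[2:(s / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((s + 1) / 2)] <- 2
  }
  analytic <- t(stats::mvfft(t(X * rep(h, each = nrow(x))), inverse = TRUE)) / s
  atan2(Im(analytic), Re(analytic))
}

# Ordered 1-ring (cyclic) around a node, following the manifold
# orientation: each incident triangle (node, a, b) contributes the directed
# edge a -> b, and the fan walk concatenates them, so winding signs are
# globally consistent.
.ordered_ring <- function(mesh, node) {
  tris <- mesh$triangles[apply(mesh$triangles == node, 1, any), ,
                         drop = FALSE]
  nxt <- integer(0)
  for (i in seq_len(nrow(tris))) {
    t <- tris[i, ]
    j <- which(t == node)[1]
    a <- t[(j %% 3) + 1L]
    b <- t[((j + 1L) %% 3) + 1L]
    nxt[as.character(a)] <- b
  }
  start <- as.integer(names(nxt)[1])
  ring <- start
  cur <- start
  repeat {
    cur <- unname(nxt[as.character(cur)])
    if (is.na(cur) || cur == start) break
    ring <- c(ring, cur)
    if (length(ring) > length(nxt)) break
  }
  ring
}

# Connected clusters of silent nodes (fibrotic or never activated) and the
# ordered cycle of active nodes around each: re-entry anchored to an
# obstacle has no node-level phase singularity — the circulation shows up
# as a +-1 winding along the obstacle's perimeter.
.silent_clusters <- function(mesh, silent) {
  idx <- which(silent)
  if (!length(idx)) return(list())
  comp <- integer(length(silent))
  cid <- 0L
  for (s in idx) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      k <- queue[1]; queue <- queue[-1]
      if (comp[k] != 0L) next
      comp[k] <- cid
      nb <- mesh$neighbors[[k]]
      queue <- c(queue, nb[silent[nb] & comp[nb] == 0L])
    }
  }
  lapply(seq_len(cid), function(c) {
    members <- which(comp == c)
    boundary <- setdiff(unique(unlist(mesh$neighbors[members])), members)
    boundary <- boundary[!silent[boundary]]
    if (length(boundary) < 3) return(NULL)
    ctr <- colMeans(mesh$node_coords[members, , drop = FALSE])
    cdir <- ctr / sqrt(sum(ctr^2))
    a <- if (abs(cdir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- a - cdir * sum(a * cdir); e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(cdir[2] * e1[3] - cdir[3] * e1[2],
            cdir[3] * e1[1] - cdir[1] * e1[3],
            cdir[1] * e1[2] - cdir[2] * e1[1])
    rel <- sweep(mesh$node_coords[boundary, , drop = FALSE], 2, ctr)
    ang <- atan2(rel %*% e2, rel %*% e1)
    core <- members[which.min(colSums((t(mesh$node_coords[members, ,
                                                          drop = FALSE]) -
                                        ctr)^2))]
    list(members = members, boundary = boundary[order(ang)], core = core)
  })
}

# Flattened ring structure: index pairs (i1 -> i2) for consecutive ring
# members of every node, plus the owning node, so winding numbers for a
# whole frame reduce to one vectorized wrap + rowsum.
.ring_structure <- function(mesh) {
  n <- nrow(mesh$node_coords)
  rings <- lapply(seq_len(n), function(k) .ordered_ring(mesh, k))
  i1 <- unlist(lapply(rings, function(r) r))
  i2 <- unlist(lapply(rings, function(r) c(r[-1], r[1])))
  owner <- rep.int(seq_len(n), lengths(rings))
  list(rings = rings, i1 = i1, i2 = i2, owner = owner, n = n)
}

#' Detect phase singularities in one frame
#'
#' A node is a phase-singularity core candidate when the winding number of
#' the instantaneous phase around its ordered 1-ring is +-1.
#'
#' @param phase_frame numeric vector of per-node phases
#' @param mesh atrial_mesh
#' @param rings precomputed ring structure from previous calls (optional)
#' @return integer vector of PS core node indices
#' @export
detect_phase_singularity <- function(phase_frame, mesh, rings = NULL) {
  rs <- if (is.list(rings) && !is.null(rings$owner)) rings
        else .ring_structure(mesh)
  d <- phase_frame[rs$i2] - phase_frame[rs$i1]
  d <- (d + pi) %% (2 * pi) - pi
  w <- rowsum(d, rs$owner) / (2 * pi)
  which(abs(abs(w) - 1) < 0.01)
}

#' Driver region label for one frame
#'
#' Primary mode returns the protocol ground truth carried by the episode.
#' Verification mode locates phase singularities and returns the modal
#' region of the detected cores (0 when none); disagreement with the
#' ground truth is reported by [verify_driver_labels()].
#'
#' @param vm_series vm_series
#' @param mesh atrial_mesh
#' @param frame frame index
#' @param mode `"protocol"` or `"phase"`
#' @param phase,rings precomputed phase matrix / rings (optional)
#' @return integer label 0..7
#' @export
detect_driver_label <- function(vm_series, mesh, frame,
                                mode = c("protocol", "phase"),
                                phase = NULL, rings = NULL) {
  mode <- match.arg(mode)
  if (mode == "protocol") return(vm_series$labels[frame])
  if (ncol(vm_series$vm) < vm_series$fs * 0.2)
    stop_af("episode too short for phase estimation")
  .phase_driver_labels(vm_series, mesh, frame)[1]
}

# Shared phase-based driver labeling engine.  Core mechanisms: functional
# re-entry shows a node-level +-1 phase winding on a fully active 1-ring
# (signed consistently thanks to the oriented rings); anatomical re-entry
# around a silent obstacle shows a +-1 winding along the obstacle's
# perimeter.  Cores are then linked across frames into tracks (same
# chirality, within a 2-ring hop, gaps up to 4 frames); the driver is the
# longest-lived track, and each queried frame gets the region of that
# track's core at (or nearest to) that frame.
.phase_driver_labels <- function(vm_series, mesh, frames) {
  vm <- vm_series$vm
  s <- ncol(vm)
  phase <- instantaneous_phase(vm_series)
  silent <- apply(vm, 1, function(r) diff(range(r))) < 0.1
  rs <- .ring_structure(mesh)
  # node-level windings are meaningless on rings touching silent nodes
  ring_ok <- !silent & vapply(rs$rings, function(r) !any(silent[r]),
                              logical(1))
  clusters <- Filter(Negate(is.null), .silent_clusters(mesh, silent))
  wrap <- function(d) (d + pi) %% (2 * pi) - pi
  winding <- function(ph) {
    d <- wrap(ph[rs$i2] - ph[rs$i1])
    rowsum(d, rs$owner) / (2 * pi)
  }
  cores_at <- lapply(seq_len(s), function(f) {
    ph <- phase[, f]
    w <- winding(ph)
    ps <- which(abs(abs(w) - 1) < 0.01 & ring_ok)
    sgn <- sign(w[ps])
    for (cl in clusters) {
      th <- ph[cl$boundary]
      wc <- sum(wrap(diff(c(th, th[1])))) / (2 * pi)
      if (abs(abs(wc) - 1) < 0.1) {
        ps <- c(ps, cl$core)
        sgn <- c(sgn, sign(wc))
      }
    }
    list(nodes = as.integer(ps), sign = as.integer(sgn))
  })
  two_ring <- lapply(seq_len(nrow(vm)), function(k)
    unique(c(k, mesh$neighbors[[k]],
             unlist(mesh$neighbors[mesh$neighbors[[k]]]))))
  # greedy chirality-respecting tracking
  tracks <- list()   # each: node, sign, first, last, path (frame -> node)
  for (f in seq_len(s)) {
    ca <- cores_at[[f]]
    for (i in seq_along(ca$nodes)) {
      k <- ca$nodes[i]
      matched <- FALSE
      for (t in seq_along(tracks)) {
        tr <- tracks[[t]]
        if (tr$sign == ca$sign[i] && f - tr$last <= 4L &&
            k %in% two_ring[[tr$node]]) {
          tr$node <- k; tr$last <- f
          tr$path[as.character(f)] <- k
          tracks[[t]] <- tr
          matched <- TRUE
          break
        }
      }
      if (!matched)
        tracks[[length(tracks) + 1L]] <-
          list(node = k, sign = ca$sign[i], first = f, last = f,
               path = stats::setNames(k, as.character(f)))
    }
  }
  if (!length(tracks))
    return(vapply(frames, function(f) 0L, integer(1)))
  span <- vapply(tracks, function(tr) tr$last - tr$first + 1L, integer(1))
  driver <- tracks[[which.max(span)]]
  pf <- as.integer(names(driver$path))
  vapply(frames, function(f) {
    if (max(vm[, f]) < 0.05) return(0L)
    if (f < driver$first - 4L || f > driver$last + 4L) return(0L)
    node <- driver$path[[as.character(pf[which.min(abs(pf - f))])]]
    mesh$region_id[node]
  }, integer(1))
}

#' Fraction of frames where the phase detector confirms the ground truth
#'
#' @param vm_series vm_series (rotor episode)
#' @param mesh atrial_mesh
#' @param frames frames to check (default: frames with a nonzero label)
#' @return agreement fraction in [0, 1]
#' @export
verify_driver_labels <- function(vm_series, mesh, frames = NULL) {
  frames <- frames %||% which(vm_series$labels > 0)
  if (!length(frames)) return(NA_real_)
  pred <- .phase_driver_labels(vm_series, mesh, frames)
  mean(pred == vm_series$labels[frames])
}

#' Build a labeled tensor dataset from simulated episodes
#'
#' Each episode supplies a 64-channel BSP recording and per-frame labels;
#' frames (optionally strided) are tensorized and stacked.
#'
#' @param episodes list; each element needs `$bsp` (64-channel
#'   bsp_recording) and `$labels` (per-frame 0..7)
#' @param layout_kind,resize,normalize see [tensorize_frames()]
#' @param frame_stride keep every k-th frame (1 = all)
#' @return `labeled_dataset`: `images` (n, H, W, C), `labels`, `episode`,
#'   `frame_idx`, `manifest`
#' @export
build_labeled_dataset <- function(episodes, layout_kind = "1ch",
                                  resize = NULL, normalize = "zscore",
                                  frame_stride = 1L) {
  stopifnot(length(episodes) >= 1L)
  imgs <- list(); labs <- list(); eps <- list(); fidx <- list()
  for (e in seq_along(episodes)) {
    ep <- episodes[[e]]
    s <- ncol(ep$bsp$potentials)
    if (length(ep$labels) != s)
      stop_af("episode %d: %d labels for %d frames", e, length(ep$labels), s)
    frames <- seq(1L, s, by = frame_stride)
    imgs[[e]] <- tensorize_frames(ep$bsp, layout_kind, resize, frames,
                                  normalize)
    labs[[e]] <- as.integer(ep$labels[frames])
    eps[[e]] <- rep(e, length(frames))
    fidx[[e]] <- frames
  }
  images <- do.call(abind_1, imgs)
  labels <- unlist(labs)
  structure(list(
    images = images, labels = labels,
    episode = unlist(eps), frame_idx = unlist(fidx),
    manifest = list(layout_kind = layout_kind,
                    resize = dim(images)[2:3],
                    normalize = normalize, frame_stride = frame_stride,
                    n_episodes = length(episodes),
                    label_histogram = as.list(table(factor(labels, 0:7))))),
    class = "labeled_dataset")
}

# minimal abind along dim 1 for 4-d arrays (avoids an extra dependency)
abind_1 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], numeric(1)))
  out <- array(0, c(n, d[2], d[3], d[4]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d samples (%s), labels: %s\n",
              length(x$labels),
              paste(dim(x$images)[-1], collapse = "x"),
              paste(names(table(x$labels)), table(x$labels),
                    sep = "=", collapse = " ")))
  invisible(x)
}

#' Random frame-level train/validation/test split
#'
#' 80/20 train/test with 20% of the training portion held out for
#' validation: 64% / 16% / 20% of the dataset.
#'
#' @param ds labeled_dataset (or an integer sample count)
#' @param seed integer seed
#' @param stratify when TRUE, split each class separately so label
#'   proportions are preserved across train/val/test (default FALSE:
#'   plain random split)
#' @return list of disjoint index vectors `train`, `val`, `test`
#' @export
split_time_independent <- function(ds, seed = 1L, stratify = FALSE) {
  n <- if (inherits(ds, "labeled_dataset")) length(ds$labels) else ds
  if (n < 10) stop_af("need at least 10 samples to split, got %d", n)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  split_idx <- function(idx) {
    m <- length(idx)
    n_test <- round(0.2 * m)
    n_val <- round(0.2 * (m - n_test))
    list(test = idx[seq_len(n_test)],
         val = idx[n_test + seq_len(n_val)],
         train = idx[(n_test + n_val + 1L):m])
  }
  if (stratify && inherits(ds, "labeled_dataset")) {
    perm <- sample.int(n)
    groups <- split(perm, ds$labels[perm])
    parts <- lapply(groups, split_idx)
    res <- list(test = sort(unlist(lapply(parts, `[[`, "test"))),
                val = sort(unlist(lapply(parts, `[[`, "val"))),
                train = sort(unlist(lapply(parts, `[[`, "train"))))
  } else {
    s <- split_idx(sample.int(n))
    res <- list(test = sort(s$test), val = sort(s$val),
                train = sort(s$train))
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  res
}

#' Consecutive-block split per episode
#'
#' Within every episode: first 64% of frames train, next 16% validation,
#' final 20% test.  Deterministic; no future frames leak into training.
#'
#' @param ds labeled_dataset
#' @return list of index vectors `train`, `val`, `test`
#' @export
split_blocks <- function(ds) {
  stopifnot(inherits(ds, "labeled_dataset"))
  train <- val <- test <- integer(0)
  for (e in unique(ds$episode)) {
    idx <- which(ds$episode == e)
    s <- length(idx)
    if (s < 5) stop_af("episode %d has only %d frames (< 5)", e, s)
    i1 <- floor(0.64 * s); i2 <- floor(0.8 * s)
    train <- c(train, idx[seq_len(i1)])
    val <- c(val, idx[(i1 + 1L):i2])
    test <- c(test, idx[(i2 + 1L):s])
  }
  list(train = train, val = val, test = test)
}

#' Inverse-frequency class weights
#'
#' `w_c = Total / (K_present * n_c)` for classes present in the labels
#' (`K_present` = number of non-empty classes); absent classes get 0.
#' The weighted mean over samples is 1 by construction.
#'
#' @param labels integer labels 0..(n_classes-1)
#' @param n_classes number of classes (default 8)
#' @return numeric weight per class (named 0..n_classes-1)
#' @export
class_weights <- function(labels, n_classes = 8L) {
  if (!length(labels)) stop_af("no labels supplied")
  cnt <- tabulate(labels + 1L, n_classes)
  k <- sum(cnt > 0)
  w <- ifelse(cnt > 0, length(labels) / (k * cnt), 0)
  names(w) <- as.character(seq_len(n_classes) - 1L)
  w
}
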