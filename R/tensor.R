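# BSP-frame -> image tensor conversion: the two vest image layouts
# (3-channel front/sides/back stack and 1-channel unrolled cylinder with
# mirror columns), bilinear resizing, channel replication and
# normalization.

#' Default vest image layout
#'
#' Describes how the canonical 64-channel order maps onto the image grids:
#' front and back panels are 6 rows x 4 columns; the 16 side electrodes
#' form four columns (two left, two right) occupying the last four rows.
#' The unrolled cylinder has 12 base columns in the order front(1-4),
#' left side(5-6), back(7-10), right side(11-12); two mirror columns are
#' added on each side.
#' @return `vest_layout` object
#' @export
default_vest_layout <- function() {
  structure(list(
    n_rows = 6L, n_front = 24L, n_back = 24L, n_side = 16L,
    side_rows = 3:6,                      # occupied rows in side columns
    base_cols = c(front = 4L, side_left = 2L, back = 4L, side_right = 2L),
    mirror_width = 2L), class = "vest_layout")
}

# 64-channel canonical frame -> named pieces
.split_frame64 <- function(frame64) {
  if (length(frame64) != 64L)
    stop_af("expected 64 electrode values, got %d", length(frame64))
  list(front = matrix(frame64[1:24], 6, 4, byrow = TRUE),
       back = matrix(frame64[25:48], 6, 4, byrow = TRUE),
       side = matrix(frame64[49:64], 4, 4))   # rows 3..6 x (L1,L2,R1,R2)
}

#' Build the 3-channel (6 x 4 x 3) tensor from one BSP frame
#'
#' Channel 1 = front panel, channel 3 = back panel, channel 2 = the side
#' electrodes on the last four rows with the remaining eight cells zero.
#'
#' @param frame64 numeric vector of 64 electrode values in canonical order
#' @param layout vest_layout
#' @return array (6, 4, 3)
#' @export
make_3channel <- function(frame64, layout = default_vest_layout()) {
  p <- .split_frame64(frame64)
  side <- matrix(0, 6, 4)
  side[layout$side_rows, ] <- p$side
  out <- array(0, c(6L, 4L, 3L))
  out[, , 1] <- p$front
  out[, , 2] <- side
  out[, , 3] <- p$back
  out
}

# Occupancy and values of the 12-column unrolled cylinder.
.cylinder12 <- function(frame64, layout) {
  p <- .split_frame64(frame64)
  grid <- matrix(NA_real_, 6, 12)
  grid[, 1:4] <- p$front
  grid[layout$side_rows, 5:6] <- p$side[, 1:2]
  grid[, 7:10] <- p$back
  grid[layout$side_rows, 11:12] <- p$side[, 3:4]
  grid
}

# Gap filling: mean of the 3 nearest occupied electrodes under
# wrap-aware Chebyshev grid distance, ties broken by (row, col).
.fill_gaps <- function(grid) {
  occ <- which(!is.na(grid), arr.ind = TRUE)
  gaps <- which(is.na(grid), arr.ind = TRUE)
  if (!nrow(gaps)) return(grid)
  n_col <- ncol(grid)
  for (g in seq_len(nrow(gaps))) {
    dr <- abs(occ[, 1] - gaps[g, 1])
    dcr <- abs(occ[, 2] - gaps[g, 2])
    dc <- pmin(dcr, n_col - dcr)
    d <- pmax(dr, dc)
    ord <- order(d, occ[, 1], occ[, 2])[1:3]
    grid[gaps[g, 1], gaps[g, 2]] <- mean(grid[occ[ord, , drop = FALSE]])
  }
  grid
}

#' Build the 1-channel (6 x 16) matrix from one BSP frame
#'
#' Unrolls the vest cylinder to 12 columns, fills the eight empty side
#' cells with the mean of the three nearest occupied electrodes
#' (wrap-aware Chebyshev grid distance, ties by row then column), then
#' prepends the last two base columns and appends the first two so the
#' cylinder seam is represented on both edges.
#'
#' @inheritParams make_3channel
#' @return matrix (6, 16)
#' @export
make_1channel <- function(frame64, layout = default_vest_layout()) {
  grid <- .fill_gaps(.cylinder12(frame64, layout))
  w <- layout$mirror_width
  cbind(grid[, (12 - w + 1):12], grid, grid[, 1:w])
}

#' Separable bilinear image resize (align-corners convention)
#'
#' Corner pixels of the output reproduce corner pixels of the input
#' exactly; channels are resized independently; constant images stay
#' constant.
#'
#' @param image matrix or 3-d array (H x W or H x W x C)
#' @param out_height,out_width target size (>= 2)
#' @return resized matrix / array
#' @export
bilinear_resize <- function(image, out_height, out_width) {
  if (out_height < 2 || out_width < 2)
    stop_af("output dimensions must be at least 2")
  dims <- dim(image)
  if (length(dims) == 2L) {
    return(.bilinear2d(image, out_height, out_width))
  }
  out <- array(0, c(out_height, out_width, dims[3]))
  for (c in seq_len(dims[3]))
    out[, , c] <- .bilinear2d(image[, , c], out_height, out_width)
  out
}

.bilinear2d <- function(img, oh, ow) {
  ih <- nrow(img); iw <- ncol(img)
  if (ih < 2 || iw < 2) stop_af("input dimensions must be at least 2")
  yi <- (seq_len(oh) - 1) * (ih - 1) / (oh - 1) + 1
  xi <- (seq_len(ow) - 1) * (iw - 1) / (ow - 1) + 1
  y0 <- pmin(floor(yi), ih - 1); fy <- yi - y0
  x0 <- pmin(floor(xi), iw - 1); fx <- xi - x0
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x0 + 1, drop = FALSE]
  c <- img[y0 + 1, x0, drop = FALSE]; d <- img[y0 + 1, x0 + 1, drop = FALSE]
  wy <- matrix(fy, oh, ow); wx <- matrix(fx, oh, ow, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx +
    c * wy * (1 - wx) + d * wy * wx
}

#' Replicate a single-channel image to k identical channels
#'
#' Adapter for 3-channel network inputs built from 1-channel tensors.
#' @param image matrix or H x W x 1 array
#' @param k number of channels
#' @return H x W x k array (k = 1 returns the input shape as array)
#' @export
replicate_channels <- function(image, k = 3) {
  if (length(dim(image)) == 3L) {
    if (dim(image)[3] != 1L) stop_af("input must be single-channel")
    image <- image[, , 1]
  }
  array(rep(as.numeric(image), k), c(nrow(image), ncol(image), k))
}

#' Normalize an image tensor
#'
#' @param image numeric array
#' @param mode `"zscore"` (per-tensor, default), `"minmax"`, or `"none"`
#' @return normalized array with attribute `normalization`; a zero-variance
#'   tensor under zscore returns zeros flagged with attribute `degenerate`
#' @export
normalize_tensor <- function(image, mode = c("zscore", "minmax", "none")) {
  mode <- match.arg(mode)
  if (any(!is.finite(image))) stop_af("image contains non-finite values")
  out <- switch(mode,
    none = image,
    minmax = {
      rg <- range(image)
      if (diff(rg) == 0) {
        res <- image * 0
        attr(res, "degenerate") <- TRUE
        res
      } else (image - rg[1]) / diff(rg)
    },
    zscore = {
      s <- stats::sd(as.numeric(image))
      if (s == 0) {
        res <- image * 0
        attr(res, "degenerate") <- TRUE
        res
      } else (image - mean(image)) / s
    })
  attr(out, "normalization") <- mode
  out
}

# The per-frame layout and the align-corners resize are both linear in the
# 64 electrode values, so batch tensorization precomputes (a) the layout
# operator by pushing the 64 unit frames through the reference per-frame
# function, and (b) the separable row/column interpolation matrices.  The
# fast path is therefore exactly the composition of the documented
# per-frame operations.
.layout_operator <- function(layout_kind, layout) {
  f <- if (layout_kind == "1ch") function(v) make_1channel(v, layout)
       else function(v) make_3channel(v, layout)
  cols <- lapply(seq_len(64), function(k) {
    v <- numeric(64); v[k] <- 1
    as.numeric(f(v))
  })
  op <- do.call(cbind, cols)
  list(op = op, dim = dim(f(numeric(64))))
}

.resize_matrices <- function(ih, iw, oh, ow) {
  mk <- function(n_in, n_out) {
    xi <- (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1) + 1
    x0 <- pmin(floor(xi), n_in - 1)
    fx <- xi - x0
    M <- matrix(0, n_out, n_in)
    M[cbind(seq_len(n_out), x0)] <- 1 - fx
    M[cbind(seq_len(n_out), x0 + 1)] <- M[cbind(seq_len(n_out), x0 + 1)] + fx
    M
  }
  list(R = mk(ih, oh), C = t(mk(iw, ow)))
}

#' Convert every frame of a 64-channel BSP recording to image tensors
#'
#' @param bsp 64-channel bsp_recording (canonical vest order) or 64 x S
#'   matrix
#' @param layout_kind `"1ch"` (6 x 16, resized to 78 x 192 by default) or
#'   `"3ch"` (6 x 4 x 3, resized to 150 x 152 x 3)
#' @param resize integer c(height, width) or NULL to keep the raw grid
#' @param frames integer frame indices (default all)
#' @param normalize normalization mode per tensor
#' @param layout vest_layout
#' @return array (n_frames, H, W, C)
#' @export
tensorize_frames <- function(bsp, layout_kind = c("1ch", "3ch"),
                             resize = NULL, frames = NULL,
                             normalize = "zscore",
                             layout = default_vest_layout()) {
  layout_kind <- match.arg(layout_kind)
  x <- if (inherits(bsp, "bsp_recording")) bsp$potentials else bsp
  if (nrow(x) != 64L) stop_af("expected a 64-channel recording")
  frames <- frames %||% seq_len(ncol(x))
  resize <- resize %||% switch(layout_kind, "1ch" = c(78L, 192L),
                               "3ch" = c(150L, 152L))
  n_ch <- if (layout_kind == "1ch") 1L else 3L
  lop <- .layout_operator(layout_kind, layout)
  rs <- .resize_matrices(lop$dim[1], lop$dim[2], resize[1], resize[2])
  raw <- lop$op %*% x[, frames, drop = FALSE]   # (h*w*ch) x n
  out <- array(0, c(length(frames), resize[1], resize[2], n_ch))
  hw <- lop$dim[1] * lop$dim[2]
  for (i in seq_along(frames)) {
    img <- array(0, c(resize[1], resize[2], n_ch))
    for (c in seq_len(n_ch))
      img[, , c] <- rs$R %*%
        matrix(raw[(c - 1) * hw + seq_len(hw), i], lop$dim[1]) %*% rs$C
    img <- normalize_tensor(img, normalize)
    out[i, , , ] <- img
  }
  out
}
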