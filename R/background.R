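# shift a matrix by (dy, dx), filling exposed cells
shift_matrix <- function(m, dy, dx, fill) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  if (abs(dy) >= n || abs(dx) >= p) return(out)
  ys <- max(1, 1 - dy):min(n, n - dy)
  xs <- max(1, 1 - dx):min(p, p - dx)
  out[ys, xs] <- m[ys + dy, xs + dx]
  out
}

# grayscale erosion/dilation by a non-flat structuring surface given as a
# data.frame of offsets (dy, dx) and heights z
nonflat_erode <- function(m, offs) {
  out <- matrix(Inf, nrow(m), ncol(m))
  for (r in seq_len(nrow(offs)))
    out <- pmin(out, shift_matrix(m, offs$dy[r], offs$dx[r], Inf) - offs$z[r])
  out
}

nonflat_dilate <- function(m, offs) {
  out <- matrix(-Inf, nrow(m), ncol(m))
  for (r in seq_len(nrow(offs)))
    out <- pmax(out, shift_matrix(m, -offs$dy[r], -offs$dx[r], -Inf) + offs$z[r])
  out
}

ball_offsets <- function(radius) {
  h <- ceiling(radius)
  g <- expand.grid(dy = -h:h, dx = -h:h)
  d2 <- g$dy^2 + g$dx^2
  keep <- d2 <= radius^2
  data.frame(dy = g$dy[keep], dx = g$dx[keep],
             z = sqrt(radius^2 - d2[keep]) - radius)
}

# block-min downsample by integer factor s (pads the border by replication);
# min pooling keeps the shrunk surface under the original, so the ball never
# rides above the true background envelope
downsample_min <- function(m, s) {
  n <- ceiling(nrow(m) / s) * s
  p <- ceiling(ncol(m) / s) * s
  mp <- m[c(seq_len(nrow(m)), rep(nrow(m), n - nrow(m))),
          c(seq_len(ncol(m)), rep(ncol(m), p - ncol(m))), drop = FALSE]
  blk <- array(mp, dim = c(s, n / s, s, p / s))
  apply(blk, c(2, 4), min)
}

# bilinear upsample of a downsampled grid back to (n, p); grid cell centres
upsample_bilinear <- function(sm, s, n, p) {
  ys <- (seq_len(n) - 0.5) / s + 0.5
  xs <- (seq_len(p) - 0.5) / s + 0.5
  y0 <- pmin(pmax(floor(ys), 1), nrow(sm) - 1); fy <- pmin(pmax(ys - y0, 0), 1)
  x0 <- pmin(pmax(floor(xs), 1), ncol(sm) - 1); fx <- pmin(pmax(xs - x0, 0), 1)
  a <- sm[y0, x0, drop = FALSE]; b <- sm[y0 + 1, x0, drop = FALSE]
  cc <- sm[y0, x0 + 1, drop = FALSE]; dd <- sm[y0 + 1, x0 + 1, drop = FALSE]
  FY <- matrix(fy, n, p); FX <- matrix(fx, n, p, byrow = TRUE)
  a * (1 - FY) * (1 - FX) + b * FY * (1 - FX) + cc * (1 - FY) * FX +
    dd * FY * FX
}

rolling_ball_background <- function(img, radius) {
  s <- if (radius < 16) 1L else if (radius < 64) 4L else 8L
  work <- if (s > 1L) downsample_min(img, s) else img
  offs <- ball_offsets(radius / s)
  bg <- nonflat_dilate(nonflat_erode(work, offs), offs)
  if (s > 1L) bg <- upsample_bilinear(bg, s, nrow(img), ncol(img))
  pmin(bg, img)
}

# 1D parabolic erosion/dilation applied along rows then columns; the
# paraboloid z = -d^2/(2*radius) is separable into two orthogonal parabolas
parabola_pass <- function(m, radius, dilate = FALSE) {
  w <- min(ceiling(sqrt(2 * radius * max(diff(range(m)), 1e-12))) + 1L,
           max(dim(m)))
  zs <- -(seq(-w, w))^2 / (2 * radius)
  run <- function(mm) {
    out <- matrix(if (dilate) -Inf else Inf, nrow(mm), ncol(mm))
    for (i in seq_along(zs)) {
      d <- i - w - 1L
      if (dilate)
        out <- pmax(out, shift_matrix(mm, -d, 0, -Inf) + zs[i])
      else
        out <- pmin(out, shift_matrix(mm, d, 0, Inf) - zs[i])
    }
    out
  }
  m <- run(m)           # along y
  t(run(t(m)))          # along x
}

sliding_paraboloid_background <- function(img, radius) {
  bg <- parabola_pass(parabola_pass(img, radius, dilate = FALSE),
                      radius, dilate = TRUE)
  pmin(bg, img)
}

#' Morphological background subtraction for fluorescence images
#'
#' Removes smooth background from a 2D image by grayscale opening with a
#' non-flat structuring surface:
#' \describe{
#'   \item{`rolling_ball`}{a ball of the given radius rolled along the
#'     underside of the intensity surface (for large radii the image is
#'     processed at reduced resolution and the background bilinearly
#'     interpolated back, the standard acceleration for this filter).}
#'   \item{`sliding_paraboloid`}{a paraboloid of the given apex curvature
#'     radius, applied as separable one-dimensional parabolic passes along
#'     rows then columns.}
#' }
#' The estimated background (clamped to lie at or below the image) is
#' subtracted; output is >= 0 wherever the input is at or above the
#' background.
#'
#' @param image Numeric matrix.
#' @param method `"rolling_ball"` or `"sliding_paraboloid"`.
#' @param radius Ball radius / paraboloid curvature radius in pixels
#'   (default 50, approximating cell size); must be positive and no larger
#'   than the largest image dimension.
#' @return List with `subtracted` (image minus background) and `background`.
#' @export
subtract_image_background <- function(image,
                                      method = c("rolling_ball",
                                                 "sliding_paraboloid"),
                                      radius = 50) {
  method <- match.arg(method)
  stopifnot(is.matrix(image))
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  if (radius > max(dim(image)))
    stop("radius larger than the image")
  bg <- switch(method,
               rolling_ball = rolling_ball_background(image, radius),
               sliding_paraboloid = sliding_paraboloid_background(image, radius))
  list(subtracted = image - bg, background = bg)
}
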