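# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
# xy minimum-image displacement; z is assumed non-wrapped for a whole bilayer.
min_image_xy <- function(d, box_xy) {
  d[, 1] <- d[, 1] - box_xy[1] * round(d[, 1] / box_xy[1])
  d[, 2] <- d[, 2] - box_xy[2] * round(d[, 2] / box_xy[2])
  d
}

# Minimum distance from each row of `a` (n x 3) to any row of `b` (m x 3),
# with xy minimum-image convention. Used for proximity/contact selections.
min_dist_to_set <- function(a, b, box_xy) {
  n <- nrow(a)
  m <- nrow(b)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  dx <- dx - box_xy[1] * round(dx / box_xy[1])
  dy <- dy - box_xy[2] * round(dy / box_xy[2])
  d2 <- dx * dx + dy * dy + dz * dz
  sqrt(apply(d2, 1, min))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
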