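# Small geometry / numeric helpers shared across modules.
#
# Coordinate conventions: the arena is the 2D range/crossrange plane with
# x = crossrange (m) and y = range (m).  Headings are unit vectors; heading
# angles in degrees are measured counterclockwise from +y, so 0 deg points
# "up range" and +90 deg points to the bat's left (-x).  Azimuths reported
# by the receiver use the opposite (clockwise-positive) sign so that
# positive azimuth means "target to the right of the beam".

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

#' @keywords internal
rotate_ccw <- function(v, deg) {
  a <- deg2rad(deg)
  c(cos(a) * v[1] - sin(a) * v[2],
    sin(a) * v[1] + cos(a) * v[2])
}

# Signed angle (deg, CCW positive) that rotates `from` onto `to`.
signed_angle <- function(from, to) {
  rad2deg(atan2(from[1] * to[2] - from[2] * to[1],
                from[1] * to[1] + from[2] * to[2]))
}

heading_to_vec <- function(deg) c(-sin(deg2rad(deg)), cos(deg2rad(deg)))
vec_to_heading <- function(v) rad2deg(atan2(-v[1], v[2]))

# Rotate `v` toward `target` by at most `max_deg` (both unit vectors).
turn_toward <- function(v, target, max_deg) {
  a <- signed_angle(v, target)
  rotate_ccw(v, sign(a) * min(abs(a), max_deg))
}

# Distance from point p to the segment a--b (used for capture tests so a
# fast-moving agent cannot step over a small capture disk).
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(vec_norm(p - a))
  t <- max(0, min(1, sum((p - a) * ab) / len2))
  vec_norm(p - (a + t * ab))
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
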