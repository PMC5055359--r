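# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. A NULL seed leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a bounded substream seed from a master seed and stream indices, so
# that stack i / stage j always sees the same stream regardless of how many
# other stacks run. Kept below 2^31 - 1.
substream_seed <- function(master, stack = 0L, stage = 0L) {
  as.integer((as.double(master) * 7919 + stack * 1009 + stage * 101) %%
               2147483647)
}

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Any unit vector orthogonal to u (deterministic).
perp_vector <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitize(a - sum(a * u) * u)
}

# Rodrigues rotation of vector v about unit axis k by angle theta (radians).
rotate_about <- function(v, k, theta) {
  v * cos(theta) + pracma_cross(k, v) * sin(theta) +
    k * sum(k * v) * (1 - cos(theta))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Angle in degrees between two 3D vectors, clamped against fp drift.
angle_between <- function(a, b) {
  ca <- sum(a * b) / (vnorm(a) * vnorm(b))
  rad2deg(acos(pmin(1, pmax(-1, ca))))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
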