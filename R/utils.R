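#' @importFrom stats rnorm runif qnorm pnorm dnorm uniroot rbinom sd aggregate
#'   quantile aov anova lm pf var complete.cases
#' @importFrom utils read.csv write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula for the proper rotation of `angle_deg` degrees about
#' the unit vector `axis` (right-hand rule).
#'
#' @param axis numeric length-3 axis (normalised internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  a <- as.numeric(axis)
  n <- sqrt(sum(a^2))
  if (n < 1e-12) stop("rotation axis has zero length")
  a <- a / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotate points about an axis through a point
#'
#' @param pts n x 3 matrix of points.
#' @param center point on the rotation axis.
#' @param axis axis direction.
#' @param angle_deg angle in degrees.
#' @return rotated n x 3 matrix.
#' @export
rotate_points <- function(pts, center, axis, angle_deg) {
  R <- rotation_about_axis(axis, angle_deg)
  pts <- as.matrix(pts)
  ctr <- matrix(center, nrow(pts), 3, byrow = TRUE)
  (pts - ctr) %*% t(R) + ctr
}

# Independent per-unit RNG streams: adding patients must never perturb the
# draws of existing ones, so each unit gets its own seed derived from the
# master seed.  Kept below 2^31 (R integers are 32-bit).
derive_seed <- function(master, index, salt = 0L) {
  x <- (as.numeric(master) * 48271 + as.numeric(index) * 16807 +
          as.numeric(salt) * 69621) %% 2147483647
  as.integer(max(1, x))
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Mean of N(mu, sd) truncated to [lo, hi]
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  Z <- pnorm(b) - pnorm(a)
  mu + sd * (dnorm(a) - dnorm(b)) / Z
}

# Location parameter such that the [lo, hi]-truncated normal with the given
# sd has mean `target` (the printed cohort means are means of the realised,
# i.e. range-limited, sample).
truncnorm_mu_for_mean <- function(target, sd, lo, hi) {
  f <- function(mu) truncnorm_mean(mu, sd, lo, hi) - target
  uniroot(f, lower = lo - 3 * sd, upper = hi + 3 * sd, tol = 1e-10)$root
}

# Inverse-CDF truncated-normal sampler (n draws)
rtruncnorm <- function(n, mu, sd, lo, hi) {
  if (sd <= 0) return(rep(pmin(pmax(mu, lo), hi), n))
  u <- runif(n, pnorm(lo, mu, sd), pnorm(hi, mu, sd))
  qnorm(u, mu, sd)
}
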