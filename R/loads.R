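# Physiological activity load schedule and landmark-based registration.
#
# The default template is a synthetic 15-step schedule (3 activities x 5
# instances: fast walking, chair rise, squat) of joint-contact and
# patellar-tendon forces expressed per unit body weight in the template
# frame; chair rise and squat carry higher resultants than fast walking.
# Templates are plain CSV and fully user-replaceable.  Registration to a
# patient is a similarity transform (scale, rotation, translation) fitted
# to the five planning landmarks by least squares (Umeyama's closed
# form); forces are rotated but never scaled by the transform -- only
# body weight scales them.

#' Read an activity load table
#'
#' @param table_csv CSV with columns step, activity, instance,
#'   point_name, fx, fy, fz (forces per unit body weight).
#' @param points_csv CSV with columns point_name, x, y, z (template
#'   frame, mm).
#' @param landmarks_csv CSV of the five template landmarks (name,x,y,z).
#' @return object of class `activity_load_table`.
#' @export
read_load_table <- function(table_csv, points_csv, landmarks_csv) {
  tb <- read.csv(table_csv, stringsAsFactors = FALSE)
  need <- c("step", "activity", "instance", "point_name", "fx", "fy", "fz")
  if (!all(need %in% names(tb)))
    stop("parse error in ", table_csv, " line 1: need columns ",
         paste(need, collapse = ","))
  pts <- read.csv(points_csv, stringsAsFactors = FALSE)
  lm <- read.csv(landmarks_csv, stringsAsFactors = FALSE)
  lms <- landmark_set(
    hip_center = unlist(lm[lm$name == "hip_center", c("x", "y", "z")]),
    knee_center = unlist(lm[lm$name == "knee_center", c("x", "y", "z")]),
    plateau_medial = unlist(lm[lm$name == "plateau_medial",
                               c("x", "y", "z")]),
    plateau_lateral = unlist(lm[lm$name == "plateau_lateral",
                                c("x", "y", "z")]),
    ankle_center = unlist(lm[lm$name == "ankle_center", c("x", "y", "z")]))
  out <- structure(list(table = tb, points = pts, landmarks = lms),
                   class = "activity_load_table")
  validate_load_table(out)
  out
}

#' Default (installed) activity load table
#' @return an `activity_load_table`.
#' @export
default_load_table <- function() {
  d <- system.file("extdata", package = "osteotrial")
  read_load_table(file.path(d, "loads_template.csv"),
                  file.path(d, "loads_points.csv"),
                  file.path(d, "template_landmarks.csv"))
}

validate_load_table <- function(lt) {
  tb <- lt$table
  steps <- sort(unique(tb$step))
  if (!identical(steps, 1:15))
    stop("load table must define exactly load steps 1..15")
  per <- table(unique(tb[, c("activity", "instance")])$activity)
  if (!all(per == 5))
    stop("each activity must have exactly 5 instances")
  if (!all(tb$point_name %in% lt$points$point_name))
    stop("load table references unknown application points")
  res <- resultant_by_step(lt)
  m <- tapply(res$magnitude, res$activity, mean)
  if (!(m["ACT2"] > m["ACT1"] && m["ACT3"] > m["ACT1"]))
    warning("expected chair-rise/squat resultants to exceed fast walking")
  invisible(lt)
}

resultant_by_step <- function(lt) {
  tb <- lt$table
  tb$norm <- sqrt(tb$fx^2 + tb$fy^2 + tb$fz^2)
  agg <- aggregate(list(magnitude = tb$norm),
                   by = list(step = tb$step, activity = tb$activity), sum)
  agg[order(agg$step), ]
}

#' Fit a similarity transform between landmark sets
#'
#' Minimises sum ||s R x_i + t - y_i||^2 over scale s > 0, proper
#' rotation R and translation t (Umeyama's closed-form solution).
#'
#' @param source,target `landmark_set` objects (or n x 3 matrices with
#'   matching row order), n >= 3 and non-collinear.
#' @return list with `s`, `R`, `t`, and the RMS `residual`.
#' @export
fit_similarity <- function(source, target) {
  X <- as.matrix(unclass(source)); Y <- as.matrix(unclass(target))
  stopifnot(nrow(X) == nrow(Y), ncol(X) == 3)
  n <- nrow(X)
  if (n < 3) stop("rank-deficiency error: need at least 3 landmarks")
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  sv_x <- svd(Xc)$d
  if (sv_x[2] < 1e-9 * max(sv_x[1], 1))
    stop("rank-deficiency error: landmarks are collinear")
  S <- crossprod(Yc, Xc) / n          # covariance, 3 x 3
  sv <- svd(S)
  d <- sign(det(sv$u) * det(sv$v))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  var_x <- sum(Xc^2) / n
  s <- sum(sv$d * diag(D)) / var_x
  t <- my - s * as.numeric(R %*% mx)
  fitted <- s * X %*% t(R) + matrix(t, n, 3, byrow = TRUE)
  list(s = s, R = R, t = t,
       residual = sqrt(mean(rowSums((fitted - Y)^2))))
}

#' Scale template forces by body weight
#'
#' Template forces are per unit body weight; each force vector is
#' multiplied by `mass_kg * g` (g = 9.81 m/s^2) to give Newtons.
#'
#' @param lt an `activity_load_table`.
#' @param mass_kg body mass (> 0).
#' @return the table with forces in N (class unchanged).
#' @export
scale_loads <- function(lt, mass_kg) {
  if (!is.numeric(mass_kg) || mass_kg <= 0)
    stop("input error: mass must be positive")
  lt$table[, c("fx", "fy", "fz")] <-
    lt$table[, c("fx", "fy", "fz")] * (mass_kg * 9.81)
  lt$scaled_N <- TRUE
  lt
}

#' Register a load table into a patient frame
#'
#' Application points map through `s R x + t`; force directions rotate
#' with R only (magnitudes are preserved by the registration).
#'
#' @param lt an `activity_load_table`.
#' @param transform a [fit_similarity()] result.
#' @return the registered table.
#' @export
register_loads <- function(lt, transform) {
  P <- as.matrix(lt$points[, c("x", "y", "z")])
  P2 <- transform$s * P %*% t(transform$R) +
    matrix(transform$t, nrow(P), 3, byrow = TRUE)
  lt$points[, c("x", "y", "z")] <- P2
  F <- as.matrix(lt$table[, c("fx", "fy", "fz")])
  lt$table[, c("fx", "fy", "fz")] <- F %*% t(transform$R)
  lt
}

#' Register and scale the template loads for one patient
#'
#' @param lt template `activity_load_table`.
#' @param landmarks patient `landmark_set`.
#' @param mass_kg patient body mass.
#' @return registered, body-weight-scaled table (forces in N).
#' @export
patient_loads <- function(lt, landmarks, mass_kg) {
  tr <- fit_similarity(lt$landmarks, landmarks)
  register_loads(scale_loads(lt, mass_kg), tr)
}
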