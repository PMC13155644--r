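#' Reduced sagittal-plane musculoskeletal model
#'
#' A desk-scale stand-in for a full 3D lower-limb model: three sagittal
#' joints (hip, knee, ankle) actuated by eight lumped muscle groups with
#' constant moment arms, rigid tendons, a Gaussian active force-length
#' curve and an exponential passive curve. Normalized fiber length is
#' driven by joint-angle excursion,
#' `l = 1 - sum_j r_mj (theta_j - theta_ref_j) / l_opt`.
#'
#' Sign conventions (also used by the synthetic generator): hip flexion,
#' knee extension and ankle plantarflexion are positive, for both angles
#' and moments. A positive moment arm therefore means the muscle produces
#' a positive moment and shortens as the angle increases.
#'
#' @param body_mass Body mass in kg.
#' @param height Height in m.
#' @param w_res Reserve-actuator cost weight (>= 100); reserves guarantee
#'   feasibility, and frames where a reserve exceeds 5% of the joint moment
#'   are flagged.
#' @param muscles Optional replacement muscle table (see
#'   [default_muscle_table()]).
#' @return Object of class `msk_model`.
#' @export
msk_model <- function(body_mass, height, w_res = 1000,
                      muscles = default_muscle_table()) {
  stopifnot(body_mass > 0, height > 0)
  if (w_res < 100) stop("`w_res` must be >= 100")
  req <- c("name", "f_max", "r_hip", "r_knee", "r_ankle", "l_opt", "c_knee")
  if (!all(req %in% names(muscles))) stop("malformed muscle table")
  if (any(muscles$f_max <= 0)) stop("F_max must be > 0")
  arms <- as.matrix(muscles[, c("r_hip", "r_knee", "r_ankle")])
  if (any(abs(arms) > 0.1)) stop("moment arms must satisfy |r| <= 0.1 m")
  if (any(muscles$c_knee < 0 | muscles$c_knee > 1))
    stop("knee axial projection c must lie in [0, 1]")
  spanned <- colSums(arms != 0)
  if (any(spanned < 2)) stop("every joint must be spanned by >= 2 muscles")
  structure(list(muscles = muscles,
                 joints = c("hip", "knee", "ankle"),
                 theta_ref = c(hip = 0, knee = 0, ankle = 0),
                 w_res = w_res,
                 body_mass = body_mass, height = height),
            class = "msk_model")
}

#' Default muscle parameter table
#'
#' Eight lumped muscle groups. Values are order-of-magnitude physiological
#' (maximum isometric forces in N, moment arms in m, optimal fiber lengths
#' in m) chosen so that baseline walking produces a two-humped knee contact
#' force of roughly 2-3 body weights. `c_knee` is the axial (tibia-aligned)
#' projection coefficient of each knee-spanning muscle's force.
#'
#' @return data.frame with one row per muscle.
#' @export
default_muscle_table <- function() {
  data.frame(
    name   = c("gluteals", "iliopsoas", "hamstrings", "rectus_femoris",
               "vasti", "gastrocnemius", "soleus", "tibialis_anterior"),
    f_max  = c(3000, 2000, 2800, 1200, 5000, 2200, 3500, 1000),
    r_hip  = c(-0.060, 0.050, -0.050, 0.040, 0, 0, 0, 0),
    r_knee = c(0, 0, -0.035, 0.040, 0.042, -0.020, 0, 0),
    r_ankle = c(0, 0, 0, 0, 0, 0.045, 0.040, -0.035),
    l_opt  = c(0.15, 0.12, 0.11, 0.10, 0.09, 0.06, 0.05, 0.07),
    c_knee = c(0, 0, 0.60, 0.70, 0.75, 0.90, 0, 0)
  )
}

# Active force-length: unimodal Gaussian, f_L(1) = 1.
active_fl <- function(lnorm, width = 0.45) exp(-(lnorm - 1)^2 / width)

# Passive force-length: zero at or below optimal length, exponential above.
passive_fl <- function(lnorm, k_pe = 4, e0 = 0.6) {
  ifelse(lnorm > 1,
         (exp(k_pe * (lnorm - 1) / e0) - 1) / (exp(k_pe) - 1),
         0)
}

# Normalized fiber lengths for all muscles at one frame.
# angles_deg: named (hip, knee, ankle) joint angles in degrees.
fiber_lengths <- function(model, angles_deg) {
  th <- (angles_deg[model$joints] - model$theta_ref[model$joints]) * pi / 180
  arms <- as.matrix(model$muscles[, c("r_hip", "r_knee", "r_ankle")])
  1 - as.numeric(arms %*% th) / model$muscles$l_opt
}

#' Hill-type muscle force (rigid tendon, quasi-static)
#'
#' `F = F_max * (a * f_L(l) + f_P(l))` with a Gaussian active force-length
#' curve and an exponential passive curve; force-velocity effects are
#' omitted (each frame is treated as quasi-static).
#'
#' @param f_max Maximum isometric force in N.
#' @param a Activation in `[0, 1]`.
#' @param lnorm Normalized fiber length.
#' @return Muscle force in N.
#' @export
muscle_force <- function(f_max, a, lnorm) {
  if (any(a < -1e-9 | a > 1 + 1e-9)) stop("activation outside [0, 1]")
  f_max * (pmin(pmax(a, 0), 1) * active_fl(lnorm) + passive_fl(lnorm))
}

# ---- per-frame box-constrained quadratic program ------------------------

# Primal active-set solver for min 0.5 a'H a + g'a, lo <= a <= hi,
# H symmetric positive definite. Feasible iterates; single add/drop per
# iteration. Deterministic.
solve_box_qp <- function(H, g, lo, hi, maxit = 400L) {
  n <- length(g)
  if (any(lo > hi + 1e-12)) stop("empty constraint box (lo > hi)")
  fixed <- (hi - lo) < 1e-14
  a <- pmin(pmax(rep(0, n), lo), hi)
  state <- integer(n)                       # -1 at lo, +1 at hi, 0 free
  state[a <= lo + 1e-14] <- -1L
  state[a >= hi - 1e-14] <- 1L
  # release tolerance: far above linear-solve noise (~1e-9 relative) but
  # far below any practically meaningful multiplier
  tolg <- max(1e-9, 1e-12 * max(abs(H), abs(g)))
  for (it in seq_len(maxit)) {
    state[fixed] <- -1L
    free <- which(state == 0L)
    a[state == -1L] <- lo[state == -1L]
    a[state == 1L] <- hi[state == 1L]
    cand <- a
    if (length(free)) {
      rhs <- -g[free] - H[free, -free, drop = FALSE] %*% a[-free]
      if (length(free) == n) rhs <- -g[free]
      cand[free] <- solve(H[free, free, drop = FALSE], rhs)
    }
    viol_lo <- free[cand[free] < lo[free] - 1e-14]
    viol_hi <- free[cand[free] > hi[free] + 1e-14]
    if (length(viol_lo) || length(viol_hi)) {
      # step toward candidate until the first blocking bound
      d <- cand - a
      alpha <- 1
      block <- NA_integer_; bstate <- 0L
      for (i in free) {
        if (d[i] < -1e-16) {
          s <- (lo[i] - a[i]) / d[i]
          if (s < alpha) { alpha <- s; block <- i; bstate <- -1L }
        } else if (d[i] > 1e-16) {
          s <- (hi[i] - a[i]) / d[i]
          if (s < alpha) { alpha <- s; block <- i; bstate <- 1L }
        }
      }
      a <- a + alpha * d
      if (!is.na(block)) {
        state[block] <- bstate
        a[block] <- if (bstate < 0) lo[block] else hi[block]
      }
      next
    }
    a <- cand
    grad <- as.numeric(H %*% a + g)
    rel_lo <- which(state == -1L & !fixed & grad < -tolg)
    rel_hi <- which(state == 1L & !fixed & grad > tolg)
    if (length(rel_lo) == 0L && length(rel_hi) == 0L) return(a)
    worst <- c(rel_lo, rel_hi)[which.max(abs(grad[c(rel_lo, rel_hi)]))]
    state[worst] <- 0L
  }
  stop("box-QP active-set solver failed to converge")
}

# Assemble and solve the per-frame static-optimization QP.
# Returns list(a, forces, reserves, objective).
solve_frame <- function(model, moments_j, lnorm, lo, hi) {
  mus <- model$muscles
  arms <- as.matrix(mus[, c("r_hip", "r_knee", "r_ankle")])
  fl <- active_fl(lnorm)
  fp <- passive_fl(lnorm)
  # K[m, j] = r_mj * F_max_m * f_L_m : moment produced per unit activation
  K <- arms * (mus$f_max * fl)
  m_eff <- moments_j - as.numeric(t(arms) %*% (mus$f_max * fp))
  w <- model$w_res
  H <- 2 * diag(nrow(mus)) + 2 * w * (K %*% t(K))
  g <- -2 * w * as.numeric(K %*% m_eff)
  a <- solve_box_qp(H, g, lo, hi)
  forces <- muscle_force(mus$f_max, a, lnorm)
  reserves <- moments_j - as.numeric(t(arms) %*% forces)
  obj <- sum(a^2) + w * sum(reserves^2)
  list(a = a, forces = forces, reserves = reserves, objective = obj)
}

#' Activation-squared static optimization over a stance curve
#'
#' Per frame, solves
#' `min sum_m a_m^2 + w_res * sum_j rho_j^2` subject to the sagittal moment
#' balance `sum_m r_mj F_m(a_m) + rho_j = M_j`, activation bounds
#' `0 <= a <= 1` and, optionally, per-frame EMG box constraints. With the
#' reserve moments `rho` eliminated, each frame is a strictly convex
#' box-constrained quadratic program solved exactly by an active-set
#' method.
#'
#' @param model A [msk_model()].
#' @param moments Matrix (frames x 3) of joint moments in N·m, columns
#'   `hip`, `knee`, `ankle`.
#' @param angles Matrix (frames x 3) of joint angles in degrees, same
#'   columns.
#' @param emg_constraints Optional named list, muscle name ->
#'   `list(lo = , hi = )` per-frame activation bounds (from
#'   [build_emg_constraints()]).
#' @return Object of class `so_solution`: `activations`, `forces`,
#'   `reserves` (all per frame), `objective`, and `flagged_frames` where a
#'   reserve moment exceeds 5% of the corresponding joint moment.
#' @export
solve_static_optimization <- function(model, moments, angles,
                                      emg_constraints = NULL) {
  stopifnot(inherits(model, "msk_model"))
  moments <- as.matrix(moments); angles <- as.matrix(angles)
  if (!all(model$joints %in% colnames(moments)) ||
      !all(model$joints %in% colnames(angles)))
    stop("moments and angles need columns hip, knee, ankle")
  if (nrow(moments) != nrow(angles))
    stop("moments and angles must share the stance grid")
  nf <- nrow(moments)
  nm <- nrow(model$muscles)
  lo_all <- matrix(0, nf, nm); hi_all <- matrix(1, nf, nm)
  if (!is.null(emg_constraints)) {
    for (mu in names(emg_constraints)) {
      i <- match(mu, model$muscles$name)
      if (is.na(i)) stop("unknown muscle in constraints: ", mu)
      cc <- emg_constraints[[mu]]
      if (any(cc$lo > cc$hi + 1e-12))
        stop("empty constraint box for ", mu)
      lo_all[, i] <- cc$lo; hi_all[, i] <- cc$hi
    }
  }
  act <- matrix(NA_real_, nf, nm, dimnames = list(NULL, model$muscles$name))
  forces <- act
  res <- matrix(NA_real_, nf, 3, dimnames = list(NULL, model$joints))
  obj <- numeric(nf)
  for (f in seq_len(nf)) {
    ln <- fiber_lengths(model, angles[f, model$joints])
    sol <- tryCatch(
      solve_frame(model, moments[f, model$joints], ln, lo_all[f, ], hi_all[f, ]),
      error = function(e) stop("static optimization failed at frame ", f,
                               ": ", conditionMessage(e)))
    act[f, ] <- sol$a; forces[f, ] <- sol$forces
    res[f, ] <- sol$reserves; obj[f] <- sol$objective
  }
  flagged <- which(rowSums(abs(res) > 0.05 * pmax(abs(moments[, model$joints]), 1)) > 0)
  structure(list(activations = act, forces = forces, reserves = res,
                 objective = obj, flagged_frames = flagged),
            class = "so_solution")
}

#' EMG-to-activation scale factor from baseline representative steps
#'
#' For each of the five baseline representative steps, the ratio of the
#' stance-mean static-optimization activation to the stance-mean delayed
#' EMG; the factor is the mean of the five ratios.
#'
#' @param activation_means Stance-mean activations, one per step.
#' @param emg_means Stance-mean delayed normalized EMG, one per step (> 0).
#' @return Scalar scale factor.
#' @export
emg_scale_factor <- function(activation_means, emg_means) {
  if (length(activation_means) != length(emg_means))
    stop("need one EMG mean per activation mean")
  if (any(emg_means <= 0)) stop("zero stance-mean EMG in a representative step")
  mean(activation_means / emg_means)
}

#' Per-frame activation bounds from scaled EMG
#'
#' The feedback-trial gastrocnemius activation is constrained to follow the
#' measured (delayed, normalized) EMG scaled by the baseline-calibrated
#' factor, within a relative tolerance band, intersected with `[0, 1]`.
#'
#' @param emg Delayed normalized EMG on the stance grid.
#' @param factor Scale factor (> 0) from [emg_scale_factor()].
#' @param tolerance Relative half-width of the band (default 0.02).
#' @return `list(lo, hi)` per-frame bounds.
#' @export
build_emg_constraints <- function(emg, factor, tolerance = 0.02) {
  if (factor <= 0) stop("`factor` must be > 0")
  target <- factor * emg
  lo <- (1 - tolerance) * target
  hi <- (1 + tolerance) * target
  if (any(lo > 1)) {
    warning("scaled EMG target exceeds activation ceiling; clamping to 1")
    lo <- pmin(lo, 1)
  }
  hi <- pmin(hi, 1)
  lo <- pmax(pmin(lo, hi), 0)
  list(lo = lo, hi = hi)
}

#' Axial knee contact force from a static-optimization solution
#'
#' Joint-reaction superposition along the tibia's longitudinal axis: the
#' intersegmental axial force plus each knee-spanning muscle's axial force
#' component, normalized to body weights.
#'
#' @param model A [msk_model()].
#' @param sol An `so_solution` on the stance grid.
#' @param intersegmental_axial Intersegmental axial knee force in N, same
#'   grid.
#' @param body_mass Body mass in kg.
#' @param stance_duration Stance time in s (stored on the returned curve).
#' @param grid Percent-stance grid (default `seq(0, 100, length.out = nf)`).
#' @return Object of class `contact_curve`: `bw` (force in body weights),
#'   `grid` (percent stance), `stance_duration`.
#' @export
knee_contact_force <- function(model, sol, intersegmental_axial, body_mass,
                               stance_duration = NA_real_, grid = NULL) {
  nf <- nrow(sol$forces)
  if (length(intersegmental_axial) != nf)
    stop("intersegmental force grid (", length(intersegmental_axial),
         ") does not match solution grid (", nf, ")")
  cvec <- model$muscles$c_knee
  muscle_axial <- as.numeric(sol$forces %*% cvec)
  bw <- (intersegmental_axial + muscle_axial) / (body_mass * 9.81)
  if (is.null(grid)) grid <- seq(0, 100, length.out = nf)
  structure(list(bw = bw, grid = grid, stance_duration = stance_duration),
            class = "contact_curve")
}

#' Early- and late-stance contact force peaks
#'
#' Maximum contact force over 15-35% and 65-85% of stance (inclusive grid
#' endpoints), accommodating timing variation around the typical 25% and
#' 75% peaks.
#'
#' @param curve A `contact_curve`.
#' @return Named numeric: `early_peak`, `late_peak` (BW).
#' @export
peak_metrics <- function(curve) {
  g <- curve$grid
  c(early_peak = max(curve$bw[g >= 15 & g <= 35]),
    late_peak  = max(curve$bw[g >= 65 & g <= 85]))
}

#' Knee contact force impulse over stance
#'
#' Trapezoidal integral of the contact force (BW) over stance time (s).
#'
#' @param curve A `contact_curve` with a finite `stance_duration`.
#' @return Impulse in BW·s.
#' @export
contact_impulse <- function(curve) {
  dur <- curve$stance_duration
  if (!is.finite(dur) || dur <= 0) stop("positive stance duration required")
  t <- curve$grid / 100 * dur
  sum(diff(t) * (utils::head(curve$bw, -1) + utils::tail(curve$bw, -1)) / 2)
}

#' Extrema of the first and second halves of stance
#'
#' For a curve on a percent-stance grid, returns the configured extremum
#' (max or min) over `[0, 50]%` and `(50, 100]%`.
#'
#' @param values Curve values on the grid.
#' @param grid Percent-stance grid covering 0-100.
#' @param sense Length-2 character, extremum sense for each half
#'   (`"max"`/`"min"`).
#' @return Named numeric: `first_half`, `second_half`.
#' @export
stance_half_extrema <- function(values, grid = seq(0, 100, length.out = length(values)),
                                sense = c("max", "max")) {
  f <- function(x, s) if (s == "min") min(x) else max(x)
  c(first_half = f(values[grid <= 50], sense[1]),
    second_half = f(values[grid > 50], sense[2]))
}
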