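test_that("muscle_force follows the Hill-type active+passive structure", {
  expect_equal(muscle_force(1000, 0.5, 1), 500)
  expect_equal(gaitretrain:::active_fl(1), 1)
  expect_equal(gaitretrain:::passive_fl(0.9), 0)
  expect_equal(gaitretrain:::passive_fl(1), 0)
  # passive force adds at zero activation
  expect_equal(muscle_force(1000, 0, 1.2),
               1000 * gaitretrain:::passive_fl(1.2))
  expect_gt(muscle_force(1000, 0, 1.2), 0)
  # passive curve is monotone above optimal length
  l <- seq(1, 1.6, by = 0.05)
  expect_true(all(diff(gaitretrain:::passive_fl(l)) >= 0))
  # active curve is unimodal with its peak at optimal length
  la <- seq(0.5, 1.5, by = 0.01)
  expect_equal(la[which.max(gaitretrain:::active_fl(la))], 1)
  expect_error(muscle_force(1000, 1.2, 1), "outside")
})

test_that("single-muscle frame recovers the closed form a = M / (r F_max)", {
  m <- toy_model(knee_muscle("solo", 1000, 0.05))
  sol <- gaitretrain:::solve_frame(m, c(0, 25, 0), lnorm = 1,
                                   lo = 0, hi = 1)
  expect_equal(sol$a, 0.5, tolerance = 1e-4)
  expect_equal(sol$forces, 500, tolerance = 0.1)
})

test_that("two identical agonists share the load equally", {
  m <- toy_model(rbind(knee_muscle("a1", 1000, 0.05),
                       knee_muscle("a2", 1000, 0.05)))
  sol <- gaitretrain:::solve_frame(m, c(0, 25, 0), lnorm = c(1, 1),
                                   lo = c(0, 0), hi = c(1, 1))
  expect_equal(sol$a[1], sol$a[2], tolerance = 1e-9)
  expect_equal(sol$a[1], 0.25, tolerance = 1e-4)
})

test_that("EMG-constrained toy frame matches the KKT oracle to 1e-6", {
  # gastrocnemius box-constrained with a redundant soleus available: a small
  # well-conditioned frame where the enumeration oracle is exact
  mus <- rbind(
    data.frame(name = "gastrocnemius", f_max = 2200, r_hip = 0, r_knee = -0.02,
               r_ankle = 0.045, l_opt = 0.06, c_knee = 0.9),
    data.frame(name = "soleus", f_max = 3500, r_hip = 0, r_knee = 0,
               r_ankle = 0.040, l_opt = 0.05, c_knee = 0),
    data.frame(name = "hamstrings", f_max = 2800, r_hip = -0.05,
               r_knee = -0.035, r_ankle = 0, l_opt = 0.11, c_knee = 0.6))
  m <- toy_model(mus)
  lo <- c(0.294, 0, 0); hi <- c(0.306, 1, 1)
  sol <- gaitretrain:::solve_frame(m, c(-15, -20, 90), lnorm = c(1, 1, 1),
                                   lo = lo, hi = hi)
  qp <- frame_qp(m, c(-15, -20, 90), c(1, 1, 1))
  ora <- oracle_box_qp(qp$H, qp$g, lo, hi)
  expect_equal(sol$a, ora$a, tolerance = 1e-6)
  expect_equal(sol$a[1], 0.294, tolerance = 1e-9)  # bound is active here
})

test_that("full-model frames match the exhaustive KKT oracle", {
  # the 8-muscle QP is nearly flat along some recruitment directions
  # (objective ~1e7, differences below double resolution at that scale), so
  # activations agree to 5e-3 and objectives to 1e-6 relative
  model <- msk_model(75, 1.7)
  ang <- matrix(c(5, -12, -6), 1, 3,
                dimnames = list(NULL, c("hip", "knee", "ankle")))
  mom <- matrix(c(-20, 28, 85), 1, 3,
                dimnames = list(NULL, c("hip", "knee", "ankle")))
  obj <- function(qp, a) 0.5 * sum(a * (qp$H %*% a)) + sum(qp$g * a)
  for (cons in list(NULL,
                    list(gastrocnemius = list(lo = 0.294, hi = 0.306)),
                    list(gastrocnemius = list(lo = 0, hi = 0.05)))) {
    sol <- solve_static_optimization(model, mom, ang, cons)
    lnorm <- gaitretrain:::fiber_lengths(model, ang[1, ])
    qp <- frame_qp(model, mom[1, ], lnorm)
    lo <- rep(0, 8); hi <- rep(1, 8)
    if (!is.null(cons)) {
      i <- match("gastrocnemius", model$muscles$name)
      lo[i] <- cons$gastrocnemius$lo; hi[i] <- cons$gastrocnemius$hi
    }
    ora <- oracle_box_qp(qp$H, qp$g, lo, hi)
    a_pkg <- as.numeric(sol$activations[1, ])
    expect_equal(a_pkg, ora$a, tolerance = 5e-3)
    denom <- max(1, abs(ora$value))
    expect_lt((obj(qp, a_pkg) - ora$value) / denom, 1e-6)
  }
})

test_that("two-muscle frame matches a 1e-3 grid search within 2e-3", {
  m <- toy_model(rbind(knee_muscle("big", 1500, 0.04),
                       knee_muscle("small", 600, 0.05)))
  sol <- gaitretrain:::solve_frame(m, c(0, 30, 0), lnorm = c(1, 1),
                                   lo = c(0, 0), hi = c(1, 1))
  qp <- frame_qp(m, c(0, 30, 0), c(1, 1))
  grid <- oracle_grid_qp(qp$H, qp$g, c(0, 0), c(1, 1), step = 1e-3)
  expect_lt(max(abs(sol$a - grid)), 2e-3)
})

test_that("tightening the gastrocnemius bound is monotone (KKT)", {
  model <- msk_model(75, 1.7)
  ang <- matrix(0, 1, 3, dimnames = list(NULL, c("hip", "knee", "ankle")))
  mom <- matrix(c(0, -15, 90), 1, 3,
                dimnames = list(NULL, c("hip", "knee", "ankle")))
  free <- solve_static_optimization(model, mom, ang)
  a0 <- free$activations[1, "gastrocnemius"]
  expect_gt(a0, 0.1)
  prev_force <- free$forces[1, "gastrocnemius"]
  prev_obj <- free$objective[1]
  for (ub in c(0.8, 0.6, 0.4, 0.2, 0.1) * a0) {
    sol <- solve_static_optimization(
      model, mom, ang, list(gastrocnemius = list(lo = 0, hi = ub)))
    expect_lte(sol$forces[1, "gastrocnemius"], prev_force + 1e-8)
    expect_gte(sol$objective[1], prev_obj - 1e-8)
    prev_force <- sol$forces[1, "gastrocnemius"]
    prev_obj <- sol$objective[1]
  }
})

test_that("moment balance holds with reserves included, and reserves vanish
           for a feasible problem as their weight grows", {
  model <- msk_model(75, 1.7, w_res = 1e8)
  ang <- matrix(c(10, -15, -5), 1, 3,
                dimnames = list(NULL, c("hip", "knee", "ankle")))
  mom <- matrix(c(-30, 25, 70), 1, 3,
                dimnames = list(NULL, c("hip", "knee", "ankle")))
  sol <- solve_static_optimization(model, mom, ang)
  arms <- as.matrix(model$muscles[, c("r_hip", "r_knee", "r_ankle")])
  residual <- mom[1, ] - as.numeric(t(arms) %*% sol$forces[1, ])
  # identity: residual is exactly the reserve moment
  expect_equal(residual, sol$reserves[1, ], tolerance = 1e-9,
               ignore_attr = TRUE)
  # and for this feasible load the reserves themselves are negligible
  expect_lt(max(abs(sol$reserves[1, ])), 1e-6)
})

test_that("constraint plumbing: scale factor and EMG bounds", {
  expect_equal(emg_scale_factor(c(0.4, 0.5, 0.45, 0.5, 0.4),
                                c(0.2, 0.25, 0.225, 0.25, 0.2)), 2)
  expect_equal(emg_scale_factor(1:5, rep(1, 5)), 3)
  expect_error(emg_scale_factor(1:5, c(1, 1, 0, 1, 1)), "zero stance-mean")

  b <- build_emg_constraints(0.3, 1)
  expect_equal(b$lo, 0.294)
  expect_equal(b$hi, 0.306)
  z <- build_emg_constraints(0, 1)
  expect_equal(c(z$lo, z$hi), c(0, 0))
  expect_warning(b2 <- build_emg_constraints(1.05, 1), "clamping")
  expect_equal(b2$hi, 1)
  expect_lte(b2$lo, b2$hi)
  expect_error(build_emg_constraints(0.3, 0), "> 0")
})

test_that("knee contact force is the normalized axial superposition", {
  model <- msk_model(71.36, 1.7)
  nm <- nrow(model$muscles)
  zero_sol <- structure(list(forces = matrix(0, 5, nm,
                             dimnames = list(NULL, model$muscles$name))),
                        class = "so_solution")
  flat <- knee_contact_force(model, zero_sol, rep(700, 5), 71.36)
  expect_equal(flat$bw, rep(700 / (71.36 * 9.81), 5))

  one <- zero_sol
  one$forces[, "gastrocnemius"] <- 500   # c = 0.9
  curve <- knee_contact_force(model, one, rep(700, 5), 71.36)
  expect_equal(curve$bw, rep((700 + 450) / (71.36 * 9.81), 5))

  # a non-knee-spanning muscle (c = 0) changes nothing
  sol2 <- zero_sol
  sol2$forces[, "soleus"] <- 2000
  expect_equal(knee_contact_force(model, sol2, rep(700, 5), 71.36)$bw, flat$bw)

  # linear superposition in muscle forces and intersegmental force
  set.seed(2)
  fA <- matrix(runif(5 * nm, 0, 800), 5, nm,
               dimnames = list(NULL, model$muscles$name))
  fB <- matrix(runif(5 * nm, 0, 800), 5, nm,
               dimnames = list(NULL, model$muscles$name))
  iA <- runif(5, 400, 900); iB <- runif(5, 400, 900)
  cf <- function(f, i) knee_contact_force(model,
    structure(list(forces = f), class = "so_solution"), i, 71.36)$bw
  expect_equal(cf(fA + fB, iA + iB), cf(fA, iA) + cf(fB, iB),
               tolerance = 1e-12)
  expect_error(knee_contact_force(model, zero_sol, rep(700, 4), 71.36),
               "grid")
})

test_that("peak windows, impulse and half-stance extrema", {
  g <- seq(0, 100, length.out = 101)
  hump <- 2 * gaitretrain:::bump(g / 100, 0.25, 0.1) +
    2.5 * gaitretrain:::bump(g / 100, 0.75, 0.1)
  curve <- structure(list(bw = hump, grid = g, stance_duration = 0.6),
                     class = "contact_curve")
  pk <- peak_metrics(curve)
  expect_equal(pk[["early_peak"]], max(hump[g >= 15 & g <= 35]))
  expect_equal(pk[["late_peak"]], max(hump[g >= 65 & g <= 85]))
  expect_equal(pk[["late_peak"]], 2.5, tolerance = 1e-4)
  # a global maximum at 50% is ignored by both windows
  spike <- structure(list(bw = 5 * gaitretrain:::bump(g / 100, 0.5, 0.02),
                          grid = g, stance_duration = 0.6),
                     class = "contact_curve")
  expect_lt(max(peak_metrics(spike)), 1)
  const <- structure(list(bw = rep(2, 101), grid = g, stance_duration = 0.6),
                     class = "contact_curve")
  expect_equal(peak_metrics(const), c(early_peak = 2, late_peak = 2))

  expect_equal(contact_impulse(const) / 2, 0.6)
  expect_equal(contact_impulse(structure(list(bw = rep(0, 101), grid = g,
                                              stance_duration = 0.6),
                                         class = "contact_curve")), 0)
  tri <- structure(list(bw = c(seq(0, 2, length.out = 51),
                               seq(2, 0, length.out = 51)[-1]),
                        grid = g, stance_duration = 0.6),
                   class = "contact_curve")
  expect_equal(contact_impulse(tri), 0.6, tolerance = 1e-12)
  expect_error(contact_impulse(structure(list(bw = rep(1, 3), grid = c(0, 50, 100),
                                              stance_duration = NA),
                                         class = "contact_curve")),
               "stance duration")

  s <- sin(2 * pi * g / 100)
  he <- stance_half_extrema(s, g, sense = c("max", "min"))
  expect_equal(he[["first_half"]], max(s[g <= 50]))
  expect_equal(he[["second_half"]], min(s[g > 50]))
  mono <- seq(1, 3, length.out = 101)
  expect_equal(stance_half_extrema(mono, g, c("max", "max")),
               c(first_half = mono[51], second_half = 3))
  expect_equal(unname(stance_half_extrema(rep(4, 101), g)), c(4, 4))
})
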