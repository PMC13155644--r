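# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive implementations (brute force, enumeration) that share
# no code with the package internals they check.

# O(n * w) window scan: minimize mean(objective) over all w-windows within
# each trial; ties -> earliest start. Returns list(start, end, value).
oracle_best_window <- function(trial, objective, w) {
  best <- NULL
  for (tr in unique(trial)) {
    idx <- which(trial == tr)
    if (length(idx) < w) next
    for (s in seq_len(length(idx) - w + 1L)) {
      rows <- idx[s:(s + w - 1L)]
      v <- mean(objective[rows])
      if (is.null(best) || v < best$value - 1e-15)
        best <- list(start = rows[1], end = rows[w], value = v)
    }
  }
  best
}

# Exhaustive KKT enumeration for the box QP
#   min 0.5 a' H a + g' a,  lo <= a <= hi
# over all 3^n active-set patterns (free / at lo / at hi). Only feasible
# for small n; exact for strictly convex H.
oracle_box_qp <- function(H, g, lo, hi) {
  n <- length(g)
  pats <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), n)))
  best <- NULL
  for (r in seq_len(nrow(pats))) {
    st <- pats[r, ]
    a <- numeric(n)
    a[st == -1L] <- lo[st == -1L]
    a[st == 1L] <- hi[st == 1L]
    free <- which(st == 0L)
    if (length(free)) {
      rhs <- -g[free] - H[free, -free, drop = FALSE] %*% a[-free]
      a[free] <- tryCatch(solve(H[free, free, drop = FALSE], rhs),
                          error = function(e) rep(NA_real_, length(free)))
      if (anyNA(a)) next
      if (any(a[free] < lo[free] - 1e-10 | a[free] > hi[free] + 1e-10)) next
    }
    grad <- as.numeric(H %*% a + g)
    scale <- max(1, max(abs(grad)))
    if (any(st == -1L & grad < -1e-7 * scale)) next
    if (any(st == 1L & grad > 1e-7 * scale)) next
    val <- 0.5 * sum(a * (H %*% a)) + sum(g * a)
    if (is.null(best) || val < best$value) best <- list(a = a, value = val)
  }
  best
}

# Grid-search oracle for a two-variable box QP (activation grid `step`).
oracle_grid_qp <- function(H, g, lo, hi, step = 1e-3) {
  a1 <- seq(lo[1], hi[1], by = step)
  a2 <- seq(lo[2], hi[2], by = step)
  A1 <- rep(a1, times = length(a2))
  A2 <- rep(a2, each = length(a1))
  val <- 0.5 * (H[1, 1] * A1^2 + 2 * H[1, 2] * A1 * A2 + H[2, 2] * A2^2) +
    g[1] * A1 + g[2] * A2
  k <- which.min(val)
  c(A1[k], A2[k])
}

# Textbook step-up BH: p_(i) ordered ascending; adj_(i) = min over j >= i of
# m p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * p[o[j]] / j, 0)
    adj[o[i]] <- min(1, min(cand))
  }
  adj
}

# Monte-Carlo power of a two-sided one-sample t test on N(mu, sd) samples.
oracle_mc_power <- function(n, mu, sd, alpha, reps, seed) {
  set.seed(seed)
  x <- matrix(stats::rnorm(reps * n, mu, sd), reps, n)
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (n - 1))
  tstat <- m / (s / sqrt(n))
  mean(abs(tstat) > stats::qt(1 - alpha / 2, n - 1))
}

# Toy-frame builders shared by the static-optimization tests: bypass the
# full-model validation so single-muscle and two-muscle frames can be set up.
toy_model <- function(muscles, w_res = 1000) {
  list(muscles = muscles, w_res = w_res,
       joints = c("hip", "knee", "ankle"),
       theta_ref = c(hip = 0, knee = 0, ankle = 0))
}
knee_muscle <- function(name, f_max, r_knee) {
  data.frame(name = name, f_max = f_max, r_hip = 0, r_knee = r_knee,
             r_ankle = 0, l_opt = 0.1, c_knee = 0.5)
}
# H and g of the per-frame QP, assembled from the stated objective
# sum(a^2) + w * sum_j (k_j'a - Me_j)^2 -- used to feed the oracles.
frame_qp <- function(model, moments, lnorm) {
  mus <- model$muscles
  arms <- as.matrix(mus[, c("r_hip", "r_knee", "r_ankle")])
  K <- arms * (mus$f_max * gaitretrain:::active_fl(lnorm))
  me <- moments - as.numeric(t(arms) %*% (mus$f_max * gaitretrain:::passive_fl(lnorm)))
  list(H = 2 * diag(nrow(mus)) + 2 * model$w_res * (K %*% t(K)),
       g = -2 * model$w_res * as.numeric(K %*% me))
}

# Small synthetic participant used across pipeline tests (kept modest so the
# whole suite stays fast).
make_small_participant <- function(seed = 42, r = 0.25, kappa = 1.5,
                                   steps = 60, modeling = TRUE, ...) {
  params <- cohort_params(n_participants = 1L, steps_per_trial = steps,
                          modeling = modeling, seed = seed, ...)
  generate_participant(params, participant_seed = seed + 1000L,
                       participant_id = "TP", r = r, kappa = kappa)
}
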