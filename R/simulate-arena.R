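#' Parameters for the arena trajectory simulator
#'
#' Bundles and validates the knobs of the seeded arena simulator. Defaults
#' describe a typical optogenetic aversion experiment: ~4 mm/s baseline walking
#' speed that roughly doubles at light onset, a transient turning increase, a
#' post-offset freezing episode in about half the flies, and avoidance of lit
#' quadrants.
#'
#' @param n_flies number of flies per trial (>= 1).
#' @param frame_rate frames per second (default 30).
#' @param baseline_speed baseline forward velocity, mm/s.
#' @param onset_speed_boost added forward velocity during light, mm/s.
#' @param baseline_angular baseline angular speed, deg/s.
#' @param onset_turn_boost added angular speed during light, deg/s.
#' @param offset_freeze_prob per-fly probability of freezing after light
#'   offset, in `[0, 1]`.
#' @param freeze_duration duration of the post-offset freeze, s (default 30;
#'   post-stimulus locomotor suppression lasts tens of seconds).
#' @param light_attraction signed drift coefficient for quadrant-restricted
#'   light; negative values produce avoidance of lit quadrants.
#' @param noise_sd per-frame velocity noise SD, mm/s (angular noise uses
#'   `10 * noise_sd` deg/s).
#' @param seed integer seed for the per-call generator.
#' @return A validated list of class `"ArenaSimParams"`.
#' @export
arenaSimParams <- function(n_flies = 20L, frame_rate = 30, baseline_speed = 4,
                           onset_speed_boost = 4, baseline_angular = 20,
                           onset_turn_boost = 60, offset_freeze_prob = 0.5,
                           freeze_duration = 30, light_attraction = -0.5,
                           noise_sd = 1, seed = 1L) {
  if (frame_rate <= 0) stop("frame_rate must be positive", call. = FALSE)
  if (n_flies < 1L) stop("n_flies must be >= 1", call. = FALSE)
  if (offset_freeze_prob < 0 || offset_freeze_prob > 1)
    stop("offset_freeze_prob must be in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(n_flies = as.integer(n_flies), frame_rate = frame_rate,
                 baseline_speed = baseline_speed,
                 onset_speed_boost = onset_speed_boost,
                 baseline_angular = baseline_angular,
                 onset_turn_boost = onset_turn_boost,
                 offset_freeze_prob = offset_freeze_prob,
                 freeze_duration = freeze_duration,
                 light_attraction = light_attraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ArenaSimParams")
}

#' Simulate one tracked arena trial
#'
#' Generates per-frame kinematics and positions for a group of flies under a
#' light protocol, with known planted effects recorded as ground truth.
#' Forward velocity is baseline plus the onset boost during light epochs plus
#' Gaussian noise; angular speed likewise. After each light offset a Bernoulli
#' subset of flies "freezes": their forward velocity is drawn from
#' `|N(0, 0.1 * baseline_speed)|` for `freeze_duration` seconds. Positions
#' follow a biased random walk: during quadrant-restricted light epochs a
#' drift proportional to `light_attraction` points toward (positive) or away
#' from (negative) the centroid of the nearest lit quadrant. Positions and
#' velocity channels are simulated as separate tracker outputs.
#'
#' @param params an [arenaSimParams()] list.
#' @param protocol a [StimulusProtocol-class]; all epochs must lie within the
#'   session.
#' @return list with elements `trial` (an [ArenaTrial-class]) and
#'   `groundTruth` (list of planted values: onset boosts, freeze assignment
#'   per epoch, attraction coefficient, seed).
#' @export
#' @examples
#' p <- arenaSimParams(n_flies = 4, noise_sd = 0, offset_freeze_prob = 0,
#'                     onset_speed_boost = 0, light_attraction = 0)
#' sim <- simulateArenaTrial(p, lightPulseProtocol())
#' sim$trial
simulateArenaTrial <- function(params, protocol) {
  if (!inherits(params, "ArenaSimParams"))
    params <- do.call(arenaSimParams, as.list(params))
  stopifnot(is(protocol, "StimulusProtocol"))
  ep <- epochs(protocol)
  if (nrow(ep) && any(ep$end > sessionLength(protocol) + 1e-9))
    stop("protocol epochs must lie within the session", call. = FALSE)

  fr <- params$frame_rate
  n_frames <- as.integer(round(sessionLength(protocol) * fr))
  n <- params$n_flies
  t_frame <- (seq_len(n_frames) - 1L) / fr
  arena_r <- 50  # mm, fixed arena geometry

  light <- ep[ep$kind == "light", , drop = FALSE]

  withSeed(params$seed, {
    ## --- velocity channels ------------------------------------------------
    in_light <- rep(FALSE, n_frames)
    for (i in seq_len(nrow(light)))
      in_light <- in_light |
        (t_frame >= light$start[i] & t_frame < light$end[i])

    fwd <- matrix(params$baseline_speed +
                    params$onset_speed_boost * in_light,
                  nrow = n_frames, ncol = n)
    ang <- matrix(params$baseline_angular +
                    params$onset_turn_boost * in_light,
                  nrow = n_frames, ncol = n)
    if (params$noise_sd > 0) {
      fwd <- fwd + matrix(stats::rnorm(n_frames * n, 0, params$noise_sd),
                          n_frames, n)
      ang <- ang + matrix(stats::rnorm(n_frames * n, 0, 10 * params$noise_sd),
                          n_frames, n)
    }

    frozen <- vector("list", nrow(light))
    for (i in seq_len(nrow(light))) {
      frz <- which(stats::runif(n) < params$offset_freeze_prob)
      frozen[[i]] <- frz
      if (length(frz)) {
        idx <- which(t_frame >= light$end[i] &
                       t_frame < light$end[i] + params$freeze_duration)
        if (length(idx))
          fwd[idx, frz] <- abs(matrix(
            stats::rnorm(length(idx) * length(frz), 0,
                         0.1 * params$baseline_speed),
            length(idx), length(frz)))
      }
    }

    ## --- positions: biased random walk ------------------------------------
    qcent <- rbind(Q1 = c(1, 1), Q2 = c(-1, 1), Q3 = c(-1, -1),
                   Q4 = c(1, -1)) * arena_r / 2
    step_sd <- max(params$baseline_speed, 1) / fr
    x <- matrix(NA_real_, n_frames, n)
    y <- matrix(NA_real_, n_frames, n)
    theta0 <- stats::runif(n, 0, 2 * pi)
    r0 <- arena_r * sqrt(stats::runif(n))
    x[1L, ] <- r0 * cos(theta0)
    y[1L, ] <- r0 * sin(theta0)
    ## per-frame lit-quadrant sets for drift
    lit_masks <- rep(NA_character_, n_frames)
    for (i in seq_len(nrow(light))) {
      if (!identical(light$quadrants[i], "ALL")) {
        sel <- t_frame >= light$start[i] & t_frame < light$end[i]
        lit_masks[sel] <- light$quadrants[i]
      }
    }
    for (f in seq_len(n_frames)[-1L]) {
      dx <- stats::rnorm(n, 0, step_sd)
      dy <- stats::rnorm(n, 0, step_sd)
      if (!is.na(lit_masks[f]) && params$light_attraction != 0) {
        lit <- parseQuadrants(lit_masks[f])
        cx <- qcent[lit, 1L, drop = FALSE]
        cy <- qcent[lit, 2L, drop = FALSE]
        for (j in seq_len(n)) {
          d2 <- (cx - x[f - 1L, j])^2 + (cy - y[f - 1L, j])^2
          k <- which.min(d2)
          vx <- cx[k] - x[f - 1L, j]; vy <- cy[k] - y[f - 1L, j]
          nv <- sqrt(vx^2 + vy^2)
          if (nv > 1e-9) {
            dx[j] <- dx[j] + params$light_attraction * step_sd * vx / nv
            dy[j] <- dy[j] + params$light_attraction * step_sd * vy / nv
          }
        }
      }
      nx <- x[f - 1L, ] + dx
      ny <- y[f - 1L, ] + dy
      rr <- sqrt(nx^2 + ny^2)
      out <- rr > arena_r
      if (any(out)) {  # clip to the wall
        nx[out] <- nx[out] * arena_r / rr[out]
        ny[out] <- ny[out] * arena_r / rr[out]
      }
      x[f, ] <- nx; y[f, ] <- ny
    }
  })

  tracks <- data.frame(
    frame = rep(seq_len(n_frames), times = n),
    fly_id = rep(sprintf("fly%02d", seq_len(n)), each = n_frames),
    x = as.vector(x), y = as.vector(y),
    forward_velocity = as.vector(fwd),
    angular_velocity = as.vector(ang))

  trial <- methods::new("ArenaTrial", tracks = tracks,
                        frameRate = fr, arenaRadius = arena_r)
  gt <- list(kind = "arena", seed = params$seed,
             onset_speed_boost = params$onset_speed_boost,
             onset_turn_boost = params$onset_turn_boost,
             baseline_speed = params$baseline_speed,
             baseline_angular = params$baseline_angular,
             offset_freeze_prob = params$offset_freeze_prob,
             freeze_duration = params$freeze_duration,
             light_attraction = params$light_attraction,
             frozen_flies = frozen)
  list(trial = trial, groundTruth = gt)
}
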