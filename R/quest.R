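## QUEST Bayesian adaptive staircase with simulated Weibull observers.
##
## The staircase operates on an abstract "intensity" axis on which
## performance increases monotonically. Physical parameters are mapped onto
## it in log10 units: eccentricity rho (task harder when larger) as
## -log10(rho), diagonal offset theta (task easier when larger) as
## log10(theta). The psychometric family is the Weibull in log units,
##   p(correct | x, T) = gamma + (1 - gamma - delta) * (1 - exp(-10^(beta (x - T)))),
## with guess rate gamma (0.5 for two-alternative tasks), lapse rate delta
## and slope beta. Trials are placed at the posterior-mean threshold's
## target-probability point.

weibull_p <- function(x, threshold, beta = 3.5, gamma = 0.5, delta = 0.02) {
  gamma + (1 - gamma - delta) * (1 - exp(-10^(beta * (x - threshold))))
}

## Intensity offset from threshold at which the Weibull hits target_p.
weibull_offset <- function(target_p, beta = 3.5, gamma = 0.5, delta = 0.02) {
  f <- (target_p - gamma) / (1 - gamma - delta)
  log10(-log1p(-f)) / beta
}

#' Initialize a QUEST staircase state
#'
#' Builds a discretized Gaussian prior over the threshold axis. The first
#' recommended intensity is the prior mean's target-probability placement.
#'
#' @param prior_mean Prior threshold guess, intensity units (log10 of the
#'   physical parameter, or its negative; see [intensity_of()]).
#' @param prior_sd Prior standard deviation, same units (> 0).
#' @param beta,gamma,delta Weibull slope, guess rate, lapse rate.
#' @param target_p Percent-correct level to track (default 0.8); must lie
#'   strictly between `gamma` and `1 - delta`.
#' @param grid_span Half-width of the threshold grid around `prior_mean`.
#' @param grid_n Number of grid points.
#' @param bounds Physical clamp for recommendations, intensity units.
#' @return Object of class `quest_state`.
#' @export
quest_init <- function(prior_mean, prior_sd, beta = 3.5, gamma = 0.5,
                       delta = 0.02, target_p = 0.8, grid_span = 2.5,
                       grid_n = 251L, bounds = c(-Inf, Inf)) {
  if (prior_sd <= 0) stop("prior_sd must be positive")
  if (target_p <= gamma || target_p >= 1 - delta)
    stop("target_p must lie in (gamma, 1 - delta)")
  grid <- seq(prior_mean - grid_span, prior_mean + grid_span, length.out = grid_n)
  lp <- -(grid - prior_mean)^2 / (2 * prior_sd^2)
  lp <- lp - max(lp)
  structure(list(grid = grid, log_posterior = lp, beta = beta, gamma = gamma,
                 delta = delta, target_p = target_p, bounds = bounds,
                 n_trials = 0L),
            class = "quest_state")
}

#' @export
print.quest_state <- function(x, ...) {
  cat(sprintf("<quest_state> %d trials, threshold estimate %.3f (intensity units)\n",
              x$n_trials, quest_threshold(x)))
  invisible(x)
}

#' Posterior-mean threshold estimate
#' @param state A `quest_state`.
#' @return Posterior mean of the threshold, intensity units.
#' @export
quest_threshold <- function(state) {
  w <- exp(state$log_posterior - max(state$log_posterior))
  sum(state$grid * w) / sum(w)
}

#' Update the QUEST posterior with one trial outcome
#'
#' Multiplies the posterior by the Weibull likelihood of the observed
#' outcome at the tested intensity. Likelihoods are floored at a small
#' positive value so no grid point is ever driven to exactly zero mass.
#'
#' @param state A `quest_state`.
#' @param tested_value Intensity at which the trial was run.
#' @param correct Logical outcome.
#' @return Updated `quest_state`.
#' @export
quest_update <- function(state, tested_value, correct) {
  p <- weibull_p(tested_value, state$grid, state$beta, state$gamma, state$delta)
  like <- if (correct) p else 1 - p
  state$log_posterior <- state$log_posterior + log(pmax(like, 1e-10))
  state$log_posterior <- state$log_posterior - max(state$log_posterior)
  state$n_trials <- state$n_trials + 1L
  state
}

#' Recommend the next test intensity
#'
#' Places the next trial where the posterior-mean threshold's psychometric
#' function equals `target_p`, clamped to the physical bounds.
#'
#' @param state A `quest_state`.
#' @return Intensity for the next trial.
#' @export
quest_recommend <- function(state) {
  x <- quest_threshold(state) +
    weibull_offset(state$target_p, state$beta, state$gamma, state$delta)
  min(max(x, state$bounds[1]), state$bounds[2])
}

#' Map physical staircase parameters to the intensity axis and back
#'
#' `rho` (eccentricity, harder when larger) maps to `-log10(rho)`; `theta`
#' (offset from the diagonal, easier when larger) maps to `log10(theta)`.
#'
#' @param value Physical value (rho or theta) or intensity.
#' @param param `"rho"` or `"theta"`.
#' @return The transformed value.
#' @export
intensity_of <- function(value, param = c("rho", "theta")) {
  param <- match.arg(param)
  if (param == "rho") -log10(value) else log10(value)
}

#' @rdname intensity_of
#' @export
physical_of <- function(value, param = c("rho", "theta")) {
  param <- match.arg(param)
  if (param == "rho") 10^(-value) else 10^value
}

#' A simulated Weibull observer
#'
#' Stand-in for a human participant: responds correctly with the Weibull
#' probability of its true threshold at the tested intensity. Guess rate is
#' 0.5 (two-alternative tasks). Response times are drawn from a log-normal
#' independent of condition (pipeline completeness only).
#'
#' @param true_threshold Observer threshold, intensity units.
#' @param beta,delta Weibull slope and lapse rate.
#' @param rt_meanlog,rt_sdlog Log-normal RT parameters (seconds).
#' @return Object of class `sim_observer`.
#' @export
sim_observer <- function(true_threshold, beta = 3.5, delta = 0.02,
                         rt_meanlog = -0.5, rt_sdlog = 0.3) {
  structure(list(true_threshold = true_threshold, beta = beta, gamma = 0.5,
                 delta = delta, rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog),
            class = "sim_observer")
}

observer_respond <- function(obs, intensity) {
  p <- weibull_p(intensity, obs$true_threshold, obs$beta, obs$gamma, obs$delta)
  list(correct = runif(1) < p, p = p,
       rt = rlnorm(1, obs$rt_meanlog, obs$rt_sdlog))
}

## Intensity at which an observer performs at target_p (closed form):
## used by tests as the convergence oracle.
observer_target_intensity <- function(obs, target_p = 0.8) {
  obs$true_threshold + weibull_offset(target_p, obs$beta, obs$gamma, obs$delta)
}

#' Run a full alternating-block adaptive session
#'
#' Simulates the block design: alternating SD and SR blocks (SD first).
#' Within an SD block QUEST staircases the eccentricity rho; within an SR
#' block it staircases the diagonal offset theta; the other parameter is
#' held at its most recent value. Both staircases persist across blocks and
#' track the same target accuracy.
#'
#' @param observer_sd,observer_sr `sim_observer`s for the two tasks.
#' @param n_blocks Number of blocks (default 16).
#' @param trials_per_block Trials per block (default 70).
#' @param rho_init,theta_init Initial physical values (defaults 5.4 and 6,
#'   the staircase starting points).
#' @param rho_bounds,theta_bounds Physical clamps (items must stay on
#'   screen; |theta| <= 45).
#' @param target_p Tracked percent correct (default 0.8).
#' @param prior_sd Prior standard deviation on the intensity axis.
#' @param seed Integer seed.
#' @return Object of class `session_log`: data frame with one row per
#'   trial (block, trial, task, rho, theta, intensity, p_true, correct, rt).
#' @export
run_session <- function(observer_sd, observer_sr, n_blocks = 16L,
                        trials_per_block = 70L, rho_init = 5.4,
                        theta_init = 6, rho_bounds = c(1, 20),
                        theta_bounds = c(0.5, 45), target_p = 0.8,
                        prior_sd = 0.5, seed = 1L) {
  q_sd <- quest_init(intensity_of(rho_init, "rho"), prior_sd,
                     target_p = target_p,
                     bounds = rev(intensity_of(rho_bounds, "rho")))
  q_sr <- quest_init(intensity_of(theta_init, "theta"), prior_sd,
                     target_p = target_p,
                     bounds = intensity_of(theta_bounds, "theta"))
  rho <- rho_init; theta <- theta_init
  n_total <- n_blocks * trials_per_block
  log <- data.frame(block = integer(n_total), trial = integer(n_total),
                    task = character(n_total), rho = numeric(n_total),
                    theta = numeric(n_total), intensity = numeric(n_total),
                    p_true = numeric(n_total), correct = logical(n_total),
                    rt = numeric(n_total))
  with_seed(seed, {
    row <- 0L
    for (b in seq_len(n_blocks)) {
      task <- if (b %% 2L == 1L) "SD" else "SR"
      for (t in seq_len(trials_per_block)) {
        row <- row + 1L
        if (task == "SD") {
          x <- quest_recommend(q_sd)
          rho <- physical_of(x, "rho")
          resp <- observer_respond(observer_sd, x)
          q_sd <- quest_update(q_sd, x, resp$correct)
        } else {
          x <- quest_recommend(q_sr)
          theta <- physical_of(x, "theta")
          resp <- observer_respond(observer_sr, x)
          q_sr <- quest_update(q_sr, x, resp$correct)
        }
        log[row, ] <- list(b, t, task, rho, theta, x, resp$p, resp$correct, resp$rt)
      }
    }
  })
  structure(log, class = c("session_log", "data.frame"),
            quest_sd = q_sd, quest_sr = q_sr, seed = as.integer(seed))
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> %d blocks x %d trials, overall accuracy %.3f\n",
              max(x$block), sum(x$block == 1), mean(x$correct)))
  invisible(x)
}

#' Per-block staircase traces
#'
#' Per-block mean of the staircased parameters (the per-block rho and theta
#' trajectories adjusted by QUEST). Within a block only that block's task
#' parameter changes; the other is carried over.
#'
#' @param log A `session_log`.
#' @return Data frame with block, task, mean rho and theta.
#' @export
session_block_traces <- function(log) {
  do.call(rbind, lapply(split(log, log$block), function(d) {
    data.frame(block = d$block[1], task = d$task[1],
               rho = mean(d$rho), theta = mean(d$theta))
  }))
}

#' Accuracy over the second half of a session
#' @param log A `session_log`.
#' @return Mean proportion correct over the final half of the blocks.
#' @export
second_half_accuracy <- function(log) {
  half <- max(log$block) / 2
  mean(log$correct[log$block > half])
}
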