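# QUEST Bayesian adaptive staircase targeting 85% correct.
#
# The posterior lives on a log10-contrast grid over the threshold parameter
# of a Weibull psychometric (slope beta = 3.5, guess 0.5, lapse 0.01).
# Placement is posterior-mean: each trial presents the current posterior-mean
# estimate of the 85%-correct contrast. The study-level threshold read-out is
# the mean of the final ten presented intensities.

#' Initialize a QUEST staircase
#'
#' @param target_p targeted probability correct.
#' @param beta Weibull slope in log10 contrast.
#' @param guess guess rate (2AFC: 0.5).
#' @param lapse lapse rate.
#' @param prior_mean,prior_sd Gaussian prior over log10 threshold.
#' @param grid log10-contrast support of the posterior.
#' @return an object of class `"quest_state"`.
#' @export
quest_init <- function(target_p = 0.85, beta = 3.5, guess = 0.5,
                       lapse = 0.01, prior_mean = -0.7, prior_sd = 0.5,
                       grid = seq(-3, 0, length.out = 200)) {
  if (target_p <= guess || target_p >= 1)
    stopf("target_p must lie in (guess, 1)")
  prior <- stats::dnorm(grid, prior_mean, prior_sd)
  structure(list(grid = grid, posterior = prior / sum(prior), beta = beta,
                 guess = guess, lapse = lapse, target_p = target_p,
                 history = data.frame(intensity = numeric(0),
                                      response = logical(0))),
            class = "quest_state")
}

# Weibull probability correct at log10-contrast x for threshold parameter T
# (T is the log10 contrast of the target_p point)
quest_p_correct <- function(state, x, thresh_log) {
  f_req <- (state$target_p - state$guess) / (1 - state$guess - state$lapse)
  # offset between the target_p point and the e^-1 knee of the Weibull
  off <- log10(-log(1 - f_req)) / state$beta
  state$guess + (1 - state$guess - state$lapse) *
    (1 - exp(-10^(state$beta * (x - (thresh_log - off)))))
}

#' Bayesian update of a QUEST state
#'
#' Multiplies the posterior by the Weibull likelihood of the observed
#' response at the presented intensity and renormalizes.
#'
#' @param state a [quest_init()] state.
#' @param intensity presented contrast in `[0, 1]` (linear units).
#' @param response logical: was the report correct?
#' @return the updated `"quest_state"`.
#' @export
quest_update <- function(state, intensity, response) {
  if (!is.logical(response) || length(response) != 1L || is.na(response))
    stopf("response must be a single TRUE/FALSE")
  x <- log10(max(intensity, 10^min(state$grid)))
  if (x > max(state$grid) + 1e-9 || x < min(state$grid) - 1e-9)
    stopf("intensity %g outside the staircase grid range", intensity)
  p <- quest_p_correct(state, x, state$grid)
  like <- if (response) p else 1 - p
  post <- state$posterior * like
  s <- sum(post)
  if (s <= 0) stopf("degenerate posterior after update")
  state$posterior <- post / s
  state$history <- rbind(state$history,
                         data.frame(intensity = intensity, response = response))
  state
}

#' Next intensity to present
#'
#' Posterior-mean estimate of the `target_p` threshold contrast, clipped to
#' `[0, 1]`.
#'
#' @param state a [quest_init()] state.
#' @return contrast in `[0, 1]`.
#' @export
quest_next_intensity <- function(state) {
  m <- sum(state$grid * state$posterior)
  min(max(10^m, 0), 1)
}

#' Staircase threshold read-out
#'
#' Arithmetic mean of the final ten presented intensities.
#'
#' @param history data.frame with an `intensity` column (a `"quest_state"`
#'   history or a full staircase trace).
#' @return threshold contrast estimate.
#' @export
staircase_threshold <- function(history) {
  if (inherits(history, "quest_state")) history <- history$history
  n <- nrow(history)
  if (is.null(n) || n < 10L)
    stopf("need at least 10 presentations to read out a threshold")
  mean(history$intensity[(n - 9L):n])
}

#' Run a full staircase against a simulated observer
#'
#' @param n_trials number of trials.
#' @param threshold_contrast the observer's true 85% point.
#' @param seed integer seed.
#' @param slope,lapse observer psychometric parameters.
#' @param state optional pre-configured [quest_init()] state.
#' @return list with the final `state` and a `trace` data.frame (trial,
#'   intensity, response, posterior-mean threshold estimate).
#' @export
run_staircase <- function(n_trials, threshold_contrast, seed = 1,
                          slope = 3.5, lapse = 0.01, state = quest_init()) {
  with_seed(seed, {
    rows <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      x <- quest_next_intensity(state)
      r <- as.logical(simulate_observer(x, threshold_contrast, slope, lapse))
      state <- quest_update(state, x, r)
      rows[[i]] <- data.frame(trial = i, intensity = x, response = r,
                              estimate = quest_next_intensity(state))
    }
    list(state = state, trace = do.call(rbind, rows))
  })
}
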