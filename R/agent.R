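#' Button state with activation threshold and hysteresis
#'
#' A button turns "on" (producing one click) when its neuron's output rises
#' to `>= threshold` and turns off when the output falls below it; while on,
#' no further clicks are produced. The hysteresis prevents continuous link
#' adjustment and separates the timescales of movement (fast) and link
#' adjustment (slow).
#'
#' @param threshold activation level in (0, 1), default 0.75.
#' @return An object of class `button_state`.
#' @export
button_state <- function(threshold = 0.75) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  structure(list(on = c(left = FALSE, right = FALSE), threshold = threshold),
            class = "button_state")
}

#' An embodied CTRNN agent
#'
#' Binds a controller to a body. Neuron roles are fixed by position:
#' neuron 1 is the receptor (binary contact input scaled by the gain `r`),
#' neuron 2 drives movement (output mapped from `[0, 1]` to `[-1, 1]` and
#' scaled by `e["move"]`), neurons 3 and 4 drive the left and right buttons,
#' and neurons 5 onward are interneurons with no dedicated function.
#'
#' @param params a [ctrnn_params()] with at least 4 neurons.
#' @param mirror +1 (agent 1) or -1 (agent 2).
#' @param rf_pos initial RF position.
#' @param d initial link distance.
#' @param threshold button activation threshold (default 0.75).
#' @return An object of class `agent_controller` with elements `params`,
#'   `state` (neuron states start at 0), `buttons` and `body`.
#' @export
agent_controller <- function(params, mirror, rf_pos, d, threshold = 0.75) {
  if (params$n < 4L)
    stop("embodied controller needs at least 4 neurons (roles 1-4)")
  structure(list(params = params,
                 state = ctrnn_state(params),
                 buttons = button_state(threshold),
                 body = body_state(rf_pos, d, mirror)),
            class = "agent_controller")
}

#' One sensorimotor step of an embodied agent
#'
#' Feeds `r * contact` into the receptor neuron, advances the CTRNN by one
#' Euler step, maps the movement neuron's output to an egocentric velocity
#' `e_move * (2 * o2 - 1 + noise_draw)` (noise enters the mapped motor
#' output, before the effector gain), and updates both buttons. Click events
#' are off-to-on transitions only; a button held above threshold clicks once.
#'
#' @param agent an [agent_controller()].
#' @param contact binary contact input (0 or 1).
#' @param h step size (time units).
#' @param noise_draw movement-noise realization for this step (the trial
#'   loop draws one `N(0, noise_sd)` value per agent per step).
#' @return List with `agent` (updated), `velocity` (egocentric), and
#'   `clicks` (character subset of `c("left", "right")`, left first when
#'   both fire).
#' @export
agent_step <- function(agent, contact, h, noise_draw = 0) {
  if (!contact %in% c(0, 1)) stop("contact must be 0 or 1")
  input <- rep(0, agent$params$n)
  input[1L] <- agent$params$r * contact
  agent$state <- ctrnn_step(agent$params, agent$state, input, h)
  velocity <- agent$params$e[["move"]] *
    (2 * agent$state$o[2L] - 1 + noise_draw)
  now_on <- c(left = agent$state$o[3L] >= agent$buttons$threshold,
              right = agent$state$o[4L] >= agent$buttons$threshold)
  clicks <- names(now_on)[now_on & !agent$buttons$on]
  agent$buttons$on <- now_on
  list(agent = agent, velocity = velocity, clicks = clicks)
}

#' Route click events into link adjustments
#'
#' Applies each emitted click to the agent's body via [apply_click()], with
#' the evolved effector gains `e["left"]` / `e["right"]` as the step sizes
#' (one step per click event). Left is applied before right when both fire
#' in the same step.
#'
#' @param agent an [agent_controller()].
#' @param clicks character vector from [agent_step()].
#' @return The agent with its body's link distance adjusted.
#' @export
click_to_body <- function(agent, clicks) {
  for (side in intersect(c("left", "right"), clicks)) {
    agent$body <- apply_click(agent$body, side, agent$params$e[[side]])
  }
  agent
}
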