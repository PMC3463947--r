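#' Body state of one agent in the 1D world
#'
#' An agent is embodied twice: as a receptor field (RF), the locus through
#' which it senses, and as a body-object (BO), the part of it the other agent
#' can touch. BO and RF are connected by a rigid link of signed allocentric
#' length `d` (the link distance D): the BO center is always `rf_pos + d`.
#' The `mirror` sign converts egocentric motor commands into allocentric
#' effects: +1 for agent 1 and -1 for agent 2, modeling two agents facing
#' each other across the axis.
#'
#' @param rf_pos allocentric center position of the RF (space units).
#' @param d allocentric link distance D; negative puts the BO to the left of
#'   the RF.
#' @param mirror +1 or -1.
#' @return An object of class `body_state`.
#' @export
body_state <- function(rf_pos, d, mirror = 1) {
  if (!is.finite(rf_pos) || !is.finite(d)) stop("rf_pos and d must be finite")
  if (!mirror %in% c(-1, 1)) stop("mirror must be +1 or -1")
  structure(list(rf_pos = as.numeric(rf_pos), d = as.numeric(d),
                 mirror = as.numeric(mirror)),
            class = "body_state")
}

#' @export
print.body_state <- function(x, ...) {
  cat(sprintf("body: RF at %.3f, BO at %.3f (D = %.3f), mirror %+d\n",
              x$rf_pos, x$rf_pos + x$d, x$d, as.integer(x$mirror)))
  invisible(x)
}

#' Geometry of the shared 1D space
#'
#' All RFs and BOs have the same extent (`object_size`, default 1 space
#' unit). Contact registers when the center of an observer's RF is within
#' `contact_radius` (inclusive) of the other's BO center; the default 0.5
#' places each center inside the other object's extent and reproduces a
#' simultaneous mutual-contact window of body offsets `[-1, 1]`. The space
#' is an infinite line by default; a periodic wrap of circumference `length`
#' is available but plays no role in the model's results.
#'
#' @param object_size extent of every RF and BO (> 0).
#' @param contact_radius maximum center-to-center distance registering
#'   contact (> 0, inclusive boundary).
#' @param periodic wrap the space into a circle?
#' @param length circumference when `periodic` (ignored otherwise).
#' @return An object of class `world_config`.
#' @export
world_config <- function(object_size = 1, contact_radius = 0.5,
                         periodic = FALSE, length = 600) {
  if (object_size <= 0 || contact_radius <= 0)
    stop("object_size and contact_radius must be positive")
  if (periodic && (!is.finite(length) || length <= 0))
    stop("periodic space needs a positive length")
  structure(list(object_size = object_size, contact_radius = contact_radius,
                 periodic = isTRUE(periodic), length = length),
            class = "world_config")
}

#' Binary tactile sensing
#'
#' Returns 1 iff the observer's RF center lies within the contact radius of
#' the other agent's BO center (`other$rf_pos + other$d`), inclusive. The
#' relation is not symmetric in its arguments: each agent senses the other's
#' BO with its own RF, and neither ever senses a BO with a BO or its own
#' body.
#'
#' @param observer,other [body_state()] objects.
#' @param world a [world_config()].
#' @return 0 or 1.
#' @export
sense_contact <- function(observer, other, world = world_config()) {
  dist <- abs(observer$rf_pos - (other$rf_pos + other$d))
  if (world$periodic) {
    dist <- dist %% world$length
    dist <- min(dist, world$length - dist)
  }
  as.integer(dist <= world$contact_radius)
}

#' Move a body by an egocentric velocity command
#'
#' The RF position advances by `mirror * h * (velocity + noise_draw)`; the
#' BO is dragged along rigidly (`d` unchanged). Agent 2's mirror of -1
#' inverts the allocentric effect of its commands.
#'
#' @param body a [body_state()].
#' @param velocity egocentric velocity command (space/time).
#' @param h step size (time units, > 0).
#' @param noise_draw additive velocity noise (default 0; the trial loop
#'   injects movement noise upstream, at the mapped motor output).
#' @return The moved `body_state`.
#' @export
apply_motion <- function(body, velocity, h, noise_draw = 0) {
  if (h <= 0) stop("h must be positive")
  body$rf_pos <- body$rf_pos + body$mirror * h * (velocity + noise_draw)
  body
}

#' Shift a body's BO by one button click
#'
#' An egocentric left click moves the BO leftward around the RF, a right
#' click rightward, each by `step` space units; the RF does not move. For
#' agent 2 the mirror sign inverts the allocentric direction, so "left" for
#' both agents means the same thing from each one's own perspective.
#'
#' @param body a [body_state()].
#' @param side `"left"` or `"right"`.
#' @param step link-adjustment step size (>= 0, space units).
#' @return The adjusted `body_state`.
#' @export
apply_click <- function(body, side = c("left", "right"), step) {
  side <- match.arg(side)
  if (step < 0) stop("step must be >= 0")
  body$d <- body$d + if (side == "left") -body$mirror * step
                     else body$mirror * step
  body
}

#' Body offset of a dyad
#'
#' `D1 + D2`, the relative mismatch between the two body configurations.
#' Zero iff the configurations are complementary (`D2 = -D1`), the model's
#' operationalization of mimicry; within `[-1, 1]` (default geometry) the
#' agents can touch each other simultaneously.
#'
#' @param a1,a2 [body_state()] objects of agents 1 and 2.
#' @return `a1$d + a2$d` (space units).
#' @export
body_offset <- function(a1, a2) a1$d + a2$d

#' Can two agents with a given body offset touch simultaneously?
#'
#' Brute-force certificate: holds the link distances fixed (`d1 = offset`,
#' `d2 = 0`; only the sum matters) and scans a grid of RF separations,
#' asking [sense_contact()] in both directions at each. Used to verify that
#' the contact rule yields the mutual-contact window `|D1 + D2| <= 1`.
#'
#' @param offset body offset D1 + D2 to test.
#' @param world a [world_config()].
#' @param separations grid of RF1 - RF2 separations to scan. The default
#'   steps by 1/20 so that the exact window boundary (offset of +/-1, met
#'   only at a half-integer separation) is on the grid.
#' @return `TRUE` if some separation gives contact for both agents.
#' @export
mutual_contact_achievable <- function(offset, world = world_config(),
                                      separations = seq(-60L, 60L) / 20) {
  b2 <- body_state(0, 0, mirror = -1)
  for (x in separations) {
    b1 <- body_state(x, offset, mirror = 1)
    if (sense_contact(b1, b2, world) == 1L &&
        sense_contact(b2, b1, world) == 1L) return(TRUE)
  }
  FALSE
}
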