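#' Canonical figure template
#'
#' Builds the reference geometry of the basic figure every item is drawn
#' from: six corners on an irregular convex outline, five internal line
#' segments joining the corners as a simple path c1-c2-...-c6, a broken
#' circle (arc glyph) attached next to corners 5 and 6, and a trapezium
#' attached outside the outline with its own rotation pivot.  Four preset
#' arrangements ("A"-"D") are available independently for the internal
#' lines (`form_int`) and for the trapezium (`form_ext`); all presets share
#' the same topology (6 corners, 5 path edges), they only differ in how the
#' parts are arranged visually.
#'
#' @param form_int Internal-line arrangement preset, one of `"A"`, `"B"`,
#'   `"C"`, `"D"`.  `"A"` is the default used throughout generation.
#' @param form_ext Trapezium arrangement preset, same domain.
#' @return An object of class `fa_template` with components
#'   `corners` (6 x 2 coordinate matrix in path order c1..c6),
#'   `lines` (5 x 2 matrix, row i joins corners i and i+1),
#'   `trapezium` (local polygon coordinates plus anchor radius),
#'   `broken_circle` (attachment corners, arc radius and gap), and the
#'   preset ids.
#' @examples
#' tpl <- fa_template()
#' nrow(tpl$corners)  # 6
#' nrow(tpl$lines)    # 5
#' @export
fa_template <- function(form_int = "A", form_ext = "A") {
  forms <- c("A", "B", "C", "D")
  if (!(is.character(form_int) && length(form_int) == 1L && form_int %in% forms))
    stop_invalid("`form_int` must be one of \"A\", \"B\", \"C\", \"D\"")
  if (!(is.character(form_ext) && length(form_ext) == 1L && form_ext %in% forms))
    stop_invalid("`form_ext` must be one of \"A\", \"B\", \"C\", \"D\"")

  # Outline vertices of the main shape, in convex order, spanning the unit box.
  outline <- rbind(
    c(-0.95,  0.20),
    c(-0.45,  0.90),
    c( 0.50,  0.75),
    c( 0.95, -0.05),
    c( 0.45, -0.90),
    c(-0.55, -0.80)
  )

  # Corner labels c1..c6 visit the outline vertices in a form-specific
  # zig-zag order, so the path edges run through the interior of the shape.
  path_order <- switch(form_int,
    A = c(1L, 4L, 2L, 6L, 3L, 5L),
    B = c(2L, 5L, 1L, 4L, 6L, 3L),
    C = c(1L, 3L, 6L, 2L, 4L, 5L),
    D = c(3L, 6L, 2L, 5L, 1L, 4L)
  )
  corners <- outline[path_order, , drop = FALSE]
  rownames(corners) <- paste0("c", 1:6)

  lines <- cbind(from = 1:5, to = 2:6)

  # Trapezium polygon in local coordinates (pivot at local origin).
  trap_poly <- switch(form_ext,
    A = rbind(c(-0.16, -0.09), c(0.16, -0.09), c(0.09, 0.09), c(-0.09, 0.09)),
    B = rbind(c(-0.20, -0.07), c(0.20, -0.07), c(0.08, 0.07), c(-0.08, 0.07)),
    C = rbind(c(-0.12, -0.12), c(0.12, -0.12), c(0.06, 0.12), c(-0.06, 0.12)),
    D = rbind(c(-0.18, -0.08), c(0.14, -0.08), c(0.10, 0.08), c(-0.12, 0.08))
  )

  structure(list(
    corners = corners,
    outline = outline,
    lines = lines,
    trapezium = list(poly = trap_poly, anchor_radius = 1.25),
    broken_circle = list(corners = c(5L, 6L), radius = 0.14, gap_deg = 70),
    form_int = form_int,
    form_ext = form_ext
  ), class = "fa_template")
}

#' Figure state
#'
#' The position of every movable part of the figure: the rotational state of
#' the main shape (eight 45-degree-spaced positions), whether it is
#' reflected, the rotational state of the trapezium, the corner holding the
#' dot, and which internal lines are present.
#'
#' @param main Main-shape rotational state, integer 1..8 (state k renders
#'   the template rotated 45*(k-1) degrees counterclockwise).
#' @param flip Logical; is the main shape reflected?
#' @param trap Trapezium rotational state, integer 1..8.
#' @param dot Corner holding the dot, integer 1..6.
#' @param lines Subset of 1:5, the internal lines present.
#' @return An object of class `fa_state`.
#' @examples
#' fa_state(main = 1, flip = FALSE, trap = 2, dot = 6)
#' @export
fa_state <- function(main = 1L, flip = FALSE, trap = 1L, dot = 6L, lines = 1:5) {
  if (!is_count(main, 1L) || main > 8) stop_invalid("`main` must be an integer in 1..8")
  if (!(is.logical(flip) && length(flip) == 1L && !is.na(flip)))
    stop_invalid("`flip` must be TRUE or FALSE")
  if (!is_count(trap, 1L) || trap > 8) stop_invalid("`trap` must be an integer in 1..8")
  if (!is_count(dot, 1L) || dot > 6) stop_invalid("`dot` must be an integer in 1..6")
  lines <- sort(unique(as.integer(lines)))
  if (length(lines) < 1L || any(lines < 1L | lines > 5L))
    stop_invalid("`lines` must be a non-empty subset of 1:5")
  structure(list(
    main = as.integer(main), flip = flip, trap = as.integer(trap),
    dot = as.integer(dot), lines = lines
  ), class = "fa_state")
}

#' @export
format.fa_state <- function(x, ...) {
  sprintf("<fa_state main=%d%s trap=%d dot=%d lines={%s}>",
          x$main, if (x$flip) " flipped" else "", x$trap, x$dot,
          paste(x$lines, collapse = ","))
}

#' @export
print.fa_state <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Test two figure states for equality
#'
#' @param a,b `fa_state` objects.
#' @return `TRUE` if every part is in the same position.
#' @export
states_equal <- function(a, b) {
  identical(state_key(a), state_key(b))
}

# Canonical string key for distinctness checks.
state_key <- function(s) {
  paste(s$main, as.integer(s$flip), s$trap, s$dot,
        paste(s$lines, collapse = ""), sep = "|")
}

check_angle <- function(angle) {
  if (!(length(angle) == 1L && is.numeric(angle) && !is.na(angle)))
    stop_invalid("rotation angle must be a single number")
  if (angle %% 45 != 0)
    stop_invalid("rotation angle must be a multiple of 45 (got %s)", angle)
  if (angle < -135 || angle > 180)
    stop_invalid("rotation angle must lie in [-135, 180] (got %s)", angle)
  invisible(angle)
}

#' Rotate the main shape
#'
#' Advances the rotational state of the main shape.  Positive angles rotate
#' counterclockwise, negative angles clockwise; angles must be multiples of
#' 45 within \[-135, 180\].  All other parts are untouched.
#'
#' @param state An `fa_state`.
#' @param angle Rotation angle in degrees.
#' @return The rotated `fa_state`.
#' @examples
#' s <- fa_state(main = 1)
#' rotate_main(s, 90)$main   # 3
#' rotate_main(rotate_main(s, 90), -90)$main  # 1
#' @export
rotate_main <- function(state, angle) {
  check_angle(angle)
  state$main <- as.integer(((state$main - 1L + angle / 45) %% 8) + 1L)
  state
}

#' Reflect the main shape
#'
#' Reflects the main shape about the x or y axis.  The reflection is realized
#' as a toggle of the flip flag plus a remap of the rotational state, so that
#' reflecting twice restores the original state exactly.  A y-axis reflection
#' equals an x-axis reflection followed by a 180-degree rotation.
#'
#' @param state An `fa_state`.
#' @param axis `"x"` or `"y"`.
#' @return The reflected `fa_state`.
#' @examples
#' s <- fa_state(main = 3)
#' states_equal(reflect_main(reflect_main(s, "x"), "x"), s)  # TRUE
#' @export
reflect_main <- function(state, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (axis == "x") {
    # M_x o R_theta = R_{-theta} o M_x : negate the rotation, toggle the flip.
    state$main <- as.integer(((-(state$main - 1L)) %% 8) + 1L)
    state$flip <- !state$flip
    state
  } else {
    rotate_main(reflect_main(state, "x"), 180)
  }
}

#' Rotate the trapezium
#'
#' Advances the rotational state of the trapezium independently of the main
#' shape and its internal lines.  Same angle domain as [rotate_main()].
#'
#' @inheritParams rotate_main
#' @return The `fa_state` with the trapezium advanced.
#' @examples
#' rotate_trapezium(fa_state(trap = 1), 180)$trap  # 5
#' @export
rotate_trapezium <- function(state, angle) {
  check_angle(angle)
  state$trap <- as.integer(((state$trap - 1L + angle / 45) %% 8) + 1L)
  state
}

#' Subtract an internal line
#'
#' Removes one of the five internal line segments from the figure.
#'
#' @param state An `fa_state`.
#' @param line Line id in 1..5; must currently be present.
#' @return The `fa_state` without that line.
#' @examples
#' subtract_line(fa_state(), 1)$lines  # 2 3 4 5
#' @export
subtract_line <- function(state, line) {
  if (!is_count(line, 1L) || line > 5)
    stop_invalid("`line` must be an integer in 1..5")
  line <- as.integer(line)
  if (!(line %in% state$lines))
    stop_infeasible("line %d is already absent from the figure", line)
  state$lines <- setdiff(state$lines, line)
  state
}

#' Move the dot along the internal-line path
#'
#' The dot travels along the path of internal lines (corner 1 to corner 6),
#' `n_edges` edges in the given direction, and settles on a corner.  It never
#' crosses the broken circle or the trapezium, which are off the path.  A
#' traversal that would run off the end of the path is infeasible.
#'
#' @param state An `fa_state`.
#' @param n_edges Non-negative number of edges to traverse.
#' @param direction `+1` to move toward corner 6, `-1` toward corner 1.
#' @return The `fa_state` with the dot moved.
#' @examples
#' move_dot(fa_state(dot = 1), 2, 1)$dot  # 3
#' @export
move_dot <- function(state, n_edges, direction = 1L) {
  if (!is_count(n_edges)) stop_invalid("`n_edges` must be a non-negative integer")
  if (!(length(direction) == 1L && direction %in% c(-1, 1)))
    stop_invalid("`direction` must be +1 or -1")
  target <- state$dot + as.integer(direction) * as.integer(n_edges)
  if (target < 1L || target > 6L)
    stop_infeasible(
      "dot movement of %d edges from corner %d in direction %+d runs off the path",
      n_edges, state$dot, direction)
  state$dot <- as.integer(target)
  state
}
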