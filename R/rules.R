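#' Rule set (radicals) of a figural analogy item
#'
#' Encodes which of the five general rules an item manipulates and with which
#' arguments.  Each rotation-type rule takes a pair of angles, the first for
#' the A-to-B change and the second for the A-to-C change; reflection takes a
#' single flag (x-axis reflection A-to-B, y-axis A-to-C); subtraction names
#' one internal line per pathway (or `"R"` for a random choice at build
#' time); dot movement gives the number of path edges travelled per pathway.
#' Rules whose arguments are all zero are inactive.  The reflection rule and
#' the main-rotation rule can never be combined (their composition mimics
#' other rules), so a rule set manipulates at most four radicals at once.
#'
#' @param main.rot Numeric pair of main-shape rotation angles (A-to-B,
#'   A-to-C), multiples of 45 in \[-135, 180\], or `NULL`.
#' @param mirror `1` (or `TRUE`) to activate the reflection rule, or `NULL`.
#' @param trap.rot Numeric pair of trapezium rotation angles, or `NULL`.
#' @param subtract Integer pair of distinct line ids in 1..5, or `"R"` to
#'   draw the pair at random at build time, or `NULL`.
#' @param dot.mov Pair of non-negative edge counts (A-to-B, A-to-C) whose
#'   sum is at most 5 (the path has five edges), or `NULL`.
#' @return An object of class `fa_rules`.
#' @examples
#' fa_rules(main.rot = c(90, 45))
#' fa_rules(mirror = 1, dot.mov = c(1, 2))
#' @seealso [validate_rules()], [build_analogies()]
#' @export
fa_rules <- function(main.rot = NULL, mirror = NULL, trap.rot = NULL,
                     subtract = NULL, dot.mov = NULL) {
  pair <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (!(is.numeric(x) && length(x) %in% 1:2) || anyNA(x))
      stop_invalid("`%s` must be one or two numbers", what)
    if (length(x) == 1L) x <- c(x, x)
    x
  }
  r <- list(
    main.rot = pair(main.rot, "main.rot"),
    mirror   = if (is.null(mirror)) NULL else isTRUE(mirror == 1 || isTRUE(mirror)),
    trap.rot = pair(trap.rot, "trap.rot"),
    subtract = if (is.null(subtract)) NULL else subtract,
    dot.mov  = pair(dot.mov, "dot.mov")
  )
  if (!is.null(r$mirror) && !r$mirror) r$mirror <- NULL
  structure(r, class = "fa_rules")
}

#' @export
print.fa_rules <- function(x, ...) {
  act <- active_rules(x)
  cat("<fa_rules>", if (length(act)) paste(act, collapse = ", ") else "(none)", "\n")
  for (nm in names(x)) {
    if (!is.null(x[[nm]])) cat(" ", nm, "=", paste(x[[nm]], collapse = ", "), "\n")
  }
  invisible(x)
}

# General-rule names in canonical order.
GENERAL_RULES <- c("main_rotation", "reflection", "trapezium_rotation",
                   "subtraction", "dot_movement")

#' Active general rules of a rule set
#'
#' @param rules An `fa_rules` object.
#' @return Character vector of the general-rule names whose arguments have a
#'   non-zero effect.
#' @export
active_rules <- function(rules) {
  act <- character(0)
  if (!is.null(rules$main.rot) && any(rules$main.rot != 0)) act <- c(act, "main_rotation")
  if (isTRUE(rules$mirror)) act <- c(act, "reflection")
  if (!is.null(rules$trap.rot) && any(rules$trap.rot != 0)) act <- c(act, "trapezium_rotation")
  if (!is.null(rules$subtract)) act <- c(act, "subtraction")
  if (!is.null(rules$dot.mov) && any(rules$dot.mov != 0)) act <- c(act, "dot_movement")
  act
}

valid_angle <- function(a) is.numeric(a) & !is.na(a) & a %% 45 == 0 & a >= -135 & a <= 180

#' Validate a rule set
#'
#' Checks every combination constraint of the rule algebra and returns the
#' violations as data (never as errors): at least one radical must be active;
#' reflection and main rotation are mutually exclusive; rotation angles must
#' be multiples of 45 in \[-135, 180\]; the two dot-movement counts must be
#' non-negative and sum to five at most (the internal-line path has five
#' edges); subtraction must name two distinct lines in 1..5 or `"R"`.
#'
#' @param rules An `fa_rules` object.
#' @return An object of class `fa_validation`: list with elements `ok`
#'   (logical) and `violations` (character vector, empty on a pass).
#' @examples
#' validate_rules(fa_rules(main.rot = c(90, 45)))$ok          # TRUE
#' validate_rules(fa_rules(dot.mov = c(3, 3)))$violations     # sum exceeds five
#' @export
validate_rules <- function(rules) {
  if (!inherits(rules, "fa_rules")) stop_invalid("`rules` must be an `fa_rules` object")
  v <- character(0)
  if (length(active_rules(rules)) == 0L)
    v <- c(v, "at least one radical must be manipulated")
  if (!is.null(rules$main.rot) && isTRUE(rules$mirror))
    v <- c(v, "mutually exclusive radicals: mirror and main rotation cannot be manipulated together")
  for (nm in c("main.rot", "trap.rot")) {
    a <- rules[[nm]]
    if (!is.null(a) && !all(valid_angle(a)))
      v <- c(v, sprintf("%s angles must be multiples of 45 within [-135, 180]", nm))
  }
  if (!is.null(rules$dot.mov)) {
    dm <- rules$dot.mov
    if (any(dm < 0) || any(dm != round(dm)))
      v <- c(v, "dot.mov counts must be non-negative integers")
    else if (sum(dm) > 5)
      v <- c(v, "dot.mov sum exceeds five (the path has only five edges)")
  }
  if (!is.null(rules$subtract)) {
    s <- rules$subtract
    random <- is.character(s) && length(s) == 1L && identical(toupper(s), "R")
    if (!random) {
      if (!(is.numeric(s) && length(s) == 2L && all(s == round(s)) &&
            all(s >= 1 & s <= 5)))
        v <- c(v, "subtract must name two lines in 1..5, or be \"R\"")
      else if (s[1] == s[2])
        v <- c(v, "subtract lines must differ between the two pathways")
    }
  }
  structure(list(ok = length(v) == 0L, violations = v), class = "fa_validation")
}

#' @export
print.fa_validation <- function(x, ...) {
  if (x$ok) cat("Rule set: pass\n")
  else cat("Rule set violations:\n", paste0(" - ", x$violations, collapse = "\n"), "\n")
  invisible(x)
}

# Resolve build-time randomness in a rule set relative to a concrete shape A:
# draw the random subtraction pair, fix the dot travel direction, and (if
# needed) relocate A's dot toward the corners attached to the broken circle.
# Returns list(A = possibly moved A, rules = concrete rules).
resolve_rules <- function(A, rules) {
  if (!is.null(rules$subtract)) {
    s <- rules$subtract
    if (is.character(s)) {
      s <- sample(1:5, 2L)
      rules$subtract <- s
    }
  }
  if (!is.null(rules$dot.mov) && any(rules$dot.mov != 0)) {
    A <- relocate_dot_if_needed(A, rules$dot.mov)
    total <- sum(rules$dot.mov)
    dir <- if (A$dot + total <= 6L) 1L else -1L
    attr(rules, "dot_dir") <- dir
  }
  list(A = A, rules = rules)
}

#' Apply one solution pathway of a rule set
#'
#' Applies the pathway component (A-to-B or A-to-C) of every active rule to a
#' figure, in the fixed order reflection/main rotation, trapezium rotation,
#' line subtraction, dot movement.  Reflection uses the x axis on the A-to-B
#' pathway and the y axis on A-to-C.  The rules must be concrete: a random
#' subtraction (`"R"`) has to be resolved (as [build_analogies()] does)
#' before a pathway can be applied.
#'
#' @param state The starting `fa_state`.
#' @param rules An `fa_rules` object with concrete arguments.
#' @param pathway `"AB"` or `"AC"`.
#' @return The transformed `fa_state`.
#' @examples
#' A <- fa_state()
#' B <- apply_pathway(A, fa_rules(main.rot = c(90, 45)), "AB")
#' B$main  # 3
#' @export
apply_pathway <- function(state, rules, pathway = c("AB", "AC")) {
  pathway <- match.arg(pathway)
  i <- if (pathway == "AB") 1L else 2L
  if (isTRUE(rules$mirror)) {
    state <- reflect_main(state, if (pathway == "AB") "x" else "y")
  }
  if (!is.null(rules$main.rot) && rules$main.rot[i] != 0) {
    state <- rotate_main(state, rules$main.rot[i])
  }
  if (!is.null(rules$trap.rot) && rules$trap.rot[i] != 0) {
    state <- rotate_trapezium(state, rules$trap.rot[i])
  }
  if (!is.null(rules$subtract)) {
    if (is.character(rules$subtract))
      stop_invalid("random subtraction (\"R\") must be resolved before applying a pathway")
    if (rules$subtract[i] != 0) state <- subtract_line(state, rules$subtract[i])
  }
  if (!is.null(rules$dot.mov) && rules$dot.mov[i] != 0) {
    dir <- attr(rules, "dot_dir")
    if (is.null(dir)) dir <- if (state$dot + sum(rules$dot.mov) <= 6L) 1L else -1L
    state <- move_dot(state, rules$dot.mov[i], dir)
  }
  state
}

#' Build an analogy stem from a shape A and a rule set
#'
#' Resolves build-time randomness (random subtraction, dot travel direction,
#' dot relocation), then derives B and C by applying the two pathway
#' components of the rules to A.
#'
#' @param A The starting `fa_state` (incidentals of shape A).
#' @param rules An `fa_rules` object that passes [validate_rules()].
#' @return An object of class `fa_stem`: list with `A`, `B`, `C` and the
#'   concrete `rules`.
#' @examples
#' stem <- make_stem(fa_state(), fa_rules(dot.mov = c(1, 2)))
#' solve_item(stem)
#' @export
make_stem <- function(A, rules) {
  val <- validate_rules(rules)
  if (!val$ok) stop_invalid("invalid rule set: %s", paste(val$violations, collapse = "; "))
  res <- resolve_rules(A, rules)
  A <- res$A; rules <- res$rules
  B <- apply_pathway(A, rules, "AB")
  C <- apply_pathway(A, rules, "AC")
  structure(list(A = A, B = B, C = C, rules = rules), class = "fa_stem")
}

#' Solve an analogy stem
#'
#' Computes the unique missing figure D.  Both solution pathways must agree:
#' applying the A-to-C changes to B has to give the same figure as applying
#' the A-to-B changes to C; a disagreement signals an internal inconsistency
#' in the rule engine and raises an error.
#'
#' @param stem An `fa_stem` from [make_stem()].
#' @return The `fa_state` of the correct answer D.
#' @examples
#' stem <- make_stem(fa_state(main = 1), fa_rules(main.rot = c(90, 45)))
#' solve_item(stem)$main  # 1 + (90+45)/45 = 4
#' @export
solve_item <- function(stem) {
  if (!inherits(stem, "fa_stem")) stop_invalid("`stem` must be an `fa_stem` object")
  D1 <- apply_pathway(stem$B, stem$rules, "AC")
  D2 <- apply_pathway(stem$C, stem$rules, "AB")
  if (!states_equal(D1, D2))
    fa_stop("fa_inconsistent", "solution pathways disagree: %s vs %s",
            format(D1), format(D2))
  D1
}

#' The nine specific rules
#'
#' The canonical catalogue of specific rules: three main-shape rotations
#' (short clockwise, short counterclockwise, long clockwise), three
#' trapezium rotations with the same variants, reflection, line subtraction
#' and dot movement.  Each specific rule maps to exactly one of the five
#' general rules.
#'
#' @return A data frame with columns `id` (1..9), `general` (general-rule
#'   name) and `label`.
#' @examples
#' specific_rules()
#' @export
specific_rules <- function() {
  data.frame(
    id = 1:9,
    general = c(rep("main_rotation", 3), rep("trapezium_rotation", 3),
                "reflection", "subtraction", "dot_movement"),
    label = c(
      "short clockwise main-shape rotation",
      "short counterclockwise main-shape rotation",
      "long clockwise main-shape rotation",
      "short clockwise trapezium rotation",
      "short counterclockwise trapezium rotation",
      "long clockwise trapezium rotation",
      "reflection", "subtraction", "dot movement"
    ),
    stringsAsFactors = FALSE
  )
}

#' Canonical arguments of a specific rule
#'
#' @param id Specific-rule id in 1..9.
#' @return A named list of `fa_rules()` arguments realizing that rule
#'   (e.g. id 2 is `main.rot = c(90, 45)`: counterclockwise by 90 degrees
#'   A-to-B and by 45 degrees A-to-C).
#' @examples
#' specific_rule_args(6)  # trap.rot = c(180, -135)
#' @export
specific_rule_args <- function(id) {
  if (!is_count(id, 1L) || id > 9) stop_invalid("`id` must be an integer in 1..9")
  switch(as.integer(id),
    list(main.rot = c(-90, -45)),
    list(main.rot = c(90, 45)),
    list(main.rot = c(180, -135)),
    list(trap.rot = c(-90, -45)),
    list(trap.rot = c(90, 45)),
    list(trap.rot = c(180, -135)),
    list(mirror = 1),
    list(subtract = "R"),
    list(dot.mov = c(1, 2))
  )
}

# Classify the active rules of a rule set into specific-rule ids 1..9.
# Rotation variants are classified by the A-to-B angle: magnitude <= 90 is
# "short" (sign gives the direction), larger magnitudes are "long".
classify_specific <- function(rules) {
  ids <- integer(0)
  rot_id <- function(a, base) {
    if (abs(a[1]) <= 90) {
      if (a[1] < 0) base else base + 1L
    } else base + 2L
  }
  if (!is.null(rules$main.rot) && any(rules$main.rot != 0))
    ids <- c(ids, rot_id(rules$main.rot, 1L))
  if (!is.null(rules$trap.rot) && any(rules$trap.rot != 0))
    ids <- c(ids, rot_id(rules$trap.rot, 4L))
  if (isTRUE(rules$mirror)) ids <- c(ids, 7L)
  if (!is.null(rules$subtract)) ids <- c(ids, 8L)
  if (!is.null(rules$dot.mov) && any(rules$dot.mov != 0)) ids <- c(ids, 9L)
  sort(ids)
}
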