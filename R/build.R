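#' Incidental space of shape A
#'
#' The incidentals of an item are the initial positions of the parts of
#' shape A: main-shape rotational state (1..8), flip (yes/no), trapezium
#' state (1..8) and dot corner (1..6).  The full space therefore holds
#' 8 x 2 x 8 x 6 = 768 configurations.  A part can be *constricted* so that
#' every run of n consecutive isomorphs covers all n positions of that part.
#'
#' @param main Subset of 1:8 allowed for the main-shape state.
#' @param flip Subset of `c(FALSE, TRUE)`.
#' @param trap Subset of 1:8 for the trapezium state.
#' @param dot Subset of 1:6 for the dot corner.
#' @param constrict `"none"`, `"main"`, `"trap"` or `"dot"`.
#' @return An object of class `fa_incidental_space` with a `capacity`
#'   attribute (product of the domain sizes).
#' @examples
#' attr(incidental_space(), "capacity")  # 768
#' @export
incidental_space <- function(main = 1:8, flip = c(FALSE, TRUE), trap = 1:8,
                             dot = 1:6, constrict = c("none", "main", "trap", "dot")) {
  constrict <- match.arg(constrict)
  main <- unique(as.integer(main)); trap <- unique(as.integer(trap))
  dot <- unique(as.integer(dot)); flip <- unique(as.logical(flip))
  if (length(main) == 0L || any(main < 1L | main > 8L))
    stop_invalid("`main` must be a non-empty subset of 1:8")
  if (length(trap) == 0L || any(trap < 1L | trap > 8L))
    stop_invalid("`trap` must be a non-empty subset of 1:8")
  if (length(dot) == 0L || any(dot < 1L | dot > 6L))
    stop_invalid("`dot` must be a non-empty subset of 1:6")
  if (length(flip) == 0L || anyNA(flip))
    stop_invalid("`flip` must be a non-empty subset of c(FALSE, TRUE)")
  sp <- structure(list(main = main, flip = flip, trap = trap, dot = dot,
                       constrict = constrict),
                  class = "fa_incidental_space")
  attr(sp, "capacity") <- length(main) * length(flip) * length(trap) * length(dot)
  sp
}

#' Enumerate incidental configurations
#'
#' Yields the first `n` shape-A configurations of a seeded traversal of the
#' incidental space.  Without constriction this is a seeded permutation of
#' the full Cartesian product which, once exhausted, runs again from its
#' start — so with the full space the first repetition occurs at index 769.
#' With `constrict` set, every consecutive block of m configurations covers
#' all m positions of the constricted part (m = that part's domain size)
#' while the remaining parts still cycle through a seeded permutation of
#' their own product.
#'
#' @param space An [incidental_space()].
#' @param n Number of configurations to produce.
#' @param seed Optional seed making the traversal reproducible.
#' @return A data frame with `n` rows and columns `main`, `flip`, `trap`,
#'   `dot`.
#' @examples
#' inc <- enumerate_incidentals(incidental_space(), 4, seed = 1)
#' @export
enumerate_incidentals <- function(space, n, seed = NULL) {
  if (!inherits(space, "fa_incidental_space"))
    stop_invalid("`space` must come from incidental_space()")
  if (!is_count(n, 1L)) stop_invalid("`n` must be a positive integer")
  n <- as.integer(n)
  with_seed(seed, {
    if (space$constrict == "none") {
      grid <- expand.grid(main = space$main, flip = space$flip,
                          trap = space$trap, dot = space$dot,
                          KEEP.OUT.ATTRS = FALSE)
      perm <- sample(nrow(grid))
      idx <- perm[((seq_len(n) - 1L) %% nrow(grid)) + 1L]
      grid[idx, , drop = FALSE]
    } else {
      part <- space$constrict
      dom <- space[[part]]
      m <- length(dom)
      rest_names <- setdiff(c("main", "flip", "trap", "dot"), part)
      rest <- expand.grid(space[rest_names], KEEP.OUT.ATTRS = FALSE)
      rest_perm <- sample(nrow(rest))
      n_blocks <- ceiling(n / m)
      part_vals <- unlist(lapply(seq_len(n_blocks), function(b) dom[sample(m)]))
      out <- rest[rest_perm[((seq_len(n) - 1L) %% nrow(rest)) + 1L], , drop = FALSE]
      out[[part]] <- part_vals[seq_len(n)]
      out[, c("main", "flip", "trap", "dot"), drop = FALSE]
    }
  }) -> res
  rownames(res) <- NULL
  res
}

#' Relocate the dot for long traversals
#'
#' A dot-movement rule whose two edge counts sum to s needs s free edges in
#' one direction from shape A's dot corner.  When the sum exceeds 3 and the
#' current corner cannot host both traversals, the dot is moved to the
#' nearest feasible corner among those attached to the broken circle
#' (corners 5 and 6, corner 6 being a path endpoint); sums of 3 or less are
#' feasible from every corner and leave A unchanged.
#'
#' @param A Shape A, an `fa_state`.
#' @param dot_mov Pair of non-negative edge counts, summing to at most 5.
#' @return The (possibly relocated) `fa_state`; always feasible.
#' @examples
#' relocate_dot_if_needed(fa_state(dot = 3), c(2, 3))$dot  # 6
#' @export
relocate_dot_if_needed <- function(A, dot_mov) {
  if (!(is.numeric(dot_mov) && length(dot_mov) == 2L) || any(dot_mov < 0))
    stop_invalid("`dot_mov` must be a pair of non-negative counts")
  s <- sum(dot_mov)
  if (s > 5) stop_invalid("dot movement sum exceeds the five path edges")
  feasible <- function(cr) (cr + s <= 6L) || (cr - s >= 1L)
  if (s <= 3 || feasible(A$dot)) return(A)
  bc <- c(5L, 6L)  # corners attached to the broken circle
  cand <- bc[vapply(bc, feasible, logical(1))]
  A$dot <- cand[order(abs(cand - A$dot), cand)][1L]
  A
}

#' Build a family of figural analogy items
#'
#' The main generator.  Given the radicals (rules) of an item model, builds
#' `isomorphs` items that share those rules and differ only in incidentals:
#' for each item it draws shape A from the incidental space, derives B and C
#' along the two solution pathways, solves for D, and assembles the eight
#' figural response options with a Solutions Combination Design.  One-rule
#' items receive a randomly drawn extra rule that varies in the options only
#' (suppress it with `add.rule = -1`, accepting that some single rules
#' cannot furnish seven distinct alternatives).
#'
#' @param isomorphs Number of items to create within the family.
#' @param main.rot,mirror,trap.rot,subtract,dot.mov Rule arguments, see
#'   [fa_rules()].  At least one rule must be active; `mirror` and
#'   `main.rot` cannot be combined.
#' @param correct Optional set of positions in 1..9 for the correct answer
#'   (9 keys the "no answer is correct" option); used cyclically across
#'   isomorphs.  By default a seeded random draw from 1..8.
#' @param add.rule For one-rule items: `NULL` to draw the extra option rule
#'   at random, an integer 1..5 naming a general rule (order: main rotation,
#'   reflection, trapezium rotation, subtraction, dot movement), or `-1` to
#'   suppress it.
#' @param a.main,a.flip,a.trap,a.dot Incidental domains, see
#'   [incidental_space()].
#' @param constrict Optional part whose positions must all appear in every
#'   block of consecutive isomorphs (`"main"`, `"trap"` or `"dot"`).
#' @param user_alts Optional named list of user-chosen alternative solutions
#'   (see [generate_alternatives()]); used instead of random draws.
#' @param seed Optional master seed; the same seed reproduces the bank
#'   bit-identically.
#' @return An object of class `fa_item_bank`: list with `items` (each of
#'   class `fa_item`), the family `rules`, `seed` and accumulated
#'   `warnings`.
#' @examples
#' two <- build_analogies(isomorphs = 2, dot.mov = c(1, 2), seed = 7)
#' length(two$items)            # 2
#' two$items[[1]]$correct_position
#' @export
build_analogies <- function(isomorphs = 1L, main.rot = NULL, mirror = NULL,
                            trap.rot = NULL, subtract = NULL, dot.mov = NULL,
                            correct = NULL, add.rule = NULL,
                            a.main = 1:8, a.flip = c(FALSE, TRUE),
                            a.trap = 1:8, a.dot = 1:6,
                            constrict = c("none", "main", "trap", "dot"),
                            user_alts = NULL, seed = NULL) {
  if (!is_count(isomorphs, 1L)) stop_invalid("`isomorphs` must be a positive integer")
  isomorphs <- as.integer(isomorphs)
  rules <- fa_rules(main.rot = main.rot, mirror = mirror, trap.rot = trap.rot,
                    subtract = subtract, dot.mov = dot.mov)
  val <- validate_rules(rules)
  if (!val$ok)
    stop_invalid("invalid rule set: %s", paste(val$violations, collapse = "; "))
  if (!is.null(correct)) {
    if (!(is.numeric(correct) && all(correct == round(correct)) &&
          all(correct >= 1 & correct <= 9)))
      stop_invalid("`correct` positions must be integers in 1..9")
    correct <- as.integer(correct)
  }
  constrict <- match.arg(constrict)
  space <- incidental_space(a.main, a.flip, a.trap, a.dot, constrict)
  warnings <- character(0)
  capacity <- attr(space, "capacity")
  if (isomorphs > capacity) {
    warnings <- c(warnings, sprintf(
      "items after number %d may repeat the main problem of an earlier isomorph (incidental capacity reached)",
      capacity))
  }

  act <- active_rules(rules)
  suppress_extra <- !is.null(add.rule) && length(add.rule) == 1L && add.rule == -1
  if (suppress_extra && length(act) == 1L) {
    warnings <- c(warnings,
      "extra option rule suppressed: a single rule must furnish seven distinct alternatives")
  }

  inc <- enumerate_incidentals(space, isomorphs, seed = sub_seed(seed, "incidentals"))
  positions <- with_seed(sub_seed(seed, "correct"), {
    if (is.null(correct)) sample(1:8, isomorphs, replace = TRUE)
    else correct[((seq_len(isomorphs) - 1L) %% length(correct)) + 1L]
  })

  items <- vector("list", isomorphs)
  for (i in seq_len(isomorphs)) {
    items[[i]] <- with_seed(sub_seed(seed, paste0("item", i)), {
      build_one_item(rules, inc[i, ], positions[i], add.rule, suppress_extra,
                     user_alts, space, isomorph_index = i)
    })
  }
  structure(list(items = items, rules = rules, seed = seed,
                 warnings = warnings),
            class = "fa_item_bank")
}

# Build a single item; redraws incidentals (within the space) on infeasible
# draws, bounded at 100 attempts.
build_one_item <- function(rules, inc_row, correct_position, add.rule,
                           suppress_extra, user_alts, space, isomorph_index) {
  act <- active_rules(rules)
  for (attempt in 1:100) {
    res <- tryCatch({
      A <- fa_state(main = inc_row$main, flip = inc_row$flip,
                    trap = inc_row$trap, dot = inc_row$dot)
      stem <- make_stem(A, rules)
      D <- solve_item(stem)

      extra_rule <- NULL
      if (length(act) == 1L && !suppress_extra) {
        pool <- setdiff(GENERAL_RULES, act)
        # a reflection-type extra would act on the same part as a rotation
        # alternative (the main shape), risking option collisions
        if (act %in% c("main_rotation", "reflection"))
          pool <- setdiff(pool, c("main_rotation", "reflection"))
        if (!is.null(add.rule) && add.rule %in% 1:5) {
          chosen <- GENERAL_RULES[c(1L, 2L, 3L, 4L, 5L)][as.integer(add.rule)]
          if (!chosen %in% pool)
            stop_invalid("`add.rule` names a rule already active in the stem (or incompatible)")
          extra_rule <- chosen
        } else {
          extra_rule <- sample(pool, 1L)
        }
      }
      layout <- if (length(act) == 1L && suppress_extra) scd_single_suppressed()
                else scd_design(length(act))
      sets <- generate_alternatives(stem$rules, layout, D,
                                    A_lines = stem$A$lines,
                                    extra_rule = extra_rule,
                                    user_alts = user_alts)
      opts <- assemble_options(layout, sets, D, A_lines = stem$A$lines,
                               correct_position = correct_position)
      structure(list(
        stem = stem, solution = D, options = opts,
        correct_position = opts$correct_position,
        isomorph_index = isomorph_index,
        rules_used = act, extra_rule = extra_rule,
        specific_rules = classify_specific(stem$rules)
      ), class = "fa_item")
    }, fa_infeasible = function(e) e, fa_assembly = function(e) e)
    if (!inherits(res, "condition")) return(res)
    # unlucky draw: redraw the incidentals at random within the space
    inc_row <- list(main = sample(space$main, 1L),
                    flip = sample(space$flip, 1L),
                    trap = sample(space$trap, 1L),
                    dot = sample(space$dot, 1L))
  }
  fa_stop("fa_infeasible", "no feasible item found in 100 incidental draws: %s",
          conditionMessage(res))
}

#' @export
print.fa_item <- function(x, ...) {
  cat(sprintf("<fa_item #%d> rules: %s | correct position: %d\n",
              x$isomorph_index, paste(x$rules_used, collapse = ", "),
              x$correct_position))
  invisible(x)
}

#' @export
print.fa_item_bank <- function(x, ...) {
  cat(sprintf("Figural analogy item bank: %d item(s)\n", length(x$items)))
  if (!is.null(x$rules)) {
    cat("Family rules:", paste(active_rules(x$rules), collapse = ", "), "\n")
  }
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' Combine item banks into one test
#'
#' Concatenates the items of several banks (e.g. one-isomorph families with
#' different rules) into a single heterogeneous bank, renumbering items
#' consecutively.  The combined bank has no single family rule set.
#'
#' @param ... `fa_item_bank` objects.
#' @return An `fa_item_bank` whose `rules` is `NULL`.
#' @export
c.fa_item_bank <- function(...) {
  banks <- list(...)
  items <- do.call(c, lapply(banks, function(b) b$items))
  for (i in seq_along(items)) items[[i]]$isomorph_index <- i
  structure(list(items = items, rules = NULL, seed = NULL,
                 warnings = unlist(lapply(banks, function(b) b$warnings))),
            class = "fa_item_bank")
}
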