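#' Solutions Combination Design layout
#'
#' Returns the Solutions Combination Design (SCD) used to build the eight
#' figural response options of an item, as a function of how many rules the
#' item manipulates:
#' * 1 rule: a 4 x 2 design — four solutions for the manipulated rule
#'   crossed with two solutions for an extra rule that is absent from the
#'   stem; nothing eliminated (8 options).
#' * 2 rules: a 3 x 3 design — nine raw combinations, of which one that is
#'   not the right answer is eliminated (8 options).  All four
#'   both-incorrect candidates differ from the key in exactly two parts, so
#'   the eliminated one is a seeded uniform draw among them.
#' * 3 rules: a 2^3 design, nothing eliminated (8 options).
#' * 4 rules: a 2^4 design with the combinations holding exactly three
#'   correct or exactly three incorrect solutions eliminated, for a balanced
#'   mix (8 options).
#'
#' In the returned combination matrices, column j refers to rule j of the
#' design and entry 1 denotes that rule's correct solution; entries 2, 3,
#' ... denote its alternatives.
#'
#' @param n_rules Number of rules the item manipulates, 1..4.
#' @param seed Optional seed for the 3 x 3 elimination draw.
#' @return An object of class `fa_scd`: list with `n_rules`, `counts`
#'   (solutions per rule), `combos` (8 x k surviving combinations),
#'   `eliminated` (matrix of dropped combinations, possibly empty) and
#'   `raw_n` (raw combination count).
#' @examples
#' scd_design(2)$raw_n          # 9
#' nrow(scd_design(4)$combos)   # 8
#' @export
scd_design <- function(n_rules, seed = NULL) {
  if (!is_count(n_rules, 1L) || n_rules > 4)
    stop_invalid("`n_rules` must be an integer in 1..4")
  n_rules <- as.integer(n_rules)
  counts <- switch(n_rules, c(4L, 2L), c(3L, 3L), rep(2L, 3), rep(2L, 4))
  combos <- as.matrix(expand.grid(lapply(counts, seq_len), KEEP.OUT.ATTRS = FALSE))
  dimnames(combos) <- list(NULL, paste0("rule", seq_along(counts)))
  raw_n <- nrow(combos)
  eliminated <- combos[0, , drop = FALSE]
  if (n_rules == 2L) {
    both_wrong <- which(combos[, 1] > 1L & combos[, 2] > 1L)
    drop <- with_seed(seed, sample(both_wrong, 1L))
    eliminated <- combos[drop, , drop = FALSE]
    combos <- combos[-drop, , drop = FALSE]
  } else if (n_rules == 4L) {
    n_correct <- rowSums(combos == 1L)
    drop <- which(n_correct %in% c(1L, 3L))
    eliminated <- combos[drop, , drop = FALSE]
    combos <- combos[-drop, , drop = FALSE]
  }
  stopifnot(nrow(combos) == 8L, sum(rowSums(combos == 1L) == ncol(combos)) == 1L)
  structure(list(n_rules = n_rules, counts = counts, combos = combos,
                 eliminated = eliminated, raw_n = raw_n),
            class = "fa_scd")
}

# Single-rule design with the extra rule suppressed: eight solutions for the
# one manipulated rule (the correct one plus seven alternatives).
scd_single_suppressed <- function() {
  combos <- matrix(1:8, ncol = 1, dimnames = list(NULL, "rule1"))
  structure(list(n_rules = 1L, counts = 8L, combos = combos,
                 eliminated = combos[0, , drop = FALSE], raw_n = 8L),
            class = "fa_scd")
}

# ---- alternative solutions ---------------------------------------------

# An alternative solution is a transformation applied to the correct answer
# D ("the right answer as the reference"):
#   main_rotation      : list(offset)           rotate D's main shape
#   reflection         : list(offset, flip)     optional flip toggle + rotation
#   trapezium_rotation : list(offset)           rotate D's trapezium
#   subtraction        : list(lines)            remove these lines from A
#                                               instead of the correct ones
#   dot_movement       : list(corner)           place the dot on this corner
apply_alternative <- function(state, rule, spec, A_lines) {
  switch(rule,
    main_rotation = rotate_main(state, spec$offset),
    reflection = {
      if (spec$flip) state <- reflect_main(state, "x")
      if (spec$offset != 0) state <- rotate_main(state, spec$offset)
      state
    },
    trapezium_rotation = rotate_trapezium(state, spec$offset),
    subtraction = {
      state$lines <- sort(setdiff(A_lines, spec$lines))
      if (length(state$lines) == 0L)
        stop_infeasible("subtraction alternative would remove every line")
      state
    },
    dot_movement = {
      state$dot <- as.integer(spec$corner)
      state
    },
    stop_invalid("unknown rule '%s'", rule)
  )
}

# Default pools for randomly drawn alternatives.  Rotation offsets prefer the
# near misses (+-45, +-90) and fall back to the remaining distinct rotations
# when a design needs more than four alternatives.
draw_alternatives <- function(rule, n, D, A_lines, correct_subtract = NULL,
                              partial = FALSE) {
  key_of <- function(spec) state_key(apply_alternative(D, rule, spec, A_lines))
  d_key <- state_key(D)
  specs <- switch(rule,
    main_rotation = ,
    trapezium_rotation = {
      near <- c(-90, -45, 45, 90)
      far <- c(-135, 135, 180)
      pool <- c(sample(near), sample(far))
      lapply(pool, function(o) list(offset = o))
    },
    reflection = {
      pool <- list(
        list(offset = 0, flip = TRUE), list(offset = 45, flip = FALSE),
        list(offset = -45, flip = FALSE), list(offset = 45, flip = TRUE),
        list(offset = -45, flip = TRUE), list(offset = 90, flip = FALSE),
        list(offset = -90, flip = FALSE), list(offset = 90, flip = TRUE),
        list(offset = -90, flip = TRUE), list(offset = 180, flip = FALSE)
      )
      pool[sample(length(pool))]
    },
    subtraction = {
      pairs <- utils::combn(1:5, 2, simplify = FALSE)
      singles <- as.list(1:5)
      pool <- c(pairs, singles)[sample(length(pairs) + 5L)]
      if (!is.null(correct_subtract)) {
        pool <- Filter(function(p) length(setdiff(p, correct_subtract)) >= 1L, pool)
      }
      lapply(pool, function(p) list(lines = p))
    },
    dot_movement = {
      corners <- sample(setdiff(1:6, D$dot))
      lapply(corners, function(cr) list(corner = cr))
    },
    stop_invalid("unknown rule '%s'", rule)
  )
  out <- list(); seen <- d_key
  for (s in specs) {
    k <- tryCatch(key_of(s), error = function(e) NA_character_)
    if (is.na(k) || k %in% seen) next
    out <- c(out, list(s)); seen <- c(seen, k)
    if (length(out) == n) break
  }
  if (length(out) < n && !partial)
    fa_stop("fa_assembly", "rule '%s' cannot furnish %d distinct alternatives", rule, n)
  out
}

#' Generate per-rule solution sets for the response options
#'
#' For every rule in the design, produces the correct solution plus the
#' number of alternative (incorrect) solutions the SCD layout requires.
#' Alternatives use the right answer D as the reference: rotation
#' alternatives are angular offsets from D, subtraction alternatives remove
#' up to two lines with at least one differing from the correct subtraction,
#' dot alternatives are corners distinct in effect from the correct corner.
#' Alternatives are drawn at random (seeded) by default; user-supplied
#' alternatives are validated against the layout counts and must never
#' reproduce the correct solution's effect.
#'
#' @param rules Concrete `fa_rules` of the item (as found in a built stem).
#' @param layout An `fa_scd` layout from [scd_design()].
#' @param D The correct answer, an `fa_state` from [solve_item()].
#' @param A_lines The internal lines present in shape A (context for
#'   subtraction alternatives).
#' @param extra_rule For one-rule items, the general-rule name of the extra
#'   rule that varies in the options only.
#' @param user_alts Optional named list (by general-rule name) of alternative
#'   specs; each spec is a list as documented in the package vignette.
#' @param seed Optional seed for the random draws.
#' @return A list of class `fa_solution_sets`: one element per design rule,
#'   each with `rule`, and `alternatives` (list of transformation specs).
#' @export
generate_alternatives <- function(rules, layout, D, A_lines = 1:5,
                                  extra_rule = NULL, user_alts = NULL,
                                  seed = NULL) {
  design_rules <- active_rules(rules)
  if (!is.null(extra_rule)) {
    if (!extra_rule %in% GENERAL_RULES || extra_rule %in% design_rules)
      stop_invalid("`extra_rule` must be a general rule absent from the stem")
    design_rules <- c(design_rules, extra_rule)
  }
  if (length(design_rules) != length(layout$counts))
    stop_invalid("layout expects %d rules, stem provides %d",
                 length(layout$counts), length(design_rules))
  with_seed(seed, {
    sets <- vector("list", length(design_rules))
    for (j in seq_along(design_rules)) {
      rule <- design_rules[j]
      n_alt <- layout$counts[j] - 1L
      if (!is.null(user_alts) && !is.null(user_alts[[rule]])) {
        alts <- user_alts[[rule]]
        if (length(alts) != n_alt)
          stop_invalid("rule '%s' needs exactly %d alternative(s), got %d",
                       rule, n_alt, length(alts))
        keys <- character(0)
        for (s in alts) {
          k <- state_key(apply_alternative(D, rule, s, A_lines))
          if (k == state_key(D))
            fa_stop("fa_invalid_alternative",
                    "an alternative for rule '%s' reproduces the correct solution", rule)
          if (k %in% keys)
            fa_stop("fa_invalid_alternative",
                    "two alternatives for rule '%s' have the same effect", rule)
          keys <- c(keys, k)
        }
      } else {
        alts <- draw_alternatives(rule, n_alt, D, A_lines,
                                  correct_subtract = rules$subtract)
      }
      sets[[j]] <- list(rule = rule, alternatives = alts)
    }
    structure(sets, class = "fa_solution_sets")
  })
}

# Realize one SCD combination as a figure state.
combo_state <- function(combo, sets, D, A_lines) {
  state <- D
  for (j in seq_along(combo)) {
    m <- combo[j]
    if (m > 1L) {
      state <- apply_alternative(state, sets[[j]]$rule,
                                 sets[[j]]$alternatives[[m - 1L]], A_lines)
    }
  }
  state
}

#' Assemble the eight response options of an item
#'
#' Maps the surviving SCD combinations to the eight option slots (read left
#' to right, top down).  The all-correct combination lands on
#' `correct_position` when that is 1..8; the remaining combinations are
#' placed in seeded random order.  When `correct_position` is 9 (the
#' "no answer is correct" slot is keyed), the all-correct combination is
#' replaced by a similar near-miss — the key with one rule's solution
#' swapped to a fresh alternative that duplicates no existing option — or,
#' failing that, by a previously eliminated combination.
#'
#' @inheritParams generate_alternatives
#' @param sets Solution sets from [generate_alternatives()].
#' @param correct_position Integer 1..9.
#' @param seed Optional placement seed.
#' @return A list of class `fa_options`: `states` (8 pairwise-distinct
#'   `fa_state`s), `correct_position`, and `combos` (the combination behind
#'   each slot).
#' @export
assemble_options <- function(layout, sets, D, A_lines = 1:5,
                             correct_position = 1L, seed = NULL) {
  if (!is_count(correct_position, 1L) || correct_position > 9)
    stop_invalid("`correct_position` must be an integer in 1..9")
  correct_position <- as.integer(correct_position)
  with_seed(seed, {
    combos <- layout$combos
    states <- lapply(seq_len(nrow(combos)), function(r)
      combo_state(combos[r, ], sets, D, A_lines))
    keys <- vapply(states, state_key, character(1))
    if (anyDuplicated(keys)) {
      dup <- which(keys == keys[anyDuplicated(keys)])
      fa_stop("fa_assembly", "options %s collide (identical figures)",
              paste(dup, collapse = " and "))
    }
    key_row <- which(rowSums(combos == 1L) == ncol(combos))

    if (correct_position == 9L) {
      repl <- NULL
      for (j in seq_along(sets)) {
        cands <- draw_alternatives(sets[[j]]$rule, 20L, D, A_lines, partial = TRUE)
        for (cand in cands) {
          st <- apply_alternative(D, sets[[j]]$rule, cand, A_lines)
          if (!(state_key(st) %in% keys)) { repl <- st; break }
        }
        if (!is.null(repl)) break
      }
      if (is.null(repl) && nrow(layout$eliminated) > 0L) {
        for (r in seq_len(nrow(layout$eliminated))) {
          st <- combo_state(layout$eliminated[r, ], sets, D, A_lines)
          if (!(state_key(st) %in% keys)) { repl <- st; break }
        }
      }
      if (is.null(repl))
        fa_stop("fa_assembly", "cannot construct a distinct replacement option")
      states[[key_row]] <- repl
      combos[key_row, ] <- NA_integer_
      slots <- sample(8L)
      states <- states[slots]
      combos <- combos[slots, , drop = FALSE]
    } else {
      others <- setdiff(seq_len(8L), key_row)
      other_slots <- setdiff(seq_len(8L), correct_position)
      perm <- sample(length(others))
      slot_of <- integer(8L)
      slot_of[key_row] <- correct_position
      slot_of[others] <- other_slots[perm]
      inv <- order(slot_of)
      states <- states[inv]
      combos <- combos[inv, , drop = FALSE]
    }
    structure(list(states = states, correct_position = correct_position,
                   combos = combos), class = "fa_options")
  })
}
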