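test_that("rule validation reports every combination constraint as data", {
  v <- validate_rules(fa_rules(main.rot = c(90, 45), mirror = 1))
  expect_false(v$ok)
  expect_match(v$violations, "mutually exclusive", all = FALSE)

  v <- validate_rules(fa_rules())
  expect_false(v$ok)
  expect_match(v$violations, "at least one radical", all = FALSE)

  v <- validate_rules(fa_rules(dot.mov = c(3, 3)))
  expect_false(v$ok)
  expect_match(v$violations, "exceeds five", all = FALSE)

  expect_true(validate_rules(fa_rules(main.rot = c(90, 45)))$ok)
  expect_true(validate_rules(fa_rules(dot.mov = c(2, 3)))$ok)
  expect_true(validate_rules(fa_rules(subtract = "R"))$ok)
  expect_false(validate_rules(fa_rules(subtract = c(2, 2)))$ok)
  expect_false(validate_rules(fa_rules(main.rot = c(30, 45)))$ok)
  expect_false(validate_rules(fa_rules(trap.rot = c(225, 0)))$ok)
})

test_that("pathways apply the stated changes: reflection axes, rotations, identity", {
  A <- fa_state(main = 3, trap = 2, dot = 4)

  B <- apply_pathway(A, fa_rules(mirror = 1), "AB")
  expect_true(states_equal(B, reflect_main(A, "x")))
  C <- apply_pathway(A, fa_rules(mirror = 1), "AC")
  expect_true(states_equal(C, reflect_main(A, "y")))

  r <- fa_rules(trap.rot = c(180, -135))
  expect_equal(apply_pathway(A, r, "AB")$trap, rotate_trapezium(A, 180)$trap)
  expect_equal(apply_pathway(A, r, "AC")$trap, rotate_trapezium(A, -135)$trap)

  expect_true(states_equal(apply_pathway(A, fa_rules(main.rot = c(0, 0)), "AB"), A))
})

test_that("solving a single-rotation stem composes both pathway angles", {
  stem <- make_stem(fa_state(main = 1), fa_rules(main.rot = c(90, 45)))
  D <- solve_item(stem)
  expect_equal(D$main, rotate_main(fa_state(main = 1), 135)$main)
  # clockwise variant
  stem2 <- make_stem(fa_state(main = 5), fa_rules(main.rot = c(-90, -45)))
  expect_equal(solve_item(stem2)$main, rotate_main(fa_state(main = 5), -135)$main)
})

test_that("each of the nine specific rules is expressible and reproduces its changes", {
  A <- fa_state(main = 4, flip = FALSE, trap = 6, dot = 3)
  for (id in 1:9) {
    rules <- do.call(fa_rules, specific_rule_args(id))
    expect_true(validate_rules(rules)$ok)
    stem <- make_stem(A, rules)
    expect_true(states_equal(stem$A, A) ||
                  id == 9)  # the dot rule may relocate A's dot
    D <- solve_item(stem)
    expect_s3_class(D, "fa_state")
  }
  # stated changes, spot checks
  s1 <- make_stem(A, do.call(fa_rules, specific_rule_args(2)))
  expect_equal(s1$B$main, rotate_main(A, 90)$main)
  expect_equal(s1$C$main, rotate_main(A, 45)$main)
  s6 <- make_stem(A, do.call(fa_rules, specific_rule_args(6)))
  expect_equal(s6$B$trap, rotate_trapezium(A, 180)$trap)
  expect_equal(s6$C$trap, rotate_trapezium(A, -135)$trap)
  s9 <- make_stem(fa_state(dot = 1), do.call(fa_rules, specific_rule_args(9)))
  expect_equal(abs(s9$B$dot - s9$A$dot), 1L)
  expect_equal(abs(s9$C$dot - s9$A$dot), 2L)
})

test_that("both pathway orders give the same D for sampled rule sets and incidentals", {
  set.seed(42)
  inc <- all_incidentals()
  for (rules in canonical_rule_sets()) {
    rows <- sample(nrow(inc), 40)
    for (i in rows) {
      A <- fa_state(main = inc$main[i], flip = inc$flip[i],
                    trap = inc$trap[i], dot = inc$dot[i])
      stem <- make_stem(A, rules)
      D1 <- apply_pathway(stem$B, stem$rules, "AC")
      D2 <- apply_pathway(stem$C, stem$rules, "AB")
      expect_true(states_equal(D1, D2))
    }
  }
})

test_that("a four-rule stem solves identically through both pathways over random draws", {
  rules <- fa_rules(mirror = 1, trap.rot = c(90, 45), subtract = c(2, 5),
                    dot.mov = c(1, 2))
  set.seed(7)
  ok <- TRUE
  for (rep in 1:100) {
    A <- fa_state(main = sample(8, 1), flip = sample(c(TRUE, FALSE), 1),
                  trap = sample(8, 1), dot = sample(6, 1))
    stem <- make_stem(A, rules)
    D1 <- apply_pathway(stem$B, stem$rules, "AC")
    D2 <- apply_pathway(stem$C, stem$rules, "AB")
    ok <- ok && states_equal(D1, D2)
  }
  expect_true(ok)
})

test_that("every accepted rule set yields a constructible stem for some incidentals", {
  for (rules in canonical_rule_sets()) {
    expect_true(validate_rules(rules)$ok)
    built <- FALSE
    for (m in 1:2) {
      for (d in 1:6) {
        A <- fa_state(main = m, dot = d)
        res <- tryCatch(make_stem(A, rules), error = function(e) NULL)
        if (!is.null(res)) { built <- TRUE; break }
      }
      if (built) break
    }
    expect_true(built)
  }
})

test_that("random subtraction must be resolved before a pathway can be applied", {
  expect_error(apply_pathway(fa_state(), fa_rules(subtract = "R"), "AB"),
               class = "fa_invalid_argument")
  stem <- make_stem(fa_state(), fa_rules(subtract = "R"))
  expect_true(is.numeric(stem$rules$subtract))
  expect_length(setdiff(stem$A$lines, stem$B$lines), 1L)
})
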