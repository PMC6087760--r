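test_that("SCD layouts match the published designs for one to four rules", {
  d1 <- scd_design(1)
  expect_equal(d1$counts, c(4L, 2L))
  expect_equal(d1$raw_n, 8L)
  expect_equal(nrow(d1$combos), 8L)
  expect_equal(nrow(d1$eliminated), 0L)

  d2 <- scd_design(2, seed = 3)
  expect_equal(d2$raw_n, 9L)
  expect_equal(nrow(d2$combos), 8L)
  expect_equal(nrow(d2$eliminated), 1L)
  expect_true(all(d2$eliminated > 1L))  # never the right answer

  d3 <- scd_design(3)
  expect_equal(d3$raw_n, 8L)
  expect_equal(nrow(d3$combos), 8L)
  expect_equal(nrow(d3$eliminated), 0L)

  d4 <- scd_design(4)
  expect_equal(d4$raw_n, 16L)
  expect_equal(nrow(d4$combos), 8L)
  expect_equal(nrow(d4$eliminated), 8L)
  # eliminated: exactly three correct or three incorrect solutions
  n_correct_elim <- rowSums(d4$eliminated == 1L)
  expect_setequal(unique(n_correct_elim), c(1L, 3L))
  expect_setequal(unique(rowSums(d4$combos == 1L)), c(4L, 2L, 0L))

  for (n in 1:4) {
    expect_equal(sum(rowSums(scd_design(n, seed = 1)$combos == 1L) ==
                       ncol(scd_design(n, seed = 1)$combos)), 1L)
  }
  expect_error(scd_design(5), class = "fa_invalid_argument")
  expect_error(scd_design(0), class = "fa_invalid_argument")
})

test_that("items of every rule count produce 8 pairwise-distinct options with a unique key", {
  specs <- list(
    list(mirror = 1),
    list(main.rot = c(90, 45), dot.mov = c(1, 2)),
    list(mirror = 1, trap.rot = c(90, 45), subtract = c(1, 4)),
    list(main.rot = c(-90, -45), trap.rot = c(180, -135), subtract = "R",
         dot.mov = c(1, 1))
  )
  for (n in 1:4) {
    for (seed in 1:20) {
      b <- do.call(build_analogies, c(list(isomorphs = 1, seed = seed), specs[[n]]))
      it <- b$items[[1]]
      keys <- sapply(it$options$states, figana:::state_key)
      expect_length(keys, 8L)
      expect_equal(anyDuplicated(keys), 0L)
      D <- solve_item(it$stem)
      expect_equal(sum(keys == figana:::state_key(D)), 1L)
      expect_equal(which(keys == figana:::state_key(D)), it$correct_position)
    }
  }
})

test_that("keying the no-answer-is-correct slot removes D from the figural options", {
  for (seed in 1:10) {
    b <- build_analogies(isomorphs = 1, mirror = 1, dot.mov = c(1, 2),
                         correct = 9, seed = seed)
    it <- b$items[[1]]
    expect_equal(it$correct_position, 9L)
    D <- solve_item(it$stem)
    keys <- sapply(it$options$states, figana:::state_key)
    expect_equal(sum(keys == figana:::state_key(D)), 0L)
    expect_equal(anyDuplicated(keys), 0L)
  }
})

test_that("alternative solutions are offsets from the right answer and never reproduce it", {
  b <- build_analogies(isomorphs = 1, main.rot = c(90, 45), correct = 1, seed = 2)
  it <- b$items[[1]]
  D <- solve_item(it$stem)
  mains <- sapply(it$options$states, `[[`, "main")
  # the key holds D's main state; rotation alternatives sit elsewhere
  expect_equal(mains[1], D$main)
  combos <- it$options$combos
  alt_rows <- which(combos[, 1] > 1L)
  expect_true(all(mains[alt_rows] != D$main))
})

test_that("user-chosen alternatives are validated for count and effect", {
  A <- fa_state(main = 2, trap = 3, dot = 4)
  stem <- make_stem(A, fa_rules(mirror = 1, trap.rot = c(90, 45)))
  D <- solve_item(stem)
  layout <- scd_design(2, seed = 1)
  ok <- generate_alternatives(stem$rules, layout, D, A_lines = stem$A$lines,
    user_alts = list(
      reflection = list(list(offset = 0, flip = TRUE),
                        list(offset = 45, flip = FALSE)),
      trapezium_rotation = list(list(offset = 45), list(offset = -45))),
    seed = 1)
  expect_s3_class(ok, "fa_solution_sets")
  # an alternative that reproduces the correct solution
  expect_error(
    generate_alternatives(stem$rules, layout, D, A_lines = stem$A$lines,
      user_alts = list(
        reflection = list(list(offset = 0, flip = FALSE),
                          list(offset = 45, flip = FALSE)),
        trapezium_rotation = list(list(offset = 45), list(offset = -45)))),
    class = "fa_invalid_alternative")
  # wrong count
  expect_error(
    generate_alternatives(stem$rules, layout, D, A_lines = stem$A$lines,
      user_alts = list(
        reflection = list(list(offset = 0, flip = TRUE)),
        trapezium_rotation = list(list(offset = 45), list(offset = -45)))),
    class = "fa_invalid_argument")
})

test_that("seeded alternative generation and option placement are reproducible", {
  A <- fa_state()
  stem <- make_stem(A, fa_rules(subtract = c(1, 4), dot.mov = c(1, 2)))
  D <- solve_item(stem)
  layout <- scd_design(2, seed = 8)
  s1 <- generate_alternatives(stem$rules, layout, D, A_lines = stem$A$lines, seed = 8)
  s2 <- generate_alternatives(stem$rules, layout, D, A_lines = stem$A$lines, seed = 8)
  expect_identical(s1, s2)
  o1 <- assemble_options(layout, s1, D, A_lines = stem$A$lines,
                         correct_position = 4, seed = 21)
  o2 <- assemble_options(layout, s1, D, A_lines = stem$A$lines,
                         correct_position = 4, seed = 21)
  expect_identical(o1, o2)
  # a different placement seed permutes the same option multiset
  o3 <- assemble_options(layout, s1, D, A_lines = stem$A$lines,
                         correct_position = 4, seed = 22)
  k1 <- sort(sapply(o1$states, figana:::state_key))
  k3 <- sort(sapply(o3$states, figana:::state_key))
  expect_identical(k1, k3)
})
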