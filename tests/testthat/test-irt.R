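test_that("the elementary-symmetric-function recursion matches direct expansion", {
  set.seed(1)
  for (k in c(2, 3, 5, 8, 10)) {
    eps <- exp(stats::runif(k, -2, 2))
    expect_equal(figana:::esf(eps), esf_direct(eps), tolerance = 1e-10)
  }
})

test_that("the two-item CML closed form holds: beta2 - beta1 = log(n10/n01)", {
  x <- pattern_matrix(list(c(1, 0), c(0, 1), c(1, 1), c(0, 0)),
                      c(20, 10, 5, 5))
  fit <- fit_rasch(x)
  expect_equal(unname(diff(fit$beta)), log(20 / 10), tolerance = 1e-8)
  expect_equal(mean(fit$beta), 0, tolerance = 1e-10)
  # only the 30 discordant persons are informative
  expect_equal(fit$n_persons, 30L)
})

test_that("the conditional likelihood optimum matches brute-force maximization", {
  set.seed(11)
  for (spec in list(list(k = 4, n = 30), list(k = 5, n = 25))) {
    x <- simulate_responses(beta = stats::runif(spec$k, -1, 1),
                            n_persons = spec$n, seed = spec$k)
    # degenerate margins are possible at tiny n; redraw deterministically
    tries <- 0
    while (tries < 20) {
      fit <- tryCatch(fit_rasch(x), fa_error = function(e) NULL)
      if (!is.null(fit)) break
      tries <- tries + 1
      x <- simulate_responses(beta = stats::runif(spec$k, -1, 1),
                              n_persons = spec$n, seed = spec$k + 100 * tries)
    }
    bf <- brute_force_cml(x)
    expect_equal(fit$cond_loglik, bf$loglik, tolerance = 1e-6)
    expect_equal(unname(fit$beta - fit$beta[1]),
                 bf$beta - bf$beta[1], tolerance = 1e-3)
    # the package's own evaluator agrees with the enumerated likelihood
    expect_equal(fit$cond_loglik, enum_cond_loglik(fit$beta, x), tolerance = 1e-9)
  }
})

test_that("item relabelling permutes the estimates identically", {
  x <- simulate_responses(beta = c(-1, -0.2, 0.4, 1), n_persons = 300, seed = 5)
  fit <- fit_rasch(x)
  perm <- c(3, 1, 4, 2)
  fit_p <- fit_rasch(x[, perm])
  expect_equal(unname(fit_p$beta), unname(fit$beta[perm]), tolerance = 1e-8)
})

test_that("item difficulties are recovered at scale", {
  beta <- seq(-2, 2, length.out = 23)
  x <- simulate_responses(beta, n_persons = 1000, seed = 8)
  fit <- fit_rasch(x)
  expect_gt(stats::cor(fit$beta, beta), 0.98)
  expect_equal(mean(fit$beta), 0, tolerance = 1e-8)
})

test_that("a saturated Q reparameterization reproduces the Rasch fit", {
  x <- simulate_responses(beta = c(-0.8, -0.2, 0.3, 0.9), n_persons = 400, seed = 12)
  fr <- fit_rasch(x)
  q_sat <- rbind(0, diag(3))  # item 1 as reference; saturated and identified
  fl <- fit_lltm(x, q_sat)
  expect_equal(fl$cond_loglik, fr$cond_loglik, tolerance = 1e-6)
  expect_equal(unname(fl$beta_hat_centered), unname(fr$beta), tolerance = 1e-5)
  cmp <- compare_deviance(fr, fl)
  expect_equal(unname(cmp$statistic), 0, tolerance = 1e-5)
})

test_that("the difficulty decomposition beta = Q alpha is exact and matches row sums", {
  set.seed(3)
  q <- matrix(rbinom(23 * 9, 1, 0.4), 23, 9)
  q[cbind(1:9, 1:9)] <- 1L  # ensure full rank and no empty column
  alpha <- stats::runif(9, -1, 1)
  beta <- lltm_predict(q, alpha)
  brute <- vapply(1:23, function(i) sum(q[i, ] * alpha), numeric(1))
  expect_equal(beta, brute, tolerance = 1e-12)
  expect_equal(lltm_predict(rbind(c(0, 0, 0)), c(1, 2, 3)), 0)
  expect_equal(lltm_predict(rbind(c(1, 0, 1)), c(1, 2, 3)), 4)
  expect_error(lltm_predict(q, alpha[-1]), class = "fa_invalid_argument")
})

test_that("LLTM basic parameters are recovered within sampling error", {
  q <- qmatrix_from_bank(build_reference_test(seed = 2), 9)
  alpha <- fa_reference_alpha()
  x <- simulate_responses(lltm_predict(q, alpha), n_persons = 2000, seed = 77)
  fit <- fit_lltm(x, q)
  expect_true(all(abs(fit$alpha - alpha) < 3 * fit$se))
  expect_equal(unname(fit$beta_hat), unname(as.numeric(q %*% fit$alpha)),
               tolerance = 1e-12)
})

test_that("the LLTM never exceeds the Rasch conditional likelihood (nesting)", {
  q <- qmatrix_from_bank(build_reference_test(seed = 4), 5)
  for (seed in 1:3) {
    x <- simulate_responses(lltm_predict(q, c(0.9, 0.4, 1.1, 0.6, 0.3)),
                            n_persons = 400, seed = seed)
    fr <- fit_rasch(x)
    fl <- fit_lltm(x, q)
    expect_lte(fl$cond_loglik, fr$cond_loglik + 1e-8)
  }
})

test_that("unidentified or ill-formed Q matrices are rejected", {
  x <- simulate_responses(beta = c(-1, 0, 0.5, 1), n_persons = 200, seed = 2)
  expect_error(fit_lltm(x, matrix(1, 4, 1)), class = "fa_identifiability")
  expect_error(fit_lltm(x, cbind(c(1, 1, 0, 0), c(1, 1, 0, 0))),
               class = "fa_identifiability")
  expect_error(fit_lltm(x, cbind(c(1, 0, 1, 0), c(0, 0, 0, 0))),
               class = "fa_invalid_argument")
  expect_error(fit_lltm(x, diag(4)), class = "fa_invalid_argument")
})

test_that("Andersen's test is zero on duplicated halves and carries the right df", {
  x <- simulate_responses(beta = seq(-1, 1, length.out = 6), n_persons = 150, seed = 3)
  xx <- rbind(x, x)
  split <- rep(c("a", "b"), each = nrow(x))
  res <- andersen_lr(xx, split = split)
  expect_equal(unname(res$statistic), 0, tolerance = 1e-6)
  expect_equal(unname(res$parameter), 5)
  w <- wald_item_test(xx, split = split)
  expect_equal(w$z, rep(0, 6), tolerance = 1e-6)
  expect_error(andersen_lr(x, split = rep("a", nrow(x))), class = "fa_grouping")
})

test_that("the Wald test flags a truly shifted item with the largest |z|", {
  beta <- seq(-1, 1, length.out = 10)
  beta_shift <- beta; beta_shift[4] <- beta_shift[4] + 1
  hits <- 0
  for (rep in 1:20) {
    x1 <- simulate_responses(beta, 400, seed = 1000 + rep)
    x2 <- simulate_responses(beta_shift, 400, seed = 2000 + rep)
    w <- wald_item_test(rbind(x1, x2),
                        split = rep(c("g1", "g2"), each = 400))
    if (which.max(abs(w$z)) == 4) hits <- hits + 1
  }
  expect_gt(hits / 20, 0.9)
})

test_that("deviance comparison reports (k-1)-p degrees of freedom and rejects non-fits", {
  q5 <- qmatrix_from_bank(build_reference_test(seed = 6), 5)
  x <- simulate_responses(lltm_predict(q5, c(0.8, 0.3, 1.0, 0.6, 0.4)),
                          n_persons = 400, seed = 41)
  fr <- fit_rasch(x)
  f5 <- fit_lltm(x, q5)
  cmp <- compare_deviance(fr, f5)
  expect_equal(unname(cmp$parameter), (23 - 1) - 5)
  expect_gte(unname(cmp$statistic), 0)
  expect_error(compare_deviance(f5, f5), class = "fa_invalid_argument")
})

test_that("Cronbach's alpha follows its definition on toy data", {
  # perfectly consistent items
  v <- rbinom(50, 1, 0.5)
  expect_equal(cronbach_alpha(cbind(v, v, v)), 1)
  # hand-computed two-item example
  x <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0), c(1, 1), c(0, 1))
  k <- 2
  by_hand <- k / (k - 1) * (1 - sum(apply(x, 2, var)) / var(rowSums(x)))
  expect_equal(cronbach_alpha(x), by_hand, tolerance = 1e-12)
  # independent fair coins have alpha near zero
  set.seed(9)
  coins <- matrix(rbinom(5000 * 10, 1, 0.5), 5000, 10)
  expect_lt(abs(cronbach_alpha(coins)), 0.05)
  expect_error(cronbach_alpha(cbind(rep(1, 10), rep(0, 10))),
               class = "fa_undefined")
})

test_that("missing responses are conditioned on the observed item subsets", {
  x <- simulate_responses(beta = c(-1, -0.3, 0.3, 1), n_persons = 600, seed = 15)
  x_na <- x
  x_na[sample(length(x_na), 200)] <- NA
  fit <- fit_rasch(x_na)
  expect_true(all(is.finite(fit$beta)))
  expect_true(all(is.finite(fit$se)))
  full <- fit_rasch(x)
  expect_gt(stats::cor(fit$beta, full$beta), 0.95)
  # all-extreme data cannot be calibrated
  expect_error(fit_rasch(rbind(c(1, 1, 1), c(0, 0, 0))), class = "fa_estimation")
})

test_that("responses are validated and readable from CSV", {
  expect_error(fit_rasch(matrix(c(0, 2, 1, 0), 2, 2)), class = "fa_invalid_argument")
  expect_error(fit_rasch(matrix(0:1, 4, 1)), class = "fa_invalid_argument")
  f <- withr::local_tempfile(fileext = ".csv")
  x <- simulate_responses(beta = c(-0.5, 0.5), n_persons = 5, seed = 1)
  utils::write.csv(data.frame(person = rownames(x), x), f, row.names = FALSE)
  rd <- read_responses(f)
  expect_equal(unname(rd), unname(x), ignore_attr = "theta")
  expect_equal(rownames(rd), rownames(x))
})
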