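# Conditional maximum likelihood machinery for the Rasch model and the LLTM.
#
# The conditional likelihood of a binary persons x items matrix, given the
# raw scores, is
#   L(beta) = prod_v exp(-sum_i x_vi beta_i) / gamma_{r_v}(eps),
# with eps_i = exp(-beta_i) and gamma_r the elementary symmetric function of
# order r.  It depends on the data only through the item margins and the
# raw-score distribution, and is invariant under beta -> beta + c, so one
# contrast is fixed during optimization and estimates are mean-centered for
# reporting.

# Elementary symmetric functions gamma_0..gamma_k of eps, by the summation
# recursion (all terms positive, numerically stable for the test lengths
# used here).
esf <- function(eps) {
  g <- 1
  for (e in eps) g <- c(g, 0) + e * c(0, g)
  g
}

# Person groups by missing-data pattern.  Each group carries the observed
# item subset, the item margins and the raw-score counts of its informative
# persons (0 < score < number of observed items).
cml_groups <- function(x) {
  k <- ncol(x)
  obs <- !is.na(x)
  pat <- apply(obs, 1L, function(o) paste(as.integer(o), collapse = ""))
  groups <- list()
  n_informative <- 0L
  for (p in unique(pat)) {
    rows <- which(pat == p)
    items <- which(obs[rows[1L], ])
    if (length(items) < 2L) next
    sub <- x[rows, items, drop = FALSE]
    r <- rowSums(sub)
    keep <- r > 0 & r < length(items)
    if (!any(keep)) next
    sub <- sub[keep, , drop = FALSE]
    r <- r[keep]
    n_informative <- n_informative + nrow(sub)
    groups[[length(groups) + 1L]] <- list(
      items = items,
      margins = colSums(sub),
      score_counts = tabulate(r, nbins = length(items) - 1L)
    )
  }
  if (length(groups) == 0L)
    fa_stop("fa_estimation", "no informative persons (all raw scores extreme)")
  list(groups = groups, k = k, n_informative = n_informative)
}

# Conditional log-likelihood, gradient and (negative) observed information
# at beta, over missingness groups.  Returns list(loglik, grad, hess).
cml_eval <- function(beta, gr, hessian = TRUE) {
  k <- gr$k
  loglik <- 0
  grad <- numeric(k)
  hess <- if (hessian) matrix(0, k, k) else NULL
  for (g in gr$groups) {
    items <- g$items
    kk <- length(items)
    eps <- exp(-beta[items])
    gam <- esf(eps)
    nr <- g$score_counts
    rr <- which(nr > 0L)
    loglik <- loglik - sum(g$margins * beta[items]) - sum(nr[rr] * log(gam[rr + 1L]))
    # pi[i, r] = P(x_i = 1 | score r) = eps_i * gamma_{r-1}^{(i)} / gamma_r
    gam_ex <- matrix(0, kk, kk)  # row i: esf of eps[-i], orders 0..kk-1
    for (i in seq_len(kk)) gam_ex[i, ] <- esf(eps[-i])
    pi_ir <- matrix(0, kk, length(rr))
    for (j in seq_along(rr)) {
      r <- rr[j]
      pi_ir[, j] <- eps * gam_ex[, r] / gam[r + 1L]
    }
    grad[items] <- grad[items] - g$margins + pi_ir %*% nr[rr]
    if (hessian) {
      # pair-deleted esf, computed once per group:
      # gamma^{(ij)} gives P(x_i = x_j = 1 | r) = eps_i eps_j gamma_{r-2}^{(ij)} / gamma_r
      h <- matrix(0, kk, kk)
      if (kk >= 2L) {
        pair_gam <- vector("list", kk * kk)
        for (i in seq_len(kk - 1L)) {
          for (j2 in (i + 1L):kk) {
            pair_gam[[(i - 1L) * kk + j2]] <- esf(eps[-c(i, j2)])
          }
        }
        for (jr in seq_along(rr)) {
          r <- rr[jr]
          p1 <- pi_ir[, jr]
          p2 <- matrix(0, kk, kk)
          if (r >= 2L) {
            for (i in seq_len(kk - 1L)) {
              for (j2 in (i + 1L):kk) {
                v <- eps[i] * eps[j2] * pair_gam[[(i - 1L) * kk + j2]][r - 1L] /
                  gam[r + 1L]
                p2[i, j2] <- v
                p2[j2, i] <- v
              }
            }
          }
          cov_r <- p2 - tcrossprod(p1)
          diag(cov_r) <- p1 * (1 - p1)
          h <- h - nr[r] * cov_r
        }
      }
      hess[items, items] <- hess[items, items] + h
    }
  }
  list(loglik = loglik, grad = grad, hess = hess)
}

coerce_responses <- function(data) {
  x <- as.matrix(data)
  if (!is.numeric(x)) stop_invalid("responses must be numeric 0/1 (NA allowed)")
  if (ncol(x) < 2L) stop_invalid("at least 2 items are required")
  bad <- !(x %in% c(0, 1) | is.na(x))
  if (any(bad)) stop_invalid("responses must be 0, 1 or NA")
  if (is.null(colnames(x))) colnames(x) <- paste0("I", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- paste0("P", seq_len(nrow(x)))
  x
}

# Newton-Raphson with step halving on a free parameterization.
# f(par) must return list(loglik, grad, hess) in the free coordinates.
# Converged when the gradient infinity-norm falls below `tol` or the Newton
# update no longer moves the parameters (the likelihood's floating-point
# noise floor grows with its magnitude, so large samples can stall a pure
# gradient criterion a hair above `tol`).
newton_cml <- function(par, f, tol = 1e-8, max_iter = 200L) {
  ev <- f(par, hessian = TRUE)
  for (it in seq_len(max_iter)) {
    if (max(abs(ev$grad)) < tol) {
      return(list(par = par, eval = ev, iterations = it - 1L, converged = TRUE))
    }
    step <- tryCatch(solve(ev$hess, ev$grad),
                     error = function(e) fa_stop("fa_estimation",
                       "singular information matrix during estimation"))
    if (max(abs(step)) < 1e-10) {
      return(list(par = par, eval = ev, iterations = it - 1L, converged = TRUE))
    }
    lambda <- 1
    repeat {
      cand <- par - lambda * step
      ev_cand <- f(cand, hessian = TRUE)
      if (is.finite(ev_cand$loglik) && ev_cand$loglik >= ev$loglik - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) {
        noise_floor <- 1e-6 * max(1, abs(ev$loglik)) * .Machine$double.eps / 1e-16
        if (max(abs(ev$grad)) < noise_floor) {
          return(list(par = par, eval = ev, iterations = it, converged = TRUE))
        }
        fa_stop("fa_convergence", "step halving failed to improve the likelihood")
      }
    }
    par <- cand
    ev <- ev_cand
  }
  noise_floor <- 1e-6 * max(1, abs(ev$loglik)) * .Machine$double.eps / 1e-16
  if (max(abs(ev$grad)) < noise_floor) {
    return(list(par = par, eval = ev, iterations = max_iter, converged = TRUE))
  }
  fa_stop("fa_convergence",
          "no convergence in %d Newton iterations (gradient norm %.2e)",
          max_iter, max(abs(ev$grad)))
}

check_margins <- function(gr) {
  k <- gr$k
  s <- numeric(k)
  n <- numeric(k)
  for (g in gr$groups) {
    s[g$items] <- s[g$items] + g$margins
    n[g$items] <- n[g$items] + sum(g$score_counts)
  }
  if (any(n == 0))
    fa_stop("fa_estimation", "item(s) %s have no informative responses",
            paste(which(n == 0), collapse = ", "))
  if (any(s == 0) || any(s == n))
    fa_stop("fa_estimation",
            "item(s) %s were solved by everyone or no one among informative persons; their difficulty is not finitely estimable",
            paste(which(s == 0 | s == n), collapse = ", "))
}

#' Fit the Rasch model by conditional maximum likelihood
#'
#' Estimates item difficulty parameters beta of the Rasch model
#' (P(correct) = logistic(theta - beta)) by maximizing the conditional
#' likelihood given the raw scores, computed via elementary symmetric
#' functions; person parameters are eliminated entirely.  Persons with
#' all-correct or all-incorrect raw scores carry no conditional information
#' and are dropped.  Missing responses are handled by conditioning each
#' person on their observed item subset.  Estimates are reported
#' mean-centered with observed-information standard errors.
#'
#' @param data Persons x items binary matrix (or data frame); `NA` allowed.
#' @return An object of class `rasch_cml` with components `beta`
#'   (mean-centered difficulties), `se`, `vcov`, `cond_loglik`,
#'   `n_persons` (informative persons), `n_items`, `iterations`,
#'   `converged`.
#' @examples
#' x <- simulate_responses(beta = c(-1, 0, 1), n_persons = 300, seed = 1)
#' fit <- fit_rasch(x)
#' coef(fit)
#' @seealso [fit_lltm()], [andersen_lr()], [wald_item_test()]
#' @export
fit_rasch <- function(data) {
  x <- coerce_responses(data)
  gr <- cml_groups(x)
  check_margins(gr)
  k <- gr$k
  # free parameterization: beta_1 = 0
  f <- function(par, hessian = TRUE) {
    ev <- cml_eval(c(0, par), gr, hessian = hessian)
    list(loglik = ev$loglik, grad = ev$grad[-1L],
         hess = if (hessian) ev$hess[-1L, -1L, drop = FALSE] else NULL)
  }
  opt <- newton_cml(numeric(k - 1L), f)
  beta_ref <- c(0, opt$par)
  v_free <- solve(-opt$eval$hess)
  v_full <- matrix(0, k, k)
  v_full[-1L, -1L] <- v_free
  ctr <- diag(k) - matrix(1 / k, k, k)
  vc <- ctr %*% v_full %*% t(ctr)
  beta <- beta_ref - mean(beta_ref)
  names(beta) <- colnames(x)
  dimnames(vc) <- list(colnames(x), colnames(x))
  structure(list(
    beta = beta, se = sqrt(pmax(diag(vc), 0)), vcov = vc,
    cond_loglik = opt$eval$loglik,
    n_persons = gr$n_informative, n_items = k,
    iterations = opt$iterations, converged = opt$converged,
    call = match.call()
  ), class = "rasch_cml")
}

#' Fit the Linear Logistic Test Model by conditional maximum likelihood
#'
#' The LLTM decomposes every item difficulty into a weighted sum of basic
#' parameters, beta_i = sum_j w_ij alpha_j, where alpha_j is the difficulty
#' of cognitive operation j and w_ij its weight on item i (the Q matrix).
#' The conditional likelihood is maximized over alpha with beta
#' reparameterized as Q alpha.  The Q matrix must have full column rank and
#' must not contain the constant vector in its column span (the conditional
#' likelihood only identifies difficulty differences).
#'
#' @inheritParams fit_rasch
#' @param q Items x operations weight matrix (binary in the usual design).
#' @return An object of class `lltm_cml` with components `alpha`, `se`,
#'   `vcov`, `beta_hat` (= `q %*% alpha`, exactly), `beta_hat_centered`,
#'   `cond_loglik`, `n_persons`, `n_items`, `iterations`, `converged`.
#' @examples
#' q <- cbind(op1 = c(1, 1, 0, 0), op2 = c(0, 1, 1, 1))
#' x <- simulate_responses(beta = q %*% c(0.5, 1), n_persons = 400, seed = 2)
#' fit <- fit_lltm(x, q)
#' coef(fit)
#' @export
fit_lltm <- function(data, q) {
  x <- coerce_responses(data)
  q <- as.matrix(q)
  if (!is.numeric(q)) stop_invalid("`q` must be a numeric matrix")
  if (nrow(q) != ncol(x))
    stop_invalid("`q` must have one row per item (%d), got %d", ncol(x), nrow(q))
  p <- ncol(q)
  if (p >= ncol(x)) stop_invalid("the Q matrix must have fewer columns than items")
  if (any(colSums(abs(q)) == 0)) stop_invalid("the Q matrix has an all-zero column")
  if (qr(q)$rank < p)
    fa_stop("fa_identifiability", "the Q matrix is rank deficient")
  if (qr(cbind(1, q))$rank <= p)
    fa_stop("fa_identifiability",
            "the constant vector lies in the column span of Q; basic parameters are not identified under conditional likelihood")
  if (is.null(colnames(q))) colnames(q) <- paste0("op", seq_len(p))
  gr <- cml_groups(x)
  check_margins(gr)
  f <- function(par, hessian = TRUE) {
    ev <- cml_eval(as.numeric(q %*% par), gr, hessian = hessian)
    list(loglik = ev$loglik, grad = as.numeric(crossprod(q, ev$grad)),
         hess = if (hessian) crossprod(q, ev$hess %*% q) else NULL)
  }
  opt <- newton_cml(numeric(p), f)
  alpha <- opt$par
  names(alpha) <- colnames(q)
  vc <- solve(-opt$eval$hess)
  dimnames(vc) <- list(colnames(q), colnames(q))
  beta_hat <- as.numeric(q %*% alpha)
  names(beta_hat) <- colnames(x)
  structure(list(
    alpha = alpha, se = sqrt(pmax(diag(vc), 0)), vcov = vc,
    beta_hat = beta_hat, beta_hat_centered = beta_hat - mean(beta_hat),
    q = q, cond_loglik = opt$eval$loglik,
    n_persons = gr$n_informative, n_items = ncol(x),
    iterations = opt$iterations, converged = opt$converged,
    call = match.call()
  ), class = "lltm_cml")
}

#' Predict item difficulties from a Q matrix and basic parameters
#'
#' Computes beta_i = sum_j w_ij alpha_j.
#'
#' @param q Items x operations weight matrix.
#' @param alpha Basic parameter vector, one entry per Q column.
#' @return Numeric vector of item difficulties.
#' @examples
#' lltm_predict(rbind(c(1, 0), c(1, 1)), c(0.5, 0.3))  # 0.5 0.8
#' @export
lltm_predict <- function(q, alpha) {
  q <- as.matrix(q)
  if (ncol(q) != length(alpha))
    stop_invalid("`alpha` must have one entry per column of `q` (%d)", ncol(q))
  as.numeric(q %*% alpha)
}

#' @export
print.rasch_cml <- function(x, ...) {
  cat(sprintf("Rasch model (CML): %d items, %d informative persons\n",
              x$n_items, x$n_persons))
  cat(sprintf("Conditional log-likelihood: %.4f (%d Newton iterations)\n",
              x$cond_loglik, x$iterations))
  cat("Mean-centered item difficulties:\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
print.lltm_cml <- function(x, ...) {
  cat(sprintf("LLTM (CML): %d items, %d basic parameters, %d informative persons\n",
              x$n_items, length(x$alpha), x$n_persons))
  cat(sprintf("Conditional log-likelihood: %.4f\n", x$cond_loglik))
  cat("Basic parameters:\n")
  print(round(x$alpha, 4))
  invisible(x)
}

#' @export
summary.rasch_cml <- function(object, ...) {
  tab <- data.frame(beta = object$beta, se = object$se,
                    z = object$beta / object$se)
  structure(list(fit = object, table = tab), class = "summary.rasch_cml")
}

#' @export
print.summary.rasch_cml <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(round(x$table, 4))
  invisible(x)
}

#' @export
summary.lltm_cml <- function(object, ...) {
  z <- object$alpha / object$se
  tab <- data.frame(alpha = object$alpha, se = object$se, z = z,
                    p = 2 * stats::pnorm(-abs(z)))
  structure(list(fit = object, table = tab), class = "summary.lltm_cml")
}

#' @export
print.summary.lltm_cml <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(round(x$table, 4))
  invisible(x)
}

#' @export
coef.rasch_cml <- function(object, ...) object$beta

#' @export
coef.lltm_cml <- function(object, ...) object$alpha

#' @export
vcov.rasch_cml <- function(object, ...) object$vcov

#' @export
vcov.lltm_cml <- function(object, ...) object$vcov

#' @export
logLik.rasch_cml <- function(object, ...) {
  structure(object$cond_loglik, df = object$n_items - 1L,
            nobs = object$n_persons, class = "logLik")
}

#' @export
logLik.lltm_cml <- function(object, ...) {
  structure(object$cond_loglik, df = length(object$alpha),
            nobs = object$n_persons, class = "logLik")
}

#' @export
predict.lltm_cml <- function(object, q = NULL, ...) {
  if (is.null(q)) return(object$beta_hat)
  lltm_predict(q, object$alpha)
}

default_split <- function(x) {
  r <- rowSums(x, na.rm = TRUE)
  med <- stats::median(r)
  # ties at the median go to the lower group, deterministically
  factor(ifelse(r <= med, "low", "high"), levels = c("low", "high"))
}

#' Andersen's conditional likelihood-ratio test
#'
#' Splits the sample into groups (raw-score median split by default, ties to
#' the lower group), fits the Rasch model by CML in every group and overall,
#' and compares: LR = 2 * (sum of group conditional log-likelihoods - total
#' conditional log-likelihood), with (groups - 1) * (items - 1) degrees of
#' freedom.  Under Rasch homogeneity the item parameters are invariant
#' across groups and the statistic is asymptotically chi-square.
#'
#' @inheritParams fit_rasch
#' @param split Optional grouping vector/factor of length `nrow(data)`;
#'   defaults to the raw-score median split.
#' @return An object of class `htest` with the statistic, df and p-value.
#' @examples
#' x <- simulate_responses(beta = seq(-1, 1, length.out = 8),
#'                         n_persons = 400, seed = 3)
#' andersen_lr(x)
#' @export
andersen_lr <- function(data, split = NULL) {
  x <- coerce_responses(data)
  if (is.null(split)) split <- default_split(x)
  split <- as.factor(split)
  if (length(split) != nrow(x))
    stop_invalid("`split` must have one entry per person")
  split <- droplevels(split)
  if (nlevels(split) < 2L)
    fa_stop("fa_grouping", "the split must define at least two groups")
  total <- fit_rasch(x)
  ll_groups <- 0
  for (g in levels(split)) {
    fit_g <- tryCatch(fit_rasch(x[split == g, , drop = FALSE]),
      fa_error = function(e) fa_stop("fa_grouping",
        "group '%s' does not support a Rasch fit: %s", g, conditionMessage(e)))
    ll_groups <- ll_groups + fit_g$cond_loglik
  }
  stat <- 2 * (ll_groups - total$cond_loglik)
  df <- (nlevels(split) - 1L) * (total$n_items - 1L)
  structure(list(
    statistic = c(LR = stat), parameter = c(df = df),
    p.value = stats::pchisq(stat, df, lower.tail = FALSE),
    method = "Andersen conditional likelihood-ratio test",
    data.name = deparse(substitute(data)),
    alternative = "item parameters differ between groups"
  ), class = "htest")
}

#' Wald test of item-parameter invariance
#'
#' Fits the Rasch model by CML in two subsamples and tests, per item,
#' whether the (commonly mean-centered) difficulty estimates agree:
#' z = (beta_1 - beta_2) / sqrt(se_1^2 + se_2^2), with a two-sided normal
#' p-value.
#'
#' @inheritParams andersen_lr
#' @param split Grouping with exactly two groups; raw-score median split by
#'   default.
#' @return A data frame (class `fa_wald`) with one row per item: the two
#'   group estimates, `z` and `p`.
#' @export
wald_item_test <- function(data, split = NULL) {
  x <- coerce_responses(data)
  if (is.null(split)) split <- default_split(x)
  split <- droplevels(as.factor(split))
  if (nlevels(split) != 2L)
    fa_stop("fa_grouping", "the Wald test needs exactly two groups")
  fits <- lapply(levels(split), function(g)
    tryCatch(fit_rasch(x[split == g, , drop = FALSE]),
      fa_error = function(e) fa_stop("fa_grouping",
        "group '%s' does not support a Rasch fit: %s", g, conditionMessage(e))))
  b1 <- fits[[1]]$beta; b2 <- fits[[2]]$beta
  z <- (b1 - b2) / sqrt(fits[[1]]$se^2 + fits[[2]]$se^2)
  out <- data.frame(item = colnames(x), beta_group1 = b1, beta_group2 = b2,
                    z = z, p = 2 * stats::pnorm(-abs(z)), row.names = NULL)
  class(out) <- c("fa_wald", "data.frame")
  out
}

#' Compare Rasch and LLTM deviances
#'
#' Conditional likelihood-ratio test of the LLTM against the Rasch model in
#' which it is nested: LR = 2 * (rasch loglik - lltm loglik) with
#' (items - 1) - p degrees of freedom, p the number of basic parameters.
#' A significantly positive statistic means the rule-based decomposition
#' does not fully explain the item difficulties.
#'
#' @param rasch A `rasch_cml` fit.
#' @param lltm An `lltm_cml` fit of the same data.
#' @return An object of class `htest`.
#' @export
compare_deviance <- function(rasch, lltm) {
  if (!inherits(rasch, "rasch_cml") || !inherits(lltm, "lltm_cml"))
    stop_invalid("`rasch` and `lltm` must be CML fits")
  if (rasch$n_items != lltm$n_items)
    stop_invalid("fits are based on different numbers of items")
  stat <- 2 * (rasch$cond_loglik - lltm$cond_loglik)
  if (stat < -1e-6)
    fa_stop("fa_nesting",
            "the LLTM likelihood exceeds the Rasch likelihood; the models are not nested as fitted")
  stat <- max(stat, 0)
  df <- (rasch$n_items - 1L) - length(lltm$alpha)
  structure(list(
    statistic = c(LR = stat), parameter = c(df = df),
    p.value = stats::pchisq(stat, df, lower.tail = FALSE),
    method = "Conditional LR test: Rasch model vs. LLTM",
    data.name = "conditional log-likelihoods",
    alternative = "the LLTM restriction does not hold"
  ), class = "htest")
}

#' Cronbach's alpha
#'
#' alpha = k/(k-1) * (1 - sum of item variances / variance of total scores),
#' on complete response rows.
#'
#' @inheritParams fit_rasch
#' @return A single numeric value.
#' @examples
#' x <- simulate_responses(beta = rep(0, 10), n_persons = 200, seed = 4)
#' cronbach_alpha(x)
#' @export
cronbach_alpha <- function(data) {
  x <- coerce_responses(data)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 2L) stop_invalid("at least two complete response rows are required")
  k <- ncol(x)
  total_var <- stats::var(rowSums(x))
  if (total_var == 0)
    fa_stop("fa_undefined", "total-score variance is zero; alpha is undefined")
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / total_var)
}

#' Read a response matrix from a delimited file
#'
#' Expects a CSV with a header row of item labels and one row per person;
#' cells are 0, 1 or NA.  An optional first column of person ids is detected
#' by a non-numeric first column.
#'
#' @param file Path to the CSV file.
#' @return A persons x items numeric matrix.
#' @export
read_responses <- function(file) {
  d <- utils::read.csv(file, check.names = FALSE)
  if (ncol(d) >= 2L && !is.numeric(d[[1L]])) {
    ids <- as.character(d[[1L]])
    d <- d[, -1L, drop = FALSE]
    rownames(d) <- ids
  }
  coerce_responses(d)
}
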