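# Independent oracles and fixture builders used across the suite.

# Conditional log-likelihood by direct pattern enumeration: for every person
# with raw score r, P(x | r) = exp(-sum x_i beta_i) / gamma_r, with gamma_r
# summed over all C(k, r) response patterns.  Independent of the package's
# elementary-symmetric-function recursion.
enum_cond_loglik <- function(beta, x) {
  k <- ncol(x)
  gamma_r <- function(r) {
    if (r == 0 || r == k) return(1)
    sum(apply(utils::combn(k, r), 2, function(idx) exp(-sum(beta[idx]))))
  }
  gam <- vapply(0:k, gamma_r, numeric(1))
  ll <- 0
  for (v in seq_len(nrow(x))) {
    r <- sum(x[v, ])
    if (r == 0 || r == k) next
    ll <- ll + (-sum(x[v, ] * beta)) - log(gam[r + 1])
  }
  ll
}

# Brute-force CML maximizer over beta with beta_1 = 0, via optim on the
# enumerated likelihood.
brute_force_cml <- function(x) {
  k <- ncol(x)
  nll <- function(par) -enum_cond_loglik(c(0, par), x)
  opt <- stats::optim(numeric(k - 1), nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  list(beta = c(0, opt$par), loglik = -opt$value)
}

# Direct-expansion elementary symmetric functions (subset enumeration).
esf_direct <- function(eps) {
  k <- length(eps)
  vapply(0:k, function(r) {
    if (r == 0) return(1)
    sum(apply(utils::combn(k, r), 2, function(idx) prod(eps[idx])))
  }, numeric(1))
}

# Canonical concrete arguments per general rule (random subtraction pinned
# to a concrete pair so traversals are deterministic).
canonical_rule_args <- list(
  main_rotation      = list(main.rot = c(90, 45)),
  reflection         = list(mirror = 1),
  trapezium_rotation = list(trap.rot = c(180, -135)),
  subtraction        = list(subtract = c(1, 4)),
  dot_movement       = list(dot.mov = c(1, 2))
)

# All valid single- and two-rule canonical rule sets (mirror and main
# rotation never combined).
canonical_rule_sets <- function() {
  singles <- lapply(names(canonical_rule_args), function(nm)
    do.call(fa_rules, canonical_rule_args[[nm]]))
  pairs <- utils::combn(names(canonical_rule_args), 2, simplify = FALSE)
  pairs <- Filter(function(p)
    !all(c("main_rotation", "reflection") %in% p), pairs)
  doubles <- lapply(pairs, function(p)
    do.call(fa_rules, c(canonical_rule_args[[p[1]]], canonical_rule_args[[p[2]]])))
  c(singles, doubles)
}

# Every incidental configuration of shape A as a data frame (768 rows).
all_incidentals <- function() {
  expand.grid(main = 1:8, flip = c(FALSE, TRUE), trap = 1:8, dot = 1:6,
              KEEP.OUT.ATTRS = FALSE)
}

# Small binary response fixture with prescribed pattern counts.
pattern_matrix <- function(patterns, counts) {
  do.call(rbind, mapply(function(p, n) {
    matrix(rep(p, n), nrow = n, byrow = TRUE)
  }, patterns, counts, SIMPLIFY = FALSE))
}
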