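#' Simulate Rasch/LLTM-structured response data
#'
#' Draws person abilities theta from a normal distribution and scores each
#' person x item cell as Bernoulli with success probability
#' logistic(theta - beta).  Abilities and responses use separate named
#' substreams of the master seed, so either component can be reproduced on
#' its own.
#'
#' @param beta Item difficulty vector (e.g. from [lltm_predict()]).
#' @param n_persons Number of simulated persons.
#' @param ability_mean,ability_sd Normal ability distribution parameters
#'   (defaults 0 and 1).
#' @param seed Optional master seed; identical calls give identical data.
#' @return A persons x items 0/1 matrix with the abilities attached as
#'   attribute `"theta"`.
#' @examples
#' x <- simulate_responses(beta = c(-1, 0, 1), n_persons = 100, seed = 1)
#' colMeans(x)
#' @export
simulate_responses <- function(beta, n_persons, ability_mean = 0,
                               ability_sd = 1, seed = NULL) {
  beta <- as.numeric(beta)
  if (any(!is.finite(beta))) stop_invalid("`beta` must be finite")
  if (!is_count(n_persons, 1L)) stop_invalid("`n_persons` must be a positive integer")
  if (!(is.numeric(ability_sd) && length(ability_sd) == 1L && ability_sd > 0))
    stop_invalid("`ability_sd` must be positive")
  theta <- with_seed(sub_seed(seed, "abilities"),
                     stats::rnorm(n_persons, ability_mean, ability_sd))
  pr <- stats::plogis(outer(theta, beta, "-"))
  x <- with_seed(sub_seed(seed, "responses"), {
    matrix(stats::rbinom(length(pr), 1L, pr), nrow = n_persons)
  })
  dimnames(x) <- list(paste0("P", seq_len(n_persons)),
                      paste0("I", seq_along(beta)))
  attr(x, "theta") <- theta
  x
}

#' Q matrix of an item bank
#'
#' Derives the binary items x rules weight matrix from the rule metadata of
#' a generated bank, at either the five-general-rule or the
#' nine-specific-rule granularity.  Every specific rule maps to exactly one
#' general rule, so an item's row sums agree between the two granularities.
#'
#' @param bank An `fa_item_bank`.
#' @param n_rules `5` (general rules) or `9` (specific rules).
#' @return A binary matrix with one row per item.
#' @examples
#' b <- build_analogies(isomorphs = 2, mirror = 1, seed = 1)
#' qmatrix_from_bank(b, 5)
#' @export
qmatrix_from_bank <- function(bank, n_rules = 5) {
  if (!inherits(bank, "fa_item_bank")) stop_invalid("`bank` must be an `fa_item_bank`")
  if (!(length(n_rules) == 1L && n_rules %in% c(5, 9)))
    stop_invalid("`n_rules` must be 5 or 9")
  sr <- specific_rules()
  q <- matrix(0L, nrow = length(bank$items), ncol = n_rules)
  rownames(q) <- paste0("item", seq_along(bank$items))
  if (n_rules == 9) {
    colnames(q) <- paste0("sr", 1:9)
    for (i in seq_along(bank$items)) q[i, bank$items[[i]]$specific_rules] <- 1L
  } else {
    colnames(q) <- GENERAL_RULES
    for (i in seq_along(bank$items)) {
      gen <- sr$general[bank$items[[i]]$specific_rules]
      q[i, unique(gen)] <- 1L
    }
  }
  q
}

#' Reference basic-parameter values for the nine specific rules
#'
#' A labelled set of LLTM basic-parameter estimates for the nine specific
#' rules, taken from a published calibration of automatically generated
#' figural analogy items (traditional conditional-ML LLTM).  They are
#' empirical estimates shipped for demonstrations and recovery studies, not
#' ground truth.
#'
#' @return A named numeric vector of length 9 (names `sr1`..`sr9`).
#' @examples
#' fa_reference_alpha()
#' @export
fa_reference_alpha <- function() {
  c(sr1 = 0.82, sr2 = 1.55, sr3 = 1.23,
    sr4 = 0.36, sr5 = -0.26, sr6 = 0.11,
    sr7 = 1.14, sr8 = 0.61, sr9 = 0.36)
}

#' Rule sets of the synthetic 23-item reference test
#'
#' Defines 23 rule specifications covering all nine specific rules with rule
#' counts between one and four, in the spirit of the published 23-item
#' figural analogy test (whose exact Q matrix is not publicly available —
#' this composition is synthetic).  Items 1-9 manipulate each specific rule
#' alone; items 10-15 combine two rules, 16-20 three, and 21-23 four.
#'
#' @return A list of 23 argument lists for [build_analogies()].
#' @export
reference_test_rules <- function() {
  sra <- specific_rule_args
  merge_args <- function(...) do.call(c, list(...))
  c(
    lapply(1:9, sra),
    list(
      merge_args(sra(1), sra(4)),
      merge_args(sra(2), sra(8)),
      merge_args(sra(3), sra(9)),
      merge_args(sra(7), sra(5)),
      merge_args(sra(8), sra(9)),
      merge_args(sra(6), sra(7)),
      merge_args(sra(1), sra(5), sra(8)),
      merge_args(sra(2), sra(6), sra(9)),
      merge_args(sra(7), sra(4), sra(8)),
      merge_args(sra(3), sra(4), sra(9)),
      merge_args(sra(7), sra(8), sra(9)),
      merge_args(sra(1), sra(6), sra(8), sra(9)),
      merge_args(sra(7), sra(5), sra(8), sra(9)),
      merge_args(sra(2), sra(4), sra(8), sra(9))
    )
  )
}

#' Build the synthetic 23-item reference test
#'
#' Builds one item per rule set of [reference_test_rules()] and combines
#' them into a single bank, suitable for Q-matrix derivation and
#' simulation-based recovery studies.
#'
#' @param seed Optional master seed.
#' @return An `fa_item_bank` with 23 items.
#' @examples
#' \donttest{
#' test <- build_reference_test(seed = 1)
#' dim(qmatrix_from_bank(test, 9))  # 23 x 9
#' }
#' @export
build_reference_test <- function(seed = NULL) {
  specs <- reference_test_rules()
  banks <- lapply(seq_along(specs), function(i) {
    do.call(build_analogies,
            c(list(isomorphs = 1L, seed = sub_seed(seed, paste0("ref", i))),
              specs[[i]]))
  })
  do.call(c, banks)
}
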