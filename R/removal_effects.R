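#' Removal effect of losing one node on another
#'
#' The log-ratio biomass change of node `i` after node `k`'s removal,
#' scaled by the removed node's pre-removal biomass:
#' \deqn{RE_i = \log\left[(B_i^+ + 1)/(B_i^- + 1)\right] / (B_k + 1)}
#' with the natural logarithm (configurable). Adding one to the biomass
#' densities prevents very small `B_k` from inflating RE. Swapping `B+` and
#' `B-` negates RE.
#'
#' @param b_plus Biomass of `i` with `k` present (g C m^-2).
#' @param b_minus Biomass of `i` after `k`'s removal (g C m^-2).
#' @param b_k Pre-removal biomass of the removed node `k`.
#' @param base Logarithm base (default `exp(1)`).
#' @return RE (dimensionless). Vectorized over `b_plus` / `b_minus`.
#' @examples
#' removal_effect(1, 0, 1)  # log(2) / 2
#' @export
removal_effect <- function(b_plus, b_minus, b_k, base = exp(1)) {
  stopifnot(all(b_plus >= 0), all(b_minus >= 0), b_k >= 0)
  log((b_plus + 1) / (b_minus + 1), base = base) / (b_k + 1)
}

#' Within- and between-compartment mean removal effects
#'
#' Splits the removal-effect vector of one experiment by the removed node's
#' compartment: the within mean averages over the nodes sharing `k`'s
#' compartment (excluding `k` itself) and the between mean over all other
#' nodes. Effects are averaged as magnitudes `|RE|` by default, so opposite
#' responses do not cancel; `signed = TRUE` averages raw values.
#'
#' @param outcome A [removal_experiment()] result.
#' @param membership Compartment labels (any form accepted by
#'   [flow_modularity()]).
#' @param signed Average signed RE instead of `|RE|`.
#' @return List with `within`, `between` (means; `within` is `NA` when `k`'s
#'   compartment is a singleton), `n_within`, `n_between`.
#' @export
aggregate_re <- function(outcome, membership, signed = FALSE) {
  stopifnot(inherits(outcome, "removal_outcome"))
  re <- outcome$re
  m <- as_membership(membership, length(re))
  k <- match(outcome$removed, names(re))
  val <- if (signed) re else abs(re)
  same <- which(m == m[k])
  same <- setdiff(same, k)
  other <- which(m != m[k])
  list(within = if (length(same)) mean(val[same]) else NA_real_,
       between = if (length(other)) mean(val[other]) else NA_real_,
       n_within = length(same), n_between = length(other))
}

#' Paired t-test on per-web mean removal effects
#'
#' Standard paired t-test (df = n - 1) comparing, e.g., within-compartment
#' against between-compartment mean |RE| across webs. A thin wrapper over
#' [stats::t.test()] returning the statistic, degrees of freedom and
#' p-value; zero variance of the differences is flagged as an infinite
#' statistic rather than an error.
#'
#' @param x,y Numeric vectors of equal length `n >= 2` (paired by web).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
re_paired_test <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    t_ <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(t = t_, df = length(d) - 1L,
                p = if (mean(d) == 0) 1 else 0, mean_diff = mean(d)))
  }
  ht <- stats::t.test(x, y, paired = TRUE, alternative = alternative)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate))
}
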