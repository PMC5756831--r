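#' Detect energy-channel compartments
#'
#' The four-step detection algorithm:
#' 1. compute every node's fractional reliance on each basal resource
#'    ([basal_reliance()]);
#' 2. seed one subgroup per basal node and assign every node to its dominant
#'    energy origin ([dominant_source_groups()]);
#' 3. compute the modularity gain for every pair of current subgroups
#'    ([merge_gain_matrix()]);
#' 4. merge the pair with the largest gain if that gain is positive, and
#'    repeat from step 3 until no merge increases modularity.
#'
#' Ties in step 4 are broken toward the lexicographically smallest label
#' pair, so the procedure is deterministic. Subgroups are only ever merged,
#' never split, so the final partition is a coarsening of the seed
#' subgroups.
#'
#' @param net A [flow_network], assumed balanced (use [balance_flows()]
#'   first; an unbalanced web triggers a warning, not an error).
#' @param imports_as_source Passed to [basal_reliance()].
#' @return A list of class `compartment_fit`: `membership` (named integer
#'   vector, contiguous labels), `n_compartments`, `q` (final modularity),
#'   `seed_groups` (the initial [dominant_source_groups()] assignment),
#'   `reliance` (the [basal_reliance] matrix) and `trace` (data frame of
#'   accepted merges: `step`, `group_a`, `group_b`, `delta_q`, `q`).
#' @export
detect_compartments <- function(net, imports_as_source = FALSE) {
  stopifnot(inherits(net, "flow_network"))
  rep_ <- validate_network(net, tol = 1e-4)
  if (!rep_$balanced) {
    warning("network is not balanced to 1e-4; consider balance_flows()",
            call. = FALSE)
  }
  br <- basal_reliance(net, imports_as_source = imports_as_source)
  seeds <- dominant_source_groups(br)
  membership <- seeds$membership
  labels <- seeds$seed

  q <- flow_modularity(net, membership)
  trace <- data.frame(step = integer(), group_a = character(),
                      group_b = character(), delta_q = numeric(),
                      q = numeric(), stringsAsFactors = FALSE)

  step <- 0L
  while (length(unique(membership)) > 1L) {
    gain <- merge_gain_matrix(net, membership)
    best <- max(gain, na.rm = TRUE)
    if (best <= 0) break
    # lexicographically smallest (row, col) pair among the maximizers
    cand <- which(gain == best, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    a <- cand[1L, 1L]; b <- cand[1L, 2L]
    labs <- sort(unique(membership))
    la <- labs[a]; lb <- labs[b]
    membership[membership == lb] <- la
    step <- step + 1L
    q <- q + best
    trace <- rbind(trace, data.frame(
      step = step, group_a = labels[la], group_b = labels[lb],
      delta_q = best, q = q, stringsAsFactors = FALSE))
  }

  final <- as.integer(factor(membership))
  names(final) <- net$node_ids
  structure(list(membership = final,
                 n_compartments = length(unique(final)),
                 q = flow_modularity(net, final),
                 seed_groups = seeds, reliance = br, trace = trace),
            class = "compartment_fit")
}

#' @export
print.compartment_fit <- function(x, ...) {
  cat("<compartment_fit> ", x$n_compartments, " compartments, Q = ",
      format(round(x$q, 4)), "\n", sep = "")
  cat("  seeds: ", length(x$seed_groups$seed), " subgroups; ",
      nrow(x$trace), " merges accepted\n", sep = "")
  sizes <- table(x$membership)
  cat("  sizes: ", paste(as.integer(sizes), collapse = ", "), "\n", sep = "")
  invisible(x)
}
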