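#' Balance a flow network to steady state
#'
#' Empirical flow accounts are often slightly unbalanced: energy entering a
#' node does not exactly equal energy leaving it. This routine brings a web
#' to steady state while preserving its topology (the zero/nonzero pattern of
#' the flux matrix), by alternately rescaling each node's inputs (internal
#' inflows plus imports) and outputs (internal outflows plus exports and
#' respiration) toward the arithmetic mean of the two totals, in the spirit
#' of the input/output-averaging family of balancing algorithms, until every
#' node's residual is below tolerance.
#'
#' Exports and respiration are rescaled proportionally as a single output
#' boundary block, imports as the input boundary block.
#'
#' @param net A [flow_network].
#' @param tol Relative tolerance on per-node residuals (default `1e-6`).
#' @param max_iter Maximum number of rescaling sweeps (default `10000`).
#' @return The balanced [flow_network], with attribute `"trace"`: the
#'   numeric vector of max relative residuals after each sweep.
#' @export
balance_flows <- function(net, tol = 1e-6, max_iter = 10000L) {
  stopifnot(inherits(net, "flow_network"), tol > 0)
  f <- net$flows
  imp <- net$imports
  exp_ <- net$exports
  resp <- net$respiration
  s <- n_nodes(net)
  if (sum(f) + sum(imp) <= 0) {
    stop("network has no positive throughflow to balance", call. = FALSE)
  }

  totals <- function() {
    input <- imp + colSums(f)
    output <- exp_ + resp + rowSums(f)
    list(input = input, output = output,
         rel = ifelse(pmax(input, output) > 0,
                      abs(input - output) / pmax(input, output), 0))
  }

  # Structural dead ends cannot be balanced by rescaling: a node with inputs
  # but no output channels (or vice versa) and a nonzero residual.
  t0 <- totals()
  sink_bad <- which(t0$input > 0 & t0$output == 0 & t0$rel > tol)
  src_bad <- which(t0$output > 0 & t0$input == 0 & t0$rel > tol)
  if (length(sink_bad) || length(src_bad)) {
    stop("cannot balance: node(s) with one-sided flow structure: ",
         paste(net$node_ids[c(sink_bad, src_bad)], collapse = ", "),
         call. = FALSE)
  }

  trace <- numeric()
  best <- Inf
  for (it in seq_len(max_iter)) {
    t <- totals()
    if (max(t$rel) <= tol) break
    target <- (t$input + t$output) / 2
    # input side: scale column j of f and imports[j] toward target[j]
    cin <- ifelse(t$input > 0, target / t$input, 1)
    f <- sweep(f, 2L, cin, `*`)
    imp <- imp * cin
    # output side: scale row i of f and the export/respiration block
    t <- totals()
    target <- (t$input + t$output) / 2
    cout <- ifelse(t$output > 0, target / t$output, 1)
    f <- sweep(f, 1L, cout, `*`)
    exp_ <- exp_ * cout
    resp <- resp * cout
    cur <- max(totals()$rel)
    trace <- c(trace, cur)
    best <- min(best, cur)
  }
  t <- totals()
  if (max(t$rel) > tol) {
    stop("balancing did not converge in ", max_iter,
         " iterations; worst relative residual ", format(max(t$rel)),
         call. = FALSE)
  }
  out <- flow_network(net$node_ids, net$category, net$biomass, imp, exp_,
                      resp, f, names = net$names)
  attr(out, "trace") <- trace
  out
}
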