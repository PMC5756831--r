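#' Run the full energy-channel analysis pipeline
#'
#' Executes the whole workflow on one web: balance, basal reliance,
#' compartment detection, Monte Carlo significance, benchmark partitions,
#' and (optionally) node-removal experiments with within/between-compartment
#' aggregation. Every stage is a pure function of `(input, config, seed)`.
#'
#' @param net A [flow_network], or a path to a `network.json` document.
#' @param reps Monte Carlo replicates (default 1000).
#' @param n_removals Number of random node removals to simulate (0 skips
#'   the dynamics stage). Candidates are living (non-detritus) nodes, drawn
#'   uniformly without replacement (recycled if `n_removals` exceeds the
#'   pool).
#' @param seed Master integer seed for randomization and removal draws.
#' @param h,q Functional-response shape parameters for the dynamics stage.
#' @param burn_in,window Simulation phase lengths in days.
#' @param balance_tol Balancing tolerance.
#' @param out_dir Optional directory; when given, writes `partition.tsv`
#'   (id, compartment), `reliance.tsv`, `mc.json`, `comparison.json`,
#'   `removals.tsv` and `summary.json`.
#' @return A list of class `channel_analysis` with elements `net`
#'   (balanced), `fit` ([detect_compartments()] result), `mc`
#'   ([modularity_significance()] result), `benchmarks` (both baseline
#'   partitions), `removals` (data frame of per-removal within/between
#'   means, or `NULL`), `paired` (paired test across removals, or `NULL`)
#'   and `summary` (S, S_c, Q, p, null mean/SEM).
#' @export
run_full_analysis <- function(net, reps = 1000L, n_removals = 0L,
                              seed = 1L, h = 1.2, q = 1,
                              burn_in = 1000, window = 1000,
                              balance_tol = 1e-6, out_dir = NULL) {
  if (is.character(net)) net <- read_flow_json(net)
  stopifnot(inherits(net, "flow_network"))
  bal <- balance_flows(net, tol = balance_tol)
  fit <- detect_compartments(bal)
  mc <- modularity_significance(bal, fit, reps = reps, seed = seed)
  bench <- list(edge_betweenness = edge_betweenness_partition(bal),
                random_walk = random_walk_partition(bal))

  removals <- paired <- NULL
  if (n_removals > 0L) {
    params <- calibrate_dynamics(bal, h = h, q = q)
    pool <- which(bal$category != "detritus")
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(as.integer(seed))
    picks <- rep_len(pool[sample.int(length(pool))], n_removals)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    rows <- lapply(picks, function(k) {
      out <- removal_experiment(bal, removed = k, params = params,
                                burn_in = burn_in, window = window)
      ag <- aggregate_re(out, fit)
      data.frame(removed_id = out$removed,
                 removed_compartment = fit$membership[[out$removed]],
                 within_mean_re = ag$within, between_mean_re = ag$between,
                 n_within = ag$n_within, n_between = ag$n_between,
                 stringsAsFactors = FALSE)
    })
    removals <- do.call(rbind, rows)
    ok <- stats::complete.cases(removals[, c("within_mean_re",
                                             "between_mean_re")])
    if (sum(ok) >= 2L) {
      paired <- re_paired_test(removals$within_mean_re[ok],
                               removals$between_mean_re[ok])
    }
  }

  summary <- list(s = n_nodes(bal), s_c = fit$n_compartments,
                  q = fit$q, p = mc$p, null_mean = mc$null_mean,
                  null_sem = mc$null_sem, reps = mc$reps, seed = seed)
  res <- structure(list(net = bal, fit = fit, mc = mc, benchmarks = bench,
                        removals = removals, paired = paired,
                        summary = summary),
                   class = "channel_analysis")
  if (!is.null(out_dir)) .write_analysis(res, out_dir)
  res
}

.write_analysis <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  utils::write.table(
    data.frame(id = names(res$fit$membership),
               compartment = unname(res$fit$membership)),
    p("partition.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    cbind(data.frame(id = rownames(res$fit$reliance)),
          as.data.frame(unclass(res$fit$reliance))),
    p("reliance.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(q = res$mc$q, p = res$mc$p, n_ge = res$mc$n_ge,
         null_mean = res$mc$null_mean, null_sem = res$mc$null_sem,
         reps = res$mc$reps, seed = res$mc$seed,
         comparison = res$mc$comparison, null_q = res$mc$null_q),
    p("mc.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(energy_channel = list(q = res$fit$q,
                               s_c = res$fit$n_compartments),
         edge_betweenness = list(q = res$benchmarks$edge_betweenness$q,
                                 s_c = res$benchmarks$edge_betweenness$n_compartments),
         random_walk = list(q = res$benchmarks$random_walk$q,
                            s_c = res$benchmarks$random_walk$n_compartments)),
    p("comparison.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(res$removals)) {
    utils::write.table(res$removals, p("removals.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(c(res$summary,
                         list(paired = res$paired,
                              merge_trace = res$fit$trace)),
                       p("summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' @export
print.channel_analysis <- function(x, ...) {
  cat("<channel_analysis> S = ", x$summary$s, ", S_c = ", x$summary$s_c,
      ", Q = ", format(round(x$summary$q, 4)), ", p = ",
      format(x$summary$p), "\n", sep = "")
  invisible(x)
}
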