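#' Generate a balanced synthetic web with planted energy channels
#'
#' Builds a quantitative food web with known ground-truth compartments:
#' `channels` parallel energy channels, each seeded by one basal node
#' (alternating detritus and producer) and stacked into `levels - 1`
#' consumer trophic levels. Within-channel diets get lognormal weights and a
#' 10% level-to-level transfer efficiency (a consumer's intake is ten times
#' the predation it sustains), emulating the strongly uneven link-weight
#' distributions of real flow webs. A fraction `eps` of every consumer's
#' intake is rerouted to randomly chosen same-level prey in foreign
#' channels, so `eps = 0` gives an exactly block-diagonal flux matrix and
#' `eps -> 0.5` progressively erases the planted structure.
#'
#' Boundary flows are assigned last so that every node balances exactly:
#' basal nodes receive imports covering their consumption, consumers split
#' their surplus (intake minus predation minus egestion) 80/20 between
#' respiration and export, and in detritus-based channels each consumer
#' egests `egestion_frac` of its intake back into the channel's detritus
#' pool (providing the recycling loops and the assimilation efficiencies
#' `a = 1 - egestion_frac` the dynamics module calibrates). First-level
#' consumers of a detritus channel are categorized as decomposers.
#'
#' @param channels Number of channels `k >= 1`.
#' @param per_channel Nodes per channel `m` (one basal + `m - 1` consumers),
#'   `m >= levels`.
#' @param levels Trophic levels per channel `L >= 2` (level 0 = basal).
#' @param eps Cross-channel coupling in `[0, 1]`: fraction of each
#'   consumer's diet drawn from foreign channels.
#' @param flux_meanlog,flux_sdlog Lognormal parameters of top-consumer
#'   intakes and diet weights.
#' @param egestion_frac Fraction of intake egested to the home detritus pool
#'   (detritus channels only).
#' @param transfer_efficiency Level-to-level transfer efficiency (predation
#'   sustained / intake).
#' @param couple_top If `TRUE`, top-level consumers feed evenly across all
#'   channels (mobile top predators coupling the channels).
#' @param seed Integer seed; the same seed reproduces the web exactly.
#' @return A list of class `planted_web`: `net` (a balanced
#'   [flow_network]), `truth` (named integer vector: the planted channel of
#'   every node) and `spec` (the generator settings).
#' @export
generate_planted_web <- function(channels = 2L, per_channel = 6L,
                                 levels = 3L, eps = 0,
                                 flux_meanlog = 0, flux_sdlog = 0.5,
                                 egestion_frac = 0.2,
                                 transfer_efficiency = 0.1,
                                 couple_top = FALSE, seed = NULL) {
  stopifnot(channels >= 1L, levels >= 2L, eps >= 0, eps <= 1,
            egestion_frac >= 0, egestion_frac < 0.8,
            transfer_efficiency > 0, transfer_efficiency < 0.5)
  if (per_channel < levels) {
    stop("per_channel must be >= levels (one node per trophic level)",
         call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }

  k <- as.integer(channels)
  m <- as.integer(per_channel)
  l_cons <- as.integer(levels) - 1L           # consumer levels 1..l_cons
  # distribute m - 1 consumers over consumer levels, extras to lower levels
  n_per_level <- rep((m - 1L) %/% l_cons, l_cons)
  extra <- (m - 1L) %% l_cons
  if (extra > 0L) n_per_level[seq_len(extra)] <- n_per_level[seq_len(extra)] + 1L

  ids <- character(); channel <- integer(); level <- integer()
  category <- character()
  for (c in seq_len(k)) {
    basal_is_detritus <- (c %% 2L == 1L)
    ids <- c(ids, sprintf("c%d_basal", c))
    channel <- c(channel, c); level <- c(level, 0L)
    category <- c(category, if (basal_is_detritus) "detritus" else "producer")
    for (l in seq_len(l_cons)) {
      for (t in seq_len(n_per_level[l])) {
        ids <- c(ids, sprintf("c%d_l%d_n%d", c, l, t))
        channel <- c(channel, c); level <- c(level, l)
        category <- c(category,
                      if (l == 1L && basal_is_detritus) "decomposer"
                      else "consumer")
      }
    }
  }
  s <- length(ids)
  f <- matrix(0, s, s, dimnames = list(ids, ids))
  intake <- numeric(s)

  # assign diets top-down so each node's sustained predation is known
  # before its own intake is fixed
  for (l in rev(seq_len(l_cons))) {
    for (j in which(level == l)) {
      pred_j <- sum(f[j, ])
      intake[j] <- if (pred_j > 0) pred_j / transfer_efficiency else
        stats::rlnorm(1, flux_meanlog, flux_sdlog)
      home <- which(level == l - 1L & channel == channel[j])
      foreign <- which(level == l - 1L & channel != channel[j])
      frac_foreign <- if (couple_top && l == l_cons && k > 1L) {
        (k - 1L) / k
      } else if (length(foreign)) eps else 0
      t_home <- intake[j] * (1 - frac_foreign)
      w <- stats::rlnorm(length(home), flux_meanlog, flux_sdlog)
      f[home, j] <- f[home, j] + t_home * w / sum(w)
      if (frac_foreign > 0) {
        nf <- min(length(foreign), max(1L, length(home)))
        pick <- if (length(foreign) == 1L) foreign else sample(foreign, nf)
        wf <- stats::rlnorm(length(pick), flux_meanlog, flux_sdlog)
        f[pick, j] <- f[pick, j] +
          intake[j] * frac_foreign * wf / sum(wf)
      }
    }
  }

  # egestion into the home detritus pool, then boundary flows for balance
  imports <- exports <- respiration <- numeric(s)
  for (j in which(level > 0L)) {
    home_basal <- which(level == 0L & channel == channel[j])
    if (category[home_basal] == "detritus" && egestion_frac > 0) {
      f[j, home_basal] <- f[j, home_basal] + egestion_frac * intake[j]
    }
  }
  for (j in which(level > 0L)) {
    surplus <- intake[j] - sum(f[j, ])
    respiration[j] <- 0.8 * surplus
    exports[j] <- 0.2 * surplus
  }
  for (b in which(level == 0L)) {
    net_out <- sum(f[b, ]) - sum(f[, b])
    if (net_out >= 0) imports[b] <- net_out else exports[b] <- -net_out
  }

  biomass <- numeric(s)
  biomass[level == 0L] <- rowSums(f)[level == 0L] * 10 *
    stats::rlnorm(sum(level == 0L), 0, 0.25)
  biomass[level > 0L] <- intake[level > 0L] * 5 *
    stats::rlnorm(sum(level > 0L), 0, 0.25)

  net <- flow_network(ids, category, biomass, imports, exports, respiration,
                      f)
  truth <- channel
  names(truth) <- ids
  structure(list(net = net, truth = truth,
                 spec = list(channels = k, per_channel = m, levels = levels,
                             eps = eps, flux_meanlog = flux_meanlog,
                             flux_sdlog = flux_sdlog,
                             egestion_frac = egestion_frac,
                             transfer_efficiency = transfer_efficiency,
                             couple_top = couple_top, seed = seed)),
            class = "planted_web")
}

#' Agreement between a detected and a planted partition
#'
#' Label-permutation-invariant exact-recovery check plus the Rand index.
#'
#' @param membership Detected labels (vector or fit object).
#' @param truth Planted labels.
#' @return List with `exact` (logical: identical partitions up to label
#'   permutation) and `rand` (Rand index in `[0, 1]`).
#' @export
partition_agreement <- function(membership, truth) {
  m <- as_membership(membership, length(truth))
  t_ <- as.integer(factor(truth))
  same_m <- outer(m, m, `==`)
  same_t <- outer(t_, t_, `==`)
  up <- upper.tri(same_m)
  list(exact = all(same_m == same_t),
       rand = mean(same_m[up] == same_t[up]))
}
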