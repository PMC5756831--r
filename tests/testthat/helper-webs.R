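# Small constructed webs and independent oracles shared across tests.

# Two disjoint directed links a->b (1.0), c->d (1.0).
toy_two_links <- function() {
  f <- matrix(0, 4, 4)
  f[1, 2] <- 1
  f[3, 4] <- 1
  flow_network(c("a", "b", "c", "d"),
               c("producer", "consumer", "producer", "consumer"),
               biomass = rep(1, 4),
               imports = c(1, 0, 1, 0), exports = c(0, 0.2, 0, 0.2),
               respiration = c(0, 0.8, 0, 0.8), flows = f)
}

# Balanced 2-node chain: import -> b -> c -> export.
toy_chain <- function(flux = 1) {
  f <- matrix(c(0, 0, flux, 0), 2, 2)
  flow_network(c("b", "c"), c("producer", "consumer"),
               biomass = c(2, 1), imports = c(flux, 0),
               exports = c(0, 0.3 * flux), respiration = c(0, 0.7 * flux),
               flows = f)
}

# Random layered web with `n_basal` basal nodes and random consumer diets
# (each consumer eats 1-3 lower-indexed nodes); used for modularity and
# reliance property tests. Not balanced; reliance and modularity do not
# require balance.
random_web <- function(s = 12, n_basal = 3, seed = 1) {
  set.seed(seed)
  stopifnot(s >= n_basal + 2)
  cat_ <- c(rep(c("detritus", "producer"), length.out = n_basal),
            sample(c("consumer", "decomposer"), s - n_basal, replace = TRUE))
  f <- matrix(0, s, s)
  for (j in (n_basal + 1):s) {
    np <- sample(1:min(3, j - 1), 1)
    prey <- sample(seq_len(j - 1), np)
    f[prey, j] <- stats::rlnorm(np)
  }
  # occasional consumer-consumer feedback edge to exercise cycles
  if (s - n_basal >= 3 && stats::runif(1) < 0.7) {
    i <- sample((n_basal + 1):s, 2)
    f[i[1], i[2]] <- stats::rlnorm(1)
  }
  flow_network(sprintf("n%02d", seq_len(s)), cat_,
               biomass = stats::rlnorm(s, 1),
               imports = c(rowSums(f)[seq_len(n_basal)],
                           rep(0, s - n_basal)),
               exports = rep(0.1, s), respiration = rep(0.1, s), flows = f)
}

# Independent oracle for basal reliance: fixed-point iteration of
# row_i = sum_j P[j, i] row_j with basal rows pinned, run to convergence.
br_fixed_point <- function(net, iters = 20000, tol = 1e-13) {
  p <- diet_proportions(net)
  basal <- basal_nodes(net)
  s <- n_nodes(net)
  br <- matrix(0, s, length(basal))
  for (k in seq_along(basal)) br[basal[k], k] <- 1
  cons <- setdiff(seq_len(s), basal)
  for (it in seq_len(iters)) {
    old <- br
    for (i in cons) br[i, ] <- colSums(p[, i] * old)
    for (k in seq_along(basal)) br[basal[k], ] <- 0
    for (k in seq_along(basal)) br[basal[k], k] <- 1
    if (max(abs(br - old)) < tol) break
  }
  dimnames(br) <- list(net$node_ids, net$node_ids[basal])
  br
}

# Brute-force modularity straight from the defining double sum.
q_brute <- function(net, membership) {
  w <- net$flows
  two_w <- sum(w)
  m <- as.integer(factor(membership))
  wout <- rowSums(w)
  win <- colSums(w)
  q <- 0
  for (i in seq_len(nrow(w))) {
    for (j in seq_len(ncol(w))) {
      if (m[i] == m[j]) q <- q + w[i, j] - wout[i] * win[j] / two_w
    }
  }
  unname(q / two_w)
}
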