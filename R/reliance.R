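#' Diet proportions of every consumer
#'
#' For each node `j` with total internal inflow `T_j = sum_i F[i, j] > 0`,
#' the diet proportion `P[i, j] = F[i, j] / T_j` is the fraction of `j`'s
#' internal diet supplied by resource `i`. Imports are excluded from the
#' denominator: basal reliance traces carbon to in-web energy origins only
#' (set `imports_as_source = TRUE` in [basal_reliance()] to treat imports as
#' a pseudo-basal source instead). Columns of nodes with no internal inflow
#' are all zero.
#'
#' @param net A [flow_network].
#' @return S-by-S matrix `P`, columns summing to 1 wherever inflow exists.
#' @export
diet_proportions <- function(net) {
  stopifnot(inherits(net, "flow_network"))
  tj <- colSums(net$flows)
  p <- sweep(net$flows, 2L, ifelse(tj > 0, tj, 1), `/`)
  p[, tj == 0] <- 0
  p
}

#' Fractional reliance of every node on every basal resource
#'
#' The basal reliance of a consumer is the diet-weighted average of its
#' resources' reliances: `BR[i, ] = sum_j P[j, i] * BR[j, ]`, where `P[j, i]`
#' is the proportion of `i`'s diet supplied by `j`. Basal nodes (producers
#' and detritus pools) are absorbing energy origins: their reliance is fixed
#' at the unit vector on themselves and their own inflows (detrital
#' recycling) are never traversed, which cuts every loop through detritus.
#' Remaining consumer-consumer cycles are handled exactly by solving the
#' linear system with the basal rows as boundary conditions.
#'
#' @param net A [flow_network].
#' @param imports_as_source If `TRUE`, add a pseudo-basal column `"@import"`
#'   and count imports in the diet denominator, so externally subsidized
#'   nodes show their import reliance instead of renormalizing over internal
#'   prey.
#' @return A matrix of class `basal_reliance` (rows = all nodes, columns =
#'   basal node ids), rows summing to 1 for every node reachable from the
#'   basal set. Attributes: `"unreachable"` (logical per node: structurally
#'   zero basal input, row all zero) and `"diet"` (the `P` matrix used).
#' @export
basal_reliance <- function(net, imports_as_source = FALSE) {
  stopifnot(inherits(net, "flow_network"))
  s <- n_nodes(net)
  basal <- basal_nodes(net)
  if (!length(basal)) stop("no basal node in network", call. = FALSE)

  p <- diet_proportions(net)
  extra <- 0L
  if (imports_as_source) {
    tj <- colSums(net$flows) + net$imports
    p <- sweep(rbind(net$flows, net$imports), 2L, ifelse(tj > 0, tj, 1), `/`)
    p[, tj == 0] <- 0
    extra <- 1L
  }

  b <- length(basal) + extra
  br <- matrix(0, s, b,
               dimnames = list(net$node_ids,
                               c(net$node_ids[basal],
                                 if (extra) "@import")))
  for (k in seq_along(basal)) br[basal[k], k] <- 1

  cons <- setdiff(seq_len(s), basal)
  if (length(cons)) {
    # rows i in cons satisfy br[i, ] = sum_j p[j, i] br[j, ]; split the sum
    # into basal + import boundary terms and the consumer-consumer part.
    a <- t(p[cons, cons, drop = FALSE])          # a[i, j] = p[j, i]
    cb <- t(p[basal, cons, drop = FALSE])        # boundary from basal rows
    if (extra) cb <- cbind(cb, p[s + 1L, cons])  # import pseudo-source
    sol <- tryCatch(solve(diag(length(cons)) - a, cb),
                    error = function(e) {
                      stop("singular reliance system: a consumer cycle ",
                           "retains all of its flow (no leakage); ",
                           conditionMessage(e), call. = FALSE)
                    })
    br[cons, ] <- sol
  }

  rs <- rowSums(br)
  unreachable <- rs < 1 - 1e-9
  structure(br, class = c("basal_reliance", "matrix", "array"),
            unreachable = unreachable, diet = p[seq_len(s), , drop = FALSE])
}

#' Seed subgroups by dominant energy origin
#'
#' Every basal node seeds its own subgroup; every other node joins the
#' subgroup of the basal resource supplying the largest share of its carbon
#' (ties broken toward the basal node appearing first in the node table).
#' Nodes with structurally zero basal reliance become singleton subgroups so
#' the merge phase can still absorb them.
#'
#' @param br A [basal_reliance] matrix.
#' @return A list of class `subgroup_assignment`: `membership` (named
#'   integer vector over nodes; labels are contiguous `1..n_groups`),
#'   `seed` (character label of each subgroup: basal node id or the
#'   unreachable node's own id) and `margin` (dominant share minus runner-up
#'   share per node, `NA` for basal/unreachable nodes).
#' @export
dominant_source_groups <- function(br) {
  stopifnot(inherits(br, "basal_reliance"))
  nodes <- rownames(br)
  basal_ids <- colnames(br)
  unreachable <- attr(br, "unreachable")
  seed <- basal_ids[basal_ids %in% nodes]         # drop "@import" pseudo-col
  membership <- integer(length(nodes))
  names(membership) <- nodes
  margin <- rep(NA_real_, length(nodes))
  names(margin) <- nodes
  for (i in seq_along(nodes)) {
    id <- nodes[i]
    if (id %in% seed) {
      membership[i] <- match(id, seed)
    } else if (unreachable[i]) {
      seed <- c(seed, id)                          # singleton subgroup
      membership[i] <- length(seed)
    } else {
      row <- br[i, colnames(br) %in% nodes, drop = TRUE]
      k <- which.max(row)                          # first max = lowest index
      membership[i] <- k
      srt <- sort(row, decreasing = TRUE)
      margin[i] <- srt[1L] - if (length(srt) > 1L) srt[2L] else 0
    }
  }
  structure(list(membership = membership, seed = seed, margin = margin),
            class = "subgroup_assignment")
}
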