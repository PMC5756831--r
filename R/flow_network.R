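#' Construct a quantitative flow network
#'
#' A `flow_network` holds a quantitative (carbon-flux) food web: a set of
#' nodes with ecological categories, standing biomass and boundary flows,
#' plus an S-by-S matrix of internal fluxes. It is the universal input object
#' of the package; all analysis functions take one.
#'
#' @param node_ids Character vector of unique node identifiers.
#' @param category Character vector, one of `"producer"`, `"consumer"`,
#'   `"decomposer"`, `"detritus"` per node. Producers and detritus pools are
#'   the basal energy origins.
#' @param biomass Numeric vector of standing stocks (g C m^-2), non-negative.
#' @param imports,exports,respiration Numeric vectors of boundary flows
#'   (g C m^-2 day^-1), non-negative.
#' @param flows S-by-S numeric matrix; `flows[i, j]` is the internal carbon
#'   flux from node `i` to node `j` (g C m^-2 day^-1), non-negative.
#' @param names Optional character vector of display names (defaults to ids).
#'
#' @return An object of class `flow_network`: a list with elements
#'   `node_ids`, `names`, `category`, `biomass`, `imports`, `exports`,
#'   `respiration` and `flows` (the matrix carries node ids as dimnames).
#'
#' @examples
#' net <- flow_network(
#'   node_ids = c("det", "worm"),
#'   category = c("detritus", "consumer"),
#'   biomass  = c(5, 1),
#'   imports  = c(1, 0), exports = c(0, 0.2), respiration = c(0, 0.8),
#'   flows    = matrix(c(0, 0, 1, 0), 2, 2)
#' )
#' basal_nodes(net)
#' @export
flow_network <- function(node_ids, category, biomass, imports, exports,
                         respiration, flows, names = node_ids) {
  node_ids <- as.character(node_ids)
  s <- length(node_ids)
  if (s < 2L) stop("a flow network needs at least 2 nodes", call. = FALSE)
  if (anyDuplicated(node_ids)) {
    stop("duplicate node ids: ",
         paste(unique(node_ids[duplicated(node_ids)]), collapse = ", "),
         call. = FALSE)
  }
  category <- match.arg(as.character(category), .node_categories,
                        several.ok = TRUE)
  if (length(category) != s) stop("category must have one entry per node",
                                  call. = FALSE)
  if (!any(category %in% c("producer", "detritus"))) {
    stop("no basal node: at least one producer or detritus node is required",
         call. = FALSE)
  }
  flows <- as.matrix(flows)
  if (!all(dim(flows) == c(s, s))) {
    stop("flows must be an S-by-S matrix (S = ", s, ")", call. = FALSE)
  }
  for (nm in c("biomass", "imports", "exports", "respiration")) {
    v <- get(nm)
    if (length(v) != s || !is.numeric(v)) {
      stop(nm, " must be a numeric vector of length S", call. = FALSE)
    }
    if (any(v < 0)) stop(nm, " must be non-negative", call. = FALSE)
  }
  if (any(flows < 0)) stop("fluxes must be non-negative", call. = FALSE)
  dimnames(flows) <- list(node_ids, node_ids)
  structure(
    list(node_ids = node_ids, names = as.character(names),
         category = category,
         biomass = as.numeric(biomass), imports = as.numeric(imports),
         exports = as.numeric(exports),
         respiration = as.numeric(respiration), flows = flows),
    class = "flow_network"
  )
}

.node_categories <- c("producer", "consumer", "decomposer", "detritus")

#' @export
print.flow_network <- function(x, ...) {
  cat("<flow_network> ", n_nodes(x), " nodes (",
      paste(sprintf("%d %s", table(factor(x$category, .node_categories)),
                    .node_categories), collapse = ", "),
      ")\n", sep = "")
  cat("  total internal flow: ", format(sum(x$flows)), " g C m-2 day-1\n",
      sep = "")
  invisible(x)
}

#' Number of nodes in a flow network
#' @param net A `flow_network`.
#' @return Integer node count S.
#' @export
n_nodes <- function(net) length(net$node_ids)

#' Indices of basal nodes
#'
#' Basal status is assigned by category: producers and detritus pools are the
#' energy origins, regardless of topology (detritus receives recycled inflow
#' yet still acts as a source).
#'
#' @param net A `flow_network`.
#' @return Integer vector of basal node indices (node-table order).
#' @export
basal_nodes <- function(net) which(net$category %in% c("producer", "detritus"))

#' Per-node steady-state residuals and structural warnings
#'
#' At steady state every node's total input (imports plus internal inflow)
#' equals its total output (exports, respiration and internal outflow). The
#' residual reported here is input minus output, in g C m^-2 day^-1.
#'
#' @param net A `flow_network`.
#' @param tol Relative tolerance: a node is flagged unbalanced when
#'   `|residual| > tol * throughflow` (throughflow = max of total input and
#'   total output).
#' @return A list of class `validation_report` with elements `residual`
#'   (named numeric), `relative` (residual scaled by throughflow),
#'   `balanced` (logical scalar) and `warnings` (character vector covering
#'   self-loops, isolated nodes and zero-biomass living nodes).
#' @export
validate_network <- function(net, tol = 1e-6) {
  stopifnot(inherits(net, "flow_network"))
  input <- net$imports + colSums(net$flows)
  output <- net$exports + net$respiration + rowSums(net$flows)
  residual <- input - output
  through <- pmax(input, output)
  rel <- ifelse(through > 0, abs(residual) / through, 0)
  names(residual) <- names(rel) <- net$node_ids
  warn <- character()
  self <- which(diag(net$flows) > 0)
  if (length(self)) {
    warn <- c(warn, paste0("self-loop (cannibalism) at: ",
                           paste(net$node_ids[self], collapse = ", ")))
  }
  iso <- which(input == 0 & output == 0)
  if (length(iso)) {
    warn <- c(warn, paste0("isolated node (no flows at all): ",
                           paste(net$node_ids[iso], collapse = ", ")))
  }
  dead <- which(net$biomass == 0 & net$category != "detritus")
  if (length(dead)) {
    warn <- c(warn, paste0("zero-biomass living node: ",
                           paste(net$node_ids[dead], collapse = ", ")))
  }
  structure(list(residual = residual, relative = rel,
                 balanced = all(rel <= tol), tol = tol, warnings = warn),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", if (x$balanced) "balanced" else "UNBALANCED",
      " (tol ", format(x$tol), ")\n", sep = "")
  cat("  max |residual|/throughflow: ", format(max(x$relative)), "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}
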