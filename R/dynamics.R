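#' Calibrate the bioenergetic model from a balanced flow network
#'
#' Builds the parameter set of the food-web dynamics model so that the
#' observed flows are an exact equilibrium (inverse calibration in the
#' de Ruiter tradition). Node categories map onto four equation blocks:
#'
#' * **producers** grow logistically over summed producer biomass, lose to
#'   herbivory, death (routed to detritus) and constant boundary drains;
#' * **consumers and decomposers** gain assimilated intake through the
#'   multi-prey functional response and lose to predation and respiration;
#' * **detritus pools** receive producer death, consumer egestion and
#'   inter-pool conversion, and lose to detritivory and conversion.
#'
#' Calibration maps every recorded flux onto a rate: respiration rate
#' `x = respiration / B`; assimilation `a = 1 - egestion / intake` (egestion
#' = outflow to detritus pools); prey preferences `omega[i, j]` proportional
#' to `F[i, j] / B_i^h` (the unique column-stochastic choice for which the
#' calibrated functional response reproduces every observed flux at the
#' empirical state), half-saturation `H` = total prey biomass, and the
#' maximum consumption rate `y` solving `Phi * B = F` exactly. Producer
#' imports are gross primary production, mapped onto the logistic term with
#' shared `K = 2 * sum(B_producers)` and `r = 2 * import / B`; death rate
#' `d` = flux-to-detritus / B. Detritus conversion `c[j, i] = F[j, i] / B_j`.
#' Remaining boundary flows (non-producer imports, exports, and the
#' respiration of non-consumer nodes) enter as constant forcings so that
#' open webs have an equilibrium.
#'
#' @param net A balanced [flow_network].
#' @param h Hill exponent of the functional response, between 1 (Holling
#'   type II) and 2 (type III); default 1.2.
#' @param q Predator interference coefficient (default 1). With `q = 0`
#'   consumers have no self-damping (their per-capita gain is independent of
#'   their own density) and the calibrated equilibria of layered webs are
#'   locally unstable; moderate interference restores asymptotic stability,
#'   which the removal protocol's settled baselines presuppose. See the
#'   methods vignette.
#' @return A list of class `dynamics_params` holding all rate and shape
#'   parameters plus the empirical state `b0`.
#' @export
calibrate_dynamics <- function(net, h = 1.2, q = 1) {
  stopifnot(inherits(net, "flow_network"), h >= 1, h <= 2, q >= 0)
  v <- validate_network(net, tol = 1e-4)
  if (!v$balanced) {
    warning("calibrating an unbalanced network: the empirical state will ",
            "not be an equilibrium", call. = FALSE)
  }
  s <- n_nodes(net)
  f <- net$flows
  b <- net$biomass
  cat_ <- net$category
  is_pro <- cat_ == "producer"
  is_det <- cat_ == "detritus"
  is_con <- cat_ %in% c("consumer", "decomposer")

  active <- rowSums(f) + colSums(f) > 0
  if (any(active & b <= 0 & !is_det)) {
    stop("living node(s) with zero biomass but nonzero flux: ",
         paste(net$node_ids[active & b <= 0 & !is_det], collapse = ", "),
         call. = FALSE)
  }
  if (any(active & b <= 0 & is_det)) {
    stop("detritus pool(s) with zero stock but nonzero flux: ",
         paste(net$node_ids[active & b <= 0 & is_det], collapse = ", "),
         call. = FALSE)
  }
  if (any(colSums(f)[is_pro] > 0)) {
    stop("producer(s) with internal inflow are not supported by the ",
         "producer equation: ",
         paste(net$node_ids[is_pro & colSums(f) > 0], collapse = ", "),
         call. = FALSE)
  }
  intake <- colSums(f)
  egest <- rowSums(f[, is_det, drop = FALSE])

  a <- rep(1, s)
  x <- rep(0, s)
  y <- rep(0, s)
  hh <- rep(1, s)
  omega <- matrix(0, s, s, dimnames = dimnames(f))
  for (j in which(is_con)) {
    x[j] <- net$respiration[j] / b[j]
    if (intake[j] <= 0) {
      if (egest[j] > 0) {
        stop("node ", net$node_ids[j], " egests to detritus but has no ",
             "intake: infeasible assimilation", call. = FALSE)
      }
      next
    }
    a[j] <- 1 - egest[j] / intake[j]
    if (a[j] <= 0) {
      stop("node ", net$node_ids[j], " egests its entire intake or more: ",
           "infeasible assimilation efficiency", call. = FALSE)
    }
    prey <- which(f[, j] > 0)
    raw <- f[prey, j] / b[prey]^h
    z <- sum(raw)
    omega[prey, j] <- raw / z
    hh[j] <- sum(b[prey])
    den <- hh[j]^h * (1 + q * b[j]) + sum(omega[prey, j] * b[prey]^h)
    y[j] <- z * den / b[j]
  }

  d <- rep(0, s)
  p_route <- matrix(0, s, s, dimnames = dimnames(f))
  for (j in which(is_pro)) {
    dj <- egest[j]
    if (dj > 0) {
      d[j] <- dj / b[j]
      p_route[j, is_det] <- f[j, is_det] / dj
    }
  }
  for (j in which(is_con)) {
    if (egest[j] > 0) p_route[j, is_det] <- f[j, is_det] / egest[j]
  }
  conv <- matrix(0, s, s, dimnames = dimnames(f))
  for (j in which(is_det)) {
    conv[j, is_det] <- f[j, is_det] / b[j]
  }

  b_pro <- sum(b[is_pro])
  k_cap <- if (b_pro > 0) 2 * b_pro else Inf
  r <- rep(0, s)
  r[is_pro] <- 2 * net$imports[is_pro] / b[is_pro]

  forcing <- numeric(s)
  forcing[is_pro] <- -net$exports[is_pro] - net$respiration[is_pro]
  forcing[is_con] <- net$imports[is_con] - net$exports[is_con]
  forcing[is_det] <- net$imports[is_det] - net$exports[is_det] -
    net$respiration[is_det]

  structure(list(node_ids = net$node_ids, category = cat_, b0 = b,
                 is_producer = is_pro, is_consumer = is_con,
                 is_detritus = is_det,
                 r = r, k_cap = k_cap, d = d,
                 y = y, a = a, x = x, h = h, q = rep(q, s), hsat = hh,
                 omega = omega, p_route = p_route, conv = conv,
                 forcing = forcing, floor = 1e-10),
            class = "dynamics_params")
}

# Feeding-rate matrix: phi[i, j] = per-unit-biomass rate at which consumer j
# takes resource i at state b.
.phi_matrix <- function(params, b) {
  h <- params$h
  bh <- pmax(b, 0)^h
  num <- params$omega * bh            # omega_ij * B_i^h, recycled by column
  den <- params$hsat^h * (1 + params$q * pmax(b, 0)) + colSums(num)
  phi <- sweep(num, 2L, ifelse(den > 0, params$y / den, 0), `*`)
  phi[, !params$is_consumer] <- 0
  phi
}

#' Functional response of one consumer on one resource
#'
#' The multi-prey feeding rate
#' \deqn{\Phi_{ij} = \frac{y_j \omega_{ij} B_i^h}{H_j^h + q_j B_j H_j^h +
#'   \sum_k \omega_{kj} B_k^h}}
#' in day^-1 per unit consumer biomass; `h = 1, q = 0` gives the Holling
#' type II form, `h = 2` the sigmoid type III form.
#'
#' @param params A [calibrate_dynamics()] parameter set (or any list with
#'   fields `y`, `omega`, `hsat`, `q`, `h`, `is_consumer`).
#' @param state Biomass vector (g C m^-2).
#' @param i Resource index or id.
#' @param j Consumer index or id.
#' @return `Phi_ij` (day^-1).
#' @export
functional_response <- function(params, state, i, j) {
  if (is.character(i)) i <- match(i, params$node_ids)
  if (is.character(j)) j <- match(j, params$node_ids)
  .phi_matrix(params, state)[i, j]
}

#' Time derivatives of the bioenergetic model
#'
#' Evaluates the biomass rate of change of every node at a given state:
#' logistic producers minus herbivory and death, consumers/decomposers
#' gaining assimilated intake and losing predation and respiration, and
#' detritus pools balancing death, egestion, conversion and detritivory,
#' plus the constant boundary forcings. States below the biomass floor are
#' held there (their negative derivatives are zeroed).
#'
#' @param params A `dynamics_params` object.
#' @param state Biomass vector (g C m^-2), non-negative.
#' @return Named vector `dB/dt` (g C m^-2 day^-1).
#' @export
flow_derivatives <- function(params, state) {
  b <- pmax(as.numeric(state), 0)
  s <- length(b)
  phi <- .phi_matrix(params, b)
  flux <- sweep(phi, 2L, b, `*`)      # flux[i, j] = Phi_ij * B_j
  intake <- colSums(flux)
  pred <- rowSums(flux)

  db <- numeric(s)
  pro <- params$is_producer
  con <- params$is_consumer
  det <- params$is_detritus

  if (any(pro)) {
    logistic <- if (is.finite(params$k_cap)) {
      1 - sum(b[pro]) / params$k_cap
    } else 1
    db[pro] <- params$r[pro] * b[pro] * logistic - pred[pro] -
      params$d[pro] * b[pro]
  }
  db[con] <- params$a[con] * intake[con] - pred[con] -
    params$x[con] * b[con]
  if (any(det)) {
    death_in <- drop(crossprod(params$p_route[pro, , drop = FALSE],
                               (params$d * b)[pro]))
    egest_in <- drop(crossprod(params$p_route[con, , drop = FALSE],
                               ((1 - params$a) * intake)[con]))
    conv_in <- drop(crossprod(params$conv, b))
    conv_out <- rowSums(params$conv) * b
    db[det] <- death_in[det] + egest_in[det] + conv_in[det] - pred[det] -
      conv_out[det]
  }
  db <- db + params$forcing
  db[b <= params$floor & db < 0] <- 0
  names(db) <- params$node_ids
  db
}

#' Integrate the bioenergetic model
#'
#' Adaptive embedded Runge-Kutta 4(5) integration (via
#' [deSolve::ode()], `method = "ode45"`), with a biomass floor of
#' `params$floor` (clamp, not extinction) and an optional frozen node whose
#' biomass is pinned at zero (a removed species).
#'
#' @param params A `dynamics_params` object.
#' @param b0 Initial biomass vector (defaults to the empirical state).
#' @param times Output time grid in days.
#' @param removed Optional node index or id frozen at zero biomass.
#' @param rtol,atol Integrator tolerances.
#' @return A matrix (time x nodes) of biomasses; attribute `"times"`.
#' @export
simulate_flows <- function(params, b0 = params$b0,
                           times = seq(0, 1000, by = 2), removed = NULL,
                           rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(params, "dynamics_params"))
  if (is.character(removed)) removed <- match(removed, params$node_ids)
  y0 <- pmax(as.numeric(b0), 0)
  if (!is.null(removed)) y0[removed] <- 0
  rhs <- function(t, y, p) {
    if (!is.null(removed)) y[removed] <- 0
    db <- flow_derivatives(params, y)
    if (!is.null(removed)) db[removed] <- 0
    list(db)
  }
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "ode45", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0) {
    stop("integrator failure at t = ", max(sol[, 1L]),
         "; worst state = ", format(min(sol[, -1L])), call. = FALSE)
  }
  out <- pmax(unname(sol[, -1L, drop = FALSE]), 0)
  colnames(out) <- params$node_ids
  attr(out, "times") <- sol[, 1L]
  out
}

#' Node-removal experiment
#'
#' The simulation protocol of the removal study: integrate the calibrated
#' model for `burn_in` days from the empirical biomasses so transients
#' settle, record each node's average biomass over the next `window` days
#' as `B+`, then set the removed node's biomass to zero (frozen), integrate
#' another `window` days and record the averages as `B-`. Removal effects
#' per node follow [removal_effect()] with `B_k` the removed node's `B+`.
#'
#' @param net A balanced [flow_network], or `NULL` if `params` is given.
#' @param removed Node id or index to remove (must not be the only basal
#'   node).
#' @param params Optional pre-computed [calibrate_dynamics()] result.
#' @param burn_in,window Phase lengths in days (study design: 1000 each).
#' @param dt Output step used for averaging (days).
#' @param ... Passed to [calibrate_dynamics()] when `params` is `NULL`.
#' @return A list of class `removal_outcome`: `removed` (id), `b_k`,
#'   `b_plus`, `b_minus` (named vectors) and `re` (named vector,
#'   `NA` at the removed node).
#' @export
removal_experiment <- function(net, removed, params = NULL,
                               burn_in = 1000, window = 1000, dt = 2, ...) {
  if (is.null(params)) params <- calibrate_dynamics(net, ...)
  stopifnot(inherits(params, "dynamics_params"))
  if (is.character(removed)) removed <- match(removed, params$node_ids)
  if (is.na(removed) || removed < 1 || removed > length(params$node_ids)) {
    stop("unknown node to remove", call. = FALSE)
  }
  basal <- which(params$is_producer | params$is_detritus)
  if (length(basal) == 1L && basal == removed) {
    stop("cannot remove the only basal node", call. = FALSE)
  }

  t1 <- seq(0, burn_in + window, by = dt)
  traj1 <- simulate_flows(params, times = t1)
  keep <- attr(traj1, "times") > burn_in
  b_plus <- colMeans(traj1[keep, , drop = FALSE])
  state <- traj1[nrow(traj1), ]
  state[removed] <- 0

  t2 <- seq(0, window, by = dt)
  traj2 <- simulate_flows(params, b0 = state, times = t2, removed = removed)
  b_minus <- colMeans(traj2[attr(traj2, "times") > 0, , drop = FALSE])

  b_k <- b_plus[removed]
  re <- removal_effect(b_plus, b_minus, b_k)
  re[removed] <- NA_real_
  structure(list(removed = params$node_ids[removed], b_k = unname(b_k),
                 b_plus = b_plus, b_minus = b_minus, re = re),
            class = "removal_outcome")
}

#' Relative equilibrium residual of a calibrated model
#'
#' Convenience check: `max_i |dB_i/dt| / B_i` over nodes with positive
#' biomass, evaluated at the empirical state. Calibration constructs the
#' data to be an equilibrium, so this should be at rounding level.
#'
#' @param params A `dynamics_params` object.
#' @param state Biomass vector (defaults to the empirical state).
#' @return Maximum relative residual (day^-1).
#' @export
equilibrium_residual <- function(params, state = params$b0) {
  db <- flow_derivatives(params, state)
  pos <- state > 0
  if (!any(pos)) return(0)
  max(abs(db[pos]) / state[pos])
}
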