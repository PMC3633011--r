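## Deterministic and stochastic dynamics of rate-bound Petri nets.
##
## A transition t with rate constant k and input multiplicities I-(t,.)
## fires, in the deterministic limit, at velocity k * prod_h X_h^I-(t,h)
## (generalized mass action with kinetic orders equal to the input
## stoichiometry); it contributes +/- (I+ - I-) times that velocity to each
## species equation. The stochastic semantics is the standard SPN
## continuous-time Markov chain, simulated by Gillespie's direct method
## with combinatorial (falling-factorial) propensities.

#' Derive the mass-action ODE system of a rate-bound net
#'
#' @param net a \code{petri_net} with every transition rate-bound.
#' @param params named vector of rate constants (and optionally initial
#'   amounts, which override the net's initial marking species-wise).
#' @return object of class \code{"ode_system"} with \code{species},
#'   \code{initial_amounts}, and the stoichiometric machinery needed by
#'   \code{\link{integrate_odes}}.
#' @examples
#' p <- parse_reactions("R1 A -> B ; kf=k")
#' sys <- derive_odes(p$net, c(k = 1, A = 1))
#' @export
derive_odes <- function(net, params) {
  stopifnot(inherits(net, "petri_net"))
  if (is.null(net$rates)) stop("net has no rate binding")
  unbound <- net$transitions[is.na(net$rates)]
  if (length(unbound) > 0L) stop("unbound transition: ", unbound[1L])
  missing <- setdiff(net$rates, names(params))
  if (length(missing) > 0L) stop("missing rate parameter: ", missing[1L])
  k <- stats::setNames(as.numeric(params[net$rates]), net$transitions)

  x0 <- net$initial_marking
  override <- intersect(net$places, names(params))
  x0[override] <- params[override]

  structure(list(species = net$places, transitions = net$transitions,
                 input = net$input, stoich = t(incidence_matrix(net)),
                 k = k, initial_amounts = x0, net = net),
            class = "ode_system")
}

## velocity vector over transitions at state x (x may go slightly negative
## inside a stiff solver step; clip for the monomials)
.velocities <- function(sys, x) {
  xc <- pmax(x, 0)
  v <- sys$k
  for (j in seq_along(v)) {
    need <- sys$input[j, ]
    nz <- which(need > 0)
    if (length(nz) > 0L) v[j] <- v[j] * prod(xc[nz]^need[nz])
  }
  v
}

.ode_rhs <- function(sys, x, t) {
  as.numeric(sys$stoich %*% .velocities(sys, x))
}

#' Tabulate the generalized mass-action terms of an ODE system
#'
#' One row per (species, transition) pair with non-zero net stoichiometry:
#' the species' equation gains the term
#' \code{coefficient * prod_h X_h^exponent_h} with exponents equal to the
#' transition's input multiplicities.
#'
#' @param sys an \code{ode_system}.
#' @return data frame with columns \code{species}, \code{transition},
#'   \code{coefficient} (signed, rate constant included) and
#'   \code{monomial} (human-readable).
#' @export
ode_terms <- function(sys) {
  stopifnot(inherits(sys, "ode_system"))
  rows <- list()
  for (j in seq_along(sys$transitions)) {
    dm <- sys$stoich[, j]
    need <- sys$input[j, ]
    mono <- paste(ifelse(need[need > 0] > 1,
                         paste0(names(need[need > 0]), "^", need[need > 0]),
                         names(need[need > 0])), collapse = "*")
    if (mono == "") mono <- "1"
    for (i in which(dm != 0)) {
      rows[[length(rows) + 1L]] <- data.frame(
        species = sys$species[i], transition = sys$transitions[j],
        coefficient = dm[i] * sys$k[j], monomial = mono,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Reduce an ODE system using minimal P-semiflows
#'
#' For each semiflow one support variable is eliminated and rewritten as a
#' linear combination of the remaining support variables via the invariant
#' \code{x . X(t) = x . X(0)}; the eliminated variable chosen is the support
#' place with the largest species index not yet eliminated. Elimination is
#' exact: integrating the reduced system and reconstructing the eliminated
#' variables reproduces the full-system trajectory.
#'
#' @param sys an \code{ode_system}.
#' @param semiflows list from \code{\link{p_semiflows}} of the same net.
#' @return object of class \code{"reduced_ode_system"}.
#' @export
reduce_odes <- function(sys, semiflows) {
  stopifnot(inherits(sys, "ode_system"))
  if (length(semiflows) == 0L) return(sys)
  elim <- integer(0)
  for (f in semiflows) {
    idx <- match(f$support, sys$species)
    if (anyNA(idx)) stop("semiflow references unknown species")
    cand <- setdiff(idx, elim)
    if (length(cand) == 0L) {
      stop("cannot reduce: semiflow support {",
           paste(f$support, collapse = ", "),
           "} is already fully eliminated")
    }
    elim <- c(elim, max(cand))
  }
  A <- do.call(rbind, lapply(semiflows, function(f) {
    f$coefficients[sys$species]
  }))                                    # k x E semiflow matrix
  constants <- as.numeric(A %*% sys$initial_amounts)
  free <- setdiff(seq_along(sys$species), elim)
  Ae <- A[, elim, drop = FALSE]
  if (abs(det(Ae)) < .Machine$double.eps) {
    stop("eliminated-variable choice is singular; semiflows are dependent")
  }
  structure(list(full = sys, free = free, eliminated = elim,
                 A = A, Ae_inv = solve(Ae), constants = constants),
            class = "reduced_ode_system")
}

## full state from free state, given current invariant constants
.reconstruct <- function(red, xfree, constants) {
  x <- numeric(length(red$full$species))
  names(x) <- red$full$species
  x[red$free] <- xfree
  rhs <- constants - as.numeric(red$A[, red$free, drop = FALSE] %*% xfree)
  x[red$eliminated] <- as.numeric(red$Ae_inv %*% rhs)
  x
}

#' Number of state equations actually integrated
#' @param sys an \code{ode_system} or \code{reduced_ode_system}.
#' @return integer count of free differential equations.
#' @export
n_equations <- function(sys) {
  if (inherits(sys, "reduced_ode_system")) length(sys$free)
  else length(sys$species)
}

#' Build a timed event schedule
#'
#' Actions model external interventions on the molecular state:
#' \code{add} injects an amount of a species (growth-factor injection),
#' \code{scale} multiplies a species by a factor in [0, 1] (vaccination as
#' surface-receptor down-regulation / functional block).
#'
#' @param time numeric event times.
#' @param action character, \code{"add"} or \code{"scale"}.
#' @param species target species name.
#' @param amount injected amount (for \code{add}) or retention factor in
#'   [0, 1] (for \code{scale}).
#' @return data frame of class \code{"event_schedule"}, sorted by time.
#' @export
event_schedule <- function(time = numeric(0), action = character(0),
                           species = character(0), amount = numeric(0)) {
  ev <- data.frame(time = as.numeric(time), action = as.character(action),
                   species = as.character(species),
                   amount = as.numeric(amount), stringsAsFactors = FALSE)
  if (!all(ev$action %in% c("add", "scale"))) {
    stop("event action must be 'add' or 'scale'")
  }
  if (any(ev$amount < 0)) stop("event amounts must be non-negative")
  if (any(ev$action == "scale" & ev$amount > 1)) {
    stop("scale factors must lie in [0, 1]")
  }
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("event_schedule", "data.frame")
  ev
}

.apply_event <- function(x, ev_row) {
  sp <- ev_row$species
  if (!sp %in% names(x)) stop("event targets unknown species: ", sp)
  if (ev_row$action == "add") x[sp] <- x[sp] + ev_row$amount
  else x[sp] <- x[sp] * ev_row$amount
  x
}

#' Integrate a (possibly reduced) mass-action ODE system
#'
#' Integration uses a stiff-capable solver (\code{deSolve::lsoda}) and is
#' restarted at every event time: the state is modified per the event action
#' and the invariant constants of a reduced system are recomputed, so events
#' that break a conservation law remain consistent. The returned trajectory
#' is sampled on \code{t_grid} plus all event times (rows at event times
#' hold the post-event state; pre-event states are kept in the
#' \code{events} attribute).
#'
#' @param sys an \code{ode_system} or \code{reduced_ode_system}.
#' @param t_grid increasing sample times.
#' @param events optional \code{\link{event_schedule}} with times strictly
#'   inside the integration window.
#' @param x0 optional initial amounts overriding the system's.
#' @param rtol,atol solver tolerances.
#' @return a \code{pn_trajectory} over all species (eliminated variables of
#'   a reduced system are reconstructed).
#' @export
integrate_odes <- function(sys, t_grid, events = NULL, x0 = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  reduced <- inherits(sys, "reduced_ode_system")
  full <- if (reduced) sys$full else sys
  stopifnot(inherits(full, "ode_system"))
  if (is.unsorted(t_grid, strictly = TRUE)) {
    stop("t_grid must be strictly increasing")
  }
  if (is.null(x0)) x0 <- full$initial_amounts
  x0 <- as_marking(full$species, x0)

  ev <- if (is.null(events)) event_schedule() else events
  if (nrow(ev) > 0L &&
      (min(ev$time) <= t_grid[1] || max(ev$time) >= t_grid[length(t_grid)])) {
    stop("event times must lie strictly within the integration window")
  }

  times_all <- sort(unique(c(t_grid, ev$time)))
  breaks <- c(t_grid[1], unique(ev$time), t_grid[length(t_grid)])

  out_times <- numeric(0)
  out_states <- list()
  ev_log <- list()
  x <- x0
  constants <- if (reduced) as.numeric(sys$A %*% x0) else NULL

  deriv_full <- function(t, y, parms) {
    list(.ode_rhs(full, stats::setNames(y, full$species), t))
  }
  deriv_red <- function(t, y, parms) {
    xf <- .reconstruct(sys, y, parms$constants)
    list(.ode_rhs(full, xf, t)[sys$free])
  }

  for (seg in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[seg]; t1 <- breaks[seg + 1L]
    seg_times <- times_all[times_all >= t0 & times_all <= t1]
    if (seg_times[1] > t0) seg_times <- c(t0, seg_times)
    if (length(seg_times) < 2L) seg_times <- c(t0, t1)
    sol <- if (reduced) {
      deSolve::lsoda(y = x[sys$free], times = seg_times, func = deriv_red,
                     parms = list(constants = constants),
                     rtol = rtol, atol = atol)
    } else {
      deSolve::lsoda(y = unname(x), times = seg_times, func = deriv_full,
                     parms = NULL, rtol = rtol, atol = atol)
    }
    if (attr(sol, "istate")[1] < 0) {
      stop("ODE solver failed in segment starting at t = ", t0)
    }
    states <- sol[, -1, drop = FALSE]
    if (reduced) {
      states <- t(apply(states, 1L, function(y) {
        .reconstruct(sys, y, constants)
      }))
    }
    keep <- sol[, 1] %in% times_all & sol[, 1] < t1
    if (seg == length(breaks) - 1L) keep <- sol[, 1] %in% times_all
    out_times <- c(out_times, sol[keep, 1])
    out_states <- c(out_states, list(states[keep, , drop = FALSE]))
    x <- stats::setNames(states[nrow(states), ], full$species)

    if (seg < length(breaks) - 1L) {
      here <- ev[ev$time == t1, , drop = FALSE]
      for (r in seq_len(nrow(here))) {
        pre <- x[here$species[r]]
        x <- .apply_event(x, here[r, ])
        ev_log[[length(ev_log) + 1L]] <- data.frame(
          time = t1, action = here$action[r], species = here$species[r],
          pre = unname(pre), post = unname(x[here$species[r]]))
      }
      if (reduced) constants <- as.numeric(sys$A %*% x)
    }
  }
  amounts <- do.call(rbind, out_states)
  amounts[amounts < 0 & amounts > -atol * 10] <- 0
  traj <- new_trajectory(out_times, amounts, full$species,
                         event_times = unique(ev$time))
  traj$events <- if (length(ev_log) > 0L) do.call(rbind, ev_log) else NULL
  traj
}

#' Stochastic simulation (Gillespie direct method)
#'
#' Simulates the continuous-time Markov chain of the stochastic Petri net:
#' transition t in marking m has propensity
#' \code{k_t * prod_h falling_factorial(m_h, I-(t,h)) / I-(t,h)!}
#' (combinatorial convention). Intended as a stochastic oracle for the
#' deterministic dynamics: as token counts grow, ensemble means converge to
#' the mass-action ODE solution.
#'
#' @param net rate-bound \code{petri_net}.
#' @param params named rate constants.
#' @param m0 integer marking (defaults to the net's initial marking).
#' @param t_end end time.
#' @param seed integer seed (reproducible event sequence).
#' @param n_samples number of equally spaced sample times in [0, t_end].
#' @return a \code{pn_trajectory} sampled on the grid (state just before
#'   each sample time).
#' @export
ssa_simulate <- function(net, params, m0 = net$initial_marking, t_end,
                         seed, n_samples = 101L) {
  stopifnot(inherits(net, "petri_net"))
  m <- as_marking(net, m0)
  .stopifnot_integer_marking(m)
  sys <- derive_odes(net, c(params, m))
  k <- sys$k
  set.seed(seed)

  grid <- seq(0, t_end, length.out = n_samples)
  out <- matrix(0, n_samples, length(net$places),
                dimnames = list(NULL, net$places))
  gi <- 1L
  t <- 0
  nz_in <- lapply(seq_along(net$transitions),
                  function(j) which(net$input[j, ] > 0))
  prop <- function(m) {
    a <- k
    for (j in seq_along(a)) {
      for (i in nz_in[[j]]) {
        mm <- net$input[j, i]
        n <- m[i]
        if (n < mm) { a[j] <- 0; break }
        a[j] <- a[j] * prod((n - seq_len(mm) + 1)) / factorial(mm)
      }
    }
    a
  }

  repeat {
    a <- prop(m)
    a0 <- sum(a)
    t_next <- if (a0 > 0) t + stats::rexp(1L, a0) else Inf
    while (gi <= n_samples && grid[gi] <= t_next) {
      out[gi, ] <- m
      gi <- gi + 1L
    }
    if (gi > n_samples || t_next > t_end) break
    t <- t_next
    j <- sample.int(length(a), 1L, prob = a)
    m <- m + net$output[j, ] - net$input[j, ]
  }
  while (gi <= n_samples) { out[gi, ] <- m; gi <- gi + 1L }
  new_trajectory(grid, out, net$places)
}
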