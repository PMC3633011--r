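## Hierarchical tumour population model: cancer stem cells (CSC) divide
## symmetrically (probability Psy, yielding a net CSC gain) or
## asymmetrically (Pasy, seeding the first progenitor stage); progenitors
## mature through npc stages, doubling at each proliferation step, with the
## first three stages able to de-differentiate back to CSC at rate
## gamma_pc; the last stage terminally differentiates into TC at rate eta3.
## The system is linear and homogeneous in the cell counts, with
## proliferation rates omega_csc / omega_pc that may be constants or
## time functions supplied by the molecular layer.

#' Population model parameters
#'
#' @param Psy,Pasy probabilities of symmetric and asymmetric CSC division
#'   (\code{Psy + Pasy <= 1}; the remainder leaves room for symmetric
#'   differentiation).
#' @param omega_csc,omega_pc proliferation rates (1/time): non-negative
#'   constants or functions of time.
#' @param gamma_pc bidirectional CSC/progenitor inter-convertibility rate,
#'   acting on the first three progenitor stages.
#' @param eta1,eta2,eta3 differentiation rates: CSC to PC1, PCj to PCj+1,
#'   and PC_last to TC.
#' @param d1,d2,d3 death rates of CSC, PC and TC.
#' @param npc number of progenitor stages (7 in the full model; smaller
#'   chains are supported for testing).
#' @return object of class \code{"population_params"}.
#' @export
population_params <- function(Psy = 0.5, Pasy = 0.5,
                              omega_csc = 0.02, omega_pc = 0.04,
                              gamma_pc = 0.002,
                              eta1 = 0.005, eta2 = 0.01, eta3 = 0.01,
                              d1 = 0.005, d2 = 0.005, d3 = 0.002,
                              npc = 7L) {
  if (Psy < 0 || Pasy < 0 || Psy + Pasy > 1 + 1e-12) {
    stop("Psy and Pasy must be probabilities with Psy + Pasy <= 1")
  }
  scalars <- c(gamma_pc = gamma_pc, eta1 = eta1, eta2 = eta2, eta3 = eta3,
               d1 = d1, d2 = d2, d3 = d3)
  if (any(scalars < 0)) {
    stop("rate must be non-negative: ", names(scalars)[scalars < 0][1L])
  }
  for (om in list(omega_csc, omega_pc)) {
    if (!is.function(om) && (!is.numeric(om) || om < 0)) {
      stop("proliferation rates must be non-negative constants or functions")
    }
  }
  if (npc < 1L) stop("npc must be >= 1")
  structure(list(Psy = Psy, Pasy = Pasy, omega_csc = omega_csc,
                 omega_pc = omega_pc, gamma_pc = gamma_pc,
                 eta1 = eta1, eta2 = eta2, eta3 = eta3,
                 d1 = d1, d2 = d2, d3 = d3, npc = as.integer(npc)),
            class = "population_params")
}

.pop_species <- function(npc) c("CSC", paste0("PC", seq_len(npc)), "TC")

.omega_at <- function(om, t) if (is.function(om)) om(t) else om

#' Right-hand side of the population ODE system
#'
#' The derivative is linear and homogeneous in the state. The bidirectional
#' inter-convertibility term couples CSC with progenitor stages 1 to 3
#' only, and each progenitor proliferation event moves the mother cell into
#' the next stage as two daughters (the \code{2 omega_pc N_(j-1)} inflow).
#'
#' @param state non-negative numeric vector \code{(CSC, PC1..PCnpc, TC)}
#'   (names optional).
#' @param params a \code{\link{population_params}}.
#' @param t time at which time-varying proliferation rates are evaluated.
#' @return named derivative vector of the same dimension.
#' @export
population_rhs <- function(state, params, t = 0) {
  stopifnot(inherits(params, "population_params"))
  npc <- params$npc
  sp <- .pop_species(npc)
  if (length(state) != length(sp)) {
    stop("state must have ", length(sp), " compartments")
  }
  state <- stats::setNames(as.numeric(state), sp)
  if (any(state < 0)) stop("negative cell count in state")

  wc <- .omega_at(params$omega_csc, t)
  wp <- .omega_at(params$omega_pc, t)
  g <- params$gamma_pc
  n_gamma <- min(3L, npc)
  pc <- state[paste0("PC", seq_len(npc))]

  d <- numeric(length(sp)); names(d) <- sp
  d["CSC"] <- params$Psy * wc * state["CSC"] +
    g * sum(pc[seq_len(n_gamma)]) -
    params$eta1 * state["CSC"] - params$d1 * state["CSC"]
  d["PC1"] <- params$Pasy * wc * state["CSC"] - wp * pc[1L] -
    (if (n_gamma >= 1L) g * pc[1L] else 0) +
    params$eta1 * state["CSC"] - params$eta2 * pc[1L] - params$d2 * pc[1L]
  if (npc >= 2L) {
    for (j in 2:npc) {
      inflow <- 2 * wp * pc[j - 1L] + params$eta2 * pc[j - 1L]
      if (j < npc) {
        d[paste0("PC", j)] <- inflow - wp * pc[j] -
          (if (j <= n_gamma) g * pc[j] else 0) -
          params$eta2 * pc[j] - params$d2 * pc[j]
      } else {
        d[paste0("PC", j)] <- inflow - params$eta3 * pc[j] -
          params$d2 * pc[j]
      }
    }
  } else {
    ## single-stage chain: PC1 also terminally differentiates
    d["PC1"] <- d["PC1"] - params$eta3 * pc[1L]
  }
  d["TC"] <- params$eta3 * pc[npc] - params$d3 * state["TC"]
  d
}

#' System matrix of the population model at a fixed time
#'
#' Because the right-hand side is linear and homogeneous, the dynamics at
#' constant rates are \code{dN/dt = M N}; the dominant eigenvalue of M
#' gives the asymptotic exponential growth rate.
#'
#' @param params a \code{population_params}.
#' @param t evaluation time for time-varying rates.
#' @return square matrix with compartment dimnames.
#' @export
population_matrix <- function(params, t = 0) {
  sp <- .pop_species(params$npc)
  M <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  for (i in seq_along(sp)) {
    e <- stats::setNames(numeric(length(sp)), sp)
    e[i] <- 1
    M[, i] <- population_rhs(e, params, t)
  }
  M
}

#' Simulate the population model
#'
#' @param params a \code{\link{population_params}} (proliferation rates may
#'   be functions of time, e.g. built by \code{\link{make_rate_function}}).
#' @param init non-negative initial state; defaults to the spheroid-derived
#'   composition of 15 CSC per 1000 cells with the remainder terminal.
#' @param t_grid increasing sample times.
#' @param rtol,atol solver tolerances.
#' @return a \code{pn_trajectory} over \code{CSC, PC1..PCnpc, TC}.
#' @export
simulate_population <- function(params, init = NULL,
                                t_grid = seq(0, 6000, by = 10),
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "population_params"))
  sp <- .pop_species(params$npc)
  if (is.null(init)) {
    init <- stats::setNames(numeric(length(sp)), sp)
    init["CSC"] <- 15
    init["TC"] <- 985
  }
  init <- as_marking(sp, init)
  deriv <- function(t, y, parms) {
    list(unname(population_rhs(pmax(y, 0), params, t)))
  }
  sol <- deSolve::lsoda(y = unname(init), times = t_grid, func = deriv,
                        parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) stop("population solver failed")
  amounts <- sol[, -1, drop = FALSE]
  amounts[amounts < 0 & amounts > -atol * 10] <- 0
  new_trajectory(sol[, 1], amounts, sp)
}

#' Time at which a compartment starts exponential expansion
#'
#' Operationalized as the earliest trajectory time at which the compartment
#' exceeds \code{threshold_ratio} times its initial value.
#'
#' @param traj a population \code{pn_trajectory}.
#' @param threshold_ratio fold-increase defining onset (default 10).
#' @param species compartment name (default \code{"TC"}).
#' @return the onset time, or \code{NA_real_} if never reached.
#' @export
growth_onset <- function(traj, threshold_ratio = 10, species = "TC") {
  stopifnot(inherits(traj, "pn_trajectory"))
  if (!species %in% colnames(traj$amounts)) {
    stop("trajectory lacks compartment: ", species)
  }
  v <- traj$amounts[, species]
  hit <- which(v > threshold_ratio * v[1])
  if (length(hit) == 0L) return(NA_real_)
  traj$times[hit[1L]]
}
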