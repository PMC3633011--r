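## Coupling of the molecular and population levels. The molecular nets for
## the CSC and PC populations are integrated first (with their injection /
## vaccination schedules); the trajectories of three interaction-point
## species -- cyclin D, NF-kB and Akt-phosphorylated BAD -- are turned into
## dimensionless time functions whose product, times a per-population scale
## constant, gives the time-varying proliferation rates omega_csc(t) and
## omega_pc(t) of the population model.

#' The Pten conservation subnet (reactions R:41 to R:45)
#'
#' Five reactions describing the Pten-dependent dephosphorylation of Pip3
#' and regeneration of Pip2: three reversible bindings and two catalytic
#' steps, giving 6 places and 8 transitions. Rate constants are positive
#' placeholders on an arbitrary time scale.
#'
#' @return list with \code{net} (a rate-bound \code{petri_net}),
#'   \code{params} (named rate vector) and \code{reactions}.
#' @examples
#' pten <- build_pten_subnet()
#' p_semiflows(pten$net)
#' @export
build_pten_subnet <- function() {
  txt <- c(
    "R:41 Pip3 + Pten <-> Pip3:Pten ; kf=k67 ; kb=k68",
    "R:42 Pip3:Pten -> Pip2 + Pten ; kf=k69",
    "R:43 Pten + Pip2 <-> Pten:Pip2 ; kf=k70 ; kb=k71",
    "R:44 Pten:Pip2 + Pip3 <-> Pten:Pip2:Pip3 ; kf=k72 ; kb=k73",
    "R:45 Pten:Pip2:Pip3 -> Pten:Pip2 + Pip2 ; kf=k74"
  )
  parsed <- parse_reactions(txt)
  params <- c(k67 = 0.02, k68 = 0.01, k69 = 0.05, k70 = 0.02,
              k71 = 0.01, k72 = 0.02, k73 = 0.01, k74 = 0.05)
  list(net = parsed$net, params = params, reactions = parsed$reactions)
}

#' Build the simplified ErbB2/TLR2 proliferation network
#'
#' A documented reduction (about 35 species) of the full 111-place
#' signalling model, organized in the same five portions: (A) ErbB-family
#' ligand binding and dimerization, with ErbB2 optionally dimerizing
#' constitutively (the transforming-oncogene configuration); (B) PI3K
#' recruitment by active dimers, Pip3 production, the exact Pten subnet of
#' \code{\link{build_pten_subnet}}, and Akt activation; (C) the Akt targets
#' BAD (inhibitory phosphorylation), cyclin D (stabilization via GSK-3beta
#' inhibition) and NF-kB (activation via IKKalpha); (D) the
#' TSC2/Rheb/mTOR loop; (E) the TLR2-MyD88-IRAK-TRAF6 cascade converging
#' on NF-kB. Kinetic constants are repository-defined on the model's
#' arbitrary time scale.
#'
#' @param portions subset of \code{c("A","B","C","D","E")} to include;
#'   portion C (the interaction-point targets) is mandatory.
#' @param erbb2_constitutive include the ligand-independent ErbB2 homodimer
#'   (default TRUE, matching the transgenic oncogene).
#' @param turnover include free-ligand degradation (default TRUE; required
#'   for injection responses to be transient peaks). Disabling it makes
#'   every place semiflow-covered.
#' @param tlr2_amount initial amount of surface TLR2 (100 for the CSC net,
#'   1 for the PC net under the default configuration).
#' @return list with \code{net}, \code{params} (rates and initial
#'   amounts), \code{reactions} and \code{targets} (the three
#'   interaction-point species names).
#' @export
build_demo_erbb2_net <- function(portions = c("A", "B", "C", "D", "E"),
                                 erbb2_constitutive = TRUE,
                                 turnover = TRUE,
                                 tlr2_amount = 100) {
  portions <- match.arg(portions, c("A", "B", "C", "D", "E"),
                        several.ok = TRUE)
  if (!"C" %in% portions) {
    stop("portion C holds the interaction-point targets and cannot be excluded")
  }
  if (!"B" %in% portions) {
    stop("portion B (PI3K/Akt activation) is required by portion C")
  }
  rx <- character(0)
  dimers <- character(0)

  if ("A" %in% portions) {
    rx <- c(rx,
      "A:1 EGF + ErbB1 <-> EGF:ErbB1 ; kf=a1 ; kb=a2",
      "A:2 EGF:ErbB1 + ErbB2 <-> EGF:ErbB1:ErbB2 ; kf=a3 ; kb=a4",
      "A:3 HRG + ErbB3 <-> HRG:ErbB3 ; kf=a5 ; kb=a6",
      "A:4 HRG:ErbB3 + ErbB2 <-> HRG:ErbB3:ErbB2 ; kf=a7 ; kb=a8")
    dimers <- c(dimers, "EGF:ErbB1:ErbB2", "HRG:ErbB3:ErbB2")
    if (erbb2_constitutive) {
      rx <- c(rx, "A:5 ErbB2 + ErbB2 <-> ErbB2:ErbB2 ; kf=a9 ; kb=a10")
      dimers <- c(dimers, "ErbB2:ErbB2")
    }
    if (turnover) {
      ## free-ligand decay plus receptor-mediated internalization of the
      ## bound ligand: without the latter, injected ligand is trapped in
      ## stable complexes and injection responses never relax
      rx <- c(rx,
        "A:6 EGF -> 0 ; kf=a11", "A:7 HRG -> 0 ; kf=a12",
        "A:8 EGF:ErbB1 -> ErbB1 ; kf=a13",
        "A:9 HRG:ErbB3 -> ErbB3 ; kf=a14",
        "A:12 EGF:ErbB1:ErbB2 -> ErbB1 + ErbB2 ; kf=a13",
        "A:13 HRG:ErbB3:ErbB2 -> ErbB3 + ErbB2 ; kf=a14",
        ## constitutive (transgene-driven) receptor expression: surface
        ## ErbB2 recovers after vaccination on a ~1000 time-unit scale
        "A:10 0 -> ErbB2 ; kf=a15",
        "A:11 ErbB2 -> 0 ; kf=a16")
    }
  }

  ## portion B: PI3K recruitment by each dimer, Pip3 production, the exact
  ## Pten subnet, Akt activation
  bi <- 0L
  for (d in dimers) {
    bi <- bi + 1L
    rx <- c(rx,
      sprintf("B:%d %s + PI3K <-> %s:PI3K ; kf=b1 ; kb=b2", bi, d, d))
    bi <- bi + 1L
    rx <- c(rx,
      sprintf("B:%d %s:PI3K + Pip2 -> %s:PI3K + Pip3 ; kf=b3", bi, d, d))
  }
  rx <- c(rx,
    "R:41 Pip3 + Pten <-> Pip3:Pten ; kf=k67 ; kb=k68",
    "R:42 Pip3:Pten -> Pip2 + Pten ; kf=k69",
    "R:43 Pten + Pip2 <-> Pten:Pip2 ; kf=k70 ; kb=k71",
    "R:44 Pten:Pip2 + Pip3 <-> Pten:Pip2:Pip3 ; kf=k72 ; kb=k73",
    "R:45 Pten:Pip2:Pip3 -> Pten:Pip2 + Pip2 ; kf=k74",
    "B:90 Pip3 + Akt <-> Pip3:Akt ; kf=b4 ; kb=b5",
    "B:91 Pip3:Akt -> Pip3 + pAkt ; kf=b6",
    "B:92 pAkt -> Akt ; kf=b7")

  ## portion C: the three proliferation targets
  rx <- c(rx,
    "C:1 pAkt + BAD -> pAkt + pBAD ; kf=c1",
    "C:2 pBAD -> BAD ; kf=c2",
    "C:3 pAkt + GSK3b -> pAkt + pGSK3b ; kf=c3",
    "C:4 pGSK3b -> GSK3b ; kf=c4",
    "C:5 pGSK3b + cyclinD_off -> pGSK3b + cyclinD ; kf=c5",
    "C:6 cyclinD -> cyclinD_off ; kf=c6",
    "C:7 pAkt + IKKa -> pAkt + pIKKa ; kf=c7",
    "C:8 pIKKa -> IKKa ; kf=c8",
    "C:9 pIKKa + NFkB:IkB -> pIKKa + NFkB ; kf=c9",
    "C:10 NFkB -> NFkB:IkB ; kf=c10")

  if ("D" %in% portions) {
    rx <- c(rx,
      "D:1 pAkt + TSC2 -> pAkt + pTSC2 ; kf=d1",
      "D:2 pTSC2 -> TSC2 ; kf=d2",
      "D:3 TSC2 + RhebGTP -> TSC2 + RhebGDP ; kf=d3",
      "D:4 RhebGDP -> RhebGTP ; kf=d4",
      "D:5 RhebGTP + mTOR <-> RhebGTP:mTOR ; kf=d5 ; kb=d6")
  }

  if ("E" %in% portions) {
    rx <- c(rx,
      "E:1 TL2L + TLR2 <-> TL2L:TLR2 ; kf=e1 ; kb=e2",
      "E:2 TL2L:TLR2 + MyD88 <-> TL2L:TLR2:MyD88 ; kf=e3 ; kb=e4",
      "E:3 TL2L:TLR2:MyD88 + IRAK -> TL2L:TLR2:MyD88 + pIRAK ; kf=e5",
      "E:4 pIRAK -> IRAK ; kf=e6",
      "E:5 pIRAK + TRAF6 -> pIRAK + aTRAF6 ; kf=e7",
      "E:6 aTRAF6 -> TRAF6 ; kf=e8",
      "E:7 aTRAF6 + NFkB:IkB -> aTRAF6 + NFkB ; kf=e9")
    if (turnover) {
      rx <- c(rx, "E:8 TL2L -> 0 ; kf=e10",
              "E:9 TL2L:TLR2 -> TLR2 ; kf=e11",
              "E:10 0 -> TLR2 ; kf=e12",
              "E:11 TLR2 -> 0 ; kf=e13")
    }
  }

  parsed <- parse_reactions(rx)

  rates <- c(
    a1 = 2e-3, a2 = 1e-2, a3 = 1e-2, a4 = 1e-2, a5 = 2e-3, a6 = 1e-2,
    a7 = 1e-2, a8 = 1e-2, a9 = 5e-6, a10 = 1e-2, a11 = 5e-3, a12 = 5e-3,
    a13 = 5e-3, a14 = 5e-3, a15 = 0.2, a16 = 1e-3,
    b1 = 2e-4, b2 = 1e-2, b3 = 1e-4, b4 = 2e-4, b5 = 1e-2, b6 = 5e-2,
    b7 = 2e-2,
    k67 = 2e-4, k68 = 1e-2, k69 = 5e-2, k70 = 2e-5, k71 = 1e-2,
    k72 = 2e-5, k73 = 1e-2, k74 = 5e-2,
    c1 = 2e-4, c2 = 3e-2, c3 = 2e-4, c4 = 1e-2, c5 = 2e-4, c6 = 3e-2,
    c7 = 2e-4, c8 = 1e-2, c9 = 2e-4, c10 = 3e-2,
    d1 = 2e-4, d2 = 1e-2, d3 = 2e-4, d4 = 1e-2, d5 = 2e-4, d6 = 1e-2,
    e1 = 2e-3, e2 = 1e-2, e3 = 2e-4, e4 = 1e-2, e5 = 5e-5, e6 = 1e-2,
    e7 = 5e-5, e8 = 1e-2, e9 = 2e-4, e10 = 5e-3, e11 = 5e-3,
    e12 = tlr2_amount * 1e-3, e13 = 1e-3
  )
  amounts <- c(
    "EGF" = 0, "ErbB1" = 100, "ErbB2" = 200, "HRG" = 0, "ErbB3" = 100,
    "PI3K" = 100, "Pip2" = 500, "Pip3" = 0, "Pten" = 100,
    "Akt" = 100, "pAkt" = 0,
    "BAD" = 90, "pBAD" = 10, "GSK3b" = 90, "pGSK3b" = 10,
    "cyclinD_off" = 90, "cyclinD" = 10,
    "IKKa" = 90, "pIKKa" = 10, "NFkB:IkB" = 90, "NFkB" = 10,
    "TSC2" = 100, "RhebGTP" = 50, "RhebGDP" = 50, "mTOR" = 100,
    "TL2L" = 0, "TLR2" = tlr2_amount, "MyD88" = 100, "IRAK" = 100,
    "TRAF6" = 100
  )
  amounts <- amounts[names(amounts) %in% parsed$net$places]
  net <- parsed$net
  net$initial_marking <- as_marking(net, amounts)
  used <- unique(net$rates)
  params <- c(rates[names(rates) %in% used], amounts)
  list(net = net, params = params, reactions = parsed$reactions,
       targets = c(cyclinD = "cyclinD", nfkb = "NFkB", bad = "pBAD"))
}

#' Load a full reaction network from converted supplement files
#'
#' Reads a reaction-list document and a parameter/initial-amount table
#' (both in the package's canonical formats) and reports the structural
#' counts of the resulting net.
#'
#' @param reactions_file path to a reaction-list document.
#' @param params_file path to a name/value TSV of rate constants and
#'   initial amounts.
#' @return list with \code{net}, \code{params}, \code{n_places},
#'   \code{n_transitions}, \code{n_reactions} and \code{n_parameters}
#'   (distinct names in the parameter table).
#' @export
load_full_network <- function(reactions_file, params_file) {
  parsed <- tryCatch(parse_reactions(reactions_file), error = function(e) {
    stop("failed to parse ", reactions_file, ": ", conditionMessage(e),
         call. = FALSE)
  })
  params <- tryCatch(read_parameter_table(params_file), error = function(e) {
    stop("failed to read ", params_file, ": ", conditionMessage(e),
         call. = FALSE)
  })
  net <- parsed$net
  marked <- intersect(net$places, names(params))
  net$initial_marking <- as_marking(net, params[marked])
  list(net = net, params = params,
       n_places = length(net$places),
       n_transitions = length(net$transitions),
       n_reactions = nrow(parsed$reactions),
       n_parameters = length(params))
}

#' Coupling specification for one population's molecular net
#'
#' @param targets named character vector of length 3 giving the
#'   interaction-point species for cyclin D, NF-kB and BAD in the
#'   molecular net.
#' @param transforms per-target transform, each one of
#'   \code{"normalize_to_baseline"} (value divided by its value at the
#'   first trajectory time), \code{"reciprocal_normalized"}
#'   (baseline divided by value; for a target whose abundance opposes
#'   proliferation) or \code{"identity"}.
#' @param scale positive rate constant (1/time) mapping the dimensionless
#'   product of the three transformed trajectories to a proliferation rate.
#' @return object of class \code{"coupling_spec"}.
#' @export
coupling_spec <- function(targets = c(cyclinD = "cyclinD", nfkb = "NFkB",
                                      bad = "pBAD"),
                          transforms = rep("normalize_to_baseline", 3),
                          scale = 0.02) {
  if (length(targets) != 3L) stop("exactly three target species required")
  transforms <- match.arg(transforms,
                          c("normalize_to_baseline", "reciprocal_normalized",
                            "identity"), several.ok = TRUE)
  if (length(transforms) == 1L) transforms <- rep(transforms, 3)
  if (length(transforms) != 3L) stop("need one transform per target")
  if (!is.numeric(scale) || scale <= 0) stop("scale must be positive")
  structure(list(targets = targets, transforms = transforms, scale = scale),
            class = "coupling_spec")
}

#' Build a proliferation-rate time function from a molecular trajectory
#'
#' \code{omega(t) = scale * f1(t) * f2(t) * f3(t)} where each factor is the
#' transformed, linearly interpolated trajectory of one interaction-point
#' species; evaluation outside the trajectory window clamps to the
#' endpoints. Negative products (impossible for non-negative trajectories)
#' are clipped at zero.
#'
#' @param traj a \code{pn_trajectory} covering the three targets.
#' @param spec a \code{\link{coupling_spec}}.
#' @return a vectorized function of time.
#' @export
make_rate_function <- function(traj, spec) {
  stopifnot(inherits(traj, "pn_trajectory"), inherits(spec, "coupling_spec"))
  fs <- vector("list", 3L)
  for (i in 1:3) {
    target <- spec$targets[i]
    if (!target %in% colnames(traj$amounts)) {
      stop("trajectory lacks coupling target: ", target)
    }
    v <- traj$amounts[, target]
    base <- v[1]
    tr <- spec$transforms[i]
    if (tr != "identity" && base <= 0) {
      stop("zero baseline for target ", target,
           " is incompatible with transform ", tr)
    }
    y <- switch(tr,
                normalize_to_baseline = v / base,
                reciprocal_normalized = base / pmax(v, .Machine$double.eps),
                identity = v)
    fs[[i]] <- stats::approxfun(traj$times, y, rule = 2)
  }
  function(t) {
    pmax(spec$scale * fs[[1]](t) * fs[[2]](t) * fs[[3]](t), 0)
  }
}

#' Assemble a coupled two-level model
#'
#' @param csc,pc lists with components \code{net} and \code{params} (as
#'   returned by \code{\link{build_demo_erbb2_net}}); under the default
#'   configuration the CSC net carries 100x the PC net's surface TLR2.
#' @param coupling list with \code{csc} and \code{pc}
#'   \code{\link{coupling_spec}}s.
#' @param population_params a \code{\link{population_params}} whose
#'   proliferation rates will be overridden by the molecular coupling.
#' @param schedules list with \code{csc} and \code{pc}
#'   \code{\link{event_schedule}}s.
#' @param init optional population initial state.
#' @return object of class \code{"coupled_model"}.
#' @export
coupled_model <- function(csc, pc, coupling, population_params,
                          schedules = list(csc = event_schedule(),
                                           pc = event_schedule()),
                          init = NULL) {
  stopifnot(inherits(csc$net, "petri_net"), inherits(pc$net, "petri_net"),
            inherits(coupling$csc, "coupling_spec"),
            inherits(coupling$pc, "coupling_spec"),
            inherits(population_params, "population_params"))
  structure(list(csc = csc, pc = pc, coupling = coupling,
                 population_params = population_params,
                 schedules = schedules, init = init),
            class = "coupled_model")
}

#' Run a coupled molecular/population experiment
#'
#' Integrates the CSC and PC molecular nets with their event schedules,
#' builds the time-varying proliferation rates from the interaction-point
#' trajectories, then integrates the population system on the same
#' (shared, arbitrary-unit) time axis.
#'
#' @param model a \code{\link{coupled_model}}.
#' @param t_grid shared sample times.
#' @param rtol,atol solver tolerances for both levels.
#' @return list with \code{csc}, \code{pc} (molecular trajectories),
#'   \code{population} (population trajectory) and \code{omega_csc},
#'   \code{omega_pc} (the rate functions).
#' @export
run_coupled <- function(model, t_grid = seq(0, 6000, by = 10),
                        rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(model, "coupled_model"))
  run_net <- function(part, sched, label) {
    sys <- derive_odes(part$net, part$params)
    tryCatch(
      integrate_odes(sys, t_grid, events = sched, rtol = rtol, atol = atol),
      error = function(e) stop(label, " molecular stage failed: ",
                               conditionMessage(e), call. = FALSE))
  }
  traj_csc <- run_net(model$csc, model$schedules$csc, "CSC")
  traj_pc <- run_net(model$pc, model$schedules$pc, "PC")
  omega_csc <- make_rate_function(traj_csc, model$coupling$csc)
  omega_pc <- make_rate_function(traj_pc, model$coupling$pc)

  pp <- model$population_params
  pp$omega_csc <- omega_csc
  pp$omega_pc <- omega_pc
  pop <- tryCatch(
    simulate_population(pp, init = model$init, t_grid = t_grid,
                        rtol = rtol, atol = atol),
    error = function(e) stop("population stage failed: ",
                             conditionMessage(e), call. = FALSE))
  list(csc = traj_csc, pc = traj_pc, population = pop,
       omega_csc = omega_csc, omega_pc = omega_pc)
}

#' Injection / vaccination schedule presets for the demo experiments
#'
#' \describe{
#'   \item{fig4}{three growth-factor injections at t = 1500, 2500, 3500.}
#'   \item{fig5}{fig4 plus five ErbB2 vaccinations from t = 1000 every
#'     1000 time units.}
#'   \item{fig7a}{fig4 plus a single ErbB2 vaccination at t = 1500.}
#'   \item{fig7b}{fig4 plus combined ErbB2 and TLR2 vaccination, both at
#'     t = 1500.}
#' }
#' Injections add \code{ligand_amount} of EGF and HRG (plus the TLR2
#' ligand on the CSC net, which carries the high TLR2 load); a vaccination
#' multiplies the free receptor and its homodimer by \code{retention}.
#'
#' @param preset one of \code{"fig4"}, \code{"fig5"}, \code{"fig7a"},
#'   \code{"fig7b"}.
#' @param population \code{"csc"} or \code{"pc"} (the TLR2 ligand is only
#'   injected into the CSC net).
#' @param net the molecular net the schedule targets (used to enumerate the
#'   receptor-containing membrane species); defaults to the demo net.
#' @param ligand_amount amount added per injection.
#' @param retention retention factor of a vaccination (default 0.1).
#' @return an \code{\link{event_schedule}}.
#' @export
preset_schedule <- function(preset = c("fig4", "fig5", "fig7a", "fig7b"),
                            population = c("csc", "pc"),
                            net = NULL,
                            ligand_amount = 100, retention = 0.1) {
  preset <- match.arg(preset)
  population <- match.arg(population)
  if (is.null(net)) net <- build_demo_erbb2_net()$net
  inj_times <- c(1500, 2500, 3500)
  ligands <- intersect(c("EGF", "HRG",
                         if (population == "csc") "TL2L"), net$places)
  ev <- list()
  for (tt in inj_times) for (lg in ligands) {
    ev[[length(ev) + 1L]] <- data.frame(time = tt, action = "add",
                                        species = lg, amount = ligand_amount)
  }
  vacc <- function(times, receptors) {
    for (tt in times) for (sp in receptors) {
      ev[[length(ev) + 1L]] <<- data.frame(time = tt, action = "scale",
                                           species = sp, amount = retention)
    }
  }
  erbb2 <- receptor_species(net, "ErbB2")
  tlr2 <- receptor_species(net, "TLR2")
  if (preset == "fig5") vacc(seq(1000, 5000, by = 1000), erbb2)
  if (preset == "fig7a") vacc(1500, erbb2)
  if (preset == "fig7b") vacc(1500, c(erbb2, tlr2))
  df <- do.call(rbind, ev)
  event_schedule(df$time, df$action, df$species, df$amount)
}

#' Membrane species carrying a given receptor
#'
#' A vaccination antibody binds its receptor in every surface complex, so a
#' vaccination event scales all places whose (colon-separated) complex name
#' contains the receptor: the free receptor, its homodimer, ligand-bound
#' forms and preformed signalling complexes.
#'
#' @param net a \code{petri_net}.
#' @param receptor receptor name (e.g. \code{"ErbB2"}).
#' @return character vector of place names.
#' @export
receptor_species <- function(net, receptor) {
  grep(paste0("(^|:)", receptor, "(:|$)"), net$places, value = TRUE)
}

#' Relax a molecular net to its unstimulated steady state
#'
#' Integrates the net without events and replaces the initial amounts by
#' the final state. Coupling transforms normalize to the value at the
#' first trajectory time, so the molecular baseline must be a resting
#' state: without this step the autonomous relaxation of the net would be
#' mistaken for a proliferation signal.
#'
#' @param part list with \code{net} and \code{params}.
#' @param t_relax relaxation horizon (arbitrary time units).
#' @return the same list with updated initial amounts.
#' @export
equilibrate_net <- function(part, t_relax = 5000) {
  sys <- derive_odes(part$net, part$params)
  tr <- integrate_odes(sys, c(0, t_relax / 2, t_relax),
                       rtol = 1e-8, atol = 1e-10)
  x_eq <- pmax(tr$amounts[nrow(tr$amounts), ], 0)
  part$net$initial_marking <- as_marking(part$net, x_eq)
  hit <- intersect(names(part$params), part$net$places)
  part$params[hit] <- x_eq[hit]
  part
}

#' Build the default coupled demo model
#'
#' CSC and PC nets share the demo topology; the CSC net carries 100x the
#' PC net's surface TLR2 amount. The coupling scale constants are chosen
#' so that the unvaccinated model reproduces the baseline growth of the
#' constant-rate population model at t = 0.
#'
#' @param preset experiment preset passed to \code{\link{preset_schedule}};
#'   \code{NULL} gives empty schedules.
#' @param scale_csc,scale_pc coupling scale constants (1/time).
#' @param tlr2_csc,tlr2_pc initial surface TLR2 amounts.
#' @param equilibrate relax both nets to their unstimulated steady state
#'   before coupling (see \code{\link{equilibrate_net}}; default TRUE).
#' @param ... further arguments to \code{\link{build_demo_erbb2_net}}.
#' @return a \code{\link{coupled_model}}.
#' @export
build_demo_coupled_model <- function(preset = NULL,
                                     scale_csc = 0.02, scale_pc = 0.04,
                                     tlr2_csc = 100, tlr2_pc = 1,
                                     equilibrate = TRUE, ...) {
  csc <- build_demo_erbb2_net(tlr2_amount = tlr2_csc, ...)
  pc <- build_demo_erbb2_net(tlr2_amount = tlr2_pc, ...)
  if (equilibrate) {
    csc <- equilibrate_net(csc)
    pc <- equilibrate_net(pc)
  }
  sched <- if (is.null(preset)) {
    list(csc = event_schedule(), pc = event_schedule())
  } else {
    list(csc = preset_schedule(preset, "csc", net = csc$net),
         pc = preset_schedule(preset, "pc", net = pc$net))
  }
  coupled_model(
    csc = csc, pc = pc,
    coupling = list(csc = coupling_spec(csc$targets, scale = scale_csc),
                    pc = coupling_spec(pc$targets, scale = scale_pc)),
    population_params = population_params(),
    schedules = sched
  )
}
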