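#' Construct a Petri net
#'
#' A Petri net is a bipartite structure \code{N = (P, T, I-, I+, m0)}: a set
#' of places (biochemical species), a set of transitions (reactions), input
#' and output arc multiplicity matrices, and an initial marking. Multiplicity
#' matrices are stored dense with one row per transition and one column per
#' place, in the declared order; this keeps the incidence algebra and all
#' downstream analyses deterministic.
#'
#' @param places character vector of unique place (species) names. Names may
#'   contain \code{":"} (protein complexes such as \code{"Pip3:Pten"}) but not
#'   whitespace, \code{"+"}, \code{";"} or arrow tokens.
#' @param transitions character vector of unique transition (reaction) names,
#'   disjoint from \code{places}.
#' @param input,output non-negative integer matrices of dimension
#'   \code{length(transitions) x length(places)} giving the arc
#'   multiplicities I-(t,p) and I+(t,p). Dimnames, if present, must match.
#' @param initial_marking optional named non-negative numeric vector; missing
#'   places default to 0.
#' @param rates optional named character vector mapping transition name to a
#'   rate-constant name (required before ODE derivation or SSA).
#' @return an object of class \code{"petri_net"}.
#' @examples
#' net <- petri_net(
#'   places = c("A", "B"), transitions = c("conv"),
#'   input = matrix(c(1, 0), 1, 2), output = matrix(c(0, 1), 1, 2),
#'   initial_marking = c(A = 2), rates = c(conv = "k1")
#' )
#' incidence_matrix(net)
#' @export
petri_net <- function(places, transitions, input, output,
                      initial_marking = NULL, rates = NULL) {
  if (length(places) == 0L) stop("a Petri net needs at least one place")
  if (length(transitions) == 0L) stop("a Petri net needs at least one transition")
  places <- as.character(places)
  transitions <- as.character(transitions)
  if (anyDuplicated(places)) {
    stop("duplicate place name: ", places[duplicated(places)][1L])
  }
  if (anyDuplicated(transitions)) {
    stop("duplicate transition name: ", transitions[duplicated(transitions)][1L])
  }
  if (length(intersect(places, transitions)) > 0L) {
    stop("place and transition names must be disjoint: ",
         intersect(places, transitions)[1L])
  }
  bad <- grepl("[[:space:]+;]|->|<->", places)
  if (any(bad)) stop("invalid place name: ", places[bad][1L])

  input <- .check_arc_matrix(input, transitions, places, "input")
  output <- .check_arc_matrix(output, transitions, places, "output")
  dimnames(input) <- dimnames(output) <- list(transitions, places)
  untouched <- rowSums(input) + rowSums(output) == 0
  if (any(untouched)) {
    stop("transition without any arc: ", transitions[untouched][1L])
  }

  m0 <- stats::setNames(numeric(length(places)), places)
  if (!is.null(initial_marking)) {
    m0 <- as_marking(places, initial_marking)
  }
  if (!is.null(rates)) {
    rates <- .check_rate_binding(rates, transitions)
  }
  structure(
    list(places = places, transitions = transitions,
         input = input, output = output,
         initial_marking = m0, rates = rates),
    class = "petri_net"
  )
}

.check_arc_matrix <- function(m, transitions, places, what) {
  if (!is.matrix(m) || nrow(m) != length(transitions) ||
      ncol(m) != length(places)) {
    stop(what, " arc matrix must be ", length(transitions), " x ",
         length(places))
  }
  if (!is.null(rownames(m)) && !identical(rownames(m), transitions)) {
    stop(what, " arc matrix rownames do not match the transition order")
  }
  if (!is.null(colnames(m)) && !identical(colnames(m), places)) {
    stop(what, " arc matrix colnames do not match the place order")
  }
  storage.mode(m) <- "double"
  if (anyNA(m) || any(m < 0) || any(m != round(m))) {
    idx <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)[1L, ]
    stop("malformed ", what, " arc (", transitions[idx[1L]], ", ",
         places[idx[2L]], "): multiplicities must be non-negative integers")
  }
  m
}

.check_rate_binding <- function(rates, transitions) {
  rates <- unlist(rates)
  if (is.null(names(rates)) || !all(names(rates) %in% transitions)) {
    stop("rate binding names an unknown transition")
  }
  stats::setNames(as.character(rates)[match(transitions, names(rates))],
                  transitions)
}

#' Coerce a (possibly sparse) amount vector to a dense marking
#'
#' @param places place order of the owning net, or a \code{petri_net}.
#' @param x named numeric vector; unnamed is accepted only when its length
#'   equals the number of places.
#' @return named numeric vector over all places in net order.
#' @export
as_marking <- function(places, x) {
  if (inherits(places, "petri_net")) places <- places$places
  if (is.null(names(x))) {
    if (length(x) != length(places)) {
      stop("unnamed marking must cover all ", length(places), " places")
    }
    names(x) <- places
  }
  unknown <- setdiff(names(x), places)
  if (length(unknown) > 0L) stop("marking names unknown place: ", unknown[1L])
  m <- stats::setNames(numeric(length(places)), places)
  m[names(x)] <- as.numeric(x)
  if (anyNA(m) || any(m < 0)) stop("marking amounts must be non-negative")
  m
}

.stopifnot_integer_marking <- function(m) {
  if (any(m != round(m))) {
    stop("marking must be integer-valued for firing semantics; place ",
         names(m)[which(m != round(m))[1L]], " is not")
  }
}

#' Incidence matrix of a Petri net
#'
#' The incidence matrix C has one row per transition and one column per
#' place, with entry \code{c[t, p] = I+(t, p) - I-(t, p)}: the net token
#' change in place p caused by one firing of transition t.
#'
#' @param net a \code{petri_net}.
#' @return integer matrix with transition rownames and place colnames.
#' @export
incidence_matrix <- function(net) {
  stopifnot(inherits(net, "petri_net"))
  net$output - net$input
}

#' Transitions enabled in a marking
#'
#' A transition is enabled iff every input place holds at least as many
#' tokens as the input-arc multiplicity requires.
#'
#' @param net a \code{petri_net}.
#' @param m an integer marking (sparse named vectors accepted).
#' @return character vector of enabled transition names, in net order.
#' @export
enabled_transitions <- function(net, m) {
  stopifnot(inherits(net, "petri_net"))
  m <- as_marking(net, m)
  .stopifnot_integer_marking(m)
  ok <- apply(net$input, 1L, function(need) all(need <= m))
  net$transitions[ok]
}

#' Fire a transition
#'
#' Firing removes \code{I-(t, p)} tokens from each input place and adds
#' \code{I+(t, p)} tokens to each output place.
#'
#' @param net a \code{petri_net}.
#' @param m an integer marking in which \code{t} is enabled.
#' @param t a transition name.
#' @return the successor marking (dense named vector).
#' @export
fire <- function(net, m, t) {
  stopifnot(inherits(net, "petri_net"))
  m <- as_marking(net, m)
  .stopifnot_integer_marking(m)
  if (!t %in% net$transitions) stop("unknown transition: ", t)
  need <- net$input[t, ]
  short <- need > m
  if (any(short)) {
    stop("transition ", t, " is not enabled: place ",
         names(m)[short][1L], " holds ", m[short][1L],
         " token(s) but ", need[short][1L], " required")
  }
  m + net$output[t, ] - need
}

#' @export
print.petri_net <- function(x, ...) {
  cat("Petri net: ", length(x$places), " places, ",
      length(x$transitions), " transitions\n", sep = "")
  cat("  places: ", paste(utils::head(x$places, 8L), collapse = ", "),
      if (length(x$places) > 8L) ", ..." else "", "\n", sep = "")
  n_tok <- sum(x$initial_marking)
  cat("  initial marking: ", sum(x$initial_marking > 0),
      " marked place(s), total amount ", format(n_tok), "\n", sep = "")
  if (!is.null(x$rates)) cat("  rate-bound: yes\n")
  invisible(x)
}
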