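#' Build the reachability graph of a bounded net
#'
#' Breadth-first exploration of all integer markings reachable from
#' \code{m0} by transition firing. States are numbered in discovery order
#' (state 1 is the initial marking) and successors of a state are explored
#' in the net's declared transition order, so the graph is deterministic.
#'
#' @param net a \code{petri_net}.
#' @param m0 integer marking (defaults to the net's initial marking).
#' @param max_states exploration cap; exceeding it raises an error (for an
#'   unbounded net, check \code{\link{is_covered}} first).
#' @return object of class \code{"reachability_graph"}: \code{states}
#'   (matrix, one row per marking, place columns), \code{edges} (data frame
#'   \code{from}, \code{transition}, \code{to} with 1-based state indices)
#'   and \code{deadlocks} (indices of states without outgoing edges).
#' @export
reachability_graph <- function(net, m0 = net$initial_marking,
                               max_states = 10000L) {
  stopifnot(inherits(net, "petri_net"), max_states >= 1L)
  m0 <- as_marking(net, m0)
  .stopifnot_integer_marking(m0)

  key <- function(m) paste(m, collapse = ",")
  index <- new.env(parent = emptyenv(), hash = TRUE)
  states <- list(m0)
  assign(key(m0), 1L, envir = index)
  edges_from <- integer(0); edges_t <- character(0); edges_to <- integer(0)

  queue <- 1L
  while (length(queue) > 0L) {
    s <- queue[1L]; queue <- queue[-1L]
    m <- states[[s]]
    for (t in net$transitions) {
      if (all(net$input[t, ] <= m)) {
        m2 <- m + net$output[t, ] - net$input[t, ]
        k <- key(m2)
        i <- index[[k]]
        if (is.null(i)) {
          if (length(states) + 1L > max_states) {
            stop("reachability graph exceeds ", max_states,
                 " states; the net may be unbounded (see is_covered)")
          }
          states[[length(states) + 1L]] <- m2
          i <- length(states)
          assign(k, i, envir = index)
          queue <- c(queue, i)
        }
        edges_from <- c(edges_from, s)
        edges_t <- c(edges_t, t)
        edges_to <- c(edges_to, i)
      }
    }
  }
  smat <- do.call(rbind, states)
  colnames(smat) <- net$places
  deadlocks <- setdiff(seq_len(nrow(smat)), unique(edges_from))
  structure(list(states = smat,
                 edges = data.frame(from = edges_from, transition = edges_t,
                                    to = edges_to, stringsAsFactors = FALSE),
                 deadlocks = deadlocks),
            class = "reachability_graph")
}

#' @export
print.reachability_graph <- function(x, ...) {
  cat("Reachability graph: ", nrow(x$states), " states, ",
      nrow(x$edges), " edges, ", length(x$deadlocks), " deadlock(s)\n",
      sep = "")
  invisible(x)
}
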