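## Generators for test networks: random mass-action nets with planted
## conservation laws (every reaction is built or rejected so that its net
## stoichiometry is orthogonal to each planted place vector) and tiny
## bounded nets with known reachability graphs for model-checking oracles.

#' Random mass-action net with planted conservation laws
#'
#' Planted laws must have pairwise disjoint supports. For each law a chain
#' of conversion reactions is laid along its support with stoichiometries
#' balancing the law's weights; this connects the support, making the
#' planted vector the unique minimal P-semiflow on it. Species outside all
#' supports are linked by plain conversions. The remaining reaction budget
#' is filled with randomly sampled reactions accepted only when orthogonal
#' to every planted law. Rates are log-uniform in [1e-2, 1e2] and initial
#' token counts uniform in 1..5; everything is reproducible from the seed.
#'
#' @param n_species number of places.
#' @param n_reactions total number of reactions (must cover the mandatory
#'   chain reactions).
#' @param planted_laws list of non-negative integer vectors of length
#'   \code{n_species} with pairwise disjoint, non-empty supports.
#' @param seed integer seed fixing all randomness.
#' @param max_stoichiometry largest multiplicity sampled for the random
#'   reactions.
#' @param max_attempts rejection-sampling budget per random reaction.
#' @return list with \code{net} (rate-bound, marked), \code{params} and
#'   \code{planted_laws}.
#' @export
random_conservative_net <- function(n_species, n_reactions,
                                    planted_laws = list(rep(1, n_species)),
                                    seed = 1L, max_stoichiometry = 2L,
                                    max_attempts = 1000L) {
  stopifnot(n_species >= 2L, n_reactions >= 1L)
  L <- do.call(rbind, lapply(planted_laws, function(x) {
    x <- as.numeric(x)
    if (length(x) != n_species || any(x < 0) || any(x != round(x)) ||
        all(x == 0)) {
      stop("planted laws must be non-negative integer vectors of length ",
           n_species, " with non-empty support")
    }
    x
  }))
  supp <- L > 0
  if (nrow(L) > 1L) {
    overlap <- crossprod(t(supp) * 1)
    diag(overlap) <- 0
    if (any(overlap > 0)) {
      stop("planted laws must have pairwise disjoint supports")
    }
  }
  set.seed(seed)
  species <- sprintf("S%02d", seq_len(n_species))

  rx_in <- list(); rx_out <- list()
  add_rx <- function(ins, outs) {
    rx_in[[length(rx_in) + 1L]] <<- ins
    rx_out[[length(rx_out) + 1L]] <<- outs
  }
  vec <- function(idx, mult) {
    v <- numeric(n_species)
    v[idx] <- mult
    v
  }
  ## mandatory chains along each planted support
  for (r in seq_len(nrow(L))) {
    s <- which(supp[r, ])
    if (length(s) >= 2L) {
      for (q in seq_len(length(s) - 1L)) {
        i <- s[q]; j <- s[q + 1L]
        g <- .gcd2(L[r, i], L[r, j])
        add_rx(vec(i, L[r, j] / g), vec(j, L[r, i] / g))
      }
    }
  }
  ## link species outside every support by conversions (a lone leftover
  ## joins the previous pair's cycle)
  free <- which(colSums(supp) == 0)
  if (length(free) >= 2L) {
    for (q in seq_len(length(free) - 1L)) {
      add_rx(vec(free[q], 1), vec(free[q + 1L], 1))
    }
    add_rx(vec(free[length(free)], 1), vec(free[1L], 1))
  }
  if (length(rx_in) > n_reactions) {
    stop("infeasible spec: ", length(rx_in),
         " mandatory reactions exceed n_reactions = ", n_reactions)
  }

  ## random orthogonal reactions by rejection
  while (length(rx_in) < n_reactions) {
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      nr <- sample(1:2, 1L)
      np <- sample(1:2, 1L)
      ri <- sample(n_species, nr)
      po <- sample(n_species, np)
      ins <- vec(ri, sample(max_stoichiometry, nr, replace = TRUE))
      outs <- vec(po, sample(max_stoichiometry, np, replace = TRUE))
      delta <- outs - ins
      if (all(delta == 0)) next
      if (all(abs(L %*% delta) < 0.5)) {
        add_rx(ins, outs)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("infeasible spec: no orthogonal reaction found in ",
           max_attempts, " attempts")
    }
  }

  tnames <- sprintf("T%02d", seq_along(rx_in))
  input <- do.call(rbind, rx_in)
  output <- do.call(rbind, rx_out)
  rownames(input) <- rownames(output) <- tnames
  colnames(input) <- colnames(output) <- species
  rate_names <- sprintf("kr%02d", seq_along(tnames))
  m0 <- stats::setNames(sample(1:5, n_species, replace = TRUE), species)
  net <- petri_net(species, tnames, input, output, initial_marking = m0,
                   rates = stats::setNames(rate_names, tnames))
  params <- stats::setNames(10^stats::runif(length(rate_names), -2, 2),
                            rate_names)
  list(net = net, params = c(params, m0), planted_laws = planted_laws)
}

#' Tiny bounded nets with known reachability graphs
#'
#' \describe{
#'   \item{cycle}{a token ring: k places, k transitions, one token; the
#'     reachability graph is a k-cycle (k states, k edges, no deadlock).}
#'   \item{chain}{a linear chain: one token migrates irreversibly through k
#'     places; k states and a terminal deadlock.}
#'   \item{fork}{a root place with \code{size} competing transitions into
#'     distinct branch places; \code{size + 1} states, each branch a
#'     deadlock.}
#' }
#'
#' @param kind \code{"cycle"}, \code{"fork"} or \code{"chain"}.
#' @param size number of places (cycle/chain) or branches (fork); >= 2.
#' @return a rate-bound \code{petri_net} with one initial token.
#' @export
toy_bounded_net <- function(kind = c("cycle", "fork", "chain"), size = 3L) {
  kind <- match.arg(kind)
  stopifnot(size >= 2L)
  if (kind == "fork") {
    places <- c("root", paste0("branch", seq_len(size)))
    tnames <- paste0("t", seq_len(size))
    input <- matrix(0, size, size + 1L)
    output <- matrix(0, size, size + 1L)
    input[, 1L] <- 1
    for (j in seq_len(size)) output[j, j + 1L] <- 1
  } else {
    places <- sprintf("P%d", seq_len(size))
    nt <- if (kind == "cycle") size else size - 1L
    tnames <- paste0("t", seq_len(nt))
    input <- matrix(0, nt, size)
    output <- matrix(0, nt, size)
    for (j in seq_len(nt)) {
      input[j, j] <- 1
      output[j, if (j < size) j + 1L else 1L] <- 1
    }
  }
  rownames(input) <- rownames(output) <- tnames
  petri_net(places, tnames, input, output,
            initial_marking = stats::setNames(1, places[1L]),
            rates = stats::setNames(rep("k1", length(tnames)), tnames))
}
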