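# Independent oracles and generators used across the suite. These
# deliberately avoid the package's own algorithms: semiflows by exhaustive
# enumeration, CTL by naive path/graph search, nets by direct matrix
# construction.

# All minimal P-semiflows with coefficients <= max_coef, by brute force:
# enumerate every non-negative integer vector, keep exact solutions of
# x C = 0, then filter to support-minimal, gcd-normalized vectors.
brute_semiflows <- function(net, max_coef = 3L) {
  C <- incidence_matrix(net)
  P <- ncol(C)
  stopifnot(P <= 8L)
  grid <- as.matrix(expand.grid(rep(list(0:max_coef), P)))
  colnames(grid) <- colnames(C)
  ok <- rowSums(abs(grid %*% t(C))) == 0 & rowSums(grid) > 0
  sols <- grid[ok, , drop = FALSE]
  if (nrow(sols) == 0L) return(list())
  gcd2 <- function(a, b) { while (b > 0) { r <- a %% b; a <- b; b <- r }; a }
  norm1 <- t(apply(sols, 1L, function(v) {
    g <- Reduce(gcd2, v[v > 0])
    v / g
  }))
  norm1 <- norm1[!duplicated(norm1), , drop = FALSE]
  supp <- norm1 > 0
  keep <- vapply(seq_len(nrow(norm1)), function(i) {
    !any(vapply(seq_len(nrow(norm1)), function(k) {
      k != i && all(supp[k, ] <= supp[i, ]) && sum(supp[k, ]) < sum(supp[i, ])
    }, NA))
  }, NA)
  sols <- norm1[keep, , drop = FALSE]
  lapply(seq_len(nrow(sols)), function(i) sols[i, ])
}

# canonical string form of a coefficient vector, for set comparison
flow_key <- function(x) paste(names(x)[x > 0], x[x > 0], sep = ":", collapse = "|")

# Naive CTL semantics by explicit graph search on the totalized RG
# (self-loops on deadlocks). EF/EU via DFS through admissible states,
# EG via reachability of a cycle inside the satisfying set.
ctl_oracle <- function(rg, f) {
  n <- nrow(rg$states)
  from <- c(rg$edges$from, rg$deadlocks)
  to <- c(rg$edges$to, rg$deadlocks)
  succ <- split(to, factor(from, levels = seq_len(n)))

  reach_through <- function(start, allowed, goal) {
    # is a goal state reachable from start via states in 'allowed'
    # (start need not be allowed for the EU semantics: handled by caller)
    seen <- rep(FALSE, n)
    stack <- start
    while (length(stack) > 0L) {
      s <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (goal[s]) return(TRUE)
      if (seen[s] || !allowed[s]) next
      seen[s] <- TRUE
      stack <- c(stack, succ[[s]])
    }
    FALSE
  }
  has_infinite_path <- function(start, allowed) {
    # exists an infinite path from start staying in 'allowed': i.e. a
    # cycle within 'allowed' reachable from start through 'allowed'
    if (!allowed[start]) return(FALSE)
    on_cycle <- rep(FALSE, n)
    for (c0 in which(allowed)) {
      # can c0 reach itself through allowed states?
      seen <- rep(FALSE, n)
      stack <- succ[[c0]]
      found <- FALSE
      while (length(stack) > 0L && !found) {
        s <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (s == c0) { found <- TRUE; break }
        if (seen[s] || !allowed[s]) next
        seen[s] <- TRUE
        stack <- c(stack, succ[[s]])
      }
      on_cycle[c0] <- found
    }
    reach_through(start, allowed, on_cycle)
  }
  sat <- function(f) {
    res <- switch(f$op,
      atom = {
        v <- rg$states[, f$place]
        switch(f$cmp,
               ">" = v > f$value, ">=" = v >= f$value,
               "<" = v < f$value, "<=" = v <= f$value,
               "=" = v == f$value, "!=" = v != f$value)
      },
      not = !sat(f$f),
      and = sat(f$lhs) & sat(f$rhs),
      or = sat(f$lhs) | sat(f$rhs),
      imp = !sat(f$lhs) | sat(f$rhs),
      EX = { s <- sat(f$f); vapply(seq_len(n), function(i) any(s[succ[[i]]]), NA) },
      AX = { s <- sat(f$f); vapply(seq_len(n), function(i) all(s[succ[[i]]]), NA) },
      EF = { s <- sat(f$f)
             vapply(seq_len(n), function(i) reach_through(i, rep(TRUE, n), s), NA) },
      EG = { s <- sat(f$f)
             vapply(seq_len(n), function(i) has_infinite_path(i, s), NA) },
      EU = { sf <- sat(f$lhs); sg <- sat(f$rhs)
             vapply(seq_len(n), function(i) {
               if (sg[i]) TRUE else sf[i] && reach_through(i, sf, sg)
             }, NA) },
      AF = { s <- sat(f$f)   # AF f = no infinite path avoiding f
             vapply(seq_len(n), function(i) !has_infinite_path(i, !s), NA) },
      AG = { s <- sat(f$f)   # AG f = cannot reach !f
             vapply(seq_len(n), function(i) !reach_through(i, rep(TRUE, n), !s), NA) },
      AU = { sf <- sat(f$lhs); sg <- sat(f$rhs)
             # A[f U g] = !(E[!g U (!f & !g)] | EG !g)
             bad1 <- vapply(seq_len(n), function(i) {
               tgt <- !sf & !sg
               if (tgt[i]) TRUE else (!sg[i]) && reach_through(i, !sg, tgt)
             }, NA)
             bad2 <- vapply(seq_len(n), function(i) has_infinite_path(i, !sg), NA)
             !(bad1 | bad2) },
      stop("oracle: unknown op ", f$op))
    res
  }
  s <- sat(f)
  list(holds = unname(s[1]), satisfying = which(s))
}

# random CTL formula of bounded depth over given places
random_ctl <- function(places, depth = 4L) {
  atom <- function() {
    p <- sample(places, 1L)
    if (stats::runif(1) < 0.5) {
      list(op = "atom", place = p, cmp = ">", value = 0L)
    } else {
      list(op = "atom", place = p,
           cmp = sample(c(">", ">=", "<", "<=", "=", "!="), 1L),
           value = sample(0:2, 1L))
    }
  }
  go <- function(d) {
    if (d <= 0L || stats::runif(1) < 0.25) return(atom())
    op <- sample(c("not", "and", "or", "imp", "EX", "EF", "EG",
                   "AX", "AF", "AG", "EU", "AU"), 1L)
    if (op %in% c("and", "or", "imp", "EU", "AU")) {
      list(op = op, lhs = go(d - 1L), rhs = go(d - 1L))
    } else if (op == "not") {
      list(op = op, f = go(d - 1L))
    } else {
      list(op = op, f = go(d - 1L))
    }
  }
  structure(go(depth), class = "ctl_formula")
}

# random well-formed net by direct matrix construction
random_net <- function(n_places = 5L, n_transitions = 6L,
                       max_mult = 2L) {
  repeat {
    input <- matrix(sample(0:max_mult, n_places * n_transitions,
                           replace = TRUE, prob = c(0.6, 0.3, 0.1)[1:(max_mult + 1)]),
                    n_transitions, n_places)
    output <- matrix(sample(0:max_mult, n_places * n_transitions,
                            replace = TRUE, prob = c(0.6, 0.3, 0.1)[1:(max_mult + 1)]),
                     n_transitions, n_places)
    if (all(rowSums(input) + rowSums(output) > 0)) break
  }
  petri_net(sprintf("p%d", seq_len(n_places)),
            sprintf("t%d", seq_len(n_transitions)),
            input, output,
            initial_marking = stats::setNames(
              sample(0:3, n_places, replace = TRUE),
              sprintf("p%d", seq_len(n_places))))
}
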