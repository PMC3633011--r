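## Minimal P-semiflow computation by Farkas elimination over the incidence
## matrix, in exact integer arithmetic (all values stay far below 2^53, and
## every row is re-divided by its gcd after each combination step, so double
## storage is exact).

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { r <- a %% b; a <- b; b <- r }
  a
}

.gcd_vec <- function(v) {
  v <- abs(v[v != 0])
  if (length(v) == 0L) return(1)
  Reduce(.gcd2, v)
}

#' Minimal P-semiflows of a Petri net
#'
#' A P-semiflow is a non-negative integer place vector x with \code{x C = 0}
#' (C the incidence matrix): the x-weighted token sum over its support is
#' invariant under any firing (a P-invariant, biologically a conservation law
#' for a kind of correlated matter). Every P-semiflow is a non-negative
#' combination of the minimal ones, which this function computes by Farkas
#' (Fourier-Motzkin) elimination of the transition columns followed by
#' support-minimality filtering and gcd normalization.
#'
#' @param net a \code{petri_net}.
#' @param max_rows safety cap on the intermediate row count of the
#'   elimination (the worst case is exponential; biochemical nets are sparse
#'   and benign). Exceeding it raises an error.
#' @return a list of objects of class \code{"semiflow"}, each with
#'   \code{coefficients} (named integer vector over all places),
#'   \code{support} (places with non-zero coefficient) and
#'   \code{invariant_constant} (x . m0 for the net's initial marking).
#'   Sorted by support size, then lexicographically by support names. The
#'   empty list is returned for nets without conservation laws.
#' @examples
#' pten <- build_pten_subnet()
#' p_semiflows(pten$net)
#' @export
p_semiflows <- function(net, max_rows = 10000L) {
  stopifnot(inherits(net, "petri_net"))
  C <- incidence_matrix(net)          # |T| x |P|
  P <- length(net$places)
  ## rows = candidate combinations: [effect over transitions | coefficients]
  D <- cbind(t(C), diag(P))
  nT <- nrow(C)

  for (j in seq_len(nT)) {
    col <- D[, j]
    keep <- D[col == 0, , drop = FALSE]
    pos <- which(col > 0)
    neg <- which(col < 0)
    if (length(pos) > 0L && length(neg) > 0L) {
      combos <- vector("list", length(pos) * length(neg))
      k <- 0L
      for (ip in pos) for (im in neg) {
        k <- k + 1L
        row <- (-col[im]) * D[ip, ] + col[ip] * D[im, ]
        g <- .gcd_vec(row)
        combos[[k]] <- row / g
      }
      keep <- rbind(keep, do.call(rbind, combos))
    }
    if (nrow(keep) > 0L) {
      keep <- keep[!duplicated(keep), , drop = FALSE]
    }
    if (nrow(keep) > max_rows) {
      stop("semiflow elimination exceeded ", max_rows,
           " intermediate rows (raise max_rows for dense nets)")
    }
    D <- keep
    if (nrow(D) == 0L) break
  }

  if (nrow(D) == 0L) return(list())
  X <- D[, nT + seq_len(P), drop = FALSE]
  X <- X[rowSums(abs(X)) > 0, , drop = FALSE]
  if (nrow(X) == 0L) return(list())
  ## gcd-normalize and deduplicate
  X <- t(apply(X, 1L, function(r) r / .gcd_vec(r)))
  X <- X[!duplicated(X), , drop = FALSE]
  ## support-minimality: drop rows whose support strictly contains another's
  supp <- X > 0
  minimal <- rep(TRUE, nrow(X))
  for (i in seq_len(nrow(X))) {
    for (k in seq_len(nrow(X))) {
      if (i != k && minimal[i] &&
          all(supp[k, ] <= supp[i, ]) && sum(supp[k, ]) < sum(supp[i, ])) {
        minimal[i] <- FALSE
        break
      }
    }
  }
  X <- X[minimal, , drop = FALSE]
  colnames(X) <- net$places

  flows <- lapply(seq_len(nrow(X)), function(i) {
    x <- X[i, ]
    structure(list(
      coefficients = x,
      support = net$places[x > 0],
      invariant_constant = sum(x * net$initial_marking)
    ), class = "semiflow")
  })
  key <- vapply(flows, function(f) {
    sprintf("%04d|%s", length(f$support), paste(f$support, collapse = "|"))
  }, "")
  flows[order(key)]
}

#' @export
print.semiflow <- function(x, ...) {
  co <- x$coefficients[x$coefficients > 0]
  cat("P-semiflow: ",
      paste(ifelse(co > 1, paste0(co, "*", names(co)), names(co)),
            collapse = " + "),
      " = ", format(x$invariant_constant), "\n", sep = "")
  invisible(x)
}

#' Check conservation of P-invariants along a trajectory
#'
#' For each semiflow x the weighted sum \code{x . m(t)} is compared with its
#' initial value; the worst relative deviation
#' \code{max_t |x.m(t) - x.m(0)| / max(1, |x.m(0)|)} is reported against
#' \code{rel_tol}.
#'
#' @param semiflows list of \code{semiflow} objects.
#' @param traj a \code{pn_trajectory} covering every support place.
#' @param rel_tol relative tolerance (default \code{1e-8}).
#' @return data frame with one row per semiflow: \code{support},
#'   \code{constant}, \code{max_rel_dev}, \code{worst_time}, \code{pass}.
#' @export
verify_invariants <- function(semiflows, traj, rel_tol = 1e-8) {
  stopifnot(inherits(traj, "pn_trajectory"))
  rows <- lapply(semiflows, function(f) {
    missing <- setdiff(f$support, colnames(traj$amounts))
    if (length(missing) > 0L) {
      stop("trajectory lacks support species: ", missing[1L])
    }
    co <- f$coefficients[f$support]
    s <- as.numeric(traj$amounts[, f$support, drop = FALSE] %*% co)
    dev <- abs(s - s[1]) / max(1, abs(s[1]))
    i <- which.max(dev)
    data.frame(support = paste(f$support, collapse = "+"),
               constant = s[1], max_rel_dev = dev[i],
               worst_time = traj$times[i], pass = dev[i] <= rel_tol,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Is every place covered by a P-semiflow?
#'
#' When all places lie in the support of some P-semiflow, every place's
#' marking is bounded and the reachability set is finite.
#'
#' @param net a \code{petri_net}.
#' @param semiflows optional precomputed list from \code{\link{p_semiflows}}.
#' @return list with \code{covered} (logical) and \code{uncovered}
#'   (character vector of places outside every support).
#' @export
is_covered <- function(net, semiflows = NULL) {
  if (is.null(semiflows)) semiflows <- p_semiflows(net)
  in_supp <- unique(unlist(lapply(semiflows, `[[`, "support")))
  uncovered <- setdiff(net$places, in_supp)
  list(covered = length(uncovered) == 0L, uncovered = uncovered)
}

#' Write semiflows as a TSV table
#' @param semiflows list from \code{\link{p_semiflows}}.
#' @param net the generating net (for the place order).
#' @param file optional path.
#' @export
write_semiflows <- function(semiflows, net, file = NULL) {
  body <- c(paste(c(net$places, "support"), collapse = "\t"),
            vapply(semiflows, function(f) {
              paste(c(format(f$coefficients, trim = TRUE),
                      paste(f$support, collapse = ",")), collapse = "\t")
            }, ""))
  lines <- c(.file_header("semiflows", body), body)
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
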