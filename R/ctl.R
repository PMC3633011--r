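## CTL (Computation Tree Logic) over reachability graphs: a recursive-
## descent parser for the textual query language and a fixed-point
## labelling model checker.
##
## Query grammar (loosest binding first):
##   f := g "=>" f | g              (implication, right-associative)
##   g := h ("|" h)*                (disjunction; unicode variants accepted)
##   h := u ("&" u)*                (conjunction)
##   u := "!" u | EX f | EF f | EG f | AX f | AF f | AG f
##        | E "[" f "U" f "]" | A "[" f "U" f "]" | "(" f ")" | atom
##   atom := place cmp int | place  (bare place is sugar for place > 0)
##   cmp  := > >= < <= = !=
## Every temporal operator must be paired with a path quantifier (E or A);
## fused operators like "AXG" are rejected.

.ctl_tokenize <- function(text) {
  text <- gsub("¬", "!", text)     # logical unicode aliases
  text <- gsub("∧", "&", text)
  text <- gsub("∨", "|", text)
  text <- gsub("⇒", "=>", text)
  text <- gsub("≠", "!=", text)
  text <- gsub("≥", ">=", text)
  text <- gsub("≤", "<=", text)

  toks <- list(); pos <- 1L; n <- nchar(text)
  two <- c("=>", ">=", "<=", "!=")
  one <- c("(", ")", "[", "]", "!", "&", "|", ">", "<", "=")
  while (pos <= n) {
    ch <- substr(text, pos, pos)
    if (grepl("^[[:space:]]$", ch)) { pos <- pos + 1L; next }
    pair <- substr(text, pos, pos + 1L)
    if (pair %in% two) {
      toks[[length(toks) + 1L]] <- list(type = pair, pos = pos)
      pos <- pos + 2L
    } else if (ch %in% one) {
      toks[[length(toks) + 1L]] <- list(type = ch, pos = pos)
      pos <- pos + 1L
    } else {
      m <- regexpr("^[^][()!&|><=[:space:]]+", substring(text, pos))
      w <- regmatches(substring(text, pos), m)
      toks[[length(toks) + 1L]] <- list(type = "word", value = w, pos = pos)
      pos <- pos + attr(m, "match.length")
    }
  }
  toks
}

#' Parse a CTL query
#'
#' @param text a query string such as \code{"EF(Pten:Pip2 > 0)"} or
#'   \code{"EG((Pten => EF !Pten) & (!Pten => EF Pten))"}. A bare place
#'   name abbreviates \code{place > 0}.
#' @param places optional character vector of valid place names; when given,
#'   atoms referencing other names are rejected at parse time.
#' @return the formula AST, class \code{"ctl_formula"}.
#' @export
parse_ctl <- function(text, places = NULL) {
  toks <- .ctl_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$i <- 1L; st$places <- places

  peek <- function() if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
  advance <- function() { t <- peek(); st$i <- st$i + 1L; t }
  fail <- function(msg, tok = peek()) {
    at <- if (is.null(tok)) "end of input" else paste0("position ", tok$pos)
    stop("CTL syntax error at ", at, ": ", msg, call. = FALSE)
  }
  expect <- function(type) {
    t <- peek()
    if (is.null(t) || t$type != type) fail(paste0("expected '", type, "'"))
    advance()
  }

  parse_formula <- function() {
    lhs <- parse_or()
    t <- peek()
    if (!is.null(t) && t$type == "=>") {
      advance()
      return(list(op = "imp", lhs = lhs, rhs = parse_formula()))
    }
    lhs
  }
  parse_or <- function() {
    lhs <- parse_and()
    while (!is.null(peek()) && peek()$type == "|") {
      advance()
      lhs <- list(op = "or", lhs = lhs, rhs = parse_and())
    }
    lhs
  }
  parse_and <- function() {
    lhs <- parse_unary()
    while (!is.null(peek()) && peek()$type == "&") {
      advance()
      lhs <- list(op = "and", lhs = lhs, rhs = parse_unary())
    }
    lhs
  }
  parse_unary <- function() {
    t <- peek()
    if (is.null(t)) fail("unexpected end of formula")
    if (t$type == "!") { advance(); return(list(op = "not", f = parse_unary())) }
    if (t$type == "(") {
      advance()
      f <- parse_formula()
      expect(")")
      return(f)
    }
    if (t$type == "word") {
      w <- t$value
      if (w %in% c("EX", "EF", "EG", "AX", "AF", "AG")) {
        advance()
        return(list(op = w, f = parse_unary()))
      }
      if (w %in% c("E", "A")) {
        advance()
        expect("[")
        f <- parse_formula()
        ut <- peek()
        if (is.null(ut) || ut$type != "word" || ut$value != "U") {
          fail("expected 'U' inside path-quantified until")
        }
        advance()
        g <- parse_formula()
        expect("]")
        return(list(op = paste0(w, "U"), lhs = f, rhs = g))
      }
      if (grepl("^[EA][XFGU]{2,}$", w) &&
          !(!is.null(st$places) && w %in% st$places)) {
        ## 'AXG' style fusions are invalid CTL; but a word like 'EGF' can be
        ## a species. A fused operator is followed by the start of a
        ## formula, an atom by a comparator / closing token / end of input.
        nxt <- if (st$i + 1L <= length(st$toks)) st$toks[[st$i + 1L]] else NULL
        if (!is.null(nxt) && nxt$type %in% c("word", "(", "!")) {
          fail(paste0("'", w, "' is not a valid CTL operator: every ",
                      "temporal operator must be immediately preceded by ",
                      "a path quantifier"), t)
        }
      }
      if (w %in% c("X", "F", "G", "U")) {
        fail(paste0("temporal operator '", w,
                    "' lacks a path quantifier (use E", w, " or A", w, ")"), t)
      }
      advance()
      return(parse_atom_tail(w, t))
    }
    fail(paste0("unexpected token '", t$type, "'"))
  }
  parse_atom_tail <- function(place, tok) {
    if (!is.null(st$places) && !place %in% st$places) {
      fail(paste0("unknown place '", place, "'"), tok)
    }
    t <- peek()
    if (!is.null(t) && t$type %in% c(">", ">=", "<", "<=", "=", "!=")) {
      cmp <- advance()$type
      vt <- peek()
      if (is.null(vt) || vt$type != "word" ||
          !grepl("^[0-9]+$", vt$value)) {
        fail("comparator must be followed by a non-negative integer")
      }
      advance()
      return(list(op = "atom", place = place, cmp = cmp,
                  value = as.integer(vt$value)))
    }
    list(op = "atom", place = place, cmp = ">", value = 0L)
  }

  f <- parse_formula()
  if (!is.null(peek())) fail("trailing input after formula")
  structure(f, class = "ctl_formula")
}

.ctl_deparse <- function(f) {
  switch(f$op,
    atom = if (f$cmp == ">" && f$value == 0L) f$place
           else paste(f$place, f$cmp, f$value),
    not = paste0("!", .ctl_deparse(f$f)),
    and = paste0("(", .ctl_deparse(f$lhs), " & ", .ctl_deparse(f$rhs), ")"),
    or = paste0("(", .ctl_deparse(f$lhs), " | ", .ctl_deparse(f$rhs), ")"),
    imp = paste0("(", .ctl_deparse(f$lhs), " => ", .ctl_deparse(f$rhs), ")"),
    EU = paste0("E[", .ctl_deparse(f$lhs), " U ", .ctl_deparse(f$rhs), "]"),
    AU = paste0("A[", .ctl_deparse(f$lhs), " U ", .ctl_deparse(f$rhs), "]"),
    paste0(f$op, " ", .ctl_deparse(f$f))
  )
}

#' @export
print.ctl_formula <- function(x, ...) {
  cat("CTL formula: ", .ctl_deparse(x), "\n", sep = "")
  invisible(x)
}

#' Model-check a CTL formula on a reachability graph
#'
#' Standard fixed-point labelling: \code{EX} by direct predecessor lookup,
#' \code{EF}/\code{EU} as least fixed points, \code{EG} as a greatest fixed
#' point, and the universal operators by duality. Deadlock states are
#' totalized with a self-loop before path semantics are applied, so
#' temporal operators are well-defined on terminal markings.
#'
#' @param rg a \code{\link{reachability_graph}}.
#' @param f a \code{ctl_formula} (or a query string, parsed on the fly).
#' @return list with \code{holds} (TRUE iff the initial marking satisfies
#'   \code{f}) and \code{satisfying} (integer indices of satisfying states).
#' @export
check_ctl <- function(rg, f) {
  stopifnot(inherits(rg, "reachability_graph"))
  if (is.character(f)) f <- parse_ctl(f, places = colnames(rg$states))
  n <- nrow(rg$states)
  from <- c(rg$edges$from, rg$deadlocks)   # self-loop totalization
  to <- c(rg$edges$to, rg$deadlocks)
  succ <- split(to, factor(from, levels = seq_len(n)))

  ex_set <- function(s) {
    unname(vapply(succ, function(v) any(s[v]), NA))
  }
  eu_set <- function(sf, sg) {
    s <- sg
    repeat {
      s2 <- s | (sf & ex_set(s))
      if (identical(s2, s)) return(s)
      s <- s2
    }
  }
  eg_set <- function(sf) {
    s <- sf
    repeat {
      s2 <- s & ex_set(s)
      if (identical(s2, s)) return(s)
      s <- s2
    }
  }
  sat <- function(f) {
    switch(f$op,
      atom = {
        if (!f$place %in% colnames(rg$states)) {
          stop("formula references unknown place: ", f$place)
        }
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
      EX = ex_set(sat(f$f)),
      EF = eu_set(rep(TRUE, n), sat(f$f)),
      EG = eg_set(sat(f$f)),
      EU = eu_set(sat(f$lhs), sat(f$rhs)),
      AX = !ex_set(!sat(f$f)),
      AF = !eg_set(!sat(f$f)),
      AG = !eu_set(rep(TRUE, n), !sat(f$f)),
      AU = {
        sf <- sat(f$lhs); sg <- sat(f$rhs)
        !(eu_set(!sg, !sf & !sg) | eg_set(!sg))
      },
      stop("unknown CTL node: ", f$op)
    )
  }
  s <- unname(sat(f))
  list(holds = s[1], satisfying = which(s))
}
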