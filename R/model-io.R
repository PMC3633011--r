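## Reaction-list text format, parameter/marking tables (TSV), trajectory
## output (TSV) and PNML export. One reaction per line:
##
##   LABEL  reactants -> products ; kf=NAME          (irreversible)
##   LABEL  reactants <-> products ; kf=NAME ; kb=NAME   (reversible)
##
## Reactant/product lists are '+'-separated species; repeating a species
## raises its stoichiometric multiplicity ("Pip2 + Pip2" is 2 Pip2). An
## empty side (or the token "0") denotes synthesis/degradation. '#' starts
## a comment; blank lines are ignored.

.oncolevel_version <- function() {
  as.character(utils::packageVersion("oncolevel"))
}

## FNV-1a 32-bit over the UTF-8 bytes of a string, reported as 8 hex digits.
## Used to stamp written files with a content/config hash.
.fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  ## track the 32-bit state as two 16-bit halves: the modular product would
  ## overflow both R's integers and exact double arithmetic otherwise
  lo <- 2166136261 %% 65536
  hi <- 2166136261 %/% 65536
  m <- 16777619
  for (b in bytes) {
    lo <- bitwXor(lo, b)
    prod_lo <- lo * m + ((hi * m) %% 65536) * 65536
    h <- prod_lo %% 4294967296
    lo <- h %% 65536
    hi <- h %/% 65536
  }
  sprintf("%04x%04x", as.integer(hi), as.integer(lo))
}

.file_header <- function(kind, payload_lines) {
  c(sprintf("# oncolevel %s %s", .oncolevel_version(), kind),
    sprintf("# content-hash: %s", .fnv1a(payload_lines)))
}

#' Parse a reaction-list document into a Petri net
#'
#' Each reaction becomes one transition (two, suffixed \code{_f}/\code{_b},
#' when reversible, keeping the incidence algebra standard). Species are
#' registered in first-appearance order; complexes keep their \code{":"}
#' names.
#'
#' @param text either a character vector of lines or a length-1 path to a
#'   file (interpreted as a path when the string names an existing file).
#' @return a list with components \code{net} (a \code{\link{petri_net}},
#'   rate-bound) and \code{reactions} (a data frame with columns
#'   \code{label}, \code{reversible}, \code{kf}, \code{kb}).
#' @examples
#' parse_reactions("R:41 Pip3 + Pten <-> Pip3:Pten ; kf=k67 ; kb=k68")$net
#' @export
parse_reactions <- function(text) {
  lines <- .as_lines(text)
  lines <- sub("#.*$", "", lines)
  keep <- which(trimws(lines) != "")
  if (length(keep) == 0L) stop("no reactions in document")

  species <- character(0)
  labels <- character(0)
  recs <- list()
  rows_in <- list(); rows_out <- list(); tnames <- character(0)
  rates <- character(0)

  register <- function(sp) {
    new <- setdiff(sp, species)
    species <<- c(species, new)
  }

  for (i in keep) {
    ln <- trimws(lines[i])
    rec <- tryCatch(.parse_reaction_line(ln),
                    error = function(e) stop("line ", i, ": ",
                                             conditionMessage(e), call. = FALSE))
    if (rec$label %in% labels) {
      stop("line ", i, ": duplicate reaction label ", rec$label, call. = FALSE)
    }
    labels <- c(labels, rec$label)
    register(names(rec$reactants))
    register(names(rec$products))
    recs[[length(recs) + 1L]] <- rec

    add_t <- function(nm, from, to, k) {
      rows_in[[length(rows_in) + 1L]] <<- from
      rows_out[[length(rows_out) + 1L]] <<- to
      tnames <<- c(tnames, nm)
      rates <<- c(rates, stats::setNames(k, nm))
    }
    if (rec$reversible) {
      add_t(paste0(rec$label, "_f"), rec$reactants, rec$products, rec$kf)
      add_t(paste0(rec$label, "_b"), rec$products, rec$reactants, rec$kb)
    } else {
      add_t(rec$label, rec$reactants, rec$products, rec$kf)
    }
  }

  to_row <- function(mult) {
    r <- stats::setNames(numeric(length(species)), species)
    r[names(mult)] <- mult
    r
  }
  input <- do.call(rbind, lapply(rows_in, to_row))
  output <- do.call(rbind, lapply(rows_out, to_row))
  rownames(input) <- rownames(output) <- tnames

  net <- petri_net(species, tnames, input, output, rates = rates)
  reactions <- data.frame(
    label = vapply(recs, `[[`, "", "label"),
    reversible = vapply(recs, `[[`, NA, "reversible"),
    kf = vapply(recs, `[[`, "", "kf"),
    kb = vapply(recs, function(r) if (r$reversible) r$kb else NA_character_, ""),
    stringsAsFactors = FALSE
  )
  list(net = net, reactions = reactions)
}

.as_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    return(readLines(text, warn = FALSE))
  }
  unlist(strsplit(text, "\n", fixed = TRUE))
}

.parse_reaction_line <- function(ln) {
  m <- regexpr("^\\S+", ln)
  label <- regmatches(ln, m)
  rest <- trimws(substring(ln, attr(m, "match.length") + 1L))
  if (rest == "") stop("missing reaction body after label ", label)

  parts <- strsplit(rest, ";", fixed = TRUE)[[1]]
  eqn <- trimws(parts[1])
  opts <- trimws(parts[-1])

  reversible <- grepl("<->", eqn, fixed = TRUE)
  arrow <- if (reversible) "<->" else "->"
  sides <- strsplit(eqn, arrow, fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop("expected one '", arrow, "' in: ", eqn)

  kf <- kb <- NULL
  for (o in opts) {
    kv <- regmatches(o, regexec("^(kf|kb)\\s*=\\s*(\\S+)$", o))[[1]]
    if (length(kv) != 3L) stop("cannot parse rate option '", o, "'")
    if (kv[2] == "kf") kf <- kv[3] else kb <- kv[3]
  }
  if (is.null(kf)) stop("missing kf= rate name")
  if (reversible && is.null(kb)) stop("reversible reaction lacks kb=")
  if (!reversible && !is.null(kb)) stop("kb= given for an irreversible reaction")

  reactants <- .parse_side(sides[1])
  products <- .parse_side(sides[2])
  if (length(reactants) == 0L && length(products) == 0L) {
    stop("reaction with neither reactants nor products")
  }
  list(label = label, reactants = reactants, products = products,
       reversible = reversible, kf = kf, kb = if (reversible) kb else NULL)
}

## '+'-separated multiset; "" or "0" is the empty side
.parse_side <- function(s) {
  s <- trimws(s)
  if (s == "" || s == "0") return(stats::setNames(numeric(0), character(0)))
  sp <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
  if (any(sp == "")) stop("empty species name in '", s, "'")
  tab <- table(factor(sp, levels = unique(sp)))
  stats::setNames(as.numeric(tab), names(tab))
}

#' Serialize a parsed reaction system back to the reaction-list grammar
#'
#' @param parsed the list returned by \code{\link{parse_reactions}}.
#' @return character vector of lines (header comments included).
#' @export
serialize_reactions <- function(parsed) {
  net <- parsed$net
  recs <- parsed$reactions
  side <- function(mult) {
    mult <- mult[mult > 0]
    if (length(mult) == 0L) return("0")
    paste(unlist(mapply(function(n, k) rep(n, k), names(mult), mult,
                        SIMPLIFY = FALSE)), collapse = " + ")
  }
  lines <- character(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    lab <- recs$label[i]
    tf <- if (recs$reversible[i]) paste0(lab, "_f") else lab
    l <- paste0(lab, " ", side(net$input[tf, ]),
                if (recs$reversible[i]) " <-> " else " -> ",
                side(net$output[tf, ]), " ; kf=", recs$kf[i])
    if (recs$reversible[i]) l <- paste0(l, " ; kb=", recs$kb[i])
    lines[i] <- l
  }
  c(.file_header("reactions", lines), lines)
}

#' Read a two-column (name, value) TSV parameter or marking table
#'
#' @param text lines or a file path.
#' @return named numeric vector; all values are required to be >= 0.
#' @export
read_parameter_table <- function(text) {
  lines <- .as_lines(text)
  lines <- lines[!grepl("^\\s*#", lines) & trimws(lines) != ""]
  if (length(lines) > 0L && grepl("^name\\tvalue$", lines[1])) {
    lines <- lines[-1]
  }
  if (length(lines) == 0L) return(stats::setNames(numeric(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 0L) != 2L
  if (any(bad)) stop("malformed table line: ", lines[bad][1L])
  nm <- vapply(parts, `[`, "", 1L)
  val <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(val)) stop("non-numeric value for ", nm[is.na(val)][1L])
  if (anyDuplicated(nm)) stop("duplicate name: ", nm[duplicated(nm)][1L])
  if (any(val < 0)) stop("negative value for ", nm[val < 0][1L])
  stats::setNames(val, nm)
}

#' Write a parameter table as TSV
#' @param params named numeric vector.
#' @param file optional path; when NULL the lines are returned invisibly.
#' @export
write_parameter_table <- function(params, file = NULL) {
  body <- c("name\tvalue",
            paste0(names(params), "\t", format(params, digits = 15,
                                               scientific = FALSE,
                                               trim = TRUE)))
  lines <- c(.file_header("parameters", body), body)
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Write a trajectory as TSV
#'
#' Columns are \code{time} followed by one column per species in net order;
#' values keep 15 significant digits so that a write/read round trip is
#' lossless well beyond 12 digits.
#'
#' @param traj a trajectory as returned by \code{\link{integrate_odes}} or
#'   \code{\link{simulate_population}}.
#' @param file optional output path.
#' @export
write_trajectory <- function(traj, file = NULL) {
  stopifnot(inherits(traj, "pn_trajectory"))
  if (length(traj$times) == 0L) stop("empty trajectory")
  tab <- cbind(time = traj$times, traj$amounts)
  body <- c(paste(colnames(tab), collapse = "\t"),
            apply(tab, 1L, function(r) {
              paste(format(r, digits = 15, trim = TRUE), collapse = "\t")
            }))
  lines <- c(.file_header("trajectory", body), body)
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Read a trajectory TSV written by \code{\link{write_trajectory}}
#' @param text lines or a file path.
#' @return a \code{pn_trajectory}.
#' @export
read_trajectory <- function(text) {
  lines <- .as_lines(text)
  lines <- lines[!grepl("^\\s*#", lines) & trimws(lines) != ""]
  if (length(lines) < 2L) stop("trajectory document has no data rows")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "time") stop("first trajectory column must be 'time'")
  vals <- t(vapply(strsplit(lines[-1], "\t", fixed = TRUE),
                   function(p) as.numeric(p), numeric(length(header))))
  new_trajectory(vals[, 1], vals[, -1, drop = FALSE], header[-1])
}

new_trajectory <- function(times, amounts, species, event_times = numeric(0)) {
  amounts <- as.matrix(amounts)
  colnames(amounts) <- species
  if (is.unsorted(times, strictly = FALSE)) stop("times must be increasing")
  structure(list(times = as.numeric(times), amounts = amounts,
                 event_times = event_times),
            class = "pn_trajectory")
}

#' @export
print.pn_trajectory <- function(x, ...) {
  cat("Trajectory: ", length(x$times), " time points x ",
      ncol(x$amounts), " species, t in [",
      format(min(x$times)), ", ", format(max(x$times)), "]\n", sep = "")
  invisible(x)
}

#' Export a Petri net as PNML (place/transition net)
#'
#' Identifiers are sanitized to XML NCNames; the original species names are
#' kept in the \code{<name>} labels. The initial marking is written only
#' when it is integral (PNML markings are token counts); otherwise it is
#' omitted with a warning.
#'
#' @param net a \code{petri_net}.
#' @param file optional path to write to.
#' @return an \code{xml2::xml_document}, invisibly when \code{file} is given.
#' @export
export_pnml <- function(net, file = NULL) {
  stopifnot(inherits(net, "petri_net"))
  ids <- .ncname_ids(c(net$places, net$transitions))
  pid <- ids[seq_along(net$places)]
  tid <- ids[length(net$places) + seq_along(net$transitions)]

  doc <- xml2::xml_new_root("pnml",
    xmlns = "http://www.pnml.org/version-2009/grammar/pnml")
  netnode <- xml2::xml_add_child(doc, "net", id = "net0",
    type = "http://www.pnml.org/version-2009/grammar/ptnet")
  page <- xml2::xml_add_child(netnode, "page", id = "page0")

  integral <- all(net$initial_marking == round(net$initial_marking))
  if (!integral) {
    warning("initial marking is not integral; omitted from PNML")
  }
  for (i in seq_along(net$places)) {
    p <- xml2::xml_add_child(page, "place", id = pid[i])
    nm <- xml2::xml_add_child(p, "name")
    xml2::xml_add_child(nm, "text", net$places[i])
    if (integral && net$initial_marking[i] > 0) {
      mk <- xml2::xml_add_child(p, "initialMarking")
      xml2::xml_add_child(mk, "text", format(round(net$initial_marking[i])))
    }
  }
  for (j in seq_along(net$transitions)) {
    tr <- xml2::xml_add_child(page, "transition", id = tid[j])
    nm <- xml2::xml_add_child(tr, "name")
    xml2::xml_add_child(nm, "text", net$transitions[j])
  }
  arc_n <- 0L
  add_arc <- function(src, dst, w) {
    arc_n <<- arc_n + 1L
    a <- xml2::xml_add_child(page, "arc", id = paste0("arc", arc_n),
                             source = src, target = dst)
    if (w > 1) {
      ins <- xml2::xml_add_child(a, "inscription")
      xml2::xml_add_child(ins, "text", format(w))
    }
  }
  for (j in seq_along(net$transitions)) {
    for (i in seq_along(net$places)) {
      if (net$input[j, i] > 0) add_arc(pid[i], tid[j], net$input[j, i])
      if (net$output[j, i] > 0) add_arc(tid[j], pid[i], net$output[j, i])
    }
  }
  if (!is.null(file)) {
    xml2::write_xml(doc, file)
    return(invisible(doc))
  }
  doc
}

.ncname_ids <- function(names) {
  ids <- gsub("[^A-Za-z0-9_.-]", "_", names)
  ids <- ifelse(grepl("^[A-Za-z_]", ids), ids, paste0("n_", ids))
  ids <- make.unique(ids, sep = "_")
  ids
}
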