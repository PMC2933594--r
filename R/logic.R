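# Two-input Boolean regulatory logic over the nitrogen (N) and light (L)
# signals. A gene cluster's regulation is summarized as a Boolean function
# f(N, L) plus a sign: with sign "activation", expression is high exactly
# where f = 1; with "repression", low where f = 1. The genotype factor never
# enters the gate itself; it modulates the N/L logic (see classify_deregulation).
#
# Truth tables are stored over the four (N, L) cells in canonical order
# (0,0), (1,0), (0,1), (1,1) — i.e. -N-L, +N-L, -N+L, +N+L.

LOGIC_CELLS <- c("-N-L", "+N-L", "-N+L", "+N+L")
CELL_N <- c(0L, 1L, 0L, 1L)
CELL_L <- c(0L, 0L, 1L, 1L)

#' Construct a Boolean regulatory specification
#'
#' @param inputs Character vector, subset of `c("N", "L")` (empty for an
#'   unregulated/constant spec).
#' @param negate Logical vector parallel to `inputs`; `TRUE` renders the
#'   input negated (the "black circle" on an edge).
#' @param gate One of `"NONE"` (zero or one input), `"AND"`, `"OR"`,
#'   `"XOR"` (two inputs), or `"UNRESOLVED"` for a gate the inference could
#'   not determine.
#' @param sign `"activation"` (expression high where the gate output is 1)
#'   or `"repression"`.
#' @param modulator Role of the genotype factor: `"absent"`, `"enables"`,
#'   `"represses"` or `"switches"`.
#' @return Object of class `boolean_spec`.
#' @export
boolean_spec <- function(inputs = character(0), negate = logical(length(inputs)),
                         gate = NULL, sign = "activation", modulator = "absent") {
  inputs <- as.character(inputs)
  if (!all(inputs %in% c("N", "L")) || anyDuplicated(inputs))
    stop("inputs must be a subset of c('N','L')")
  if (length(negate) != length(inputs))
    stop("negate must be parallel to inputs")
  if (is.null(gate)) gate <- if (length(inputs) == 2) "AND" else "NONE"
  gate <- match.arg(gate, c("NONE", "AND", "OR", "XOR", "UNRESOLVED"))
  if (gate %in% c("AND", "OR", "XOR") && length(inputs) != 2)
    stop("two-input gates require both N and L as inputs")
  if (gate == "NONE" && length(inputs) > 1)
    stop("gate NONE admits at most one input")
  sign <- match.arg(sign, c("activation", "repression"))
  modulator <- match.arg(modulator, c("absent", "enables", "represses", "switches"))
  structure(list(inputs = inputs, negate = as.logical(negate), gate = gate,
                 sign = sign, modulator = modulator),
            class = "boolean_spec")
}

#' Parse a compact Boolean logic expression
#'
#' Accepts `"0"` (constant, unregulated), a possibly negated literal
#' (`"N"`, `"!L"`), or two literals joined by `&`, `|` or `^`.
#'
#' @param text Expression string.
#' @param sign `"activation"` or `"repression"`.
#' @return A `boolean_spec`.
#' @examples
#' parse_logic("!N & !L")           # on only when both signals absent
#' parse_logic("L", "repression")   # repressed by light
#' @export
parse_logic <- function(text, sign = "activation") {
  s <- gsub("[[:space:]]", "", text)
  if (s == "0") return(boolean_spec(sign = sign))
  lit <- function(tok) {
    neg <- startsWith(tok, "!")
    nm <- sub("^!", "", tok)
    if (!nm %in% c("N", "L")) stop("cannot parse literal: ", tok)
    list(input = nm, negate = neg)
  }
  op <- regmatches(s, regexpr("[&|^]", s))
  if (length(op) == 0) {
    a <- lit(s)
    return(boolean_spec(a$input, a$negate, "NONE", sign))
  }
  parts <- strsplit(s, "[&|^]", fixed = FALSE)[[1]]
  if (length(parts) != 2) stop("cannot parse logic expression: ", text)
  a <- lit(parts[1]); b <- lit(parts[2])
  gate <- c("&" = "AND", "|" = "OR", "^" = "XOR")[[op]]
  ord <- order(match(c(a$input, b$input), c("N", "L")))  # canonical order N, L
  boolean_spec(c(a$input, b$input)[ord], c(a$negate, b$negate)[ord], gate, sign)
}

# raw gate output f(N, L) over the 4 canonical cells (before sign)
spec_gate_table <- function(spec) {
  if (spec$gate == "UNRESOLVED") return(rep(NA_integer_, 4))
  if (length(spec$inputs) == 0) return(rep(0L, 4))
  vals <- lapply(seq_along(spec$inputs), function(i) {
    v <- if (spec$inputs[i] == "N") CELL_N else CELL_L
    if (spec$negate[i]) 1L - v else v
  })
  out <- switch(spec$gate,
    NONE = vals[[1]],
    AND  = vals[[1]] & vals[[2]],
    OR   = vals[[1]] | vals[[2]],
    XOR  = xor(vals[[1]], vals[[2]]))
  stats::setNames(as.integer(out), LOGIC_CELLS)
}

#' Truth table of high-expression cells implied by a spec
#'
#' Applies the sign: with activation the high cells are the gate output,
#' with repression its complement. Unregulated (no-input) specs map to all
#' zeros under activation.
#'
#' @param spec A `boolean_spec`.
#' @return Integer vector of length 4 named by condition (`NA` for an
#'   unresolved spec).
#' @export
spec_truth_table <- function(spec) {
  tt <- spec_gate_table(spec)
  if (spec$sign == "repression") tt <- 1L - tt
  stats::setNames(as.integer(tt), LOGIC_CELLS)
}

#' Whether a spec encodes no N/L regulation
#' @param spec A `boolean_spec`.
#' @return Logical.
#' @export
is_unregulated <- function(spec) {
  length(spec$inputs) == 0 && spec$gate == "NONE"
}

#' Whether a spec is the unresolved marker
#' @param spec A `boolean_spec`.
#' @return Logical.
#' @export
is_unresolved <- function(spec) spec$gate == "UNRESOLVED"

#' Canonical spec for a high-expression truth table
#'
#' Maps any of the 16 two-input Boolean tables to its canonical
#' representation: constants become the unregulated spec; a single-input
#' table is rendered as a positive literal whose negation is absorbed into
#' the sign (e.g. high only at -N becomes "N, repression"); genuine
#' two-input tables are rendered with sign "activation" and negations on
#' the inputs (the AND-family for one high cell, the OR-family for three,
#' XOR/XNOR via the XOR gate).
#'
#' @param tt Integer/logical vector of length 4 over the canonical cells.
#' @return A `boolean_spec`.
#' @export
spec_from_table <- function(tt) {
  tt <- as.integer(tt)
  stopifnot(length(tt) == 4, all(tt %in% c(0L, 1L)))
  dep_N <- !identical(tt[c(1, 3)], tt[c(2, 4)])
  dep_L <- !identical(tt[c(1, 2)], tt[c(3, 4)])
  if (!dep_N && !dep_L) return(boolean_spec())  # constant 0 or 1: unregulated
  if (dep_N && !dep_L) {
    return(if (tt[2] == 1L) boolean_spec("N", FALSE, "NONE", "activation")
           else boolean_spec("N", FALSE, "NONE", "repression"))
  }
  if (dep_L && !dep_N) {
    return(if (tt[3] == 1L) boolean_spec("L", FALSE, "NONE", "activation")
           else boolean_spec("L", FALSE, "NONE", "repression"))
  }
  n_high <- sum(tt)
  if (n_high == 1) {        # AND of (possibly negated) inputs
    cell <- which(tt == 1L)
    return(boolean_spec(c("N", "L"), c(CELL_N[cell] == 0L, CELL_L[cell] == 0L),
                        "AND", "activation"))
  }
  if (n_high == 3) {        # OR: complement has a single low cell
    cell <- which(tt == 0L)
    return(boolean_spec(c("N", "L"), c(CELL_N[cell] == 1L, CELL_L[cell] == 1L),
                        "OR", "activation"))
  }
  # two high cells depending on both inputs: XOR or XNOR
  if (tt[1] == 0L) return(boolean_spec(c("N", "L"), c(FALSE, FALSE), "XOR", "activation"))
  boolean_spec(c("N", "L"), c(TRUE, FALSE), "XOR", "activation")
}

#' All 16 two-input Boolean truth tables
#' @return List of 16 integer vectors of length 4 (canonical cell order).
#' @export
all_truth_tables <- function() {
  lapply(0:15, function(i) {
    stats::setNames(as.integer(bitwAnd(bitwShiftR(i, 0:3), 1L)), LOGIC_CELLS)
  })
}

# description-length keys for tie-breaking: fewer inputs, then fewer negations
spec_complexity <- function(spec) {
  c(n_inputs = length(spec$inputs), n_negations = sum(spec$negate))
}

#' Test two specs for logical equivalence
#'
#' Equivalence is judged on the implied high-expression truth table, so
#' "NOT L, activation" and "L, repression" are the same regulation.
#'
#' @param a,b `boolean_spec` objects.
#' @return Logical.
#' @export
spec_equivalent <- function(a, b) {
  if (is_unresolved(a) || is_unresolved(b)) return(FALSE)
  identical(unname(spec_truth_table(a)), unname(spec_truth_table(b)))
}

#' @export
format.boolean_spec <- function(x, ...) {
  if (is_unresolved(x)) return("<unresolved>")
  if (is_unregulated(x)) return("<unregulated>")
  lit <- ifelse(x$negate, paste0("NOT ", x$inputs), x$inputs)
  body <- if (length(lit) == 1) lit else paste(lit, collapse = paste0(" ", x$gate, " "))
  paste0(body, " -> ", x$sign)
}

#' @export
print.boolean_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
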