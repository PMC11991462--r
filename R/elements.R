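#' Element reference table
#'
#' Atomic data for the twelve elements required by the study materials:
#' symbol, atomic number Z, standard atomic weight A (g/mol), and the K-shell
#' binding energy in keV. K-edges that lie below the reporting grid
#' (20--120 keV) are stored as 0; only Ba, Ta and Bi have an edge inside the
#' diagnostic range.
#'
#' @return A data.frame with columns `symbol`, `z`, `a_weight`, `k_edge_keV`.
#' @export
#' @examples
#' element_table()
element_table <- function() {
  el <- .radiopeek_env$elements
  if (is.null(el)) {
    path <- system.file("extdata", "elements.csv", package = "radiopeek",
                        mustWork = TRUE)
    el <- utils::read.csv(path, stringsAsFactors = FALSE)
    .radiopeek_env$elements <- el
  }
  el
}

.element_row <- function(symbol) {
  el <- element_table()
  i <- match(symbol, el$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol(s): ",
         paste(symbol[is.na(i)], collapse = ", "), call. = FALSE)
  }
  el[i, , drop = FALSE]
}

#' Parse a chemical formula into element counts
#'
#' Accepts element symbols, integer multiplicities and parenthesised groups,
#' e.g. `"BaSO4"`, `"Bi2O3"` or `"Ca10(PO4)6(OH)2"` (hydroxyapatite). Symbols
#' must belong to [element_table()].
#'
#' @param formula Single character string.
#' @return Named integer vector of atom counts per element.
#' @export
#' @examples
#' parse_formula("Ca10(PO4)6(OH)2")
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || !nzchar(formula))
    stop("'formula' must be a non-empty string", call. = FALSE)
  known <- element_table()$symbol
  chars <- strsplit(formula, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pos <- 1L

  read_int <- function() {
    start <- pos
    while (pos <= n && grepl("[0-9]", chars[pos])) pos <<- pos + 1L
    if (pos == start) return(1L)
    as.integer(paste(chars[start:(pos - 1L)], collapse = ""))
  }

  merge_counts <- function(a, b) {
    for (s in names(b)) a[s] <- (if (s %in% names(a)) a[[s]] else 0L) + b[[s]]
    a
  }

  parse_group <- function() {
    counts <- integer(0)
    while (pos <= n) {
      ch <- chars[pos]
      if (ch == "(") {
        pos <<- pos + 1L
        inner <- parse_group()
        if (pos > n || chars[pos] != ")")
          stop(sprintf("formula error at position %d: unmatched '('", pos),
               call. = FALSE)
        pos <<- pos + 1L
        mult <- read_int()
        counts <- merge_counts(counts, inner * mult)
      } else if (ch == ")") {
        break
      } else if (grepl("[A-Z]", ch)) {
        sym <- ch
        pos <<- pos + 1L
        if (pos <= n && grepl("[a-z]", chars[pos])) {
          sym <- paste0(sym, chars[pos])
          pos <<- pos + 1L
        }
        if (!sym %in% known)
          stop(sprintf("formula error at position %d: unknown element '%s'",
                       pos - nchar(sym), sym), call. = FALSE)
        cnt <- read_int()
        counts <- merge_counts(counts, stats::setNames(cnt, sym))
      } else {
        stop(sprintf("formula error at position %d: unexpected character '%s'",
                     pos, ch), call. = FALSE)
      }
    }
    counts
  }

  counts <- parse_group()
  if (pos <= n)
    stop(sprintf("formula error at position %d: unmatched ')'", pos),
         call. = FALSE)
  if (length(counts) == 0L)
    stop("formula error: no elements found", call. = FALSE)
  storage.mode(counts) <- "integer"
  counts
}

#' Weight fractions from atom counts
#'
#' Converts stoichiometric atom counts to mass (weight) fractions
#' \eqn{w_i = n_i A_i / \sum_j n_j A_j}.
#'
#' @param counts Named numeric vector of atom counts (e.g. from
#'   [parse_formula()]).
#' @return Named numeric vector of weight fractions summing to 1.
#' @export
#' @examples
#' weight_fractions(parse_formula("BaSO4"))
weight_fractions <- function(counts) {
  if (length(counts) == 0L || is.null(names(counts)))
    stop("'counts' must be a named vector", call. = FALSE)
  if (any(counts <= 0)) stop("atom counts must be positive", call. = FALSE)
  a <- .element_row(names(counts))$a_weight
  w <- counts * a / sum(counts * a)
  stats::setNames(as.numeric(w), names(counts))
}

#' Atom (mole) fractions of a composition
#'
#' \eqn{f_i = (w_i/A_i) / \sum_j (w_j/A_j)}: the number of atoms of element i
#' relative to the total number of atoms, recovered from weight fractions.
#'
#' @param composition Named numeric vector of weight fractions.
#' @return Named numeric vector of atom fractions summing to 1.
#' @export
#' @examples
#' atom_fractions(weight_fractions(parse_formula("Ca10(PO4)6(OH)2")))
atom_fractions <- function(composition) {
  validate_composition(composition)
  a <- .element_row(names(composition))$a_weight
  f <- (composition / a) / sum(composition / a)
  stats::setNames(as.numeric(f), names(composition))
}

#' Validate a composition
#'
#' A composition is a named numeric vector of weight fractions in (0, 1]
#' whose values sum to 1 within 1e-9 and whose names are known elements.
#'
#' @param composition Named numeric vector.
#' @return The composition, invisibly, if valid; otherwise an error.
#' @export
validate_composition <- function(composition) {
  if (length(composition) == 0L || is.null(names(composition)))
    stop("composition must be a named numeric vector", call. = FALSE)
  if (any(composition <= 0) || any(composition > 1))
    stop("weight fractions must lie in (0, 1]", call. = FALSE)
  if (abs(sum(composition) - 1) > 1e-9)
    stop("weight fractions must sum to 1 (got ",
         format(sum(composition), digits = 12), ")", call. = FALSE)
  .element_row(names(composition))
  invisible(composition)
}
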