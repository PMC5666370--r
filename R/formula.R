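#' Elemental formulas with exact integer arithmetic
#'
#' An `elemental_formula` is a named integer vector of per-element atom
#' counts (C, H, N, O, S, ...). Counts are always non-negative; subtraction
#' that would drive any count negative is an error, because a molecule
#' cannot contain a negative number of atoms.
#'
#' @param counts Named integer (or coercible) vector of atom counts, e.g.
#'   `c(C = 2, H = 5, N = 1, O = 2)`. An empty vector is the empty formula.
#' @return An object of class `elemental_formula`.
#' @examples
#' gly <- elemental_formula(c(C = 2, H = 5, N = 1, O = 2))
#' water <- elemental_formula(c(H = 2, O = 1))
#' gly + water
#' @seealso [parse_formula()], [format_formula()], [formula_mass()]
#' @export
elemental_formula <- function(counts = integer()) {
  if (length(counts) == 0) {
    x <- integer()
  } else {
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      stop("all atom counts must be named by an element symbol", call. = FALSE)
    }
    if (any(counts != round(counts))) {
      stop("atom counts must be integers", call. = FALSE)
    }
    x <- as.integer(round(counts))
    names(x) <- names(counts)
    # merge duplicated element symbols
    if (anyDuplicated(names(x))) {
      x <- vapply(split(x, names(x)), sum, integer(1))
    }
    if (any(x < 0)) {
      stop(
        "negative atom count for element(s): ",
        paste(names(x)[x < 0], collapse = ", "),
        call. = FALSE
      )
    }
    x <- x[x > 0]
  }
  structure(x, class = "elemental_formula")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

# element order for display: Hill convention (C, H, then alphabetical)
.hill_order <- function(elements) {
  rest <- sort(setdiff(elements, c("C", "H")))
  intersect(c("C", "H", rest), elements)
}

#' Serialize an elemental formula as Hill-order text
#'
#' @param formula An [elemental_formula()].
#' @return A string such as `"C95H152N24O23S2"`; the empty formula gives `""`.
#' @examples
#' format_formula(elemental_formula(c(O = 1, H = 2)))
#' @export
format_formula <- function(formula) {
  formula <- as_elemental_formula(formula)
  if (length(formula) == 0) return("")
  ord <- .hill_order(names(formula))
  paste0(ord, unclass(formula)[ord], collapse = "")
}

#' Parse Hill-order formula text
#'
#' Inverse of [format_formula()]: `"C2H5NO2"` (an omitted count means 1)
#' becomes an [elemental_formula()].
#'
#' @param text A single formula string.
#' @return An [elemental_formula()].
#' @examples
#' parse_formula("C95H152N24O23S2")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- gsub("[[:space:]_]", "", text)
  if (!nzchar(text)) return(elemental_formula())
  matches <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(attr(matches, "match.length")) != nchar(text)) {
    stop("cannot parse formula text: '", text, "'", call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", tokens)
  num <- sub("^[A-Za-z]+", "", tokens)
  counts <- ifelse(nzchar(num), suppressWarnings(as.integer(num)), 1L)
  names(counts) <- sym
  elemental_formula(counts)
}

#' Coerce to an elemental formula
#'
#' Accepts an existing `elemental_formula`, a named count vector, or a
#' Hill-order string.
#'
#' @param x Object to coerce.
#' @return An [elemental_formula()].
#' @export
as_elemental_formula <- function(x) {
  if (inherits(x, "elemental_formula")) return(x)
  if (is.character(x)) return(parse_formula(x))
  if (is.numeric(x)) return(elemental_formula(x))
  stop("cannot coerce object of class '", class(x)[1],
       "' to elemental_formula", call. = FALSE)
}

# signed element-wise combination; result validated by elemental_formula()
.formula_combine <- function(a, b, sign) {
  a <- unclass(as_elemental_formula(a))
  b <- unclass(as_elemental_formula(b))
  elements <- union(names(a), names(b))
  out <- integer(length(elements))
  names(out) <- elements
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] + sign * b
  elemental_formula(out)
}

#' @export
Ops.elemental_formula <- function(e1, e2) {
  switch(.Generic,
    "+" = .formula_combine(e1, e2, 1L),
    "-" = .formula_combine(e1, e2, -1L),
    "*" = {
      if (inherits(e1, "elemental_formula") && is.numeric(e2)) {
        f <- e1; k <- e2
      } else if (inherits(e2, "elemental_formula") && is.numeric(e1)) {
        f <- e2; k <- e1
      } else {
        stop("'*' needs one formula and one integer scalar", call. = FALSE)
      }
      stopifnot(length(k) == 1, k == round(k), k >= 0)
      elemental_formula(unclass(f) * as.integer(k))
    },
    "==" = identical(
      unclass(as_elemental_formula(e1))[.hill_order(names(as_elemental_formula(e1)))],
      unclass(as_elemental_formula(e2))[.hill_order(names(as_elemental_formula(e2)))]
    ),
    stop("operation '", .Generic, "' not defined for elemental_formula",
         call. = FALSE)
  )
}

#' Exact mass of an elemental formula
#'
#' Sums per-element atomic masses times atom counts. The empty formula has
#' mass zero.
#'
#' @param formula An [elemental_formula()] (or string / named counts).
#' @param kind `"monoisotopic"` (default; what high-resolution MS reports)
#'   or `"average"`.
#' @return Mass in Da at full double precision. Round only for display.
#' @examples
#' formula_mass(parse_formula("H2O"))
#' formula_mass(parse_formula("C95H152N24O23S2"))
#' @export
formula_mass <- function(formula, kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  formula <- as_elemental_formula(formula)
  if (length(formula) == 0) return(0)
  masses <- atomic_masses(kind)
  unknown <- setdiff(names(formula), names(masses))
  if (length(unknown) > 0) {
    stop(
      "unknown element symbol(s): ", paste(unknown, collapse = ", "),
      "; known: ", paste(names(masses), collapse = ", "),
      call. = FALSE
    )
  }
  sum(masses[names(formula)] * unclass(formula))
}
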