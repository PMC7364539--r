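#' Parse a human-readable reaction equation
#'
#' Accepts equations like `"2 A + B -> C"`, `"A <-> B"` or `"C <- A"`.
#' Coefficients default to 1, duplicate species on one side are summed,
#' and the arrow decides reversibility (`<->` reversible; `<-` is parsed
#' as the mirrored irreversible equation).
#'
#' @param text Equation string with exactly one arrow token.
#' @return List with `stoich` (named numeric, negative = consumed),
#'   `reversible` (logical) and the input `text`.
#' @export
parse_reaction_equation <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(trimws(text))) stop("empty reaction equation", call. = FALSE)
  arrows <- c("<->", "<=>", "->", "=>", "<-", "<=")
  hit <- NULL
  for (a in arrows) if (grepl(a, text, fixed = TRUE)) { hit <- a; break }
  if (is.null(hit))
    stop("no arrow ('->', '<->' or '<-') in equation: ", text, call. = FALSE)
  sides <- strsplit(text, hit, fixed = TRUE)[[1]]
  if (length(sides) > 2)
    stop("more than one arrow in equation: ", text, call. = FALSE)
  if (length(sides) == 1) sides <- c(sides, "")
  reversible <- hit %in% c("<->", "<=>")
  if (hit %in% c("<-", "<=")) sides <- rev(sides)
  lhs <- parse_equation_side(sides[1], text)
  rhs <- parse_equation_side(sides[2], text)
  st <- c(-lhs, rhs)
  if (length(st)) {
    st <- tapply(st, names(st), sum)            # net duplicates across sides
    st <- st[st != 0]
    st <- stats::setNames(as.numeric(st), names(st))
  }
  if (!length(st))
    stop("equation has net-zero stoichiometry: ", text, call. = FALSE)
  list(stoich = st, reversible = reversible, text = text)
}

parse_equation_side <- function(side, full) {
  side <- trimws(side)
  if (!nzchar(side)) return(stats::setNames(numeric(0), character(0)))
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  out <- numeric(0)
  for (term in terms) {
    if (!nzchar(term))
      stop("empty term in equation: ", full, call. = FALSE)
    toks <- strsplit(term, "[[:space:]]+")[[1]]
    coef <- 1
    if (length(toks) == 2 && grepl("^[0-9.]+$", toks[1])) {
      coef <- as.numeric(toks[1])
      toks <- toks[-1]
    }
    if (length(toks) != 1)
      stop("cannot parse term '", term, "' in equation: ", full, call. = FALSE)
    if (grepl("^[0-9.]+$", toks))
      stop("term '", term, "' has no species name: ", full, call. = FALSE)
    if (is.na(coef) || coef <= 0)
      stop("coefficient must be positive in term '", term, "': ", full,
           call. = FALSE)
    out <- c(out, stats::setNames(coef, toks))
  }
  if (anyDuplicated(names(out))) {
    out <- tapply(out, names(out), sum)         # duplicates on one side sum
    out <- stats::setNames(as.numeric(out), names(out))
  }
  out
}

#' Format a reaction as an equation string
#'
#' Inverse of [parse_reaction_equation()] up to term order.
#'
#' @param rxn A [reaction()] object.
#' @return Equation string; the arrow is `<->` when the lower bound is
#'   negative.
#' @export
format_reaction_equation <- function(rxn) {
  fmt <- function(v) {
    if (!length(v)) return("")
    paste(ifelse(v == 1, names(v), paste(v, names(v))), collapse = " + ")
  }
  lhs <- -rxn$stoich[rxn$stoich < 0]
  rhs <- rxn$stoich[rxn$stoich > 0]
  arrow <- if (rxn$lb < 0) "<->" else "->"
  trimws(paste(fmt(lhs), arrow, fmt(rhs)))
}
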