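#' Atom selection language
#'
#' A small selection grammar over a \code{\link{topology}}:
#' \itemize{
#'   \item keywords: \code{all}, \code{none}, \code{protein},
#'     \code{backbone} (atoms named N, CA, C, O), \code{calpha},
#'     \code{hydrogen}, \code{heavy} (non-hydrogen)
#'   \item fields: \code{name CA CB}, \code{resname POPC},
#'     \code{resid 1961-2063} (ranges and lists, comma or space separated),
#'     \code{chain A B}, \code{elem C N O}, \code{mol 3}
#'   \item operators: \code{and}, \code{or}, \code{not}, parentheses
#'   \item a label registered in \code{top$selections} may be used as a term
#' }
#' Returns 1-based atom positions, in ascending order.
#'
#' @param top a \code{"topology"}.
#' @param expr selection string, e.g. \code{"resid 1961-2063 and backbone"}.
#' @return integer vector of atom positions (possibly empty).
#' @export
#' @examples
#' \dontrun{select_atoms(top, "protein and name CA")}
select_atoms <- function(top, expr) {
  stopifnot(inherits(top, "topology"))
  if (is.numeric(expr)) return(as.integer(sort(expr)))
  toks <- .sel_tokenize(expr)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  mask <- .sel_or(st, top)
  if (st$pos <= length(st$toks))
    stop("selection parse error near '", st$toks[st$pos], "' in: ", expr)
  which(mask)
}

.sel_tokenize <- function(expr) {
  expr <- gsub("([()])", " \\1 ", expr)
  expr <- gsub(",", " ", expr)
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  if (!length(toks) || identical(toks, "")) stop("empty selection")
  toks
}

.sel_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
.sel_next <- function(st) { t <- .sel_peek(st); st$pos <- st$pos + 1L; t }

.sel_or <- function(st, top) {
  m <- .sel_and(st, top)
  while (identical(tolower(.sel_peek(st)), "or")) {
    .sel_next(st)
    m <- m | .sel_and(st, top)
  }
  m
}

.sel_and <- function(st, top) {
  m <- .sel_unary(st, top)
  while (identical(tolower(.sel_peek(st)), "and")) {
    .sel_next(st)
    m <- m & .sel_unary(st, top)
  }
  m
}

.sel_unary <- function(st, top) {
  t <- .sel_peek(st)
  if (is.na(t)) stop("selection ended unexpectedly")
  if (tolower(t) == "not") { .sel_next(st); return(!.sel_unary(st, top)) }
  if (t == "(") {
    .sel_next(st)
    m <- .sel_or(st, top)
    if (!identical(.sel_next(st), ")")) stop("unbalanced parenthesis in selection")
    return(m)
  }
  .sel_term(st, top)
}

.sel_field_stop <- c("and", "or", "not", "(", ")")

.sel_values <- function(st) {
  vals <- character()
  repeat {
    t <- .sel_peek(st)
    if (is.na(t) || tolower(t) %in% .sel_field_stop) break
    vals <- c(vals, .sel_next(st))
  }
  if (!length(vals)) stop("selection field with no values")
  vals
}

.sel_resid_set <- function(vals) {
  out <- integer()
  for (v in vals) {
    if (grepl("^-?[0-9]+--?[0-9]+$", v)) {
      ab <- regmatches(v, regexec("^(-?[0-9]+)-(-?[0-9]+)$", v))[[1]][2:3]
      out <- c(out, seq(as.integer(ab[1]), as.integer(ab[2])))
    } else if (grepl("^-?[0-9]+$", v)) {
      out <- c(out, as.integer(v))
    } else stop("bad resid token: ", v)
  }
  out
}

.sel_term <- function(st, top) {
  at <- top$atoms
  t <- tolower(.sel_next(st))
  switch(t,
    all      = rep(TRUE, nrow(at)),
    none     = rep(FALSE, nrow(at)),
    protein  = at$resname %in% .protein_resnames,
    backbone = at$resname %in% .protein_resnames & at$name %in% .backbone_names,
    calpha   = at$resname %in% .protein_resnames & at$name == "CA",
    hydrogen = at$elem == "H",
    heavy    = at$elem != "H",
    name     = at$name %in% .sel_values(st),
    resname  = at$resname %in% toupper(.sel_values(st)),
    resid    = at$resno %in% .sel_resid_set(.sel_values(st)),
    chain    = at$chain %in% .sel_values(st),
    elem     = at$elem %in% toupper(.sel_values(st)),
    mol      = at$molno %in% as.integer(.sel_values(st)),
    {
      orig <- st$toks[st$pos - 1L]
      if (orig %in% names(top$selections)) {
        m <- rep(FALSE, nrow(at)); m[top$selections[[orig]]] <- TRUE; m
      } else stop("unknown selection term: '", orig, "'")
    })
}
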