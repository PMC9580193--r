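#' Class expressions
#'
#' Vaccine descriptions are represented as class expressions in a small
#' description logic: named classes, conjunctions, and existential
#' restrictions (`property some filler`). These constructors build the
#' expression tree used by [compile_set()], [is_subsumed()] and
#' [entailed_fillers()].
#'
#' @param id Identifier of a named ontology class.
#' @return A `vacc_expr` object.
#' @examples
#' ce_and(ce_named("Vaccine"), ce_some("immunizes-against", ce_named("Influenza")))
#' @export
ce_named <- function(id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(kind = "named", id = id), class = "vacc_expr")
}

#' @rdname ce_named
#' @param ... Conjunct expressions (or a single list of them). Named-class
#'   identifiers given as strings are promoted to named-class expressions.
#' @export
ce_and <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && !inherits(args[[1]], "vacc_expr")) {
    args <- args[[1]]
  }
  args <- lapply(args, as_vacc_expr)
  if (length(args) == 0L) stop("conjunction must have at least one conjunct")
  if (length(args) == 1L) return(args[[1]])
  structure(list(kind = "and", args = args), class = "vacc_expr")
}

#' @rdname ce_named
#' @param property Identifier of an object property.
#' @param filler Filler expression (or named-class identifier).
#' @export
ce_some <- function(property, filler) {
  stopifnot(is.character(property), length(property) == 1L)
  structure(list(kind = "some", property = property, filler = as_vacc_expr(filler)),
            class = "vacc_expr")
}

#' @rdname ce_named
#' @param x Object to coerce: a `vacc_expr` or a class-identifier string.
#' @export
as_vacc_expr <- function(x) {
  if (inherits(x, "vacc_expr")) return(x)
  if (is.character(x) && length(x) == 1L) return(ce_named(x))
  stop("cannot interpret object of class '", paste(class(x), collapse = "/"),
       "' as a class expression")
}

#' Format a class expression in Manchester-like syntax
#'
#' @param x A `vacc_expr`.
#' @param ... Ignored.
#' @return A single string, e.g.
#'   `"Vaccine and (immunizes-against some Influenza)"`.
#' @export
format.vacc_expr <- function(x, ...) {
  switch(x$kind,
    named = x$id,
    some  = paste0("(", x$property, " some ", format(x$filler), ")"),
    and   = paste(vapply(x$args, format, character(1)), collapse = " and ")
  )
}

#' @export
print.vacc_expr <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Flatten a conjunction into named conjuncts and (property, filler-expr) pairs.
# Nested conjunctions are flattened; duplicates preserved order, deduplicated.
expr_conjuncts <- function(x) {
  named <- character(0)
  exis <- list()
  walk <- function(e) {
    switch(e$kind,
      named = named <<- c(named, e$id),
      some  = exis[[length(exis) + 1L]] <<- e,
      and   = for (a in e$args) walk(a)
    )
  }
  walk(x)
  list(named = unique(named), exis = exis)
}

# All named class ids / property ids mentioned anywhere in an expression.
expr_class_ids <- function(x) {
  switch(x$kind,
    named = x$id,
    some  = expr_class_ids(x$filler),
    and   = unique(unlist(lapply(x$args, expr_class_ids)))
  )
}

expr_property_ids <- function(x) {
  switch(x$kind,
    named = character(0),
    some  = unique(c(x$property, expr_property_ids(x$filler))),
    and   = unique(unlist(lapply(x$args, expr_property_ids)))
  )
}
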