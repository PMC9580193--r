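#' Compile an identified class into a vaccine class expression
#'
#' A class identified in a descriptor is compiled into a description-logic
#' expression describing a vaccine, according to its fundamental category:
#' a vaccine class stands for itself; a strategy, immunization target
#' (pathogen or disease), ingredient, valence or route `c` becomes
#' `Vaccine and (p some c)` with the corresponding vaccine property `p`.
#'
#' @param id Class identifier.
#' @param ont A validated `vacc_ontology`.
#' @return A `vacc_expr`.
#' @examples
#' format(compile_class("Tuberculosis", mini_vacco()))
#' @export
compile_class <- function(id, ont) {
  roots <- attr(ont, "roots")
  if (is.null(roots)) {
    ont <- validate_ontology(ont)
    roots <- attr(ont, "roots")
  }
  if (!id %in% names(roots)) stop("unknown class identifier(s): ", id)
  root <- roots[[id]]
  prop <- switch(root,
    Vaccine    = NULL,
    Strategy   = "has-strategy",
    Pathogen   = "immunizes-against",
    Disease    = "immunizes-against",
    Ingredient = "has-ingredient",
    Valence    = "has-valence",
    Route      = "has-route",
    stop("class '", id, "' has no determinable fundamental category")
  )
  if (is.null(prop)) return(ce_named(id))
  ce_and(ce_named("Vaccine"), ce_some(prop, ce_named(id)))
}

#' Compile a set of identified classes
#'
#' A set of classes compiles to the conjunction of the individually compiled
#' classes, in lexicographic order for reproducibility. The empty set
#' compiles to the bare `Vaccine` category and the result is flagged
#' *uninformative*: a descriptor in which no class was recognized carries no
#' usable information, and similarity methods treat such codes as similar to
#' nothing rather than equal to every other unparsed code.
#'
#' @param ids Character vector of class identifiers (possibly empty).
#' @param ont A `vacc_ontology`.
#' @return A `vacc_expr` with attribute `uninformative` (logical).
#' @export
compile_set <- function(ids, ont) {
  ids <- sort(unique(ids))
  if (length(ids) == 0L) {
    out <- ce_named("Vaccine")
    attr(out, "uninformative") <- TRUE
    return(out)
  }
  compiled <- lapply(ids, compile_class, ont = ont)
  # merge conjuncts, deduplicating the shared Vaccine category conjunct
  named <- character(0)
  exis <- list()
  for (e in compiled) {
    parts <- expr_conjuncts(e)
    named <- union(named, parts$named)
    exis <- c(exis, parts$exis)
  }
  out <- ce_and(c(lapply(named, ce_named), exis))
  attr(out, "uninformative") <- FALSE
  out
}

#' Compile a free-text descriptor into its vaccine class V(t)
#'
#' Composition of [tag_text()] and [compile_set()]: the classes identified
#' in the text are compiled into a single vaccine class expression.
#'
#' @param text Character scalar descriptor.
#' @param ont A `vacc_ontology`.
#' @param dictionary A `vacc_dictionary`; built from `ont` if missing.
#' @param languages Optional language filter for tagging.
#' @return A `vacc_expr` with attributes `uninformative` and `classes`
#'   (the identified class set C(t)).
#' @examples
#' ont <- mini_vacco()
#' format(vaccine_class("Live/attenuated influenza vaccine", ont))
#' @export
vaccine_class <- function(text, ont, dictionary = build_dictionary(ont),
                          languages = NULL) {
  tags <- tag_text(text, dictionary, languages = languages)
  out <- compile_set(tags$classes, ont)
  attr(out, "classes") <- tags$classes
  out
}

#' Normalize a descriptor or expression to property values P(t)
#'
#' The property values of a vaccine description assign to each vaccine
#' property (`immunizes-against`, `has-strategy`, `has-ingredient`,
#' `has-valence`, `has-route`, and any other property whose domain lies
#' under `Vaccine`) the set of all named subclasses of the property's range
#' that the ontology entails for the description. Causal pathogen/disease
#' unification and ingredient-to-vaccine propagation happen in the reasoner
#' through the declared property chains.
#'
#' @param x A descriptor string or a `vacc_expr`.
#' @param index A `vacc_index` from [classify()].
#' @param dictionary Dictionary used when `x` is text.
#' @param languages Optional language filter used when `x` is text.
#' @param exclude_roots Drop fundamental category classes from the value
#'   sets (default `TRUE`).
#' @return A `vacc_propvals`: named list mapping each vaccine property to a
#'   sorted character vector of entailed filler classes, with attribute
#'   `uninformative`.
#' @examples
#' ix <- classify(mini_vacco())
#' property_values("DTwP", ix)
#' @export
property_values <- function(x, index, dictionary = NULL, languages = NULL,
                            exclude_roots = TRUE) {
  stopifnot(inherits(index, "vacc_index"))
  if (is.character(x)) {
    if (is.null(dictionary)) dictionary <- build_dictionary(index$ont)
    x <- vaccine_class(x, index$ont, dictionary, languages = languages)
  }
  x <- as_vacc_expr(x)
  uninformative <- isTRUE(attr(x, "uninformative"))
  props <- vaccine_properties(index)
  if (uninformative) {
    vals <- stats::setNames(rep(list(character(0)), length(props)), props)
    return(structure(vals, uninformative = TRUE, class = "vacc_propvals"))
  }
  if (x$kind == "named") {
    ix <- index
    id <- x$id
  } else {
    aug <- augment_index(index, list(x))
    ix <- aug$index
    id <- aug$ids[1]
  }
  vals <- lapply(props, function(p) {
    entailed_fillers_id(ix, id, p, exclude_roots = exclude_roots)
  })
  names(vals) <- props
  structure(vals, uninformative = FALSE, class = "vacc_propvals")
}

# Properties whose domain descends from the Vaccine category.
vaccine_properties <- function(index) {
  roots <- index$roots
  dom <- index$ont$properties$domain
  keep <- !is.na(roots[dom]) & roots[dom] == "Vaccine"
  sort(index$ont$properties$id[keep])
}

#' @export
print.vacc_propvals <- function(x, ...) {
  if (isTRUE(attr(x, "uninformative"))) cat("(uninformative descriptor)\n")
  for (p in names(x)) {
    cat(p, ": {", paste(x[[p]], collapse = ", "), "}\n", sep = "")
  }
  invisible(x)
}

#' @export
format.vacc_propvals <- function(x, ...) {
  nonempty <- x[lengths(x) > 0]
  if (!length(nonempty)) return("[]")
  paste0("[", paste(vapply(names(nonempty), function(p) {
    paste0(p, ": {", paste(nonempty[[p]], collapse = ", "), "}")
  }, character(1)), collapse = "; "), "]")
}
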