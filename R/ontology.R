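#' Fundamental property categories
#'
#' The seven fundamental classes that lay out the structure of a vaccine
#' description ontology: `Vaccine`, `Valence`, `Route`, `Ingredient`,
#' `Strategy`, `Disease`, `Pathogen`. Every class in a valid ontology reaches
#' exactly one of them via its parent links.
#'
#' @return Character vector of the seven root identifiers.
#' @export
fundamental_roots <- function() {
  c("Vaccine", "Valence", "Route", "Ingredient", "Strategy", "Disease", "Pathogen")
}

#' Create an empty vaccine-description ontology
#'
#' An ontology holds named classes with multilingual terms and subclass
#' (parent) links, object properties with a domain and ranges, length-2
#' property chains `p1 o p2 => p`, and existential assertions
#' `subject SubClassOf (property some filler)`. Build it up with
#' [add_class()], [add_property()], [add_chain()] and [add_assertion()],
#' then check it with [validate_ontology()].
#'
#' @param roots Root classes to create initially (default: all seven
#'   fundamental categories).
#' @return A `vacc_ontology` object.
#' @seealso [read_ontology()], [classify()], [mini_vacco()]
#' @examples
#' ont <- ontology() |>
#'   add_class("Influenza", parent = "Disease", labels = c(en = "influenza"))
#' @export
ontology <- function(roots = fundamental_roots()) {
  ont <- structure(list(
    classes    = data.frame(id = character(0)),
    parents    = data.frame(class = character(0), parent = character(0)),
    labels     = data.frame(class = character(0), term = character(0),
                            lang = character(0)),
    properties = data.frame(id = character(0), domain = character(0)),
    ranges     = data.frame(property = character(0), range = character(0)),
    chains     = data.frame(p1 = character(0), p2 = character(0),
                            rhs = character(0)),
    assertions = data.frame(subject = character(0), property = character(0),
                            filler = character(0))
  ), class = "vacc_ontology")
  for (r in roots) ont <- add_class(ont, r)
  ont
}

#' Add a class to an ontology
#'
#' @param ont A `vacc_ontology`.
#' @param id Class identifier (unique within the ontology).
#' @param parent Character vector of parent class identifiers (empty for the
#'   fundamental roots).
#' @param labels Terms naming the class in free text. Either an unnamed
#'   character vector (language `"en"`) or a named vector whose names are
#'   language tags, e.g. `c(en = "influenza", es = "gripe")`. Repeated names
#'   give a class several terms in one language.
#' @return The modified ontology.
#' @export
add_class <- function(ont, id, parent = character(0), labels = character(0)) {
  stopifnot(inherits(ont, "vacc_ontology"), is.character(id), length(id) == 1L)
  if (id %in% ont$classes$id) stop("class '", id, "' already defined")
  ont$classes <- rbind(ont$classes, data.frame(id = id))
  if (length(parent)) {
    ont$parents <- rbind(ont$parents, data.frame(class = id, parent = parent))
  }
  if (length(labels)) {
    langs <- names(labels)
    if (is.null(langs)) langs <- rep("en", length(labels))
    langs[!nzchar(langs)] <- "en"
    ont$labels <- rbind(ont$labels, data.frame(class = id, term = unname(labels),
                                               lang = langs))
  }
  ont
}

#' @rdname add_class
#' @param domain Domain class identifier of the property.
#' @param range Character vector of range class identifiers.
#' @export
add_property <- function(ont, id, domain, range) {
  stopifnot(inherits(ont, "vacc_ontology"))
  if (id %in% ont$properties$id) stop("property '", id, "' already defined")
  ont$properties <- rbind(ont$properties, data.frame(id = id, domain = domain))
  ont$ranges <- rbind(ont$ranges, data.frame(property = id, range = range))
  ont
}

#' @rdname add_class
#' @param p1,p2 Left-hand-side property identifiers of a chain
#'   `p1 o p2 => rhs`.
#' @param rhs Right-hand-side (implied) property identifier.
#' @export
add_chain <- function(ont, p1, p2, rhs) {
  ont$chains <- rbind(ont$chains, data.frame(p1 = p1, p2 = p2, rhs = rhs))
  ont
}

#' @rdname add_class
#' @param subject,property,filler An existential assertion
#'   `subject SubClassOf (property some filler)`.
#' @export
add_assertion <- function(ont, subject, property, filler) {
  ont$assertions <- rbind(ont$assertions,
                          data.frame(subject = subject, property = property,
                                     filler = filler))
  ont
}

#' Validate an ontology
#'
#' Checks referential integrity (parents, property domains/ranges, chain
#' members, assertion subjects/properties/fillers all name declared
#' entities), acyclicity of the parent links, and that every class reaches
#' exactly one fundamental root.
#'
#' @param ont A `vacc_ontology`.
#' @param require_roots If `TRUE` (default) every class must descend from
#'   exactly one fundamental category; internal callers that introduce
#'   anonymous helper classes disable this.
#' @return `ont`, invisibly, with the derived `root` lookup attached as
#'   attribute `roots` (a named character vector class id -> fundamental
#'   root).
#' @export
validate_ontology <- function(ont, require_roots = TRUE) {
  stopifnot(inherits(ont, "vacc_ontology"))
  ids <- ont$classes$id
  if (anyDuplicated(ids)) {
    stop("duplicate class ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  miss <- function(x) unique(x[!x %in% ids])
  bad <- miss(ont$parents$parent)
  if (length(bad)) stop("undeclared parent class(es): ", paste(bad, collapse = ", "))
  bad <- miss(c(ont$properties$domain, ont$ranges$range))
  if (length(bad)) stop("undeclared class(es) in property domain/range: ",
                        paste(bad, collapse = ", "))
  bad <- miss(c(ont$assertions$subject, ont$assertions$filler))
  if (length(bad)) stop("undeclared class(es) in assertions: ",
                        paste(bad, collapse = ", "))
  pids <- ont$properties$id
  bad <- unique(setdiff(c(ont$chains$p1, ont$chains$p2, ont$chains$rhs,
                          ont$assertions$property), pids))
  if (length(bad)) stop("undeclared property id(s): ", paste(bad, collapse = ", "))
  bad <- ont$labels$class[!ont$labels$class %in% ids]
  if (length(bad)) stop("labels refer to undeclared class(es): ",
                        paste(unique(bad), collapse = ", "))

  cyc <- find_parent_cycle(ont)
  if (!is.null(cyc)) {
    stop("cycle in parent links: ", paste(cyc, collapse = " -> "))
  }

  roots <- derive_roots(ont, require_roots = require_roots)
  attr(ont, "roots") <- roots
  invisible(ont)
}

# Returns NULL or a character vector describing one cycle.
find_parent_cycle <- function(ont) {
  adj <- split(ont$parents$parent, ont$parents$class)
  state <- new.env(parent = emptyenv())  # 1 = in progress, 2 = done
  path <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    s <- mget(v, envir = state, ifnotfound = list(0L))[[1]]
    if (s == 2L) return()
    if (s == 1L) {
      i <- match(v, path)
      found <<- c(path[i:length(path)], v)
      return()
    }
    assign(v, 1L, envir = state)
    path <<- c(path, v)
    for (p in adj[[v]] %||% character(0)) visit(p)
    path <<- path[-length(path)]
    assign(v, 2L, envir = state)
  }
  for (v in ont$classes$id) visit(v)
  found
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Named character vector: class id -> fundamental root it descends from.
# Classes that reach no root (or several) are an error when require_roots.
derive_roots <- function(ont, require_roots = TRUE) {
  anc <- ancestor_sets(ont)
  fr <- fundamental_roots()
  out <- vapply(ont$classes$id, function(id) {
    hit <- intersect(anc[[id]], fr)
    if (length(hit) == 1L) return(hit)
    if (length(hit) == 0L) {
      if (require_roots) stop("class '", id, "' reaches no fundamental root")
      return(NA_character_)
    }
    stop("class '", id, "' reaches several fundamental roots: ",
         paste(hit, collapse = ", "))
  }, character(1))
  out
}

# Reflexive-transitive closure of the parent relation: id -> ancestors incl self.
ancestor_sets <- function(ont) {
  ids <- ont$classes$id
  padj <- split(ont$parents$parent, ont$parents$class)
  memo <- new.env(parent = emptyenv())
  anc <- function(id) {
    got <- mget(id, envir = memo, ifnotfound = list(NULL))[[1]]
    if (!is.null(got)) return(got)
    assign(id, id, envir = memo)  # placeholder; cycles rejected elsewhere
    res <- unique(c(id, unlist(lapply(padj[[id]] %||% character(0), anc))))
    assign(id, res, envir = memo)
    res
  }
  out <- lapply(ids, anc)
  names(out) <- ids
  out
}

#' @export
print.vacc_ontology <- function(x, ...) {
  cat("Vaccine-description ontology\n")
  cat("  classes:    ", nrow(x$classes),
      " (", sum(x$classes$id %in% fundamental_roots()), " fundamental)\n", sep = "")
  cat("  terms:      ", nrow(x$labels),
      " in ", length(unique(x$labels$lang)), " language(s)\n", sep = "")
  cat("  properties: ", nrow(x$properties), "\n", sep = "")
  cat("  chains:     ", nrow(x$chains), "\n", sep = "")
  cat("  assertions: ", nrow(x$assertions), "\n", sep = "")
  invisible(x)
}
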