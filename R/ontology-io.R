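#' Read and write the canonical ontology serialization
#'
#' The canonical format is a YAML document with four sections:
#'
#' ```yaml
#' classes:
#'   - id: Influenza
#'     parents: [Disease]
#'     labels:
#'       - {term: influenza, lang: en}
#'       - {term: gripe, lang: es}
#' properties:
#'   - {id: immunizes-against, domain: Vaccine, ranges: [Pathogen, Disease]}
#' chains:
#'   - {lhs: [has-ingredient, immunizes-against], rhs: immunizes-against}
#' assertions:
#'   - {subject: Havrix, property: has-ingredient, filler: HAV-antigen}
#' ```
#'
#' The fundamental root of each class is derived from its parent links on
#' load, and [validate_ontology()] runs on every load. Chains must have a
#' left-hand side of exactly two properties; longer chains are rejected.
#' Writing uses a canonical ordering (classes, labels, properties sorted by
#' identifier) so that save/load round-trips are byte-identical.
#'
#' @param path File path.
#' @return `read_ontology` returns a validated `vacc_ontology`;
#'   `write_ontology` returns `path` invisibly.
#' @export
read_ontology <- function(path) {
  if (!file.exists(path)) stop("ontology file not found: ", path)
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("malformed ontology file '", path,
                                           "': ", conditionMessage(e)))
  if (!is.list(doc)) stop("malformed ontology file '", path, "': not a mapping")
  ont <- ontology(roots = character(0))
  for (i in seq_along(doc$classes)) {
    cl <- doc$classes[[i]]
    if (is.null(cl$id)) stop("class record ", i, " has no id")
    labs <- character(0)
    if (length(cl$labels)) {
      labs <- vapply(cl$labels, function(l) as.character(l$term), character(1))
      names(labs) <- vapply(cl$labels, function(l) {
        if (is.null(l$lang)) "en" else as.character(l$lang)
      }, character(1))
    }
    ont <- add_class(ont, as.character(cl$id),
                     parent = as.character(unlist(cl$parents)),
                     labels = labs)
  }
  for (i in seq_along(doc$properties)) {
    pr <- doc$properties[[i]]
    if (is.null(pr$id) || is.null(pr$domain)) {
      stop("property record ", i, " must have id and domain")
    }
    ont <- add_property(ont, as.character(pr$id), as.character(pr$domain),
                        as.character(unlist(pr$ranges)))
  }
  for (i in seq_along(doc$chains)) {
    ch <- doc$chains[[i]]
    lhs <- as.character(unlist(ch$lhs))
    if (length(lhs) != 2L) {
      stop("chain record ", i, ": property chains must have exactly two ",
           "properties on the left-hand side (got ", length(lhs), ")")
    }
    ont <- add_chain(ont, lhs[1], lhs[2], as.character(ch$rhs))
  }
  for (i in seq_along(doc$assertions)) {
    a <- doc$assertions[[i]]
    ont <- add_assertion(ont, as.character(a$subject), as.character(a$property),
                         as.character(a$filler))
  }
  validate_ontology(ont)
  ont
}

#' @rdname read_ontology
#' @param ont A `vacc_ontology`.
#' @export
write_ontology <- function(ont, path) {
  stopifnot(inherits(ont, "vacc_ontology"))
  ord <- order(ont$classes$id)
  classes <- lapply(ont$classes$id[ord], function(id) {
    rec <- list(id = id)
    par <- sort(ont$parents$parent[ont$parents$class == id])
    if (length(par)) rec$parents <- as.list(par)
    lab <- ont$labels[ont$labels$class == id, , drop = FALSE]
    if (nrow(lab)) {
      lab <- lab[order(lab$lang, lab$term), , drop = FALSE]
      rec$labels <- lapply(seq_len(nrow(lab)), function(i) {
        list(term = lab$term[i], lang = lab$lang[i])
      })
    }
    rec
  })
  pord <- order(ont$properties$id)
  properties <- lapply(ont$properties$id[pord], function(id) {
    list(id = id,
         domain = ont$properties$domain[ont$properties$id == id],
         ranges = as.list(sort(ont$ranges$range[ont$ranges$property == id])))
  })
  ch <- ont$chains[order(ont$chains$p1, ont$chains$p2, ont$chains$rhs), ,
                   drop = FALSE]
  chains <- lapply(seq_len(nrow(ch)), function(i) {
    list(lhs = list(ch$p1[i], ch$p2[i]), rhs = ch$rhs[i])
  })
  as_ <- ont$assertions[order(ont$assertions$subject, ont$assertions$property,
                              ont$assertions$filler), , drop = FALSE]
  assertions <- lapply(seq_len(nrow(as_)), function(i) {
    list(subject = as_$subject[i], property = as_$property[i],
         filler = as_$filler[i])
  })
  doc <- list(classes = classes, properties = properties, chains = chains,
              assertions = assertions)
  yaml::write_yaml(doc, path, indent.mapping.sequence = TRUE)
  invisible(path)
}

#' Export an ontology to OWL2 functional syntax
#'
#' Writes subclass axioms, `SubObjectPropertyOf` chain axioms, existential
#' assertions as `SubClassOf(subject ObjectSomeValuesFrom(p filler))`, and
#' labels as `rdfs:label` annotations with language tags. Import of
#' arbitrary OWL is not supported; this exporter exists for interoperability
#' with OWL tooling.
#'
#' @param ont A `vacc_ontology`.
#' @param path Output file path.
#' @param iri_base Base IRI prefix for the generated entities.
#' @return `path`, invisibly.
#' @export
write_owl <- function(ont, path, iri_base = "http://example.org/vacco#") {
  esc <- function(x) gsub("([^A-Za-z0-9_.-])", "_", x)
  ent <- function(x) paste0(":", esc(x))
  lines <- c(
    sprintf("Prefix(:=<%s>)", iri_base),
    "Prefix(owl:=<http://www.w3.org/2002/07/owl#>)",
    "Prefix(rdfs:=<http://www.w3.org/2000/01/rdf-schema#>)",
    sprintf("Ontology(<%s>", sub("#$", "", iri_base))
  )
  for (id in sort(ont$classes$id)) {
    lines <- c(lines, sprintf("Declaration(Class(%s))", ent(id)))
  }
  for (id in sort(ont$properties$id)) {
    lines <- c(lines, sprintf("Declaration(ObjectProperty(%s))", ent(id)))
  }
  p <- ont$parents[order(ont$parents$class, ont$parents$parent), , drop = FALSE]
  lines <- c(lines, sprintf("SubClassOf(%s %s)", ent(p$class), ent(p$parent)))
  pr <- ont$properties[order(ont$properties$id), , drop = FALSE]
  lines <- c(lines, sprintf("ObjectPropertyDomain(%s %s)",
                            ent(pr$id), ent(pr$domain)))
  rg <- ont$ranges[order(ont$ranges$property, ont$ranges$range), , drop = FALSE]
  lines <- c(lines, sprintf("ObjectPropertyRange(%s %s)",
                            ent(rg$property), ent(rg$range)))
  ch <- ont$chains
  lines <- c(lines, sprintf(
    "SubObjectPropertyOf(ObjectPropertyChain(%s %s) %s)",
    ent(ch$p1), ent(ch$p2), ent(ch$rhs)))
  a <- ont$assertions
  lines <- c(lines, sprintf(
    "SubClassOf(%s ObjectSomeValuesFrom(%s %s))",
    ent(a$subject), ent(a$property), ent(a$filler)))
  lb <- ont$labels
  lines <- c(lines, sprintf(
    'AnnotationAssertion(rdfs:label %s "%s"@%s)',
    ent(lb$class), gsub('"', '\\\\"', lb$term), lb$lang))
  lines <- c(lines, ")")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
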