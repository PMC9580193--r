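#' Classify an ontology
#'
#' Computes the deductive closure of the ontology under the EL-style
#' completion rules and returns a queryable subsumption index. The closure
#' covers, iterated to a fixpoint:
#'
#' * reflexivity and transitivity of the subclass relation on named classes;
#' * inheritance of existential assertions along the subclass relation
#'   (if `A SubClassOf A'` and `A' SubClassOf (p some B)` then
#'   `A SubClassOf (p some B)`);
#' * filler generalization (if `A SubClassOf (p some B)` and
#'   `B SubClassOf B'` then `A SubClassOf (p some B')`);
#' * property chains (if `A SubClassOf (p1 some B)`,
#'   `B SubClassOf (p2 some C)` and `p1 o p2 => p` then
#'   `A SubClassOf (p some C)`).
#'
#' This fragment (conjunction, existential restriction, subclass axioms,
#' binary property chains) is exactly what vaccine-description ontologies
#' use; there is no negation, disjunction or cardinality.
#'
#' @param ont A validated `vacc_ontology`.
#' @param require_roots Passed to [validate_ontology()]; internal callers
#'   that add anonymous classes set this to `FALSE`.
#' @return A `vacc_index` object; query it with [is_subsumed()] and
#'   [entailed_fillers()].
#' @export
classify <- function(ont, require_roots = TRUE) {
  ont <- validate_ontology(ont, require_roots = require_roots)
  anc <- ancestor_sets(ont)
  sub_pairs <- data.frame(
    sub = rep(names(anc), lengths(anc)),
    sup = unlist(anc, use.names = FALSE)
  )
  R <- unique(ont$assertions)
  names(R) <- c("subject", "property", "filler")
  repeat {
    n0 <- nrow(R)
    inh <- merge(sub_pairs, R, by.x = "sup", by.y = "subject")
    inh <- data.frame(subject = inh$sub, property = inh$property,
                      filler = inh$filler)
    gen <- merge(R, sub_pairs, by.x = "filler", by.y = "sub")
    gen <- data.frame(subject = gen$subject, property = gen$property,
                      filler = gen$sup)
    chs <- NULL
    if (nrow(ont$chains)) {
      chs <- lapply(seq_len(nrow(ont$chains)), function(i) {
        a <- R[R$property == ont$chains$p1[i], , drop = FALSE]
        b <- R[R$property == ont$chains$p2[i], , drop = FALSE]
        if (!nrow(a) || !nrow(b)) return(NULL)
        m <- merge(a, b, by.x = "filler", by.y = "subject")
        if (!nrow(m)) return(NULL)
        data.frame(subject = m$subject, property = ont$chains$rhs[i],
                   filler = m$filler.y)
      })
      chs <- do.call(rbind, chs)
    }
    R <- unique(rbind(R, inh, gen, chs))
    if (nrow(R) == n0) break
  }
  rownames(R) <- NULL
  relkey <- new.env(parent = emptyenv(), size = max(nrow(R), 29L))
  if (nrow(R)) {
    keys <- paste(R$subject, R$property, R$filler, sep = "\r")
    for (k in keys) assign(k, TRUE, envir = relkey)
  }
  structure(list(ont = ont, anc = anc, rel = R, relkey = relkey,
                 roots = attr(ont, "roots")),
            class = "vacc_index")
}

#' @export
print.vacc_index <- function(x, ...) {
  cat("Subsumption index over", length(x$anc), "named classes;",
      nrow(x$rel), "entailed existential triples\n")
  invisible(x)
}

index_has_class <- function(index, id) id %in% names(index$anc)

# A SubClassOf B on named classes.
index_isa <- function(index, a, b) {
  b %in% index$anc[[a]]
}

# A SubClassOf (p some B) on named classes.
index_rel <- function(index, a, p, b) {
  exists(paste(a, p, b, sep = "\r"), envir = index$relkey, inherits = FALSE)
}

check_known <- function(index, expr) {
  cls <- expr_class_ids(expr)
  bad <- cls[!cls %in% names(index$anc)]
  if (length(bad)) stop("unknown class identifier(s): ",
                        paste(unique(bad), collapse = ", "))
  prp <- expr_property_ids(expr)
  bad <- prp[!prp %in% index$ont$properties$id]
  if (length(bad)) stop("unknown property identifier(s): ",
                        paste(unique(bad), collapse = ", "))
  invisible(TRUE)
}

#' Internalize compound expressions into an index
#'
#' Adds one fresh anonymous named class per compound expression (the
#' standard EL internalization technique: named conjuncts become parents,
#' existential conjuncts become assertions, compound fillers recurse) and
#' re-classifies. Querying the fresh class is then equivalent to querying
#' the compound expression.
#'
#' @param index A `vacc_index`.
#' @param exprs List of `vacc_expr` (or class-identifier strings).
#' @return A list with elements `index` (the augmented `vacc_index`) and
#'   `ids` (character vector naming, for each input expression, the named
#'   class that represents it).
#' @export
augment_index <- function(index, exprs) {
  stopifnot(inherits(index, "vacc_index"))
  exprs <- lapply(exprs, as_vacc_expr)
  for (e in exprs) check_known(index, e)
  ont <- index$ont
  counter <- 0L
  intern <- function(e) {
    if (e$kind == "named") return(e$id)
    counter <<- counter + 1L
    fresh <- sprintf(".anon%03d", counter)
    parts <- expr_conjuncts(e)
    ont <<- add_class(ont, fresh, parent = parts$named)
    for (ex in parts$exis) {
      ont <<- add_assertion(ont, fresh, ex$property, intern(ex$filler))
    }
    fresh
  }
  ids <- vapply(exprs, intern, character(1))
  list(index = classify(ont, require_roots = FALSE), ids = ids)
}

# Structural check that named class `id` is subsumed by expression `b`
# under the closure in `index`.
entails_expr <- function(index, id, b) {
  parts <- expr_conjuncts(b)
  for (n in parts$named) {
    if (!index_isa(index, id, n)) return(FALSE)
  }
  for (ex in parts$exis) {
    fl <- ex$filler
    cand <- index$rel[index$rel$subject == id &
                      index$rel$property == ex$property, "filler"]
    ok <- if (fl$kind == "named") {
      any(vapply(cand, function(b2) index_isa(index, b2, fl$id), logical(1)))
    } else {
      any(vapply(cand, function(b2) entails_expr(index, b2, fl), logical(1)))
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Test subsumption between class expressions
#'
#' `is_subsumed(index, a, b)` is `TRUE` iff the ontology entails
#' `a SubClassOf b` under the closure computed by [classify()]. Compound
#' left-hand sides are handled by internalization ([augment_index()]);
#' right-hand sides are checked structurally conjunct by conjunct.
#' Equivalence of two expressions is mutual subsumption.
#'
#' @param index A `vacc_index`.
#' @param a,b Class expressions ([ce_named()], [ce_and()], [ce_some()]) or
#'   class-identifier strings.
#' @return Logical scalar.
#' @examples
#' ix <- classify(mini_vacco())
#' is_subsumed(ix,
#'   ce_and("Vaccine", ce_some("immunizes-against", "Influenza"),
#'          ce_some("has-strategy", "Live-attenuated")),
#'   ce_and("Vaccine", ce_some("immunizes-against", "Influenza")))
#' @export
is_subsumed <- function(index, a, b) {
  stopifnot(inherits(index, "vacc_index"))
  a <- as_vacc_expr(a)
  b <- as_vacc_expr(b)
  check_known(index, a)
  check_known(index, b)
  if (a$kind == "named") {
    return(entails_expr(index, a$id, b))
  }
  aug <- augment_index(index, list(a))
  entails_expr(aug$index, aug$ids[1], b)
}

#' Entailed property fillers of an expression
#'
#' Returns every named class `c` in the subtree of the range of property
#' `p` such that the ontology entails
#' `expr SubClassOf (Vaccine and (p some c))`. These are the normalized
#' property values a vaccine description carries for `p`.
#'
#' @param index A `vacc_index`.
#' @param expr A class expression or class-identifier string.
#' @param p An object-property identifier.
#' @param exclude_roots Drop the seven fundamental category classes from the
#'   result (default `TRUE`): a description should be characterized by
#'   specific diseases, strategies, and so on, not by the categories
#'   themselves, which every vaccine trivially reaches once any filler in
#'   the category is entailed.
#' @return Sorted character vector of class identifiers.
#' @export
entailed_fillers <- function(index, expr, p, exclude_roots = TRUE) {
  stopifnot(inherits(index, "vacc_index"))
  if (!p %in% index$ont$properties$id) stop("unknown property identifier(s): ", p)
  expr <- as_vacc_expr(expr)
  check_known(index, expr)
  if (expr$kind == "named") {
    id <- expr$id
  } else {
    aug <- augment_index(index, list(expr))
    index <- aug$index
    id <- aug$ids[1]
  }
  entailed_fillers_id(index, id, p, exclude_roots)
}

# Same, for a subject already named in the index (used after augment_index).
entailed_fillers_id <- function(index, id, p, exclude_roots = TRUE) {
  if (!index_has_class(index, "Vaccine") || !index_isa(index, id, "Vaccine")) {
    return(character(0))
  }
  ranges <- index$ont$ranges$range[index$ont$ranges$property == p]
  fillers <- index$rel$filler[index$rel$subject == id & index$rel$property == p]
  fillers <- unique(fillers)
  in_range <- vapply(fillers, function(f) {
    any(vapply(ranges, function(r) index_isa(index, f, r), logical(1)))
  }, logical(1))
  out <- fillers[in_range]
  if (exclude_roots) out <- setdiff(out, fundamental_roots())
  sort(out)
}

#' Entailed existential triples of a classified ontology
#'
#' Returns the full materialized closure: every `(subject, property,
#' filler)` with `subject SubClassOf (property some filler)` entailed among
#' named classes.
#'
#' @param index A `vacc_index`.
#' @return Data frame with columns `subject`, `property`, `filler`, sorted.
#' @export
entailments <- function(index) {
  stopifnot(inherits(index, "vacc_index"))
  R <- index$rel
  R <- R[order(R$subject, R$property, R$filler), , drop = FALSE]
  rownames(R) <- NULL
  R
}
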