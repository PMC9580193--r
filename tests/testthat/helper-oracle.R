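# Independent semantic oracle: derives every subsumption pair and every
# existential triple by dumb repeated rule application over all facts until
# nothing changes. Deliberately unindexed and separate from the package's
# completion procedure.

oracle_closure <- function(ont) {
  ids <- ont$classes$id
  subs <- unique(rbind(
    data.frame(a = ids, b = ids),
    data.frame(a = ont$parents$class, b = ont$parents$parent)
  ))
  rels <- unique(data.frame(s = ont$assertions$subject,
                            p = ont$assertions$property,
                            f = ont$assertions$filler))
  has_sub <- function(a, b) any(subs$a == a & subs$b == b)
  has_rel <- function(s, p, f) any(rels$s == s & rels$p == p & rels$f == f)
  repeat {
    n0 <- nrow(subs) + nrow(rels)
    # transitivity of subclass
    for (i in seq_len(nrow(subs))) {
      for (j in seq_len(nrow(subs))) {
        if (subs$b[i] == subs$a[j] && !has_sub(subs$a[i], subs$b[j])) {
          subs <- rbind(subs, data.frame(a = subs$a[i], b = subs$b[j]))
        }
      }
    }
    # inherit existentials down the hierarchy
    for (i in seq_len(nrow(subs))) {
      for (j in seq_len(nrow(rels))) {
        if (subs$b[i] == rels$s[j] &&
            !has_rel(subs$a[i], rels$p[j], rels$f[j])) {
          rels <- rbind(rels, data.frame(s = subs$a[i], p = rels$p[j],
                                         f = rels$f[j]))
        }
      }
    }
    # generalize fillers up the hierarchy
    for (j in seq_len(nrow(rels))) {
      for (i in seq_len(nrow(subs))) {
        if (rels$f[j] == subs$a[i] &&
            !has_rel(rels$s[j], rels$p[j], subs$b[i])) {
          rels <- rbind(rels, data.frame(s = rels$s[j], p = rels$p[j],
                                         f = subs$b[i]))
        }
      }
    }
    # property chains
    for (k in seq_len(nrow(ont$chains))) {
      for (i in seq_len(nrow(rels))) {
        for (j in seq_len(nrow(rels))) {
          if (rels$p[i] == ont$chains$p1[k] && rels$p[j] == ont$chains$p2[k] &&
              rels$f[i] == rels$s[j] &&
              !has_rel(rels$s[i], ont$chains$rhs[k], rels$f[j])) {
            rels <- rbind(rels, data.frame(s = rels$s[i],
                                           p = ont$chains$rhs[k],
                                           f = rels$f[j]))
          }
        }
      }
    }
    if (nrow(subs) + nrow(rels) == n0) break
  }
  list(subs = subs, rels = rels)
}

# Random small ontology: every class is parented under a fundamental root
# (keeping validation happy), with random properties, chains and assertions.
random_ontology <- function(seed, max_classes = 12, max_properties = 3,
                            max_chains = 2) {
  set.seed(seed)
  roots <- sample(fundamental_roots(), sample(2:3, 1))
  if (!"Vaccine" %in% roots) roots <- c(roots[-1], "Vaccine")
  ont <- ontology(roots = roots)
  n_extra <- sample(1:(max_classes - length(roots)), 1)
  ids <- sprintf("C%02d", seq_len(n_extra))
  for (i in seq_along(ids)) {
    pool <- c(roots, ids[seq_len(i - 1)])
    ont <- add_class(ont, ids[i], parent = sample(pool, 1))
  }
  all_cls <- ont$classes$id
  n_prop <- sample(1:max_properties, 1)
  props <- sprintf("p%d", seq_len(n_prop))
  for (p in props) {
    ont <- add_property(ont, p, sample(all_cls, 1),
                        sample(all_cls, sample(1:2, 1)))
  }
  n_chain <- sample(0:max_chains, 1)
  for (k in seq_len(n_chain)) {
    ont <- add_chain(ont, sample(props, 1), sample(props, 1), sample(props, 1))
  }
  n_assert <- sample(2:8, 1)
  for (k in seq_len(n_assert)) {
    ont <- add_assertion(ont, sample(all_cls, 1), sample(props, 1),
                         sample(all_cls, 1))
  }
  ont
}

# Compare the package's classification with the oracle on every named
# subsumption pair and every existential triple. Returns TRUE or a string.
agrees_with_oracle <- function(ont) {
  ix <- classify(ont)
  orc <- oracle_closure(ont)
  ids <- ont$classes$id
  for (a in ids) {
    for (b in ids) {
      want <- any(orc$subs$a == a & orc$subs$b == b)
      got <- is_subsumed(ix, a, b)
      if (want != got) {
        return(sprintf("subsumption mismatch %s <= %s: oracle %s, index %s",
                       a, b, want, got))
      }
    }
  }
  got_rel <- entailments(ix)
  got_keys <- sort(paste(got_rel$subject, got_rel$property, got_rel$filler))
  want_keys <- sort(paste(orc$rels$s, orc$rels$p, orc$rels$f))
  if (!identical(got_keys, want_keys)) {
    return(sprintf("triple sets differ: %d in index, %d in oracle",
                   length(got_keys), length(want_keys)))
  }
  TRUE
}

# Minimal fixtures reproducing the three canonical chain inferences.
chain_fixture_ingredient_target <- function() {
  ont <- ontology(roots = c("Vaccine", "Ingredient", "Disease"))
  ont <- add_class(ont, "Active-ingredient", parent = "Ingredient")
  ont <- add_class(ont, "I", parent = "Active-ingredient")
  ont <- add_class(ont, "Flu", parent = "Disease")
  ont <- add_class(ont, "v", parent = "Vaccine")
  ont <- add_property(ont, "has-ingredient", "Vaccine", "Ingredient")
  ont <- add_property(ont, "immunizes-against", "Vaccine", "Disease")
  ont <- add_chain(ont, "has-ingredient", "immunizes-against",
                   "immunizes-against")
  ont <- add_assertion(ont, "v", "has-ingredient", "I")
  ont <- add_assertion(ont, "I", "immunizes-against", "Flu")
  ont
}

chain_fixture_ingredient_strategy <- function() {
  ont <- ontology(roots = c("Vaccine", "Ingredient", "Strategy"))
  ont <- add_class(ont, "Active-ingredient", parent = "Ingredient")
  ont <- add_class(ont, "I", parent = "Active-ingredient")
  ont <- add_class(ont, "Inactivated", parent = "Strategy")
  ont <- add_class(ont, "v", parent = "Vaccine")
  ont <- add_property(ont, "has-ingredient", "Vaccine", "Ingredient")
  ont <- add_property(ont, "has-strategy", "Vaccine", "Strategy")
  ont <- add_chain(ont, "has-ingredient", "has-strategy", "has-strategy")
  ont <- add_assertion(ont, "v", "has-ingredient", "I")
  ont <- add_assertion(ont, "I", "has-strategy", "Inactivated")
  ont
}

chain_fixture_causal <- function() {
  # the pathogen/disease pairing here is deliberately arbitrary: the chain
  # must fire on whatever causal assertion is present
  ont <- ontology(roots = c("Vaccine", "Pathogen", "Disease"))
  ont <- add_class(ont, "Hib", parent = "Pathogen")
  ont <- add_class(ont, "Cervical-cancer", parent = "Disease")
  ont <- add_class(ont, "v", parent = "Vaccine")
  ont <- add_property(ont, "immunizes-against", "Vaccine",
                      c("Pathogen", "Disease"))
  ont <- add_property(ont, "causes", "Pathogen", "Disease")
  ont <- add_chain(ont, "immunizes-against", "causes", "immunizes-against")
  ont <- add_assertion(ont, "v", "immunizes-against", "Hib")
  ont <- add_assertion(ont, "Hib", "causes", "Cervical-cancer")
  ont
}
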