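test_that("ingredient and causal chains derive the canonical inferences", {
  # immunization target propagates from an active ingredient to the vaccine
  ix <- classify(chain_fixture_ingredient_target())
  expect_true(is_subsumed(ix, "v",
    ce_and("Vaccine", ce_some("immunizes-against", "Flu"))))

  # strategy propagates from an active ingredient to the vaccine
  ix <- classify(chain_fixture_ingredient_strategy())
  expect_true(is_subsumed(ix, "v",
    ce_and("Vaccine", ce_some("has-strategy", "Inactivated"))))

  # a pathogen immunization target implies its caused disease
  ix <- classify(chain_fixture_causal())
  expect_true(is_subsumed(ix, "v",
    ce_and("Vaccine", ce_some("immunizes-against", "Cervical-cancer"))))
})

test_that("subsumption is reflexive and transitive on named classes", {
  ont <- mini_vacco()
  ix <- classify(ont)
  ids <- ont$classes$id
  for (a in sample(ids, 10)) expect_true(is_subsumed(ix, a, a))
  # transitivity via a known three-level path
  expect_true(is_subsumed(ix, "Influenza-virus", "Virus"))
  expect_true(is_subsumed(ix, "Virus", "Pathogen"))
  expect_true(is_subsumed(ix, "Influenza-virus", "Pathogen"))
})

test_that("compound-expression subsumption follows EL semantics", {
  ix <- classify(mini_vacco())
  flu <- ce_and("Vaccine", ce_some("immunizes-against", "Influenza"))
  flu_att <- ce_and("Vaccine", ce_some("immunizes-against", "Influenza"),
                    ce_some("has-strategy", "Live-attenuated"))
  # conjunct dropping
  expect_true(is_subsumed(ix, flu_att, flu))
  expect_false(is_subsumed(ix, flu, flu_att))
  # causal link + chains make pathogen- and disease-based targets equivalent
  expect_true(is_subsumed(ix, ce_some("immunizes-against", "HPV"),
                          ce_some("immunizes-against", "Cervical-cancer")))
  expect_true(is_subsumed(ix,
    ce_and("Vaccine", ce_some("immunizes-against", "Cervical-cancer")),
    ce_and("Vaccine", ce_some("immunizes-against", "HPV"))))
  # unrelated fillers are not subsumed
  expect_false(is_subsumed(ix, ce_some("immunizes-against", "Influenza"),
                           ce_some("immunizes-against", "Tuberculosis")))
  # filler generalization: a specific disease filler implies the category
  expect_true(is_subsumed(ix, flu, ce_some("immunizes-against", "Disease")))
})

test_that("unknown identifiers raise lookup errors naming them", {
  ix <- classify(mini_vacco())
  expect_error(is_subsumed(ix, "Nonesuch", "Vaccine"), "Nonesuch")
  expect_error(entailed_fillers(ix, "Vaccine", "no-such-property"),
               "no-such-property")
})

test_that("entailed fillers match the worked normalization examples", {
  ix <- classify(mini_vacco())
  expect_setequal(entailed_fillers(ix, "DTwP", "immunizes-against"),
                  c("Diphtheria", "Tetanus", "Pertussis"))
  expect_equal(entailed_fillers(ix, "DTwP", "has-strategy"), "Inactivated")
  # nothing is entailed for a bare category
  expect_length(entailed_fillers(ix, "Vaccine", "has-route"), 0)
  # root exclusion: with exclude_roots = FALSE the category appears
  with_roots <- entailed_fillers(ix, "DTwP", "immunizes-against",
                                 exclude_roots = FALSE)
  expect_true("Disease" %in% with_roots)
})

test_that("classification agrees with the naive fixpoint oracle", {
  for (seed in 1:40) {
    ont <- random_ontology(seed)
    expect_true(isTRUE(agrees_with_oracle(ont)),
                info = paste("seed", seed))
  }
})

test_that("adding an axiom never removes an entailment (monotonicity)", {
  for (seed in c(3, 11, 27)) {
    ont <- random_ontology(seed)
    before <- entailments(classify(ont))
    ont2 <- add_assertion(ont, ont$classes$id[1], ont$properties$id[1],
                          ont$classes$id[nrow(ont$classes)])
    after <- entailments(classify(ont2))
    k_before <- paste(before$subject, before$property, before$filler)
    k_after <- paste(after$subject, after$property, after$filler)
    expect_true(all(k_before %in% k_after), info = paste("seed", seed))
  }
})

test_that("every instantiated chain premise yields its conclusion", {
  for (seed in c(18, 33, 35)) {
    ont <- random_ontology(seed)
    ix <- classify(ont)
    R <- entailments(ix)
    for (k in seq_len(nrow(ont$chains))) {
      a <- R[R$property == ont$chains$p1[k], , drop = FALSE]
      b <- R[R$property == ont$chains$p2[k], , drop = FALSE]
      if (!nrow(a) || !nrow(b)) next
      m <- merge(a, b, by.x = "filler", by.y = "subject")
      for (i in seq_len(nrow(m))) {
        expect_true(is_subsumed(ix, m$subject[i],
                                ce_some(ont$chains$rhs[k], m$filler.y[i])),
                    info = paste("seed", seed, "chain", k))
      }
    }
  }
})
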