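ont <- mini_vacco()
ix <- classify(ont)
dic <- build_dictionary(ont)

test_that("classes compile according to their fundamental category", {
  expect_equal(format(compile_class("Tuberculosis", ont)),
               "Vaccine and (immunizes-against some Tuberculosis)")
  expect_equal(format(compile_class("M-tuberculosis", ont)),
               "Vaccine and (immunizes-against some M-tuberculosis)")
  expect_equal(format(compile_class("Inactivated", ont)),
               "Vaccine and (has-strategy some Inactivated)")
  expect_equal(format(compile_class("HAV-antigen", ont)),
               "Vaccine and (has-ingredient some HAV-antigen)")
  expect_equal(format(compile_class("Valence-3", ont)),
               "Vaccine and (has-valence some Valence-3)")
  expect_equal(format(compile_class("Oral-route", ont)),
               "Vaccine and (has-route some Oral-route)")
  # a vaccine class stands for itself
  expect_equal(format(compile_class("Influvac", ont)), "Influvac")
  expect_error(compile_class("Nonesuch", ont), "Nonesuch")
})

test_that("sets compile to deduplicated conjunctions; empty set is flagged", {
  e <- compile_set(c("Influenza", "Live-attenuated"), ont)
  expect_equal(format(e),
    paste("Vaccine and (immunizes-against some Influenza)",
          "and (has-strategy some Live-attenuated)"))
  expect_false(attr(e, "uninformative"))
  expect_equal(format(compile_set("Tuberculosis", ont)),
               format(compile_class("Tuberculosis", ont)))
  empty <- compile_set(character(0), ont)
  expect_equal(format(empty), "Vaccine")
  expect_true(attr(empty, "uninformative"))
})

test_that("V(t) reproduces the worked compilation example from raw text", {
  v <- vaccine_class("Live/attenuated influenza vaccine", ont, dic)
  expect_equal(format(v),
    paste("Vaccine and (immunizes-against some Influenza)",
          "and (has-strategy some Live-attenuated)"))
  expect_setequal(attr(v, "classes"), c("Influenza", "Live-attenuated"))
  expect_true(attr(vaccine_class("xyzzy", ont, dic), "uninformative"))
})

test_that("property values reproduce the worked normalization examples", {
  pv <- property_values("DTwP", ix, dic)
  expect_setequal(pv[["immunizes-against"]],
                  c("Diphtheria", "Tetanus", "Pertussis"))
  expect_equal(pv[["has-strategy"]], "Inactivated")
  expect_length(pv[["has-ingredient"]], 0)
  expect_length(pv[["has-valence"]], 0)
  expect_length(pv[["has-route"]], 0)

  # pathogen-, disease-, abbreviation- and product-based descriptors
  # normalize to the same immunization target
  for (d in c("Influenza virus vaccine", "Flu vaccine", "IIV3", "Influvac")) {
    expect_equal(property_values(d, ix, dic)[["immunizes-against"]],
                 "Influenza", info = d)
  }

  un <- property_values("no recognizable words", ix, dic)
  expect_true(attr(un, "uninformative"))
  expect_true(all(lengths(un) == 0))
})

test_that("equivalent expressions have identical property values", {
  a <- vaccine_class("Vaccine against cervical cancer", ont, dic)
  b <- vaccine_class("Human papillomavirus vaccine", ont, dic)
  expect_true(is_subsumed(ix, a, b))
  expect_true(is_subsumed(ix, b, a))
  expect_identical(unclass(property_values(a, ix))[TRUE],
                   unclass(property_values(b, ix))[TRUE])
})

test_that("adding identified classes only ever adds property values", {
  base <- c("Influenza")
  richer <- c("Influenza", "Inactivated", "Valence-3")
  pv1 <- property_values(compile_set(base, ont), ix)
  pv2 <- property_values(compile_set(richer, ont), ix)
  for (p in names(pv1)) {
    expect_true(all(pv1[[p]] %in% pv2[[p]]), info = p)
  }
})

test_that("every compiled set is subsumed by the vaccine category", {
  sets <- list("Influenza", c("HPV", "Inactivated"), "Havrix",
               c("Tetanus", "Oral-route", "Valence-2"), character(0))
  for (s in sets) {
    expect_true(is_subsumed(ix, compile_set(s, ont), "Vaccine"))
  }
})
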