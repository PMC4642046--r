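test_that("generation is deterministic given the seed", {
  spec <- generator_spec(n_documents = 5, seed = 99, nesting_rate = 0.3,
                         shared_trigger_rate = 0.3, equiv_rate = 0.3,
                         site_rate = 0.5, negation_rate = 0.2)
  a <- generate_corpus(spec)
  b <- generate_corpus(spec)
  expect_identical(write_interaction_xml(a$corpus),
                   write_interaction_xml(b$corpus))
  expect_identical(lapply(a$st_documents, write_st_document),
                   lapply(b$st_documents, write_st_document))
  expect_identical(a$manifest, b$manifest)
  # a different seed changes the corpus
  c2 <- generate_corpus(generator_spec(n_documents = 5, seed = 100))
  expect_false(identical(write_interaction_xml(a$corpus),
                         write_interaction_xml(c2$corpus)))
})

test_that("manifest counts equal realized counts (self-audit)", {
  g <- gen_corpus(10, seed = 105, shared_trigger_rate = 1, equiv_rate = 0,
                  nesting_rate = 0, site_rate = 0)
  sentences <- gather_sentences(g$corpus)
  mem <- dplyr::bind_rows(lapply(sentences, function(s) s$events))
  shared <- sum(table(mem$trigger) > 1)
  expect_equal(g$manifest[["shared_triggers"]], shared)
  expect_gt(shared, 0)
  expect_equal(g$manifest[["events"]], nrow(mem))
  expect_equal(g$manifest[["documents"]], length(g$corpus$documents))
  # equivalence groups counted exactly
  g2 <- gen_corpus(10, seed = 106, equiv_rate = 1)
  n_groups <- sum(vapply(g2$corpus$documents, function(d)
    length(d$equivs), integer(1)))
  expect_equal(g2$manifest[["equiv_groups"]], n_groups)
  expect_gt(n_groups, 0)
  # negations counted exactly
  g3 <- gen_corpus(10, seed = 107, negation_rate = 1)
  ents <- dplyr::bind_rows(lapply(gather_sentences(g3$corpus),
                                  function(s) s$entities))
  expect_equal(g3$manifest[["negations"]], sum(ents$negation))
  expect_gt(sum(ents$negation), 0)
})

test_that("unsatisfiable generator settings raise a specification error", {
  no_events <- annotation_scheme(entity_types = "Protein")
  expect_error(generate_corpus(generator_spec(scheme = no_events)),
               "specification error")
  # nesting requested against a scheme with no event-valued arguments
  flat <- annotation_scheme(
    entity_types = "Protein",
    events = tibble::tibble(
      type = "X", overall_min = 1L, overall_max = 1L,
      arguments = list(bioevex:::arg_constraint("Theme", 1, 1, "Protein"))),
    targets = list(entities = "X", interactions = "Theme"))
  expect_error(generate_corpus(generator_spec(scheme = flat,
                                              nesting_rate = 0.5)),
               "specification error")
  expect_no_error(generate_corpus(generator_spec(scheme = flat,
                                                 n_documents = 2,
                                                 nesting_rate = 0)))
  expect_error(generator_spec(equiv_rate = 1.2), "\\[0,1\\]")
})

test_that("every generated corpus is valid and repair-clean", {
  for (seed in c(108, 109)) {
    g <- gen_corpus(6, seed = seed, nesting_rate = 0.3,
                    shared_trigger_rate = 0.3, equiv_rate = 0.3,
                    site_rate = 0.5, cross_sentence_rate = 0.2,
                    sentences_per_document = 3)
    expect_equal(nrow(validate_graph(g$corpus)), 0)
    sc <- learn_scheme(g$corpus)
    for (d in g$st_documents) expect_true(st_is_valid(d, sc))
  }
})

test_that("saturated generation recovers the generating scheme", {
  sc <- random_scheme(42)
  g <- generate_corpus(generator_spec(scheme = sc, saturate = TRUE,
                                      seed = 1))
  expect_identical(serialize_scheme(learn_scheme(g$corpus)),
                   serialize_scheme(sc))
})

test_that("perturbations hit their stated counts", {
  g <- gen_corpus(8, seed = 110, site_rate = 0.5)
  pert <- perturb_predictions(
    g$st_documents,
    errors = list(invalid_role = 2, duplicate_event = 2),
    scheme = g$scheme)
  expect_equal(sum(pert$applied$op == "invalid_role"), 2)
  expect_equal(sum(pert$applied$op == "duplicate_event"), 2)
  expect_error(perturb_predictions(g$st_documents,
                                   errors = list(bogus_op = 1)),
               "unknown perturbation")
})
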