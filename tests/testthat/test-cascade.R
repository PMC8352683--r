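# Full 3x3x3 disjoint dataset shared across cascade tests (cached per run).
cascade_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- preset_disjoint(seed = 11)
      tp <- generate_taxonomy(cfg)
      cache <<- list(config = cfg, taxonomy = tp$taxonomy,
                     profiles = tp$profiles,
                     records = generate_records(tp$taxonomy, tp$profiles, cfg))
    }
    cache
  }
})

test_that("a 3x3x3 dataset trains one main, three subclass and nine disease nodes", {
  fx <- cascade_fixture()
  model <- train_cascade(fx$records, fx$taxonomy, "svm", cascade_config(seed = 1))
  expect_identical(length(model$subclass_models), 3L)
  expect_identical(length(model$disease_models), 9L)
  gl <- glance(model)
  expect_identical(gl$n_passthrough, 0L)
  expect_identical(nrow(tidy(model)), 13L)
})

test_that("records from a single category cannot train the main level", {
  fx <- cascade_fixture()
  anc <- symtriage:::code_ancestry(fx$taxonomy, fx$records$disease)
  one_cat <- fx$records[anc$main_code == anc$main_code[1], ]
  expect_error(train_cascade(one_cat, fx$taxonomy, "svm"),
               "fewer than two populated categories")
})

test_that("single-child nodes become pass-throughs, not models", {
  fx <- cascade_fixture()
  anc <- symtriage:::code_ancestry(fx$taxonomy, fx$records$disease)
  # keep only one subclass within the first category
  keep <- anc$main_code != anc$main_code[1] |
    anc$subclass_code == anc$subclass_code[1]
  model <- train_cascade(fx$records[keep, ], fx$taxonomy, "svm",
                         cascade_config(seed = 1))
  first_cat <- as.character(anc$main_code[1])
  expect_s3_class(model$subclass_models[[first_cat]], "passthrough_node")
  expect_gt(length(model$notes), 0)
  # the pass-through still routes probes to its only child
  dg <- diagnose(model, fx$records[1, , drop = FALSE])
  expect_identical(dg$subclass_code, anc$subclass_code[1])
})

test_that("noise-free disjoint profiles are diagnosed along the full path", {
  fx <- cascade_fixture()
  cfg <- cascade_config(seed = 5)
  for (backend in c("nn", "svm")) {
    model <- train_cascade(fx$records, fx$taxonomy, backend, cfg)
    dg <- diagnose(model, fx$records)
    expect_true(all(dg$disease_code == fx$records$disease),
                label = paste(backend, "full-path resubstitution"))
    # hierarchical consistency of every emitted path
    for (i in seq_len(nrow(dg))) {
      d <- decode_code(fx$taxonomy, dg$disease_code[i])
      expect_identical(d$ancestors, c(dg$main_code[i], dg$subclass_code[i]))
    }
  }
})

test_that("both back-ends agree on noise-free disjoint probes", {
  fx <- cascade_fixture()
  cfg <- cascade_config(seed = 5)
  nn <- diagnose(train_cascade(fx$records, fx$taxonomy, "nn", cfg), fx$records)
  svm <- diagnose(train_cascade(fx$records, fx$taxonomy, "svm", cfg), fx$records)
  expect_identical(nn$disease_code, svm$disease_code)
})

test_that("training and diagnosis are deterministic given the seed", {
  fx <- cascade_fixture()
  probes <- fx$records[seq(1, nrow(fx$records), by = 9), ]
  d1 <- diagnose(train_cascade(fx$records, fx$taxonomy, "nn",
                               cascade_config(seed = 7)), probes)
  d2 <- diagnose(train_cascade(fx$records, fx$taxonomy, "nn",
                               cascade_config(seed = 7)), probes)
  expect_identical(d1$disease_code, d2$disease_code)
  expect_equal(d1$main_scores, d2$main_scores, tolerance = 0)
})

test_that("a non-firing sequential main plane leaves all levels absent", {
  fx <- cascade_fixture()
  cfg <- cascade_config(seed = 2, svm_mode = "sequential")
  model <- train_cascade(fx$records, fx$taxonomy, "svm", cfg)
  # an all-zero symptom vector lies outside every category's member region
  probe <- matrix(0, 1, length(fx$taxonomy$symptom_names))
  dg <- diagnose(model, probe)
  if (is.na(dg$main_code)) {
    expect_true(is.na(dg$subclass_code))
    expect_true(is.na(dg$disease_code))
  } else {
    succeed("main plane fired on the null probe; propagation not exercised")
  }
})

test_that("diagnosis can condition on a given (true) parent", {
  fx <- cascade_fixture()
  cfg <- cascade_config(seed = 3, conditioning = "given")
  model <- train_cascade(fx$records, fx$taxonomy, "svm", cfg)
  expect_error(diagnose(model, as.matrix(fx$records[1:2, fx$taxonomy$symptom_names])),
               "requires a `disease` column")
  dg <- diagnose(model, fx$records)
  expect_true(all(dg$disease_code == fx$records$disease))
})

test_that("cascade JSON persistence round-trips diagnoses", {
  fx <- cascade_fixture()
  model <- train_cascade(fx$records, fx$taxonomy, "svm", cascade_config(seed = 4))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_identical(diagnose(back, fx$records)$disease_code,
                   diagnose(model, fx$records)$disease_code)
})

test_that("concurrence combinations train as composite classes", {
  fx <- cascade_fixture()
  subs <- taxonomy_codes(fx$taxonomy)
  subs <- subs$code[subs$level == "subclass"]
  combos <- list(pair_a = subs[c(1, 4)], pair_b = subs[c(1, 7)],
                 pair_c = subs[c(4, 7)])
  crec <- generate_concurrence_records(fx$taxonomy, fx$profiles, combos,
                                       fx$config)
  expect_identical(sort(unique(crec$combo)), sort(names(combos)))
  model <- train_concurrence(crec, fx$taxonomy, combos, "svm",
                             cascade_config(seed = 6))
  dg <- diagnose_concurrence(model, crec)
  # noise-free unions of disjoint profiles are perfectly identifiable
  expect_true(all(dg$combo == crec$combo))
  expect_identical(dg$member_codes[[1]], combos[[dg$combo[1]]])

  # a triple-combination task trains a 3-class model over 3-sets
  triples <- list(t1 = subs[c(1, 4, 7)], t2 = subs[c(2, 5, 8)],
                  t3 = subs[c(3, 6, 9)])
  trec <- generate_concurrence_records(fx$taxonomy, fx$profiles, triples,
                                       fx$config)
  tmodel <- train_concurrence(trec, fx$taxonomy, triples, "nn",
                              cascade_config(seed = 6, epochs = 120))
  expect_identical(sort(tmodel$model$classes), sort(names(triples)))
  expect_true(all(lengths(tmodel$combos) == 3L))
})

test_that("concurrence labels must be declared", {
  fx <- cascade_fixture()
  subs <- taxonomy_codes(fx$taxonomy)
  subs <- subs$code[subs$level == "subclass"]
  combos <- list(pair_a = subs[c(1, 4)], pair_b = subs[c(2, 5)])
  crec <- generate_concurrence_records(fx$taxonomy, fx$profiles, combos,
                                       fx$config)
  crec$combo[1] <- "undeclared"
  expect_error(train_concurrence(crec, fx$taxonomy, combos, "svm"),
               "not declared")
  expect_error(train_concurrence(crec, fx$taxonomy,
                                 list(only = subs[c(1, 2)]), "svm"),
               "at least two")
  expect_error(symtriage:::validate_combos(fx$taxonomy,
                                           list(bad = c(subs[1], 101))),
               "mixes taxonomy levels")
})
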