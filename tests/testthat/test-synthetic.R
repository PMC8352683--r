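test_that("generator configuration is validated", {
  expect_error(generator_config(flip_noise = 1.5), "\\[0, 1\\]")
  expect_error(generator_config(T_bj = c(5, 10)), "at most 9")
  expect_error(generator_config(profile_size = c(8, 45), n_symptoms = 40),
               "exceed")
  expect_error(generator_config(global_disjoint = TRUE, overlap = 0.4),
               "overlap = 0")
  expect_error(generator_config(T_b = c(4, 2)), "range")
})

test_that("a fixed-shape taxonomy has the expected node counts", {
  cfg <- generator_config(B = 3, T_b = 3, T_bj = 3, n_symptoms = 40,
                          profile_size = c(2, 3), overlap = 0, seed = 1)
  tp <- generate_taxonomy(cfg)
  nodes <- taxonomy_codes(tp$taxonomy)
  expect_identical(sum(nodes$level == "disease"), 27L)
  expect_identical(nrow(nodes), 39L)  # 3 + 9 + 27
  expect_identical(length(tp$profiles), 27L)
})

test_that("taxonomy generation is deterministic per seed", {
  cfg <- preset_reference(seed = 77)
  t1 <- generate_taxonomy(cfg)
  t2 <- generate_taxonomy(cfg)
  expect_identical(taxonomy_codes(t1$taxonomy), taxonomy_codes(t2$taxonomy))
  expect_identical(t1$profiles, t2$profiles)
  r1 <- generate_records(t1$taxonomy, t1$profiles, cfg)
  r2 <- generate_records(t2$taxonomy, t2$profiles, cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("zero overlap makes sibling profiles disjoint; positive overlap shares a core", {
  cfg0 <- generator_config(overlap = 0, seed = 5)
  tp0 <- generate_taxonomy(cfg0)
  nodes <- taxonomy_codes(tp0$taxonomy)
  by_parent <- split(nodes$code[nodes$level == "disease"],
                     nodes$parent_code[nodes$level == "disease"])
  for (sibs in by_parent) {
    if (length(sibs) < 2) next
    profs <- lapply(as.character(sibs), function(cd) tp0$profiles[[cd]])
    expect_identical(anyDuplicated(unlist(profs)), 0L)
  }
  cfg4 <- generator_config(overlap = 0.9, seed = 5)
  tp4 <- generate_taxonomy(cfg4)
  nodes4 <- taxonomy_codes(tp4$taxonomy)
  by_parent4 <- split(nodes4$code[nodes4$level == "disease"],
                      nodes4$parent_code[nodes4$level == "disease"])
  shared <- vapply(by_parent4, function(sibs) {
    if (length(sibs) < 2) return(NA_integer_)
    length(Reduce(intersect,
                  lapply(as.character(sibs), function(cd) tp4$profiles[[cd]])))
  }, integer(1))
  expect_true(any(stats::na.omit(shared) > 0))
})

test_that("profiles never contain the gender pseudo-symptom", {
  tp <- generate_taxonomy(preset_reference(seed = 9))
  expect_true(all(vapply(tp$profiles, function(p) all(p >= 2), logical(1))))
})

test_that("noise-free records repeat the profile pattern exactly", {
  dat <- small_disjoint_data(seed = 41)
  for (cd in unique(dat$records$disease)) {
    rows <- dat$records[dat$records$disease == cd, dat$taxonomy$symptom_names]
    somatic <- as.matrix(rows)[, -1, drop = FALSE]
    expect_true(all(apply(somatic, 2, function(col) length(unique(col)) == 1)))
    on <- which(colMeans(as.matrix(rows)) == 1)
    expect_identical(sort(setdiff(on, 1L)),
                     as.integer(dat$profiles[[as.character(cd)]]))
  }
  # and the ground-truth profiles are recoverable exactly
  rec <- recover_profiles(dat$records, dat$taxonomy)
  for (cd in names(rec)) {
    expect_identical(rec[[cd]],
                     as.integer(sort(dat$profiles[[cd]])))
  }
})

test_that("flip noise matches its binomial expectations", {
  cfg <- generator_config(B = 1, T_b = 1, T_bj = 2, n_symptoms = 30,
                          profile_size = c(4, 4), overlap = 0,
                          flip_noise = 0.5, gender_bias = 0.5,
                          n_per_disease = 400, seed = 55)
  tp <- generate_taxonomy(cfg)
  rec <- generate_records(tp$taxonomy, tp$profiles, cfg)
  n_som <- cfg$n_symptoms - 1
  for (cd in unique(rec$disease)) {
    X <- as.matrix(rec[rec$disease == cd, tp$taxonomy$symptom_names])[, -1]
    prof <- matrix(0, 1, n_som)
    prof[tp$profiles[[as.character(cd)]] - 1] <- 1
    hamming <- rowSums(abs(X - prof[rep(1, nrow(X)), ]))
    # Binomial(n_som, 0.5): mean 14.5, sd ~2.69; 3 sigma band on the mean
    expect_lt(abs(mean(hamming) - n_som * 0.5),
              3 * sqrt(n_som * 0.25 / nrow(X)))
  }
  # expected number of set flags: s(1-p) + (n-s)p
  cfg2 <- generator_config(B = 1, T_b = 1, T_bj = 2, n_symptoms = 30,
                           profile_size = c(4, 4), overlap = 0,
                           flip_noise = 0.1, gender_bias = 0.5,
                           n_per_disease = 400, seed = 56)
  tp2 <- generate_taxonomy(cfg2)
  rec2 <- generate_records(tp2$taxonomy, tp2$profiles, cfg2)
  s <- 4
  expected <- s * 0.9 + (n_som - s) * 0.1
  got <- mean(rowSums(as.matrix(rec2[tp2$taxonomy$symptom_names])[, -1]))
  var_one <- s * 0.9 * 0.1 + (n_som - s) * 0.1 * 0.9
  expect_lt(abs(got - expected), 3 * sqrt(var_one / nrow(rec2)))
})

test_that("concurrence unions of disjoint profiles add their sizes", {
  dat <- small_disjoint_data(seed = 61)
  dis <- taxonomy_codes(dat$taxonomy)
  dis <- dis$code[dis$level == "disease"]
  combos <- list(ab = dis[c(1, 5)], cd = dis[c(2, 6)])
  crec <- generate_concurrence_records(dat$taxonomy, dat$profiles, combos,
                                       dat$config)
  sizes <- rowSums(as.matrix(crec[dat$taxonomy$symptom_names])[, -1])
  want <- vapply(crec$combo, function(nm) {
    sum(lengths(dat$profiles[as.character(combos[[nm]])]))
  }, numeric(1))
  expect_identical(unname(sizes), unname(want))
  # identical unions at zero noise are flagged as confusable
  expect_warning(
    generate_concurrence_records(dat$taxonomy, dat$profiles,
                                 list(a = dis[c(1, 5)], b = dis[c(5, 1)]),
                                 dat$config),
    "confusable")
})

test_that("classification difficulty grows with flip noise", {
  accs <- vapply(c(0.02, 0.15, 0.35), function(p) {
    a <- vapply(1:3, function(s) {
      cfg <- small_disjoint_config(seed = 100 + s, flip_noise = p,
                                   global_disjoint = FALSE,
                                   profile_size = c(3, 3), n_per_disease = 8)
      tp <- generate_taxonomy(cfg)
      rec <- generate_records(tp$taxonomy, tp$profiles, cfg)
      loocv(rec, tp$taxonomy, "svm", level = "disease",
            config = cascade_config(seed = s))$accuracy
    }, numeric(1))
    mean(a)
  }, numeric(1))
  expect_true(accs[1] >= accs[2] && accs[2] >= accs[3])
})

test_that("the worked-example fixture carries the documented record", {
  fx <- worked_example_fixture()
  expect_identical(unname(unlist(fx$record[fx$taxonomy$symptom_names])),
                   c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L))
  expect_identical(fx$record$disease, 10111L)
  expect_identical(length(fx$taxonomy$symptom_names), 11L)
})
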