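# Synthetic cohort generator: planted shells, class profiles, demographics,
# determinism, and the train/validation/test split rules.

test_that("zero-noise cases are exactly piecewise constant at the profile means", {
  spec <- cohort_spec(n_gb = 1, n_sbm = 1, grid_shape = c(32, 32, 32),
                      tumor_radius_range = c(6, 10), noise_sd = 0)
  gb <- generate_case(spec, "GB", seed = 3)
  prof <- default_class_profiles()
  margin_icvf <- prof$mean[prof$diagnosis == "GB" & prof$shell == "margin" &
                           prof$map == "ICVF"]
  expect_true(all(gb$maps$ICVF[gb$truth_labels == 2] == margin_icvf))
  # every shell of every map is a single constant
  for (m in names(gb$maps)) for (s in 1:3)
    expect_length(unique(gb$maps[[m]][gb$truth_labels == s]), 1)
})

test_that("margin contrasts follow the configured class profiles", {
  spec <- cohort_spec(n_gb = 1, n_sbm = 1, grid_shape = c(32, 32, 32),
                      tumor_radius_range = c(6, 10), noise_sd = 0)
  gb <- generate_case(spec, "GB", seed = 3)
  sbm <- generate_case(spec, "SBM", seed = 4)
  m_gb <- gb$truth_labels == 2; m_sbm <- sbm$truth_labels == 2
  expect_lt(mean(gb$maps$ISOVF[m_gb]), mean(sbm$maps$ISOVF[m_sbm]))
  expect_gt(mean(gb$maps$ODI[m_gb]), mean(sbm$maps$ODI[m_sbm]))
  expect_gt(mean(gb$maps$ICVF[m_gb]), mean(sbm$maps$ICVF[m_sbm]))
})

test_that("same spec and seed reproduce bit-identical cases and cohorts", {
  spec <- cohort_spec(n_gb = 2, n_sbm = 1, grid_shape = c(28, 28, 28),
                      tumor_radius_range = c(6, 9))
  a <- generate_case(spec, "GB", seed = 7)
  b <- generate_case(spec, "GB", seed = 7)
  expect_identical(a$maps, b$maps)
  expect_identical(a$roi, b$roi)
  expect_identical(a$truth_labels, b$truth_labels)
  ca <- generate_cohort(spec); cb <- generate_cohort(spec)
  expect_identical(ca$manifest, cb$manifest)
  expect_identical(ca$cases, cb$cases)
})

test_that("shell volume fractions match the configuration up to discretization", {
  spec <- cohort_spec(n_gb = 1, n_sbm = 0, grid_shape = c(40, 40, 40),
                      tumor_radius_range = c(10, 14))
  case <- generate_case(spec, "GB", seed = 9)
  tl <- case$truth_labels[case$roi]
  frac <- tabulate(tl, 3) / length(tl)
  expect_equal(frac, c(0.40, 0.35, 0.25), tolerance = 0.06)
})

test_that("map values stay in [0,1] and the manifest is well formed", {
  spec <- cohort_spec(n_gb = 2, n_sbm = 2, grid_shape = c(28, 28, 28),
                      tumor_radius_range = c(6, 9))
  coh <- generate_cohort(spec)
  for (cs in coh$cases) {
    for (m in cs$maps) expect_true(all(m >= 0 & m <= 1))
    expect_gt(sum(cs$roi), 0)
  }
  expect_setequal(names(coh$manifest)[1:6],
                  c("patient_id", "diagnosis", "age", "sex", "center", "split"))
  expect_equal(sum(coh$manifest$diagnosis == "GB"), 2)
})

test_that("a grid too small for the tumor errors; an empty cohort errors", {
  expect_error(generate_case(cohort_spec(grid_shape = c(10, 10, 10),
                                         tumor_radius_range = c(8, 16)), "GB"),
               "too small")
  expect_error(generate_cohort(cohort_spec(n_gb = 0, n_sbm = 0)), "empty")
})

test_that("sampled demographics converge to the configured parameters", {
  spec <- cohort_spec(n_gb = 10000, n_sbm = 0)
  ages <- vapply(seq_len(10000), function(i)
    generate_case(spec, "GB", seed = i, maps = FALSE)$age, numeric(1))
  expect_lt(abs(mean(ages) - 53.2), 0.5)
  expect_lt(abs(sd(ages) - 11.2), 0.5)
  sex <- vapply(seq_len(4000), function(i)
    generate_case(spec, "GB", seed = i, maps = FALSE)$sex, character(1))
  expect_lt(abs(mean(sex == "male") - 0.58), 0.03)
})

test_that("the 7:3 split yields ceiling-sized validation sets and fixed test center", {
  man <- data.frame(patient_id = sprintf("P%03d", 1:204),
                    diagnosis = rep(c("GB", "SBM"), c(146, 58)),
                    center = "A")
  sp <- split_cohort(man, ratio = 0.7, seed = 1)
  expect_equal(sum(sp$split == "training"), 142)
  expect_equal(sum(sp$split == "validation"), 62)

  man10 <- data.frame(patient_id = sprintf("Q%02d", 1:10),
                      diagnosis = rep(c("GB", "SBM"), c(7, 3)), center = "A")
  sp10 <- split_cohort(man10, ratio = 0.7, seed = 1)
  expect_equal(as.integer(table(sp10$split)[c("training", "validation")]), c(7L, 3L))

  manB <- rbind(man, data.frame(patient_id = sprintf("B%03d", 1:75),
                                diagnosis = rep(c("GB", "SBM"), c(50, 25)),
                                center = "B"))
  spB <- split_cohort(manB, ratio = 0.7, seed = 2)
  expect_true(all(spB$split[spB$center == "B"] == "test"))
  expect_equal(sum(spB$split == "training"), 142)
  # deterministic given seed
  expect_identical(spB, split_cohort(manB, ratio = 0.7, seed = 2))
})

test_that("stratified splitting preserves the class fraction within one case", {
  man <- data.frame(patient_id = sprintf("P%03d", 1:100),
                    diagnosis = rep(c("GB", "SBM"), c(70, 30)), center = "A")
  sp <- split_cohort(man, ratio = 0.7, seed = 3, scheme = "stratified")
  for (s in c("training", "validation")) {
    n <- sum(sp$split == s)
    gb <- sum(sp$split == s & sp$diagnosis == "GB")
    expect_lte(abs(gb - 0.7 * n), 1)
  }
  expect_error(split_cohort(data.frame(patient_id = "x"), 0.7), "diagnosis")
})
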