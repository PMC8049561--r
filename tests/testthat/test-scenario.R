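test_that("the benchmark tree has 16 sampled populations and fixed beta", {
  sc <- build_standard_tree(0.3)
  sampled <- sc$populations$label[!is.na(sc$populations$samples) &
                                   sc$populations$samples > 0]
  expect_length(sampled, 16)
  expect_setequal(sampled, as.character(0:15))
  adm <- sc$admixtures
  expect_equal(adm$proportion[adm$derived == "p14"], 0.3)
  # beta is fixed at 0.55 regardless of the alpha argument
  expect_equal(adm$proportion[adm$derived == "p15"], 0.55)
  expect_equal(build_standard_tree(0.9)$admixtures$proportion[2], 0.55)
  # population 9 splits from the recent pulse's donor lineage at gen 280
  i9 <- which(vapply(sc$splits$derived, function(d) "p9" %in% d, logical(1)))
  expect_equal(sc$splits$time[i9], 280)
  expect_true("L14b" %in% sc$splits$derived[[i9]])
  # the donor splits from the 5/6 lineage at generation 250
  i14a <- which(vapply(sc$splits$derived, function(d) "L14a" %in% d, logical(1)))
  expect_equal(sc$splits$time[i14a], 250)
  # effective sizes stay inside the human-like window
  expect_true(all(sc$populations$size >= 2.5e4 & sc$populations$size <= 8e5))
  expect_error(build_standard_tree(1.2))
})

test_that("zero-rate reference gene flow reduces to the standard tree", {
  sc0 <- build_standard_tree(0.5)
  scg <- build_reference_geneflow_tree(0.5, gamma = 0, pulse_generation = 200)
  expect_equal(nrow(scg$pulses), 0)
  expect_identical(scg$splits, sc0$splits)
  expect_identical(scg$populations, sc0$populations)
})

test_that("reference gene flow targets the lineage alive at the pulse time", {
  after <- build_reference_geneflow_tree(0.5, 0.1, pulse_generation = 200)
  expect_equal(after$pulses$recipient, "p9")
  expect_equal(after$pulses$donor, "p10")
  # at generation 350 population 9 has already merged into its ancestor
  before <- build_reference_geneflow_tree(0.5, 0.1, pulse_generation = 350)
  expect_equal(before$pulses$recipient, "R1")
})

test_that("the many-populations tree has 118 populations built from stars", {
  sc <- build_many_pops_tree()
  sampled <- sc$populations$label[!is.na(sc$populations$samples) &
                                    sc$populations$samples > 0]
  expect_length(sampled, 118)
  expect_true(all(as.character(0:15) %in% sampled))
  # the original splits are preserved as a subtree
  base <- build_standard_tree(0.5)
  expect_true(all(base$splits$ancestral %in% sc$splits$ancestral))
  # each star pair's internal split is exactly 50 generations after its
  # attachment to the host branch
  expect_equal(nrow(sc$merges), 51)
  for (i in seq_len(nrow(sc$merges))) {
    s <- sc$merges$derived[i]
    j <- which(sc$splits$ancestral == s)
    expect_equal(sc$splits$time[j], sc$merges$time[i] - 50)
  }
})

test_that("the stepping-stone scenario matches its published structure", {
  sc <- build_stepping_stone(m = 0.01)
  sampled <- sc$populations$label[!is.na(sc$populations$samples) &
                                    sc$populations$samples > 0]
  expect_length(sampled, 9)
  expect_true(all(sc$populations$size == 5000))
  expect_equal(sort(sc$splits$time), c(1000, 2000))
  # m = 0.01 with Ne 5,000 means 100 migrant lineages per generation
  expect_equal(unique(sc$migrations$rate) * 2 * 5000, 100)
  expect_equal(nrow(sc$migrations), 10)  # 5 neighbor pairs, both directions
  expect_equal(nrow(build_stepping_stone(0)$migrations), 0)
})

test_that("scenarios serialize to JSON and back without loss", {
  for (sc in list(build_standard_tree(0.37),
                  build_reference_geneflow_tree(0.5, 0.1, 200),
                  build_continuous_after_pulse(0.2, 0.001),
                  build_stepping_stone(0.01))) {
    path <- tempfile(fileext = ".json")
    write_scenario(sc, path)
    sc2 <- read_scenario(path)
    expect_equal(sc2$populations$name, sc$populations$name)
    expect_equal(sc2$populations$size, sc$populations$size)
    expect_equal(sc2$splits$time, sc$splits$time)
    expect_equal(sc2$splits$derived, sc$splits$derived)
    expect_equal(sc2$admixtures, sc$admixtures)
    expect_equal(nrow(sc2$migrations), nrow(sc$migrations))
    if (nrow(sc$migrations)) expect_equal(sc2$migrations$rate, sc$migrations$rate)
  }
})

test_that("the continuous-flow variant moves the pulse to generation 240", {
  sc <- build_continuous_after_pulse(0.5, 0.001)
  expect_equal(sc$admixtures$time[sc$admixtures$derived == "p14"], 240)
  expect_setequal(sc$migrations$donor, c("p5", "p9"))
  expect_equal(unique(sc$migrations$end), 240)
  expect_equal(nrow(build_continuous_after_pulse(0.5, 0)$migrations), 0)
})
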