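test_that("generation handles empty and complete designs", {
  cfg <- sim_preset("well_separated", n_subjects = 0, seed = 1)
  sim <- sim_generate(cfg)
  expect_equal(nrow(sim$data$subjects), 0)
  expect_equal(length(sim$truth), 0)
  tr <- truth_report(sim)
  expect_equal(sum(tr$class_counts$count), 0)

  cfg <- sim_preset("well_separated", n_subjects = 10, seed = 1,
                    missing_rate = c(self = 0, parent = 0))
  sim <- sim_generate(cfg)
  expect_equal(nrow(sim$data$records), 20)
  expect_true(all(table(sim$data$records$id) == 2))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(-1, mixing = c(0.5, 0.5), beta = matrix(0, 2, 5)),
               class = "sdqmix_config_error")
  expect_error(sim_config(10, mixing = c(0.5, 0.4), beta = matrix(0, 2, 5)),
               class = "sdqmix_config_error")
  expect_error(sim_config(10, mixing = c(0.5, 0.5), beta = matrix(0, 3, 5)),
               class = "sdqmix_config_error")
  expect_error(sim_preset("well_separated", n_subjects = 10, n_categories = 1),
               class = "sdqmix_config_error")
})

test_that("generation is bit-reproducible given the seed", {
  a <- sim_generate(sim_preset("moderate", n_subjects = 200, seed = 9))
  b <- sim_generate(sim_preset("moderate", n_subjects = 200, seed = 9))
  expect_identical(a$data$records, b$data$records)
  expect_identical(a$data$subjects, b$data$subjects)
  expect_identical(a$truth, b$truth)
  c <- sim_generate(sim_preset("moderate", n_subjects = 200, seed = 10))
  expect_false(identical(a$data$records, c$data$records))
})

test_that("class draws and record missingness match their binomial targets", {
  cfg <- sim_preset("well_separated", n_subjects = 2000, seed = 3,
                    mixing = c(0.5, 0.3, 0.2),
                    missing_rate = c(self = 0.1, parent = 0.3))
  sim <- sim_generate(cfg)
  p1 <- mean(sim$truth == 1)
  se <- sqrt(0.5 * 0.5 / 2000)
  expect_lt(abs(p1 - 0.5), 3 * se)

  tr <- truth_report(sim)
  parent_rate <- tr$informant_rates$observed_rate[tr$informant_rates$informant == "parent"]
  se_p <- sqrt(0.7 * 0.3 / 2000)
  expect_lt(abs(parent_rate - 0.7), 3 * se_p)
})

test_that("marginal category frequencies converge to the model probabilities", {
  cfg <- sim_preset("moderate", n_subjects = 50000, seed = 5,
                    missing_rate = c(self = 0, parent = 0))
  sim <- sim_generate(cfg)
  sm <- sdqmix:::score_matrix(sim$data)
  S <- length(cfg$scales)
  for (cell in list(c(cls = 1L, j = 1L, s = 1L), c(cls = 3L, j = 2L, s = 5L))) {
    idx <- which(sim$truth == cell[["cls"]])
    x <- sm[idx, (cell[["j"]] - 1L) * S + cell[["s"]]]
    emp <- tabulate(x + 1L, nbins = cfg$n_categories) / length(x)
    p <- category_probs(sim$params_true, cell[["cls"]], cell[["j"]], cell[["s"]])
    expect_lt(max(abs(emp - p)), 0.01)
  }
})

test_that("post-hoc random deletion matches built-in missingness distributionally", {
  n <- 20000
  full <- sim_generate(sim_preset("moderate", n_subjects = n, seed = 21,
                                  missing_rate = c(self = 0, parent = 0)))
  built_in <- sim_generate(sim_preset("moderate", n_subjects = n, seed = 22,
                                      missing_rate = c(self = 0, parent = 0.3)))
  set.seed(23)
  rec <- full$data$records
  is_parent <- rec$informant == "parent"
  drop <- is_parent & runif(nrow(rec)) < 0.3
  thinned <- sdq_data(full$data$subjects, rec[!drop, , drop = FALSE])

  rate_thin <- sum(thinned$records$informant == "parent") / n
  rate_built <- sum(built_in$data$records$informant == "parent") / n
  expect_lt(abs(rate_thin - rate_built), 3 * sqrt(2 * 0.7 * 0.3 / n))
  m_thin <- mean(thinned$records$emotional[thinned$records$informant == "parent"])
  m_built <- mean(built_in$data$records$emotional[built_in$data$records$informant == "parent"])
  expect_lt(abs(m_thin - m_built), 0.15)
})

test_that("the covariate-dependent missingness hook is honoured", {
  cfg <- sim_preset("well_separated", n_subjects = 4000, seed = 13,
                    missing_model = function(subjects, informant) {
                      if (informant == "parent") {
                        ifelse(!is.na(subjects$setting) & subjects$setting == "community",
                               0.5, 0.05)
                      } else {
                        rep(0, nrow(subjects))
                      }
                    })
  sim <- sim_generate(cfg)
  has_parent <- sim$data$subjects$id %in%
    sim$data$records$id[sim$data$records$informant == "parent"]
  comm <- sim$data$subjects$setting == "community"
  expect_lt(mean(has_parent[comm]), 0.58)
  expect_gt(mean(has_parent[!comm]), 0.90)
  expect_true(all(has_parent | !has_parent))  # self records always present
  expect_equal(sum(sim$data$records$informant == "self"), 4000)
})

test_that("truth_report summarizes counts, rates and group distributions", {
  sim <- sim_generate(sim_preset("well_separated", n_subjects = 500, seed = 2))
  tr <- truth_report(sim)
  expect_equal(sum(tr$class_counts$count), 500)
  expect_equal(tr$class_counts$count, tabulate(sim$truth, 3))
  expect_true(all(abs(rowSums(tr$by_setting[, paste0("class", 1:3)]) - 1) < 1e-12))
  expect_setequal(tr$by_setting$group, c("community", "CASC", "CAMH"))
  # implied P(class | setting) from the design: community is dominated by class 1
  imp <- tr$implied_by_setting
  expect_gt(imp$class1[imp$group == "community"], 0.7)
  expect_true(all(abs(rowSums(imp[, paste0("class", 1:3)]) - 1) < 1e-12))
})
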