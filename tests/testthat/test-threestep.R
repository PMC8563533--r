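test_that("modal assignment takes the argmax with ties to the lowest index", {
  W <- rbind(c(0.2, 0.8), c(0.5, 0.5), c(0.7, 0.3))
  expect_equal(modal_assign(W), c(2L, 1L, 1L))
  expect_equal(modal_assign(matrix(numeric(0), 0, 2)), integer(0))
})

test_that("the classification error matrix matches its hand-computed example", {
  # perfect separation -> identity
  W <- rbind(c(1, 0), c(0, 1), c(1, 0))
  expect_equal(error_matrix(W, modal_assign(W)), diag(2))

  # hand computation: D[c, w] = sum_i p_i(c) 1[w_i = w] / sum_i p_i(c)
  W <- rbind(c(0.8, 0.2), c(0.3, 0.7))
  D <- error_matrix(W, c(1L, 2L))
  expect_equal(D, rbind(c(0.8 / 1.1, 0.3 / 1.1), c(0.2 / 0.9, 0.7 / 0.9)),
               tolerance = 1e-12)
  expect_equal(rowSums(D), c(1, 1), tolerance = 1e-12)

  set.seed(3)
  g <- matrix(rgamma(30 * 3, 1), 30, 3)
  W <- g / rowSums(g)
  D <- error_matrix(W, modal_assign(W))
  expect_equal(rowSums(D), rep(1, 3), tolerance = 1e-12)
  expect_warning(error_matrix(rbind(c(1, 0), c(1, 0)), c(1L, 1L)),
                 "zero posterior mass")
})

test_that("with an identity error matrix the correction reduces to counting", {
  assignments <- c(rep(1L, 6), rep(2L, 4))
  groups <- rep("g", 10)
  dist <- adjusted_distribution(assignments, diag(2), groups)
  expect_equal(unname(dist$theta["g", ]), c(0.6, 0.4))
  expect_equal(unname(dist$n_g["g"]), 10L)
  # NA groups are excluded and counted
  dist2 <- adjusted_distribution(c(assignments, 1L), diag(2), c(groups, NA))
  expect_equal(unname(dist2$theta["g", ]), c(0.6, 0.4))
  expect_equal(dist2$excluded, 1L)
  expect_error(adjusted_distribution(assignments, matrix(c(1, 1, 0, 1), 2), groups),
               class = "sdqmix_config_error")
})

test_that("the K=2 corrected estimate matches a 1-D grid-search oracle", {
  D <- rbind(c(0.9, 0.1), c(0.4, 0.6))
  # corner case: everyone assigned class 1 -> theta at the simplex corner
  asg <- rep(1L, 50)
  dist <- adjusted_distribution(asg, D, rep("g", 50))
  expect_equal(unname(dist$theta["g", ]), c(1, 0), tolerance = 1e-6)
  expect_equal(grid_theta_k2(asg, D), 1)

  # interior cases across several assignment mixes
  set.seed(14)
  for (r in 1:8) {
    D <- rbind(c(runif(1, 0.6, 0.95), 0), c(runif(1, 0.05, 0.45), 0))
    D[, 2] <- 1 - D[, 1]
    asg <- sample(1:2, 200, replace = TRUE, prob = runif(2, 0.2, 0.8))
    est <- adjusted_distribution(asg, D, rep("g", 200))$theta["g", 1]
    expect_lt(abs(est - grid_theta_k2(asg, D)), 0.002)
  }
})

test_that("theta rows stay on the simplex and bootstrap SEs are returned", {
  set.seed(5)
  W <- matrix(rgamma(120 * 3, 1), 120, 3)
  W <- W / rowSums(W)
  asg <- modal_assign(W)
  D <- error_matrix(W, asg)
  groups <- sample(c("x", "y"), 120, replace = TRUE)
  dist <- adjusted_distribution(asg, D, groups, boot = 25, seed = 2)
  expect_equal(rowSums(dist$theta), c(x = 1, y = 1), tolerance = 1e-10)
  expect_true(all(dist$theta >= -1e-12))
  expect_true(all(is.finite(dist$se)))
  dist_b <- adjusted_distribution(asg, D, groups, boot = 25, seed = 2)
  expect_identical(dist$se, dist_b$se)
})

test_that("gender interaction recovers a designed male/female prevalence gap", {
  # class 1 prevalence 0.6 among males vs 0.2 among females in one group,
  # observed through a moderately noisy assignment channel
  set.seed(7)
  n <- 2000
  gender <- rep(c("male", "female"), each = n)
  truth <- c(sample(1:2, n, replace = TRUE, prob = c(0.6, 0.4)),
             sample(1:2, n, replace = TRUE, prob = c(0.2, 0.8)))
  D <- rbind(c(0.85, 0.15), c(0.2, 0.8))
  asg <- vapply(truth, function(c) sample(1:2, 1, prob = D[c, ]), 1L)
  gi <- gender_interaction(asg, D, groups = rep("care", 2 * n), gender = gender)
  d <- gi$differences
  m_est <- d$male[d$class == 1]
  f_est <- d$female[d$class == 1]
  expect_lt(abs(m_est - 0.6), 0.05)
  expect_lt(abs(f_est - 0.2), 0.05)

  # identical male/female data -> zero differences
  gi0 <- gender_interaction(rep(c(1L, 2L), 50), diag(2),
                            groups = rep("g", 100),
                            gender = rep(c("male", "female"), each = 2, length.out = 100))
  expect_true(all(gi0$differences$abs_diff < 1e-12))

  # an empty cell is flagged with no estimate
  gi_e <- gender_interaction(c(1L, 2L), diag(2), groups = c("g", "g"),
                             gender = c("male", "male"), min_cell = 5)
  cells <- gi_e$cells
  expect_true(all(cells$unstable))
  expect_equal(cells$n[cells$gender == "female"], integer(0))
})

test_that("prevalence reporting applies the gender and minimum-count rules", {
  theta <- rbind(grpA = c(0.57, 0.43), grpB = c(0.30, 0.70))
  colnames(theta) <- c("class1", "class2")
  dist <- structure(list(theta = theta, n_g = c(grpA = 150L, grpB = 99L),
                         se = NULL, excluded = 0L),
                    class = "sdqmix_groupdist")
  gi <- list(differences = data.frame(
    group = c("grpA", "grpA", "grpB", "grpB"), class = c(1, 2, 1, 2),
    male = c(0.57, 0.43, 0.30, 0.70), female = c(0.20, 0.80, 0.40, 0.60),
    abs_diff = c(0.37, 0.37, 0.10, 0.10)))
  rep1 <- report_prevalence(dist, gi, threshold_pct = 20, min_n = 100)
  # grpB suppressed (n = 99 < 100)
  expect_equal(rep1$group, "grpA")
  expect_equal(attr(rep1, "suppressed"), "grpB")
  # 37-point gender difference -> per-gender breakdown shown
  expect_equal(rep1$class1, "57 (57/20)")
  rep2 <- report_prevalence(dist, gi, threshold_pct = 20, min_n = 0)
  # 10-point difference -> suppressed gender columns
  expect_equal(rep2$class1[rep2$group == "grpB"], "30")
  tidy <- attr(rep2, "tidy")
  expect_true(tidy$reported_gender[tidy$group == "grpA" & tidy$class == 1])
  expect_false(tidy$reported_gender[tidy$group == "grpB" & tidy$class == 1])
})

test_that("diagnosis label sets map to the nominal grouping scheme", {
  d <- c("ADHD", "ADHD;CD/ODD", "CD/ODD;ADHD;Anxiety/Mood", "Dyslexia", "",
         NA, "ASD;Anxiety/Mood")
  g <- diagnosis_group(d)
  expect_equal(g, c("ADHD", "CD/ODD and ADHD", "Multi-problem", "Other",
                    "No diagnosis", NA, "Anxiety/Mood and ASD"))
  # setting restriction: only CAMH subjects are grouped
  g2 <- diagnosis_group(c("ADHD", "ADHD"), setting = c("CAMH", "community"))
  expect_equal(g2, c("ADHD", NA))
  # explicit mapping override
  g3 <- diagnosis_group("ADHD;ASD", mapping = c("ADHD;ASD" = "neurodev"))
  expect_equal(g3, "neurodev")
})
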