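test_that("class means are exact expectations, including total difficulties", {
  # uniform 11-category distribution -> mean 5; degenerate at 7 -> 7
  p_unif <- mixture_params(pi = 1, beta = array(0, c(1, 2, 5)))
  m <- class_means(p_unif)
  expect_true(all(abs(m$mean[m$scale != "total_difficulties"] - 5) < 1e-12))
  expect_true(all(abs(m$mean[m$scale == "total_difficulties"] - 20) < 1e-12))

  # hand expectation for explicit 3-category probabilities (0.2, 0.3, 0.5)
  pm <- mixture_params(pi = 1, beta = NULL, parameterization = "multinomial",
                       logp = array(log(c(0.2, 0.3, 0.5)), c(1, 1, 1, 3)),
                       scales = "emotional", informants = "self", n_categories = 3)
  m3 <- class_means(pm)
  expect_equal(m3$mean[m3$scale == "emotional"], 0.2 * 0 + 0.3 * 1 + 0.5 * 2)

  # means are permutation-equivariant
  set.seed(2)
  p <- mixture_params(pi = c(0.3, 0.7), beta = array(rnorm(20), c(2, 2, 5)))
  m1 <- class_means(p)
  m2 <- class_means(sdqmix:::permute_params(p, c(2, 1)))
  expect_equal(m2$mean[m2$class == 1], m1$mean[m1$class == 2], tolerance = 1e-12)
})

test_that("band classification honours boundaries, inclusion rule and direction", {
  cut <- example_cutoffs()
  # total difficulties boundaries (15, 19)
  expect_equal(classify_band(12, "self", "total_difficulties", cut), "normal")
  expect_equal(classify_band(15, "self", "total_difficulties", cut), "normal")  # on-boundary -> lower band
  expect_equal(classify_band(16, "self", "total_difficulties", cut), "borderline")
  expect_equal(classify_band(19, "self", "total_difficulties", cut), "borderline")
  expect_equal(classify_band(19.5, "self", "total_difficulties", cut), "abnormal")
  # prosocial is reversed: a low score is abnormal
  expect_equal(classify_band(2, "self", "prosocial", cut), "abnormal")
  expect_equal(classify_band(10, "self", "prosocial", cut), "normal")
  expect_equal(classify_band(4, "self", "prosocial", cut), "borderline")
  expect_equal(classify_band(3, "self", "prosocial", cut), "abnormal")  # on-boundary
  expect_error(classify_band(3, "self", "impact", cut), class = "sdqmix_config_error")
})

test_that("profile labels are a pure function of the band pattern", {
  scales <- c("emotional", "conduct", "hyperactivity", "social", "prosocial")
  mk <- function(self_bands, parent_bands, class = 1) {
    rbind(data.frame(class = class, informant = "self", scale = scales,
                     mean = 0, band = self_bands),
          data.frame(class = class, informant = "parent", scale = scales,
                     mean = 0, band = parent_bands))
  }
  all_norm <- rep("normal", 5)
  expect_equal(unname(label_profiles(mk(all_norm, all_norm), scales)),
               "no difficulties")
  hyper_b <- replace(all_norm, 3, "borderline")
  expect_equal(unname(label_profiles(mk(all_norm, hyper_b), scales)),
               "borderline hyperactivity difficulties")
  em_soc_a <- replace(all_norm, c(1, 4), "abnormal")
  expect_equal(unname(label_profiles(mk(em_soc_a, all_norm), scales)),
               "emotional and social difficulties")
  # >= 4 affected domains with an abnormal band -> overall
  most <- c("abnormal", "borderline", "abnormal", "abnormal", "normal")
  worst <- replace(most, 5, "borderline")
  expect_equal(unname(label_profiles(mk(most, worst), scales)),
               "overall difficulties")
  # same bands -> same label regardless of the means
  b1 <- mk(hyper_b, all_norm)
  b2 <- mk(hyper_b, all_norm)
  b2$mean <- 99
  expect_equal(label_profiles(b1, scales), label_profiles(b2, scales))
})

test_that("paired informant tests match closed forms and the Bonferroni rule", {
  scales <- c("emotional", "conduct", "hyperactivity", "social", "prosocial")
  subj <- data.frame(id = sprintf("s%d", 1:3))
  # self - parent differences on 'emotional' are (1, 2, 3); other scales equal
  rec_self <- data.frame(id = subj$id, informant = "self",
                         emotional = c(4L, 5L, 6L), conduct = 2L,
                         hyperactivity = 3L, social = 4L, prosocial = 5L)
  rec_parent <- data.frame(id = subj$id, informant = "parent",
                           emotional = c(3L, 3L, 3L), conduct = 2L,
                           hyperactivity = 3L, social = 4L, prosocial = 5L)
  d <- sdq_data(subj, rbind(rec_self, rec_parent))
  tab <- informant_tests(d, assignments = rep(1L, 3))
  emo <- tab[tab$scale == "emotional", ]
  expect_equal(emo$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(emo$df, 2)
  # identical scores -> t = 0, p = 1
  con <- tab[tab$scale == "conduct", ]
  expect_equal(con$t, 0)
  expect_equal(con$p, 1)
  expect_equal(con$p_adj, 1)
  # Bonferroni multiplier = scales tested in the cluster (5 here)
  expect_equal(emo$p_adj, min(1, emo$p * 5), tolerance = 1e-12)
  expect_true(all(tab$p_adj >= tab$p - 1e-15))
  expect_true(all(tab$p_adj <= 1))
  # p = 0.004 with multiplier 6 -> 0.024, not significant at alpha = 0.01
  expect_equal(min(1, 0.004 * 6), 0.024)
  expect_false(min(1, 0.004 * 6) < 0.01)

  # a cluster with < 2 complete pairs is skipped and flagged
  rec_one <- rbind(rec_self[1, ], rec_parent[1, ])
  d1 <- sdq_data(subj[1, , drop = FALSE], rec_one)
  tab1 <- informant_tests(d1, assignments = 1L)
  expect_true(all(tab1$skipped))
})

test_that("total-difficulties crosstab bands subjects and sums to 100 per setting", {
  sim <- sim_generate(sim_preset("well_separated", n_subjects = 800, seed = 12))
  fit <- em_fit(sim$data, K = 3, n_starts = 4, seed = 5)
  D <- error_matrix(fit$posteriors, fit$modal)
  cut <- example_cutoffs()
  tab <- crosstab_total_band(sim$data, fit$modal, D, cut, "self")
  expect_true(all(tab$band %in% c("normal", "borderline/abnormal")))
  pct <- tapply(tab$pct_within_setting, tab$setting, sum)
  expect_true(all(abs(pct - 100) < 1e-9))
  cls_cols <- grep("^class", names(tab))
  expect_true(all(abs(rowSums(tab[, cls_cols]) - 1) < 1e-9))
  # the low-severity class dominates the community 'normal' band
  norm_comm <- tab[tab$setting == "community" & tab$band == "normal", ]
  expect_gt(norm_comm$class1, 0.5)

  # score arithmetic: (3, 2, 5, 1) on the difficulties scales -> total 11 -> normal
  expect_equal(classify_band(3 + 2 + 5 + 1, "self", "total_difficulties", cut),
               "normal")
})

test_that("a self-report-only refit merges profiles that differ only by parent report", {
  # two classes separated ONLY in parent-reported scales, one clearly distinct
  beta <- rbind(c(-0.8, -0.8, -0.8, -0.8, 0.8),
                c(-0.8, -0.8, -0.8, -0.8, 0.8),
                c(0.8, 0.8, 0.8, 0.8, -0.8))
  b_arr <- array(NA_real_, c(3, 2, 5))
  b_arr[, 1, ] <- beta                       # self: classes 1 and 2 identical
  b_arr[, 2, ] <- rbind(beta[1, ], -beta[1, ], beta[3, ])  # parent separates them
  cfg <- sim_config(n_subjects = 700, mixing = c(0.4, 0.3, 0.3), beta = b_arr,
                    missing_rate = c(self = 0, parent = 0), seed = 77)
  sim <- sim_generate(cfg)
  full <- em_fit(sim$data, K = 3, n_starts = 6, seed = 9)
  cmp <- single_informant_comparison(sim$data, full, informant = "self",
                                     K_range = 1:4, n_starts = 6, seed = 9)
  expect_lt(cmp$K_single, 3)
  expect_error(
    single_informant_comparison(sim$data, full, informant = "teacher"),
    class = "sdqmix_validation_error")
})

test_that("cutoff YAML round-trips and the shipped example file loads", {
  cut <- example_cutoffs()
  path <- tempfile(fileext = ".yaml")
  write_cutoffs(cut, path)
  cut2 <- read_cutoffs(path)
  expect_equal(cut2$self$emotional$boundaries, c(5, 6))
  expect_equal(cut2$self$prosocial$direction, "low_worse")
  shipped <- system.file("extdata", "example_cutoffs.yaml", package = "sdqmix")
  expect_true(nzchar(shipped))
  cut3 <- read_cutoffs(shipped)
  expect_equal(classify_band(12, "self", "total_difficulties", cut3), "normal")
})
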