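between_design <- function(n_per_cell = 5, seed = 1) {
  set.seed(seed)
  cells <- expand.grid(level_a = c("a1", "a2"), level_b = c("b1", "b2"),
                       stringsAsFactors = FALSE)
  asg <- do.call(rbind, lapply(seq_len(4), function(i)
    data.frame(subject = character(n_per_cell), level_a = cells$level_a[i],
               level_b = cells$level_b[i])))
  asg$subject <- sprintf("s%03d", seq_len(nrow(asg)))
  design_info(assignments = asg)
}

test_that("CPD subject scores are the weighted subject-mode columns", {
  amp <- c(1, 3, 0.5, 2)
  x <- outer(outer(outer(abs(rnorm(6)) + 0.2, abs(rnorm(5)) + 0.2),
                   abs(rnorm(4)) + 0.2), amp)
  fit <- nn_cpd(x, R = 1, seed = 2)
  sc <- subject_scores_cpd(fit, 1)
  # proportional to the planted subject amplitudes
  expect_gt(cor(sc, amp), 0.99999)
  # equals the least-squares projection of each subject slice onto the
  # rank-1 basis formed by the other modes
  basis <- outer(outer(fit$factors[[1]][, 1], fit$factors[[2]][, 1]),
                 fit$factors[[3]][, 1])
  proj <- vapply(seq_len(4), function(s)
    sum(x[, , , s] * basis) / sum(basis^2), 1)
  expect_equal(unname(sc), proj, tolerance = 1e-6)
  expect_error(subject_scores_cpd(fit, 2), "out of range")
})

test_that("Tucker subject scores are core fibers under the identity factor", {
  set.seed(4)
  y <- array(rnorm(12 * 6 * 9), c(12, 6, 9))
  fit <- orthogonal_tucker(y, c(8, 6))
  expect_equal(unname(subject_scores_td(fit, 3, 2)), fit$core[3, 2, ])
  expect_equal(sqrt(sum(subject_scores_td(fit, 1, 1)^2)),
               sqrt(sum(fit$core[1, 1, ]^2)))
  # an 8 x 10 component grid yields 80 score vectors
  y2 <- array(rnorm(20 * 10 * 7), c(20, 10, 7))
  fit2 <- orthogonal_tucker(y2, c(8, 10))
  combos <- expand.grid(rt = 1:8, rc = 1:10)
  scores <- apply(combos, 1, function(z)
    subject_scores_td(fit2, z["rt"], z["rc"]))
  expect_equal(ncol(scores), 80L)
  expect_error(subject_scores_td(fit2, 9, 1), "out of range")
})

test_that("between-subjects ANOVA matches the projection oracle on random
           (including unbalanced) designs", {
  set.seed(10)
  for (i in 1:50) {
    sizes <- sample(3:8, 4, replace = TRUE)
    a <- rep(rep(c("a1", "a2"), 2), times = sizes)
    b <- rep(rep(c("b1", "b2"), each = 2), times = sizes)
    ids <- sprintf("s%03d", seq_along(a))
    design <- design_info(assignments = data.frame(subject = ids, level_a = a,
                                                   level_b = b))
    sc <- setNames(rnorm(length(a), mean = 0.3 * (a == "a1")), ids)
    got <- anova_2x2_between(sc, design)
    want <- oracle_anova_between(as.numeric(sc), a, b)
    expect_equal(got$F, c(want$main_a["F"], want$main_b["F"],
                          want$interaction["F"]),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(got$p, c(want$main_a["p"], want$main_b["p"],
                          want$interaction["p"]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("exactly equal cell patterns give zero F", {
  design <- between_design(3)
  sc <- setNames(rep(c(1, 2, 3), 4), design$assignments$subject)
  got <- anova_2x2_between(sc, design)
  expect_equal(got$F, rep(0, 3), tolerance = 1e-20)
  # smoke at the published scale: 70 subjects in 4 cells
  sizes <- c(18, 18, 17, 17)
  a <- rep(rep(c("a1", "a2"), 2), times = sizes)
  b <- rep(rep(c("b1", "b2"), each = 2), times = sizes)
  ids <- sprintf("s%03d", seq_along(a))
  d70 <- design_info(assignments = data.frame(subject = ids, level_a = a,
                                              level_b = b))
  got70 <- anova_2x2_between(setNames(rnorm(70), ids), d70)
  expect_s3_class(got70, "effect_test")
  expect_true(all(got70$F >= 0) && all(got70$p >= 0 & got70$p <= 1))
  # empty cell is a design error
  bad <- design_info(assignments = data.frame(
    subject = sprintf("s%d", 1:6),
    level_a = c("a1", "a1", "a1", "a1", "a2", "a2"),
    level_b = c("b1", "b1", "b2", "b2", "b1", "b1")))
  expect_error(anova_2x2_between(setNames(rnorm(6), sprintf("s%d", 1:6)), bad),
               "empty cell")
})

test_that("mixed ANOVA matches the classical sums-of-squares oracle", {
  set.seed(20)
  for (i in 1:50) {
    n <- sample(4:9, 1)   # subjects per between group
    subj <- sprintf("m%02d", seq_len(2 * n))
    grp <- rep(c("b1", "b2"), each = n)
    design <- design_info(scope_a = "within",
                          assignments = data.frame(subject = subj,
                                                   level_b = grp),
                          levels_a = c("a1", "a2"))
    slots <- data.frame(subject_id = rep(subj, each = 2),
                        level_a = rep(c("a1", "a2"), 2 * n),
                        level_b = rep(grp, each = 2))
    sc <- rnorm(nrow(slots), mean = 0.4 * (slots$level_a == "a1") +
                  0.2 * (slots$level_b == "b2") * (slots$level_a == "a1"))
    got <- anova_2x2_mixed(sc, design, slots)
    want <- oracle_anova_mixed(sc, slots$level_b, slots$level_a,
                               slots$subject_id)
    # factor a is within (W), factor b between (G)
    expect_equal(got$F, unname(c(want$W["F"], want$G["F"], want$GW["F"])),
                 tolerance = 1e-8)
    expect_equal(got$p, unname(c(want$W["p"], want$G["p"], want$GW["p"])),
                 tolerance = 1e-8)
  }
})

test_that("identical within-level scores give zero within-factor F", {
  n <- 18   # published group size
  subj <- sprintf("m%02d", seq_len(2 * n))
  grp <- rep(c("b1", "b2"), each = n)
  design <- design_info(scope_a = "within",
                        assignments = data.frame(subject = subj, level_b = grp),
                        levels_a = c("a1", "a2"))
  slots <- data.frame(subject_id = rep(subj, each = 2),
                      level_a = rep(c("a1", "a2"), 2 * n),
                      level_b = rep(grp, each = 2))
  base <- rnorm(2 * n)
  sc <- base[match(slots$subject_id, subj)]   # no within-level variation
  got <- anova_2x2_mixed(sc, design, slots)
  expect_equal(got$F[got$effect == "main_a"], 0, tolerance = 1e-16)
  expect_s3_class(got, "effect_test")
  # a subject missing one within level is a design error
  expect_error(anova_2x2_mixed(sc[-1], design, slots[-1, ]), "within level")
})

test_that("profile summation selects significant components and commutes", {
  mk_test <- function(pa, pb, pi) data.frame(
    effect = c("main_a", "main_b", "interaction"), F = 1, p = c(pa, pb, pi))
  comps <- lapply(1:6, function(i)
    list(temporal = sin(1:20 / i), spatial = cos(1:5 * i),
         spectral = NULL, weight = ifelse(i <= 3, 1, 0.5),
         id = sprintf("c%d", i)))
  tests <- list(mk_test(0.01, 0.2, 0.9), mk_test(0.04, 0.5, 0.9),
                mk_test(0.2, 0.6, 0.9), mk_test(0.01, 0.7, 0.9),
                mk_test(0.9, 0.8, 0.9), mk_test(0.9, 0.9, 0.9))
  prof <- select_and_sum(tests, comps, alpha = 0.05)
  expect_named(prof, "main_a")
  expect_equal(prof$main_a$n_components, 3L)
  expect_equal(prof$main_a$weighted_count, 2.5)
  expect_equal(prof$main_a$temporal_profile,
               abs(comps[[1]]$temporal) + abs(comps[[2]]$temporal) +
                 0.5 * abs(comps[[4]]$temporal))
  expect_true(all(prof$main_a$spatial_profile >= 0))
  # summation commutes with component order
  ord <- c(4, 2, 6, 1, 3, 5)
  prof2 <- select_and_sum(tests[ord], comps[ord], alpha = 0.05)
  expect_equal(prof2$main_a$temporal_profile, prof$main_a$temporal_profile)
  # a single significant component yields its own absolute vectors
  prof1 <- select_and_sum(tests[1], comps[1], alpha = 0.05)
  expect_equal(prof1$main_a$temporal_profile, abs(comps[[1]]$temporal))
  # nothing significant -> empty profile set
  expect_length(select_and_sum(tests[5:6], comps[5:6], alpha = 0.05), 0L)
})

test_that("TOI determination follows the peak and post-stimulus rules", {
  ep <- epoch_definition(2, 15, 10, fs = 10)
  bump <- function(center, sd = 1) exp(-(ep$times - center)^2 / (2 * sd^2))
  toi <- determine_toi(list(temporal_profile = bump(12)), ep$times, ep)
  expect_equal(toi$peak_time_s, 12)
  expect_equal(c(toi$start_s, toi$end_s), c(11, 13))
  # monotone profile peaking after stimulus offset -> no TOI
  expect_null(determine_toi(list(temporal_profile = exp(ep$times / 4)),
                            ep$times, ep))
  # two equal within-stimulus peaks: the earlier wins
  two <- bump(5, 0.5) + bump(10, 0.5)
  toi2 <- determine_toi(list(temporal_profile = two), ep$times, ep)
  expect_equal(toi2$peak_time_s, 5)
  # post-stimulus peak tolerated when a comparable stimulus peak exists
  mix <- bump(20, 0.5) + 0.8 * bump(8, 0.5)
  toi3 <- determine_toi(list(temporal_profile = mix), ep$times, ep)
  expect_equal(toi3$peak_time_s, 8)
  expect_null(determine_toi(list(temporal_profile = NULL), ep$times, ep))
})

test_that("ROI determination keeps channels above the prominence fraction", {
  chans <- sprintf("ch%02d", 1:5)
  prof <- list(spatial_profile = c(1, 0.2, 0.3, 0.45, 0.8))
  expect_equal(determine_roi(prof, chans), c("ch01", "ch05"))
  expect_equal(determine_roi(list(spatial_profile = rep(0.3, 5)), chans),
               chans)
  expect_equal(determine_roi(prof, chans, fraction_of_max = 0.9), "ch01")
  expect_length(determine_roi(list(spatial_profile = NULL), chans), 0L)
})

test_that("JZS Bayes factors match the noncentral-t oracle", {
  set.seed(30)
  cases <- data.frame(t = c(0, runif(19, -4, 6)),
                      n1 = sample(8:30, 20, replace = TRUE),
                      n2 = sample(8:30, 20, replace = TRUE))
  for (i in seq_len(nrow(cases))) {
    got <- jzs_bf(cases$t[i], cases$n1[i], cases$n2[i])
    want <- oracle_jzs_bf(cases$t[i], cases$n1[i], cases$n2[i])
    expect_lt(abs(got - want) / want, 1e-3)
    # paired form
    gp <- jzs_bf(cases$t[i], cases$n1[i])
    wp <- oracle_jzs_bf(cases$t[i], cases$n1[i])
    expect_lt(abs(gp - wp) / wp, 1e-3)
  }
  expect_lt(jzs_bf(0, 20, 20), 1)
  # three within-group SDs of separation at n = 18/group is strong evidence
  t_sep <- 3 / sqrt(2 / 18)
  expect_gt(jzs_bf(t_sep, 18, 18), 10)
})

test_that("null two-sample data favours the null on median", {
  set.seed(31)
  bfs <- replicate(100, jzs_bf(two_sample_t_oracle(rnorm(20), rnorm(20)),
                               20, 20))
  expect_lt(median(bfs), 1)
})

test_that("Bayes follow-up averages the right window and pairs within
           subjects", {
  ep <- epoch_definition(2, 12, 6, fs = 10)
  design <- between_design(10, seed = 7)
  toi <- structure(list(start_s = 5, end_s = 7, peak_time_s = 6),
                   class = "toi")
  win <- ep$times >= 4 & ep$times <= 8
  set.seed(8)
  hrfs <- lapply(seq_len(nrow(design$assignments)), function(i) {
    row <- design$assignments[i, ]
    amp <- ifelse(row$level_a == "a1" & row$level_b == "b1", 2, 0)
    m <- matrix(0.1 + rnorm(1, sd = 0.05), ep$n_samples, 2)
    m[win, 1] <- m[win, 1] + amp
    subject_hrf(row$subject, row$level_a, row$level_b, m, ep,
                c("ch01", "ch02"), 1)
  })
  res <- bayes_followup(hrfs, toi, "ch01", design)
  expect_length(res, 2L)
  b1 <- res[[which(grepl("b1", vapply(res, `[[`, "", "contrast")))]]
  expect_gt(b1$BF10, 100)           # planted separation in b1
  b2 <- res[[which(grepl("b2", vapply(res, `[[`, "", "contrast")))]]
  expect_lt(b2$BF10, 3)             # nothing planted in b2
  expect_equal(unname(b1$means["a1"] - b1$means["a2"]), 2, tolerance = 0.2)
  expect_error(bayes_followup(hrfs, NULL, "ch01", design), "TOI")
})
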