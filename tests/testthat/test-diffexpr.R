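log2_matrix <- function(values, meta) {
  rownames(values) <- sprintf("e%d", seq_len(nrow(values)))
  colnames(values) <- meta$sample_id
  attr(values, "scale") <- "log2"
  values
}

two_group_meta <- function(n_rep = 2) {
  data.frame(sample_id = paste0("s", seq_len(2 * n_rep)), organ = "leaf",
             nitrogen = rep(c("limiting", "optimal"), each = n_rep),
             water = 1L, replicate = rep(seq_len(n_rep), 2))
}

test_that("fold change is the difference of mean log2 signals", {
  meta <- two_group_meta()
  m <- log2_matrix(rbind(c(3, 3, 1, 1), c(2, 2, 2, 2)), meta)
  fc <- fold_change(m, meta,
                    groupA = list(nitrogen = "limiting"),
                    groupB = list(nitrogen = "optimal"))
  expect_equal(fc$log2_fc, c(2, 0))
  expect_equal(fc$fc_linear, c(4, 1))
  expect_equal(fc$direction, c("up", "none"))

  set.seed(4)
  r <- log2_matrix(matrix(rnorm(200), 50), two_group_meta())
  fcr <- fold_change(r, two_group_meta(),
                     list(nitrogen = "limiting"), list(nitrogen = "optimal"))
  brute <- apply(r, 1, function(v) mean(v[1:2]) - mean(v[3:4]))
  expect_equal(fcr$log2_fc, unname(brute))
})

test_that("pooled t-test matches the closed-form oracle and t^2 = F", {
  ident <- ttest_equal_var(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  a <- c(1, 2, 3); b <- c(3, 4, 5)
  tt <- ttest_equal_var(a, b)
  # closed form: pooled variance 1, se = sqrt(2/3), t = -2/se
  t_hand <- (mean(a) - mean(b)) / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(tt$statistic, t_hand, tolerance = 1e-12)
  expect_equal(tt$p_value, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)

  # near-separated groups: p approaches 0
  sep <- ttest_equal_var(c(0, 0, 1e-9), c(1, 1, 1 + 1e-9))
  expect_lt(sep$p_value, 1e-8)

  # t^2 equals the one-way ANOVA F on the same two groups
  set.seed(5)
  x <- rnorm(5); y <- rnorm(6) + 1
  f <- anova(lm(v ~ g, data.frame(v = c(x, y),
                                  g = rep(c("a", "b"), c(5, 6)))))$`F value`[1]
  expect_equal(ttest_equal_var(x, y)$statistic^2, f, tolerance = 1e-10)

  expect_error(ttest_equal_var(1, c(1, 2)), ">= 2")
  expect_error(ttest_equal_var(c(1, 1), c(2, 2)), "zero pooled variance")
  flat <- ttest_equal_var(c(2, 2), c(2, 2))
  expect_equal(flat$p_value, 1)
})

test_that("BH adjustment reproduces the step-up definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.04, 0.03, 0.005))$p_adj,
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(benjamini_hochberg(rep(0.07, 9))$p_adj, rep(0.07, 9))
  expect_equal(benjamini_hochberg(0.3)$p_adj, 0.3)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(6)
  for (i in 1:25) {
    p <- runif(sample(1:60, 1))
    got <- benjamini_hochberg(p, alpha = 0.1)
    oracle <- bh_stepup_oracle(p)
    expect_equal(got$p_adj, oracle, tolerance = 1e-12)
    # rejection set equals the classic step-up rule
    m <- length(p); o <- order(p)
    k <- which(p[o] <= 0.1 * seq_len(m) / m)
    classic <- if (length(k) == 0) rep(FALSE, m) else
      seq_len(m) %in% o[seq_len(max(k))]
    expect_equal(got$reject, classic)
    # adjusted values are monotone in sorted raw p
    expect_true(all(diff(got$p_adj[o]) >= -1e-12))
  }
})

test_that("de_call flags planted effects and respects the family order", {
  cfg <- sim_config(n_entities = 800, organs = "leaf", n_clusters = 1,
                    noise_sigma = 0.2, frac_interaction = 0,
                    frac_trend_change = 0, frac_nitrogen = 0.1,
                    nitrogen_effect = 2, seed = 31)
  sim <- simulate_stress_experiment(cfg)
  lb <- log_and_baseline(sim$raw)
  de <- de_call(lb, sim$metadata, "leaf", "nitrogen")
  truth <- sim$truth$labels$is_nitrogen
  tp <- sum(de$significant & truth)
  fp <- sum(de$significant & !truth)
  expect_gte(tp / sum(truth), 0.9)
  expect_lte(fp / max(tp + fp, 1), 0.1)
  # p_adj >= p_raw within the family
  fam <- de$in_family
  expect_true(all(de$p_adj[fam] >= de$p_raw[fam]))

  # infinite fold-change threshold empties the family
  expect_warning(none <- de_call(lb, sim$metadata, "leaf", "nitrogen",
                                 fc_threshold = Inf), "empty")
  expect_equal(sum(none$significant), 0L)

  # invariance to sample column order
  perm <- sample(ncol(lb))
  lp <- lb[, perm, drop = FALSE]
  attr(lp, "scale") <- "log2-baselined"
  de2 <- de_call(lp, sim$metadata[perm, ], "leaf", "nitrogen")
  expect_equal(de2, de)
})

test_that("null simulations keep false-positive calls at the FDR level", {
  fp_rates <- vapply(1:15, function(s) {
    cfg <- sim_config(n_entities = 400, organs = "leaf", n_clusters = 1,
                      frac_interaction = 0,
                      frac_trend_change = 0, frac_nitrogen = 0, seed = 500 + s)
    sim <- simulate_stress_experiment(cfg)
    lb <- log_and_baseline(sim$raw)
    de <- suppressWarnings(de_call(lb, sim$metadata, "leaf", "nitrogen"))
    fam <- sum(de$in_family)
    if (fam == 0) 0 else sum(de$significant) / fam
  }, numeric(1))
  expect_lte(mean(fp_rates), 0.05 + 2 * sd(fp_rates) / sqrt(15) + 1e-9)
})

test_that("venn partition matches brute-force membership tallies", {
  v <- venn_partition(list(A = c("a", "b"), B = c("b", "c")))
  expect_equal(unname(v[c("A", "B", "A&B")]), c(1L, 1L, 1L))

  same <- venn_partition(list(X = c("a", "b"), Y = c("a", "b")))
  expect_equal(unname(same["X&Y"]), 2L)
  expect_equal(unname(same["X"]), 0L)

  set.seed(7)
  sets <- lapply(1:3, function(i) sample(sprintf("id%03d", 1:150), 100))
  names(sets) <- c("leaf", "root", "stem")
  v3 <- venn_partition(sets)
  expect_equal(sum(v3), length(unique(unlist(sets))))
  # brute force: tally each id's membership pattern
  ids <- unique(unlist(sets))
  pat <- vapply(ids, function(id) paste(names(sets)[vapply(sets, function(s)
    id %in% s, logical(1))], collapse = "&"), character(1))
  for (region in names(v3)) {
    expect_equal(unname(v3[region]), sum(pat == region))
  }
  expect_error(venn_partition(list(A = "a")), ">= 2")
})
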