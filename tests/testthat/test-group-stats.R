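sim_ancova_data <- function(n_per_group = 12, group_shift = 0, task_shift = 0,
                            interaction = 0, seed = 1, balanced = TRUE) {
  set.seed(seed)
  n2 <- if (balanced) n_per_group else n_per_group + 3
  g <- rep(c("A", "B"), c(n_per_group, n2))
  n <- length(g)
  age <- rnorm(n, 70, 6); edu <- rnorm(n, 12, 3)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  base <- rnorm(n) + 0.03 * age - 0.05 * edu
  y1 <- base + rnorm(n)
  y2 <- base + task_shift + rnorm(n)
  y1[g == "A"] <- y1[g == "A"] + group_shift
  y2[g == "A"] <- y2[g == "A"] + group_shift + interaction
  data.frame(group = g, sex = sex, age = age, education = edu,
             phonemic = y1, semantic = y2, stringsAsFactors = FALSE)
}

test_that("mixed ANCOVA matches the aov Error-strata reference on balanced data", {
  for (seed in c(2, 7)) {
    d <- sim_ancova_data(14, group_shift = 0.8, task_shift = 0.5,
                         interaction = 0.4, seed = seed)
    got <- mixed_ancova(d, c("phonemic", "semantic"))

    long <- data.frame(
      id = factor(rep(seq_len(nrow(d)), 2)),
      group = factor(rep(d$group, 2)), sex = factor(rep(d$sex, 2)),
      age = rep(d$age, 2), education = rep(d$education, 2),
      task = factor(rep(c("t1", "t2"), each = nrow(d))),
      y = c(d$phonemic, d$semantic))
    # covariates first so the sequential SS for group equals its partial SS
    ref <- summary(aov(y ~ sex + age + education + group + task + group:task +
                         Error(id), data = long))
    btab <- ref[["Error: id"]][[1]]
    wtab <- ref[["Error: Within"]][[1]]
    ref_F <- c(btab["group", "F value"], wtab["task", "F value"],
               wtab["group:task", "F value"])
    ref_p <- c(btab["group", "Pr(>F)"], wtab["task", "Pr(>F)"],
               wtab["group:task", "Pr(>F)"])
    expect_equal(got$terms$F, unname(ref_F), tolerance = 1e-8)
    expect_equal(got$terms$p, unname(ref_p), tolerance = 1e-8)
    expect_equal(got$terms$df2,
                 unname(c(btab["Residuals", "Df"], wtab["Residuals", "Df"],
                          wtab["Residuals", "Df"])))
    # eta_p_sq from the same SS decomposition
    expect_equal(got$terms$eta_p_sq[1],
                 btab["group", "Sum Sq"] /
                   (btab["group", "Sum Sq"] + btab["Residuals", "Sum Sq"]),
                 tolerance = 1e-8)
    expect_equal(got$terms$eta_p_sq[3],
                 wtab["group:task", "Sum Sq"] /
                   (wtab["group:task", "Sum Sq"] + wtab["Residuals", "Sum Sq"]),
                 tolerance = 1e-8)
    expect_equal(got$terms$mse[3], wtab["Residuals", "Mean Sq"], tolerance = 1e-8)
  }
})

test_that("planted effects are detected and guards fire", {
  d <- sim_ancova_data(30, group_shift = 1.5, seed = 3)
  got <- mixed_ancova(d, c("phonemic", "semantic"))
  expect_lt(got$terms$p[got$terms$term == "group"], 0.001)

  d_int <- sim_ancova_data(30, interaction = 1.2, seed = 4)
  got_int <- mixed_ancova(d_int, c("phonemic", "semantic"))
  expect_lt(got_int$terms$p[got_int$terms$term == "group:task"], 0.01)

  d3 <- d; d3$group <- sample(c("A", "B", "C"), nrow(d3), replace = TRUE)
  expect_error(mixed_ancova(d3, c("phonemic", "semantic")), "two levels")
  d4 <- d[c(1:2, 31:60), ]
  expect_error(mixed_ancova(d4, c("phonemic", "semantic")), "fewer than 3")
  d5 <- d; d5$phonemic <- 1; d5$semantic <- 1
  expect_error(mixed_ancova(d5, c("phonemic", "semantic")), "constant")
})

test_that("eta_p_sq is invariant under affine rescaling of the outcome", {
  d <- sim_ancova_data(12, group_shift = 0.7, interaction = 0.3, seed = 9,
                       balanced = FALSE)
  a <- mixed_ancova(d, c("phonemic", "semantic"))
  d2 <- d
  d2$phonemic <- 3.7 * d$phonemic + 11
  d2$semantic <- 3.7 * d$semantic + 11
  b <- mixed_ancova(d2, c("phonemic", "semantic"))
  expect_equal(a$terms$eta_p_sq, b$terms$eta_p_sq, tolerance = 1e-10)
  expect_equal(a$terms$F, b$terms$F, tolerance = 1e-10)
})

test_that("listwise deletion is counted", {
  d <- sim_ancova_data(10, seed = 6)
  d$age[2] <- NA; d$semantic[5] <- NA
  got <- mixed_ancova(d, c("phonemic", "semantic"))
  expect_equal(got$n_dropped, 2)
  expect_equal(got$n_used, nrow(d) - 2)
})

test_that("permuting group labels destroys a planted group effect", {
  set.seed(33)
  d <- sim_ancova_data(20, group_shift = 1.2, seed = 33)
  f_obs <- mixed_ancova(d, c("phonemic", "semantic"))$terms$F[1]
  f_perm <- replicate(30, {
    dp <- d; dp$group <- sample(dp$group)
    mixed_ancova(dp, c("phonemic", "semantic"))$terms$F[1]
  })
  expect_gt(f_obs, quantile(f_perm, 0.95))
  expect_lt(mean(f_perm), f_obs / 3)
})

test_that("Tukey post-hocs agree with the studentized-range formula", {
  set.seed(12)
  cells <- rep(c("A.t1", "A.t2", "B.t1", "B.t2"), each = 9)
  y <- rnorm(length(cells)) + (cells == "A.t2") * 1.5
  got <- tukey_posthoc(y, cells)
  expect_equal(nrow(got), 6)

  # oracle: Tukey-Kramer p from ptukey on the one-way decomposition
  k <- 4; n <- length(y)
  mse <- sum(unlist(lapply(split(y, cells), function(v) (v - mean(v))^2))) / (n - k)
  ns <- table(cells); ms <- tapply(y, cells, mean)
  for (r in seq_len(nrow(got))) {
    ab <- strsplit(got$contrast[r], "-", fixed = TRUE)[[1]]
    q <- abs(ms[ab[1]] - ms[ab[2]]) /
      sqrt(mse / 2 * (1 / ns[ab[1]] + 1 / ns[ab[2]]))
    expect_equal(got$p_tukey[r],
                 unname(ptukey(q, k, n - k, lower.tail = FALSE)),
                 tolerance = 1e-8)
  }

  # identical cells: p ~ 1, d = 0
  y0 <- rep(c(1, 2, 3, 4, 5), 4)
  got0 <- tukey_posthoc(y0, rep(c("a", "b", "c", "d"), each = 5))
  expect_true(all(got0$p_tukey > 0.999))
  expect_true(all(got0$cohen_d == 0))

  expect_error(tukey_posthoc(c(1, 2), c("a", "b")), "degenerate")
})

test_that("Cohen's d follows the pooled-SD formula", {
  set.seed(14)
  a <- rnorm(20); b <- rnorm(25)
  sp <- sqrt((19 * var(a) + 24 * var(b)) / 43)
  expect_equal(cohen_d(a, b), (mean(a) - mean(b)) / sp, tolerance = 1e-12)
  expect_equal(cohen_d(a, a), 0)
  # two cells two pooled SDs apart have d ~ 2
  x <- rnorm(4000); y <- rnorm(4000) + 2
  expect_equal(cohen_d(y, x), 2, tolerance = 0.1)
})

test_that("eta_squared_partial is SS_effect / (SS_effect + SS_error)", {
  expect_equal(eta_squared_partial(3, 3), 0.5)
  expect_equal(eta_squared_partial(1, 3), 0.25)
  expect_error(eta_squared_partial(1, 0), "error sum of squares")
})
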