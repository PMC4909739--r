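test_that("one-way ANOVA matches its classical special cases", {
  # two identical groups with nonzero spread: no between-group variance
  x <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  av <- anova_one_way(x, g)
  expect_equal(av$F, 0)
  expect_equal(av$p, 1)

  # k = 2: F is the square of the pooled-variance t statistic
  set.seed(31)
  x2 <- c(rnorm(6, 0), rnorm(6, 1))
  g2 <- rep(c("a", "b"), each = 6)
  tt <- t.test(x2 ~ g2, var.equal = TRUE)
  av2 <- anova_one_way(x2, g2)
  expect_equal(av2$F, unname(tt$statistic)^2)
  expect_equal(av2$p, tt$p.value)

  # 3-SD separation at n = 5 is decisively significant
  set.seed(32)
  x3 <- c(rnorm(5, 0, 1), rnorm(5, 3, 1), rnorm(5, 6, 1))
  av3 <- anova_one_way(x3, rep(c("a", "b", "c"), each = 5))
  expect_lt(av3$p, 0.001)

  # degenerate: zero variance everywhere, equal means
  avd <- anova_one_way(rep(2, 6), rep(c("a", "b"), each = 3))
  expect_true(is.na(avd$F))
  expect_match(avd$flags, "degenerate")

  expect_error(anova_one_way(1:3, c("a", "a", "a")), "2 groups")
  expect_error(anova_one_way(1:3, c("a", "a", "b")), "n >= 2")
})

test_that("group mean and SE follow the closed forms", {
  sm <- summarize_mean_se(1:5, rep("a", 5))
  expect_equal(sm$mean, 3)
  expect_equal(sm$se, sd(1:5) / sqrt(5))
  expect_equal(sm$se, 0.7071, tolerance = 1e-4)
  expect_equal(summarize_mean_se(rep(4, 4), rep("a", 4))$se, 0)
  # scaling the data scales the SE by |c|
  x <- rnorm(8); g <- rep(c("a", "b"), 4)
  expect_equal(summarize_mean_se(-2.5 * x, g)$se,
               2.5 * summarize_mean_se(x, g)$se)
  expect_error(summarize_mean_se(1:3, c("a", "a", "b")), "n < 2")
})

test_that("SNK letters separate clear patterns and share letters under ties", {
  set.seed(41)
  x_same <- rnorm(15, 10, 1)
  r_same <- snk_letters(x_same, rep(c("a", "b", "c"), each = 5))
  expect_true(all(r_same$groups$letters == "a"))

  x_sep <- c(rnorm(5, 0, 0.5), rnorm(5, 10, 0.5), rnorm(5, 20, 0.5))
  r_sep <- snk_letters(x_sep, rep(c("g1", "g2", "g3"), each = 5))
  expect_equal(sort(r_sep$groups$letters), c("a", "b", "c"))
  expect_true(all(r_sep$significant_pairs$significant))

  # a published-style pattern: reference fertilizer well above the other two
  set.seed(42)
  x_pat <- c(rnorm(5, 19.7, 2.0), rnorm(5, 12.5, 2.0), rnorm(5, 11.5, 2.0))
  g_pat <- rep(c("TSP", "TCSS", "control"), each = 5)
  r_pat <- snk_letters(x_pat, g_pat)
  lt <- setNames(r_pat$groups$letters, r_pat$groups$group)
  expect_equal(unname(lt["TSP"]), "a")
  expect_equal(unname(lt["TCSS"]), unname(lt["control"]))
  expect_false(grepl("a", lt["TCSS"], fixed = TRUE))
})

test_that("SNK at k = 2 agrees with the pooled t-test decision", {
  set.seed(43)
  for (i in 1:30) {
    delta <- runif(1, 0, 2.5)
    x <- c(rnorm(5, 0), rnorm(5, delta))
    g <- rep(c("a", "b"), each = 5)
    r <- snk_letters(x, g, alpha = 0.05)
    t_sig <- t.test(x ~ g, var.equal = TRUE)$p.value < 0.05
    share <- any(strsplit(r$groups$letters[1], "")[[1]] %in%
                   strsplit(r$groups$letters[2], "")[[1]])
    expect_equal(!share, t_sig, info = paste("case", i))
  }
})

test_that("the letter display is a valid cover of the SNK decisions", {
  set.seed(44)
  for (i in 1:20) {
    k <- sample(3:5, 1)
    mu <- runif(k, 0, 6)
    x <- rnorm(5 * k, rep(mu, each = 5), 1)
    g <- rep(paste0("g", seq_len(k)), each = 5)
    r <- snk_letters(x, g)
    lt <- setNames(strsplit(r$groups$letters, ""), r$groups$group)
    for (p in seq_len(nrow(r$significant_pairs))) {
      pr <- r$significant_pairs[p, ]
      share <- any(lt[[pr$group1]] %in% lt[[pr$group2]])
      if (pr$significant) expect_false(share) else expect_true(share)
    }
  }
})

test_that("unequal group sizes use the harmonic mean and are flagged", {
  set.seed(45)
  x <- c(rnorm(5, 0), rnorm(7, 5), rnorm(4, 10))
  g <- rep(c("a", "b", "c"), c(5, 7, 4))
  r <- snk_letters(x, g)
  expect_match(r$flags, "harmonic")
  expect_equal(sort(r$groups$letters), c("a", "b", "c"))
  expect_error(snk_letters(x, g, alpha = 1.2), "alpha")
})
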