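test_that("t and F tail probabilities reproduce printed and exact values", {
  expect_equal(t_sf(0, 7), 1)
  expect_equal(t_sf(1.921, 6), 0.1031, tolerance = 5e-4)
  expect_equal(t_sf(12.706, 1), 0.05, tolerance = 1e-4)
  expect_equal(f_sf(0, 3, 12), 1)
  # the printed two-decimal value carries its own rounding error: the exact
  # tail probability is 0.4337
  expect_equal(f_sf(0.982, 3, 12), 0.44, tolerance = 0.015)
  expect_error(t_sf(1, 0), "df")
  expect_error(f_sf(-1, 2, 2), "F")
  # F-t identity at arbitrary (fractional) dfs
  for (tt in c(0.3, 1.9, 3.4)) for (d in c(2.5, 6, 17.3))
    expect_equal(f_sf(tt^2, 1, d), t_sf(tt, d), tolerance = 1e-12)
})

test_that("tail probabilities agree with numerical quadrature of densities", {
  t_tail <- function(t, df) {
    const <- gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2))
    2 * integrate(function(u) const * (1 + u^2 / df)^(-(df + 1) / 2),
                  abs(t), Inf, rel.tol = 1e-12)$value
  }
  f_tail <- function(f, d1, d2) {
    dens <- function(x) df(x, d1, d2)
    integrate(dens, f, Inf, rel.tol = 1e-12)$value
  }
  for (tt in c(0.5, 1.921, 3.2)) for (d in c(1.7, 6, 11.4))
    expect_equal(t_sf(tt, d), t_tail(tt, d), tolerance = 1e-8)
  for (ff in c(0.5, 2.978)) for (d1 in c(1.196, 3)) for (d2 in c(7.173, 12))
    expect_equal(f_sf(ff, d1, d2), f_tail(ff, d1, d2), tolerance = 1e-8)
})

test_that("two-sample t matches hand computation and conventions", {
  r <- two_sample_t(c(1, 2, 3), c(2, 3, 4), "pooled")
  expect_equal(r$statistic, -1.2247, tolerance = 1e-4)
  expect_equal(r$df1, 4)
  expect_equal(r$p, t_sf(-1.2247449, 4), tolerance = 1e-6)
  same <- two_sample_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # Welch df never exceeds the pooled df
  set.seed(5)
  for (i in 1:25) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1), sd = runif(1, 0.2, 3))
    expect_lte(two_sample_t(x, y, "welch")$df1,
               length(x) + length(y) - 2 + 1e-12)
  }
  # cross-check both variants against stats::t.test
  x <- rnorm(8); y <- rnorm(6, 1)
  expect_equal(two_sample_t(x, y, "pooled")$p,
               t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-12)
  expect_equal(two_sample_t(x, y, "welch")$p,
               t.test(x, y)$p.value, tolerance = 1e-12)
  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
})

test_that("one-way ANOVA matches lm and degenerates gracefully", {
  set.seed(2)
  groups <- list(rnorm(5), rnorm(6, 0.5), rnorm(4, 1))
  r <- one_way_anova(groups)
  dat <- data.frame(y = unlist(groups),
                    g = factor(rep(seq_along(groups), lengths(groups))))
  ref <- anova(lm(y ~ g, dat))
  expect_equal(r$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(r$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  # two groups: F equals the pooled t squared
  two <- list(rnorm(7), rnorm(5, 0.8))
  expect_equal(one_way_anova(two)$statistic,
               two_sample_t(two[[1]], two[[2]], "pooled")$statistic^2,
               tolerance = 1e-10)
  # all-identical data: F = 0 convention
  expect_equal(one_way_anova(list(c(1, 1), c(1, 1)))$statistic, 0)
  expect_error(one_way_anova(list(rnorm(3))), "2 groups")
})

test_that("one-way ANOVA holds its nominal type-I error", {
  set.seed(42)
  rej <- 0
  for (i in 1:2000) {
    g <- lapply(1:4, function(j) rnorm(4))
    if (one_way_anova(g)$p < 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / 2000 - 0.05), 0.01)
})

test_that("GG epsilon is 1 under exact compound symmetry, bounded below", {
  # construct data whose sample covariance is exactly I + c J
  set.seed(9)
  n <- 12; k <- 4
  Z <- matrix(rnorm(n * k), n, k)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Z <- Z %*% solve(chol(cov(Z)))          # exact identity covariance
  Y <- Z + rnorm(n) %o% rep(1, k)         # adds c * J
  r <- mixed_rm_anova_gg(Y, rep("A", n))
  expect_equal(r$epsilon, 1, tolerance = 1e-10)
  # lower bound 1/(k-1) over random data
  for (i in 1:20) {
    Y2 <- matrix(rnorm(8 * k) * rep(c(1, 5, 0.2, 3), each = 8), 8, k)
    e <- mixed_rm_anova_gg(Y2, rep(c("A", "B"), 4))$epsilon
    expect_gte(e, 1 / (k - 1) - 1e-12)
    expect_lte(e, 1 + 1e-12)
  }
})

test_that("mixed RM ANOVA agrees with a longhand split-plot oracle", {
  set.seed(31)
  n <- 8; k <- 3
  grp <- rep(c("MS", "CTL"), each = 4)
  Y <- matrix(rnorm(n * k), n, k) + outer(rnorm(n), rep(0, k)) +
    outer(as.numeric(grp == "MS"), c(0, 0.5, 1))
  r <- mixed_rm_anova_gg(Y, grp)
  # oracle 1: aov with an Error stratum for the within-donor effects
  long <- data.frame(y = as.vector(Y),
                     donor = factor(rep(seq_len(n), k)),
                     level = factor(rep(seq_len(k), each = n)),
                     grp = factor(rep(grp, k)))
  sm <- summary(aov(y ~ grp * level + Error(donor), data = long))
  within_tab <- sm[["Error: Within"]][[1]]
  rn <- trimws(rownames(within_tab))
  expect_equal(r$within_uncorrected$statistic,
               within_tab[rn == "level", "F value"], tolerance = 1e-8)
  expect_equal(r$interaction_uncorrected$statistic,
               within_tab[rn == "grp:level", "F value"], tolerance = 1e-8)
  between_tab <- sm[["Error: donor"]][[1]]
  expect_equal(r$between$statistic,
               between_tab[trimws(rownames(between_tab)) == "grp",
                           "F value"], tolerance = 1e-8)
  # oracle 2: epsilon from an independently chosen orthonormal contrast
  # basis (polynomial contrasts) over the pooled covariance
  S <- (cov(Y[grp == "MS", ]) * 3 + cov(Y[grp == "CTL", ]) * 3) / 6
  C <- qr.Q(qr(contr.poly(k)))
  M <- t(C) %*% S %*% C
  eps_ref <- sum(diag(M))^2 / ((k - 1) * sum(M^2))
  expect_equal(r$epsilon, eps_ref, tolerance = 1e-10)
  # corrected dfs and p follow from epsilon
  expect_equal(r$within$df1, r$epsilon * (k - 1))
  expect_equal(r$within$df2, r$epsilon * (k - 1) * (n - 2))
  expect_equal(r$within$p,
               f_sf(r$within$statistic, r$within$df1, r$within$df2))
  expect_error(mixed_rm_anova_gg(rbind(Y, NA), c(grp, "MS")), "incomplete")
})

test_that("the GG correction is conservative where it matters (F >= 1)", {
  # Shrinking both degrees of freedom by epsilon raises the tail
  # probability for large F but can lower it for unremarkable F, so the
  # guarantee is asserted where rejections happen: nominally significant
  # results never become more significant after correction.
  set.seed(13)
  checked <- 0
  for (i in 1:80) {
    k <- sample(3:5, 1)
    Y <- matrix(rnorm(10 * k, sd = rep(runif(k, 0.3, 3), each = 10)), 10, k)
    Y[6:10, ] <- Y[6:10, ] + rnorm(1)
    Y <- Y + outer(rep(c(0, 1), each = 5), seq(0, 1, length.out = k))
    r <- mixed_rm_anova_gg(Y, rep(c("A", "B"), each = 5))
    for (part in list(c("within", "within_uncorrected"),
                      c("interaction", "interaction_uncorrected"))) {
      if (r[[part[2]]]$p <= 0.10) {
        expect_gte(r[[part[1]]]$p, r[[part[2]]]$p - 1e-12)
        checked <- checked + 1
      }
    }
  }
  expect_gte(checked, 20)
})

test_that("group reports assemble summaries and the three comparisons", {
  set.seed(77)
  donors <- c(paste0("MS", 1:5), paste0("C", 1:6))
  grp <- rep(c("MS", "non-MS"), c(5, 6))
  long <- do.call(rbind, lapply(c(125, 133, 140), function(lv)
    data.frame(donor = donors, group = grp, treatment = "none", level = lv,
               density = rlnorm(11, log(ifelse(grp == "MS", 3e5, 6e4)), 0.3))))
  alln <- data.frame(donor = paste0("A", 1:4), group = "MS",
                     treatment = "ALLN", level = 125,
                     density = rlnorm(4, log(1e5), 0.3))
  rep_ <- group_report(rbind(long, alln))
  expect_s3_class(rep_$baseline, "thg_test")
  expect_s3_class(rep_$sodium, "thg_rm_anova")
  expect_s3_class(rep_$alln, "thg_test")
  expect_true(all(c("mean", "sd", "sem", "n") %in% names(rep_$summary)))
  # single group, single level: summary collapses to mean/sd
  one <- data.frame(donor = 1:4, group = "G", treatment = "none",
                    level = 1, density = c(2, 4, 6, 8))
  r1 <- group_report(one)
  expect_equal(r1$summary$mean, 5)
  expect_equal(r1$summary$sd, sd(c(2, 4, 6, 8)))
  expect_null(r1$baseline)
  # exchanging the sample roles negates t and preserves p
  a <- rlnorm(5, 12, 0.4); b <- rlnorm(6, 11, 0.3)
  t12 <- two_sample_t(a, b); t21 <- two_sample_t(b, a)
  expect_equal(t12$statistic, -t21$statistic, tolerance = 1e-12)
  expect_equal(t12$p, t21$p, tolerance = 1e-12)
  expect_error(group_report(one[0, ]), "empty")
})

test_that("group separation at preset effect sizes is reliably detected", {
  hits <- 0
  for (s in 1:200) {
    ms <- simulate_donor_densities(preset_ms(), 5, seed = 1000 + s)
    nm <- simulate_donor_densities(preset_nonms(), 6, seed = 5000 + s)
    if (two_sample_t(ms, nm, variant = "pooled")$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.80)
})
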