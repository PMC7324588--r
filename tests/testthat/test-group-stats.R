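test_that("the pooled t statistic matches the closed form and stats::t.test", {
  r <- student_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3 / sqrt(1 * (2 / 3)))    # sp2 = 1, se = sqrt(2/3)
  expect_equal(r$df, 4)
  ref <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)

  set.seed(31)
  for (i in 1:20) {
    a <- rnorm(sample(2:9, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:9, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    mine <- student_t_test(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
    welch <- student_t_test(a, b, var_equal = FALSE)
    refw <- t.test(a, b)
    expect_equal(welch$t, unname(refw$statistic), tolerance = 1e-9)
    expect_equal(welch$df, unname(refw$parameter), tolerance = 1e-9)
    # p-value against numerical quadrature of the t density
    quad <- 2 * stats::integrate(function(x) stats::dt(x, mine$df),
                                 abs(mine$t), Inf, rel.tol = 1e-10)$value
    expect_equal(mine$p, quad, tolerance = 1e-6)
  }
})

test_that("degenerate inputs follow the documented conventions", {
  same <- student_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_false(same$significant)

  flat <- student_t_test(c(2, 2), c(2, 2))
  expect_equal(flat$t, 0)
  expect_equal(flat$p, 1)
  shifted <- student_t_test(c(2, 2), c(3, 3))
  expect_equal(shifted$t, -Inf)
  expect_equal(shifted$p, 0)

  expect_error(student_t_test(1, c(1, 2)), ">= 2")
  expect_error(student_t_test(c(1, NA), c(1, 2)), "finite")
})

test_that("swapping groups flips t and preserves p", {
  set.seed(12)
  a <- rnorm(6, 10); b <- rnorm(6, 12)
  r1 <- student_t_test(a, b)
  r2 <- student_t_test(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
})

test_that("empirical type-I error at n = 6 sits at the nominal level", {
  set.seed(2024)
  n_sim <- 10000
  p <- vapply(seq_len(n_sim), function(i)
    student_t_test(rnorm(6), rnorm(6))$p, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
})

test_that("groups simulated from the fed/starved fat volumes separate", {
  set.seed(77)
  fed <- rnorm(6, 31.804, 0.656)
  starved <- rnorm(6, 18.207, 0.774)
  r <- student_t_test(fed, starved)
  expect_true(r$significant)
  expect_lt(r$p, 0.05)
})

test_that("compare_cohorts tests each shared parameter and flags asterisks", {
  rec <- function(vol, fat, w, l, cond) data.frame(
    id = paste0(cond, seq_along(vol)), condition = cond,
    weight_g = w, length_cm = l, total_volume_cm3 = vol,
    fat_volume_cm3 = fat, fat_fraction_pct = 100 * fat / vol)
  set.seed(9)
  fed <- rec(rnorm(6, 71.3, 0.7), rnorm(6, 31.8, 0.7),
             rnorm(6, 53, 6.9), rnorm(6, 16, 1), "fed")
  starved <- rec(rnorm(6, 37.1, 2.1), rnorm(6, 18.2, 0.8),
                 rnorm(6, 19.7, 2.2), rnorm(6, 12.4, 1.6), "starved")
  cmp <- compare_cohorts(fed, starved)
  tab <- cmp$table
  expect_setequal(tab$parameter,
                  c("weight_g", "length_cm", "total_volume_cm3",
                    "fat_volume_cm3", "fat_fraction_pct"))
  expect_true(tab$significant[tab$parameter == "total_volume_cm3"])
  expect_true(tab$significant[tab$parameter == "fat_volume_cm3"])

  same <- compare_cohorts(fed, fed)
  expect_false(any(same$table$significant))

  swapped <- compare_cohorts(starved, fed)
  expect_equal(swapped$table$t, -cmp$table$t)
  expect_equal(swapped$table$p, cmp$table$p)

  expect_error(compare_cohorts(fed[, 1:2], starved[, 1:2]), "parameter")
})
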