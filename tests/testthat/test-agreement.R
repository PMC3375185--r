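test_that("decile dichotomization uses the interpolated quantile and low ties", {
  d <- dichotomize_decile(1:10)
  expect_equal(d$cutoff, 7.3)
  expect_identical(which(d$labels), 8:10)

  same <- dichotomize_decile(rep(4.2, 20))
  expect_false(any(same$labels))          # nothing exceeds the cutoff

  set.seed(401)
  u <- runif(10000)
  frac_high <- mean(dichotomize_decile(u)$labels)
  expect_equal(frac_high, 0.3, tolerance = 0.02)

  expect_error(dichotomize_decile(numeric(0)), "no values")
})

test_that("contingency tables cross-tabulate binary labels", {
  a <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  t_same <- contingency(a, a)
  expect_equal(t_same$b + t_same$c, 0)
  set.seed(402)
  x <- runif(40) > 0.5; y <- runif(40) > 0.5
  tab <- contingency(x, y)
  expect_equal(tab$a, sum(!x & !y))
  expect_equal(tab$d, sum(x & y))
  expect_equal(tab$n, 40)
  expect_error(contingency(x, y[1:10]), "length")
  expect_error(contingency_table(0, 0, 0, 0), "empty")
})

test_that("published contingency cells reproduce the printed statistics", {
  ki67 <- contingency_table(115, 15, 13, 42)   # visual low/high x automated
  expect_equal(ki67$n, 185)
  expect_equal(round(percent_agreement(ki67)), 85)
  expect_equal(round(cohens_kappa(ki67), 2), 0.64)

  seg <- contingency_table(264, 5, 7, 131)     # epithelium/stroma x automated
  expect_equal(seg$n, 407)
  expect_equal(round(percent_agreement(seg)), 97)
  expect_equal(percent_agreement(seg), 100 * 395 / 407)
  expect_equal(round(cohens_kappa(seg), 2), 0.93)
})

test_that("kappa is zero under independence and one only for perfect tables", {
  expect_equal(cohens_kappa(contingency_table(50, 50, 50, 50)), 0)
  expect_equal(cohens_kappa(contingency_table(30, 0, 0, 70)), 1)
  expect_lt(cohens_kappa(contingency_table(30, 1, 0, 70)), 1)
  expect_equal(percent_agreement(contingency_table(3, 0, 0, 9)), 100)
  # degenerate marginals: everything in one cell
  expect_error(cohens_kappa(contingency_table(10, 0, 0, 0)), "degenerate")
})

test_that("closed-form kappa equals the brute-force label-vector oracle", {
  brute_kappa <- function(t) {
    a <- c(rep(FALSE, t$a + t$b), rep(TRUE, t$c + t$d))
    b <- c(rep(FALSE, t$a), rep(TRUE, t$b), rep(FALSE, t$c), rep(TRUE, t$d))
    po <- mean(a == b)
    # expected agreement: average the equality indicator over all pairings
    pe <- mean(outer(a, b, `==`))
    (po - pe) / (1 - pe)
  }
  set.seed(403)
  for (i in 1:25) {
    repeat {
      cells <- as.vector(stats::rmultinom(1, sample(4:50, 1), rep(0.25, 4)))
      t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
      pe <- ((t$a + t$b) * (t$a + t$c) + (t$c + t$d) * (t$b + t$d)) / t$n^2
      if (abs(1 - pe) > 1e-9) break
    }
    expect_equal(cohens_kappa(t), brute_kappa(t), tolerance = 1e-12)
  }
})

test_that("kappa agrees with an independent implementation", {
  tab <- matrix(c(115, 13, 15, 42), 2, 2)
  expect_equal(cohens_kappa(contingency_table(115, 15, 13, 42)),
               e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
})

test_that("agreement statistics respect table symmetries", {
  set.seed(404)
  for (i in 1:10) {
    cells <- sample(1:30, 4, replace = TRUE)
    t1 <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    t2 <- contingency_table(cells[1], cells[3], cells[2], cells[4])  # transpose
    expect_equal(cohens_kappa(t1), cohens_kappa(t2), tolerance = 1e-12)
    # consistent relabelling of both raters: swap positive/negative
    t3 <- contingency_table(cells[4], cells[3], cells[2], cells[1])
    expect_equal(percent_agreement(t1), percent_agreement(t3))
    expect_true(t1$b == 0 && t1$c == 0 || cohens_kappa(t1) < 1)
  }
})
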