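test_that("two-point RBF hard-margin fit matches the closed form", {
  for (nu in c(0.1, 0.5, 1)) {
    for (D in c(0.5, 1, 4)) {
      x <- rbind(c(1, 1), c(1 + sqrt(D), 1))
      fit <- meb_fit(x, nu = nu, C = 1)
      expect_equal(fit$alpha, c(0.5, 0.5), tolerance = 1e-6)
      expect_equal(fit$r_squared, (1 - exp(-nu * D)) / 2, tolerance = 1e-6)
    }
  }
})

test_that("linear-kernel collinear points recover the Euclidean ball", {
  for (a in c(1, 3, 7.5)) {
    fit <- meb_fit(cbind(c(-a, -a / 3, a)), kernel = "linear", C = 10)
    expect_equal(fit$r_squared, a^2, tolerance = 1e-6)
  }
})

test_that("hard-margin fits contain every training point", {
  x <- fixture_counts(15, 3, seed = 5)
  fit <- meb_fit(x, nu = 1e-3, C = 1)
  expect_true(all(predict(fit) <= 1e-4))
  expect_equal(sum(fit$alpha), 1, tolerance = 1e-6)
})

test_that("boundary support vectors sit on the ball (KKT)", {
  x <- fixture_counts(25, 2, seed = 9)
  for (C in c(0.1, 1)) {
    fit <- meb_fit(x, nu = 5e-4, C = C)
    expect_gt(length(fit$boundary_sv), 0)
    f_sv <- predict(fit)[fit$boundary_sv]
    expect_true(all(abs(f_sv) <= 1e-4))
  }
})

test_that("squared radius is non-decreasing in C", {
  x <- fixture_counts(60, 2, seed = 12)
  r2 <- vapply(c(0.05, 0.1, 1),
               function(C) meb_fit(x, nu = 5e-4, C = C)$r_squared,
               numeric(1))
  expect_true(all(diff(r2) >= -1e-9))
})

test_that("RBF decisions are translation invariant", {
  x <- fixture_counts(12, 2, seed = 31)
  test_pts <- fixture_counts(6, 2, lambda = 120, seed = 32)
  f0 <- meb_fit(x, nu = 2e-3, C = 1)
  shift <- c(1000, -17)
  f1 <- meb_fit(sweep(x, 2, shift, "+"), nu = 2e-3, C = 1)
  expect_equal(predict(f0, test_pts),
               predict(f1, sweep(test_pts, 2, shift, "+")),
               tolerance = 1e-9)
})

test_that("far-away points approach the finite RBF decision limit", {
  x <- fixture_counts(10, 2, seed = 77)
  fit <- meb_fit(x, nu = 1e-2, C = 1)
  far <- matrix(c(1e6, 1e6), 1)
  limit <- 1 + fit$offset - fit$r_squared
  expect_equal(unname(predict(fit, far)), limit, tolerance = 1e-9)
  expect_gt(limit, 0)  # a far outlier is always called DE
})

test_that("calls follow the strict sign rule, zero maps to nonDE", {
  x <- fixture_counts(10, 2, seed = 3)
  fit <- meb_fit(x, nu = 1e-3, C = 1)
  f <- predict(fit)
  cl <- predict(fit, type = "class")
  expect_identical(as.character(cl), ifelse(f > 0, "DE", "nonDE"))
  # exactly-zero decision value is non-DE by convention
  fit0 <- fit; fit0$r_squared <- 1 + fit$offset
  expect_identical(as.character(predict(fit0, matrix(c(1e7, 1e7), 1),
                                        type = "class")), "nonDE")
})

test_that("a degenerate identical training set fits a radius-0 ball", {
  x <- matrix(4, 5, 2)
  expect_warning(fit <- meb_fit(x, nu = 0.5, C = 1), "degenerate")
  expect_equal(fit$r_squared, 0, tolerance = 1e-8)
  expect_identical(as.character(predict(fit, c(5, 4), type = "class")), "DE")
})

test_that("all-zero training genes are kept with a warning", {
  x <- rbind(matrix(rpois(18, 30), 9, 2), c(0, 0))
  expect_warning(fit <- meb_fit(x, nu = 1e-3, C = 1), "all-zero")
  expect_equal(nrow(fit$x), 10)
})

test_that("score_genes is consistent, stable and row-independent", {
  x <- fixture_counts(20, 2, seed = 21)
  rownames(x) <- sprintf("hk%02d", 1:20)
  fit <- meb_fit(x, nu = 1e-3, C = 0.1)
  sc <- score_genes(fit, x)
  expect_equal(sc$score, unname(predict(fit)))
  expect_identical(sort(sc$rank), 1:20)
  # permuting rows permutes scores identically
  perm <- sample(20)
  sc_p <- score_genes(fit, x[perm, ])
  expect_equal(sc_p$score, sc$score[perm])
  # genes identical to a boundary SV score within tolerance of zero
  sv <- x[fit$boundary_sv[1L], , drop = FALSE]
  dup <- sv[rep(1, 3), ]
  expect_true(all(abs(score_genes(fit, dup)$score) <= 1e-4))
})

test_that("fit errors are actionable", {
  expect_error(meb_fit(fixture_counts(5), nu = 1e-3, C = 0.1), "at least 10")
  expect_error(predict(meb_fit(fixture_counts(4), nu = 1e-3, C = 1),
                       matrix(1, 1, 5)), "dimension")
})
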