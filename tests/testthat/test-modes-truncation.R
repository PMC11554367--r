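test_that("mode counts match the generating shape and interleave", {
  set.seed(10)
  uni <- find_modes_antimodes(rnorm(5000))
  expect_length(uni$modes, 1)
  expect_length(uni$antimodes, 0)

  bi <- find_modes_antimodes(c(rnorm(3000, 0), rnorm(3000, 6)))
  expect_length(bi$modes, 2)
  expect_length(bi$antimodes, 1)
  expect_gt(bi$antimodes, 0)
  expect_lt(bi$antimodes, 6)
  # strict interleaving: sorted positions alternate mode/antimode
  pos <- sort(c(bi$modes, bi$antimodes))
  types <- ifelse(pos %in% bi$modes, "m", "a")
  expect_equal(types, c("m", "a", "m"))
})

# helper: a mixture_model built from known parameters (bypasses EM)
known_mixture <- function(w, mu, sg) {
  structure(list(k = length(w), weights = w, means = mu, sds = sg,
                 loglik = NA_real_, bic = NA_real_, bic_by_k = NA_real_,
                 converged = TRUE, n_iter = 0L, n = 0L),
            class = "mixture_model")
}
identity_tr <- structure(list(family = "identity", lambda = NA_real_,
                              offset = 0), class = "transform_spec")

test_that("k = 1 yields the full-range window", {
  set.seed(11)
  x <- rnorm(1000)
  mix <- known_mixture(1, 0, 1)
  modes <- find_modes_antimodes(x)
  win <- choose_truncation(mix, modes, identity_tr, range(x))
  expect_equal(c(win$lower, win$upper), range(x))
  expect_equal(win$source, c("data_extreme", "data_extreme"))
})

test_that("the responsibility-0.5 boundary sits between separated components", {
  # 0.75 N(0,1) + 0.25 N(5,1): the 0.5-responsibility crossing solves
  # 0.75 phi(x) = 0.25 phi(x-5), i.e. x = (25 + 2 log 3) / 10 = 2.72
  set.seed(12)
  x <- c(rnorm(7500, 0), rnorm(2500, 5))
  mix <- known_mixture(c(0.75, 0.25), c(0, 5), c(1, 1))
  modes <- find_modes_antimodes(x)
  win <- choose_truncation(mix, modes, identity_tr, range(x),
                           resp_threshold = 0.5)
  expect_gt(win$upper, 1.5)
  expect_lt(win$upper, 3.5)
  expect_gt(mix$means[1], win$lower)
  # pure responsibility crossing (antimodes suppressed) matches the
  # analytic solution on a fine grid
  no_anti <- modes
  no_anti$antimodes <- numeric(0)
  win2 <- choose_truncation(mix, no_anti, identity_tr, range(x),
                            resp_threshold = 0.5)
  expect_equal(win2$upper, (25 + 2 * log(3)) / 10, tolerance = 0.02)
  expect_equal(win2$source[2], "posterior_responsibility")
})

test_that("two-sided contamination leaves a window around the healthy mean", {
  set.seed(13)
  x <- c(rnorm(1000, -6), rnorm(6000, 0), rnorm(1000, 6))
  mix <- known_mixture(c(0.125, 0.75, 0.125), c(-6, 0, 6), c(1, 1, 1))
  modes <- find_modes_antimodes(x)
  win <- choose_truncation(mix, modes, identity_tr, range(x),
                           resp_threshold = 0.5)
  expect_gt(win$lower, -6)
  expect_lt(win$upper, 6)
  expect_true(win$lower < 0 && win$upper > 0)
})

test_that("antimode override is recorded in the window provenance", {
  set.seed(14)
  x <- c(rnorm(6000, 0), rnorm(4000, 6))
  mix <- known_mixture(c(0.6, 0.4), c(0, 6), c(1, 1))
  modes <- find_modes_antimodes(x)
  expect_length(modes$antimodes, 1)
  win <- choose_truncation(mix, modes, identity_tr, range(x),
                           resp_threshold = 0.1)
  expect_equal(win$source[2], "antimode")
  expect_equal(win$upper, modes$antimodes, tolerance = 1e-9)
})
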