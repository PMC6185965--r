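test_that("a response driven by one factor gives it all the variance", {
  tab <- tidyr::crossing(a = c("x", "y", "z"), b = c("u", "v"), c = 1:2)
  tab$y <- match(tab$a, c("x", "y", "z"))^2
  fac <- c("a", "b", "c")
  expect_equal(main_effect_index(tab, "a", fac, response = "y"), 1)
  expect_equal(main_effect_index(tab, "b", fac, response = "y"), 0)
  expect_equal(total_effect_index(tab, "b", fac, response = "y"), 0)
  expect_equal(total_effect_index(tab, "a", fac, response = "y"), 1)
})

test_that("additive responses split variance exactly and have TS = ME", {
  tab <- tidyr::crossing(a = 0:1, b = 0:1)
  tab$y <- tab$a + tab$b
  fac <- c("a", "b")
  si <- sensitivity_indices(tab, fac, response = "y")
  expect_equal(si$main_effect, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(si$total_effect, si$main_effect, tolerance = 1e-12)
  expect_equal(sum(si$main_effect), 1, tolerance = 1e-12)
})

test_that("a pure interaction has zero main effects and unit total effects", {
  tab <- tidyr::crossing(a = c(-1, 1), b = c(-1, 1))
  tab$y <- tab$a * tab$b
  si <- sensitivity_indices(tab, c("a", "b"), response = "y")
  expect_equal(si$main_effect, c(0, 0), tolerance = 1e-12)
  expect_equal(si$total_effect, c(1, 1), tolerance = 1e-12)
})

test_that("the implementation matches the brute-force oracle on random factorials", {
  for (s in 1:60) {
    tab <- random_factorial(s)
    si <- sensitivity_indices(tab, paste0("f", 1:4), response = "y")
    or <- oracle_indices(tab, paste0("f", 1:4), response = "y")
    expect_equal(si$main_effect, unname(or$me[si$factor]), tolerance = 1e-12)
    expect_equal(si$total_effect, unname(or$ts[si$factor]), tolerance = 1e-12)
    expect_true(all(si$main_effect <= si$total_effect + 1e-12))
    expect_true(all(si$main_effect >= -1e-12 & si$total_effect <= 1 + 1e-12))
  }
})

test_that("indices are invariant to row order and affine response transforms", {
  tab <- random_factorial(99)
  si <- sensitivity_indices(tab, paste0("f", 1:4), response = "y")
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(sensitivity_indices(perm, paste0("f", 1:4), response = "y"),
               si, tolerance = 1e-12, ignore_attr = TRUE)
  aff <- dplyr::mutate(tab, y = 3.2 * y - 11)
  expect_equal(sensitivity_indices(aff, paste0("f", 1:4), response = "y"),
               si, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("unbalanced or degenerate designs are rejected", {
  tab <- tidyr::crossing(a = 0:1, b = 0:1)
  tab$y <- tab$a + tab$b
  expect_error(sensitivity_indices(tab[-1, ], c("a", "b"), response = "y"),
               "balanced")
  tab$y <- 1
  expect_error(sensitivity_indices(tab, c("a", "b"), response = "y"),
               "var\\(Y\\)")
})

test_that("replicates can feed var(Y) for noise-inclusive decompositions", {
  set.seed(8)
  tab <- tidyr::crossing(g = paste0("g", 1:4), m = paste0("m", 1:4), rep = 1:50)
  g_eff <- stats::setNames(rnorm(4), paste0("g", 1:4))
  tab$y <- g_eff[tab$g] + rnorm(nrow(tab), 0, 0.5)
  me_collapsed <- main_effect_index(tab, "g", c("g", "m"), response = "y")
  me_reps <- main_effect_index(tab, "g", c("g", "m"), response = "y",
                               collapse_replicates = FALSE)
  expect_gt(me_collapsed, me_reps) # noise inflates var(Y) only when kept
})

test_that("pathway/GCM restriction recovers a balanced sub-design", {
  tab <- tidyr::crossing(gcm = c("g1", "g2", "g3"), model = c("m1", "m2"),
                         scenario = c("rcp45", "rcp85"), co2_arm = c("amb", "ele"))
  tab <- dplyr::filter(tab, !(scenario == "rcp45" & gcm == "g3"))
  set.seed(2)
  tab$yield <- rnorm(nrow(tab))
  expect_error(decompose_uncertainty(tab, policy = "error"), "unbalanced")
  expect_message(out <- decompose_uncertainty(tab), "restricting")
  expect_s3_class(out, "sensitivity_indices")
  expect_equal(sort(unique(out$factor)),
               sort(c("gcm", "model", "scenario", "co2_arm")))
  expect_s3_class(autoplot(out), "ggplot")
  expect_s3_class(tidy(out), "tbl_df")
})
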