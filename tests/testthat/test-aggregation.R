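# hand-built tables make the weighted arithmetic transparent
mini_areas <- function() {
  tibble::tibble(
    cell_id = c("a", "b", "c"),
    crop = "grain_maize",
    region = c("r1", "r1", "r2"),
    area_rainfed = c(1, 3, 2),
    area_irrigated = c(2, 1, 4)
  )
}

mini_table <- function(yields, treatment = "T4") {
  tibble::tibble(cell_id = c("a", "b", "c"), crop = "grain_maize",
                 treatment = treatment, year = 1, yield = yields)
}

test_that("aggregation is the production-weighted mean", {
  areas <- mini_areas()
  # cells {y=2, a=1} and {y=4, a=3} -> 3.5
  agg <- aggregate_yield(mini_table(c(2, 4, 5)), areas, "region", "rainfed")
  expect_equal(agg$yield[agg$unit == "r1"], 3.5)
  expect_equal(agg$yield[agg$unit == "r2"], 5) # single cell: its own yield
  # constant field -> the constant, any weights
  flat <- aggregate_yield(mini_table(c(7, 7, 7)), areas, "all", "total")
  expect_equal(flat$yield, 7)
})

test_that("the rainfed/irrigated mix weighs each regime by its own area", {
  areas <- mini_areas()
  tab <- dplyr::bind_rows(mini_table(c(2, 4, 5), "T4"),
                          mini_table(c(6, 8, 10), "T1"))
  mix <- aggregate_yield(tab, areas, "region", "mix")
  # r1: (2*1 + 6*2 + 4*3 + 8*1) / (1+2+3+1)
  expect_equal(mix$yield[mix$unit == "r1"], (2 + 12 + 12 + 8) / 7)
  expect_equal(mix$treatment[mix$unit == "r1"], "T4")
  tab_no_irr <- mini_table(c(2, 4, 5), "T4")
  expect_error(aggregate_yield(tab_no_irr, areas, "region", "mix"),
               "counterpart")
})

test_that("production mass is conserved and aggregation commutes with grouping", {
  set.seed(21)
  areas <- mini_areas()
  tab <- mini_table(runif(3, 2, 9))
  reg <- aggregate_yield(tab, areas, "region", "rainfed")
  eu <- aggregate_yield(tab, areas, "all", "rainfed")
  w <- areas$area_rainfed
  expect_equal(sum(tab$yield * w), sum(reg$yield *
    tapply(w, areas$region, sum)[reg$unit]))
  # cell -> region -> EU equals cell -> EU
  reg_w <- tapply(w, areas$region, sum)[reg$unit]
  expect_equal(sum(reg$yield * reg_w) / sum(reg_w), eu$yield)
  expect_true(eu$yield >= min(tab$yield) && eu$yield <= max(tab$yield))
})

test_that("missing cells and empty units are rejected", {
  areas <- mini_areas()
  orphan <- dplyr::mutate(mini_table(c(1, 2, 3)),
                          cell_id = c("a", "b", "zz"))
  expect_error(aggregate_yield(orphan, areas, "region", "rainfed"), "missing")
  zero <- dplyr::mutate(areas, area_irrigated = 0)
  expect_error(aggregate_yield(mini_table(c(1, 2, 3)), zero, "region",
                               "irrigated"), "zero total")
})

test_that("potential on rainfed land matches the definitional slice", {
  areas <- mini_areas()
  tab <- dplyr::bind_rows(mini_table(c(2, 4, 5), "T4"),
                          mini_table(c(6, 8, 10), "T1"))
  a <- potential_on_rainfed_land(tab, areas, "region")
  b <- aggregate_yield(dplyr::filter(tab, treatment == "T1"), areas,
                       "region", "rainfed")
  expect_equal(a, b)
  # weights are permutation invariant
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(dplyr::arrange(potential_on_rainfed_land(perm, areas, "region"),
                              unit),
               dplyr::arrange(a, unit))
})

test_that("the environment index is 1 without drought and below 1 with it", {
  areas <- mini_areas()
  no_drought <- dplyr::bind_rows(mini_table(c(6, 8, 10), "T4"),
                                 mini_table(c(6, 8, 10), "T1"))
  idx <- environment_index(no_drought, areas, "region")
  expect_equal(idx$environment_index, c(1, 1))
  drought <- dplyr::bind_rows(mini_table(c(3, 4, 5), "T4"),
                              mini_table(c(6, 8, 10), "T1"))
  idx2 <- environment_index(drought, areas, "region")
  expect_true(all(idx2$environment_index < 1))
  expect_identical(environment_index(drought, areas, "region"), idx2)
})
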