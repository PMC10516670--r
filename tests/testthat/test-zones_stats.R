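test_that("row assignment bins centroid x at the given or inferred pitch", {
  rois <- list(square_roi("a", 0, 0, 10),   # centroid x = 5
               square_roi("b", 10, 0, 10),  # 15
               square_roi("c", 20, 0, 10))  # 25
  out <- assign_rows(rois, row_pitch = 10)
  expect_identical(vapply(out, `[[`, integer(1), "row_index"), 0:2)
  # identical centroids all land in row 0
  same <- assign_rows(list(square_roi("a", 0, 0, 10),
                           square_roi("b", 0, 0, 10)), row_pitch = 10)
  expect_identical(vapply(same, `[[`, integer(1), "row_index"), c(0L, 0L))
  # default pitch: median nearest-neighbor spacing of distinct centroid x
  auto <- assign_rows(rois)
  expect_identical(vapply(auto, `[[`, integer(1), "row_index"), 0:2)
})

test_that("synthetic grid scenes recover the generator's row labels", {
  spec <- scene_spec(n_nuclei = 12, rows = 3, nucleus_radius_vox = 10,
                     seed = 3, render = FALSE,
                     species_params = list(
                       "RAD-51" = species_param(647, n_mean = 1)))
  scene <- generate_scene(spec)
  rowed <- assign_rows(scene$rois)
  expect_identical(vapply(rowed, `[[`, integer(1), "row_index"),
                   scene$truth$nuclei$row)
})

test_that("the majority zone is the longest contiguous run of >50% rows", {
  rows <- rep(0:14, each = 4)
  flags <- rows >= 3 & rows <= 10
  z <- majority_zone(flags, rows)
  expect_identical(c(z$start_row, z$end_row, z$length_rows), c(3L, 10L, 8L))
  none <- majority_zone(rep(FALSE, 10), rep(0:4, 2))
  expect_identical(none$length_rows, 0L)
  expect_true(is.na(none$start_row))
  # exactly 50% is not a majority
  half <- majority_zone(c(TRUE, FALSE), c(0L, 0L))
  expect_identical(half$length_rows, 0L)
  expect_error(majority_zone(logical(0), integer(0)), "empty")
})

test_that("majority zone equals the exhaustive run-enumeration oracle", {
  set.seed(404)
  for (rep in 1:30) {
    n_rows <- sample(5:30, 1)
    rows <- sample(0:(n_rows - 1), n_rows * 3, replace = TRUE)
    flags <- runif(length(rows)) < 0.5
    got <- majority_zone(flags, rows)
    want <- oracle_majority_zone(flags, rows)
    expect_identical(got$length_rows, as.integer(want$len))
    if (want$len > 0) {
      expect_identical(got$start_row, as.integer(want$start))
      expect_identical(got$end_row, as.integer(want$end))
    }
  }
})

test_that("count-rule boundaries give the early pachytene zone construction", {
  # 20 rows, 3 nuclei each; RAD-51 present from row 4, 6 MSH-5 from row 12
  nuclei <- sprintf("n%03d", 1:60)
  rows <- stats::setNames(rep(0:19, each = 3), nuclei)
  counts <- do.call(rbind, lapply(seq_along(nuclei), function(i) {
    r <- rows[i]
    data.frame(nucleus_id = nuclei[i],
               species = c("RAD-51", "MSH-5"),
               n = c(if (r >= 4) 2L else 0L, if (r >= 12) 6L else 1L),
               stringsAsFactors = FALSE)
  }))
  z <- boundary_by_count_rule(counts, rows,
                              p_start = function(n) n[["RAD-51"]] >= 1,
                              p_end = function(n) n[["MSH-5"]] == 6)
  expect_identical(c(z$start_row, z$end_row), c(4L, 12L))
  expect_error(
    boundary_by_count_rule(counts, rows,
                           p_start = function(n) n[["RAD-51"]] >= 1,
                           p_end = function(n) n[["MSH-5"]] == 99),
    "end rule unmet")
  expect_error(
    boundary_by_count_rule(counts, rows,
                           p_start = function(n) n[["RAD-51"]] >= 50,
                           p_end = function(n) TRUE),
    "start rule unmet")
})

test_that("count-rule boundaries recover generator onset rows", {
  spec <- scene_spec(n_nuclei = 48, rows = 3, nucleus_radius_vox = 10,
                     seed = 61, render = FALSE,
                     species_params = list(
                       "RAD-51" = species_param(647, n_exact = 2,
                                                onset_row = 4),
                       "MSH-5" = species_param(555, n_exact = 6,
                                               onset_row = 10)))
  scene <- generate_scene(spec)
  rows <- stats::setNames(scene$truth$nuclei$row,
                          scene$truth$nuclei$nucleus_id)
  tr <- scene$truth$foci
  counts <- as.data.frame(table(nucleus_id = tr$nucleus_id,
                                species = tr$species),
                          stringsAsFactors = FALSE)
  names(counts) <- c("nucleus_id", "species", "n")
  z <- boundary_by_count_rule(counts, rows,
                              p_start = function(n) n[["RAD-51"]] >= 1,
                              p_end = function(n) n[["MSH-5"]] == 6)
  expect_identical(c(z$start_row, z$end_row), c(4L, 10L))
})

test_that("peak windows maximize the median count, earliest on ties", {
  rows <- rep(0:24, each = 2)
  counts <- ifelse(rows >= 8 & rows <= 17, 30, 2) + rows %% 2
  z <- peak_window(counts, rows, width_rows = 10)
  expect_identical(c(z$start_row, z$end_row), c(8L, 17L))
  const <- peak_window(rep(5, 30), rep(0:14, each = 2), width_rows = 10)
  expect_identical(const$start_row, 0L)  # tie rule: earliest window
  whole <- peak_window(1:10, 0:9, width_rows = 10)
  expect_identical(c(whole$start_row, whole$end_row), c(0L, 9L))
  expect_error(peak_window(1:3, 0:2, width_rows = 10), "exceeds")
})

test_that("peak window equals the exhaustive window-scan oracle", {
  set.seed(505)
  for (rep in 1:30) {
    n_rows <- sample(12:30, 1)
    rows <- sample(0:(n_rows - 1), n_rows * 2, replace = TRUE)
    counts <- rpois(length(rows), 5)
    width <- sample(3:10, 1)
    got <- peak_window(counts, rows, width_rows = width)
    want <- oracle_peak_window(counts, rows, width)
    expect_identical(got$start_row, as.integer(want$start))
    expect_equal(attr(got, "median_count"), want$median)
  }
})

test_that("group comparisons delegate to the canonical two-sided tests", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  mw <- compare_groups(x, x, test = "mann-whitney")
  expect_equal(mw$p_value, 1)
  fisher_flat <- compare_groups(c(10, 10), c(10, 10), test = "fisher-exact")
  expect_equal(fisher_flat$p_value, 1)
  expect_equal(fisher_flat$estimate, 1, tolerance = 1e-6)
  # [[5,0],[0,5]]: closed-form hypergeometric two-sided p = 2/choose(10,5)
  fisher_ex <- compare_groups(c(5, 0), c(0, 5), test = "fisher-exact")
  expect_equal(fisher_ex$p_value, 2 / choose(10, 5))
  w <- compare_groups(c(1, 2, 3, 4), c(10, 11, 12, 13), test = "welch-t")
  expect_equal(w$p_value,
               t.test(c(1, 2, 3, 4), c(10, 11, 12, 13))$p.value)
  expect_error(compare_groups(numeric(0), x, test = "welch-t"), "empty")
  expect_error(compare_groups(c(1, 2, 3), test = "fisher-exact"), "2x2")
})

test_that("brood viability follows the largest-count total and the footnote formulas", {
  v <- brood_viability(eggs_tp1 = 100, eggs_tp2 = 100, unhatched_tp2 = 5,
                       adults_tp3 = 90, males_tp3 = 0)
  expect_equal(v$total_eggs, 100)
  expect_equal(v$pct_hatching, 95)
  expect_equal(v$pct_adulthood, 90)
  expect_equal(v$pct_males, 0)
  # adults exceeding both egg counts set the total ("whichever was larger")
  v2 <- brood_viability(100, 100, 0, 120, 6)
  expect_equal(v2$total_eggs, 120)
  expect_equal(v2$pct_adulthood, 100)
  expect_equal(v2$pct_males, 5)
  # all eggs unhatched
  v3 <- brood_viability(50, 50, 50, 0, 0)
  expect_equal(v3$pct_hatching, 0)
  expect_true(is.na(v3$pct_males))
  expect_error(brood_viability(0, 0, 0, 0, 0), "total_eggs = 0")
  # percentages stay in [0, 100] across random legal inputs
  set.seed(9)
  for (i in 1:20) {
    tot <- sample(50:200, 1)
    unh <- sample(0:tot, 1)
    ad <- sample(0:tot, 1)
    vi <- brood_viability(tot, tot, unh, ad, sample(0:ad, 1))
    expect_true(all(unlist(vi[c("pct_hatching", "pct_adulthood")]) >= 0))
    expect_true(all(unlist(vi[c("pct_hatching", "pct_adulthood")]) <= 100))
  }
})
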