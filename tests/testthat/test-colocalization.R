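nm_foci <- function(zyx_nm, species = "q") {
  n <- nrow(zyx_nm)
  data.frame(focus_id = sprintf("%s%03d", species, seq_len(n)),
             species = rep(species, n),
             z_vox = rep(0, n), y_vox = rep(0, n), x_vox = rep(0, n),
             z_nm = zyx_nm[, 1], y_nm = zyx_nm[, 2], x_nm = zyx_nm[, 3],
             peak_height = rep(1000, n), stringsAsFactors = FALSE)
}

test_that("resolution thresholds follow the Rayleigh criterion", {
  expect_equal(resolution_threshold(555, 1.4), 0.61 * 555 / 1.4)
  expect_identical(resolution_threshold(555, 1.4, reported = TRUE), 242)
  expect_identical(resolution_threshold(647, 1.4, reported = TRUE), 282)
  expect_equal(resolution_threshold(700, 0.61), 700)  # algebraic identity
  expect_error(resolution_threshold(-555, 1.4), "positive")
})

test_that("nearest-neighbor classification is strict at the threshold", {
  q <- nm_foci(matrix(c(0, 0, 0), 1))
  r <- nm_foci(matrix(c(100, 100, 100), 1), "r")
  rec <- nearest_neighbor_classify(q, r, 242)
  expect_equal(rec$nn_dist_nm, sqrt(3) * 100)
  expect_true(rec$colocalized)
  expect_false(nearest_neighbor_classify(q, r, 150)$colocalized)
  # distance exactly at the threshold is not colocalized ("under")
  exact <- nearest_neighbor_classify(q, r, sqrt(3) * 100)
  expect_false(exact$colocalized)
  # empty reference: infinite distance, never colocalized
  none <- nearest_neighbor_classify(q, nm_foci(matrix(numeric(0), 0, 3), "r"),
                                    242)
  expect_identical(none$nn_dist_nm, Inf)
  expect_false(none$colocalized)
})

test_that("classification is directional", {
  # two a foci share the one b focus as nearest neighbor
  a <- nm_foci(matrix(c(0, 0, 0, 0, 0, 200), 2, byrow = TRUE), "a")
  b <- nm_foci(matrix(c(0, 0, 90), 1), "b")
  ab <- nearest_neighbor_classify(a, b, 242)
  ba <- nearest_neighbor_classify(b, a, 242)
  expect_identical(sum(ab$colocalized), 2L)
  expect_identical(sum(ba$colocalized), 1L)
})

test_that("classification equals the all-pairs brute-force oracle", {
  set.seed(303)
  for (rep in 1:10) {
    q <- matrix(runif(3 * 60, 0, 3000), ncol = 3)
    r <- matrix(runif(3 * 60, 0, 3000), ncol = 3)
    thr <- runif(1, 100, 500)
    got <- nearest_neighbor_classify(nm_foci(q), nm_foci(r, "r"), thr)
    want <- oracle_nearest_neighbor(q, r, thr)
    expect_equal(got$nn_dist_nm, want$nn_dist_nm)
    expect_identical(got$colocalized, want$colocalized)
  }
})

test_that("colocalized fraction is monotone non-decreasing in the threshold", {
  set.seed(17)
  q <- nm_foci(matrix(runif(90, 0, 2000), ncol = 3))
  r <- nm_foci(matrix(runif(90, 0, 2000), ncol = 3), "r")
  fr <- vapply(c(100, 242, 282, 500, 1000), function(thr)
    mean(nearest_neighbor_classify(q, r, thr)$colocalized), numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("three-species categories partition each species' foci", {
  a <- nm_foci(matrix(c(0, 0, 0,
                        0, 0, 5000), 2, byrow = TRUE), "A")
  b <- nm_foci(matrix(c(0, 0, 100), 1), "B")
  c_ <- nm_foci(matrix(c(0, 100, 0,
                         5000, 5000, 5000), 2, byrow = TRUE), "C")
  out <- categorize_three_species(list(A = a, B = b, C = c_),
                                  thresholds = 242)
  labels <- attr(out, "labels")
  expect_identical(labels$category[labels$focus_id == "A001"], "A+B+C")
  expect_identical(labels$category[labels$focus_id == "A002"], "solo")
  expect_identical(labels$category[labels$focus_id == "B001"], "B+A+C")
  expect_identical(labels$category[labels$focus_id == "C002"], "solo")
  for (sp in c("A", "B", "C")) {
    expect_identical(sum(out$n[out$species == sp]),
                     nrow(get(if (sp == "C") "c_" else tolower(sp))))
  }
})

test_that("three-species labels on a synthetic pairing match ground truth", {
  spec <- scene_spec(n_nuclei = 40, rows = 4, seed = 99, render = FALSE,
                     species_params = list(
                       "RAD-51" = species_param(647, n_mean = 6),
                       "MSH-5" = species_param(555, n_mean = 3)),
                     coloc_spec = list(pair = c("RAD-51", "MSH-5"),
                                       fraction = 0.5))
  scene <- generate_scene(spec)
  tr <- scene$truth$foci
  a <- tr[tr$species == "RAD-51", ]
  b <- tr[tr$species == "MSH-5", ]
  rec <- nearest_neighbor_classify(b, a, resolution_threshold(647))
  expect_setequal(rec$focus_id[rec$colocalized], scene$truth$pairs$b_id)
  paired <- rec[rec$colocalized, ]
  expect_identical(
    paired$nn_partner_id,
    scene$truth$pairs$a_id[match(paired$focus_id, scene$truth$pairs$b_id)])
})

test_that("coloc_report reproduces printed percentages from tallies", {
  fake_records <- function(k, n) {
    data.frame(focus_id = sprintf("f%04d", seq_len(n)),
               species = rep("s", n),
               nn_dist_nm = c(rep(100, k), rep(1000, n - k)),
               nn_partner_id = rep("p", n),
               colocalized = c(rep(TRUE, k), rep(FALSE, n - k)),
               rel_position_pct = rep(NA_real_, n),
               stringsAsFactors = FALSE)
  }
  r1 <- coloc_report(fake_records(92, 1434))
  expect_equal(round(r1$percent, 1), 6.4)
  r2 <- coloc_report(fake_records(487, 1434))
  expect_equal(round(r2$percent), 34)
  # 0/100: fraction 0, CI lower bound 0 (Wilson)
  r0 <- coloc_report(fake_records(0, 100))
  expect_equal(r0$percent, 0)
  expect_equal(r0$ci_lower, 0)
  # 50/100: Wilson interval is symmetric about 0.5
  r50 <- coloc_report(fake_records(50, 100))
  expect_equal(r50$ci_lower + r50$ci_upper, 1, tolerance = 1e-10)
  # direct evaluation of the Wilson formula at 95%
  z <- qnorm(0.975)
  p <- 0.5; n <- 100
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  center <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  expect_equal(r50$ci_lower, center - half, tolerance = 1e-10)
  # empty input: undefined fraction, count 0
  r_empty <- coloc_report(fake_records(0, 0))
  expect_identical(r_empty$n_total, 0L)
  expect_true(is.na(r_empty$fraction))
  # Clopper-Pearson alternative
  cp <- coloc_report(fake_records(50, 100), ci_method = "clopper-pearson")
  expect_equal(c(cp$ci_lower, cp$ci_upper),
               as.numeric(binom.test(50, 100)$conf.int), tolerance = 1e-10)
})

test_that("recovered pair fractions track the nominal ones at n in the hundreds", {
  for (p in c(0.1, 0.9)) {
    spec <- scene_spec(n_nuclei = 60, rows = 4, seed = 120 + round(10 * p),
                       render = FALSE,
                       species_params = list(
                         "RAD-51" = species_param(647, n_mean = 8),
                         "MSH-5" = species_param(555, n_mean = 4)),
                       coloc_spec = list(pair = c("RAD-51", "MSH-5"),
                                         fraction = p))
    scene <- generate_scene(spec)
    tr <- scene$truth$foci
    b <- tr[tr$species == "MSH-5", ]
    rec <- nearest_neighbor_classify(b, tr[tr$species == "RAD-51", ],
                                     resolution_threshold(647))
    tol <- 3 * sqrt(p * (1 - p) / nrow(b))
    expect_lt(abs(mean(rec$colocalized) - p), tol)
  }
})
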