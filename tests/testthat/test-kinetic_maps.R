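# build a tiny series where one pixel follows a prescribed curve
series_from_curve <- function(si) {
  ph <- lapply(si, function(v) matrix(v, 3, 3))
  dce_series(ph)
}
full_mask <- matrix(TRUE, 3, 3)

test_that("per-pixel formulas reproduce hand-computed values", {
  s <- series_from_curve(c(100, 200, 300, 300, 300, 300, 300, 300, 300))
  expect_equal(compute_map(s, full_mask, "E_initial")$map[1, 1], 100)
  expect_equal(compute_map(s, full_mask, "SEP")$map[1, 1], 200)
  expect_equal(compute_map(s, full_mask, "ESER")$map[1, 1], 50)

  # peak hunting and slope arithmetic
  s2 <- series_from_curve(c(100, 150, 170, 160, 140, 130, 120, 110, 105))
  expect_equal(compute_map(s2, full_mask, "MSI")$map[1, 1], 50)
  expect_equal(compute_map(s2, full_mask, "SI_slope")$map[1, 1], -34.375)
  expect_equal(compute_map(s2, full_mask, "E_peak")$map[1, 1], 70)
})

test_that("forced identities hold: ESER=100 when SI1=SI2, SER=100 when peak at phase 8", {
  s <- series_from_curve(c(100, 180, 180, 190, 200, 210, 220, 230, 240))
  expect_equal(compute_map(s, full_mask, "ESER")$map[1, 1], 100)
  expect_equal(compute_map(s, full_mask, "SER")$map[1, 1], 100)
})

test_that("constant series follows the degenerate-denominator policy", {
  s <- series_from_curve(rep(120, 9))
  for (nm in c("E_initial", "E_peak", "SEP", "MSI", "SI_slope")) {
    expect_equal(compute_map(s, full_mask, nm)$map[1, 1], 0)
  }
  for (nm in c("ESER", "SER")) {
    r <- compute_map(s, full_mask, nm)
    expect_false(r$validity[1, 1])
    expect_true(is.nan(r$map[1, 1]))
  }
})

test_that("maps are scale-invariant except MSI, which scales linearly", {
  cs <- generate_case(1, seed = 21)
  scaled <- cs$series
  scaled$phases <- lapply(scaled$phases, function(p) 3 * p)
  m1 <- compute_all_maps(cs$series, cs$mask)
  m2 <- compute_all_maps(scaled, cs$mask)
  for (nm in setdiff(kinetic_map_names(), "MSI")) {
    v <- m1$validity[[nm]] & m2$validity[[nm]]
    expect_equal(m2$maps[[nm]][v], m1$maps[[nm]][v], tolerance = 1e-9)
  }
  v <- m1$validity$MSI
  expect_equal(m2$maps$MSI[v], 3 * m1$maps$MSI[v], tolerance = 1e-9)
})

test_that("the peak dominates any single phase: E_peak >= E_initial and >= SEP", {
  for (s in 31:35) {
    cs <- generate_case(s %% 2, seed = s)
    ep <- compute_map(cs$series, cs$mask, "E_peak")
    ei <- compute_map(cs$series, cs$mask, "E_initial")
    sp <- compute_map(cs$series, cs$mask, "SEP")
    v <- ep$validity & ei$validity & sp$validity
    expect_true(all(ep$map[v] >= ei$map[v] - 1e-9))
    expect_true(all(ep$map[v] >= sp$map[v] - 1e-9))
  }
})

test_that("noise-free homogeneous lesion means equal the closed-form values", {
  tr <- kinetic_truth(S0 = 100, A = 1.5, t_p = 2, w = 0.1, h = 0)
  cs <- generate_case(1, seed = 41, snr = Inf, truth = tr)
  maps <- compute_all_maps(cs$series, cs$mask)
  si <- sample_timecourse(tr, 0:8)
  s_peak <- max(si[-1])
  s_mean <- (si[2] + si[3]) / 2
  expected <- c(E_initial = (si[2] - si[1]) / si[1] * 100,
                E_peak = (s_peak - si[1]) / si[1] * 100,
                ESER = (si[2] - si[1]) / (si[3] - si[1]) * 100,
                MSI = max(diff(si)),
                SEP = (si[3] - si[1]) / si[1] * 100,
                SER = (s_peak - si[1]) / (si[9] - si[1]) * 100,
                SI_slope = (si[9] - s_mean) / s_mean * 100)
  expect_equal(lesion_means(maps), expected, tolerance = 1e-9)
})

test_that("lesion_mean averages valid pixels and errors on empty validity", {
  m <- matrix(c(10, 20, 30, 999), 2, 2)
  v <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  expect_equal(lesion_mean(m, v), 20)
  expect_error(lesion_mean(m, matrix(FALSE, 2, 2)), "no valid pixels")

  s <- series_from_curve(1:9 * 10)
  expect_error(compute_map(s, matrix(FALSE, 3, 3), "ESER"), "empty")
  expect_error(compute_map(s, full_mask, "nope"))
})

test_that("compute_all_maps returns exactly the seven named maps", {
  cs <- generate_case(0, seed = 51, grid = 64, axes_range = c(8, 20))
  maps <- compute_all_maps(cs$series, cs$mask)
  expect_identical(names(maps$maps), kinetic_map_names())
  expect_identical(length(maps$maps), 7L)
  for (nm in kinetic_map_names()) {
    expect_true(all(is.finite(maps$maps[[nm]][maps$validity[[nm]]])))
    # validity never exceeds the lesion mask
    expect_true(all(maps$mask[maps$validity[[nm]]]))
  }
})
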