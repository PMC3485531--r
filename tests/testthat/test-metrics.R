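test_that("SDI is the standard deviation of segmental times", {
  expect_equal(compute_sdi(rep(40, 16)), 0)
  # 15 at 40, one at 56: sum of squared deviations 240, /15 = 16, sqrt = 4
  expect_equal(compute_sdi(c(rep(40, 15), 56)), 4)
  expect_equal(compute_sdi(c(rep(40, 15), 56), divisor = "n"),
               sqrt(240 / 16))
  # translation invariance
  set.seed(11)
  tt <- runif(16, 10, 60)
  expect_equal(compute_sdi(tt + 7), compute_sdi(tt))
  expect_error(compute_sdi(rep(40, 12)), "16")
  expect_warning(compute_sdi(rep(c(40, 44), 6), allow_partial = TRUE), "12")
})

test_that("L-E is the earliest-to-latest spread", {
  expect_equal(compute_le(rep(40, 16)), 0)
  expect_equal(compute_le(c(rep(40, 15), 56)), 16)
  set.seed(12)
  tt <- runif(16, 0, 80)
  expect_equal(compute_le(sample(tt)), compute_le(tt))
})

test_that("a single segment's STV area matches hand integration", {
  crv <- tv_curve(c(0, 25, 50, 75, 100), c(10, 4, 6, 8, 10), "mid_anterior")
  e <- segment_stv(crv, t_seg_es = 25, v_seg_min = 4, t_glob_es = 50)
  expect_identical(e$classification, "pre")
  expect_equal(e$area, 25)  # trapezoid of (0 at t=25, 2 at t=50)

  sync <- segment_stv(crv, 25, 4, 25)
  expect_identical(sync$classification, "synchronous")
  expect_equal(sync$area, 0)

  # linearity: doubling the excursion above the minimum doubles the area
  crv2 <- tv_curve(crv$times, 4 + 2 * (crv$volumes - 4), crv$label)
  e2 <- segment_stv(crv2, 25, 4, 50)
  expect_equal(e2$area, 2 * e$area)
})

test_that("STV sums partition the segments into pre/post/synchronous", {
  sync <- compute_stv(synchronous_study())
  expect_equal(sync$pre_stv, 0)
  expect_equal(sync$post_stv, 0)
  expect_true(all(sync$entries$classification == "synchronous"))

  # one early segment against synchronous ones reproduces the hand example:
  # 15 segments min at 50, one segment min at 25 with the example trace
  tm <- c(0, 25, 50, 75, 100)
  v <- matrix(rep(c(10, 6, 4, 6, 10), 16), ncol = 16,
              dimnames = list(NULL, lv_segments()))
  v[, 1] <- c(10, 4, 6, 8, 10)
  res <- compute_stv(curve_set(tm, v))
  expect_equal(res$pre_stv, 25)
  expect_equal(res$post_stv, 0)
  expect_identical(res$entries$classification[1], "pre")

  set.seed(21)
  for (i in 1:10) {
    r <- compute_stv(random_study(noise_sd = 0.2))
    expect_equal(r$total_stv, r$pre_stv + r$post_stv, tolerance = 1e-12)
    expect_setequal(unique(r$entries$classification) %in%
                      c("pre", "post", "synchronous"), TRUE)
    expect_equal(nrow(r$entries), 16)
  }
})

test_that("global function computes EDV, ESV and EF", {
  tm <- seq(0, 100, length.out = 5)
  v <- matrix(rep(c(188, 170, 152, 170, 188) / 16, 16), ncol = 16,
              dimnames = list(NULL, lv_segments()))
  gf <- compute_global_function(curve_set(tm, v))
  expect_equal(gf$edv, 188)
  expect_equal(gf$esv, 152)
  expect_equal(gf$ef, 100 * 36 / 188)  # 19.1%

  # EF scale invariance
  gf2 <- compute_global_function(curve_set(tm, v * 1.7))
  expect_equal(gf2$ef, gf$ef)
  expect_equal(gf2$edv, 1.7 * gf$edv)

  # flat ventricle: EF 0
  vflat <- matrix(5, nrow = 5, ncol = 16,
                  dimnames = list(NULL, lv_segments()))
  expect_equal(compute_global_function(curve_set(tm, vflat))$ef, 0)
})

test_that("analyze_study satisfies the report invariants", {
  r0 <- analyze_study(synchronous_study())
  expect_equal(r0$sdi, 0)
  expect_equal(r0$le, 0)
  expect_equal(r0$pre_stv, 0)
  expect_equal(r0$post_stv, 0)

  set.seed(31)
  for (i in 1:5) {
    r <- analyze_study(random_study(noise_sd = 0.1))
    expect_gte(r$edv, r$esv)
    expect_equal(r$ef, 100 * (r$edv - r$esv) / r$edv)
    expect_equal(r$total_stv, r$pre_stv + r$post_stv, tolerance = 1e-12)
    expect_equal(r$pre_stv,
                 sum(r$entries$area[r$entries$classification == "pre"]))
    expect_gte(r$sdi, 0)
    expect_gte(r$le, 0)
  }
  expect_named(coef(r0), c("edv", "esv", "ef", "sdi", "le",
                           "pre_stv", "post_stv", "total_stv"))
})

test_that("STV weights a delayed segment by its displaced volume", {
  # per-segment contribution is exactly linear in the amplitude scaling
  base <- single_early_study(k = 1)
  es <- end_systole_table(base)
  t_glob <- attr(es, "global_es_time")
  area1 <- segment_stv(segment_curve(base, "basal_anterior"),
                       es$es_time[1], es$es_volume[1], t_glob)$area
  for (k in c(0.5, 2)) {
    stk <- single_early_study(k = k)
    esk <- end_systole_table(stk)
    areak <- segment_stv(segment_curve(stk, "basal_anterior"),
                         esk$es_time[1], esk$es_volume[1],
                         attr(esk, "global_es_time"))$area
    expect_equal(areak, k * area1, tolerance = 1e-9)
  }

  # a hypokinetic delayed segment: timing indices keep moving, STV does not
  hypo <- analyze_study(single_early_study(k = 1e-3))
  full <- analyze_study(single_early_study(k = 1))
  expect_equal(hypo$sdi, full$sdi)
  expect_equal(hypo$le, full$le)
  expect_gt(full$pre_stv, 100 * hypo$pre_stv)
  expect_gt(hypo$sdi, 0)
})

test_that("STV is invariant under a constant volume offset of one segment", {
  set.seed(41)
  st <- random_study()
  r1 <- analyze_study(st)
  st$volumes[, 3] <- st$volumes[, 3] + 5
  st2 <- curve_set(st$times, st$volumes, study_id = st$study_id)
  r2 <- analyze_study(st2)
  expect_equal(r2$pre_stv, r1$pre_stv, tolerance = 1e-9)
  expect_equal(r2$post_stv, r1$post_stv, tolerance = 1e-9)
  expect_equal(r2$sdi, r1$sdi)
})
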