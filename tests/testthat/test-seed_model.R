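test_that("cross-section helix counts match the rim-minus-pore arithmetic", {
  s48 <- build_cross_section(cross_section_spec("square", 8, 8, 4, 4))
  expect_identical(s48$helix_count, 48L)
  h54 <- build_cross_section(cross_section_spec("honeycomb", 12, 6, 6, 3))
  expect_identical(h54$helix_count, 54L)
  # degenerate: pore swallows the rim
  d0 <- build_cross_section(cross_section_spec("square", 4, 4, 4, 4))
  expect_identical(d0$helix_count, 0L)
  expect_true(d0$degenerate)
  # exact rim*rim - pore*pore for a grid of square specs
  for (rim in c(3, 6, 9)) for (pore in 0:rim) {
    hl <- build_cross_section(cross_section_spec("square", rim, rim, pore, pore))
    expect_identical(hl$helix_count, as.integer(rim^2 - pore^2))
  }
  expect_error(cross_section_spec("square", 4, 4, 6, 2), "pore")
  # no duplicate helix centres
  expect_false(any(duplicated(s48$centres)))
  expect_false(any(duplicated(h54$centres)))
})

test_that("segment heights reproduce the printed designs and stay linear in bp", {
  expect_equal(round(segment_height(128, 0.34), 1), 43.5)
  expect_equal(round(segment_height(32, 0.34), 1), 10.9)
  expect_equal(round(segment_height(36, 0.34), 1), 12.2)
  expect_equal(round(segment_height(126, 0.34), 1), 42.8)
  expect_equal(segment_height(0, 0.34), 0)
  # additivity of concatenated segments (exact, not printed-rounded)
  bp <- c(7, 19, 32, 101)
  expect_equal(segment_height(sum(bp), 0.34), sum(segment_height(bp, 0.34)))
  expect_error(segment_height(-1), "non-negative")
  expect_error(segment_height(10, rise = 0), "positive")
})

test_that("segment twist follows the per-array calibration rates", {
  expect_equal(segment_twist(32, 3.8 / 32), 3.8)
  expect_equal(segment_twist(36, 1.2 / 36), 1.2)
  expect_equal(segment_twist(0, 0.5), 0)
  expect_error(segment_twist(-2, 0.1), "non-negative")
})

test_that("compile_stack produces the square-seed trilayer registry", {
  st <- compile_stack(seed_preset("S"))
  expect_equal(nrow(st), 3)
  expect_equal(round(st$z_lo_nm, 1), c(0, 54.4, 108.8))
  expect_equal(round(st$z_hi_nm, 1), c(43.5, 97.9, 152.3))
  expect_equal(st$orientation_deg, c(0, 3.8, 7.6))
  # conservation: total height equals the sum over all segments
  s <- seed_preset("S")
  expect_equal(attr(st, "total_height_nm"),
               sum(vapply(s$segments, function(x) x$bp, 0)) * s$rise)
})

test_that("layer orientations accumulate spacer twists exactly", {
  h <- seed_preset("H", n_layers = 2)
  st <- compile_stack(h)
  expect_equal(nrow(st), 2)
  expect_equal(diff(st$orientation_deg), 1.2)
  # property: orientation steps equal the intervening spacer twist, and are
  # non-decreasing for all-positive twists
  set.seed(41)
  for (rep in 1:5) {
    n_growth <- sample(2:4, 1)
    twists <- round(stats::runif(n_growth - 1, 0.5, 6), 2)
    segs <- list(seed_segment("Z1", "growth", 128))
    for (i in seq_along(twists)) {
      segs <- c(segs, list(
        seed_segment(paste0("S", i), "spacer_twister", 32, twist = twists[i]),
        seed_segment(paste0("G", i + 1), "growth", 128)))
    }
    sd <- seed_design("rand", cross_section_spec("square", 8, 8, 4, 4), segs)
    st <- compile_stack(sd)
    expect_equal(diff(st$orientation_deg), twists)
    expect_true(all(diff(st$orientation_deg) >= 0))
    # z intervals strictly increasing and non-overlapping
    expect_true(all(st$z_hi_nm > st$z_lo_nm))
    expect_true(all(st$z_lo_nm[-1] >= st$z_hi_nm[-nrow(st)]))
  }
})

test_that("empty and malformed segment lists are handled", {
  empty <- seed_design("none", cross_section_spec("square", 8, 8, 4, 4))
  expect_equal(nrow(compile_stack(empty)), 0)
  expect_error(seed_design("bad", cross_section_spec("square", 8, 8, 4, 4),
                           list(seed_segment("Z1", "spacer_twister", 32, 3.8))),
               "alternate")
  expect_error(seed_segment("Z1", "growth", 128, twist = 1), "no twist")
})

test_that("gradient faces carry spacer twist and spacer-plus-tilt twist", {
  sg <- seed_preset("SG")
  faces <- gradient_face_orientations(sg)
  expect_equal(unname(faces), c(2.8, 13.7))
  # additivity with zero components
  sg0 <- sg
  sg0$cross_section$taper$delta_theta <- 0
  expect_equal(unname(gradient_face_orientations(sg0)), c(2.8, 2.8))
  sg1 <- sg
  sg1$segments[[2]]$twist <- 0
  expect_equal(unname(gradient_face_orientations(sg1)), c(0, 10.9))
  expect_error(gradient_face_orientations(seed_preset("S")), "compile_stack")
})

test_that("seed designs round-trip through config files", {
  s <- seed_preset("S")
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    name = s$name,
    cross_section = list(array_type = "square", rim_cols = 8, rim_rows = 8,
                         pore_cols = 4, pore_rows = 4),
    rise = s$rise, twist_rate = s$twist_rate,
    segments = lapply(s$segments, function(x)
      list(id = x$id, role = x$role, bp = x$bp, twist = x$twist))),
    tmp, auto_unbox = TRUE, digits = NA)
  s2 <- read_seed_design(tmp)
  expect_equal(compile_stack(s2), compile_stack(s), ignore_attr = TRUE)
  # stack JSON export is readable and complete
  out <- withr::local_tempfile(fileext = ".json")
  write_stack_json(compile_stack(s), out)
  rec <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(rec$layers$orientation_deg, c(0, 3.8, 7.6))
})
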