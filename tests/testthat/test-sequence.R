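test_that("patterned block has the exact event budget and printed opening", {
  s <- build_pattern_block(duration_s = 300, rate_hz = 4)
  expect_equal(nrow(s$events), 1200)
  # opening phrase: G-G#-A#-G#-A#-C-A#-C-C#
  expect_equal(s$events$midi[1:9] %% 12, c(7, 8, 10, 8, 10, 0, 10, 0, 1))
  # onsets on a rigid 250 ms grid
  expect_equal(unique(diff(s$events$onset_s)), 0.25)
  expect_true(all(s$events$code == "pattern"))
  expect_error(build_pattern_block(duration_s = 300.1), "integer")
})

test_that("after the four shapes complete, the cycle repeats a semitone up", {
  s <- build_pattern_block(duration_s = 300)
  per_shape <- vapply(default_shapes(), function(sh) {
    3L * (length(sh$degrees) - 3L + 1L)
  }, 0L)
  cyc <- sum(per_shape) # notes per key cycle
  first_e <- s$events$midi[seq_len(per_shape[1])]
  second_e <- s$events$midi[cyc + seq_len(per_shape[1])]
  expect_equal(second_e, first_e + 1L)
  # scale closure in the second key (one semitone above G#)
  expect_true(all((second_e %% 12) %in% major_scale(9)))
})

test_that("every emitted pitch belongs to its generating key's major scale", {
  s <- build_pattern_block(duration_s = 300)
  per_shape <- vapply(default_shapes(), function(sh) {
    3L * (length(sh$degrees) - 3L + 1L)
  }, 0L)
  cyc <- sum(per_shape)
  key <- 8L + (seq_len(nrow(s$events)) - 1L) %/% cyc # key per event
  ok <- vapply(seq_len(nrow(s$events)), function(i) {
    (s$events$midi[i] %% 12L) %in% major_scale(key[i] %% 12L)
  }, TRUE)
  expect_true(all(ok))
})

test_that("random block is a seeded permutation of the pattern block", {
  s <- build_pattern_block(duration_s = 60)
  for (seed in c(1, 7, 1234)) {
    r <- build_random_block(s, seed)
    expect_equal(sort(r$events$midi), sort(s$events$midi)) # same multiset
    expect_equal(r$events$onset_s, s$events$onset_s) # same grid
    expect_true(all(r$events$code == "random"))
    expect_identical(r, build_random_block(s, seed)) # determinism
  }
  r1 <- build_random_block(s, 1)
  r2 <- build_random_block(s, 2)
  expect_false(identical(r1$events$midi, r2$events$midi))
})

test_that("oddball block has an exact deviant count in seeded order", {
  o <- build_oddball_block(n_events = 1200, p_deviant = 0.10, seed = 9)
  expect_equal(sum(o$events$code == "deviant"), 120)
  expect_equal(sum(o$events$code == "standard"), 1080)
  expect_equal(unique(o$events$midi[o$events$code == "standard"]), 43L)
  expect_equal(unique(o$events$midi[o$events$code == "deviant"]), 65L)
  expect_identical(o, build_oddball_block(n_events = 1200, seed = 9))
  # p = 0.5, n = 2: one of each
  o2 <- build_oddball_block(p_deviant = 0.5, n_events = 2L, seed = 1)
  expect_equal(sort(o2$events$code), c("deviant", "standard"))
  expect_error(build_oddball_block(n_events = 1201L, p_deviant = 0.10),
               "integer")
  expect_error(build_oddball_block(p_deviant = 0), "p_deviant")
})

test_that("Latin-square orders are permutations with no column repeats", {
  for (seed in c(1, 42)) {
    rows <- t(vapply(0:4, latin_square_order,
                     integer(5), n_blocks = 5, seed = seed))
    for (i in 1:5) expect_equal(sort(rows[i, ]), 1:5) # each row a permutation
    for (j in 1:5) expect_equal(sort(rows[, j]), 1:5) # each column too
    # subjects 5-9 reuse the rows cyclically
    expect_equal(latin_square_order(5, 5, seed), rows[1, ])
    expect_equal(latin_square_order(5, 9, seed), rows[5, ])
  }
  expect_error(latin_square_order(5, -1, 1), ">= 0")
})

test_that("event files round-trip through the tab-delimited format", {
  s <- build_oddball_block(n_events = 40, p_deviant = 0.10, seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_events(s, path, fs = 500)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 40)
  expect_equal(tab$onset_sample, as.integer(round(tab$onset_s * 500)) + 1L)
  back <- read_events(path)
  expect_equal(back$events$midi, s$events$midi)
  expect_equal(back$events$code, s$events$code)
  expect_equal(back$rate_hz, s$rate_hz)
})
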