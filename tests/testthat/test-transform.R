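test_that("propagation matches its stated examples and the subtree oracle", {
  # A(0) -> {B(2), C(3)}: root sums children
  f <- gforest(c("001", "001.001", "001.002"), c(0, 2, 3))
  p <- propagate_counts(f, propagation_config(max_level = 1))
  expect_identical(p$propagated_count[p$code == "001"], 5)

  # chain A(1)->B(1)->C(1)
  ch <- gforest(c("001", "001.001", "001.001.001"), c(1, 1, 1))
  p1 <- propagate_counts(ch, propagation_config(max_level = 1))
  expect_identical(p1$propagated_count, c(3, 2, 1))
  p2 <- propagate_counts(ch, propagation_config(max_level = 2))
  expect_identical(p2$propagated_count, c(1, 2, 1))

  # disabled config is the identity on counts
  off <- propagate_counts(p1, propagation_config(enabled = FALSE))
  expect_identical(off$propagated_count, off$raw_count)

  # random fixtures against the brute-force oracle, any max_level
  for (seed in 1:10) {
    f <- build_forest(generate_forest_records(
      fixture_spec(2, 4, c(2, 3), zero_inflation = 0.5, seed = seed)), "generic")
    for (ml in 1:4) {
      got <- propagate_counts(f, propagation_config(max_level = ml))
      expect_identical(got$propagated_count,
                       oracle_propagate(f$code, f$raw_count, ml),
                       info = sprintf("seed %d ml %d", seed, ml))
    }
  }
})

test_that("propagation is idempotent and include_self=FALSE excludes own counts", {
  f <- build_forest(make_mini_atc(), "atc")
  once <- propagate_counts(f)
  expect_identical(propagate_counts(once), once)
  # J05 carries raw 2; without self its display drops to the child sum
  no_self <- propagate_counts(f, propagation_config(include_self = FALSE))
  expect_identical(no_self$propagated_count[no_self$code == "J05"], 15)
  expect_identical(once$propagated_count[once$code == "J05"], 17)
  # leaves show 0 without self
  expect_identical(no_self$propagated_count[no_self$code == "J05AB01"], 0)
})

test_that("drop_empty prunes exactly the all-zero subtrees", {
  # zero leaf under a non-empty parent: leaf goes, parent stays
  f <- gforest(c("001", "001.001", "001.002"), c(0, 4, 0))
  d <- drop_empty(propagate_counts(f))
  expect_setequal(d$code, c("001", "001.001"))

  # an entirely empty subtree vanishes including its root
  g <- gforest(c("001", "001.001", "001.001.001", "001.002"), c(0, 0, 0, 7))
  dg <- drop_empty(propagate_counts(g))
  expect_setequal(dg$code, c("001", "001.002"))

  # all-positive forest is untouched; pruning is idempotent
  h <- propagate_counts(gforest(c("001", "001.001"), c(1, 2)))
  expect_identical(drop_empty(h), h)
  expect_identical(drop_empty(dg), dg)

  # random fixtures against the reachability oracle
  for (seed in 1:10) {
    f <- propagate_counts(build_forest(generate_forest_records(
      fixture_spec(3, 4, c(2, 3), zero_inflation = 0.85, seed = seed)),
      "generic"))
    keep <- oracle_prune_keep(f$code, f$propagated_count)
    expect_setequal(drop_empty(f)$code, f$code[keep])
  }
})

test_that("color interpolation is exact at stops and linear between them", {
  wr <- color_scale(c(0, 1), c("#FFFFFF", "#FF0000"))
  expect_identical(interpolate_color(wr, 0), "#FFFFFF")
  expect_identical(interpolate_color(wr, 1), "#FF0000")
  expect_identical(interpolate_color(wr, 0.5), "#FF8080")
  expect_error(interpolate_color(wr, 1.2), class = "domain_error")
  expect_error(interpolate_color(wr, -0.1), class = "domain_error")

  s3 <- color_scale(c(0, 0.25, 1), c("#000000", "#FFA500", "#FF0000"))
  expect_identical(interpolate_color(s3, 0.25), "#FFA500")  # interior stop exact
  # per-channel monotonicity between consecutive stops
  vs <- seq(0.25, 1, length.out = 50)
  chans <- t(vapply(interpolate_color(s3, vs), function(h)
    strtoi(substring(h, c(2, 4, 6), c(3, 5, 7)), 16L), integer(3)))
  for (j in 1:3) {
    d <- diff(chans[, j])
    expect_true(all(d >= 0) || all(d <= 0), info = paste("channel", j))
  }

  expect_error(color_scale(c(0.1, 1), c("#000000", "#FFFFFF")),
               class = "validation_error")
  expect_error(color_scale(c(0, 1), c("#000000", "red")),
               class = "validation_error")
})

test_that("assign_colors normalizes globally and honors manual colors", {
  f <- gforest(c("001", "001.001", "001.002"), c(0, 5, 10))
  a <- assign_colors(f, color_scale())
  expect_identical(a$color[match(c("001", "001.001", "001.002"), a$code)],
                   c("#FFFFFF", "#FF8080", "#FF0000"))

  m <- build_forest(term_records(c("001", "001.001"), count = c(0, 9),
                                 color = c(NA, "#00FF00")), "generic")
  am <- assign_colors(m, color_scale())
  expect_identical(am$color[am$code == "001.001"], "#00FF00")

  z <- assign_colors(gforest(c("001", "002"), c(0, 0)), color_scale())
  expect_identical(unique(z$color), "#FFFFFF")  # degenerate max -> stop 0
})

test_that("pipeline order matters when pruning precedes propagation", {
  # With self-exclusive propagation a positive leaf displays 0, so the two
  # orders disagree: canonical order prunes it, reversed order keeps it.
  f <- gforest(c("001", "001.001"), c(0, 2))
  cfg <- propagation_config(include_self = FALSE)
  canonical <- drop_empty(propagate_counts(f, cfg))
  reversed <- propagate_counts(drop_empty(f), cfg)
  expect_false(identical(sort(canonical$code), sort(reversed$code)))
  expect_setequal(canonical$code, "001")
  expect_setequal(reversed$code, c("001", "001.001"))
})
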