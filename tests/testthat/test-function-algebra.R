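test_that("the catalogue has 25 functions with bijective names/indices and the stated groups", {
  cat <- math_functions()
  expect_equal(nrow(cat), 25)
  expect_equal(cat$index, 0:24)
  expect_false(anyDuplicated(cat$name) > 0)
  groups <- split(cat$name, cat$group)
  expect_setequal(groups$Basic, c("ADD", "SUB", "MULT", "DIV", "MOD", "MOD2"))
  expect_setequal(groups$Logical, c("GT", "LT", "AND", "OR", "XOR"))
  expect_setequal(groups$Bitwise, c("BITA", "BITO", "BITX"))
  expect_setequal(groups$Unary, c("ABS", "NOT", "FAC", "LEFT", "RIGHT"))
  expect_setequal(groups$Large, c("POW", "LOG", "PER", "CHS"))
  expect_setequal(groups$Miscellaneous, c("MIN", "MAX"))
})

test_that("names are accepted case-insensitively and by symbol; unknown names name the slot", {
  expect_equal(fn_canonical("add"), "ADD")
  expect_equal(fn_canonical("+"), "ADD")
  expect_equal(fn_canonical("^^"), "XOR")
  expect_equal(fn_apply("Mod2", 1, 1), fn_apply("MOD2", 1, 1))
  expect_error(fn_canonical("FROB", slot = "f3"), "f3")
})

test_that("apply semantics match the documented table on worked cases", {
  expect_equal(fn_apply("ADD", 2, 2), 4)
  expect_equal(fn_apply("MOD2", 1, 1), 0)
  expect_equal(fn_apply("MOD2", 0, 1), 1)
  expect_equal(fn_apply("DIV", 1, 0), 0)
  expect_equal(fn_apply("DIV", -7, 2), -3) # truncated, not floored
  expect_equal(fn_apply("MOD", -7, 3), 2) # result has the sign of b
  expect_equal(fn_apply("MOD", 7, 0), 0)
  expect_equal(fn_apply("CHS", 2, 1), 2)
  expect_equal(fn_apply("CHS", 1, 2), 0) # outside 0 <= b <= a
  expect_equal(fn_apply("PER", 4, 2), 12)
  expect_equal(fn_apply("LEFT", 5, -2), 5)
  expect_equal(fn_apply("RIGHT", 5, -2), -2)
  expect_equal(fn_apply("NOT", 2, 99), -3) # bitwise complement, b ignored
  expect_equal(fn_apply("ABS", -4, 99), 4)
  expect_equal(fn_apply("FAC", 5, 99), 120)
  expect_equal(fn_apply("FAC", -1, 0), 0)
  expect_equal(fn_apply("POW", 2, 10), 1024)
  expect_equal(fn_apply("POW", 0, 0), 1)
  expect_equal(fn_apply("POW", 2, -1), 0)
  expect_equal(fn_apply("LOG", 8, 99), 3)
  expect_equal(fn_apply("LOG", 0, 99), 0)
  expect_equal(fn_apply("XOR", 2, 0), 1) # logical on truthiness
  expect_equal(fn_apply("XOR", 2, 1), 0)
  expect_equal(fn_apply("BITX", 1, 2), 3)
  expect_equal(fn_apply("MIN", -2, 1), -2)
  expect_equal(fn_apply("MAX", -2, 1), 1)
})

test_that("every function is total on large integers and saturates at the 32-bit range", {
  cap <- 2^31 - 1
  withr::with_seed(7, {
    a <- sample(-1e6:1e6, 400)
    b <- sample(-1e6:1e6, 400)
    for (fn in math_functions()$name) {
      r <- fn_apply(fn, a, b)
      expect_true(all(is.finite(r)), info = fn)
      expect_true(all(abs(r) <= cap), info = fn)
      expect_true(all(r == round(r)), info = fn)
    }
  })
  # growth cases hit the cap instead of overflowing
  expect_equal(fn_apply("FAC", 50, 0), cap)
  expect_equal(fn_apply("POW", 10, 100), cap)
  expect_equal(fn_apply("POW", -10, 101), -cap)
  expect_equal(fn_apply("MULT", 1e6, 1e6), cap)
  expect_equal(fn_apply("PER", 100, 50), cap)
})

test_that("pushforward matches the exact formula on worked cases", {
  g <- dist_genotype()
  m2 <- fn_push("MOD2", g, g)
  expect_equal(m2$value, c(0, 1))
  expect_equal(m2$prob, c(0.5, 0.5))
  # identity case: ADD with a point mass at 0
  d <- discrete_dist(c(-1, 3), c(0.4, 0.6))
  expect_equal(fn_push("ADD", discrete_dist(0, 1), d), d)
  # brute-force derived case for MULT over the 9 genotype pairs
  mm <- fn_push("MULT", g, g)
  expect_equal(mm$value, c(0, 1, 2, 4))
  expect_equal(mm$prob, c(0.4375, 0.25, 0.25, 0.0625))
})

test_that("pushforward equals exhaustive enumeration for all 25 functions", {
  d1 <- discrete_dist(c(-2, 0, 1, 3), c(0.1, 0.2, 0.3, 0.4))
  d2 <- discrete_dist(c(-1, 0, 2), c(0.25, 0.5, 0.25))
  for (fn in math_functions()$name) {
    push <- fn_push(fn, d1, d2)
    # enumeration oracle
    acc <- new.env()
    for (i in seq_len(nrow(d1))) {
      for (j in seq_len(nrow(d2))) {
        v <- fn_apply(fn, d1$value[i], d2$value[j])
        key <- as.character(v)
        acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) +
          d1$prob[i] * d2$prob[j]
      }
    }
    vals <- sort(as.numeric(ls(acc)))
    expect_equal(push$value, vals, info = fn)
    probs <- vapply(as.character(vals), function(k) acc[[k]], numeric(1))
    expect_equal(push$prob, unname(probs), tolerance = 1e-12, info = fn)
    expect_equal(sum(push$prob), 1, tolerance = 1e-12, info = fn)
    expect_true(all(push$prob >= 0), info = fn)
  }
})

test_that("MOD2 of two genotype draws is conditionally uniform but jointly determined", {
  g <- dist_genotype()
  for (a in 0:2) {
    cond <- fn_push("MOD2", discrete_dist(a, 1), g)
    expect_equal(cond$prob, c(0.5, 0.5))
  }
  for (a in 0:2) {
    for (b in 0:2) {
      point <- fn_push("MOD2", discrete_dist(a, 1), discrete_dist(b, 1))
      expect_equal(nrow(point), 1) # point mass: output fully determined
    }
  }
})

test_that("invalid distributions are rejected", {
  expect_error(discrete_dist(c(0, 0), c(0.5, 0.5)), "distinct")
  expect_error(discrete_dist(0:1, c(-0.1, 1.1)), "non-negative")
  expect_error(discrete_dist(0:1, c(0.5, 0.4)), "sum to 1")
})
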