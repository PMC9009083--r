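test_that("the shipped library has the documented option counts", {
  lib <- default_library()
  expect_length(lib$input_options, 11)
  expect_length(lib$internal_options, 134)
  expect_length(lib$output_options, 1)
  expect_identical(lib$version, "reconstructed-v1")
})

test_that("internal options behave as their manifest names state", {
  lib <- default_library()
  g <- make_uniform_grid(-5, 5, 7)
  ws <- psdvr:::new_workspace(g$points^2, g$points, 1, g$length, g$dx)
  geo <- psdvr:::ws_geometry(ws)

  # constant addition to all elements: zero matrix + 2 -> all 2
  add2 <- lib$internal_options[[find_internal(lib, "M += 2")]]
  expect_true(all(add2$fn(ws, geo)$M == 2))

  # symmetric-rule options preserve matrix symmetry
  set.seed(12)
  S <- matrix(rnorm(49), 7, 7); S <- S + t(S)
  for (op in lib$internal_options) {
    if (!op$symmetric_rule) next
    ws2 <- ws; ws2$M <- S; ws2$y <- rnorm(7)
    out <- op$fn(ws2, geo)$M
    if (all(is.finite(out)))
      expect_equal(out, t(out), tolerance = 1e-12, label = op$name)
  }

  # every option keeps M finite for a benign finite workspace
  for (op in lib$internal_options) {
    ws3 <- ws; ws3$M <- S / 10; ws3$y <- ws$V / 10
    out <- op$fn(ws3, geo)
    expect_true(all(is.finite(out$M)), label = op$name)
  }
})

test_that("code execution honours the output and masking contracts", {
  lib <- default_library()
  g <- make_uniform_grid(-1, 1, 3)
  problem <- list(grid = g, V = numeric(3), m = 1)

  # all-ones input straight to output: eigenvalues {0, 0, 3}
  code <- ps_code(c(1, 1), lib)
  res <- execute_code(code, problem, n_e = 3)
  expect_false(res$failed)
  expect_equal(res$values, c(0, 0, 3), tolerance = 1e-12)

  # tridiagonal flag: nonzeros within the band, masking idempotent
  g9 <- make_uniform_grid(-5, 5, 9)
  problem9 <- list(grid = g9, V = g9$points^2, m = 1)
  codeT <- ps_code(c(1, 5, 1), lib, tridiagonal = TRUE)
  resT <- execute_code(codeT, problem9, n_e = 2)
  expect_false(resT$failed)
  expect_lte(count_nonzeros(resT$matrix)$count, 3 * 9 - 2)
  M <- resT$matrix
  expect_identical(psdvr:::apply_tridiagonal_mask(M), M)

  # determinism: bit-identical re-execution
  set.seed(99)
  codeR <- random_code(12)
  r1 <- execute_code(codeR, problem9, n_e = 2)
  r2 <- execute_code(codeR, problem9, n_e = 2)
  expect_identical(r1, r2)

  # non-finite execution yields a failure signal, not an error:
  # engineer an overflow by repeated squaring of large entries
  big <- ps_code(c(1, rep(find_internal(lib, "M += L/dx^2"), 2),
                   rep(find_internal(lib, "M = M^2 (elementwise)"), 12), 1),
                 lib)
  res_big <- execute_code(big, problem9, n_e = 2)
  expect_true(res_big$failed)
})

test_that("mutation changes 1-3 mutable slots and never the output", {
  lib <- default_library()
  set.seed(4)
  parent <- random_code(20)
  for (i in 1:50) {
    child <- mutate_code(parent, lib)
    dist <- sum(child$instructions != parent$instructions)
    expect_gte(dist, 0)   # replacement may redraw the same index
    expect_lte(dist, 3)
    expect_identical(child$instructions[20], parent$instructions[20])
  }
  set.seed(123)
  c1 <- mutate_code(parent, lib)
  set.seed(123)
  c2 <- mutate_code(parent, lib)
  expect_identical(c1, c2)
})

test_that("codes round-trip through JSON and refuse version mismatches", {
  set.seed(8)
  code <- random_code(15, tridiagonal = TRUE)
  tmp <- withr::local_tempfile(fileext = ".json")
  serialize_code(code, tmp)
  doc <- jsonlite::fromJSON(tmp)
  expect_length(doc$instructions, 15)

  back <- deserialize_code(tmp)
  expect_identical(back, code)

  doc$library_version <- "unknown-v9"
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE)
  expect_error(deserialize_code(tmp), "library version")

  expect_error(ps_code(c(99, 1), default_library()), "out of range")
})
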