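test_that("packaged canonical rubric has the published structure", {
  rub <- canonical_rubric()
  expect_s3_class(rub, "miss_rubric")
  expect_identical(nrow(rub$items), 50L)
  expect_length(validate_rubric(rub), 0)
  optimal <- sum(tapply(rub$options$points, rub$options$item_id, max))
  expect_equal(optimal, 100, tolerance = 1e-12)
  expect_true(all(rub$items$domain %in% miss_domains))
  expect_true(all(rub$items$weight %in% 0:4))
})

test_that("a degenerate single-item instrument is valid", {
  rub <- toy_rubric(100)
  expect_length(validate_rubric(rub), 0)
  expect_equal(max(rub$options$points), rub$target_total)
})

test_that("validator reports every violation, naming item and rule", {
  rub <- toy_rubric(c(4, 3))
  # break several invariants at once on an unclassed copy
  bad <- unclass(rub)
  bad$items <- rbind(bad$items, bad$items[1, ])           # duplicate id
  bad$items$domain[2] <- "unheard-of domain"              # unknown domain
  bad$items$weight[1] <- 9L                               # weight off-scale
  bad$target_total <- 100                                 # maxima sum to 7
  v <- validate_rubric(bad)
  expect_true(any(grepl("duplicate item_id 'it01'", v)))
  expect_true(any(grepl("unknown domain", v)))
  expect_true(any(grepl("weight 9", v)))
  expect_true(any(grepl("target_total", v)))
  expect_gte(length(v), 4)
})

test_that("points decreasing in raw_rank is a monotonicity violation", {
  rub <- toy_rubric(c(5, 5))
  bad <- unclass(rub)
  bad$options$points[bad$options$item_id == "it01"] <- c(5, 0)
  v <- validate_rubric(bad)
  expect_true(any(grepl("it01.*monotone", v)))
})

test_that("miss_rubric constructor rejects an off-target instrument", {
  rub <- toy_rubric(c(4, 3))
  expect_error(
    miss_rubric(rub$items, rub$options, target_total = 100),
    "target_total"
  )
})

test_that("derive_points implements the proportional weighting convention", {
  items <- tibble::tibble(
    item_id = c("a", "b"), stem = c("A", "B"),
    domain = miss_domains[1:2],
    midwife_types = list("CNM", "CPM"),
    weight = c(4L, 1L)
  )
  options <- tibble::tibble(
    item_id = rep(c("a", "b"), each = 2),
    code = rep(c("lo", "hi"), 2), label = rep(c("lo", "hi"), 2),
    raw_rank = c(0, 4, 0, 4)
  )
  rub <- derive_points(items, options, target_total = 100)
  # c = 100 / (4*4 + 1*4) = 5: top options worth 80 and 20
  pts <- rub$options$points[rub$options$code == "hi"]
  expect_equal(pts, c(80, 20), tolerance = 1e-12)
})

test_that("derive_points trivial and replicated-item cases", {
  one <- derive_points(
    tibble::tibble(item_id = "a", stem = "A", domain = miss_domains[1],
                   midwife_types = list("CNM"), weight = 1L),
    tibble::tibble(item_id = "a", code = c("lo", "hi"),
                   label = c("lo", "hi"), raw_rank = c(0, 1)),
    target_total = 100)
  expect_equal(sort(one$options$points), c(0, 100))

  items <- tibble::tibble(
    item_id = sprintf("i%02d", 1:50), stem = "x",
    domain = miss_domains[1], midwife_types = rep(list("CNM"), 50),
    weight = 1L)
  options <- tidyr::expand_grid(item_id = items$item_id,
                                code = c("lo", "hi")) |>
    dplyr::mutate(label = code, raw_rank = ifelse(code == "hi", 1, 0))
  rub <- derive_points(items, options, target_total = 100)
  expect_equal(unique(rub$options$points[rub$options$code == "hi"]), 2,
               tolerance = 1e-12)
})

test_that("derive_points is scale-invariant in the raw ranks and errors on degenerate input", {
  items <- tibble::tibble(
    item_id = c("a", "b", "c"), stem = "s", domain = miss_domains[3],
    midwife_types = rep(list("CPM"), 3), weight = c(2L, 3L, 1L))
  options <- tidyr::expand_grid(item_id = items$item_id,
                                raw_rank = c(0, 1, 2, 3)) |>
    dplyr::mutate(code = paste0("o", raw_rank), label = code)
  r1 <- derive_points(items, options, target_total = 100)
  r2 <- derive_points(items, dplyr::mutate(options, raw_rank = raw_rank * 7),
                      target_total = 100)
  expect_equal(r1$options$points, r2$options$points, tolerance = 1e-12)
  expect_equal(sum(tapply(r1$options$points, r1$options$item_id, max)), 100,
               tolerance = 1e-12)

  expect_error(
    derive_points(dplyr::mutate(items, weight = 0L), options, 100),
    "degenerate")
})

test_that("rubric files round-trip bit-exactly through YAML and JSON", {
  rub <- derive_points(
    tibble::tibble(item_id = c("a", "b", "c"), stem = "s",
                   domain = miss_domains[1:3],
                   midwife_types = rep(list(c("CNM", "CPM")), 3),
                   weight = c(3L, 2L, 4L)),
    tidyr::expand_grid(item_id = c("a", "b", "c"), raw_rank = c(0, 1, 2)) |>
      dplyr::mutate(code = paste0("o", raw_rank), label = code),
    target_total = 100)
  for (ext in c("yaml", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_rubric(rub, f)
    back <- read_rubric(f, tolerance = 1e-9)
    expect_identical(back$items$item_id, rub$items$item_id)
    expect_identical(back$options$points, rub$options$points)  # bit-exact
    expect_identical(back$target_total, rub$target_total)
  }
})

test_that("read_rubric errors name the file and the problem", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("items:\n  - id: x\n    stem: s", f)
  expect_error(read_rubric(f), "missing field")
  expect_error(read_rubric(file.path(tempdir(), "nope.yaml")), "not found")
})
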