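test_that("tail search reproduces worked small cases", {
  cfg <- refine_config()
  # identical distributions: no tail can reach the 21:1 ratio
  set.seed(2)
  v <- sample(0:50, 1000, TRUE)
  expect_null(find_tail_criterion(v, v, "upper", cfg))
  expect_null(find_tail_criterion(v, v, "lower", cfg))

  # 22% of the disease population at 10, normals all at 0 (upper tail)
  s <- c(rep(0, 78), rep(10, 22))
  n <- rep(0, 100)
  cr <- find_tail_criterion(s, n, "upper", cfg)
  expect_equal(cr$threshold, 10)
  expect_equal(cr$n_scd_tail, 22L)
  expect_equal(cr$n_nor_tail, 0L)
  expect_equal(cr$achieved_ratio, (22 / 100) / (1 / 101))

  # fully separated populations
  cr2 <- find_tail_criterion(rep(10, 100), rep(0, 100), "upper", cfg)
  expect_equal(cr2$threshold, 10)
  expect_equal(cr2$n_scd_tail, 100L)
  expect_equal(cr2$achieved_ratio, 101)

  expect_error(find_tail_criterion(numeric(0), 1, "upper", cfg))
})

test_that("tail search matches brute force on random instances", {
  set.seed(31)
  cfg <- refine_config(ratio = 8)
  for (i in 1:30) {
    n_s <- sample(20:200, 1)
    n_n <- sample(20:200, 1)
    shift <- sample(0:6, 1)
    s <- sample(0:15, n_s, TRUE) + shift
    n <- sample(0:15, n_n, TRUE)
    for (dir in c("lower", "upper")) {
      got <- find_tail_criterion(s, n, dir, cfg)
      want <- oracle_tail_search(s, n, dir, ratio = 8, pseudo = 1)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(got$threshold, want$threshold)
        expect_equal(got$n_scd_tail, want$n_scd_tail)
        expect_equal(got$n_nor_tail, want$n_nor_tail)
        expect_equal(got$achieved_ratio, want$achieved_ratio)
      }
    }
  }
})

test_that("no more inclusive threshold satisfies the ratio", {
  set.seed(32)
  cfg <- refine_config(ratio = 10)
  s <- c(rnorm(300), rnorm(60, 4))
  n <- rnorm(300)
  cr <- find_tail_criterion(s, n, "upper", cfg)
  expect_false(is.null(cr))
  cand <- sort(unique(c(s, n)))
  more_inclusive <- cand[cand < cr$threshold]
  for (t in more_inclusive) {
    ns <- sum(s >= t); nn <- sum(n >= t)
    r <- (ns / length(s)) / ((nn + 1) / (length(n) + 1))
    expect_lt(r, 10)
  }
})

test_that("raising the required ratio never grows the refined set", {
  set.seed(33)
  tb <- tibble::tibble(
    cell_id = sprintf("c%04d", 1:800),
    class = rep(c("SCD", "NOR"), each = 400),
    f1 = c(rnorm(400, 0, 1) + c(rep(4, 60), rep(0, 340)), rnorm(400)),
    f2 = c(rnorm(400, 0, 1) - c(rep(5, 60), rep(0, 340)), rnorm(400))
  )
  sizes <- vapply(c(3, 6, 12, 24), function(r) {
    cfg <- refine_config(ratio = r, parameters_searched = c("f1", "f2"),
                         min_refined_size = 1)
    crit <- search_all_parameters(tb, cfg)
    if (nrow(crit) == 0) return(0L)
    length(build_refined_set(tb, crit, cfg)$scd_ids)
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("searching all parameters respects scope and classes", {
  tb <- tibble::tibble(
    cell_id = sprintf("c%03d", 1:200),
    class = rep(c("SCD", "NOR"), each = 100),
    f1 = c(rep(9, 40), rnorm(60), rnorm(100)),
    f2 = rnorm(200)
  )
  nor_only <- dplyr::filter(tb, class == "NOR")
  cfg <- refine_config(parameters_searched = c("f1", "f2"))
  expect_error(search_all_parameters(nor_only, cfg), "both classes")

  one <- search_all_parameters(
    tb, refine_config(parameters_searched = "f1")
  )
  expect_lte(nrow(one), 2)
  expect_error(
    search_all_parameters(tb, refine_config(parameters_searched = "nope")),
    "lacks"
  )
})

test_that("the refined set is the union of criterion tails", {
  tb <- tibble::tibble(
    cell_id = sprintf("c%03d", 1:300),
    class = rep(c("SCD", "NOR"), c(200, 100)),
    f1 = c(seq_len(200), rep(0, 100)),
    f2 = c(seq_len(200) + 20, rep(0, 100))
  )
  criteria <- tibble::tibble(
    parameter = c("f1", "f2"),
    direction = "upper",
    threshold = c(150, 150),
    achieved_ratio = 99, n_scd_tail = 51L, n_nor_tail = 0L
  )
  cfg <- refine_config(min_refined_size = 10)
  rs <- build_refined_set(tb, criteria, cfg)
  a <- tb$cell_id[tb$f1 >= 150 & tb$class == "SCD"]
  b <- tb$cell_id[tb$f2 >= 150 & tb$class == "SCD"]
  expect_setequal(rs$scd_ids, union(a, b))
  expect_equal(length(rs$nor_ids), length(rs$scd_ids))
  expect_true(all(rs$nor_ids %in% tb$cell_id[tb$class == "NOR"]))
  expect_false(rs$undersized)
  # provenance records each matching criterion per cell
  both <- intersect(a, b)
  counts <- dplyr::count(rs$provenance, cell_id)
  expect_true(all(counts$n[counts$cell_id %in% both] == 2))
})

test_that("undersized refined sets carry a warning status", {
  tb <- tibble::tibble(
    cell_id = sprintf("c%04d", 1:1200),
    class = rep(c("SCD", "NOR"), c(600, 600)),
    f1 = c(rep(5, 120), rep(0, 480), rep(0, 600))
  )
  criteria <- tibble::tibble(parameter = "f1", direction = "upper",
                             threshold = 5, achieved_ratio = 99,
                             n_scd_tail = 120L, n_nor_tail = 0L)
  expect_warning(
    rs <- build_refined_set(tb, criteria, refine_config()),
    "below the configured minimum"
  )
  expect_true(rs$undersized)
  expect_equal(length(rs$scd_ids), 120)
})

test_that("balancing fails when too few normal cells exist", {
  tb <- tibble::tibble(
    cell_id = sprintf("c%03d", 1:120),
    class = rep(c("SCD", "NOR"), c(100, 20)),
    f1 = c(rep(5, 100), rep(0, 20))
  )
  criteria <- tibble::tibble(parameter = "f1", direction = "upper",
                             threshold = 5, achieved_ratio = 99,
                             n_scd_tail = 100L, n_nor_tail = 0L)
  expect_error(build_refined_set(tb, criteria, refine_config()),
               "cannot balance")
})

test_that("normal matching is reproducible from the configured seed", {
  tb <- tibble::tibble(
    cell_id = sprintf("c%03d", 1:200),
    class = rep(c("SCD", "NOR"), each = 100),
    f1 = c(rep(5, 30), rep(0, 70), rep(0, 100))
  )
  criteria <- tibble::tibble(parameter = "f1", direction = "upper",
                             threshold = 5, achieved_ratio = 99,
                             n_scd_tail = 30L, n_nor_tail = 0L)
  cfg <- refine_config(min_refined_size = 1, seed = 42)
  a <- build_refined_set(tb, criteria, cfg)
  b <- build_refined_set(tb, criteria, cfg)
  expect_identical(a$nor_ids, b$nor_ids)
  expect_equal(glance(a)$n_scd, 30)
  expect_equal(nrow(tidy(a)), 60)
})
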