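test_that("cohort birth spans follow year minus age arithmetic", {
  expect_equal(unname(cohort_birth_span(60, 69, 1973)), c(1904L, 1913L))
  expect_equal(unname(cohort_birth_span(20, 29, 2018)), c(1989L, 1998L))
  expect_equal(unname(cohort_birth_span(0, 0, 2000)), c(2000L, 2000L))
  expect_error(cohort_birth_span(20, 29, 25), "exceed")
  expect_error(cohort_birth_span(30, 29, 2000), "exceed")
})

test_that("birth spans are translation-equivariant in the survey year", {
  set.seed(7)
  for (r in 1:25) {
    lo <- sample(0:60, 1); hi <- lo + sample(0:15, 1)
    yr <- hi + sample(1:200, 1)
    t <- sample(1:50, 1)
    expect_equal(cohort_birth_span(lo, hi, yr + t),
                 cohort_birth_span(lo, hi, yr) + t)
  }
})

test_that("cohort index enumerates calendar birth spans oldest-first", {
  full <- apc_grid(matrix(0, 5, 46), seq(20, 60, 10), seq(29, 69, 10),
                   1973:2018)
  idx <- build_cohort_index(full)
  # brute-force oracle: enumerate the distinct spans over all cells
  cells <- expand.grid(i = 1:5, j = seq_along(full$years))
  spans <- unique(data.frame(
    s = full$years[cells$j] - full$age_upper[cells$i],
    e = full$years[cells$j] - full$age_lower[cells$i]))
  expect_equal(idx$K, nrow(spans))
  expect_equal(idx$K, 86L)  # J + 10 * (I - 1) on the contiguous design
  expect_equal(sort(idx$birth_start), sort(spans$s))
  # oldest cohort: 60-69 in 1973; youngest: 20-29 in 2018
  expect_equal(idx$k[5, 1], 1L)
  expect_equal(idx$k[1, ncol(full$values)], idx$K)
  expect_equal(c(idx$birth_start[1], idx$birth_end[1]), c(1904L, 1913L))
  expect_equal(c(idx$birth_start[86], idx$birth_end[86]), c(1989L, 1998L))
})

test_that("survey-year gaps do not corrupt the cohort mapping", {
  # drop 1974 entirely: the 1905-1914 span loses its only cell
  yrs <- setdiff(1973:2018, 1974L)
  g <- apc_grid(matrix(0, 5, length(yrs)), seq(20, 60, 10), seq(29, 69, 10),
                yrs)
  idx <- build_cohort_index(g)
  expect_equal(idx$K, 85L)
  expect_false(1905L %in% idx$birth_start)
  # levels are keyed by calendar span, so the oldest/youngest are unchanged
  expect_equal(idx$birth_start[1], 1904L)
  expect_equal(idx$birth_start[idx$K], 1989L)
  # two cells share a level iff they share a span
  starts <- outer(-g$age_upper, g$years, `+`)
  same_k <- outer(as.vector(idx$k), as.vector(idx$k), `==`)
  same_s <- outer(as.vector(starts), as.vector(starts), `==`)
  expect_true(all(same_k == same_s))
})

test_that("grid constructor enforces layout invariants", {
  expect_error(apc_grid(matrix(0, 2, 2), c(30, 20), c(39, 29), 2000:2001),
               "ascending")
  expect_error(apc_grid(matrix(0, 2, 2), c(20, 25), c(29, 34), 2000:2001),
               "disjoint")
  expect_error(apc_grid(matrix(0, 2, 2), c(20, 30), c(29, 39), c(2001, 2000)),
               "increasing")
  expect_error(apc_grid(matrix(Inf, 2, 2), c(20, 30), c(29, 39), 2000:2001),
               "finite")
})

test_that("long-format CSV round trip is the identity", {
  sg <- small_grid()
  g <- sg$grid
  g$biomarker <- "sbp"; g$unit <- "mmHg"; g$sex <- "men"
  g$values[2, 3] <- NA  # one unobserved cell survives the trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_grid(g, path)
  back <- read_grid(path)
  expect_length(back, 1)
  b <- back[["men:sbp"]]
  expect_equal(b$values, g$values)
  expect_equal(b$age_lower, g$age_lower)
  expect_equal(b$years, g$years)
  expect_equal(b$unit, "mmHg")
  expect_equal(sum(!is.na(b$values)), sum(!is.na(g$values)))
})

test_that("reader reports malformed rows by number", {
  path <- withr::local_tempfile(fileext = ".csv")
  hdr <- "sex,biomarker,unit,year,age_lower,age_upper,mean"
  writeLines(c(hdr,
               "men,sbp,mmHg,2000,20,29,130.5",
               "men,sbp,mmHg,2000,30,39,135.1",
               "men,sbp,mmHg,2001,20,29,129.9"), path)
  g <- read_grid(path)[[1]]
  expect_equal(sum(!is.na(g$values)), 3L)

  writeLines(c(hdr,
               "men,sbp,mmHg,2000,20,29,130.5",
               "men,sbp,mmHg,2000,20,29,131.0"), path)
  expect_error(read_grid(path), "duplicate.*row\\(s\\) 2")

  writeLines(c(hdr, "men,sbp,mmHg,2000,20,29,abc"), path)
  expect_error(read_grid(path), "non-numeric mean")

  writeLines(c(hdr, "men,sbp,mmHg,2000,29,20,130"), path)
  expect_error(read_grid(path), "inverted.*row\\(s\\) 1")
})

test_that("an all-missing grid writes a header-only file", {
  g <- apc_grid(matrix(NA_real_, 2, 2), c(20, 30), c(29, 39), 2000:2001)
  path <- withr::local_tempfile(fileext = ".csv")
  write_grid(g, path)
  expect_length(readLines(path), 1L)
})

test_that("direct age standardization averages under normalized weights", {
  g <- apc_grid(matrix(c(100, 120, 100, 120), 2, 2),
                c(20, 30), c(29, 39), 2000:2001)
  out <- age_standardize(g, weights = c(0.25, 0.75))
  expect_equal(out$value, c(115, 115))
  # weights are normalized before use
  out2 <- age_standardize(g, weights = c(1, 3))
  expect_equal(out2$value, out$value)
  # constant grid is invariant under any weights (convexity)
  gc <- apc_grid(matrix(7.5, 3, 4), c(20, 30, 40), c(29, 39, 49), 2000:2003)
  expect_equal(age_standardize(gc, c(5, 1, 2))$value, rep(7.5, 4))
  # equal weights equal the arithmetic mean
  sg <- small_grid()$grid
  expect_equal(age_standardize(sg)$value, unname(colMeans(sg$values)))
})

test_that("years with any missing age group get a missing standardized value", {
  v <- matrix(1:6 * 1.0, 2, 3)
  v[2, 2] <- NA
  g <- apc_grid(v, c(20, 30), c(29, 39), 2000:2002)
  out <- age_standardize(g)
  expect_true(is.na(out$value[2]))
  expect_false(anyNA(out$value[-2]))
  expect_error(age_standardize(g, c(0, 0)), "zero")
  expect_error(age_standardize(g, c(1, 1, 1)), "one weight per age group")
})

test_that("the packaged reference table loads with blanks as NA", {
  t1 <- read_table1()
  expect_equal(nrow(t1), 450L)
  expect_setequal(unique(t1$biomarker), c("sbp", "sg", "tg", "hdl", "bmi"))
  expect_setequal(unique(t1$sex), c("men", "women"))
  expect_false(1974 %in% t1$year)
  q <- function(y, s, b) t1$value[t1$year == y & t1$sex == s & t1$biomarker == b]
  expect_true(is.na(q(1973, "men", "sg")))   # lipid panel starts later
  expect_true(is.na(q(2016, "women", "tg"))) # not measured that year
})
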