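test_that("binarize applies the three-fiber rule and stays monotone", {
  fc <- matrix(0L, 4, 4)
  fc[1, 2] <- fc[2, 1] <- 0L
  fc[1, 3] <- fc[3, 1] <- 2L
  fc[1, 4] <- fc[4, 1] <- 3L
  fc[2, 3] <- fc[3, 2] <- 5L
  adj <- binarize(fc, 3)
  expect_equal(adj[1, 2], 0L)
  expect_equal(adj[1, 3], 0L)  # 2 fibers: below the >= 3 rule
  expect_equal(adj[1, 4], 1L)  # exactly 3 fibers counts
  expect_equal(adj[2, 3], 1L)
  expect_equal(binarize(fc, 1), (fc > 0) * 1L, ignore_attr = TRUE)
  expect_equal(sum(binarize(matrix(0L, 5, 5), 4)), 0L)

  withr::local_seed(11)
  fc <- matrix(0L, 8, 8)
  ut <- upper.tri(fc)
  fc[ut] <- rpois(sum(ut), 3)
  fc <- fc + t(fc)
  for (t in 1:5) {
    hi <- binarize(fc, t + 1)
    lo <- binarize(fc, t)
    expect_true(all(hi <= lo))  # raising the threshold only removes edges
  }

  expect_error(binarize(fc, 0), "threshold")
  neg <- fc; neg[1, 2] <- neg[2, 1] <- -1L
  expect_error(binarize(neg, 3), "negative")
})

test_that("region labels: AAL-90 set at V = 90, generic and stable otherwise", {
  l90 <- default_region_labels(90)
  expect_length(l90, 90)
  expect_true(all(c("Precuneus_L", "SupraMarginal_L", "Frontal_Mid_L") %in% l90))
  expect_equal(l90[63], "SupraMarginal_L")
  expect_identical(l90, default_region_labels(90))
  expect_equal(default_region_labels(5), c("R001", "R002", "R003", "R004", "R005"))
  expect_false(anyDuplicated(l90) > 0)
})

test_that("connectome construction validates matrices", {
  a <- matrix(0L, 4, 4); a[1, 2] <- a[2, 1] <- 1L
  cn <- connectome(adjacency = a)
  expect_s3_class(cn, "fr_connectome")
  expect_equal(diag(cn$adjacency), rep(0L, 4), ignore_attr = TRUE)

  bad <- a; bad[1, 3] <- 1L  # asymmetric
  expect_error(connectome(adjacency = bad), "symmetric")
  nonbin <- a; nonbin[1, 2] <- nonbin[2, 1] <- 2L
  expect_error(connectome(adjacency = nonbin), "binary")
  expect_error(connectome(adjacency = a, fa = a * 2), "\\[0, 1\\]")
  expect_error(connectome(adjacency = matrix(0L, 3, 4)), "square")
})

test_that("cohort read/write round-trips matrices bit-exactly", {
  withr::local_seed(21)
  ch <- tiny_cohort(n = 3, V = 6, seed = 5)
  dir <- withr::local_tempdir()
  write_cohort(ch, dir, matrix_kind = "fiber_count")
  back <- read_cohort(file.path(dir, "covariates.csv"), dir,
                      matrix_kind = "fiber_count", fiber_threshold = 3)
  expect_equal(back$covariates$subject_id, ch$covariates$subject_id)
  for (s in seq_along(ch$connectomes)) {
    expect_identical(unname(back$connectomes[[s]]$fiber_count),
                     unname(ch$connectomes[[s]]$fiber_count))
    expect_identical(unname(back$connectomes[[s]]$adjacency),
                     unname(ch$connectomes[[s]]$adjacency))
  }
})

test_that("read_cohort rejects malformed input with informative errors", {
  dir <- withr::local_tempdir()
  cov <- data.frame(subject_id = c("s1", "s2"), group = "NC", age = 70,
                    sex = c(0, 1), education_years = c(10, 12), cdr_sob = NA)
  readr::write_csv(cov, file.path(dir, "covariates.csv"))
  m <- matrix(0L, 4, 4); m[1, 2] <- m[2, 1] <- 3L
  write.table(m, file.path(dir, "s1.csv"), sep = ",", row.names = FALSE, col.names = FALSE)
  expect_error(
    read_cohort(file.path(dir, "covariates.csv"), dir, "fiber_count"),
    "s2")

  write.table(matrix(0, 4, 5), file.path(dir, "s2.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  expect_error(
    read_cohort(file.path(dir, "covariates.csv"), dir, "fiber_count"),
    "square")

  # dimension mismatch across subjects
  write.table(matrix(0L, 5, 5), file.path(dir, "s2.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  expect_error(
    read_cohort(file.path(dir, "covariates.csv"), dir, "fiber_count"),
    "dimension")

  # asymmetric integer matrix is an error, not silently fixed
  m2 <- matrix(0L, 4, 4); m2[1, 2] <- 3L
  write.table(m2, file.path(dir, "s2.csv"), sep = ",", row.names = FALSE, col.names = FALSE)
  expect_error(
    read_cohort(file.path(dir, "covariates.csv"), dir, "fiber_count"),
    "asymmetric")

  # NaN entries rejected
  m3 <- matrix(0, 4, 4); m3[2, 3] <- m3[3, 2] <- NaN
  write.table(m3, file.path(dir, "s2.csv"), sep = ",", row.names = FALSE, col.names = FALSE)
  expect_error(
    read_cohort(file.path(dir, "covariates.csv"), dir, "fiber_count"),
    "NA/NaN")
})

test_that("symmetric fiber input is stored with zero diagonal", {
  dir <- withr::local_tempdir()
  cov <- data.frame(subject_id = "s1", group = "NC", age = 70, sex = 0,
                    education_years = 10, cdr_sob = NA)
  readr::write_csv(cov, file.path(dir, "covariates.csv"))
  m <- matrix(0L, 4, 4); m[1, 2] <- m[2, 1] <- 3L; diag(m) <- 7L
  write.table(m, file.path(dir, "s1.csv"), sep = ",", row.names = FALSE, col.names = FALSE)
  ch <- read_cohort(file.path(dir, "covariates.csv"), dir, "fiber_count")
  expect_equal(ch$connectomes[[1]]$fiber_count[1, 2], 3L)
  expect_equal(diag(ch$connectomes[[1]]$fiber_count), rep(0L, 4), ignore_attr = TRUE)
})

test_that("cohort invariants: unique ids, covariate ranges, shared labels", {
  ch <- tiny_cohort(n = 4, V = 6, seed = 2)
  cov <- ch$covariates
  cov$subject_id[2] <- cov$subject_id[1]
  expect_error(cohort(cov, ch$connectomes), "unique")
  cov <- ch$covariates; cov$sex[1] <- 2
  expect_error(cohort(cov, ch$connectomes), "sex")
  cov <- ch$covariates; cov$education_years[1] <- 25L
  expect_error(cohort(cov, ch$connectomes), "education_years")
})
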