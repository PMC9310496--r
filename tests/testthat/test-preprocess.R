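write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("CSV round-trip keeps rows, columns and declared kinds", {
  path <- write_temp_csv(c(
    "height,weight,edema_volume",
    "1.60,70,150",
    "1.72,80,320",
    "1.55,64,"
  ))
  schema <- patient_schema(
    c(height = "continuous", weight = "continuous",
      edema_volume = "continuous"),
    required = "edema_volume"
  )
  tab <- read_patient_table(path, schema)
  expect_equal(dim(tab), c(3L, 3L))
  expect_type(tab$height, "double")
  expect_true(is.na(tab$edema_volume[3]))
})

test_that("malformed files are rejected", {
  dup <- write_temp_csv(c("a,b,a", "1,2,3"))
  expect_error(read_patient_table(dup), class = "efsemble_error_schema")

  empty <- write_temp_csv(character())
  expect_error(read_patient_table(empty), class = "efsemble_error_format")

  ok <- write_temp_csv(c("a,b", "1,2"))
  schema <- patient_schema(c(a = "continuous", missing_col = "binary"))
  expect_error(read_patient_table(ok, schema), class = "efsemble_error_schema")
})

test_that("schema files round-trip through YAML and JSON", {
  spec <- list(
    columns = list(height = "continuous", grade = "categorical",
                   visit = "date"),
    required = list("height")
  )
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(spec, yml)
  s1 <- read_patient_schema(yml)
  expect_equal(unname(s1$kinds["grade"]), "categorical")
  expect_equal(s1$required, "height")

  jsn <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(spec, jsn, auto_unbox = TRUE)
  s2 <- read_patient_schema(jsn)
  expect_equal(s2$kinds, s1$kinds)

  expect_error(patient_schema(c(height = "weird")),
               class = "efsemble_error_schema")
  expect_error(patient_schema(c("continuous")),
               class = "efsemble_error_schema")
})

test_that("exclude_incomplete keeps complete cases untouched and counts the rest", {
  tab <- tibble::tibble(
    a = c(1, NA, 3, 4, NA),
    b = c(1, 2, 3, NA, 5)
  )
  out <- exclude_incomplete(tab, required = c("a", "b"), quiet = TRUE)
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "n_excluded"), 3)
  expect_equal(attr(out, "n_excluded") + nrow(out), attr(out, "n_input"))
  expect_equal(out$a, c(1, 3))

  # identity when nothing is missing
  full <- tibble::tibble(a = 1:4, b = 4:1)
  expect_equal(
    as.data.frame(exclude_incomplete(full, "a", quiet = TRUE)),
    as.data.frame(full),
    ignore_attr = TRUE
  )

  all_na <- tibble::tibble(a = c(NA, NA))
  expect_error(exclude_incomplete(all_na, "a", quiet = TRUE),
               class = "efsemble_error_degenerate")
})

test_that("planted MCAR missingness is excluded at the planted rate", {
  raw <- simulate_cohort(n_pos = 750, n_neg = 250, n_informative = 0,
                         n_noise = 2, missing_rate = 0.13, seed = 21)
  planted <- sum(is.na(raw$nodes_involved))
  out <- exclude_incomplete(raw, quiet = TRUE)
  expect_equal(attr(out, "n_excluded"), planted)
  # MCAR at 13% of n = 1000: the planted count concentrates near 130
  expect_gt(planted, 95)
  expect_lt(planted, 170)
})

test_that("derived variables follow the stated arithmetic and drop their sources", {
  tab <- tibble::tibble(
    date_of_birth = as.Date("1960-03-10"),
    diagnosis_date = as.Date("2010-03-09"),
    referral_date = as.Date("2012-01-01"),
    height = c(1.60, 160),        # metres and centimetres both accepted
    weight = c(70, 70),
    nodes_involved = c(4, 2),
    nodes_removed = c(12, 0)
  )
  out <- derive_features(tab)
  expect_equal(out$age, c(49, 49))  # one day short of the birthday: floor
  expect_equal(round(out$bmi, 2), c(27.34, 27.34))
  expect_equal(round(out$node_ratio, 4), c(0.3333, NA))
  expect_false(any(c("date_of_birth", "referral_date", "height", "weight")
                   %in% names(out)))
  # idempotence
  expect_identical(derive_features(out), out)

  bad <- dplyr::mutate(tab, height = c(-1, 160))
  expect_error(derive_features(bad), class = "efsemble_error_value")
})

test_that("alignment coding supports both conventions", {
  expect_equal(encode_alignment("right", "right"), 0L)
  expect_equal(encode_alignment("right", "left"), 1L)
  expect_equal(encode_alignment("right", "right", "aligned_is_one"), 1L)
  expect_equal(encode_alignment("Left", "l"), 0L)
  expect_equal(
    encode_alignment(c("right", "left"), c("left", "left")),
    c(1L, 0L)
  )
  # the two codings are complementary on every input
  dh <- c("right", "left", "right", "left")
  is_ <- c("right", "right", "left", "left")
  expect_equal(encode_alignment(dh, is_, "aligned_is_zero"),
               1L - encode_alignment(dh, is_, "aligned_is_one"))
  expect_error(encode_alignment("right", "up"),
               class = "efsemble_error_value")
})

test_that("volume labelling is strictly greater-than the threshold", {
  expect_equal(assign_label(c(350, 200, 0, 200.001)), c(1L, 0L, 0L, 1L))
  expect_error(assign_label(-5), class = "efsemble_error_value")
  expect_error(assign_label(100, threshold_ml = 0),
               class = "efsemble_error_config")
})

test_that("finalize encodes categoricals deterministically and reversibly", {
  tab <- tibble::tibble(
    grade = c("low", "high", "mid", "low"),
    x = c(1, 2, 3, 4),
    class = c(0L, 1L, 1L, 0L)
  )
  out <- finalize_features(tab)
  enc <- attr(out, "encodings")
  expect_equal(enc$grade, c("high", "low", "mid"))  # lexicographic
  expect_equal(out$grade, c(1L, 0L, 2L, 1L))
  expect_equal(decode_levels(out$grade, enc$grade), tab$grade)
})

test_that("minority replication yields the implied class totals", {
  tab <- tibble::tibble(
    x = rnorm(970),
    class = c(rep(1L, 740), rep(0L, 230))
  )
  out <- finalize_features(tab, balance_factor = 3)
  expect_equal(unname(attr(out, "class_counts")), c(690, 740))
  expect_equal(nrow(out), 1430)
  # balance_factor 1 is the identity on class sizes
  out1 <- finalize_features(tab)
  expect_equal(unname(attr(out1, "class_counts")), c(230, 740))

  single <- tibble::tibble(x = 1:3, class = c(1L, 1L, 1L))
  expect_error(finalize_features(single),
               class = "efsemble_error_degenerate")
})

test_that("the label column can be derived from edema volume during finalize", {
  tab <- tibble::tibble(
    x = c(1, 2, 3),
    edema_volume_ml = c(150, 200, 450)
  )
  out <- finalize_features(tab)
  expect_equal(out$class, c(0L, 0L, 1L))
  expect_false("edema_volume_ml" %in% names(out))
})

test_that("feature tables round-trip through CSV with their JSON sidecar", {
  tab <- finalize_features(tibble::tibble(
    grade = c("a", "b", "a", "c"),
    x = 1:4,
    class = c(0L, 1L, 0L, 1L)
  ))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(tab), ignore_attr = TRUE)
  sidecar <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                                 simplifyVector = TRUE)
  expect_equal(sidecar$encodings$grade, c("a", "b", "c"))
  expect_equal(sidecar$n_rows, 4)
})
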