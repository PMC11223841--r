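write_tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

test_that("a generated cohort round-trips through write, read, and scoring", {
  co <- generate_cohort(n = 20, seed = 11)
  f <- tempfile(fileext = ".csv"); on.exit(unlink(f))
  write_scores(co, f)
  expect_identical(length(readLines(f)), 21L)  # header + 20 rows
  snaps <- read_cohort(f)
  expect_identical(nrow(snaps), 20L)
  expect_identical(snaps$age_months, co$age_months)
  # derived inputs match the standalone helpers
  expect_equal(snaps$map_mmhg,
               resolve_map(sbp = co$sbp_mmhg, dbp = co$dbp_mmhg))
  expect_equal(snaps$sf_ratio, compute_sf_ratio(co$spo2_pct, co$fio2))
  expect_identical(snaps$on_imv,
                   !is.na(co$resp_support) & co$resp_support == "imv")
})

test_that("score tables serialize losslessly and deterministically", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  on.exit(unlink(c(f1, f2)))
  co <- generate_cohort(n = 20, seed = 3)
  src <- tempfile(fileext = ".csv"); on.exit(unlink(src), add = TRUE)
  write_scores(co, src)
  tbl <- score_table(read_cohort(src), "phoenix8")
  write_scores(tbl, f1)
  write_scores(tbl, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- utils::read.csv(f1)
  expect_identical(back[-1], as.data.frame(lapply(tbl[-1], as.integer)))
  # integers are written without decimal points, flags as 0/1
  body <- readLines(f1)[-1]
  expect_false(any(grepl("\\.", sub("^[^,]*,", "", body))))
  expect_false(any(grepl("TRUE|FALSE", body)))
})

test_that("a header-only file yields an empty, scoreable table", {
  f <- write_tmp_csv(paste(names(generate_cohort(n = 0)), collapse = ","))
  on.exit(unlink(f))
  snaps <- read_cohort(f)
  expect_identical(nrow(snaps), 0L)
  scores <- score_table(snaps, "phoenix")
  expect_identical(nrow(scores), 0L)
  expect_identical(ncol(scores), 8L)  # pid + 7 score columns
})

test_that("a corrupt cell is reported with its row and column; lenient mode drops it", {
  f <- write_tmp_csv(c("age_months,platelets_k_ul",
                       "12,250", "24,high", "36,90"))
  on.exit(unlink(f))
  expect_error(read_cohort(f), "row 2, column 'platelets_k_ul'.*'high'")
  snaps <- read_cohort(f, lenient = TRUE)
  expect_identical(nrow(snaps), 2L)
  errs <- attr(snaps, "errors")
  expect_identical(errs$row, 2L)
  expect_identical(errs$field, "platelets_k_ul")
  expect_identical(attr(snaps, "source_rows"), c(1L, 3L))
})

test_that("domain violations are caught at read time with row numbers", {
  f <- write_tmp_csv(c("age_months,gcs,sbp_mmhg,dbp_mmhg,spo2_pct",
                       "12,16,90,60,99",    # GCS out of range
                       "24,12,60,80,99",    # DBP > SBP
                       ",12,90,60,99",      # age missing
                       "500,12,90,60,99",   # age out of range
                       "36,12,90,60,120"))  # SpO2 > 100
  on.exit(unlink(f))
  snaps <- read_cohort(f, lenient = TRUE)
  expect_identical(nrow(snaps), 0L)
  errs <- attr(snaps, "errors")
  expect_setequal(errs$row, 1:5)
  expect_error(read_cohort(f), "row 1")
})

test_that("explicit mappings are validated strictly", {
  f <- write_tmp_csv(c("edad,plaquetas", "12,95"))
  on.exit(unlink(f))
  snaps <- read_cohort(f, mapping = c(age_months = "edad",
                                      platelets_k_ul = "plaquetas"))
  expect_identical(score_table(snaps)$phoenix_coagulation_score, 1L)
  expect_error(read_cohort(f, mapping = c(age_months = "edad", inr = "inr")),
               "not in input: inr")
  expect_error(read_cohort(f, mapping = c(age_months = "edad", inr = "edad")),
               "more than one")
  expect_error(read_cohort(f, mapping = c(age_months = "edad",
                                          not_a_field = "plaquetas")),
               "unknown canonical field")
  expect_error(read_cohort(f, mapping = c(platelets_k_ul = "plaquetas")),
               "age_months")
})

test_that("mapping files load from YAML and JSON alike", {
  fy <- tempfile(fileext = ".yaml"); fj <- tempfile(fileext = ".json")
  on.exit(unlink(c(fy, fj)))
  writeLines(c("age_months: edad", "platelets_k_ul: plaquetas"), fy)
  writeLines('{"age_months": "edad", "platelets_k_ul": "plaquetas"}', fj)
  expect_identical(read_column_map(fy), read_column_map(fj))
  expect_error(read_column_map(tempfile(fileext = ".xml")), "unsupported")
})

test_that("TSV input is supported via the separator argument", {
  f <- tempfile(fileext = ".tsv"); on.exit(unlink(f))
  writeLines(c("age_months\tplatelets_k_ul", "36\t95"), f)
  snaps <- read_cohort(f, sep = "\t")
  expect_identical(snaps$platelets_k_ul, 95)
})

test_that("precomputed ratio and count columns are trusted as given", {
  f <- write_tmp_csv(c("age_months,pf_ratio,sf_ratio,vasoactive_count,map_mmhg",
                       "36,90,NA,2,30"))
  on.exit(unlink(f))
  mp <- c(age_months = "age_months", pf_ratio = "pf_ratio",
          sf_ratio = "sf_ratio", vasoactive_count = "vasoactive_count",
          map_mmhg = "map_mmhg")
  res <- score_table(read_cohort(f, mapping = mp))
  expect_identical(res$phoenix_cardiovascular_score, 4L)  # 2 meds + MAP 2pts
  expect_identical(res$phoenix_respiratory_score, 0L)     # ratio without support
})
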