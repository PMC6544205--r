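test_that("name contraction collapses punctuation runs and appends the suffix", {
  cases <- list(
    list("Body mass index (BMI)", 21001L, 0L, 0L,
         "body_mass_index_bmi_f21001_0_0"),
    list("Sex", 31L, 0L, 0L, "sex_f31_0_0"),
    list("A", 1L, 0L, 0L, "a_f1_0_0"),
    list("  Pulse rate, automated reading  ", 102L, 2L, 1L,
         "pulse_rate_automated_reading_f102_2_1"),
    list("Townsend deprivation index at recruitment", 189L, 0L, 0L,
         "townsend_deprivation_index_at_recruitment_f189_0_0"))
  for (cs in cases) {
    expect_identical(ukb_contract_name(cs[[1]], cs[[2]], cs[[3]], cs[[4]]),
                     cs[[5]])
  }
})

test_that("name contraction is idempotent on its own stem and errors on empty input", {
  descs <- c("Body mass index (BMI)", "Sex", "Qualifications: A-levels/AS-levels")
  once <- ukb_contract_name(descs, 1:3, 0L, 0L)
  stems <- sub("_f[0-9]+_[0-9]+_[0-9]+$", "", once)
  expect_identical(ukb_contract_name(stems, 1:3, 0L, 0L), once)
  expect_error(ukb_contract_name("", 42L), "42")
  expect_error(ukb_contract_name("!!!", 43L), "43")
})

test_that("HTML dictionary parsing recognises the eid row and maps types", {
  html <- paste0(
    "<html><body><p>preamble</p><table>",
    "<tr><th>UDI</th><th>Count</th><th>Type</th><th>Description</th></tr>",
    "<tr><td>eid</td><td>3</td><td>Sequence</td><td>ID</td></tr>",
    "<tr><td>21001-0.0</td><td>3</td><td>Continuous</td>",
    "<td>Body mass index (BMI)</td></tr>",
    "<tr><td>31-0.0</td><td>3</td><td>Categorical (single)</td>",
    "<td>Sex</td></tr>",
    "</table></body></html>")
  f <- withr::local_tempfile(fileext = ".html")
  writeLines(html, f)
  d <- ukb_parse_dictionary(f)
  expect_equal(nrow(d), 2L)
  expect_identical(attr(d, "identifier"), "eid")
  expect_identical(d$column_name,
                   c("body_mass_index_bmi_f21001_0_0", "sex_f31_0_0"))
  expect_identical(d$value_type, c("continuous", "categorical_single"))
  expect_identical(d$raw_udi, c("21001-0.0", "31-0.0"))
})

test_that("dictionary parsing fails cleanly on missing tables and bad UDIs", {
  f <- withr::local_tempfile(fileext = ".html")
  writeLines("<html><body><table><tr><th>X</th></tr></table></body></html>", f)
  expect_error(ukb_parse_dictionary(f), "UDI/Type/Description")

  writeLines(paste0(
    "<html><body><table>",
    "<tr><th>UDI</th><th>Type</th><th>Description</th></tr>",
    "<tr><td>banana</td><td>Continuous</td><td>Oops</td></tr>",
    "</table></body></html>"), f)
  expect_error(ukb_parse_dictionary(f), "banana")

  writeLines(paste0(
    "<html><body><table>",
    "<tr><th>UDI</th><th>Type</th><th>Description</th></tr>",
    "<tr><td>5-0.0</td><td>Hologram</td><td>Weird</td></tr>",
    "</table></body></html>"), f)
  expect_warning(d <- ukb_parse_dictionary(f), "Hologram")
  expect_identical(d$value_type, "text")
})

test_that("coding-script parsing extracts level/label pairs without executing code", {
  script <- c(
    "lvl.9 <- c(0,1)",
    "lbl.9 <- c(\"Female\",\"Male\")",
    "bd$f.31.0.0 <- factor(bd$f.31.0.0, levels=lvl.9, labels=lbl.9)")
  p <- ukb_parse_codings(script)
  expect_named(p$codings, "9")
  expect_identical(p$codings[["9"]]$levels, c("0", "1"))
  expect_identical(p$codings[["9"]]$labels, c("Female", "Male"))
  expect_identical(p$assignments$column, "f.31.0.0")
  expect_identical(p$assignments$coding_id, 9L)

  empty <- ukb_parse_codings("")
  expect_length(empty$codings, 0)
  expect_equal(nrow(empty$assignments), 0)
})

test_that("quoted labels may contain commas, parens and escaped quotes", {
  script <- c(
    "lvl.100 <- c(1,2,3)",
    "lbl.100 <- c(\"Yes, definitely\",\"No (never)\",\"Said \\\"maybe\\\"\")",
    "bd$f.20127.0.0 <- factor(bd$f.20127.0.0, levels=lvl.100, labels=lbl.100)")
  p <- ukb_parse_codings(script)
  expect_identical(p$codings[["100"]]$labels,
                   c("Yes, definitely", "No (never)", "Said \"maybe\""))
})

test_that("coding-script parsing reports mismatches and undeclared ids", {
  expect_error(
    ukb_parse_codings(c("lvl.7 <- c(1,2)", "lbl.7 <- c(\"a\")")),
    "coding 7")
  expect_error(
    ukb_parse_codings(c("lvl.7 <- c(1,2)", "lbl.7 <- c(\"a\",\"b\")",
                        "bd$f.1.0.0 <- factor(bd$f.1.0.0, levels=lvl.8, labels=lbl.8)")),
    "undeclared coding 8")
})

make_tab <- function(path, header, rows) writeLines(c(header, rows), path)

test_that("read_tab types columns, honours the NA token, and enforces eid", {
  f <- withr::local_tempfile(fileext = ".tab")
  desc <- tibble::tibble(field_id = 21001L, instance_index = 0L,
                         array_index = 0L, description = "Body mass index (BMI)",
                         value_type = "continuous", coding_id = NA_integer_,
                         raw_udi = "21001-0.0",
                         column_name = "body_mass_index_bmi_f21001_0_0")
  make_tab(f, "f.eid\tf.21001.0.0", c("1\t25.5", "2\tNA", "3\t31.2"))
  d <- ukb_read_tab(f, desc)
  expect_equal(dim(d), c(3L, 2L))
  expect_type(d[["f.21001.0.0"]], "double")
  expect_true(is.na(d[["f.21001.0.0"]][2]))

  make_tab(f, "id\tf.21001.0.0", c("1\t25.5"))
  expect_error(ukb_read_tab(f, desc), class = "ukb_format_error")

  make_tab(f, "f.eid\tf.21001.0.0", c("1\t25.5", "1\t30.0"))
  expect_error(ukb_read_tab(f, desc), class = "ukb_integrity_error")

  make_tab(f, "f.eid\tf.21001.0.0\tf.999.0.0", c("1\t25.5\tx"))
  expect_warning(d <- ukb_read_tab(f, desc), "f.999.0.0")
  expect_type(d[["f.999.0.0"]], "character")
})

test_that("read_tab results are independent of chunk size", {
  sim <- ukb_sim_fileset(out_dir = withr::local_tempdir(),
                         spec = ukb_sim_spec(n = 100, seed = 11))
  desc <- ukb_parse_dictionary(sim$files["html"])
  whole <- ukb_read_tab(sim$files["tab"], desc, chunk_size = 1000)
  for (cs in c(1L, 7L, 100L)) {
    expect_identical(ukb_read_tab(sim$files["tab"], desc, chunk_size = cs),
                     whole)
  }
})

test_that("dataset assembly recovers the generator's ground truth exactly", {
  dir <- withr::local_tempdir()
  sim <- ukb_sim_fileset(out_dir = dir, spec = ukb_sim_spec(n = 200, seed = 3))
  d <- ukb_dataset(sim$stem, path = dir)
  expect_identical(names(d), sim$truth$column_names)
  expect_equal(as.data.frame(d), as.data.frame(sim$truth$data),
               ignore_attr = TRUE)
  # coded sex column carries labels only
  expect_setequal(levels(d$sex_f31_0_0), c("Female", "Male"))
  expect_false(any(as.character(d$sex_f31_0_0) %in% c("0", "1")))
})

test_that("values missing from a coding map are kept raw with a warning", {
  dir <- withr::local_tempdir()
  writeLines(c("f.eid\tf.31.0.0", "1\t0", "2\t1", "3\t7"),
             file.path(dir, "x.tab"))
  writeLines(c("lvl.9 <- c(0,1)", "lbl.9 <- c(\"Female\",\"Male\")",
               "bd$f.31.0.0 <- factor(bd$f.31.0.0, levels=lvl.9, labels=lbl.9)"),
             file.path(dir, "x.r"))
  writeLines(paste0(
    "<html><body><table>",
    "<tr><th>UDI</th><th>Type</th><th>Description</th></tr>",
    "<tr><td>31-0.0</td><td>Categorical (single)</td><td>Sex</td></tr>",
    "</table></body></html>"), file.path(dir, "x.html"))
  expect_warning(d <- ukb_dataset("x", path = dir), "7")
  expect_identical(as.character(d$sex_f31_0_0), c("Female", "Male", "7"))
})

test_that("a missing fileset member is reported by name", {
  dir <- withr::local_tempdir()
  writeLines("f.eid", file.path(dir, "y.tab"))
  writeLines("", file.path(dir, "y.r"))
  expect_error(ukb_dataset("y", path = dir), "y.html")
})

test_that("field lookup works in both directions and is empty on misses", {
  dir <- withr::local_tempdir()
  sim <- ukb_sim_fileset(out_dir = dir, spec = ukb_sim_spec(n = 20, seed = 5))
  d <- ukb_dataset(sim$stem, path = dir)

  by_field <- ukb_field_lookup(d, field = 21001)
  expect_true("body_mass_index_bmi_f21001_0_0" %in% by_field$column_name)
  by_name <- ukb_field_lookup(d, column = "sex_f31_0_0")
  expect_identical(by_name$field_id, 31L)
  expect_equal(nrow(ukb_field_lookup(d, field = 999999)), 0L)

  by_stem <- ukb_field_lookup(sim$stem, path = dir)
  expect_identical(sort(by_stem$column_name),
                   sort(setdiff(sim$truth$column_names, "eid")))
})

test_that("merging filesets is a full outer join with provenance-suffixed collisions", {
  a <- tibble::tibble(eid = c(1L, 2L), x = c(10, 20))
  b <- tibble::tibble(eid = c(2L, 3L), y = c("p", "q"))
  m <- ukb_merge(a, b)
  expect_equal(nrow(m), 3L)
  expect_setequal(names(m), c("eid", "x", "y"))
  expect_true(is.na(m$y[m$eid == 1]))
  expect_true(is.na(m$x[m$eid == 3]))

  b2 <- tibble::tibble(eid = c(2L, 3L), x = c(99, 98))
  attr(b2, "ukb_stem") <- "ukb222"
  expect_warning(m2 <- ukb_merge(a, b2), "x")
  expect_setequal(names(m2), c("eid", "x", "x_ukb222"))
  expect_equal(m2$x[m2$eid == 2], 20)
  expect_equal(m2$x_ukb222[m2$eid == 2], 99)

  # associative over disjoint-column inputs up to column order
  cc <- tibble::tibble(eid = 1:3, z = 1:3)
  left <- ukb_merge(ukb_merge(a, b), cc)
  right <- ukb_merge(a, ukb_merge(b, cc))
  expect_equal(left[order(left$eid), sort(names(left))],
               right[order(right$eid), sort(names(right))])
})
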