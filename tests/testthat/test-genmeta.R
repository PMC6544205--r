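test_that("sample-QC schema applies to a headerless table and checks widths", {
  nm <- ukb_sqc_names()
  expect_true(all(c("genotyping_array", "inferred_gender", "heterozygosity",
                    "used_in_pca_calculation", "pc1", "pc40") %in% nm))

  side <- ukb_sim_sidecars(out_dir = withr::local_tempdir(), n = 8, seed = 4)
  sqc <- ukb_read_sqc(side$files["sqc"])
  expect_identical(names(sqc), nm)
  expect_equal(nrow(sqc), 8L)
  expect_type(sqc$pc1, "double")

  f <- withr::local_tempfile()
  writeLines(c("1 2 3", "4 5 6"), f)
  expect_identical(ukb_read_sqc(f, names = c("a", "b", "c"))$b, c(2L, 5L))
  err <- tryCatch(ukb_read_sqc(f, names = c("a", "b", "c", "d")),
                  error = conditionMessage)
  expect_match(err, "4 names")
  expect_match(err, "3 columns")
})

test_that("kinship coefficients bin into the standard KING degrees", {
  expect_identical(as.character(ukb_kinship_degree(
    c(0.45, 0.25, 0.12, 0.05, 0.01, -0.01))),
    c("duplicate_mz", "first", "second", "third", "none", "none"))
  # bounds inclusive on the low bin
  expect_identical(as.character(ukb_kinship_degree(0.0884)), "third")
  expect_identical(as.character(ukb_kinship_degree(0.0442)), "none")
  expect_identical(as.character(ukb_kinship_degree(0.3536)), "first")
})

test_that("relatedness counts tabulate degrees and honour id restriction", {
  pairs <- tibble::tibble(id1 = c("a", "c", "e", "g"),
                          id2 = c("b", "d", "f", "h"),
                          het_het = 0.2, ibs0 = 0.001,
                          kinship = c(0.4, 0.2, 0.1, 0.05))
  rc <- ukb_rel_count(pairs)
  expect_identical(rc$degree, c("duplicate_mz", "first", "second", "third"))
  expect_identical(rc$n_pairs, rep(1L, 4))
  expect_equal(nrow(attr(rc, "points")), 4L)

  rc2 <- ukb_rel_count(pairs, restrict_to = c("a", "c", "e", "g"))
  expect_identical(rc2$n_pairs, rep(0L, 4))

  rc3 <- ukb_rel_count(pairs[0, ])
  expect_identical(rc3$n_pairs, rep(0L, 4))

  # total over degrees = pairs above the unrelated bound
  set.seed(31)
  g <- random_kinship_graph(30, 60, seed = 31)
  rc4 <- ukb_rel_count(g)
  expect_equal(sum(rc4$n_pairs), sum(g$kinship > 0.0442))
})

test_that("related_with_data keeps exactly the doubly-phenotyped pairs", {
  pairs <- tibble::tibble(id1 = c("a", "c"), id2 = c("b", "d"),
                          kinship = c(0.2, 0.2))
  expect_equal(nrow(ukb_related_with_data(pairs, c("a", "b", "c"))), 1L)
  expect_equal(nrow(ukb_related_with_data(pairs, c("a", "b", "c", "d"))), 2L)
  for (s in 1:20) {
    g <- random_kinship_graph(15, 25, seed = s)
    ph <- sample(paste0("s", 1:15), sample(3:15, 1))
    got <- ukb_related_with_data(g, ph)
    brute <- g[g$id1 %in% ph & g$id2 %in% ph, ]
    expect_equal(got, brute)
  }
})

test_that("pruning removes nothing when no pair exceeds the cutoff", {
  pairs <- tibble::tibble(id1 = "a", id2 = "b", kinship = 0.05)
  expect_length(ukb_samples_to_remove(pairs, c("a", "b")), 0L)
  # unphenotyped members never force removals
  pairs2 <- tibble::tibble(id1 = "a", id2 = "b", kinship = 0.3)
  expect_length(ukb_samples_to_remove(pairs2, c("a", "x")), 0L)
})

test_that("pruning matches brute-force minimum cover on simple families", {
  # single edge: one removal, tie broken to the smaller id
  single <- tibble::tibble(id1 = "b", id2 = "a", kinship = 0.2)
  expect_identical(ukb_samples_to_remove(single, c("a", "b")), "a")

  # star: hub removal suffices
  star <- tibble::tibble(id1 = rep("h", 3), id2 = c("a", "b", "c"),
                         kinship = 0.1)
  expect_identical(ukb_samples_to_remove(star, c("h", "a", "b", "c")), "h")

  # path a-b-c-d: cover of size 2
  path <- tibble::tibble(id1 = c("a", "b", "c"), id2 = c("b", "c", "d"),
                         kinship = 0.2)
  got <- ukb_samples_to_remove(path, letters[1:4])
  expect_length(got, brute_min_vertex_cover(path$id1, path$id2))
  expect_true(is_vertex_cover(got, path$id1, path$id2))

  # disjoint pairs: one per pair
  dp <- tibble::tibble(id1 = c("a", "c", "e"), id2 = c("b", "d", "f"),
                       kinship = 0.2)
  got <- ukb_samples_to_remove(dp, letters[1:6])
  expect_length(got, 3L)
  expect_identical(got, c("a", "c", "e"))
})

test_that("pruning yields a gratuity-free vertex cover on random graphs", {
  for (s in 1:60) {
    g <- random_kinship_graph(n_nodes = sample(4:12, 1), n_edges = sample(2:14, 1),
                              seed = 1000 + s)
    ph <- unique(c(g$id1, g$id2))
    got <- ukb_samples_to_remove(g, ph)
    over <- g[g$kinship > 0.0884, ]
    expect_true(is_vertex_cover(got, over$id1, over$id2))
    # sanity bound and determinism
    expect_gte(length(got), brute_min_vertex_cover(over$id1, over$id2))
    expect_identical(got, ukb_samples_to_remove(g, ph))
    # no gratuitous removals: each removed id covered >= 1 then-uncovered edge
    a <- over$id1; b <- over$id2
    for (v in got) {
      expect_true(any(a == v | b == v))
      keep <- !(a == v | b == v)
      a <- a[keep]; b <- b[keep]
    }
    expect_length(a, 0L)
  }
})

test_that("fam files parse with order preserved and strict column counts", {
  side <- ukb_sim_sidecars(out_dir = withr::local_tempdir(), n = 12, seed = 8)
  fam <- ukb_read_fam(side$files["fam"])
  expect_equal(nrow(fam), 12L)
  expect_identical(as.integer(fam$iid), side$truth$id)
  expect_identical(fam$sex, side$truth$sex)
  expect_true(all(fam$sex %in% 0:2))

  f <- withr::local_tempfile()
  writeLines(c("1 1 0 0 1 -9", "2 2 0 0 2"), f)
  expect_error(ukb_read_fam(f), "line 2")
  writeLines(c("1 1 0 0 7 -9"), f)
  expect_warning(ukb_read_fam(f), "sex")
})

test_that("sample files parse the two-line Oxford header", {
  side <- ukb_sim_sidecars(out_dir = withr::local_tempdir(), n = 6, seed = 15)
  smp <- ukb_read_sample(side$files["sample"])
  expect_equal(nrow(smp), 6L)                 # type line is not data
  expect_identical(smp$ID_1, as.character(side$truth$id))
  expect_identical(attr(smp, "types"), c("0", "0", "0", "D"))

  f <- withr::local_tempfile()
  writeLines(c("ID_1 ID_2 missing sex", "0 0 0", "1 1 0 2"), f)
  expect_error(ukb_read_sample(f), "type line")
  writeLines(c("ID_1 ID_2 missing sex", "1 0 0 D", "1 1 0 2"), f)
  expect_error(ukb_read_sample(f), "0 0 0")
})

test_that("BGENIE output rows follow the genotype sample order exactly", {
  set.seed(99)
  for (rep in 1:5) {
    ids <- sample(1000:9999, 15)
    data <- tibble::tibble(eid = sample(ids, 10),
                           bmi = round(rnorm(10, 27, 4), 3))
    order_ids <- sample(ids)                  # shuffled sample order
    f <- withr::local_tempfile()
    ukb_gen_write(data, f, kind = "bgenie_pheno", sample_order = order_ids)
    lines <- readLines(f)
    expect_identical(lines[1], "bmi")
    expect_length(lines, length(order_ids) + 1L)
    expected <- vapply(order_ids, function(id) {
      i <- match(id, data$eid)
      if (is.na(i)) "-999" else as.character(data$bmi[i])
    }, "")
    expect_identical(lines[-1], unname(expected))
  }
})

test_that("writers use the per-kind missing tokens and id layouts", {
  data <- tibble::tibble(eid = c(10L, 11L), pheno = c(1.5, NA))
  fp <- withr::local_tempfile()
  ukb_gen_write(data, fp, kind = "plink_pheno")
  expect_identical(readLines(fp),
                   c("FID IID pheno", "10 10 1.5", "11 11 NA"))

  fb <- withr::local_tempfile()
  ukb_gen_write(data, fb, kind = "bgenie_pheno", sample_order = c(11L, 10L))
  expect_identical(readLines(fb), c("pheno", "-999", "1.5"))

  fe <- withr::local_tempfile()
  ukb_gen_write(c(5L, 7L), fe, kind = "plink_exclusions")
  expect_identical(readLines(fe), c("5 5", "7 7"))

  expect_error(ukb_gen_write(data, fb, kind = "bgenie_pheno"),
               "sample_order")
  expect_error(ukb_gen_write(data, fp, kind = "plink_pheno",
                             columns = "nope"), "unknown column")
})
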