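# Synthetic filesets with known ground truth. These emulate the three-file
# dialect (.tab/.r/.html), KING-style kinship pair files, headerless
# sample-QC tables, PLINK .fam and Oxford .sample files, so the parsing,
# query and writing machinery is testable without real cohort data.

# R-source string literal with escaped backslashes and double quotes.
r_quote <- function(x) {
  paste0("\"", gsub("\"", "\\\\\"", gsub("\\\\", "\\\\\\\\", x)), "\"")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Specification of a synthetic fileset
#'
#' Describes the variables, codings, cohort size and missingness of a
#' synthetic fileset. The default specification mirrors a small baseline
#' extract: sex (field 31), ethnic background (21000), BMI at two
#' instances (21001), age at recruitment (21022), Townsend deprivation
#' index (189), assessment centre (54), date of attending (53), standing
#' height (50), number in household (709), and two ICD-10 diagnosis array
#' columns (41270) drawing codes from the bundled demo ICD-10 subset —
#' twelve variables, three data codings.
#'
#' Continuous fields are drawn from normal or uniform distributions and
#' categorical values uniformly over their coding levels: the fixtures
#' exercise file-dialect plumbing, not biology.
#'
#' @param n Number of individuals.
#' @param missing_rate Per-cell missingness fraction in `[0, 1]`.
#' @param seed Integer seed; fully determines the emitted bytes.
#' @return A list with `n`, `missing_rate`, `seed`, `fields` (tibble) and
#'   `codings` (list), accepted by [ukb_sim_fileset()].
#' @export
ukb_sim_spec <- function(n = 1000L, missing_rate = 0.02, seed = 1L) {
  stopifnot(n >= 1, missing_rate >= 0, missing_rate <= 1)
  fields <- tibble(
    field_id = c(31L, 21000L, 21001L, 21001L, 21022L, 189L, 54L,
                 41270L, 41270L, 53L, 50L, 709L),
    instance_index = c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    array_index = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L),
    description = c(
      "Sex", "Ethnic background", "Body mass index (BMI)",
      "Body mass index (BMI)", "Age at recruitment",
      "Townsend deprivation index at recruitment", "UK Biobank assessment centre",
      "Diagnoses - ICD10", "Diagnoses - ICD10", "Date of attending assessment centre",
      "Standing height", "Number in household"),
    type = c("Categorical (single)", "Categorical (single)", "Continuous",
             "Continuous", "Integer", "Continuous", "Categorical (single)",
             "Text", "Text", "Date", "Continuous", "Integer"),
    coding_id = c(9L, 1001L, NA, NA, NA, NA, 10L, NA, NA, NA, NA, NA),
    dist = c("coding", "coding", "normal", "normal", "unif_int", "normal",
             "coding", "icd10", "icd10", "date", "normal", "unif_int"),
    p1 = c(NA, NA, 27, 27.5, 40, 0, NA, NA, NA, NA, 168, 1),
    p2 = c(NA, NA, 4, 4, 69, 3, NA, NA, NA, NA, 9, 8)
  )
  codings <- list(
    list(coding_id = 9L, levels = c("0", "1"),
         labels = c("Female", "Male"), is_ordered = FALSE),
    list(coding_id = 1001L,
         levels = c("1001", "1002", "3001", "4001", "5", "6"),
         labels = c("British", "Irish", "Indian", "Caribbean", "Chinese",
                    "Any other group, mixed background"),
         is_ordered = FALSE),
    list(coding_id = 10L, levels = c("11010", "11011", "11012"),
         labels = c("Leeds", "Bristol", "Nottingham"), is_ordered = FALSE)
  )
  list(n = as.integer(n), missing_rate = missing_rate,
       seed = as.integer(seed), fields = fields, codings = codings)
}

#' Generate a synthetic fileset with known ground truth
#'
#' Emits `<stem>.tab`, `<stem>.r` and `<stem>.html` under `out_dir` in the
#' dialects read by [ukb_dataset()], plus the ground truth the files were
#' built from. Output is byte-identical for identical specifications
#' (including seed).
#'
#' @param out_dir Output directory (created if needed).
#' @param spec A specification from [ukb_sim_spec()].
#' @param stem Fileset stem (default `"ukbsim"`).
#' @return A list: `stem`, `path`, `files` (tab/r/html paths), and `truth`
#'   with `column_names` (eid first, in file order), `eid`, `data` (the
#'   tibble [ukb_dataset()] should reconstruct, labels applied),
#'   `label_sets` (labels per coded column), and `fields`.
#' @export
ukb_sim_fileset <- function(out_dir = tempdir(), spec = ukb_sim_spec(),
                            stem = "ukbsim") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fields <- spec$fields
  codings <- spec$codings
  names(codings) <- vapply(codings, function(x) as.character(x$coding_id), "")
  n <- spec$n

  set.seed(spec$seed)
  eid <- sort(sample.int(8999999L, n) + 1000000L)

  icd_pool <- ukb_icd_codes("icd10")$code
  raw <- list()    # strings as written to .tab
  expected <- list()  # values ukb_dataset() should reconstruct
  for (i in seq_len(nrow(fields))) {
    dist <- fields$dist[i]
    if (dist == "normal") {
      v <- sprintf("%.4f", rnorm(n, fields$p1[i], fields$p2[i]))
      ev <- as.numeric(v)
    } else if (dist == "unif_int") {
      ev <- sample(fields$p1[i]:fields$p2[i], n, replace = TRUE)
      v <- as.character(ev)
    } else if (dist == "coding") {
      cmap <- codings[[as.character(fields$coding_id[i])]]
      v <- sample(cmap$levels, n, replace = TRUE)
      ev <- factor(cmap$labels[match(v, cmap$levels)], levels = cmap$labels,
                   ordered = cmap$is_ordered)
    } else if (dist == "icd10") {
      v <- sample(icd_pool, n, replace = TRUE)
      ev <- v
    } else if (dist == "date") {
      ev <- as.Date("2008-01-01") + sample.int(1200L, n, replace = TRUE)
      v <- format(ev, "%Y-%m-%d")
    } else {
      ukb_usage_error(paste0("unknown distribution spec: ", dist))
    }
    if (spec$missing_rate > 0) {
      miss <- runif(n) < spec$missing_rate
      v[miss] <- NA
      if (is.factor(ev)) {
        ev[miss] <- NA
      } else {
        ev[miss] <- NA
      }
    }
    raw[[i]] <- v
    expected[[i]] <- ev
  }

  colnames_out <- ukb_contract_name(fields$description, fields$field_id,
                                    fields$instance_index,
                                    fields$array_index)
  tokens <- tab_token(fields$field_id, fields$instance_index,
                      fields$array_index)

  # --- .tab ---
  tab_path <- file.path(out_dir, paste0(stem, ".tab"))
  cells <- vapply(seq_len(n), function(r) {
    vals <- vapply(raw, function(col) {
      if (is.na(col[r])) "NA" else col[r]
    }, "")
    paste(c(eid[r], vals), collapse = "\t")
  }, "")
  writeLines(c(paste(c("f.eid", tokens), collapse = "\t"), cells), tab_path)

  # --- .html ---
  html_path <- file.path(out_dir, paste0(stem, ".html"))
  rows <- c(
    "<tr><th>UDI</th><th>Count</th><th>Type</th><th>Description</th></tr>",
    sprintf("<tr><td>eid</td><td>%d</td><td>Sequence</td><td>Encoded anonymised participant ID</td></tr>", n),
    sprintf("<tr><td>%d-%d.%d</td><td>%d</td><td>%s</td><td>%s</td></tr>",
            fields$field_id, fields$instance_index, fields$array_index, n,
            html_escape(fields$type), html_escape(fields$description)))
  writeLines(c("<html><head><title>Data dictionary</title></head><body>",
               "<table border=\"1\">", rows, "</table>", "</body></html>"),
             html_path)

  # --- .r ---
  r_path <- file.path(out_dir, paste0(stem, ".r"))
  lines <- character(0)
  for (cmap in codings) {
    id <- cmap$coding_id
    lines <- c(lines,
               paste0("lvl.", id, " <- c(", paste(cmap$levels, collapse = ","), ")"),
               paste0("lbl.", id, " <- c(",
                      paste(r_quote(cmap$labels), collapse = ","), ")"))
  }
  for (i in which(!is.na(fields$coding_id))) {
    id <- fields$coding_id[i]
    fn <- if (isTRUE(codings[[as.character(id)]]$is_ordered)) "ordered" else "factor"
    lines <- c(lines, paste0(
      "bd$", tokens[i], " <- ", fn, "(bd$", tokens[i],
      ", levels=lvl.", id, ", labels=lbl.", id, ")"))
  }
  writeLines(lines, r_path)

  names(expected) <- colnames_out
  truth_data <- as_tibble(c(list(eid = eid), expected))
  label_sets <- lapply(which(!is.na(fields$coding_id)), function(i) {
    codings[[as.character(fields$coding_id[i])]]$labels
  })
  names(label_sets) <- colnames_out[!is.na(fields$coding_id)]

  list(stem = stem, path = out_dir,
       files = c(tab = tab_path, r = r_path, html = html_path),
       truth = list(column_names = c("eid", colnames_out), eid = eid,
                    data = truth_data, label_sets = label_sets,
                    fields = fields))
}

#' Generate a KING-style kinship pair file
#'
#' Writes a whitespace-delimited pair file with header
#' `ID1 ID2 HetHet IBS0 Kinship`, either from an explicit edge table or at
#' random. In random mode each pair's kinship is drawn uniformly within a
#' randomly chosen relatedness band (duplicate/MZ, 1st, 2nd, 3rd degree,
#' or unrelated), strictly inside the band so the intended degree is
#' unambiguous.
#'
#' @param out_file Output file path.
#' @param edges Optional data frame with columns `id1`, `id2`, `kinship`
#'   and optionally `ibs0`; self-pairs are an error.
#' @param ids Pool of ids for random mode (default `1:(4 * n_pairs)`).
#' @param n_pairs Number of random pairs.
#' @param seed Integer seed for random mode.
#' @return A list: `file`, and `truth` (tibble `id1`, `id2`, `het_het`,
#'   `ibs0`, `kinship`, `degree` — the intended degree band).
#' @export
ukb_sim_kinship <- function(out_file, edges = NULL, ids = NULL,
                            n_pairs = 50L, seed = 1L) {
  bands <- list(duplicate_mz = c(0.3536, 0.5), first = c(0.1768, 0.3536),
                second = c(0.0884, 0.1768), third = c(0.0442, 0.0884),
                none = c(-0.05, 0.0442))
  if (is.null(edges)) {
    set.seed(seed)
    if (is.null(ids)) ids <- seq_len(4L * n_pairs)
    pool <- t(utils::combn(ids, 2L))
    take <- sample.int(nrow(pool), min(n_pairs, nrow(pool)))
    deg <- sample(names(bands), length(take), replace = TRUE)
    kin <- vapply(deg, function(d) {
      b <- bands[[d]]
      runif(1, b[1] + 1e-3, b[2] - 1e-3)
    }, 1.0)
    edges <- tibble(id1 = pool[take, 1], id2 = pool[take, 2],
                    kinship = kin, ibs0 = runif(length(take), 0, 0.01))
    intended <- deg
  } else {
    edges <- as_tibble(edges)
    if (!"ibs0" %in% names(edges)) edges$ibs0 <- 0.001
    intended <- vapply(edges$kinship, function(k) {
      hit <- vapply(bands, function(b) k > b[1] && k <= b[2], NA)
      if (any(hit)) names(bands)[which(hit)[1]] else "none"
    }, "")
  }
  if (any(edges$id1 == edges$id2)) {
    ukb_usage_error("self-pairs are not allowed in a kinship file")
  }
  key <- paste(pmin(as.character(edges$id1), as.character(edges$id2)),
               pmax(as.character(edges$id1), as.character(edges$id2)))
  if (anyDuplicated(key)) {
    ukb_integrity_error("an unordered pair appears more than once")
  }
  het <- if (!"het_het" %in% names(edges)) {
    round(runif(nrow(edges), 0.1, 0.3), 4)
  } else {
    edges$het_het
  }
  writeLines(c("ID1 ID2 HetHet IBS0 Kinship",
               sprintf("%s %s %.4f %.6f %.6f", edges$id1, edges$id2,
                       het, edges$ibs0, edges$kinship)),
             out_file)
  list(file = out_file,
       truth = tibble(id1 = edges$id1, id2 = edges$id2, het_het = het,
                      ibs0 = round(edges$ibs0, 6),
                      kinship = round(edges$kinship, 6),
                      degree = intended))
}

#' Generate matching sample-QC, .fam and .sample sidecar files
#'
#' Emits a headerless sample-QC table following the bundled column schema
#' (see [ukb_sqc_names()]), a six-column PLINK `.fam` and an Oxford
#' `.sample` file (two header lines, the second being the `0 0 0` type
#' line). All three agree on individual order.
#'
#' @param out_dir Output directory.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param stem File stem (default `"ukbsim"`).
#' @return A list: `files` (named `sqc`, `fam`, `sample`) and `truth`
#'   (tibble `id`, `sex` in emitted order, plus `n`).
#' @export
ukb_sim_sidecars <- function(out_dir = tempdir(), n = 100L, seed = 1L,
                             stem = "ukbsim") {
  stopifnot(n >= 1)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(seed)
  ids <- sort(sample.int(8999999L, n) + 1000000L)
  sex <- sample(1:2, n, replace = TRUE)

  schema <- ukb_sqc_names()
  pcs <- matrix(sprintf("%.5f", rnorm(40L * n)), nrow = n)
  sqc_rows <- vapply(seq_len(n), function(i) {
    paste(c(
      sprintf("a%07d", ids[i]), sprintf("a%07d", ids[i]),
      sample(c("UKBB", "UKBL"), 1), sprintf("Batch_b%03d", sample.int(95L, 1)),
      sprintf("Plate_%03d", sample.int(50L, 1)),
      sprintf("%s%02d", sample(LETTERS[1:8], 1), sample.int(12L, 1)),
      sprintf("%.5f", runif(1, 0.97, 0.999)), sprintf("%.5f", runif(1, 0.82, 0.99)),
      sprintf("%.2f", runif(1, 1, 4)),
      c("M", "F")[sex[i]], c("M", "F")[sex[i]],
      sprintf("%.3f", runif(1, 400, 900)), sprintf("%.3f", runif(1, 400, 900)),
      sprintf("Plate_%03d", sample.int(50L, 1)),
      sprintf("%s%02d", sample(LETTERS[1:8], 1), sample.int(12L, 1)),
      sprintf("%.6f", runif(1, 0, 0.02)), sprintf("%.5f", runif(1, 0.18, 0.21)),
      sprintf("%.5f", rnorm(1)), "0", "0",
      sample(0:1, 1), "0", "0", sample(0:1, 1), sample(0:1, 1),
      pcs[i, ], "1", "1", "1"), collapse = " ")
  }, "")
  stopifnot(length(strsplit(sqc_rows[1], " ")[[1]]) == length(schema))

  sqc_path <- file.path(out_dir, paste0(stem, "_sqc.txt"))
  fam_path <- file.path(out_dir, paste0(stem, ".fam"))
  sample_path <- file.path(out_dir, paste0(stem, ".sample"))
  writeLines(sqc_rows, sqc_path)
  writeLines(sprintf("%d %d 0 0 %d -9", ids, ids, sex), fam_path)
  writeLines(c("ID_1 ID_2 missing sex",
               "0 0 0 D",
               sprintf("%d %d 0 %d", ids, ids, sex)), sample_path)

  list(files = c(sqc = sqc_path, fam = fam_path, sample = sample_path),
       truth = tibble(id = ids, sex = sex), n = as.integer(n))
}
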