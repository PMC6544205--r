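# Genetic-metadata utilities: sample-QC column naming, KING kinship
# degree classification and counts, phenotype-aware relatedness pruning,
# and PLINK/BGENIE file readers and writers.

#' Column names for the headerless sample-QC file
#'
#' The per-sample QC table ships without a header row. This returns the
#' ordered column-name schema to apply to it: genotyping array and batch,
#' plate/well, call rate, submitted and inferred sex, intensities,
#' missingness, heterozygosity (raw and PC-corrected), QC flags, forty
#' genetic principal components, and phasing-input flags. The bundled
#' default schema is versioned with the package; supply `file` to
#' override it when the distributed table's layout drifts.
#'
#' @param file Optional path to a text file with one column name per
#'   line, replacing the bundled schema.
#' @return Character vector of column names.
#' @export
ukb_sqc_names <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "sqc_columns.txt", package = "ukbkit",
                        mustWork = TRUE)
  }
  out <- readLines(file, warn = FALSE)
  out[nzchar(trimws(out))]
}

#' Read a headerless sample-QC table and apply the column schema
#'
#' @param path Whitespace-delimited file with no header row.
#' @param names Column schema, default [ukb_sqc_names()]. A schema whose
#'   length differs from the observed column count is an error reporting
#'   both counts.
#' @return A tibble; row order (= genotype sample order) preserved.
#' @export
ukb_read_sqc <- function(path, names = ukb_sqc_names()) {
  tab <- utils::read.table(path, header = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) != length(names)) {
    ukb_format_error(paste0(
      "sample-QC schema has ", length(names), " names but the file has ",
      ncol(tab), " columns; pass a matching schema"))
  }
  names(tab) <- names
  tab <- utils::type.convert(tab, as.is = TRUE)
  as_tibble(tab)
}

#' Read a KING-style kinship pair file
#'
#' @param path Whitespace-delimited file with header
#'   `ID1 ID2 HetHet IBS0 Kinship`.
#' @return A tibble with `id1`, `id2`, `het_het`, `ibs0`, `kinship`; each
#'   unordered pair appears once.
#' @export
ukb_read_kinship <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("ID1", "ID2", "HetHet", "IBS0", "Kinship")
  if (!all(need %in% names(tab))) {
    ukb_format_error(paste0("kinship file must have header ",
                            paste(need, collapse = " ")))
  }
  out <- tibble(id1 = tab$ID1, id2 = tab$ID2, het_het = tab$HetHet,
                ibs0 = tab$IBS0, kinship = tab$Kinship)
  key <- paste(pmin(as.character(out$id1), as.character(out$id2)),
               pmax(as.character(out$id1), as.character(out$id2)))
  if (anyDuplicated(key)) {
    ukb_integrity_error("an unordered pair appears more than once")
  }
  out
}

#' Classify a KING kinship coefficient into a relatedness degree
#'
#' Standard KING powers-of-two bins: kinship above 0.3536 is a
#' duplicate/monozygotic-twin pair, (0.1768, 0.3536] first degree,
#' (0.0884, 0.1768] second degree, (0.0442, 0.0884] third degree, and at
#' or below 0.0442 unrelated (`none`). Bounds are inclusive on the low
#' bin. Thresholds are configurable.
#'
#' @param kinship Numeric vector of kinship coefficients (KING estimates
#'   may be negative).
#' @param thresholds Increasing numeric vector of the four bin bounds.
#' @return Factor with levels `duplicate_mz`, `first`, `second`, `third`,
#'   `none`.
#' @export
ukb_kinship_degree <- function(kinship,
                               thresholds = c(0.0442, 0.0884, 0.1768,
                                              0.3536)) {
  stopifnot(length(thresholds) == 4, !is.unsorted(thresholds))
  lev <- c("duplicate_mz", "first", "second", "third", "none")
  out <- ifelse(kinship > thresholds[4], "duplicate_mz",
         ifelse(kinship > thresholds[3], "first",
         ifelse(kinship > thresholds[2], "second",
         ifelse(kinship > thresholds[1], "third", "none"))))
  factor(out, levels = lev)
}

#' Count related pairs by degree of relatedness
#'
#' Tabulates pairs as duplicates/monozygotic twins, 1st-, 2nd- and
#' 3rd-degree relatives, optionally restricted to pairs whose members are
#' both in a given id set (e.g. a study subsample). The underlying
#' scatter data (IBS0 against kinship, labelled by degree) is attached as
#' the `"points"` attribute, so the classic relatedness plot can be
#' reproduced for any subset.
#'
#' @param pairs Kinship pair tibble from [ukb_read_kinship()].
#' @param restrict_to Optional id set; pairs are kept only when both
#'   members belong to it.
#' @return A tibble `degree`, `n_pairs` (four rows, zero-filled), with
#'   attribute `"points"`.
#' @export
ukb_rel_count <- function(pairs, restrict_to = NULL) {
  if (!is.null(restrict_to)) {
    keep <- as.character(pairs$id1) %in% as.character(restrict_to) &
      as.character(pairs$id2) %in% as.character(restrict_to)
    pairs <- pairs[keep, ]
  }
  deg <- ukb_kinship_degree(pairs$kinship)
  counts <- table(deg)
  lev <- c("duplicate_mz", "first", "second", "third")
  out <- tibble(degree = lev, n_pairs = as.integer(counts[lev]))
  attr(out, "points") <- tibble(ibs0 = pairs$ibs0, kinship = pairs$kinship,
                                degree = deg)
  out
}

#' Related pairs in which both members have phenotype data
#'
#' The complete subset of related pairs whose two members both carry data
#' on the phenotype of interest — the pairs that actually constrain a
#' phenotype-specific unrelated subset.
#'
#' @param pairs Kinship pair tibble.
#' @param phenotyped_ids Ids of individuals with non-missing phenotype.
#' @return The filtered pair tibble.
#' @export
ukb_related_with_data <- function(pairs, phenotyped_ids) {
  ph <- as.character(phenotyped_ids)
  pairs[as.character(pairs$id1) %in% ph &
          as.character(pairs$id2) %in% ph, ]
}

#' Samples to remove for a maximal phenotype-specific unrelated subset
#'
#' Removes the minimum practical number of phenotyped individuals so that
#' no remaining pair exceeds the relatedness cutoff (default kinship >
#' 0.0884, the 3rd-degree bound). Pairs with either member unphenotyped
#' never force a removal. The removal set is a vertex cover of the
#' above-cutoff relatedness graph over phenotyped individuals, found by
#' iteratively deleting the node with the most remaining edges; ties go
#' to the lexicographically smallest id, making the output deterministic.
#' Greedy max-degree deletion is a standard heuristic for this NP-hard
#' problem; it is exact on stars, paths and disjoint pairs — the shapes
#' relatedness graphs overwhelmingly take at this cutoff.
#'
#' @param pairs Kinship pair tibble.
#' @param phenotyped_ids Ids of individuals with data on the phenotype of
#'   interest.
#' @param cutoff Kinship cutoff; edges are pairs with kinship strictly
#'   above it (default 0.0884).
#' @return Character vector of ids in removal order (empty when no pair
#'   exceeds the cutoff).
#' @export
ukb_samples_to_remove <- function(pairs, phenotyped_ids,
                                  cutoff = 0.0884) {
  stopifnot(is.finite(cutoff))
  ph <- as.character(phenotyped_ids)
  a <- as.character(pairs$id1)
  b <- as.character(pairs$id2)
  keep <- pairs$kinship > cutoff & a %in% ph & b %in% ph
  a <- a[keep]; b <- b[keep]
  removed <- character(0)
  while (length(a)) {
    degree <- table(c(a, b))
    top <- names(degree)[degree == max(degree)]
    victim <- sort(top)[1]
    removed <- c(removed, victim)
    hit <- a == victim | b == victim
    a <- a[!hit]; b <- b[!hit]
  }
  removed
}

#' Read a PLINK .fam file
#'
#' Six whitespace-delimited columns: family id, individual id, paternal
#' and maternal ids, sex (1 = male, 2 = female, 0 = unknown), phenotype.
#' Row order is preserved — it is the genotype sample order.
#'
#' @param path Path to the `.fam` file.
#' @return A tibble `fid`, `iid`, `pid`, `mid`, `sex`, `phenotype`.
#' @export
ukb_read_fam <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fieldn <- vapply(strsplit(trimws(lines), "[ \t]+"), length, 1L)
  if (any(fieldn != 6L)) {
    ukb_format_error(paste0("fam line ", which(fieldn != 6L)[1], " has ",
                            fieldn[fieldn != 6L][1],
                            " fields, expected 6"))
  }
  tab <- utils::read.table(text = lines, header = FALSE,
                           colClasses = c("character", "character",
                                          "character", "character",
                                          "integer", "numeric"))
  names(tab) <- c("fid", "iid", "pid", "mid", "sex", "phenotype")
  if (any(!tab$sex %in% 0:2)) {
    warn("sex values outside the PLINK convention {0, 1, 2}")
  }
  as_tibble(tab)
}

#' Read an Oxford .sample file
#'
#' The dialect has two header lines: the column names, then a type line
#' whose first three entries are `0 0 0` followed by one code per
#' remaining column (`D` discrete, `C` continuous, `B` binary, `P`
#' continuous phenotype). Data columns are typed from the codes; row
#' order is preserved.
#'
#' @param path Path to the `.sample` file.
#' @return A tibble with the file's columns; attribute `"types"` holds
#'   the type-code line.
#' @export
ukb_read_sample <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) ukb_format_error("sample file has no type line")
  header <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  typeln <- strsplit(trimws(lines[2]), "[ \t]+")[[1]]
  if (length(typeln) != length(header)) {
    ukb_format_error(paste0("sample header has ", length(header),
                            " columns but the type line has ",
                            length(typeln)))
  }
  if (!identical(typeln[1:min(3, length(typeln))],
                 rep("0", min(3, length(typeln))))) {
    ukb_format_error("sample type line must begin '0 0 0'")
  }
  extra <- typeln[-(1:3)]
  if (length(extra) && any(!extra %in% c("D", "C", "B", "P"))) {
    ukb_format_error(paste0("unknown sample type code(s): ",
                            paste(setdiff(extra, c("D", "C", "B", "P")),
                                  collapse = ", ")))
  }
  classes <- c("character", "character", "numeric",
               ifelse(extra %in% c("C", "P"), "numeric", "integer"))
  if (length(lines) > 2) {
    tab <- utils::read.table(text = lines[-(1:2)], header = FALSE,
                             colClasses = classes)
  } else {
    tab <- as.data.frame(setNames(
      lapply(classes, function(cl) vector(cl, 0)), header))
  }
  names(tab) <- header
  out <- as_tibble(tab)
  attr(out, "types") <- typeln
  out
}

#' Write PLINK or BGENIE phenotype, covariate and exclusion files
#'
#' Prepares association-analysis inputs from an assembled dataset:
#'
#' * `plink_pheno` / `plink_covar`: whitespace-delimited, header
#'   `FID IID` then the variables, one row per individual present in
#'   `data`, missing values written as `missing` (default `"NA"`). FID
#'   and IID are both the `eid` (no family structure in the cohort's fam
#'   files).
#' * `plink_exclusions`: two columns `FID IID`, no header — pass the ids
#'   to exclude (e.g. from [ukb_samples_to_remove()]) as `data`.
#' * `bgenie_pheno` / `bgenie_covar`: header of variable names only, one
#'   row per sample in `sample_order` (the order of the genotype files,
#'   from [ukb_read_fam()] or [ukb_read_sample()]); individuals absent
#'   from `data` are written as missing, default `"-999"`, the BGENIE
#'   convention.
#'
#' @param data For the pheno/covar kinds, a tibble with an id column and
#'   the variables; for `plink_exclusions`, a vector of ids (or a tibble
#'   whose id column is used).
#' @param out Output file path.
#' @param kind One of `"plink_pheno"`, `"plink_covar"`,
#'   `"plink_exclusions"`, `"bgenie_pheno"`, `"bgenie_covar"`.
#' @param columns Variable columns to write; default all non-id columns.
#' @param id_col Name of the id column in `data` (default `"eid"`).
#' @param sample_order Vector of sample ids in genotype order; required
#'   for the BGENIE kinds.
#' @param missing Missing-value token; defaults to `"NA"` for PLINK and
#'   `"-999"` for BGENIE.
#' @return The output path, invisibly.
#' @export
ukb_gen_write <- function(data, out,
                          kind = c("plink_pheno", "plink_covar",
                                   "plink_exclusions", "bgenie_pheno",
                                   "bgenie_covar"),
                          columns = NULL, id_col = "eid",
                          sample_order = NULL, missing = NULL) {
  kind <- match.arg(kind)
  bgenie <- grepl("^bgenie", kind)
  if (is.null(missing)) missing <- if (bgenie) "-999" else "NA"

  if (kind == "plink_exclusions") {
    ids <- if (is.data.frame(data)) data[[id_col]] else data
    writeLines(paste(ids, ids), out)
    return(invisible(out))
  }

  if (!is.data.frame(data)) ukb_usage_error("data must be a data frame")
  if (!id_col %in% names(data)) {
    ukb_usage_error(paste0("id column '", id_col, "' not in data"))
  }
  if (is.null(columns)) columns <- setdiff(names(data), id_col)
  bad <- setdiff(columns, names(data))
  if (length(bad)) {
    ukb_usage_error(paste0("unknown column(s): ",
                           paste(bad, collapse = ", ")))
  }

  fmt <- function(x) {
    x <- as.character(x)
    ifelse(is.na(x), missing, x)
  }

  if (bgenie) {
    if (is.null(sample_order)) {
      ukb_usage_error(paste0(kind, " requires sample_order (from a fam ",
                             "or sample file)"))
    }
    idx <- match(as.character(sample_order), as.character(data[[id_col]]))
    body <- vapply(seq_along(idx), function(i) {
      if (is.na(idx[i])) {
        paste(rep(missing, length(columns)), collapse = " ")
      } else {
        paste(vapply(columns, function(cl) fmt(data[[cl]][idx[i]]), ""),
              collapse = " ")
      }
    }, "")
    writeLines(c(paste(columns, collapse = " "), body), out)
  } else {
    id <- as.character(data[[id_col]])
    body <- vapply(seq_along(id), function(i) {
      paste(c(id[i], id[i],
              vapply(columns, function(cl) fmt(data[[cl]][i]), "")),
            collapse = " ")
    }, "")
    writeLines(c(paste(c("FID", "IID", columns), collapse = " "), body),
               out)
  }
  invisible(out)
}
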