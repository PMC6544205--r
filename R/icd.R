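# ICD-9/ICD-10 reference tables and diagnosis queries. Codes are stored
# and matched undotted ("I74", "I251"), as hospital-episode fields store
# them. The chapter tables are complete; the code tables bundled with the
# package are a demonstration subset — use ukb_icd_load_codes() to supply
# a full table (TSV with columns code, description).

icd_env <- new.env(parent = emptyenv())

check_version <- function(version) {
  if (!version %in% c("icd10", "icd9")) {
    ukb_usage_error("version must be \"icd10\" or \"icd9\"")
  }
  version
}

#' ICD chapter reference table
#'
#' The complete chapter ("disease block") table for a revision: e.g.
#' ICD-10 chapter 9, block I00–I99, Diseases of the circulatory system.
#'
#' @param version `"icd10"` (default) or `"icd9"`.
#' @return A tibble with `chapter`, `block_start`, `block_end`,
#'   `description`.
#' @export
ukb_icd_chapters <- function(version = "icd10") {
  check_version(version)
  key <- paste0(version, "_chapters")
  if (is.null(icd_env[[key]])) {
    f <- system.file("extdata", paste0(version, "_chapters.tsv"),
                     package = "ukbkit", mustWork = TRUE)
    icd_env[[key]] <- as_tibble(utils::read.table(
      f, sep = "\t", header = TRUE, quote = "",
      colClasses = c("integer", "character", "character", "character")))
  }
  icd_env[[key]]
}

#' ICD code reference table (bundled demo subset)
#'
#' Diagnosis-specific code descriptions, e.g. I74, Arterial embolism and
#' thrombosis. The bundled table is a small demonstration subset of each
#' revision; load a complete table with [ukb_icd_load_codes()].
#'
#' @param version `"icd10"` (default) or `"icd9"`.
#' @return A tibble with `code` (undotted) and `description`.
#' @export
ukb_icd_codes <- function(version = "icd10") {
  check_version(version)
  key <- paste0(version, "_codes")
  if (is.null(icd_env[[key]])) {
    f <- system.file("extdata", paste0(version, "_codes_demo.tsv"),
                     package = "ukbkit", mustWork = TRUE)
    icd_env[[key]] <- as_tibble(utils::read.table(
      f, sep = "\t", header = TRUE, quote = "",
      colClasses = c("character", "character")))
  }
  icd_env[[key]]
}

#' Load a user-supplied ICD code table
#'
#' Reads a two-column TSV (`code`, `description`; codes undotted) and
#' registers it as the code table for the given revision for the rest of
#' the session, replacing the bundled demo subset.
#'
#' @param path TSV file path.
#' @param version `"icd10"` or `"icd9"`.
#' @return The loaded tibble, invisibly.
#' @export
ukb_icd_load_codes <- function(path, version = "icd10") {
  check_version(version)
  tab <- as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                     quote = "", colClasses = "character"))
  if (!all(c("code", "description") %in% names(tab))) {
    ukb_format_error("code table needs columns 'code' and 'description'")
  }
  if (anyDuplicated(tab$code)) {
    ukb_integrity_error("duplicate codes in supplied table")
  }
  icd_env[[paste0(version, "_codes")]] <- tab[c("code", "description")]
  invisible(icd_env[[paste0(version, "_codes")]])
}

# Internal: is a code string well-formed for its revision?
icd_well_formed <- function(code, version) {
  if (version == "icd10") grepl("^[A-Z][0-9]{2}[0-9A-Z]{0,2}$", code)
  else grepl("^([0-9]{3,5}|[VE][0-9]{2,4})$", code)
}

# Internal: sortable numeric key of a code's 3-character category
# (letter then two-digit number for ICD-10; leading three digits for
# ICD-9). Used for chapter containment and code ordering.
icd_category_key <- function(code, version) {
  if (version == "icd10") {
    match(substr(code, 1, 1), LETTERS) * 100L +
      as.integer(substr(code, 2, 3))
  } else {
    suppressWarnings(as.integer(substr(code, 1, 3)))
  }
}

#' Retrieve the full description of an ICD code
#'
#' Exact-match lookup of an undotted code against the loaded code table.
#' An unknown code yields `NA` with a warning that distinguishes a
#' malformed code from one merely absent from the loaded (demo) subset.
#'
#' @param code Character vector of undotted codes, e.g. `"I74"`.
#' @param version `"icd10"` (default) or `"icd9"`.
#' @param codes Optional code table overriding the loaded one.
#' @return Character vector of descriptions (`NA` where not found).
#' @examples
#' ukb_icd_meaning("I74")
#' @export
ukb_icd_meaning <- function(code, version = "icd10", codes = NULL) {
  check_version(version)
  if (is.null(codes)) codes <- ukb_icd_codes(version)
  out <- codes$description[match(code, codes$code)]
  miss <- is.na(out)
  if (any(miss)) {
    bad <- !icd_well_formed(code[miss], version)
    if (any(bad)) {
      warn(paste0("malformed ", version, " code(s): ",
                  paste(code[miss][bad], collapse = ", ")))
    }
    if (any(!bad)) {
      warn(paste0("code(s) absent from the loaded ", version,
                  " table (bundled table is a demo subset): ",
                  paste(code[miss][!bad], collapse = ", ")))
    }
  }
  out
}

#' Find ICD codes whose descriptions match a keyword
#'
#' Case-insensitive regular-expression search over code descriptions,
#' e.g. `"cardio"`. Results are ordered by code.
#'
#' @param pattern A regular expression.
#' @param version `"icd10"` (default) or `"icd9"`.
#' @param codes Optional code table overriding the loaded one.
#' @return A tibble of matching `code`, `description` rows.
#' @export
ukb_icd_keyword <- function(pattern, version = "icd10", codes = NULL) {
  check_version(version)
  if (is.null(codes)) codes <- ukb_icd_codes(version)
  hit <- tryCatch(
    suppressWarnings(grepl(pattern, codes$description, ignore.case = TRUE,
                           perl = TRUE)),
    error = function(e) {
      ukb_usage_error(paste0("invalid regular expression '", pattern,
                             "': ", conditionMessage(e)))
    })
  out <- codes[hit, ]
  out[order(out$code), ]
}

#' Resolve the chapter (disease block) of an ICD code
#'
#' Finds the chapter whose block contains the code's three-character
#' category, bounds inclusive: for ICD-10, `"I74"` (and any `I74x`
#' subcode) falls in chapter 9, block I00–I99, Diseases of the
#' circulatory system.
#'
#' @param code Character vector of undotted codes.
#' @param version `"icd10"` (default) or `"icd9"`.
#' @return A tibble with one row per input code (`code`, `chapter`,
#'   `block_start`, `block_end`, `description`); codes outside every block
#'   get `NA` fields.
#' @export
ukb_icd_chapter <- function(code, version = "icd10") {
  check_version(version)
  ch <- ukb_icd_chapters(version)
  lo <- icd_category_key(ch$block_start, version)
  hi <- icd_category_key(ch$block_end, version)
  key <- icd_category_key(code, version)
  idx <- vapply(key, function(k) {
    if (is.na(k)) return(NA_integer_)
    w <- which(k >= lo & k <= hi)
    if (length(w)) w[1] else NA_integer_
  }, 1L)
  tibble(code = code,
         chapter = ch$chapter[idx],
         block_start = ch$block_start[idx],
         block_end = ch$block_end[idx],
         description = ch$description[idx])
}

# Internal: diagnosis columns of a dataset for a revision — name-based
# discovery ("icd10"/"icd9" in the descriptive column name), overridable.
icd_columns <- function(data, version, columns = NULL) {
  if (!is.null(columns)) {
    missing <- setdiff(columns, names(data))
    if (length(missing)) {
      ukb_usage_error(paste0("diagnosis column(s) not in dataset: ",
                             paste(missing, collapse = ", ")))
    }
    return(columns)
  }
  hits <- grep(version, names(data), value = TRUE)
  if (version == "icd9") hits <- setdiff(hits, grep("icd10", names(data), value = TRUE))
  if (!length(hits)) {
    ukb_usage_error(paste0("no ", version, " diagnosis columns found; ",
                           "pass columns = explicitly"))
  }
  hits
}

#' Retrieve the ICD diagnoses of one or more individuals
#'
#' Collects all non-missing codes across the diagnosis array columns,
#' deduplicated per individual, and joins their descriptions. Useful to
#' explain why an individual is an outlier in an analysis.
#'
#' @param data Dataset from [ukb_dataset()] (or any tibble with an `eid`
#'   column and diagnosis columns).
#' @param ids Individual identifiers to query.
#' @param version `"icd10"` (default) or `"icd9"`.
#' @param columns Optional explicit diagnosis column names; by default
#'   columns whose names contain the version string are used.
#' @return A tibble with `eid`, `code`, `description` and `status`
#'   (`"ok"`, `"no_diagnoses"` or `"id_not_found"`); individuals without
#'   diagnoses and unknown ids keep one marker row each.
#' @export
ukb_icd_diagnosis <- function(data, ids, version = "icd10",
                              columns = NULL) {
  cols <- icd_columns(data, version, columns)
  codes <- ukb_icd_codes(version)
  out <- lapply(ids, function(id) {
    row <- which(data$eid == id)
    if (!length(row)) {
      return(tibble(eid = id, code = NA_character_,
                    description = NA_character_, status = "id_not_found"))
    }
    vals <- unique(stats::na.omit(unlist(
      lapply(cols, function(cl) as.character(data[[cl]][row])))))
    if (!length(vals)) {
      return(tibble(eid = id, code = NA_character_,
                    description = NA_character_, status = "no_diagnoses"))
    }
    desc <- codes$description[match(vals, codes$code)]
    if (anyNA(desc)) {
      warn(paste0("code(s) without a description in the loaded table: ",
                  paste(vals[is.na(desc)], collapse = ", ")))
    }
    tibble(eid = id, code = vals, description = desc, status = "ok")
  })
  dplyr::bind_rows(out)
}

#' Prevalence of an ICD diagnosis in a dataset
#'
#' Fraction of all individuals in the dataset carrying at least one
#' diagnosis code matching the pattern; an individual counts once however
#' many codes match. The denominator is every row of the dataset, not
#' only individuals with hospital records.
#'
#' @param data Dataset with diagnosis columns.
#' @param pattern Regular expression matched against undotted codes, e.g.
#'   `"^I74"`.
#' @param version,columns See [ukb_icd_diagnosis()].
#' @return A single frequency in `[0, 1]`.
#' @export
ukb_icd_prevalence <- function(data, pattern, version = "icd10",
                               columns = NULL) {
  cols <- icd_columns(data, version, columns)
  tryCatch(suppressWarnings(grepl(pattern, "", perl = TRUE)),
           error = function(e) {
    ukb_usage_error(paste0("invalid regular expression '", pattern, "'"))
  })
  hit <- rep(FALSE, nrow(data))
  for (cl in cols) {
    v <- as.character(data[[cl]])
    hit <- hit | (!is.na(v) & grepl(pattern, v, perl = TRUE))
  }
  sum(hit) / nrow(data)
}

#' Split a numeric vector into approximately equal-sized groups
#'
#' Rank-based grouping: the non-missing values are ordered (ties broken
#' by stable original position) and split into `n_groups` groups whose
#' sizes differ by at most one. Group labels carry the value range each
#' group spans. Missing values get `NA`.
#'
#' @param values Numeric vector, may contain `NA`.
#' @param n_groups Number of groups (default 10).
#' @return An ordered factor of length `length(values)` whose levels are
#'   `"g<k>: [lo, hi]"`.
#' @export
ukb_quantile_groups <- function(values, n_groups = 10L) {
  if (n_groups < 2) ukb_usage_error("n_groups must be at least 2")
  ok <- which(!is.na(values))
  if (length(ok) < n_groups) {
    ukb_usage_error(paste0("need at least n_groups = ", n_groups,
                           " non-missing values, have ", length(ok)))
  }
  ord <- ok[order(values[ok])]          # order() is stable: ties keep
  n <- length(ord)                      # original row order
  grp_sorted <- ceiling(seq_len(n) * n_groups / n)
  grp <- rep(NA_integer_, length(values))
  grp[ord] <- grp_sorted
  labs <- vapply(seq_len(n_groups), function(g) {
    v <- values[ord][grp_sorted == g]
    sprintf("g%d: [%g, %g]", g, min(v), max(v))
  }, "")
  factor(labs[grp], levels = labs, ordered = TRUE)
}

#' Default disease patterns: WHO 2015 top three causes of death
#'
#' Regular expressions over undotted ICD-10 codes for coronary artery
#' disease, cerebrovascular disease and lower respiratory tract
#' infection.
#'
#' @return A named character vector of three patterns.
#' @export
ukb_who_top3 <- function() {
  c(coronary_artery_disease = "^(I2[0-5])",
    cerebrovascular_disease = "^(I6[0-9])",
    lower_respiratory_tract_infection = "^(J09|J1[0-9]|J2[0-2]|P23|U04)")
}

#' Frequency of ICD diagnoses by levels of a reference variable
#'
#' For each level of a categorical reference variable — or each of
#' `n_groups` approximately equal-sized groups of a continuous one (see
#' [ukb_quantile_groups()]) — computes the fraction of the group's
#' individuals carrying at least one code matching each pattern.
#' Individuals missing the reference variable are excluded.
#'
#' @param data Dataset with diagnosis columns.
#' @param reference_var Column name of the reference variable.
#' @param patterns Named character vector of diagnosis regexes; default
#'   [ukb_who_top3()].
#' @param n_groups Group count for a continuous reference (default 10).
#' @param version,columns See [ukb_icd_diagnosis()].
#' @param plot If `TRUE`, attach a ggplot of frequency by group as the
#'   `"plot"` attribute of the result.
#' @return A tibble with `group`, `group_n`, `dx` (pattern name),
#'   `pattern`, `n_with_diagnosis`, `frequency`; one row per group ×
#'   pattern, groups with no matching individuals retained at frequency
#'   zero.
#' @export
ukb_icd_freq_by <- function(data, reference_var,
                            patterns = ukb_who_top3(), n_groups = 10L,
                            version = "icd10", columns = NULL,
                            plot = FALSE) {
  if (!reference_var %in% names(data)) {
    ukb_usage_error(paste0("reference variable '", reference_var,
                           "' not in dataset"))
  }
  cols <- icd_columns(data, version, columns)
  if (is.null(names(patterns)) || any(!nzchar(names(patterns)))) {
    names(patterns) <- paste0("dx", seq_along(patterns))
  }

  ref <- data[[reference_var]]
  if (is.numeric(ref)) {
    grp <- ukb_quantile_groups(ref, n_groups)
  } else {
    grp <- factor(as.character(ref),
                  levels = if (is.factor(ref)) levels(ref) else
                    sort(unique(as.character(stats::na.omit(ref)))))
  }

  match_mat <- vapply(patterns, function(p) {
    tryCatch(suppressWarnings(grepl(p, "", perl = TRUE)),
             error = function(e) {
      ukb_usage_error(paste0("invalid regular expression '", p, "'"))
    })
    hit <- rep(FALSE, nrow(data))
    for (cl in cols) {
      v <- as.character(data[[cl]])
      hit <- hit | (!is.na(v) & grepl(p, v, perl = TRUE))
    }
    hit
  }, logical(nrow(data)))
  if (!is.matrix(match_mat)) {
    match_mat <- matrix(match_mat, nrow = nrow(data),
                        dimnames = list(NULL, names(patterns)))
  }

  keep <- !is.na(grp)
  res <- lapply(levels(grp), function(g) {
    in_g <- keep & grp == g
    n_dx <- unname(colSums(match_mat[in_g, , drop = FALSE]))
    tibble(group = g, group_n = sum(in_g), dx = names(patterns),
           pattern = unname(patterns),
           n_with_diagnosis = as.integer(n_dx),
           frequency = if (sum(in_g) > 0) n_dx / sum(in_g) else 0)
  })
  out <- dplyr::bind_rows(res)
  if (plot) {
    p <- ggplot2::ggplot(out, ggplot2::aes(
      x = .data$group, y = .data$frequency, fill = .data$dx,
      group = .data$dx)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = reference_var, y = "diagnosis frequency",
                    fill = NULL) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
    attr(out, "plot") <- p
  }
  out
}
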