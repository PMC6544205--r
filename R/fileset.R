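#' Contract a variable description to a snake_case column name
#'
#' Column names in an assembled dataset are a contraction to snake_case of
#' the full-length variable description from the data dictionary, with all
#' punctuation and special characters removed, followed by a numeric suffix
#' `_f<field>_<index>_<array>`. The index captures the assessment instance
#' (repeat visit), the array the response slot.
#'
#' Every maximal run of non-alphanumeric characters in the description
#' becomes a single underscore; leading/trailing underscores are stripped;
#' the result is lower case. The transformation is idempotent on its own
#' output stem and, because the field/index/array suffix is unique within a
#' fileset, contracted names never collide.
#'
#' @param description Character vector of variable descriptions.
#' @param field_id Integer vector of showcase field codes.
#' @param instance_index,array_index Non-negative integer vectors (recycled
#'   if length 1).
#' @return Character vector of column names, e.g.
#'   `"body_mass_index_bmi_f21001_0_0"`.
#' @examples
#' ukb_contract_name("Body mass index (BMI)", 21001, 0, 0)
#' @export
ukb_contract_name <- function(description, field_id,
                              instance_index = 0L, array_index = 0L) {
  if (any(!nzchar(description) | is.na(description))) {
    ukb_format_error(paste0(
      "empty description for field ",
      paste(field_id[!nzchar(description) | is.na(description)],
            collapse = ", ")))
  }
  if (any(instance_index < 0) || any(array_index < 0)) {
    ukb_usage_error("instance and array indices must be non-negative")
  }
  stem <- tolower(enc2utf8(description))
  stem <- gsub("[^a-z0-9]+", "_", stem, perl = TRUE)
  stem <- gsub("^_+|_+$", "", stem)
  if (any(!nzchar(stem))) {
    ukb_format_error(paste0(
      "description contracts to an empty name for field ",
      paste(field_id[!nzchar(stem)], collapse = ", ")))
  }
  paste0(stem, "_f", field_id, "_", instance_index, "_", array_index)
}

#' Default mapping from dictionary "Type" strings to internal value types
#'
#' The HTML data dictionary describes each variable with a display type
#' string. This table maps those strings onto the internal type vocabulary
#' (`integer`, `continuous`, `categorical_single`, `categorical_multiple`,
#' `text`, `date`). Unknown strings fall back to `text` with a warning at
#' parse time.
#'
#' @param extra Named character vector of additional or overriding entries,
#'   names being dictionary strings and values internal types.
#' @param file Optional path to a two-column TSV (`type`, `value_type`)
#'   extending the mapping.
#' @return Named character vector.
#' @export
ukb_type_map <- function(extra = NULL, file = NULL) {
  map <- c(
    "Sequence"               = "integer",
    "Integer"                = "integer",
    "Continuous"             = "continuous",
    "Categorical (single)"   = "categorical_single",
    "Categorical (multiple)" = "categorical_multiple",
    "Text"                   = "text",
    "Date"                   = "date",
    "Time"                   = "date",
    "Compound"               = "text"
  )
  if (!is.null(file)) {
    ext <- utils::read.table(file, sep = "\t", header = TRUE,
                             colClasses = "character")
    map[ext[[1]]] <- ext[[2]]
  }
  if (!is.null(extra)) map[names(extra)] <- extra
  map
}

# Internal: the raw .tab header token for a descriptor row.
tab_token <- function(field_id, instance_index, array_index) {
  paste0("f.", field_id, ".", instance_index, ".", array_index)
}

#' Parse the HTML data dictionary of a fileset
#'
#' Locates the dictionary table (header cells include `UDI`, `Type`,
#' `Description`), and returns one descriptor row per variable. The `eid`
#' identifier row is recognised and excluded from the variable descriptors
#' (recorded in the `"identifier"` attribute of the result).
#'
#' @param path Path to the `.html` dictionary file (or anything
#'   [xml2::read_html()] accepts).
#' @param type_map Mapping from dictionary Type strings to internal value
#'   types, see [ukb_type_map()].
#' @return A tibble with columns `field_id`, `instance_index`,
#'   `array_index`, `description`, `value_type`, `coding_id` (all `NA`
#'   here; filled in by [ukb_dataset()] from the coding script), `raw_udi`
#'   and `column_name`.
#' @export
ukb_parse_dictionary <- function(path, type_map = ukb_type_map()) {
  doc <- xml2::read_html(path)
  tables <- xml2::xml_find_all(doc, ".//table")
  dict_rows <- NULL
  header <- NULL
  for (tb in tables) {
    rows <- xml2::xml_find_all(tb, ".//tr")
    if (length(rows) < 1) next
    hdr <- trimws(xml2::xml_text(xml2::xml_find_all(rows[[1]],
                                                    ".//th | .//td")))
    if (all(c("UDI", "Type", "Description") %in% hdr)) {
      dict_rows <- rows[-1]
      header <- hdr
      break
    }
  }
  if (is.null(dict_rows)) {
    ukb_format_error(
      "no data-dictionary table with UDI/Type/Description columns found")
  }
  i_udi <- match("UDI", header)
  i_type <- match("Type", header)
  i_desc <- match("Description", header)

  udis <- character(0); types <- character(0); descs <- character(0)
  has_eid <- FALSE
  for (r in dict_rows) {
    cells <- trimws(xml2::xml_text(xml2::xml_find_all(r, ".//th | .//td")))
    if (length(cells) < max(i_udi, i_type, i_desc)) next
    if (identical(cells[i_udi], "eid")) {
      has_eid <- TRUE
      next
    }
    udis <- c(udis, cells[i_udi])
    types <- c(types, cells[i_type])
    descs <- c(descs, cells[i_desc])
  }

  m <- regmatches(udis, regexec("^([0-9]+)-([0-9]+)\\.([0-9]+)$", udis))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    ukb_format_error(paste0("unparsable UDI in dictionary: ",
                            paste(udis[bad], collapse = ", ")))
  }
  field <- vapply(m, function(x) as.integer(x[2]), 1L)
  inst <- vapply(m, function(x) as.integer(x[3]), 1L)
  arr <- vapply(m, function(x) as.integer(x[4]), 1L)

  vt <- unname(type_map[types])
  unknown <- is.na(vt)
  if (any(unknown)) {
    warn(paste0("unknown dictionary Type string(s) mapped to 'text': ",
                paste(unique(types[unknown]), collapse = ", ")))
    vt[unknown] <- "text"
  }

  out <- tibble(
    field_id = field,
    instance_index = inst,
    array_index = arr,
    description = descs,
    value_type = vt,
    coding_id = NA_integer_,
    raw_udi = udis,
    column_name = ukb_contract_name(descs, field, inst, arr)
  )
  if (anyDuplicated(out[c("field_id", "instance_index", "array_index")])) {
    ukb_integrity_error("duplicate (field, instance, array) in dictionary")
  }
  attr(out, "identifier") <- if (has_eid) "eid" else NA_character_
  out
}

# Internal: scan s from the "(" at position `start` to its matching ")",
# honouring single/double quotes and backslash escapes. Returns the index
# of the closing paren, or NA if unbalanced.
match_paren <- function(s, start) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  quote <- ""
  i <- start
  while (i <= length(chars)) {
    ch <- chars[i]
    if (nzchar(quote)) {
      if (ch == "\\") i <- i + 1L
      else if (ch == quote) quote <- ""
    } else if (ch == "'" || ch == "\"") {
      quote <- ch
    } else if (ch == "(") {
      depth <- depth + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth == 0L) return(i)
    }
    i <- i + 1L
  }
  NA_integer_
}

# Internal: split the argument list of a c(...) call into unquoted tokens.
# Commas inside quotes do not split; \" and \' and \\ are unescaped.
split_c_args <- function(inner) {
  chars <- strsplit(inner, "", fixed = TRUE)[[1]]
  if (length(chars) == 0) return(character(0))
  toks <- character(0)
  cur <- character(0)
  quote <- ""
  depth <- 0L
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (nzchar(quote)) {
      if (ch == "\\" && i < length(chars)) {
        cur <- c(cur, chars[i + 1L])
        i <- i + 2L
        next
      }
      if (ch == quote) quote <- "" else cur <- c(cur, ch)
    } else if (ch == "'" || ch == "\"") {
      quote <- ch
    } else if (ch == "(") {
      depth <- depth + 1L
      cur <- c(cur, ch)
    } else if (ch == ")") {
      depth <- depth - 1L
      cur <- c(cur, ch)
    } else if (ch == "," && depth == 0L) {
      toks <- c(toks, paste(cur, collapse = ""))
      cur <- character(0)
    } else {
      cur <- c(cur, ch)
    }
    i <- i + 1L
  }
  toks <- c(toks, paste(cur, collapse = ""))
  trimws(toks)
}

#' Parse the categorical-coding script of a fileset
#'
#' The `.r` member of a fileset declares, for each data coding, a pair of
#' vectors `lvl.<id> <- c(...)` (raw stored values) and `lbl.<id> <- c(...)`
#' (category labels), and binds raw columns `f.<field>.<index>.<array>` to
#' a coding id in `factor()`/`ordered()` assignment statements. The script
#' is parsed textually — it is never executed, because running arbitrary
#' code shipped inside a data bundle would be unsafe. Quoted labels may
#' contain commas, parentheses and escaped quotes.
#'
#' @param text The script as a single string or a character vector of
#'   lines; or a file path (detected when `text` is a length-1 string that
#'   names an existing file with no newline).
#' @return A list with elements `codings` (named list; each entry has
#'   `coding_id`, `levels`, `labels`, `is_ordered`) and `assignments`
#'   (tibble with `column` — the raw `f.` token — and `coding_id`).
#' @export
ukb_parse_codings <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  script <- paste(text, collapse = "\n")

  decls <- list()
  pat <- "(lvl|lbl)\\.([0-9]+)\\s*<-\\s*c\\("
  m <- gregexpr(pat, script, perl = TRUE)[[1]]
  if (m[1] != -1) {
    for (k in seq_along(m)) {
      frag <- substr(script, m[k], m[k] + attr(m, "match.length")[k] - 1L)
      kind <- sub(pat, "\\1", frag, perl = TRUE)
      id <- sub(pat, "\\2", frag, perl = TRUE)
      open <- m[k] + attr(m, "match.length")[k] - 1L
      close <- match_paren(script, open)
      if (is.na(close)) {
        ukb_format_error(paste0("unbalanced parentheses in ", kind, ".", id,
                                " declaration"))
      }
      inner <- substr(script, open + 1L, close - 1L)
      key <- id
      if (is.null(decls[[key]])) decls[[key]] <- list()
      decls[[key]][[kind]] <- split_c_args(inner)
    }
  }

  codings <- list()
  for (id in names(decls)) {
    lv <- decls[[id]][["lvl"]]
    lb <- decls[[id]][["lbl"]]
    if (is.null(lv) || is.null(lb) || length(lv) != length(lb)) {
      ukb_format_error(paste0(
        "coding ", id, ": level/label mismatch (",
        length(lv), " levels, ", length(lb), " labels)"))
    }
    if (anyDuplicated(lv)) {
      ukb_integrity_error(paste0("coding ", id, ": duplicate raw values"))
    }
    codings[[id]] <- list(coding_id = as.integer(id), levels = lv,
                          labels = lb, is_ordered = NA)
  }

  lines <- strsplit(script, "\n", fixed = TRUE)[[1]]
  cols <- character(0); ids <- integer(0); ord <- logical(0)
  for (ln in lines) {
    if (!grepl("lvl\\.[0-9]+", ln)) next
    colm <- regmatches(ln, regexpr("f\\.[0-9]+\\.[0-9]+\\.[0-9]+", ln))
    if (length(colm) == 0) next
    id <- sub(".*lvl\\.([0-9]+).*", "\\1", ln)
    if (is.null(codings[[id]])) {
      ukb_format_error(paste0(
        "column assignment references undeclared coding ", id))
    }
    cols <- c(cols, colm)
    ids <- c(ids, as.integer(id))
    ord <- c(ord, grepl("ordered\\(", ln))
    codings[[id]]$is_ordered <- grepl("ordered\\(", ln)
  }

  list(codings = codings,
       assignments = tibble(column = cols, coding_id = ids,
                            is_ordered = ord))
}

#' Read the tab-delimited data table of a fileset
#'
#' Reads `<stem>.tab` (header `f.eid` plus `f.<field>.<index>.<array>`
#' tokens) in chunks, typing each column from its dictionary descriptor.
#' The result is identical for any chunk size. Header columns without a
#' descriptor are retained as text with a warning. Values equal to
#' `missing_token` become `NA`.
#'
#' @param path Path to the `.tab` file.
#' @param fields Descriptor tibble from [ukb_parse_dictionary()], or `NULL`
#'   to read every non-eid column as text.
#' @param chunk_size Rows per read chunk (default 10000).
#' @param missing_token Missing-value token in the file (default `"NA"`).
#' @return A tibble with the file's raw column names; `f.eid` checked
#'   present, unique and non-missing.
#' @export
ukb_read_tab <- function(path, fields = NULL, chunk_size = 10000L,
                         missing_token = "NA") {
  if (!file.exists(path)) {
    ukb_format_error(paste0("file not found: ", path))
  }
  header <- strsplit(readLines(path, n = 1L, warn = FALSE), "\t",
                     fixed = TRUE)[[1]]
  if (!"f.eid" %in% header) {
    ukb_format_error(paste0("no f.eid column in ", path))
  }

  type_of <- rep("character", length(header))
  names(type_of) <- header
  type_of["f.eid"] <- "integer"
  unknown <- character(0)
  if (!is.null(fields)) {
    tokens <- tab_token(fields$field_id, fields$instance_index,
                        fields$array_index)
    class_for <- c(integer = "integer", continuous = "numeric",
                   categorical_single = "character",
                   categorical_multiple = "character",
                   text = "character", date = "character")
    for (j in seq_along(header)) {
      if (header[j] == "f.eid") next
      k <- match(header[j], tokens)
      if (is.na(k)) {
        unknown <- c(unknown, header[j])
      } else {
        type_of[j] <- class_for[[fields$value_type[k]]]
      }
    }
    if (length(unknown)) {
      warn(paste0("columns without a dictionary entry kept as text: ",
                  paste(unknown, collapse = ", ")))
    }
  }

  n_data <- nrow(data.table::fread(path, sep = "\t", select = 1L,
                                   header = TRUE, showProgress = FALSE))
  chunk_size <- max(1L, as.integer(chunk_size))
  parts <- list()
  skip <- 1L
  while (skip <= n_data) {
    nr <- min(chunk_size, n_data - skip + 1L)
    parts[[length(parts) + 1L]] <- data.table::fread(
      path, sep = "\t", header = FALSE, skip = skip, nrows = nr,
      na.strings = missing_token, colClasses = unname(type_of),
      col.names = header, showProgress = FALSE)
    skip <- skip + nr
  }
  if (length(parts)) {
    dt <- data.table::rbindlist(parts)
  } else {
    dt <- data.table::fread(path, sep = "\t", header = TRUE, nrows = 0L,
                            colClasses = unname(type_of),
                            showProgress = FALSE)
    data.table::setnames(dt, header)
  }
  out <- as_tibble(dt)

  if (anyNA(out[["f.eid"]])) {
    ukb_integrity_error("missing values in f.eid")
  }
  if (anyDuplicated(out[["f.eid"]])) {
    ukb_integrity_error(paste0(
      "duplicate eid values in ", path, ": ",
      paste(head(unique(out[["f.eid"]][duplicated(out[["f.eid"]])]), 5),
            collapse = ", ")))
  }

  if (!is.null(fields)) {
    date_tokens <- tab_token(fields$field_id, fields$instance_index,
                             fields$array_index)[fields$value_type == "date"]
    for (tok in intersect(date_tokens, names(out))) {
      out[[tok]] <- as.Date(out[[tok]])
    }
  }
  out
}

#' Assemble an analysis-ready dataset from a fileset
#'
#' The main entry point: given the stem of a fileset (`<stem>.tab`,
#' `<stem>.r`, `<stem>.html` under `path`), parses the dictionary and
#' coding script, reads the data table, renames every column to its
#' descriptive snake_case name (see [ukb_contract_name()]), and replaces
#' coded categorical values by their labels. Values absent from a coding
#' map are retained unchanged with a warning. The individual identifier is
#' returned in column `eid`.
#'
#' @param stem Fileset stem, e.g. `"ukbxxxx"`.
#' @param path Directory holding the three files (default `"."`).
#' @param chunk_size,missing_token Passed to [ukb_read_tab()].
#' @return A tibble, rows = individuals, columns = variables. Attributes:
#'   `ukb_fields` (the descriptor table, see [ukb_field_lookup()]) and
#'   `ukb_stem`.
#' @examples
#' \donttest{
#' sim <- ukb_sim_fileset(out_dir = tempdir(), seed = 1)
#' d <- ukb_dataset(sim$stem, path = tempdir())
#' names(d)
#' }
#' @export
ukb_dataset <- function(stem, path = ".", chunk_size = 10000L,
                        missing_token = "NA") {
  members <- file.path(path, paste0(stem, c(".tab", ".r", ".html")))
  missing <- members[!file.exists(members)]
  if (length(missing)) {
    ukb_format_error(paste0("fileset member(s) not found: ",
                            paste(missing, collapse = ", ")))
  }

  fields <- ukb_parse_dictionary(members[3])
  cod <- ukb_parse_codings(readLines(members[2], warn = FALSE))
  tokens <- tab_token(fields$field_id, fields$instance_index,
                      fields$array_index)
  fields$coding_id[match(cod$assignments$column, tokens)] <-
    cod$assignments$coding_id

  raw <- ukb_read_tab(members[1], fields, chunk_size = chunk_size,
                      missing_token = missing_token)

  new_names <- names(raw)
  new_names[new_names == "f.eid"] <- "eid"
  hit <- match(names(raw), tokens)
  new_names[!is.na(hit)] <- fields$column_name[hit[!is.na(hit)]]
  names(raw) <- new_names

  for (i in seq_len(nrow(cod$assignments))) {
    tok <- cod$assignments$column[i]
    k <- match(tok, tokens)
    if (is.na(k)) next
    colname <- fields$column_name[k]
    if (!colname %in% names(raw)) next
    cmap <- cod$codings[[as.character(cod$assignments$coding_id[i])]]
    vals <- as.character(raw[[colname]])
    idx <- match(vals, cmap$levels)
    stray <- !is.na(vals) & is.na(idx)
    if (any(stray)) {
      warn(paste0("column ", colname, ": value(s) not in coding ",
                  cmap$coding_id, " kept unlabelled: ",
                  paste(unique(vals[stray]), collapse = ", ")))
    }
    mapped <- ifelse(stray, vals, cmap$labels[idx])
    lev <- unique(c(cmap$labels, unique(vals[stray])))
    raw[[colname]] <- factor(mapped, levels = lev,
                             ordered = isTRUE(cmap$is_ordered))
  }

  attr(raw, "ukb_fields") <- fields
  attr(raw, "ukb_stem") <- stem
  raw
}

#' Field code to column name lookup table
#'
#' Returns one row per variable of a dataset (or of a fileset's
#' dictionary), supporting lookup in both directions: by showcase field
#' code or by descriptive column name. Looking up an absent field or
#' column gives an empty table, not an error.
#'
#' @param x Either a dataset returned by [ukb_dataset()] (its descriptor
#'   attribute is used) or a fileset stem (the `.html` dictionary under
#'   `path` is parsed).
#' @param path Directory for the fileset when `x` is a stem.
#' @param field Optional field code(s) to filter on.
#' @param column Optional column name(s) to filter on.
#' @return A tibble with `column_name`, `description`, `raw_udi`,
#'   `field_id`, `instance_index`, `array_index`, `value_type`,
#'   `coding_id`.
#' @export
ukb_field_lookup <- function(x, path = ".", field = NULL, column = NULL) {
  if (is.character(x) && length(x) == 1) {
    fields <- ukb_parse_dictionary(file.path(path, paste0(x, ".html")))
  } else if (is.data.frame(x)) {
    fields <- attr(x, "ukb_fields")
    if (is.null(fields)) {
      ukb_usage_error(
        "dataset carries no field descriptors; pass a fileset stem instead")
    }
  } else {
    ukb_usage_error("x must be a dataset or a fileset stem")
  }
  out <- fields[c("column_name", "description", "raw_udi", "field_id",
                  "instance_index", "array_index", "value_type",
                  "coding_id")]
  if (!is.null(field)) out <- out[out$field_id %in% field, ]
  if (!is.null(column)) out <- out[out$column_name %in% column, ]
  out
}

#' Merge several assembled datasets on eid
#'
#' Full outer join of two or more datasets on the `eid` identifier: the
#' result has one row per eid in the union, with missing values where an
#' individual is absent from an input. When a non-eid column name occurs
#' in more than one input, the first occurrence keeps its name and later
#' duplicates are suffixed with their provenance stem (a warning reports
#' each collision).
#'
#' @param ... Datasets (tibbles with an `eid` column), or a single list of
#'   them.
#' @param stems Optional character vector of provenance stems, one per
#'   dataset; defaults to each dataset's `ukb_stem` attribute, else
#'   `"ds<i>"`.
#' @return A tibble with the union of rows and columns.
#' @export
ukb_merge <- function(..., stems = NULL) {
  datasets <- list(...)
  if (length(datasets) == 1 && is.list(datasets[[1]]) &&
      !is.data.frame(datasets[[1]])) {
    datasets <- datasets[[1]]
  }
  if (length(datasets) < 1) ukb_usage_error("no datasets to merge")
  if (is.null(stems)) {
    stems <- vapply(seq_along(datasets), function(i) {
      s <- attr(datasets[[i]], "ukb_stem")
      if (is.null(s)) paste0("ds", i) else s
    }, character(1))
  }
  for (d in datasets) {
    if (!"eid" %in% names(d)) ukb_usage_error("every dataset needs an eid column")
    if (anyDuplicated(d$eid)) ukb_integrity_error("duplicate eid in an input dataset")
  }
  out <- datasets[[1]]
  for (i in seq_along(datasets)[-1]) {
    d <- datasets[[i]]
    dup <- setdiff(intersect(names(out), names(d)), "eid")
    if (length(dup)) {
      warn(paste0("column name collision(s) suffixed with '_", stems[i],
                  "': ", paste(dup, collapse = ", ")))
      names(d)[match(dup, names(d))] <- paste0(dup, "_", stems[i])
    }
    out <- dplyr::full_join(out, d, by = "eid")
  }
  as_tibble(out)
}
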