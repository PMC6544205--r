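#' Demographic context of a subset against a reference group
#'
#' Summarises the distribution of primary demographic variables for a
#' subset of individuals (e.g. those meeting an inclusion criterion, or
#' with data on a variable of interest) relative to the rest of the
#' dataset, as tidy count tables — one cross-tabulation per categorical
#' variable and one shared-bin histogram per continuous variable. A quick
#' check of how representative a subset is.
#'
#' The default variable set is resolved by showcase field code from the
#' dataset's descriptor attribute, instance 0, when present: sex (31),
#' age at recruitment (21022), ethnic background (21000), Townsend
#' deprivation index (189), current employment status (6142), assessment
#' centre (54) and body mass index (21001). Pass `variables` to override.
#'
#' Rows where `subset` is `NA` are excluded from both groups and counted
#' in the metadata; per variable, rows missing that variable are counted
#' as missing, so subset + reference + missing = dataset rows.
#'
#' @param data Dataset from [ukb_dataset()] (any tibble works when
#'   `variables` is given).
#' @param subset Logical vector, one element per row: `TRUE` marks the
#'   subset of interest, `FALSE` the reference group.
#' @param variables Character vector of column names to summarise;
#'   default as described above.
#' @param bins Number of shared equal-width bins for continuous
#'   variables (default 20), spanning the pooled non-missing range.
#' @param subset_label Free-text description of the subset definition,
#'   kept in the metadata.
#' @return An object of class `ukb_context`: a list with `categorical`
#'   (tibble `variable`, `level`, `n_subset`, `n_reference`),
#'   `continuous` (tibble `variable`, `bin_lower`, `bin_upper`,
#'   `n_subset`, `n_reference`) and `meta` (totals, per-variable missing
#'   counts, subset definition).
#' @export
ukb_context_summary <- function(data, subset, variables = NULL,
                                bins = 20L, subset_label = "subset") {
  if (length(subset) != nrow(data)) {
    ukb_usage_error("subset indicator length must equal dataset rows")
  }
  if (!is.logical(subset)) ukb_usage_error("subset must be a logical vector")
  if (is.null(variables)) {
    variables <- default_context_variables(data)
  }
  missing_vars <- setdiff(variables, names(data))
  if (length(missing_vars)) {
    ukb_usage_error(paste0(
      "variable(s) not in dataset: ", paste(missing_vars, collapse = ", "),
      "; available: ", paste(head(setdiff(names(data), "eid"), 30),
                             collapse = ", ")))
  }

  ind_ok <- !is.na(subset)
  n_ind_missing <- sum(!ind_ok)
  cat_rows <- list(); con_rows <- list(); miss <- integer(0)

  for (v in variables) {
    x <- data[[v]]
    val_ok <- ind_ok & !is.na(x)
    miss[v] <- nrow(data) - sum(val_ok)   # value-NA or indicator-NA
    if (is.numeric(x)) {
      rng <- range(x[val_ok])
      breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
      if (rng[1] == rng[2]) breaks <- c(rng[1], rng[2] + 1e-9)
      cut_all <- cut(x, breaks = breaks, include.lowest = TRUE)
      ns <- tabulate(cut_all[val_ok & subset], nbins = length(breaks) - 1L)
      nr <- tabulate(cut_all[val_ok & !subset], nbins = length(breaks) - 1L)
      con_rows[[v]] <- tibble(
        variable = v, bin_lower = breaks[-length(breaks)],
        bin_upper = breaks[-1], n_subset = ns, n_reference = nr)
    } else {
      lev <- if (is.factor(x)) levels(x) else
        sort(unique(as.character(stats::na.omit(x))))
      xs <- factor(as.character(x), levels = lev)
      ns <- tabulate(xs[val_ok & subset], nbins = length(lev))
      nr <- tabulate(xs[val_ok & !subset], nbins = length(lev))
      cat_rows[[v]] <- tibble(variable = v, level = lev,
                              n_subset = ns, n_reference = nr)
    }
  }

  out <- list(
    categorical = dplyr::bind_rows(cat_rows),
    continuous = dplyr::bind_rows(con_rows),
    meta = list(n_total = nrow(data),
                n_subset = sum(ind_ok & subset),
                n_reference = sum(ind_ok & !subset),
                n_indicator_missing = n_ind_missing,
                n_missing_by_variable = miss,
                subset_definition = subset_label,
                instance_note = "variables taken as supplied; defaults use instance 0"))
  class(out) <- "ukb_context"
  out
}

# Default demographic panel: resolve field codes against the dataset's
# descriptor attribute (instance 0, array 0 preferred), fall back to any
# instance, silently skip absent fields.
default_context_variables <- function(data) {
  fields <- attr(data, "ukb_fields")
  if (is.null(fields)) {
    ukb_usage_error(paste0(
      "dataset has no field descriptors; pass variables = explicitly"))
  }
  wanted <- c(31L, 21022L, 21000L, 189L, 6142L, 54L, 21001L)
  vars <- character(0)
  for (f in wanted) {
    rows <- fields[fields$field_id == f & fields$column_name %in% names(data), ]
    if (!nrow(rows)) next
    rows <- rows[order(rows$instance_index, rows$array_index), ]
    vars <- c(vars, rows$column_name[1])
  }
  if (!length(vars)) {
    ukb_usage_error("none of the default demographic fields are present")
  }
  vars
}

#' @export
print.ukb_context <- function(x, ...) {
  cat("Demographic context:", x$meta$subset_definition, "\n")
  cat("  subset n =", x$meta$n_subset,
      "| reference n =", x$meta$n_reference,
      "| indicator missing =", x$meta$n_indicator_missing, "\n")
  cat("  categorical variables:",
      length(unique(x$categorical$variable)),
      "| continuous variables:",
      length(unique(x$continuous$variable)), "\n")
  invisible(x)
}

#' Render a demographic context summary
#'
#' Draws one panel per variable: bars over category levels, histogram-style
#' bars over bins for continuous variables. `"stack"` and `"dodge"` show
#' counts; `"fill"` shows the per-level proportion belonging to the subset,
#' `n_subset / (n_subset + n_reference)`.
#'
#' The numbers being drawn are returned alongside the figure so they can
#' be checked directly rather than via pixels.
#'
#' @param summary A `ukb_context` object from [ukb_context_summary()].
#' @param bar_position `"stack"`, `"dodge"` (side-by-side) or `"fill"`.
#' @return A list: `plot` (a ggplot) and `data` (the plot table: one row
#'   per variable × level/bin × group with `count`, plus `proportion` in
#'   fill mode).
#' @export
ukb_context_plot <- function(summary,
                             bar_position = c("stack", "dodge", "fill")) {
  bar_position <- match.arg(bar_position)
  if (!inherits(summary, "ukb_context")) {
    ukb_usage_error("summary must come from ukb_context_summary()")
  }
  cat_tab <- summary$categorical
  con_tab <- summary$continuous
  if ((is.null(cat_tab) || !nrow(cat_tab)) &&
      (is.null(con_tab) || !nrow(con_tab))) {
    ukb_usage_error("empty context summary")
  }

  pieces <- list()
  if (!is.null(cat_tab) && nrow(cat_tab)) {
    pieces$cat <- tibble(variable = cat_tab$variable,
                         level = as.character(cat_tab$level),
                         n_subset = cat_tab$n_subset,
                         n_reference = cat_tab$n_reference)
  }
  if (!is.null(con_tab) && nrow(con_tab)) {
    pieces$con <- tibble(
      variable = con_tab$variable,
      level = sprintf("[%.3g, %.3g]", con_tab$bin_lower, con_tab$bin_upper),
      n_subset = con_tab$n_subset,
      n_reference = con_tab$n_reference)
  }
  wide <- dplyr::bind_rows(pieces)
  long <- tidyr::pivot_longer(wide, c("n_subset", "n_reference"),
                              names_to = "group", values_to = "count")
  long$group <- ifelse(long$group == "n_subset", "subset", "reference")
  if (bar_position == "fill") {
    tot <- wide$n_subset + wide$n_reference
    wide$proportion <- ifelse(tot > 0, wide$n_subset / tot, NA_real_)
    long <- dplyr::left_join(long, wide[c("variable", "level", "proportion")],
                             by = c("variable", "level"))
  }

  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$level, y = .data$count, fill = .data$group)) +
    ggplot2::geom_col(position = bar_position) +
    ggplot2::facet_wrap(~variable, scales = "free") +
    ggplot2::labs(x = NULL,
                  y = if (bar_position == "fill") "proportion" else "count",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  list(plot = p, data = long)
}
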