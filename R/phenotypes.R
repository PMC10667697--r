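#' Construct and validate a phenotype table
#'
#' The canonical data substrate is a long (tidy) table with one row per
#' plot-level observation: columns `genotype`, `year`, `regime`, `block`,
#' `trait`, `value`. Keys must be unique and values finite. When a
#' [trial_design()] is supplied the table is checked for balance: every key
#' combination of the design present exactly once.
#'
#' @param x A data frame with the six required columns (extra columns are
#'   dropped with a message).
#' @param design Optional [trial_design()] used for the balance check.
#' @param units Optional named character vector of trait units, carried as
#'   free-text metadata (not validated).
#' @return A tibble of class `phenotype_table` with attributes `design`,
#'   `balanced` (logical, `NA` when no design is given) and `units`.
#' @export
phenotype_table <- function(x, design = NULL, units = NULL) {
  required <- c("genotype", "year", "regime", "block", "trait", "value")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(
      paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "forageQG_format_error"
    )
  }
  extra <- setdiff(names(x), required)
  if (length(extra) > 0) {
    inform(paste0("dropping extra column(s): ", paste(extra, collapse = ", ")))
  }
  tab <- as_tibble(x)[required]
  tab <- mutate(tab, across(c("genotype", "year", "regime", "block", "trait"), as.character))
  if (!is.numeric(tab$value)) {
    suppressWarnings(num <- as.numeric(tab$value))
    if (anyNA(num) && !all(is.na(tab$value) == is.na(num))) {
      bad <- head(tab$value[is.na(num) & !is.na(tab$value)], 3)
      abort(
        paste0("non-numeric value(s) in `value`: ", paste(bad, collapse = ", ")),
        class = "forageQG_data_error"
      )
    }
    tab$value <- num
  }
  if (any(!is.finite(tab$value))) {
    abort("`value` contains missing or non-finite entries.", class = "forageQG_data_error")
  }
  key <- paste(tab$genotype, tab$year, tab$regime, tab$block, tab$trait, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- tab[duplicated(key), c("genotype", "year", "regime", "block", "trait")][1, ]
    abort(
      sprintf(
        "duplicate observation key: genotype=%s year=%s regime=%s block=%s trait=%s",
        dup$genotype, dup$year, dup$regime, dup$block, dup$trait
      ),
      class = "forageQG_data_error"
    )
  }
  balanced <- NA
  if (!is.null(design)) {
    stopifnot(inherits(design, "trial_design"))
    keys <- design_keys(design)
    missing_keys <- dplyr::anti_join(
      keys, tab,
      by = c("genotype", "year", "regime", "block", "trait")
    )
    foreign <- dplyr::anti_join(
      tab, keys,
      by = c("genotype", "year", "regime", "block", "trait")
    )
    if (nrow(foreign) > 0) {
      abort(
        sprintf("%d observation(s) outside the declared design (first: genotype=%s trait=%s).",
                nrow(foreign), foreign$genotype[1], foreign$trait[1]),
        class = "forageQG_data_error"
      )
    }
    balanced <- nrow(missing_keys) == 0
    if (!balanced) {
      shown <- head(missing_keys, 5)
      warn(paste0(
        sprintf("table is unbalanced: %d design cell(s) missing, e.g. ", nrow(missing_keys)),
        paste(sprintf("(%s, %s, %s, %s, %s)", shown$genotype, shown$year,
                      shown$regime, shown$block, shown$trait), collapse = "; ")
      ), class = "forageQG_unbalanced_warning")
    }
  }
  structure(
    tab,
    design = design, balanced = balanced, units = units,
    class = c("phenotype_table", class(tab))
  )
}

#' Read a long-format phenotype table from CSV/TSV
#'
#' The file must declare the six canonical columns `genotype`, `year`,
#' `regime`, `block`, `trait`, `value` (any order; extra columns are
#' dropped). The delimiter is inferred from the extension (`.tsv`/`.txt`
#' reads as tab-separated, anything else as comma-separated).
#'
#' @param path Path to an existing CSV or TSV file.
#' @inheritParams phenotype_table
#' @return A `phenotype_table`; see [phenotype_table()] for the balance
#'   reporting behaviour.
#' @export
read_phenotypes <- function(path, design = NULL, units = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "forageQG_format_error")
  }
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  # everything is read as text; phenotype_table() coerces `value` with R's
  # correctly-rounded numeric parser, so doubles round-trip bit-exactly
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  phenotype_table(raw, design = design, units = units)
}

#' Read a wide-format phenotype table (one column per trait)
#'
#' Accepts the common field-book layout with columns `genotype`, `year`,
#' `regime`, `block` plus one numeric column per trait, and normalizes it to
#' the canonical long format on load.
#'
#' @inheritParams read_phenotypes
#' @param traits Optional subset of trait columns to keep; defaults to all
#'   non-key columns.
#' @return A `phenotype_table`.
#' @export
read_phenotypes_wide <- function(path, design = NULL, traits = NULL, units = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "forageQG_format_error")
  }
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  keys <- c("genotype", "year", "regime", "block")
  missing_cols <- setdiff(keys, names(raw))
  if (length(missing_cols) > 0) {
    abort(
      paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "forageQG_format_error"
    )
  }
  if (is.null(traits)) traits <- setdiff(names(raw), keys)
  long <- pivot_longer(raw[c(keys, traits)], cols = all_of(traits),
                       names_to = "trait", values_to = "value")
  phenotype_table(long, design = design, units = units)
}

#' Write a phenotype table to CSV or TSV
#'
#' Values round-trip bit-exactly through [read_phenotypes()] (full double
#' precision is written).
#'
#' @param table A `phenotype_table` (or compatible data frame).
#' @param path Output path; `.tsv`/`.txt` writes tab-separated.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(table, path) {
  out <- as_tibble(table)[c("genotype", "year", "regime", "block", "trait", "value")]
  # 17 significant digits guarantee the double round-trips bit-exactly
  out$value <- sprintf("%.17g", out$value)
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    readr::write_tsv(out, path)
  } else {
    readr::write_csv(out, path)
  }
  invisible(path)
}

#' @export
print.phenotype_table <- function(x, ...) {
  bal <- attr(x, "balanced")
  cat("<phenotype_table> ", nrow(x), " observations, ",
      length(unique(x$trait)), " trait(s); balanced: ",
      ifelse(is.na(bal), "unchecked", bal), "\n", sep = "")
  NextMethod()
}

#' Is a phenotype table balanced against its design?
#'
#' @param table A `phenotype_table` built with a design.
#' @return Logical, or `NA` if no design was attached at load time.
#' @export
is_balanced <- function(table) {
  attr(table, "balanced")
}

# Subset one trait in one year x regime environment and check the RCBD
# layout is complete (every genotype once per block). Internal.
environment_subset <- function(table, trait, year, regime) {
  sub <- filter(as_tibble(table),
                .data$trait == !!trait,
                .data$year == !!as.character(year),
                .data$regime == !!as.character(regime))
  if (nrow(sub) == 0) {
    abort(sprintf("no observations for trait=%s year=%s regime=%s",
                  trait, year, regime), class = "forageQG_design_error")
  }
  tabulated <- table(sub$genotype, sub$block)
  if (any(tabulated != 1)) {
    abort(sprintf(
      "unbalanced RCBD subset for trait=%s year=%s regime=%s: each genotype must appear exactly once per block",
      trait, year, regime
    ), class = "forageQG_design_error")
  }
  sub
}
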