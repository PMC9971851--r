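# Age-sex-stratified tables (prevalence, deaths, YLLs, population):
# construction, validation, file IO in the GBD results-export dialect, and
# alignment across quantities.

SEXES <- c("female", "male")
COUNT_QUANTITIES <- c("deaths", "ylls", "population")

#' Canonical age-band label
#'
#' Normalises the age-group dialects found in burden-data exports
#' (`"15 to 19"`, `"15-19"`, `"85 plus"`, `"85+"`, with or without a
#' trailing "years") to the canonical forms `"15-19"` and `"85+"`.
#'
#' @param x Character vector of age-group labels.
#' @return Character vector of canonical labels.
#' @export
normalise_age_label <- function(x) {
  lab <- tolower(trimws(as.character(x)))
  lab <- sub("\\s*years?\\s*$", "", lab)
  closed <- regmatches(lab, regexec("^(\\d+)\\s*(?:-|–|to)\\s*(\\d+)$", lab))
  open <- regmatches(lab, regexec("^(\\d+)\\s*(?:\\+|plus)$", lab))
  out <- character(length(lab))
  for (i in seq_along(lab)) {
    if (length(closed[[i]]) == 3) {
      out[i] <- paste0(closed[[i]][2], "-", closed[[i]][3])
    } else if (length(open[[i]]) == 2) {
      out[i] <- paste0(open[[i]][2], "+")
    } else {
      stop_input("unparseable age-group label: '%s'", x[i])
    }
  }
  out
}

# numeric bounds of canonical labels; upper is NA for an open terminal band
parse_age_group <- function(labels) {
  lab <- normalise_age_label(labels)
  open <- grepl("\\+$", lab)
  lower <- as.numeric(sub("[-+].*$|\\+$", "", lab))
  upper <- rep(NA_real_, length(lab))
  upper[!open] <- as.numeric(sub("^\\d+-", "", lab[!open]))
  data.frame(age_group = lab, age_lower = lower, age_upper = upper)
}

#' Age midpoint of a closed or open band
#'
#' Labels are closed integer-year ranges, so the midpoint of `[lower,
#' upper]` is `(lower + upper + 1) / 2` (e.g. 17.5 for 15-19). An
#' open-ended terminal band uses `lower + 5` (e.g. 90 for 85+).
#'
#' @param lower,upper Numeric band bounds; `upper` is `NA` for open bands.
#' @return Numeric midpoints in years.
#' @export
age_midpoint <- function(lower, upper) {
  ifelse(is.na(upper), lower + 5, (lower + upper + 1) / 2)
}

#' Default adult age bands
#'
#' Contiguous 5-year bands from `start` to `open_from - 1` plus a terminal
#' open band, e.g. `"15-19"` ... `"80-84"`, `"85+"`.
#'
#' @param start First age included (default 15, the adult mortality focus).
#' @param open_from Lower bound of the terminal open band (default 85).
#' @return Character vector of canonical band labels.
#' @export
default_age_bands <- function(start = 15, open_from = 85) {
  lowers <- seq(start, open_from - 5, by = 5)
  c(paste0(lowers, "-", lowers + 4), paste0(open_from, "+"))
}

#' Construct and validate an age-sex stratum table
#'
#' A stratum table holds one quantity (exposure prevalence as a fraction,
#' or deaths / YLLs / population as counts) for every (sex, age band) cell,
#' with optional 95% uncertainty bounds. Validation enforces: both sexes
#' present for every band, non-overlapping contiguous bands with at most one
#' terminal open band, prevalence in [0, 1], nonnegative counts, and
#' `ui_lower <= value <= ui_upper` wherever bounds are given.
#'
#' @param data Data frame with columns `sex`, `age_group`, `value` and
#'   optionally `ui_lower`, `ui_upper` (or `lower`, `upper`).
#' @param quantity One of `"prevalence"`, `"deaths"`, `"ylls"`,
#'   `"population"`, or another label (validated as a nonnegative rate).
#' @return A data frame of class `"stratum_table"` in canonical order
#'   (female then male, ascending age), with columns `sex`, `age_group`,
#'   `age_lower`, `age_upper`, `age_mid`, `value`, `ui_lower`, `ui_upper`
#'   and a `quantity` attribute.
#' @export
stratum_table <- function(data, quantity) {
  stopifnot(is.data.frame(data))
  if (!is.null(data$lower) && is.null(data$ui_lower)) data$ui_lower <- data$lower
  if (!is.null(data$upper) && is.null(data$ui_upper)) data$ui_upper <- data$upper
  need <- setdiff(c("sex", "age_group", "value"), names(data))
  if (length(need))
    stop_input("stratum table lacks column(s): %s", paste(need, collapse = ", "))

  sex <- tolower(trimws(as.character(data$sex)))
  if (any(!sex %in% SEXES))
    stop_input("sex must be 'female' or 'male'; got: %s",
               paste(unique(sex[!sex %in% SEXES]), collapse = ", "))
  bounds <- parse_age_group(data$age_group)
  tab <- data.frame(sex = sex, bounds,
                    value = as.numeric(data$value),
                    ui_lower = if (is.null(data$ui_lower)) NA_real_ else as.numeric(data$ui_lower),
                    ui_upper = if (is.null(data$ui_upper)) NA_real_ else as.numeric(data$ui_upper),
                    stringsAsFactors = FALSE)
  tab$age_mid <- age_midpoint(tab$age_lower, tab$age_upper)

  # completeness over the full sex x band grid
  bands <- unique(tab[order(tab$age_lower), c("age_group", "age_lower", "age_upper")])
  grid <- expand.grid(sex = SEXES, age_group = bands$age_group,
                      stringsAsFactors = FALSE)
  key <- paste(tab$sex, tab$age_group)
  missing_cells <- setdiff(paste(grid$sex, grid$age_group), key)
  if (length(missing_cells))
    stop_input("incomplete %s table: missing stratum cell(s) %s", quantity,
               paste0("(", sub(" ", ", ", missing_cells), ")", collapse = ", "))
  if (anyDuplicated(key))
    stop_input("duplicated stratum cell(s): %s",
               paste(unique(key[duplicated(key)]), collapse = ", "))

  # contiguity: bands must tile an integer-year range; open band last only
  if (sum(is.na(bands$age_upper)) > 1)
    stop_input("more than one open-ended age band")
  o <- order(bands$age_lower)
  bands <- bands[o, ]
  if (any(is.na(bands$age_upper)) && is.na(bands$age_upper[nrow(bands)]) == FALSE)
    stop_input("the open-ended age band must be the oldest band")
  if (nrow(bands) > 1) {
    up <- bands$age_upper[-nrow(bands)]
    lo <- bands$age_lower[-1]
    gap <- is.na(up) | (up + 1 != lo)
    if (any(gap))
      stop_input("age bands are not contiguous at: %s",
                 paste(bands$age_group[-nrow(bands)][gap], collapse = ", "))
  }

  if (any(!is.finite(tab$value)))
    stop_input("non-finite %s value(s)", quantity)
  if (quantity == "prevalence") {
    if (any(tab$value < 0 | tab$value > 1))
      stop_input("prevalence must lie in [0, 1] (fractions, not percent)")
  } else if (any(tab$value < 0)) {
    stop_input("%s values must be nonnegative", quantity)
  }
  has_ui <- is.finite(tab$ui_lower) & is.finite(tab$ui_upper)
  if (any(has_ui & (tab$ui_lower > tab$value | tab$ui_upper < tab$value)))
    stop_input("uncertainty bounds must bracket the value (%s table)", quantity)

  ord <- order(match(tab$sex, SEXES), tab$age_lower)
  tab <- tab[ord, c("sex", "age_group", "age_lower", "age_upper", "age_mid",
                    "value", "ui_lower", "ui_upper")]
  rownames(tab) <- NULL
  structure(tab, quantity = quantity, class = c("stratum_table", "data.frame"))
}

#' Read an age-sex stratum table from a delimited file
#'
#' Canonical dialect: comma-separated, header `sex, age_group, value,
#' lower, upper`. The GBD results-export dialect (`dialect = "gbd"`,
#' columns `sex, age, val, lower, upper`) or an arbitrary column mapping is
#' also accepted. A prevalence file in percent must be declared with
#' `percent = TRUE`; units are never auto-detected.
#'
#' @param path CSV file path.
#' @param quantity Quantity label, see [stratum_table()].
#' @param dialect `"canonical"` or `"gbd"`.
#' @param col_map Optional named list mapping `sex`, `age_group`, `value`,
#'   `ui_lower`, `ui_upper` to the file's column names (overrides
#'   `dialect`).
#' @param percent If `TRUE`, values (and bounds) are divided by 100.
#' @return A validated [stratum_table()].
#' @export
read_stratum_table <- function(path, quantity,
                               dialect = c("canonical", "gbd"),
                               col_map = NULL, percent = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_input("stratum table not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  map <- col_map %||% switch(dialect,
    canonical = list(sex = "sex", age_group = "age_group", value = "value",
                     ui_lower = "lower", ui_upper = "upper"),
    gbd = list(sex = "sex", age_group = "age", value = "val",
               ui_lower = "lower", ui_upper = "upper"))
  need <- setdiff(unlist(map[c("sex", "age_group", "value")]), names(raw))
  if (length(need))
    stop_input("%s lacks column(s): %s", path, paste(need, collapse = ", "))
  dat <- data.frame(sex = raw[[map$sex]],
                    age_group = raw[[map$age_group]],
                    value = raw[[map$value]],
                    stringsAsFactors = FALSE)
  dat$ui_lower <- if (!is.null(raw[[map$ui_lower]])) raw[[map$ui_lower]] else NA_real_
  dat$ui_upper <- if (!is.null(raw[[map$ui_upper]])) raw[[map$ui_upper]] else NA_real_
  if (percent) {
    dat$value <- dat$value / 100
    dat$ui_lower <- dat$ui_lower / 100
    dat$ui_upper <- dat$ui_upper / 100
  }
  stratum_table(dat, quantity)
}

#' Write a stratum table in the canonical dialect
#'
#' Writes `sex, age_group, value, lower, upper`; reading the file back with
#' [read_stratum_table()] reproduces the table exactly.
#'
#' @param tab A [stratum_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stratum_table <- function(tab, path) {
  stopifnot(inherits(tab, "stratum_table"))
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  out <- data.frame(sex = tab$sex, age_group = tab$age_group,
                    value = fmt(tab$value), lower = fmt(tab$ui_lower),
                    upper = fmt(tab$ui_upper))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align stratum tables on a common stratification
#'
#' Asserts that all tables share exactly the same (sex, age band) cells
#' (after label normalisation) and returns them reordered to the canonical
#' stratum order together with the shared key.
#'
#' @param tables Named list of [stratum_table()] objects (at least 2).
#' @return A list of class `"stratum_bundle"` with elements `key` (data
#'   frame `sex`, `age_group`, `age_lower`, `age_upper`, `age_mid`) and
#'   `tables` (the reordered input tables).
#' @export
align_tables <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- paste0("table", seq_along(tables))
  keys <- lapply(tables, function(t) paste(t$sex, t$age_group))
  ref <- keys[[1]]
  for (i in seq_along(tables)[-1]) {
    extra <- setdiff(keys[[i]], ref)
    absent <- setdiff(ref, keys[[i]])
    if (length(extra) || length(absent))
      stop_input(paste0(
        "stratification mismatch between '%s' and '%s':",
        if (length(extra)) " extra in second: %s" else "%.0s",
        if (length(absent)) " missing from second: %s" else "%.0s"),
        names(tables)[1], names(tables)[i],
        paste(extra, collapse = ", "), paste(absent, collapse = ", "))
  }
  tables <- lapply(tables, function(t) {
    t[match(ref, paste(t$sex, t$age_group)), , drop = FALSE]
  })
  key <- tables[[1]][, c("sex", "age_group", "age_lower", "age_upper", "age_mid")]
  rownames(key) <- NULL
  structure(list(key = key, tables = tables), class = "stratum_bundle")
}

#' Aggregate a stratum table to an all-age, both-sex scalar
#'
#' Counts (deaths, YLLs, population) aggregate by summation; rates and
#' prevalences aggregate by population-weighted mean. Asking for a weighted
#' mean of a count table is an error, as is summing without meaning:
#' the mode must match the quantity.
#'
#' @param tab A [stratum_table()].
#' @param population A population [stratum_table()] aligned with `tab`
#'   (required for `mode = "weighted_mean"`).
#' @param mode `"sum"` or `"weighted_mean"`.
#' @return A scalar with attributes `mode` and `quantity`.
#' @export
#' @examples
#' # two strata with prevalences 0.1 and 0.3 and populations 3 and 1
#' # population-weighted mean: (0.1 * 3 + 0.3 * 1) / 4 = 0.15
aggregate_strata <- function(tab, population = NULL,
                             mode = c("sum", "weighted_mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tab, "stratum_table"))
  quantity <- attr(tab, "quantity")
  if (mode == "weighted_mean") {
    if (quantity %in% COUNT_QUANTITIES)
      stop_input("population-weighting a count table ('%s') is not meaningful; use mode = 'sum'",
                 quantity)
    if (is.null(population))
      stop_input("mode = 'weighted_mean' requires a population table")
    b <- align_tables(list(x = tab, population = population))
    w <- b$tables$population$value
    val <- sum(b$tables$x$value * w) / sum(w)
  } else {
    val <- sum(tab$value)
  }
  structure(val, mode = mode, quantity = quantity)
}
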