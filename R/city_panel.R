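#' Variable categories recognised in a city panel catalog
#'
#' Tract-level variables are tagged with the data source and domain they come
#' from. The categories drive factor labeling: American Community Survey
#' demographics map to the DBC factor, CDC prevalence variables to the health
#' factor, and path mileage/use variables to the BPH factor.
#'
#' @format A character vector of the seven recognised category tags.
#' @export
PANEL_CATEGORIES <- c(
  "ACS_demographic",
  "CDC_health_outcome",
  "CDC_health_behavior",
  "CDC_prevention",
  "CDC_health_status",
  "path_mileage",
  "path_use"
)

# Category tags whose values are prevalence percentages in [0, 100].
prevalence_categories <- function() {
  c("CDC_health_outcome", "CDC_health_behavior", "CDC_prevention",
    "CDC_health_status")
}

#' Construct a city panel
#'
#' A city panel is a census-tract-by-year table of observed variables together
#' with a catalog tagging each variable with its category and units. It is the
#' universal input to the factor-analysis and prediction functions.
#'
#' @param data Data frame with columns `tract_id` (11-character FIPS string),
#'   `year` (integer), and one numeric column per catalog variable.
#' @param catalog Data frame with columns `name`, `category`, `units`;
#'   `category` must be one of [PANEL_CATEGORIES], and exactly one variable
#'   must carry category `path_mileage`.
#' @return An object of class `city_panel`: a list with elements `data` and
#'   `catalog`.
#' @details Structural invariants are enforced here: unique (tract, year)
#'   pairs, a contiguous year range, a catalog that matches the data columns
#'   exactly, and a single mileage variable. Value-level problems (out-of-range
#'   prevalences, constant columns, missingness) are report-only findings; see
#'   [validate_panel()].
#' @seealso [load_panel()], [write_panel()], [validate_panel()],
#'   [split_halves()]
#' @export
city_panel <- function(data, catalog) {
  stopifnot(is.data.frame(data), is.data.frame(catalog))
  mandatory <- c("tract_id", "year")
  missing_cols <- setdiff(mandatory, names(data))
  if (length(missing_cols) > 0) {
    stop("panel format error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(c("name", "category", "units") %in% names(catalog))) {
    stop("catalog format error: needs columns name, category, units",
         call. = FALSE)
  }
  catalog <- as.data.frame(catalog, stringsAsFactors = FALSE)
  catalog$name <- as.character(catalog$name)
  catalog$category <- as.character(catalog$category)
  bad_cat <- setdiff(catalog$category, PANEL_CATEGORIES)
  if (length(bad_cat) > 0) {
    stop("unknown variable category: ", paste(unique(bad_cat), collapse = ", "),
         call. = FALSE)
  }
  if (sum(catalog$category == "path_mileage") != 1) {
    stop("catalog must tag exactly one variable with category path_mileage",
         call. = FALSE)
  }

  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$tract_id <- as.character(data$tract_id)
  data$year <- as.integer(data$year)

  value_cols <- setdiff(names(data), mandatory)
  untagged <- setdiff(value_cols, catalog$name)
  if (length(untagged) > 0) {
    stop("panel column(s) not in catalog: ", paste(untagged, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(catalog$name, value_cols)
  if (length(absent) > 0) {
    stop("catalog variable(s) missing from panel: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  for (v in value_cols) data[[v]] <- as.numeric(data[[v]])

  key <- paste(data$tract_id, data$year)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("panel validation error: duplicated (tract, year) pair(s): ",
         paste(head(dup, 5), collapse = "; "), call. = FALSE)
  }
  yrs <- sort(unique(data$year))
  if (length(yrs) > 1 && !identical(yrs, seq(min(yrs), max(yrs)))) {
    stop("panel validation error: years do not form a contiguous range",
         call. = FALSE)
  }

  structure(list(data = data[order(data$tract_id, data$year), , drop = FALSE],
                 catalog = catalog),
            class = "city_panel")
}

#' @export
print.city_panel <- function(x, ...) {
  yrs <- range(x$data$year)
  cat(sprintf("city_panel: %d tracts x years %d-%d (%d rows), %d variables\n",
              length(unique(x$data$tract_id)), yrs[1], yrs[2], nrow(x$data),
              nrow(x$catalog)))
  tab <- table(x$catalog$category)
  cat("  variables by category:\n")
  for (nm in names(tab)) cat(sprintf("    %-20s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Read a city panel from CSV files
#'
#' @param path Path to the panel CSV (`tract_id,year,<var1>,...`).
#' @param catalog_path Path to the catalog CSV (`name,category,units`).
#' @return A validated [city_panel]. Rows whose tract IDs are not 11-character
#'   FIPS strings are dropped with a warning naming them.
#' @export
load_panel <- function(path, catalog_path) {
  catalog <- read.csv(catalog_path, stringsAsFactors = FALSE,
                      colClasses = "character")
  data <- read.csv(path, stringsAsFactors = FALSE,
                   colClasses = c(tract_id = "character"))
  if (!all(c("tract_id", "year") %in% names(data))) {
    stop("panel format error: CSV must contain tract_id and year columns",
         call. = FALSE)
  }
  bad <- !grepl("^[0-9]{11}$", data$tract_id)
  if (any(bad)) {
    warning(sum(bad), " row(s) dropped: malformed tract ID(s) ",
            paste(unique(data$tract_id[bad]), collapse = ", "), call. = FALSE)
    data <- data[!bad, , drop = FALSE]
  }
  city_panel(data, catalog)
}

#' Write a city panel to CSV files
#'
#' Numeric values are serialized with 17 significant digits so that a
#' write-then-read round trip reproduces the panel bit-exactly.
#'
#' @param panel A [city_panel].
#' @param path Output path for the panel CSV.
#' @param catalog_path Optional output path for the catalog CSV.
#' @return `panel`, invisibly.
#' @export
write_panel <- function(panel, path, catalog_path = NULL) {
  stopifnot(inherits(panel, "city_panel"))
  out <- panel$data
  for (v in panel$catalog$name) {
    out[[v]] <- ifelse(is.na(out[[v]]), NA, sprintf("%.17g", out[[v]]))
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(catalog_path)) {
    write.csv(panel$catalog, catalog_path, row.names = FALSE, quote = FALSE)
  }
  invisible(panel)
}

#' Report data-quality findings for a panel
#'
#' Report-only checks: zero-variance variables, prevalence values outside
#' \[0, 100\] for CDC-sourced variables, and per-variable missing-value
#' fractions. A clean panel yields a zero-row data frame.
#'
#' @param panel A [city_panel].
#' @return Data frame with columns `variable`, `finding`, `detail`.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "city_panel"))
  findings <- list()
  add <- function(variable, finding, detail) {
    findings[[length(findings) + 1]] <<- data.frame(
      variable = variable, finding = finding, detail = detail,
      stringsAsFactors = FALSE)
  }
  prev_vars <- panel$catalog$name[panel$catalog$category %in%
                                    prevalence_categories()]
  for (v in panel$catalog$name) {
    vals <- panel$data[[v]]
    frac_na <- mean(is.na(vals))
    if (frac_na > 0) {
      add(v, "missing values", sprintf("%.1f%% of tract-years missing",
                                       100 * frac_na))
    }
    obs <- vals[!is.na(vals)]
    if (length(obs) > 1 && var(obs) == 0) {
      add(v, "zero variance", sprintf("constant value %g", obs[1]))
    }
    if (v %in% prev_vars && length(obs) > 0 &&
        (min(obs) < 0 || max(obs) > 100)) {
      add(v, "out of range",
          sprintf("prevalence outside [0,100]: range %g-%g",
                  min(obs), max(obs)))
    }
  }
  if (length(findings) == 0) {
    return(data.frame(variable = character(), finding = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

#' Randomly split tracts into EFA and CFA halves
#'
#' Tracts (not tract-years) are partitioned at random so that every year of a
#' tract lands in the same half. The larger half (ceiling of n/2) is assigned
#' to exploratory factor analysis: a 77-tract city observed over 5 years
#' yields 39 EFA tracts (195 tract-year rows) and 38 CFA tracts (190 rows).
#'
#' @param panel A [city_panel] with at least 2 tracts.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return An object of class `split_assignment`: list with sorted character
#'   vectors `efa_tracts` and `cfa_tracts`.
#' @export
split_halves <- function(panel, seed) {
  stopifnot(inherits(panel, "city_panel"))
  tracts <- sort(unique(panel$data$tract_id))
  n <- length(tracts)
  if (n < 2) stop("split_halves requires at least 2 tracts", call. = FALSE)
  efa <- with_seed(seed, function() sort(sample(tracts, ceiling(n / 2))))
  structure(list(efa_tracts = efa, cfa_tracts = setdiff(tracts, efa)),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("split_assignment: %d EFA tracts / %d CFA tracts\n",
              length(x$efa_tracts), length(x$cfa_tracts)))
  invisible(x)
}

# Subset a panel to a set of tracts and/or years.
panel_subset <- function(panel, tracts = NULL, years = NULL) {
  d <- panel$data
  if (!is.null(tracts)) d <- d[d$tract_id %in% tracts, , drop = FALSE]
  if (!is.null(years)) d <- d[d$year %in% years, , drop = FALSE]
  structure(list(data = d, catalog = panel$catalog), class = "city_panel")
}

# Name of the unique path-mileage variable.
mileage_var <- function(panel_or_catalog) {
  cat <- if (inherits(panel_or_catalog, "city_panel")) {
    panel_or_catalog$catalog
  } else {
    panel_or_catalog
  }
  cat$name[cat$category == "path_mileage"]
}

#' Convert miles to kilometres
#'
#' @param miles Numeric vector of distances in miles.
#' @param exact If `TRUE` (default), use the international mile
#'   (1 mi = 1.609344 km). If `FALSE`, use the 3-decimal civil-planning
#'   approximation 1.609 km/mi commonly seen in municipal path inventories.
#' @return Distances in kilometres.
#' @export
miles_to_km <- function(miles, exact = TRUE) {
  miles * if (exact) 1.609344 else 1.609
}
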