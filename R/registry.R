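#' Registry tables
#'
#' A registry table is a tibble with one row per calendar year and columns
#' `year`, `new_cases`, `pop_under19` and `pop_19`:
#'
#' * `year` — calendar year (integer, consecutive, unique);
#' * `new_cases` — newly diagnosed patients that year (may be `NA` for
#'   trailing years where only population data exist yet);
#' * `pop_under19` — persons aged 19 or younger on the reference date;
#' * `pop_19` — 19-year-olds, i.e. the cohort that leaves the modelled
#'   population during the year.
#'
#' All downstream computation works on full-precision ratios of these counts,
#' never on rounded display rates.
#'
#' @name registry
NULL

registry_cols <- c("year", "new_cases", "pop_under19", "pop_19")

#' Validate a registry table
#'
#' Checks the column set, types, year ordering and the count invariants
#' (`pop_19 <= pop_under19`, `new_cases <= pop_under19`, no negative counts,
#' no gaps or duplicate years, at least two rows). Errors name the offending
#' year so problems in long tables are easy to locate.
#'
#' @param registry A data frame with columns `year`, `new_cases`,
#'   `pop_under19`, `pop_19`.
#' @return The validated table as a tibble, sorted by year, invisibly usable
#'   in a pipe.
#' @export
validate_registry <- function(registry) {
  if (!is.data.frame(registry)) {
    stop("`registry` must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(registry_cols, names(registry))
  if (length(missing_cols) > 0) {
    stop("registry schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(registry)[registry_cols]
  out <- dplyr::arrange(out, .data$year)
  if (nrow(out) < 2) {
    stop("registry must contain at least 2 annual records", call. = FALSE)
  }
  dup <- out$year[duplicated(out$year)]
  if (length(dup) > 0) {
    stop("duplicate registry year: ", dup[1], call. = FALSE)
  }
  gaps <- setdiff(seq(min(out$year), max(out$year)), out$year)
  if (length(gaps) > 0) {
    stop("registry year gap: missing year ", gaps[1], call. = FALSE)
  }
  bad <- function(cond) out$year[which(cond)][1]
  if (any(out$pop_under19 <= 0)) {
    stop("non-positive pop_under19 in year ", bad(out$pop_under19 <= 0),
         call. = FALSE)
  }
  if (any(out$pop_19 < 0)) {
    stop("negative pop_19 in year ", bad(out$pop_19 < 0), call. = FALSE)
  }
  if (any(out$pop_19 > out$pop_under19)) {
    stop("pop_19 exceeds pop_under19 in year ",
         bad(out$pop_19 > out$pop_under19), call. = FALSE)
  }
  cases <- out$new_cases
  if (any(!is.na(cases) & cases < 0)) {
    stop("negative new_cases in year ", bad(!is.na(cases) & cases < 0),
         call. = FALSE)
  }
  if (any(!is.na(cases) & cases > out$pop_under19)) {
    stop("new_cases exceeds pop_under19 in year ",
         bad(!is.na(cases) & cases > out$pop_under19), call. = FALSE)
  }
  out
}

#' Read or write a registry CSV
#'
#' The on-disk schema is a UTF-8 CSV with header
#' `year,new_cases,pop_under19,pop_19`; an empty `new_cases` field marks a
#' year with population data only. `read_registry()` validates the table on
#' load; `write_registry()` writes counts exactly, so a write/read round trip
#' is lossless.
#'
#' @param path Path to a CSV file.
#' @return `read_registry()` returns a validated registry tibble;
#'   `write_registry()` returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write_registry(slovenia_adhd(), tf)
#' read_registry(tf)
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) {
    stop("registry file not found: ", path, call. = FALSE)
  }
  tbl <- tryCatch(
    suppressWarnings(readr::read_csv(path,
                    col_types = readr::cols(
                      year = readr::col_integer(),
                      new_cases = readr::col_double(),
                      pop_under19 = readr::col_double(),
                      pop_19 = readr::col_double()
                    ))),
    error = function(e) {
      stop("registry schema error in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (nrow(tbl) == 0) {
    stop("registry schema error: ", path, " contains no records",
         call. = FALSE)
  }
  validate_registry(tbl)
}

#' @rdname read_registry
#' @param registry A registry table (see [validate_registry()]).
#' @export
write_registry <- function(registry, path) {
  registry <- validate_registry(registry)
  readr::write_csv(registry, path, na = "")
  invisible(path)
}

#' Slovenian ADHD registry table, 1997-2013
#'
#' Annual counts of newly diagnosed ADHD (ICD-10 F90.x) outpatients aged
#' under 19 from the Slovenian national outpatient database, together with
#' the population aged 19 or younger and the number of 19-year-olds from
#' national population statistics. The 2013 row carries population figures
#' only; case counts end in 2012.
#'
#' @return A 17-row registry tibble.
#' @examples
#' slovenia_adhd() |> add_rates()
#' @export
slovenia_adhd <- function() {
  tibble::tibble(
    year = 1997:2013,
    new_cases = c(156L, 166L, 177L, 214L, 254L, 230L, 329L, 354L, 316L,
                  303L, 224L, 334L, 229L, 299L, 329L, 378L, NA),
    pop_under19 = c(491915, 479240, 467980, 456145, 444360, 433884, 424472,
                    415850, 408383, 403028, 397958, 394304, 392987, 393176,
                    393202, 394681, 396657),
    pop_19 = c(29946, 30505, 30061, 29730, 28820, 27472, 26949, 26661,
               25069, 25880, 26388, 24955, 23184, 22898, 21506, 20669,
               20366)
  )
}

#' Derived annual rates
#'
#' Adds two columns to a registry table:
#'
#' * `incidence` — the crude annual incidence rate per 100 000 persons aged
#'   19 or younger, `1e5 * new_cases / pop_under19` (`NA` where `new_cases`
#'   is missing);
#' * `g` — the aging-out proportion, `pop_19 / pop_under19`, the annual
#'   fraction of the modelled population that turns 19 and exits.
#'
#' @param registry A registry table.
#' @return The registry tibble with `incidence` and `g` appended.
#' @export
add_rates <- function(registry) {
  registry <- validate_registry(registry)
  dplyr::mutate(
    registry,
    incidence = 1e5 * .data$new_cases / .data$pop_under19,
    g = .data$pop_19 / .data$pop_under19
  )
}

# years with an observed case count
observed_years <- function(registry) {
  registry$year[!is.na(registry$new_cases)]
}
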