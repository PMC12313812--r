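#' Read an Audacity label track as a call table
#'
#' Audacity exports annotation labels as a headerless tab-separated file
#' with one label per line: start time (s), end time (s), label text.
#' Each label is taken to be one call by `caller_id`. In the field
#' recordings this package was built around, the observer identifies the
#' caller by voice on the recording and each exported label file covers a
#' single focal individual, so the caller is supplied per file; a label
#' of the form `id:NAME` (optionally followed by free text) overrides it
#' for that call. A caller of `"unknown"` (any case), or an `id:unknown`
#' label, marks the call with the `unknown_caller` flag.
#'
#' Lines whose first field starts with `\` (Audacity frequency-range
#' continuation lines) are ignored. Labels with end time less than or
#' equal to start time cannot be calls of positive duration and are
#' dropped with a warning.
#'
#' @param path Path to the label-track file.
#' @param caller_id Default caller identity for every label in the file.
#' @param population,group Optional population and group labels attached
#'   to every call (columns of the canonical call table).
#' @return A call table: a tibble with columns `individual`,
#'   `population`, `group`, `source_file`, `onset_s`, `offset_s`,
#'   `label`, `flags`, sorted by onset (stable for ties). Times are kept
#'   at full input precision.
#' @seealso [read_raven_selection_table()], [write_call_table()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".txt")
#' writeLines(c("0.000000\t0.310000\tcaw", "0.800000\t1.050000\tcaw"), tf)
#' read_audacity_labels(tf, caller_id = "Toeffel")
read_audacity_labels <- function(path, caller_id, population = NA_character_,
                                 group = NA_character_) {
  stopifnot(is.character(caller_id), length(caller_id) == 1)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines) & !grepl("^\\\\", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) {
    warning("empty label file: ", path)
    return(empty_call_table())
  }
  fields <- stringr::str_split(lines, "\t")
  n_fields <- lengths(fields)
  if (any(n_fields < 2)) {
    stop_vocaleff("malformed label line ", lineno[which(n_fields < 2)[1]],
                  " in ", path, ": expected start<TAB>end<TAB>label",
                  class = "vocaleff_parse_error")
  }
  onset <- parse_seconds(vapply(fields, `[[`, "", 1))
  offset <- parse_seconds(vapply(fields, `[[`, "", 2))
  bad <- which(is.na(onset) | is.na(offset))
  if (length(bad) > 0) {
    stop_vocaleff("malformed label line ", lineno[bad[1]], " in ", path,
                  ": non-numeric start/end time",
                  class = "vocaleff_parse_error")
  }
  label <- vapply(fields, function(f) if (length(f) >= 3) f[[3]] else "", "")

  caller <- rep(caller_id, length(onset))
  id_override <- stringr::str_match(label, "^id:(\\S+)")[, 2]
  caller[!is.na(id_override)] <- id_override[!is.na(id_override)]

  tab <- tibble::tibble(
    individual = caller,
    population = population,
    group = group,
    source_file = basename(path),
    onset_s = onset,
    offset_s = offset,
    label = label,
    flags = ""
  )
  tab$flags <- flag_add(tab$flags, "unknown_caller",
                        tolower(tab$individual) == "unknown")
  nonpos <- tab$offset_s <= tab$onset_s
  if (any(nonpos)) {
    warning(sum(nonpos), " label(s) with end <= start dropped from ", path)
    tab <- tab[!nonpos, ]
  }
  tab[order(tab$onset_s), ]
}

#' Read a Raven Pro selection table as a call table
#'
#' Raven Pro selection tables are tab-separated with a header row;
#' `Begin Time (s)` and `End Time (s)` are required. When the table
#' carries both `Waveform` and `Spectrogram` views of the same
#' selections, rows are deduplicated by `Selection` number (first
#' occurrence kept). Caller identity is read from `caller_column` when
#' that column exists, otherwise every selection is attributed to
#' `caller_id`; a caller of `"unknown"` sets the `unknown_caller` flag.
#'
#' @param path Path to the selection table.
#' @param caller_id Default caller identity.
#' @param caller_column Name of a column holding per-selection caller
#'   identities (optional).
#' @inheritParams read_audacity_labels
#' @return A call table (see [read_audacity_labels()] for columns).
#' @export
read_raven_selection_table <- function(path, caller_id,
                                       caller_column = NULL,
                                       population = NA_character_,
                                       group = NA_character_) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("Begin Time (s)", "End Time (s)")
  if (!all(required %in% names(raw))) {
    stop_vocaleff("not a Raven selection table (need ",
                  paste(required, collapse = ", "), "); found headers: ",
                  paste(names(raw), collapse = ", "),
                  class = "vocaleff_format_error")
  }
  if ("Selection" %in% names(raw)) {
    raw <- raw[!duplicated(raw$Selection), , drop = FALSE]
  }
  onset <- parse_seconds(raw[["Begin Time (s)"]])
  offset <- parse_seconds(raw[["End Time (s)"]])
  if (anyNA(onset) || anyNA(offset)) {
    stop_vocaleff("non-numeric Begin/End Time in ", path,
                  class = "vocaleff_parse_error")
  }
  caller <- rep(caller_id, nrow(raw))
  if (!is.null(caller_column) && caller_column %in% names(raw)) {
    from_col <- raw[[caller_column]]
    use <- !is.na(from_col) & from_col != ""
    caller[use] <- from_col[use]
  }
  tab <- tibble::tibble(
    individual = caller,
    population = population,
    group = group,
    source_file = basename(path),
    onset_s = onset,
    offset_s = offset,
    label = if ("Annotation" %in% names(raw)) raw[["Annotation"]] else "",
    flags = ""
  )
  tab$flags <- flag_add(tab$flags, "unknown_caller",
                        tolower(tab$individual) == "unknown")
  keep <- tab$offset_s > tab$onset_s
  if (!all(keep)) {
    warning(sum(!keep), " selection(s) with non-positive duration dropped")
    tab <- tab[keep, ]
  }
  tab[order(tab$onset_s), ]
}

empty_call_table <- function() {
  tibble::tibble(
    individual = character(), population = character(), group = character(),
    source_file = character(), onset_s = double(), offset_s = double(),
    label = character(), flags = character()
  )
}

call_table_columns <- c("individual", "population", "group", "source_file",
                        "onset_s", "offset_s", "flags")

validate_call_table <- function(calls, what = "call table") {
  assert_columns(calls, call_table_columns, what)
  if (any(calls$offset_s <= calls$onset_s)) {
    stop_vocaleff(what, " contains calls with non-positive duration",
                  class = "vocaleff_validation_error")
  }
  invisible(calls)
}

#' Write / read the canonical call table
#'
#' The canonical call table is the interchange format every downstream
#' stage consumes: a UTF-8 CSV with header columns `individual`,
#' `population`, `group`, `source_file`, `onset_s`, `offset_s`, `flags`
#' (plus any extra columns, preserved verbatim). Times are written with
#' full double precision so that a write/read round trip reproduces all
#' fields exactly.
#'
#' @param calls A call table.
#' @param path File path.
#' @return `read_call_table()` returns the call table sorted by
#'   `source_file` then onset; `write_call_table()` returns `path`
#'   invisibly.
#' @export
write_call_table <- function(calls, path) {
  validate_call_table(calls)
  readr::write_csv(calls, path)
  invisible(path)
}

#' @rdname write_call_table
#' @export
read_call_table <- function(path) {
  calls <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                           locale = readr::locale(decimal_mark = "."))
  assert_columns(calls, call_table_columns, "call table")
  for (col in c("individual", "population", "group", "source_file", "flags")) {
    calls[[col]] <- as.character(calls[[col]])
  }
  calls$flags[is.na(calls$flags)] <- ""
  validate_call_table(calls)
  calls[order(calls$source_file, calls$onset_s), ]
}

interaction_behaviors <- list(
  agonistic = c("threat", "chase", "flight", "fight"),
  affiliative = c("allopreen", "contact_sit")
)

validate_interactions <- function(x) {
  assert_columns(x, c("date", "category", "behavior", "initiator",
                      "receiver", "winner"), "interaction table")
  bad_cat <- !x$category %in% names(interaction_behaviors)
  if (any(bad_cat)) {
    stop_vocaleff("unknown interaction category: ",
                  paste(unique(x$category[bad_cat]), collapse = ", "),
                  class = "vocaleff_validation_error")
  }
  ok_beh <- mapply(function(cat, beh) beh %in% interaction_behaviors[[cat]],
                   x$category, x$behavior)
  if (!all(ok_beh)) {
    stop_vocaleff("behavior/category mismatch in interaction table (e.g. ",
                  x$behavior[!ok_beh][1], " under ", x$category[!ok_beh][1], ")",
                  class = "vocaleff_validation_error")
  }
  if (any(x$initiator == x$receiver)) {
    stop_vocaleff("interaction with initiator == receiver",
                  class = "vocaleff_validation_error")
  }
  ago <- x$category == "agonistic"
  if (any(ago & (is.na(x$winner) | !(x$winner == x$initiator | x$winner == x$receiver)))) {
    stop_vocaleff("agonistic interaction whose winner is not one of the two parties",
                  class = "vocaleff_validation_error")
  }
  if (any(!ago & !is.na(x$winner))) {
    stop_vocaleff("affiliative interaction must not carry a winner",
                  class = "vocaleff_validation_error")
  }
  invisible(x)
}

#' Read / write focal-observation interaction logs
#'
#' Interaction logs record one dyadic event per row: CSV with header
#' `date`, `category` (`agonistic` or `affiliative`), `behavior`
#' (`threat`/`chase`/`flight`/`fight` for agonistic, `allopreen`/
#' `contact_sit` for affiliative), `initiator`, `receiver`, `winner`
#' (one of the two parties for agonistic events, where the loser is the
#' individual that retreated; empty for affiliative events). Rows
#' violating these rules raise a validation error.
#'
#' @param path File path.
#' @param interactions A validated interaction tibble.
#' @return `read_interactions()` returns a tibble sorted chronologically
#'   (ties keep input order).
#' @export
read_interactions <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         date = readr::col_date(),
                         .default = readr::col_character()
                       ))
  x$winner[!is.na(x$winner) & x$winner == ""] <- NA_character_
  validate_interactions(x)
  x[order(x$date), ]
}

#' @rdname read_interactions
#' @export
write_interactions <- function(interactions, path) {
  validate_interactions(interactions)
  readr::write_csv(interactions, path)
  invisible(path)
}

subspecies_levels <- c("carrion", "hooded", "hybrid")

validate_metadata <- function(meta) {
  assert_columns(meta, c("individual", "hatch_year", "sex", "subspecies",
                         "population"), "metadata table")
  if (any(!meta$sex %in% c("F", "M"))) {
    stop_vocaleff("unknown sex level: ",
                  paste(setdiff(unique(meta$sex), c("F", "M")), collapse = ", "),
                  class = "vocaleff_validation_error")
  }
  if (any(!meta$subspecies %in% subspecies_levels)) {
    stop_vocaleff("unknown subspecies level: ",
                  paste(setdiff(unique(meta$subspecies), subspecies_levels),
                        collapse = ", "),
                  class = "vocaleff_validation_error")
  }
  if (anyDuplicated(meta$individual)) {
    stop_vocaleff("duplicated individual in metadata",
                  class = "vocaleff_validation_error")
  }
  invisible(meta)
}

#' Read / write per-individual metadata
#'
#' Metadata is a CSV with header `individual`, `hatch_year` (integer,
#' empty when unknown), `sex` (`F`/`M`), `subspecies` (`carrion`,
#' `hooded` or `hybrid`), `population`, plus any extra columns (e.g.
#' `group`, `elo`, `csi`) preserved verbatim. Group membership over time
#' lives in a separate memberships table ([read_memberships()]).
#'
#' @param path File path.
#' @param meta A metadata tibble.
#' @export
read_metadata <- function(path) {
  meta <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta$individual <- as.character(meta$individual)
  meta$hatch_year <- as.integer(meta$hatch_year)
  validate_metadata(meta)
  meta
}

#' @rdname read_metadata
#' @export
write_metadata <- function(meta, path) {
  validate_metadata(meta)
  readr::write_csv(meta, path)
  invisible(path)
}

#' Read / write group-membership intervals
#'
#' One row per (individual, group, date range): CSV with header
#' `individual`, `group`, `date_start`, `date_end` (ISO dates,
#' `date_start <= date_end`). Used to enumerate co-housed dyads and to
#' derive group size at a recording date.
#'
#' @param path File path.
#' @param memberships A memberships tibble.
#' @export
read_memberships <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         individual = readr::col_character(),
                         group = readr::col_character(),
                         date_start = readr::col_date(),
                         date_end = readr::col_date()
                       ))
  if (any(m$date_start > m$date_end)) {
    stop_vocaleff("membership interval with date_start > date_end",
                  class = "vocaleff_validation_error")
  }
  m
}

#' @rdname read_memberships
#' @export
write_memberships <- function(memberships, path) {
  assert_columns(memberships, c("individual", "group", "date_start", "date_end"),
                 "memberships table")
  readr::write_csv(memberships, path)
  invisible(path)
}
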