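#' Quality flags carried on annotated calls
#'
#' Calls can be marked with one or more flags at ingest: `unknown_caller`
#' (the calling individual could not be identified), `overlapping` (the
#' call overlaps another call by the same individual on the same
#' recording), and `incomplete_context` (the surrounding sequence was not
#' captured in full). Flags are carried through segmentation; dropping
#' flagged material is the job of [apply_exclusions()].
#'
#' @format A character vector of the three recognised flag names.
#' @export
call_flags <- c("unknown_caller", "overlapping", "incomplete_context")

# flags are stored as a ";"-separated string, "" when clean
flag_has <- function(flags, flag) {
  !is.na(flags) & stringr::str_detect(flags, stringr::fixed(flag))
}

flag_add <- function(flags, flag, where = TRUE) {
  flags[is.na(flags)] <- ""
  add <- where & !flag_has(flags, flag)
  flags[add] <- ifelse(flags[add] == "", flag, paste(flags[add], flag, sep = ";"))
  flags
}

# strict numeric parsing: decimal point only, never locale-dependent
parse_seconds <- function(x) {
  x <- stringr::str_trim(x)
  bad <- stringr::str_detect(x, ",") | !stringr::str_detect(x, "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$")
  out <- suppressWarnings(as.numeric(x))
  out[bad] <- NA_real_
  out
}

stop_vocaleff <- function(..., class) {
  rlang::abort(paste0(...), class = c(class, "vocaleff_error"))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_vocaleff(
      what, " is missing required column(s): ", paste(missing, collapse = ", "),
      "; found: ", paste(names(df), collapse = ", "),
      class = "vocaleff_format_error"
    )
  }
  invisible(df)
}
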