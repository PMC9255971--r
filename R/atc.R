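#' WHO ATC classification: parsing, rollups and cohort annotation
#'
#' Full ATC codes have seven characters in five nested levels: anatomical main
#' group (1 letter), therapeutic subgroup (2 digits), pharmacological subgroup
#' (1 letter), chemical subgroup (1 letter), substance (2 digits), e.g.
#' C10AA05 = atorvastatin, with level-2 prefix C10 (lipid modifying agents).
#'
#' @name atc
NULL

ATC_PATTERN <- "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"
ATC_LEVEL_WIDTH <- c(1L, 3L, 4L, 5L, 7L)

#' Parse and validate ATC codes
#'
#' @param code character vector of 7-character ATC codes; case-insensitive.
#' @return the codes, uppercased, with class `atc_code`.
#' @examples
#' parse_atc("a10ba02")
#' @export
parse_atc <- function(code) {
  code <- toupper(trimws(as.character(code)))
  bad <- !grepl(ATC_PATTERN, code)
  if (any(bad)) {
    stop_("malformed ATC code(s): ",
          paste(unique(code[bad]), collapse = ", "))
  }
  structure(code, class = "atc_code")
}

#' Roll an ATC code up to a coarser level
#'
#' @param code character vector of valid 7-character ATC codes.
#' @param level integer 1-5; prefix widths are 1, 3, 4, 5 and 7 characters.
#' @return character vector of level prefixes.
#' @examples
#' atc_rollup("C10AA05", 2) # "C10"
#' @export
atc_rollup <- function(code, level) {
  if (length(level) != 1 || !level %in% 1:5) {
    stop_("ATC level must be a single integer in 1..5")
  }
  code <- unclass(parse_atc(code))
  substr(code, 1L, ATC_LEVEL_WIDTH[level])
}

#' Read a formulary table
#'
#' The formulary maps normalized generic names to one or more ATC codes;
#' `primary_index` (1-based) selects the code used for single-code rollups and
#' network node assignment.
#'
#' @param path CSV with columns `generic_name`, `atc_codes`
#'   (semicolon-separated) and `primary_index`.
#' @return data.frame of class `formulary` with list-column `atc_codes` and a
#'   `primary_code` column.
#' @export
read_formulary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  assert_cols(df, c("generic_name", "atc_codes", "primary_index"), "formulary")
  formulary(df$generic_name, strsplit(df$atc_codes, ";", fixed = TRUE),
            df$primary_index)
}

#' Construct a formulary
#'
#' @param generic_name character vector of generic names (normalized on entry).
#' @param atc_codes list of character vectors of ATC codes, one per generic.
#' @param primary_index 1-based index of the primary code within each entry.
#' @return data.frame of class `formulary`.
#' @export
formulary <- function(generic_name, atc_codes, primary_index = 1L) {
  generic_name <- normalize_name(generic_name)
  if (anyDuplicated(generic_name)) stop_("duplicate generic_name in formulary")
  atc_codes <- lapply(atc_codes, function(x) unclass(parse_atc(x)))
  primary_index <- rep_len(as.integer(primary_index), length(generic_name))
  ok <- mapply(function(codes, i) i >= 1 && i <= length(codes),
               atc_codes, primary_index)
  if (!all(ok)) {
    stop_("primary_index out of range for: ",
          paste(generic_name[!ok], collapse = ", "))
  }
  df <- data.frame(generic_name = generic_name,
                   primary_index = primary_index,
                   stringsAsFactors = FALSE)
  df$atc_codes <- atc_codes
  df$primary_code <- mapply(function(codes, i) codes[i],
                            atc_codes, primary_index)
  class(df) <- c("formulary", "data.frame")
  df
}

#' Write a formulary to CSV
#' @param fml a `formulary`.
#' @param path output path.
#' @export
write_formulary <- function(fml, path) {
  out <- data.frame(
    generic_name = fml$generic_name,
    atc_codes = vapply(fml$atc_codes, paste, character(1), collapse = ";"),
    primary_index = fml$primary_index,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Annotate regular medication occurrences with ATC classes
#'
#' Each regular-medication occurrence is annotated with its primary ATC code
#' and the level 1-3 prefixes. Occurrences whose generic is absent from the
#' formulary go to an unclassified report; they stay in medication counts but
#' are excluded from class tallies.
#'
#' @param cohort a `med_cohort`.
#' @param fml a `formulary`.
#' @return list of class `atc_annotation` with elements `annotated` (regular
#'   occurrences with `atc_code`, `atc_level1..3`) and `unclassified`
#'   (data.frame `generic_name`, `occurrence_count`).
#' @export
classify_cohort <- function(cohort, fml) {
  stopifnot(inherits(cohort, "med_cohort"), inherits(fml, "formulary"))
  reg <- cohort$meds[is_regular(cohort$meds), , drop = FALSE]
  idx <- match(reg$generic_name, fml$generic_name)
  reg$atc_code <- ifelse(is.na(idx), NA_character_, fml$primary_code[idx])
  hit <- !is.na(reg$atc_code)
  reg$atc_level1 <- reg$atc_level2 <- reg$atc_level3 <- NA_character_
  if (any(hit)) {
    reg$atc_level1[hit] <- atc_rollup(reg$atc_code[hit], 1)
    reg$atc_level2[hit] <- atc_rollup(reg$atc_code[hit], 2)
    reg$atc_level3[hit] <- atc_rollup(reg$atc_code[hit], 3)
  }
  un <- reg$generic_name[!hit]
  unclassified <- if (length(un) > 0) {
    tab <- sort(table(un), decreasing = TRUE)
    data.frame(generic_name = names(tab), occurrence_count = as.integer(tab),
               stringsAsFactors = FALSE)
  } else {
    data.frame(generic_name = character(0), occurrence_count = integer(0),
               stringsAsFactors = FALSE)
  }
  rownames(reg) <- NULL
  structure(list(annotated = reg, unclassified = unclassified),
            class = "atc_annotation")
}

#' Occurrence tallies by ATC class
#'
#' @param annotation an `atc_annotation` from [classify_cohort()].
#' @param level ATC level 1-3.
#' @return data.frame `atc_class`, `n_occurrences`, sorted by decreasing count.
#' @export
atc_tally <- function(annotation, level = 2) {
  stopifnot(inherits(annotation, "atc_annotation"), level %in% 1:3)
  col <- paste0("atc_level", level)
  cls <- annotation$annotated[[col]]
  cls <- cls[!is.na(cls)]
  tab <- sort(table(cls), decreasing = TRUE)
  data.frame(atc_class = names(tab), n_occurrences = as.integer(tab),
             stringsAsFactors = FALSE)
}
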