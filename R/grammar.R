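# ICD-10 code normalization and the exact / prefix / range pattern grammar
# used by curated diagnostic-group definitions.

# one letter, two digits, then up to four alphanumerics (dot already removed)
ICD10_REGEX <- "^[A-Z][0-9]{2}[A-Z0-9]{0,4}$"

# range separators seen in curated code lists: ASCII hyphen, U+2010 hyphen,
# U+2013 en dash
DASH_CLASS <- "[-‐–]"

#' Normalize a raw ICD-10 code
#'
#' Uppercases, strips the dot and any whitespace, and validates against the
#' ICD-10 grammar (one letter, two digits, up to four further alphanumeric
#' characters). Normalization is idempotent.
#'
#' @param raw Character vector of raw codes (dotted or undotted, any case).
#' @param strict If `TRUE` (default) malformed codes raise an error of class
#'   `caselogr_malformed_code`; if `FALSE` they become `NA`.
#' @return Character vector of normalized codes, e.g. `"Z00.129"` becomes
#'   `"Z00129"`.
#' @examples
#' normalize_code(c("Z00.129", "k5900"))
#' @export
normalize_code <- function(raw, strict = TRUE) {
  if (length(raw) == 0) return(character())
  out <- str_to_upper(str_replace_all(raw, "[.\\s]", ""))
  bad <- is.na(out) | !str_detect(out, ICD10_REGEX)
  if (any(bad)) {
    if (strict) {
      abort(
        sprintf(
          "Malformed ICD-10 code(s): %s",
          paste(unique(raw[bad]), collapse = ", ")
        ),
        class = "caselogr_malformed_code"
      )
    }
    out[bad] <- NA_character_
  }
  out
}

new_code_pattern <- function(kind, stem = NA_character_, low = NA_character_,
                             high = NA_character_, source_text) {
  structure(
    list(kind = kind, stem = stem, low = low, high = high,
         source_text = source_text),
    class = "code_pattern"
  )
}

#' @export
print.code_pattern <- function(x, ...) {
  body <- switch(x$kind,
    EXACT  = x$stem,
    PREFIX = paste0(x$stem, "*"),
    RANGE  = paste0(x$low, "–", x$high)
  )
  cat(sprintf("<code_pattern %s %s  [%s]>\n", x$kind, body, x$source_text))
  invisible(x)
}

# strip a trailing ".x"/".xx" wildcard (any case); dot may already be gone
strip_wildcard <- function(token) {
  str_replace_all(token, stringr::regex("\\.?x{1,2}$", ignore_case = TRUE), "")
}

#' Parse one diagnostic-group code token
#'
#' A token is a single comma-separated entry from a curated code list and is
#' one of three things: an exact code (`"R62.51"`, `"N39"`), a category
#' prefix written with an `.xx`/`.x` wildcard (`"K59.xx"`), or a range
#' (`"D50-D64"`, `"Z68.51-Z68.54"`). In a range, a `.xx` suffix on an
#' endpoint is dropped and a second endpoint written without its letter
#' (`"F90.0-90.2"`) inherits the first endpoint's letter. Both the ASCII
#' hyphen and typographic dashes separate range endpoints.
#'
#' @param token A single code token (length-1 character).
#' @return A `code_pattern` with fields `kind` (`"EXACT"`, `"PREFIX"` or
#'   `"RANGE"`), `stem` (exact/prefix), `low`/`high` (range endpoints,
#'   normalized) and `source_text`.
#' @examples
#' parse_pattern("K59.xx")
#' parse_pattern("D50-D64")
#' @export
parse_pattern <- function(token) {
  stopifnot(is.character(token), length(token) == 1)
  tok <- str_trim(token)
  if (!nzchar(tok)) {
    abort("Empty pattern token", class = "caselogr_malformed_pattern")
  }
  malformed <- function(msg) {
    abort(sprintf("Malformed pattern %s: %s", encodeString(token, quote = '"'), msg),
          class = "caselogr_malformed_pattern")
  }

  if (str_detect(tok, DASH_CLASS)) {
    ends <- str_trim(str_split_1(tok, DASH_CLASS))
    if (length(ends) != 2 || !all(nzchar(ends))) {
      malformed("a range needs exactly two endpoints")
    }
    ends <- strip_wildcard(ends)
    # letterless second endpoint inherits the first endpoint's letter
    if (str_detect(ends[2], "^[0-9]")) {
      ends[2] <- paste0(str_sub(ends[1], 1, 1), ends[2])
    }
    norm <- tryCatch(normalize_code(ends),
                     caselogr_malformed_code = function(e) malformed(conditionMessage(e)))
    if (norm[1] > norm[2]) {
      malformed(sprintf("inverted range (%s > %s)", norm[1], norm[2]))
    }
    return(new_code_pattern("RANGE", low = norm[1], high = norm[2],
                            source_text = token))
  }

  if (str_detect(tok, stringr::regex("\\.?x{1,2}$", ignore_case = TRUE)) &&
      !str_detect(tok, "^[A-Za-z][0-9]")) {
    malformed("wildcard with no category stem")
  }
  if (str_detect(tok, stringr::regex("\\.?x{1,2}$", ignore_case = TRUE))) {
    stem <- tryCatch(normalize_code(strip_wildcard(tok)),
                     caselogr_malformed_code = function(e) malformed(conditionMessage(e)))
    if (str_length(stem) < 3) malformed("prefix stem shorter than 3 characters")
    return(new_code_pattern("PREFIX", stem = stem, source_text = token))
  }

  stem <- tryCatch(normalize_code(tok),
                   caselogr_malformed_code = function(e) malformed(conditionMessage(e)))
  new_code_pattern("EXACT", stem = stem, source_text = token)
}

#' Test codes against a code pattern
#'
#' Matching semantics: `EXACT` is string equality; `PREFIX` is a
#' starts-with test; `RANGE` truncates the code to the length of each
#' endpoint and requires the truncation to be `>=` the low endpoint and
#' `<=` the high endpoint (lexicographically), so `"D50-D64"` admits every
#' subcode of D50 through D64.
#'
#' @param pattern A `code_pattern` from [parse_pattern()].
#' @param codes Character vector of normalized codes (see [normalize_code()]).
#' @return Logical vector, one element per code.
#' @examples
#' code_matches(parse_pattern("D50-D64"), c("D509", "D65"))
#' @export
code_matches <- function(pattern, codes) {
  stopifnot(inherits(pattern, "code_pattern"))
  if (length(codes) == 0) return(logical())
  switch(pattern$kind,
    EXACT  = codes == pattern$stem,
    PREFIX = str_starts(codes, stringr::fixed(pattern$stem)),
    RANGE  = {
      lo <- pattern$low
      hi <- pattern$high
      str_sub(codes, 1, str_length(lo)) >= lo &
        str_sub(codes, 1, str_length(hi)) <= hi
    }
  )
}

#' Deterministically enumerate sample codes satisfying a pattern
#'
#' Generates up to `k` grammar-valid codes that each satisfy
#' [code_matches()]. Used to seed the synthetic encounter generator and to
#' cross-check the matcher. For `EXACT` patterns the single code is
#' returned regardless of `k`.
#'
#' @param pattern A `code_pattern`.
#' @param k Number of samples requested (`>= 1`).
#' @return Character vector of normalized codes (length `min(k, available)`;
#'   always `>= 1`).
#' @export
enumerate_samples <- function(pattern, k = 5) {
  stopifnot(inherits(pattern, "code_pattern"), k >= 1)
  if (pattern$kind == "EXACT") return(pattern$stem)

  if (pattern$kind == "PREFIX") {
    stem <- pattern$stem
    pool <- c(stem[str_detect(stem, ICD10_REGEX)],
              paste0(stem, 0:9),
              as.vector(t(outer(paste0(stem, 0:9), 0:9, paste0))))
    pool <- pool[str_length(pool) <= 7]
  } else {
    letter <- str_sub(pattern$low, 1, 1)
    cats <- paste0(letter, str_pad(0:99, 2, pad = "0"))
    lvl4 <- as.vector(outer(cats, 0:9, paste0))
    lvl5 <- as.vector(outer(lvl4, 0:9, paste0))
    pool <- c(cats, lvl4, lvl5)
  }
  hits <- pool[code_matches(pattern, pool)]
  if (length(hits) == 0) {
    abort(sprintf("No valid code satisfies pattern %s", pattern$source_text),
          class = "caselogr_unsatisfiable_pattern")
  }
  head(hits, k)
}
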