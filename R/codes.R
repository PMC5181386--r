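#' Parse an RCGP morbidity code-range specification
#'
#' Chronic-disease status is flagged from Royal College of General
#' Practitioners (RCGP) morbidity codes. The qualifying codes are written as a
#' comma-separated list of 4-digit codes and inclusive ranges, optionally with
#' parenthesised exclusions attached to a range, e.g.
#' `"0400-0540 (excluding 0455), 0720, 2490-2510"`.
#'
#' @param spec Character scalar with the code-range specification. En dashes
#'   are accepted in place of hyphens.
#' @return An object of class `rcgp_code_set`: a membership table over 4-digit
#'   codes with `$contains(codes)` semantics via [codes_in_set()].
#' @examples
#' s <- parse_code_ranges("0400-0540 (excluding 0455), 0720")
#' codes_in_set(c("0400", "0455", "0720", "0001"), s)
#' @export
parse_code_ranges <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  txt <- gsub("–|—", "-", spec)
  # split on commas that are not inside an "(excluding ...)" group
  tokens <- character(0)
  depth <- 0L
  buf <- ""
  for (ch in strsplit(txt, "")[[1]]) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == "," && depth == 0L) {
      tokens <- c(tokens, buf)
      buf <- ""
    } else {
      buf <- paste0(buf, ch)
    }
  }
  tokens <- trimws(c(tokens, buf))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop("empty code-range specification", call. = FALSE)

  parse_code <- function(code, token) {
    if (!grepl("^[0-9]{4}$", code)) {
      stop(sprintf("malformed RCGP code '%s' in token '%s': codes must be 4 digits",
                   code, token), call. = FALSE)
    }
    as.integer(code)
  }

  lo <- integer(0); hi <- integer(0); excl <- integer(0)
  for (token in tokens) {
    body <- token
    m <- regmatches(token, regexec("\\(\\s*excluding\\s+([^)]*)\\)", token, ignore.case = TRUE))[[1]]
    if (length(m) == 2L) {
      excl_codes <- trimws(strsplit(m[2], ",")[[1]])
      excl <- c(excl, vapply(excl_codes, parse_code, integer(1), token = token))
      body <- trimws(sub("\\(\\s*excluding\\s+[^)]*\\)", "", token, ignore.case = TRUE))
    } else if (grepl("\\(", token)) {
      stop(sprintf("malformed token '%s'", token), call. = FALSE)
    }
    parts <- trimws(strsplit(body, "-")[[1]])
    if (length(parts) == 1L) {
      code <- parse_code(parts[1], token)
      lo <- c(lo, code); hi <- c(hi, code)
    } else if (length(parts) == 2L) {
      a <- parse_code(parts[1], token); b <- parse_code(parts[2], token)
      if (a > b) stop(sprintf("range '%s' has lower bound above upper bound", token), call. = FALSE)
      lo <- c(lo, a); hi <- c(hi, b)
    } else {
      stop(sprintf("malformed token '%s'", token), call. = FALSE)
    }
  }
  structure(list(lo = lo, hi = hi, exclude = unique(excl), spec = spec),
            class = "rcgp_code_set")
}

#' @export
print.rcgp_code_set <- function(x, ...) {
  cat("<rcgp_code_set> ", length(x$lo), " range(s), ",
      length(x$exclude), " exclusion(s)\n", sep = "")
  invisible(x)
}

#' Test membership of codes in a parsed code set
#'
#' @param codes Character vector of 4-digit codes.
#' @param set An `rcgp_code_set` from [parse_code_ranges()].
#' @return Logical vector: is each code in the (range minus exclusions) set?
#' @export
codes_in_set <- function(codes, set) {
  stopifnot(inherits(set, "rcgp_code_set"))
  if (length(codes) == 0L) return(logical(0))
  bad <- !grepl("^[0-9]{4}$", codes)
  if (any(bad)) {
    stop(sprintf("malformed RCGP code '%s': codes must be 4 digits",
                 codes[bad][1]), call. = FALSE)
  }
  v <- as.integer(codes)
  inside <- vapply(v, function(code) any(code >= set$lo & code <= set$hi), logical(1))
  inside & !(v %in% set$exclude)
}

#' Qualifying chronic-disease code ranges
#'
#' The default RCGP code set flagging the seven common age-associated chronic
#' diseases (coronary heart disease, stroke, chronic obstructive pulmonary
#' disease, cancer excluding skin, diabetes, Parkinson's disease, serious
#' mental health problems).
#'
#' @return An `rcgp_code_set`.
#' @export
disease_code_set <- function() {
  parse_code_ranges(paste(
    "0400-0540 (excluding 0455), 0720, 1000, 1015-1030, 1205, 1315,",
    "1940-1950, 2100-2115, 2420, 2490-2510"
  ))
}

#' Classify absence of chronic disease from RCGP codes
#'
#' @param rcgp_codes Either a character vector of codes for one respondent, or
#'   a semicolon-delimited string as stored in the participant CSV (empty
#'   string = no codes). `NA` means the code list is missing.
#' @param set Code set from [parse_code_ranges()]; defaults to
#'   [disease_code_set()].
#' @return `TRUE` if no code falls in the qualifying set, `FALSE` otherwise,
#'   `NA` if the code list is missing.
#' @export
classify_disease_free <- function(rcgp_codes, set = disease_code_set()) {
  if (length(rcgp_codes) == 1L && is.na(rcgp_codes)) return(NA)
  if (length(rcgp_codes) == 1L && is.character(rcgp_codes) && grepl(";", rcgp_codes)) {
    rcgp_codes <- strsplit(rcgp_codes, ";", fixed = TRUE)[[1]]
  }
  rcgp_codes <- trimws(rcgp_codes)
  rcgp_codes <- rcgp_codes[nzchar(rcgp_codes)]
  if (length(rcgp_codes) == 0L) return(TRUE)
  !any(codes_in_set(rcgp_codes, set))
}
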