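#' Temporary allele nomenclature
#'
#' Before an immunoglobulin or T-cell receptor allele is formally ratified and
#' named, it can be issued a temporary label of the form
#' `<locus><type><subgroup>-<identifier>*<allele>`, e.g. `IGHV0-A5B2*00`.
#' The subgroup and allele designator hold null values (`"0"` and `"00"`)
#' until specific values are assigned. The identifier is a random 20-bit
#' value rendered as 4 characters of the RFC 4648 section 6 base32 alphabet
#' (upper-case letters A-Z followed by digits 2-7; the digits 0, 1, 8 and 9
#' do not occur), giving 32^4 = 1,048,576 reasonably memorable combinations.
#'
#' @name nomenclature
NULL

GK_LOCI <- c("IGH", "IGK", "IGL", "TRA", "TRB", "TRG", "TRD")
GK_SEQUENCE_TYPES <- c("V", "D", "J")

#' The temporary-identifier alphabet
#'
#' @return Character vector of the 32 symbols of the RFC 4648 section 6
#'   base32 alphabet, in encoding order: `A`-`Z` then `2`-`7`.
#' @examples
#' identifier_alphabet()[1]   # "A"
#' identifier_alphabet()[32]  # "7"
#' @export
identifier_alphabet <- function() {
  c(LETTERS, as.character(2:7))
}

#' Encode a 20-bit value as a 4-character temporary identifier
#'
#' The value is split into four 5-bit groups, most-significant group first,
#' and each group is mapped through [identifier_alphabet()].
#'
#' @param value Integer vector, each element in `[0, 1048575]`.
#' @return Character vector of 4-character identifiers.
#' @examples
#' encode_identifier(0)        # "AAAA"
#' encode_identifier(29754)    # "A5B2"
#' encode_identifier(1048575)  # "7777"
#' @export
encode_identifier <- function(value) {
  if (!is.numeric(value) || anyNA(value) || any(value != trunc(value))) {
    stop("value must be a whole number", call. = FALSE)
  }
  value <- as.double(value)
  if (any(value < 0 | value > 1048575)) {
    stop("value out of range: identifiers encode 20-bit values in [0, 1048575]",
         call. = FALSE)
  }
  alpha <- identifier_alphabet()
  g1 <- value %/% 32768          # 32^3
  g2 <- (value %/% 1024) %% 32   # 32^2
  g3 <- (value %/% 32) %% 32
  g4 <- value %% 32
  paste0(alpha[g1 + 1L], alpha[g2 + 1L], alpha[g3 + 1L], alpha[g4 + 1L])
}

#' Decode a 4-character temporary identifier to its 20-bit value
#'
#' Inverse of [encode_identifier()].
#'
#' @param s Character vector of 4-character identifiers over the alphabet
#'   `[A-Z2-7]`.
#' @return Integer vector of decoded values.
#' @examples
#' decode_identifier("AAAA")  # 0
#' decode_identifier("A5B2")  # 29754
#' @export
decode_identifier <- function(s) {
  if (!is.character(s) || anyNA(s)) stop("s must be a character vector", call. = FALSE)
  bad_len <- nchar(s) != 4L
  if (any(bad_len)) {
    stop(sprintf("identifier '%s' must be exactly 4 characters", s[bad_len][1]),
         call. = FALSE)
  }
  alpha <- identifier_alphabet()
  chars <- matrix(unlist(strsplit(s, "", fixed = TRUE)), nrow = 4L)
  idx <- match(chars, alpha)
  if (anyNA(idx)) {
    offending <- chars[is.na(idx)][1]
    stop(sprintf(
      "invalid identifier character '%s': allowed symbols are A-Z and 2-7 (digits 0, 1, 8 and 9 are omitted)",
      offending), call. = FALSE)
  }
  idx <- matrix(idx - 1L, nrow = 4L)
  as.integer(idx[1, ] * 32768 + idx[2, ] * 1024 + idx[3, ] * 32 + idx[4, ])
}

is_valid_identifier <- function(s) {
  is.character(s) & !is.na(s) & grepl("^[A-Z2-7]{4}$", s)
}

#' Construct a temporary label
#'
#' @param locus One of `IGH`, `IGK`, `IGL`, `TRA`, `TRB`, `TRG`, `TRD`.
#' @param sequence_type One of `V`, `D`, `J`.
#' @param subgroup Subgroup designator; `"0"` (the null value) until assigned.
#' @param identifier 4-character identifier over `[A-Z2-7]`.
#' @param allele Two-digit allele designator; `"00"` (the null value) until
#'   assigned.
#' @return An object of class `temp_label`.
#' @export
temp_label <- function(locus, sequence_type, subgroup = "0", identifier,
                       allele = "00") {
  locus <- match.arg(locus, GK_LOCI)
  sequence_type <- match.arg(sequence_type, GK_SEQUENCE_TYPES)
  if (!is_valid_identifier(identifier)) {
    stop(sprintf("invalid identifier '%s': must match [A-Z2-7]{4}", identifier),
         call. = FALSE)
  }
  if (!grepl("^[0-9]{2}$", allele)) {
    stop(sprintf("invalid allele designator '%s': must be two digits", allele),
         call. = FALSE)
  }
  if (!is.character(subgroup) || length(subgroup) != 1L || !nzchar(subgroup) ||
      grepl("[-*]", subgroup)) {
    stop("subgroup must be a non-empty string without '-' or '*'", call. = FALSE)
  }
  structure(
    list(locus = locus, sequence_type = sequence_type, subgroup = subgroup,
         identifier = identifier, allele = allele),
    class = "temp_label")
}

#' Format a temporary label as a string
#'
#' @param t A [temp_label()].
#' @return The label string, e.g. `"IGHV0-A5B2*00"`.
#' @export
format_label <- function(t) {
  if (!inherits(t, "temp_label")) stop("t must be a temp_label", call. = FALSE)
  paste0(t$locus, t$sequence_type, t$subgroup, "-", t$identifier, "*", t$allele)
}

#' @export
format.temp_label <- function(x, ...) format_label(x)

#' @export
print.temp_label <- function(x, ...) {
  cat("<temporary label> ", format_label(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.legacy_label <- function(x, ...) x$raw

#' @export
print.legacy_label <- function(x, ...) {
  cat("<legacy label> ", x$raw, "\n", sep = "")
  invisible(x)
}

#' Null-valued temporary label for a fresh identifier
#'
#' Subgroup and allele designator take their null values (`"0"`, `"00"`)
#' until specific values are determined and assigned.
#'
#' @inheritParams temp_label
#' @return A [temp_label()] with subgroup `"0"` and allele `"00"`.
#' @examples
#' format_label(null_label_for("IGH", "V", "A5B2"))  # "IGHV0-A5B2*00"
#' @export
null_label_for <- function(locus, sequence_type, identifier) {
  temp_label(locus, sequence_type, subgroup = "0", identifier = identifier,
             allele = "00")
}

#' Parse an allele label
#'
#' Strings matching the temporary-label template with a valid 4-character
#' identifier are returned as `temp_label` objects. Other well-formed
#' `gene*allele` strings starting with a recognised locus are returned as
#' `legacy_label` objects carrying the raw string plus best-effort locus and
#' sequence type. Labels are upper-case; lower-case input is upper-cased with
#' a warning. A label is classified temporary only when its identifier field
#' matches `[A-Z2-7]{4}` and either contains at least one letter or the
#' subgroup and allele designators hold their null values: all-digit
#' identifiers such as `"2345"` are otherwise visually ambiguous with
#' ratified gene numbers and are treated as legacy.
#'
#' @param s A single label string.
#' @return A `temp_label` or `legacy_label` object.
#' @examples
#' parse_label("IGHV0-A5B2*00")  # temporary
#' parse_label("IGHV2-118*01")   # legacy: identifier contains excluded digits
#' @export
parse_label <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s)) {
    stop("cannot parse an empty label", call. = FALSE)
  }
  if (s != toupper(s)) {
    warning(sprintf("label '%s' upper-cased for parsing", s), call. = FALSE)
    s <- toupper(s)
  }
  locus <- substr(s, 1, 3)
  if (!locus %in% GK_LOCI) {
    stop(sprintf("label '%s' has no recognised locus prefix (%s)",
                 s, paste(GK_LOCI, collapse = ", ")), call. = FALSE)
  }
  rest <- substr(s, 4, nchar(s))
  seqtype <- substr(rest, 1, 1)
  if (!seqtype %in% GK_SEQUENCE_TYPES) seqtype <- NA_character_
  m <- regmatches(s, regexec(
    "^([A-Z]{3})([VDJ])([^-*]*)-([^-*]+)\\*([0-9]{2})$", s))[[1]]
  if (length(m)) {
    subgroup <- m[4]
    identifier <- m[5]
    allele <- m[6]
    looks_temp <- grepl("^[A-Z2-7]{4}$", identifier) &&
      (grepl("[A-Z]", identifier) || (subgroup == "0" && allele == "00"))
    if (looks_temp) {
      if (!nzchar(subgroup)) subgroup <- "0"
      return(temp_label(m[2], m[3], subgroup = subgroup,
                        identifier = identifier, allele = allele))
    }
  }
  if (!grepl("\\*", s)) {
    stop(sprintf("label '%s' is neither a temporary label nor a gene*allele string",
                 s), call. = FALSE)
  }
  structure(list(raw = s, locus = locus, sequence_type = seqtype),
            class = "legacy_label")
}

is_parseable_label <- function(s) {
  !inherits(try(suppressWarnings(parse_label(s)), silent = TRUE), "try-error")
}
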