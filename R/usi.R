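#' Parse a Universal Spectrum Identifier (USI)
#'
#' Splits a `mzspec:`-prefixed USI into its parts: collection (repository
#' accession), run (file name), index type (`scan`, `index` or `nativeId`),
#' index value, and an optional trailing interpretation segment (which may
#' itself contain `:`). [serialize_usi()] is the exact inverse:
#' `serialize_usi(parse_usi(u))` reproduces `u` byte for byte.
#'
#' @param usi a USI string, e.g. `"mzspec:MSV000086989:somefile:scan:123"`.
#' @return A list of class `usi_parts` with fields `collection`, `run`,
#'   `index_type`, `index_value`, `interpretation` (`NA` if absent).
#' @export
parse_usi <- function(usi) {
  stopifnot(is.character(usi), length(usi) == 1L)
  parts <- strsplit(usi, ":", fixed = TRUE)[[1L]]
  if (length(parts) < 5L || parts[1L] != "mzspec") {
    abort(sprintf("not a valid USI (need 'mzspec:collection:run:indexType:index'): '%s'", usi),
          "spectax_usi_error")
  }
  if (!parts[4L] %in% c("scan", "index", "nativeId")) {
    abort(sprintf("USI index type must be scan/index/nativeId, got '%s'", parts[4L]),
          "spectax_usi_error")
  }
  structure(
    list(
      collection = parts[2L],
      run = parts[3L],
      index_type = parts[4L],
      index_value = parts[5L],
      interpretation = if (length(parts) > 5L) {
        paste(parts[-(1:5)], collapse = ":")
      } else NA_character_
    ),
    class = "usi_parts"
  )
}

#' @rdname parse_usi
#' @param parts a `usi_parts` object.
#' @export
serialize_usi <- function(parts) {
  stopifnot(inherits(parts, "usi_parts"))
  base <- paste("mzspec", parts$collection, parts$run, parts$index_type,
                parts$index_value, sep = ":")
  if (!is.na(parts$interpretation)) {
    base <- paste(base, parts$interpretation, sep = ":")
  }
  base
}

#' @export
print.usi_parts <- function(x, ...) {
  cat("<usi>", serialize_usi(x), "\n")
  invisible(x)
}
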