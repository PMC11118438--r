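`%||%` <- function(x, y) if (is.null(x)) y else x

# classed conditions so callers can distinguish parse/schema/empty errors
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "spectax_error")))
}

# per-stage RNG seeds derived from one master seed; kept below 2^31 so they
# are valid R integer seeds on all platforms
stage_seed <- function(master, stage) {
  offsets <- c(taxonomy = 1, library = 2, queries = 3, fuzz = 4)
  if (!stage %in% names(offsets)) stop("unknown RNG stage: ", stage)
  as.integer((as.numeric(master) + offsets[[stage]] * 1000003) %% 2147483629)
}

is_truthy <- function(x) {
  tolower(trimws(as.character(x))) %in% c("yes", "true", "1")
}
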