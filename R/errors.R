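# Condition system: every package error is a classed condition inheriting from
# "caro_error" so the CLI can map data errors to exit code 2 without matching
# on message text. `token`/`offset`/`line` travel as condition fields.

abort_caro <- function(class, message, ..., call = NULL) {
  rlang::abort(message, class = c(paste0("caro_", class), "caro_error"), ...)
}

stop_unknown_keyword <- function(token, offset = NA_integer_) {
  abort_caro(
    "unknown_keyword",
    sprintf("Unknown keyword '%s'%s", token,
            if (is.na(offset)) "" else sprintf(" at offset %d", offset)),
    token = token, offset = offset
  )
}

stop_unknown_token <- function(token, line = NA_integer_) {
  abort_caro(
    "unknown_token",
    sprintf("Unknown fingerprint token '%s'%s", token,
            if (is.na(line)) "" else sprintf(" (line %d)", line)),
    token = token, line = line
  )
}

stop_invalid_locant <- function(token) {
  abort_caro("invalid_locant",
             sprintf("Invalid locant '%s': positions must be 1-20", token),
             token = token)
}
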