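# internal helpers shared across modules

# stop with a classed condition so callers can discriminate error families
stop_spheroscreen <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "spheroscreen_error"), ...)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0 && x == as.integer(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

# "A1" -> c(row = 0, col = 0); rows are letters (A = 0), columns 1-based digits
parse_well_name <- function(well) {
  m <- regmatches(well, regexec("^([A-Za-z])([0-9]+)$", well))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop_spheroscreen(
      sprintf("malformed well name(s): %s", paste(well[bad], collapse = ", ")),
      "spheroscreen_validation_error"
    )
  }
  row <- match(toupper(vapply(m, `[`, "", 2L)), LETTERS) - 1L
  col <- as.integer(vapply(m, `[`, "", 3L)) - 1L
  if (any(col < 0L)) {
    stop_spheroscreen("well column index must be >= 1", "spheroscreen_validation_error")
  }
  list(row = row, col = col)
}

well_name <- function(row, col) paste0(LETTERS[row + 1L], col + 1L)

# deterministic integer substream seeds derived from one master seed
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}
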