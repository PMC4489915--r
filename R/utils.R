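# internal helpers ----------------------------------------------------------

stop_ss <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# scalar type checks; all validators funnel through these so error text is
# uniform and testable
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_ss("'%s' must be a single finite number", name)
  if (strict_lower && x <= lower)
    stop_ss("'%s' must be > %s (got %s)", name, lower, x)
  if (!strict_lower && x < lower)
    stop_ss("'%s' must be >= %s (got %s)", name, lower, x)
  if (strict_upper && x >= upper)
    stop_ss("'%s' must be < %s (got %s)", name, upper, x)
  if (!strict_upper && x > upper)
    stop_ss("'%s' must be <= %s (got %s)", name, upper, x)
  x
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_ss("'%s' must be TRUE or FALSE", name)
  x
}

check_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop_ss("'%s' must be a non-empty string", name)
  x
}

# numbers are written with full double precision so that values stated to a
# few decimals round-trip exactly through the TSV writers
format_num <- function(x) {
  # element-wise so one value's width never pads its neighbours
  vapply(x, function(v) format(v, digits = 15, scientific = FALSE,
                               trim = TRUE), character(1))
}

write_tsv_ss <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_ss <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
}
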