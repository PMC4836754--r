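#' @keywords internal
poleage_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "poleage_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' @keywords internal
poleage_warn <- function(class, msg) {
  warning(structure(
    class = c(class, "poleage_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# split a ";"-separated numeric field (individuals CSV)
#' @keywords internal
split_semi <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(v) {
    v <- v[nzchar(v)]
    as.numeric(v)
  })
}

#' @keywords internal
join_semi <- function(x) {
  vapply(x, function(v) paste(format(v, trim = TRUE, scientific = FALSE), collapse = ";"), "")
}
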