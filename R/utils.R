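# Internal helpers shared across modules.

#' Nine-class label order
#'
#' Canonical ordering of the nine patch classes: the three breakup
#' morphologies first (area, spot, line), then the six non-breakup classes.
#' All confusion matrices, model heads and tile tallies use this order.
#'
#' @return Character vector of length nine.
#' @export
tbd_classes <- function() {
  c("area", "spot", "line",
    "uniform", "interference_fringe", "bright_reflection",
    "particle", "eyelash", "eyelid")
}

#' Breakup class labels
#'
#' @return The three positive-class labels.
#' @export
tbd_breakup_classes <- function() c("area", "spot", "line")

clamp01 <- function(x) pmin(pmax(x, 0), 1)

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible substream seed below 2^31 from a master seed and a
# stage name, so pipeline stages can be rerun independently.
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 17) %% 2147483647)
}

# Resolve relative file references against a base directory; empty and
# absolute entries pass through.
resolve_paths <- function(p, base) {
  rel <- p != "" & !grepl("^(/|[A-Za-z]:)", p)
  p[rel] <- file.path(base, p[rel])
  p
}

is_rgb_array <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L

assert_rgb <- function(x, what = "image") {
  if (!is_rgb_array(x)) stop_invalid("%s must be an H x W x 3 numeric array", what)
  invisible(x)
}

# Deterministic JSON writer used for all reports: fixed key order as given,
# full precision, no timestamps, trailing newline.
write_report_json <- function(x, path) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                          na = "null")
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}
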