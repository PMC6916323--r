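# shared helpers: UIDs, hashing, logging

.UID_ROOT <- "1.2.826.0.1.3680043.10.1594"

# small deterministic string hash (polynomial, 31-bit); the multiplier keeps
# every intermediate below 2^53 so double arithmetic stays exact
str_hash <- function(s) {
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 1000003 + b) %% 2147483647
  as.integer(h)
}

# Deterministic UID factory: every UID is derived from a scope string and a
# counter so re-running the same generation yields byte-identical files.
uid_factory <- function(scope, seed) {
  base <- paste0(.UID_ROOT, ".", str_hash(paste0(scope, ":", seed)))
  counter <- 0L
  function() {
    counter <<- counter + 1L
    paste0(base, ".", counter)
  }
}

.radsem_log_level <- new.env(parent = emptyenv())
.radsem_log_level$level <- "info"

.LOG_LEVELS <- c(debug = 1L, info = 2L, warning = 3L, error = 4L)

#' Set the logging threshold
#'
#' @param level one of "debug", "info", "warning", "error"
#' @return previous level, invisibly
#' @export
set_log_level <- function(level = c("info", "debug", "warning", "error")) {
  level <- match.arg(level)
  old <- .radsem_log_level$level
  .radsem_log_level$level <- level
  invisible(old)
}

rs_log <- function(level, ..., case = NULL, stage = NULL) {
  if (.LOG_LEVELS[[level]] < .LOG_LEVELS[[.radsem_log_level$level]]) return(invisible())
  parts <- c(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), toupper(level),
             if (!is.null(case)) paste0("case=", case),
             if (!is.null(stage)) paste0("stage=", stage),
             paste0(...))
  message(paste(parts, collapse = " "))
  invisible()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
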