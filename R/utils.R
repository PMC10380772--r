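# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom data.table data.table as.data.table setDT setkey setorder rbindlist
#' @importFrom data.table fread fwrite := .N .SD setnames copy dcast uniqueN setattr
#' @importFrom utils head
NULL

# round-half-up: base round() is banker's rounding, which would make window
# boundaries depend on parity of the fractional part
round_half_up <- function(x) floor(x + 0.5)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# derive a child seed from a base seed and a stage label, kept < 2^31
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  (as.integer(seed) * 1000L + as.integer(h %% 997L)) %% 2147483647L
}

AS_EVENT_TYPES <- c("SE", "A5SS", "A3SS", "MXE", "RI")
METH_CONTEXTS <- c("CpG", "CHG", "CHH")
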