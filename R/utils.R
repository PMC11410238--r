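# Shared internal helpers.

.datatable.aware <- TRUE # data.table used via :: with [.data.table syntax

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Derive an operation-local random seed
#'
#' Each stochastic operation draws from its own generator, seeded from the
#' top-level seed, the operation name and an ordinal. Modules can therefore be
#' rerun independently and still reproduce the same output byte for byte.
#'
#' @param seed top-level integer seed.
#' @param op operation name (character scalar).
#' @param ordinal ordinal of the invocation within the operation (>= 1).
#' @return an integer seed in [1, 2^31 - 1].
#' @export
derive_seed <- function(seed, op, ordinal = 1L) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_bad("seed must be a single number")
  if (!is.character(op) || length(op) != 1L)
    stop_bad("op must be a character scalar")
  m <- 2147483647 # 2^31 - 1, Mersenne prime; all arithmetic exact in doubles
  h <- 0
  for (ch in utf8ToInt(op)) h <- (h * 131 + ch) %% m
  v <- (abs(as.numeric(seed)) %% m)
  v <- (v * 48271 + h * 69621 + as.numeric(ordinal) * 16807 + 1) %% m
  as.integer(v) + 1L
}

# check a set of half-open intervals [start, start+length) for overlap
.intervals_overlap <- function(start, len) {
  if (length(start) < 2L) return(FALSE)
  o <- order(start)
  s <- start[o]; e <- start[o] + len[o]
  any(s[-1L] < e[-length(e)])
}

# overlap (1-based inclusive intervals) between one interval and a table
.overlaps_any <- function(chrom, start, end, tab) {
  if (is.null(tab) || nrow(tab) == 0L) return(FALSE)
  hit <- tab$chrom == chrom & tab$start <= end & tab$end >= start
  any(hit)
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

.is_fraction <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x <= 1
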