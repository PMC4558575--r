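# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Derive a stage seed from a master seed
#'
#' Deterministically fans a single run seed out to per-stage seeds so that
#' independent pipeline stages draw from unrelated streams while the whole
#' run stays reproducible from one integer. Results stay within 32-bit
#' integer range.
#'
#' @param master integer master seed.
#' @param offset integer stage offset (>= 0).
#' @return an integer seed.
#' @export
stage_seed <- function(master, offset) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(offset), length(offset) == 1L)
  as.integer((abs(as.numeric(master)) * 1000003 + 7919 * as.numeric(offset) + 17) %%
               (.Machine$integer.max - 1)) + 1L
}

# format a branch length compactly but losslessly enough for round trips
.fmt_len <- function(x) sprintf("%.12g", x)
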