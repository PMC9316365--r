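#' @importFrom rlang .data abort warn `%||%`
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# round-half-up to nearest integer (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

#' Build residue keys from chain, residue number and insertion code
#'
#' Residue identity throughout the package is the triple
#' (chain, residue number, insertion code), taken verbatim from the
#' coordinate file. The key is the `:`-joined string form used wherever a
#' flat identifier is convenient (set operations on pose interfaces,
#' ordered score vectors).
#'
#' @param chain character chain identifiers.
#' @param resno integer residue numbers.
#' @param icode insertion codes; `""` or `NA` for none.
#' @return character vector of keys, one per residue.
#' @export
residue_key <- function(chain, resno, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste(chain, resno, icode, sep = ":")
}

# all sources of randomness flow through here so that a single master seed
# reproduces a run; substreams are named to decouple stages
substream_seed <- function(seed, stream) {
  h <- digest::digest2int(paste0(stream, ":", seed))
  # keep within the positive 32-bit integer range expected by set.seed
  abs(h %% 2147483586L) + 1L
}

with_substream <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  force(code)
}

stopifnot_binary <- function(x, what) {
  if (!all(x %in% c(0L, 1L))) {
    abort(sprintf("`%s` must contain only 0/1 values", what))
  }
}
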