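#' Round half away from zero
#'
#' Plain decimal rounding (half-up), as used in report tables; base
#' `round()` rounds half to even, which does not match conventional
#' percentage reporting.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 2L) {
    m <- 10^digits
    # epsilon guards against values like 70.585 stored as 70.58499...
    sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

#' Report a proportion as a percentage
#'
#' @param p proportion in [0, 1].
#' @param digits decimal places (default 2, half-up).
#' @return percentage value.
#' @export
percentValue <- function(p, digits = 2L) roundHalfUp(100 * p, digits)

# SAM flag helpers (bit semantics per the SAM specification)
.flagPaired       <- function(flag) bitwAnd(flag, 0x1L)  != 0L
.flagUnmapped     <- function(flag) bitwAnd(flag, 0x4L)  != 0L
.flagMateUnmapped <- function(flag) bitwAnd(flag, 0x8L)  != 0L
.flagReverse      <- function(flag) bitwAnd(flag, 0x10L) != 0L
.flagMateReverse  <- function(flag) bitwAnd(flag, 0x20L) != 0L
.flagFirstInPair  <- function(flag) bitwAnd(flag, 0x40L) != 0L
.flagSecondary    <- function(flag) bitwAnd(flag, 0x100L) != 0L
.flagDuplicate    <- function(flag) bitwAnd(flag, 0x400L) != 0L
.flagSupplementary <- function(flag) bitwAnd(flag, 0x800L) != 0L

#' Assemble a SAM flag from its components
#'
#' @param paired,unmapped,mateUnmapped,reverse,mateReverse,first,second
#'   logical vectors (recycled).
#' @return integer vector of SAM flags.
#' @keywords internal
samFlag <- function(paired = TRUE, unmapped = FALSE, mateUnmapped = FALSE,
                    reverse = FALSE, mateReverse = FALSE,
                    first = FALSE, second = FALSE) {
    as.integer(0x1L * paired + 0x4L * unmapped + 0x8L * mateUnmapped +
               0x10L * reverse + 0x20L * mateReverse + 0x40L * first +
               0x80L * second)
}
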