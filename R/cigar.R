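# CIGAR arithmetic. Internal coordinates are 0-based half-open throughout;
# conversion to/from 1-based happens only at the SAM/VCF text boundary.

.QUERY_OPS <- c("M", "I", "S", "=", "X")
.REF_OPS   <- c("M", "D", "N", "=", "X")

#' Parse a CIGAR string into its operations
#'
#' @param cigar a single CIGAR string, e.g. \code{"60M40S"}.
#' @return data.frame with columns \code{op} (one-letter code) and
#'   \code{len} (positive integer).
#' @examples
#' parseCigar("40S60M")
#' @export
parseCigar <- function(cigar) {
    if (is.na(cigar) || cigar == "*")
        return(data.frame(op = character(), len = integer()))
    mm <- gregexpr("(\\d+)([MIDNSHP=X])", cigar, perl = TRUE)
    m <- mm[[1]]
    if (m[1L] == -1L || sum(attr(m, "match.length")) != nchar(cigar))
        stop("malformed CIGAR string: ", cigar)
    toks <- regmatches(cigar, mm)[[1]]
    len <- as.integer(sub("[A-Z=]$", "", toks))
    op <- substr(toks, nchar(toks), nchar(toks))
    if (any(len < 1L)) stop("CIGAR op length must be >= 1: ", cigar)
    # clips only at the ends (hard outside soft)
    inner <- op[!op %in% c("S", "H")]
    core <- which(!op %in% c("S", "H"))
    if (length(core) && any(op[seq(min(core), max(core))] %in% c("S", "H")))
        stop("soft/hard clips must be terminal: ", cigar)
    data.frame(op = op, len = len, stringsAsFactors = FALSE)
}

#' @rdname parseCigar
#' @return \code{cigarQueryLength}/\code{cigarRefLength}: number of query
#'   (read) or reference bases consumed. Vectorised over \code{cigar}.
#' @export
cigarQueryLength <- function(cigar) {
    vapply(cigar, function(cg) {
        ops <- parseCigar(cg)
        sum(ops$len[ops$op %in% .QUERY_OPS])
    }, integer(1), USE.NAMES = FALSE)
}

#' @rdname parseCigar
#' @export
cigarRefLength <- function(cigar) {
    vapply(cigar, function(cg) {
        ops <- parseCigar(cg)
        sum(ops$len[ops$op %in% .REF_OPS])
    }, integer(1), USE.NAMES = FALSE)
}

# Fast vectorised reference length without per-op validation; used by
# pileup/clip code paths after readSam has already validated records.
.refLenFast <- function(cigar) {
    out <- integer(length(cigar))
    ok <- !is.na(cigar) & cigar != "*"
    if (any(ok)) {
        mm <- regmatches(cigar[ok], gregexpr("\\d+(?=[MDN=X])", cigar[ok], perl = TRUE))
        out[ok] <- vapply(mm, function(x) sum(as.integer(x)), integer(1))
    }
    out
}

# Terminal soft clip lengths, vectorised: list(left=, right=)
.terminalClips <- function(cigar) {
    left <- rep(0L, length(cigar))
    right <- rep(0L, length(cigar))
    m <- regmatches(cigar, regexec("^(?:\\d+H)?(\\d+)S", cigar))
    has <- lengths(m) == 2L
    left[has] <- as.integer(vapply(m[has], `[`, "", 2L))
    m <- regmatches(cigar, regexec("(\\d+)S(?:\\d+H)?$", cigar))
    has <- lengths(m) == 2L
    right[has] <- as.integer(vapply(m[has], `[`, "", 2L))
    list(left = left, right = right)
}
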