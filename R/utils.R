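# Internal helpers shared across modules.

#' Reverse complement of character k-mers
#'
#' Vectorised reverse complement over plain character vectors (A/C/G/T only).
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @keywords internal
#' @noRd
revcomp <- function(x) {
    comp <- chartr("ACGT", "TGCA", x)
    vapply(strsplit(comp, "", fixed = TRUE),
        function(ch) paste(rev(ch), collapse = ""), character(1))
}

# fast reverse complement for equal-length k-mer vectors (used on 4^k strings)
revcompFixed <- function(x, k) {
    comp <- chartr("ACGT", "TGCA", x)
    m <- matrix(unlist(strsplit(comp, "", fixed = TRUE), use.names = FALSE),
        nrow = k)
    apply(m[k:1, , drop = FALSE], 2, paste, collapse = "")
}

# draw n sub-seeds below 2^31 from a master seed without disturbing the
# caller's RNG stream more than once
subSeeds <- function(seed, n) {
    stopifnot(is.numeric(seed), length(seed) == 1L)
    set.seed(as.integer(seed))
    sample.int(.Machine$integer.max - 1L, n)
}

assertFraction <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
        stop(sprintf("'%s' must be a single number in [0, 1]", name),
            call. = FALSE)
    invisible(x)
}

assertCount <- function(x, name, min = 1L) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
        x != as.integer(x))
        stop(sprintf("'%s' must be an integer >= %d", name, min),
            call. = FALSE)
    invisible(as.integer(x))
}

# encode a DNA string as integer codes A=1 C=2 G=3 T=4, NA otherwise
dnaCodes <- function(seq) {
    v <- utf8ToInt(toupper(seq))
    code <- rep(NA_integer_, length(v))
    code[v == 65L] <- 1L  # A
    code[v == 67L] <- 2L  # C
    code[v == 71L] <- 3L  # G
    code[v == 84L] <- 4L  # T
    code
}

BASES <- c("A", "C", "G", "T")
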